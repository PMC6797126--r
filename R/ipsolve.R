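# Primal-dual interior-point solver for the transcribed NLPs:
#   min f(z)  s.t.  c(z) = 0,  lb <= z <= ub.
# Monotone (Fiacco-McCormick) barrier strategy, Newton directions from the
# sparse primal-dual KKT system (Matrix sparse LU), delta-regularisation in
# lieu of inertia information, fraction-to-boundary rule and a backtracking
# line search on an l1 merit function. The Lagrangian Hessian is either exact
# (forward-over-reverse AD) or a damped limited-memory BFGS approximation in
# compact form (applied through the Woodbury identity).

ip_defaults <- function() {
  list(tol = 1e-6, mu_init = 0.1, max_iter = 500L,
       kappa_eps = 10, kappa_mu = 0.2, theta_mu = 1.5,
       tau_min = 0.99, delta_c = 1e-8, delta_w_min = 1e-12,
       delta_w_init = 1e-4, lbfgs_mem = 6L, s_max = 100,
       verbose = FALSE)
}

#' Solve a transcribed NLP with the interior-point method
#'
#' @param cb callbacks from [nlp_callbacks()] (or any list with the same
#'   fields: `n`, `m`, `f`, `grad`, `con`, `jac`, optional `hess`, `lb`,
#'   `ub`).
#' @param z0 initial point (clamped strictly inside the bounds, with a
#'   warning when clamping moves it).
#' @param hessian `"exact"` (requires `cb$hess`) or `"lbfgs"`.
#' @param control list overriding [solver defaults][ip_defaults]: `tol`
#'   (relative KKT error tolerance), `max_iter`, `mu_init`, verbosity, ...
#' @return List with the solution `z`, multipliers `y`, `zL`, `zU`, `status`
#'   (`"solved"`, `"max_iter"` or `"error"`), iteration count, final KKT
#'   error and objective.
#' @export
ip_solve <- function(cb, z0, hessian = c("exact", "lbfgs"), control = list()) {
  hessian <- match.arg(hessian)
  ct <- utils::modifyList(ip_defaults(), control)
  n <- cb$n; m <- cb$m
  lb <- cb$lb; ub <- cb$ub
  if (any(lb >= ub)) stop("bounds must satisfy lb < ub elementwise")
  if (hessian == "exact" && is.null(cb$hess))
    stop("exact Hessian requested but no Hessian callback available")

  hasL <- is.finite(lb); hasU <- is.finite(ub)
  # push the start strictly inside the bounds
  w <- pmin(ub, 1e10) - pmax(lb, -1e10)
  padL <- pmin(1e-2 * pmax(1, abs(pmax(lb, -1e10))), 0.25 * w)
  padU <- pmin(1e-2 * pmax(1, abs(pmin(ub, 1e10))), 0.25 * w)
  z <- z0
  moved <- (hasL & z < lb + 1e-12) | (hasU & z > ub - 1e-12)
  z <- ifelse(hasL, pmax(z, lb + padL), z)
  z <- ifelse(hasU, pmin(z, ub - padU), z)
  if (any(moved)) warning(sum(moved),
    " initial-guess component(s) clamped inside the bounds")

  mu <- ct$mu_init
  y <- numeric(m)
  dl <- function(v) ifelse(hasL, v - lb, 1)     # distance to lower, safe
  du <- function(v) ifelse(hasU, ub - v, 1)
  zL <- ifelse(hasL, mu / dl(z), 0)
  zU <- ifelse(hasU, mu / du(z), 0)

  fz <- cb$f(z); g <- cb$grad(z); cz <- cb$con(z); J <- cb$jac(z)
  if (!is.finite(fz) || any(!is.finite(cz)))
    stop("non-finite objective or constraints at the initial point",
         if (any(!is.finite(cz))) paste0(" (constraint row ",
                                         which(!is.finite(cz))[1], ")"))
  barrier <- function(zv, fv) {
    fv - mu * sum(log(dl(zv)[hasL])) - mu * sum(log(du(zv)[hasU]))
  }

  # L-BFGS memory
  mem <- list(S = NULL, Q = NULL, sigma = 1)
  bprod <- function(v) {
    if (is.null(mem$S) || ncol(mem$S) == 0) return(mem$sigma * v)
    U <- cbind(mem$sigma * mem$S, mem$Q)
    mem$sigma * v + U %*% (mem$Psi %*% crossprod(U, v))
  }
  update_lbfgs <- function(s, q) {
    sBs <- sum(s * bprod(s))
    sq <- sum(s * q)
    if (sq < 0.2 * sBs) {           # Powell damping
      th <- 0.8 * sBs / (sBs - sq)
      q <- th * q + (1 - th) * as.numeric(bprod(s))
      sq <- sum(s * q)
    }
    if (sq <= 1e-12 * max(1, sum(s^2))) return(invisible(NULL))
    mem$S <<- cbind(mem$S, s); mem$Q <<- cbind(mem$Q, q)
    if (ncol(mem$S) > ct$lbfgs_mem) {
      mem$S <<- mem$S[, -1, drop = FALSE]; mem$Q <<- mem$Q[, -1, drop = FALSE]
    }
    mem$sigma <<- min(1e6, max(1e-6, sum(q * q) / sq))
    SS <- crossprod(mem$S); SQ <- crossprod(mem$S, mem$Q)
    Dm <- diag(diag(SQ), ncol(SQ)); Lm <- SQ - Dm
    Lm[upper.tri(Lm, diag = TRUE)] <- 0
    Mi <- rbind(cbind(mem$sigma * SS, Lm), cbind(t(Lm), -Dm))
    Psi <- tryCatch(-solve(Mi), error = function(e) NULL)
    if (is.null(Psi)) { mem$S <<- NULL; mem$Q <<- NULL; mem$sigma <<- 1 }
    else mem$Psi <<- Psi
    invisible(NULL)
  }

  status <- "max_iter"
  delta_w_last <- 0
  nu <- 1; nu_last <- 1
  filt_hist <- list()                  # (theta, barrier-f) pairs
  n_restore <- 0L

  # feasibility restoration: damped Gauss-Newton steps on 0.5 ||c||^2 inside
  # the bounds, used when the regular step computation or line search fails
  # or the infeasibility stagnates
  restore <- function(z, cz, J, SigL, SigU, tau) {
    improved <- FALSE
    for (rs in 1:8) {
      dr <- 1e-6
      K0 <- rbind(cbind(Matrix::Diagonal(n, x = dr + SigL + SigU),
                        Matrix::t(J)),
                  cbind(J, -Matrix::Diagonal(m)))
      dv <- tryCatch(as.numeric(Matrix::solve(K0, c(numeric(n), -cz),
                                              sparse = FALSE)),
                     error = function(e) NULL)
      if (is.null(dv) || !all(is.finite(dv))) break
      dz <- dv[seq_len(n)]
      amax <- 1
      idx <- which(hasL & dz < 0)
      if (length(idx)) amax <- min(amax, min(-tau * dl(z)[idx] / dz[idx]))
      idx <- which(hasU & dz > 0)
      if (length(idx)) amax <- min(amax, min(tau * du(z)[idx] / dz[idx]))
      cn0 <- sum(abs(cz))
      alpha <- amax
      ok <- FALSE
      for (ls in 1:25) {
        zt <- z + alpha * dz
        ctv <- tryCatch(cb$con(zt), error = function(e) NA_real_)
        if (all(is.finite(ctv)) && sum(abs(ctv)) < (1 - 1e-4 * alpha) * cn0) {
          ok <- TRUE; break
        }
        alpha <- alpha / 2
        if (alpha < 1e-10) break
      }
      if (!ok) break
      z <- zt; cz <- ctv
      improved <- TRUE
      if (max(abs(cz)) <= ct$tol) break
      J <- cb$jac(z)
      SigL <- ifelse(hasL, pmax(mu / dl(z)^2, 1e-8), 0)
      SigU <- ifelse(hasU, pmax(mu / du(z)^2, 1e-8), 0)
    }
    list(z = z, cz = cz, improved = improved)
  }

  c_hist <- rep(Inf, 12)
  iter <- 0L
  Idn <- Matrix::Diagonal(n)
  for (iter in seq_len(ct$max_iter)) {
    SigL <- ifelse(hasL, zL / dl(z), 0)
    SigU <- ifelse(hasU, zU / du(z), 0)
    rd <- g + as.numeric(Matrix::crossprod(J, y)) - zL + zU
    sd <- max(ct$s_max, (sum(abs(y)) + sum(abs(zL)) + sum(abs(zU))) /
                (m + 2 * n)) / ct$s_max
    scb <- max(ct$s_max, (sum(abs(zL)) + sum(abs(zU))) /
                 max(1, sum(hasL) + sum(hasU))) / ct$s_max
    compL <- ifelse(hasL, dl(z) * zL, 0)
    compU <- ifelse(hasU, du(z) * zU, 0)
    E0 <- max(max(abs(rd)) / sd, max(abs(cz)),
              max(abs(compL)) / scb, max(abs(compU)) / scb)
    Emu <- max(max(abs(rd)) / sd, max(abs(cz)),
               max(abs(compL - mu * hasL)) / scb,
               max(abs(compU - mu * hasU)) / scb)
    if (ct$verbose)
      cat(sprintf("it %3d f %.6e |c| %.2e E0 %.2e mu %.1e dw %.1e nu %.1e%s\n",
                  iter, fz, max(abs(cz)), E0, mu, delta_w_last, nu,
                  if (exists("alpha") && is.numeric(alpha))
                    sprintf(" a %.1e", alpha) else ""))
    if (E0 <= ct$tol) { status <- "solved"; break }
    if (Emu <= ct$kappa_eps * mu && mu > ct$tol / 10) {
      mu <- max(ct$tol / 20, min(ct$kappa_mu * mu, mu^ct$theta_mu))
      filt_hist <- list()
      zL <- ifelse(hasL, pmax(pmin(zL, 1e10 * mu / dl(z)),
                              1e-10 * mu / dl(z)), 0)
      zU <- ifelse(hasU, pmax(pmin(zU, 1e10 * mu / du(z)),
                              1e-10 * mu / du(z)), 0)
      next
    }
    tau <- max(ct$tau_min, 1 - mu)

    # barrier gradient rhs
    gbar <- g - ifelse(hasL, mu / dl(z), 0) + ifelse(hasU, mu / du(z), 0)
    rhs <- c(-gbar, -cz)

    W <- if (hessian == "exact") cb$hess(z, 1, y) else NULL
    delta <- if (delta_w_last > 0) max(ct$delta_w_min, delta_w_last / 3)
             else 0
    delta_c <- ct$delta_c * sqrt(mu)   # vanishes with the barrier parameter
    ok <- FALSE
    for (att in 1:30) {
      Sig <- SigL + SigU + delta
      sol <- tryCatch({
        if (hessian == "exact") {
          K <- rbind(cbind(W + Matrix::Diagonal(n, x = Sig), Matrix::t(J)),
                     cbind(J, -delta_c * Matrix::Diagonal(m)))
          dv <- Matrix::solve(K, rhs, sparse = FALSE)
          list(dv = as.numeric(dv))
        } else {
          K0 <- rbind(cbind(Matrix::Diagonal(n, x = mem$sigma + Sig),
                            Matrix::t(J)),
                      cbind(J, -delta_c * Matrix::Diagonal(m)))
          if (is.null(mem$S) || ncol(mem$S) == 0) {
            dv <- Matrix::solve(K0, rhs, sparse = FALSE)
            list(dv = as.numeric(dv))
          } else {
            U <- cbind(mem$sigma * mem$S, mem$Q)
            Ub <- rbind(U, Matrix::Matrix(0, m, ncol(U)))
            x0 <- Matrix::solve(K0, cbind(rhs, as.matrix(Ub)),
                                sparse = FALSE)
            x0 <- as.matrix(x0)
            xr <- x0[, 1]; XU <- x0[, -1, drop = FALSE]
            Cap <- solve(mem$Psi) + crossprod(as.matrix(Ub), XU)
            corr <- XU %*% solve(Cap, crossprod(as.matrix(Ub), xr))
            list(dv = as.numeric(xr - corr))
          }
        }
      }, error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol$dv)) &&
          max(abs(sol$dv[n + seq_len(m)])) > 1e7) {
        # near-dependent constraint rows: lift the dual regularisation
        delta_c <- delta_c * 100
        if (delta_c < 1e-2) next
      }
      if (!is.null(sol) && all(is.finite(sol$dv))) {
        dz <- sol$dv[seq_len(n)]
        ynew <- sol$dv[n + seq_len(m)]
        # l1 penalty weight making the direction a descent direction
        gd <- sum(gbar * dz)
        cn1 <- sum(abs(cz))
        nu_req <- if (cn1 > 1e-12) gd / (0.9 * cn1) else 0
        nu <- max(nu_last, 1, 1.1 * nu_req)
        dphi <- gd - nu * cn1
        if (dphi < -1e-14 || cn1 <= 1e-12 && gd <= 1e-14) {
          ok <- TRUE; break
        }
      }
      delta <- if (delta == 0) max(ct$delta_w_min, ct$delta_w_init)
               else delta * 10
      if (delta > 1e12) break
    }
    c_hist <- c(c_hist[-1], max(abs(cz)))
    stagnant <- is.finite(c_hist[1]) &&
      c_hist[12] > 100 * ct$tol && c_hist[12] > 0.98 * c_hist[1]
    if (!ok || (stagnant && n_restore < 40L)) {
      n_restore <- n_restore + 1L
      if (n_restore > 40L) { status <- "error"; break }
      rr <- restore(z, cz, J, SigL, SigU, tau)
      if (!rr$improved && !ok) { status <- "error"; break }
      if (rr$improved) {
        z <- rr$z; cz <- rr$cz
        fz <- cb$f(z); g <- cb$grad(z); J <- cb$jac(z)
        zL <- ifelse(hasL, pmax(pmin(zL, 1e10 * mu / dl(z)),
                                1e-10 * mu / dl(z)), 0)
        zU <- ifelse(hasU, pmax(pmin(zU, 1e10 * mu / du(z)),
                                1e-10 * mu / du(z)), 0)
        filt_hist <- list()
        c_hist <- rep(Inf, 12)
        delta_w_last <- 0
        if (ct$verbose)
          cat(sprintf("   restoration -> |c| %.2e\n", max(abs(cz))))
        next
      }
    }
    delta_w_last <- delta

    # fraction-to-boundary step lengths
    alpha_max <- 1
    lim_var <- NA_integer_
    if (any(hasL)) {
      idx <- which(hasL & dz < 0)
      if (length(idx)) {
        rat <- -tau * dl(z)[idx] / dz[idx]
        if (min(rat) < alpha_max) {
          alpha_max <- min(rat); lim_var <- idx[which.min(rat)]
        }
      }
    }
    if (any(hasU)) {
      idx <- which(hasU & dz > 0)
      if (length(idx)) {
        rat <- tau * du(z)[idx] / dz[idx]
        if (min(rat) < alpha_max) {
          alpha_max <- min(rat); lim_var <- idx[which.min(rat)]
        }
      }
    }
    if (isTRUE(ct$debug))
      cat(sprintf("   |dz| %.2e |y+| %.2e dc %.0e amax %.2e lim %s\n",
                  max(abs(dz)), max(abs(ynew)), delta_c, alpha_max,
                  ifelse(is.na(lim_var), "-", lim_var)))
    dzL <- ifelse(hasL, mu / dl(z) - zL - SigL * dz, 0)
    dzU <- ifelse(hasU, mu / du(z) - zU + SigU * dz, 0)
    alpha_d <- 1
    idx <- hasL & dzL < 0
    if (any(idx)) alpha_d <- min(alpha_d, min(-tau * zL[idx] / dzL[idx]))
    idx <- hasU & dzU < 0
    if (any(idx)) alpha_d <- min(alpha_d, min(-tau * zU[idx] / dzU[idx]))

    # l1 merit line search
    nu_last <- nu
    phi0 <- barrier(z, fz) + nu * sum(abs(cz))
    alpha <- alpha_max
    accepted <- FALSE
    for (ls in 1:30) {
      zt <- z + alpha * dz
      ft <- tryCatch(cb$f(zt), error = function(e) NA_real_)
      ctv <- if (is.finite(ft))
        tryCatch(cb$con(zt), error = function(e) NA_real_) else NA_real_
      if (all(is.finite(ctv)) && is.finite(ft)) {
        cnt <- sum(abs(ctv))
        cn0 <- sum(abs(cz))
        phit <- barrier(zt, ft) + nu * cnt
        armijo <- phit <= phi0 + 1e-4 * alpha * dphi
        # filter-style acceptance avoids Maratos rejection near the solution:
        # a strict infeasibility decrease, or a barrier decrease while the
        # infeasibility stays comparable, is also acceptable
        fb0 <- barrier(z, fz); fbt <- barrier(zt, ft)
        filt <- (cnt <= (1 - 1e-5) * cn0 && fbt <= fb0 + 1e-5 * cn0) ||
          (fbt <= fb0 - 1e-5 * max(cn0, 1e-12) &&
             cnt <= max(1.5 * cn0, 1e3 * ct$tol))
        if (filt && !armijo && length(filt_hist)) {
          # filter memory: reject points dominated by earlier filter entries
          for (fe in filt_hist) {
            if (cnt >= (1 - 1e-5) * fe[1] && fbt >= fe[2] - 1e-5 * fe[1]) {
              filt <- FALSE; break
            }
          }
        }
        if (armijo || filt ||
            (alpha < 1e-8 && phit <= phi0 + 1e-8 * abs(phi0) + 1e-12)) {
          if (!armijo && filt)
            filt_hist[[length(filt_hist) + 1L]] <- c(cn0, fb0)
          accepted <- TRUE; break
        }
      }
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (!accepted) {
      # try a feasibility-restoration phase; if the problem persists with
      # escalating regularisation, give up
      if (n_restore <= 40L && max(abs(cz)) > ct$tol) {
        n_restore <- n_restore + 1L
        rr <- restore(z, cz, J, SigL, SigU, tau)
        if (rr$improved) {
          z <- rr$z; cz <- rr$cz
          fz <- cb$f(z); g <- cb$grad(z); J <- cb$jac(z)
          filt_hist <- list()
          c_hist <- rep(Inf, 12)
          delta_w_last <- 0
          if (ct$verbose)
            cat(sprintf("   restoration -> |c| %.2e\n", max(abs(cz))))
          next
        }
      }
      if (delta_w_last > 1e10) { status <- "error"; break }
      delta_w_last <- max(ct$delta_w_init, delta_w_last * 100)
      next
    }

    if (hessian == "lbfgs") {
      gL_old <- g + as.numeric(Matrix::crossprod(J, y + alpha_d * (ynew - y)))
    }
    zold <- z
    z <- z + alpha * dz
    y <- y + alpha_d * (ynew - y)
    zL <- pmax(zL + alpha_d * dzL, 0)
    zU <- pmax(zU + alpha_d * dzU, 0)
    # keep the bound multipliers in a box around mu/slack
    zL <- ifelse(hasL, pmax(pmin(zL, 1e10 * mu / dl(z)), 1e-10 * mu / dl(z)),
                 0)
    zU <- ifelse(hasU, pmax(pmin(zU, 1e10 * mu / du(z)), 1e-10 * mu / du(z)),
                 0)
    fz <- ft; cz <- ctv
    g <- cb$grad(z); J <- cb$jac(z)
    if (hessian == "lbfgs") {
      gL_new <- g + as.numeric(Matrix::crossprod(J, y))
      update_lbfgs(z - zold, gL_new - gL_old)
    }
  }

  list(z = z, y = y, zL = zL, zU = zU, status = status,
       iterations = iter, kkt_error = if (exists("E0")) E0 else NA,
       mu = mu, objective = fz, c_norm = max(abs(cz)))
}
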