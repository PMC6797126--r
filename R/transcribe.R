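# Direct-collocation transcription: states at the N+1 mesh points and at the
# N*d collocation points, piecewise-constant controls per mesh interval, the
# free final time (if any) appended as a parameter. Equality rows per
# interval: d collocation equations per state (differentiation-matrix form of
# the stiffly accurate Radau IIA scheme), one continuity row per state
# (identifying the next mesh state with the interval-end collocation state),
# and the equality path constraints imposed once per interval at the
# interval-end collocation state. Inequality path constraints are imposed
# once per interval at the mesh state and converted to equalities with
# bounded slack variables. Everything the solver sees is scaled.

#' Transcribe an optimal control problem into a sparse NLP
#'
#' @param ocp a `tt_ocp`.
#' @param N number of mesh intervals.
#' @param scheme a `tt_radau` (default third order).
#' @param scaling optional `tt_scaling` overriding the problem's own.
#' @return Object of class `tt_nlp`.
#' @export
transcribe <- function(ocp, N, scheme = make_radau(3), scaling = NULL) {
  stopifnot(inherits(ocp, "tt_ocp"), N >= 1)
  sc <- scaling %||% ocp$scaling
  if (any(c(sc$x, sc$u, sc$p) <= 0))
    stop("configuration error: scales must be positive")
  nx <- ocp$nx; nu <- ocp$nu; np <- ocp$np
  d <- scheme$degree; D <- scheme$D; wq <- scheme$w
  npe <- if (is.null(ocp$path_eq)) 0L else length(ocp$path_eq_scale)
  npi <- if (is.null(ocp$ineq_A)) 0L else nrow(ocp$ineq_A)
  nb <- if (is.null(ocp$bnd_A)) 0L else nrow(ocp$bnd_A)

  stride <- nx * (1L + d) + nu + npi
  ntot <- N * stride + nx + np
  rstride <- nx * d + nx + npe + npi
  mtot <- N * rstride + nb

  ix <- function(i) as.integer(if (i < N) i * stride + seq_len(nx) else
    N * stride + seq_len(nx))
  iz <- function(i, k)
    as.integer((i - 1) * stride + nx + (k - 1) * nx + seq_len(nx))
  iu <- function(i) as.integer((i - 1) * stride + nx * (1 + d) + seq_len(nu))
  isl <- function(i)
    as.integer((i - 1) * stride + nx * (1 + d) + nu + seq_len(npi))
  ip <- if (np) as.integer(N * stride + nx + seq_len(np)) else integer(0)

  IX <- vapply(0:N, ix, integer(nx))                      # nx x (N+1)
  IZ <- lapply(seq_len(d), function(k)
    vapply(seq_len(N), function(i) iz(i, k), integer(nx)))  # per k: nx x N
  IU <- if (nu) vapply(seq_len(N), iu, integer(nu)) else
    matrix(integer(0), 0, N)
  IS <- if (npi) vapply(seq_len(N), isl, integer(npi)) else
    matrix(integer(0), 0, N)
  dim(IX) <- c(nx, N + 1L); dim(IU) <- c(nu, N); dim(IS) <- c(npi, N)

  rcol <- function(i, k)
    as.integer((i - 1) * rstride + (k - 1) * nx + seq_len(nx))
  rcont <- function(i) as.integer((i - 1) * rstride + nx * d + seq_len(nx))
  rpe <- function(i)
    as.integer((i - 1) * rstride + nx * d + nx + seq_len(npe))
  rpi <- function(i)
    as.integer((i - 1) * rstride + nx * d + nx + npe + seq_len(npi))
  rb <- as.integer(N * rstride + seq_len(nb))

  RC <- lapply(seq_len(d), function(k)
    vapply(seq_len(N), function(i) rcol(i, k), integer(nx)))
  RCONT <- vapply(seq_len(N), rcont, integer(nx)); dim(RCONT) <- c(nx, N)
  RPE <- if (npe) vapply(seq_len(N), rpe, integer(npe)) else
    matrix(integer(0), 0, N)
  RPI <- if (npi) vapply(seq_len(N), rpi, integer(npi)) else
    matrix(integer(0), 0, N)
  dim(RPE) <- c(npe, N); dim(RPI) <- c(npi, N)

  vscale <- c(sc$x, sc$u, sc$p)       # physical = scaled * vscale, per point
  dyn_As <- ocp$dyn_A * rep(vscale, each = nx)   # acts on scaled variables
  h0 <- if (ocp$free_time) NA_real_ else ocp$horizon / N

  # exogenous data per interval
  tf_nom <- if (ocp$free_time) ocp$nominal$p[1] else ocp$horizon
  E <- if (!is.null(ocp$exog)) ocp$exog(N, tf_nom) else
    matrix(numeric(0), 0, N)
  ne <- nrow(E)

  ## ---- bounds (scaled) ------------------------------------------------------
  lb <- numeric(ntot); ub <- numeric(ntot)
  xlb <- ocp$x_lb / sc$x; xub <- ocp$x_ub / sc$x
  for (i in 0:N) { lb[ix(i)] <- xlb; ub[ix(i)] <- xub }
  for (i in seq_len(N)) for (k in seq_len(d)) {
    lb[iz(i, k)] <- xlb; ub[iz(i, k)] <- xub
  }
  if (nu) for (i in seq_len(N)) {
    lb[iu(i)] <- ocp$u_lb / sc$u; ub[iu(i)] <- ocp$u_ub / sc$u
  }
  if (np) { lb[ip] <- ocp$p_lb / sc$p; ub[ip] <- ocp$p_ub / sc$p }
  if (npi) {
    silb <- ocp$ineq_lb / ocp$ineq_scale
    siub <- ocp$ineq_ub / ocp$ineq_scale
    for (i in seq_len(N)) { lb[isl(i)] <- silb; ub[isl(i)] <- siub }
  }

  ## ---- tapes ----------------------------------------------------------------
  x_nom_s <- ocp$nominal$x / sc$x
  u_nom_s <- if (nu) ocp$nominal$u / sc$u else numeric(0)
  p_nom_s <- if (np) ocp$nominal$p / sc$p else numeric(0)
  e_nom <- if (ne) E[, 1] else numeric(0)

  pe_tape <- NULL
  nzpe <- nx + nu + np                 # decision dims of the path-eq block
  if (npe) {
    pe_tape <- record(function(z) {
      X <- z[seq_len(nx)] * sc$x
      U <- if (nu) z[nx + seq_len(nu)] * sc$u else numeric(0)
      P <- if (np) z[nx + nu + seq_len(np)] * sc$p else numeric(0)
      Ev <- if (ne) z[nx + nu + np + seq_len(ne)] else numeric(0)
      res <- ocp$path_eq(X, U, P, Ev)
      out <- lapply(seq_along(res), function(j)
        res[[j]] * (1 / ocp$path_eq_scale[j]))
      collapse_scalars(out)
    }, c(x_nom_s, u_nom_s, p_nom_s, e_nom))
  }

  nzb <- nx * (1L + d) + nu + np       # decision dims of the objective block
  obj_tape <- record(function(z) {
    xs <- lapply(seq_len(d), function(k)
      z[nx + (k - 1L) * nx + seq_len(nx)] * sc$x)
    U <- if (nu) z[nx * (1L + d) + seq_len(nu)] * sc$u else numeric(0)
    P <- if (np) z[nx * (1L + d) + nu + seq_len(np)] * sc$p else numeric(0)
    Ev <- if (ne) z[nx * (1L + d) + nu + np + seq_len(ne)] else numeric(0)
    h <- if (ocp$free_time) P[1] / N else h0
    o <- 0
    for (k in seq_len(d))
      o <- o + wq[k] * ocp$integrand(xs[[k]], U, P, Ev)
    hh <- h * o
    if (is.numeric(hh)) collapse_scalars(list(hh)) else hh
  }, c(x_nom_s, rep(x_nom_s, d), u_nom_s, p_nom_s, e_nom))

  post_tape <- NULL
  if (!is.null(ocp$obj_post)) {
    S0 <- sum(replay(obj_tape,
      rbind(matrix(rep(c(x_nom_s, rep(x_nom_s, d), u_nom_s, p_nom_s),
                       N), ncol = N), E)))
    xf_nom_s <- (ocp$nominal$xf %||% ocp$nominal$x) / sc$x
    post_tape <- record(function(z) {
      S <- z[1]
      x0 <- z[1 + seq_len(nx)] * sc$x
      xf <- z[1 + nx + seq_len(nx)] * sc$x
      P <- if (np) z[1 + 2 * nx + seq_len(np)] * sc$p else numeric(0)
      ocp$obj_post(S, x0, xf, P)
    }, c(S0, x_nom_s, xf_nom_s, p_nom_s))
  }

  ## ---- constant Jacobian triplets -------------------------------------------
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  addt <- function(i, j, v) {
    ti <<- c(ti, as.integer(i)); tj <<- c(tj, as.integer(j))
    tv <<- c(tv, rep(as.numeric(v), length.out = length(i)))
  }
  # D part of the collocation rows
  for (k in seq_len(d)) {
    addt(RC[[k]], IX[, 1:N], D[k, 1])
    for (c in seq_len(d)) addt(RC[[k]], IZ[[c]], D[k, c + 1L])
  }
  # continuity rows: x_{i} - Z_{i,d}
  addt(RCONT, IX[, 2:(N + 1L)], 1)
  addt(RCONT, IZ[[d]], -1)
  # dynamics part, constant when the horizon is fixed
  dynpat <- which(dyn_As != 0, arr.ind = TRUE)
  colvar_at <- function(k, l) {
    # decision index of block variable l (state/control/param) at point (k, i)
    if (l <= nx) IZ[[k]][l, ]
    else if (l <= nx + nu) IU[l - nx, ]
    else rep(ip[l - nx - nu], N)
  }
  if (!ocp$free_time && nrow(dynpat)) {
    for (k in seq_len(d)) for (r in seq_len(nrow(dynpat))) {
      j <- dynpat[r, 1]; l <- dynpat[r, 2]
      addt(RC[[k]][j, ], colvar_at(k, l),
           -h0 * dyn_As[j, l] / sc$x[j])
    }
  }
  # inequality path rows (mesh state, controls, params) minus slacks
  if (npi) {
    iAs <- ocp$ineq_A * rep(vscale, each = npi)
    ipat <- which(iAs != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(ipat))) {
      j <- ipat[r, 1]; l <- ipat[r, 2]
      cols <- if (l <= nx) IX[l, 1:N]
              else if (l <= nx + nu) IU[l - nx, ]
              else rep(ip[l - nx - nu], N)
      addt(RPI[j, ], cols, iAs[j, l] / ocp$ineq_scale[j])
    }
    addt(RPI, IS, -1)
  }
  # boundary rows over (x0, xN, p)
  if (nb) {
    bsc <- c(sc$x, sc$x, sc$p)
    bAs <- ocp$bnd_A * rep(bsc, each = nb)
    bpat <- which(bAs != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(bpat))) {
      j <- bpat[r, 1]; l <- bpat[r, 2]
      col <- if (l <= nx) IX[l, 1]
             else if (l <= 2 * nx) IX[l - nx, N + 1L]
             else ip[l - 2 * nx]
      addt(rb[j], col, bAs[j, l] / ocp$bnd_scale[j])
    }
  }
  const_trip <- list(i = ti, j = tj, v = tv)

  # variable (per-iteration) triplet positions
  # free-time dynamics part
  ft_pos <- NULL
  if (ocp$free_time && nrow(dynpat)) {
    fi <- integer(0); fj <- integer(0); fk <- integer(0); fr <- integer(0)
    for (k in seq_len(d)) for (r in seq_len(nrow(dynpat))) {
      j <- dynpat[r, 1]; l <- dynpat[r, 2]
      fi <- c(fi, RC[[k]][j, ]); fj <- c(fj, colvar_at(k, l))
      fk <- c(fk, rep(k, N)); fr <- c(fr, rep(r, N))
    }
    ft_pos <- list(i = fi, j = fj, k = fk, r = fr)
  }
  # path-eq tape block positions (dims 1..nzpe of the tape are decision vars)
  pe_pos <- NULL
  if (npe) {
    pecols <- rbind(IZ[[d]], IU,
                    if (np) matrix(rep(ip, N), np, N) else NULL) # nzpe x N
    pj <- integer(0); pi_ <- integer(0)
    for (i in seq_len(N)) {
      pi_ <- c(pi_, rep(RPE[, i], nzpe))
      pj <- c(pj, rep(pecols[, i], each = npe))
    }
    pe_pos <- list(i = pi_, j = pj, cols = pecols)
  }
  # objective block columns (dims 1..nzb of the obj tape are decision vars)
  objcols <- rbind(IX[, 1:N, drop = FALSE],
                   do.call(rbind, IZ), IU,
                   if (np) matrix(rep(ip, N), np, N) else NULL) # nzb x N

  env <- new.env(parent = emptyenv())
  env$neval <- c(f = 0L, grad = 0L, con = 0L, jac = 0L, hess = 0L)
  env$time <- c(f = 0, grad = 0, con = 0, jac = 0, hess = 0)

  nlp <- list(ocp = ocp, N = N, scheme = scheme, sc = sc,
              nx = nx, nu = nu, np = np, d = d,
              npe = npe, npi = npi, nb = nb, ne = ne,
              ntot = ntot, mtot = mtot,
              n_var = nx * (N + 1L) + nx * N * d + nu * N + np,
              n_eq = nx * N * d + nx * N + npe * N + nb,
              n_ineq = npi * N,
              lb = lb, ub = ub,
              IX = IX, IZ = IZ, IU = IU, IS = IS, ip = ip,
              RC = RC, RCONT = RCONT, RPE = RPE, RPI = RPI, rb = rb,
              E = E, dyn_As = dyn_As, h0 = h0,
              pe_tape = pe_tape, obj_tape = obj_tape, post_tape = post_tape,
              nzpe = nzpe, nzb = nzb,
              const_trip = const_trip, ft_pos = ft_pos, pe_pos = pe_pos,
              dynpat = dynpat, objcols = objcols,
              counters = env)
  class(nlp) <- "tt_nlp"
  nlp
}

#' @export
print.tt_nlp <- function(x, ...) {
  cat("<tt_nlp> ", x$n_var, " variables (", x$ntot,
      " including inequality slacks), ",
      x$n_eq, " equality and ", x$n_ineq,
      " inequality constraints; N = ", x$N, ", d = ", x$d, "\n", sep = "")
  invisible(x)
}

## ---- gathering helpers ------------------------------------------------------

nlp_gather_blocks <- function(nlp, z, which = c("pe", "obj")) {
  which <- match.arg(which)
  N <- nlp$N
  if (which == "pe") {
    Zd <- matrix(z[nlp$IZ[[nlp$d]]], nlp$nx, N)
    out <- rbind(Zd,
                 if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) else NULL,
                 if (nlp$np) matrix(rep(z[nlp$ip], N), nlp$np, N) else NULL,
                 if (nlp$ne) nlp$E else NULL)
  } else {
    out <- rbind(matrix(z[nlp$IX[, 1:N, drop = FALSE]], nlp$nx, N),
                 do.call(rbind, lapply(nlp$IZ, function(I)
                   matrix(z[I], nlp$nx, N))),
                 if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) else NULL,
                 if (nlp$np) matrix(rep(z[nlp$ip], N), nlp$np, N) else NULL,
                 if (nlp$ne) nlp$E else NULL)
  }
  out
}

nlp_h <- function(nlp, z) {
  if (nlp$ocp$free_time) z[nlp$ip[1]] * nlp$sc$p[1] / nlp$N else nlp$h0
}

# physical state-derivative values at all collocation points: list over k of
# nx x N matrices (used by the free-time Jacobian/Hessian couplings)
nlp_dyn_values <- function(nlp, z) {
  N <- nlp$N
  U <- if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) else
    matrix(0, 0, N)
  P <- if (nlp$np) matrix(rep(z[nlp$ip], N), nlp$np, N) else
    matrix(0, 0, N)
  lapply(seq_len(nlp$d), function(k) {
    Zk <- matrix(z[nlp$IZ[[k]]], nlp$nx, N)
    nlp$dyn_As %*% rbind(Zk, U, P) + nlp$ocp$dyn_b
  })
}

## ---- callbacks ---------------------------------------------------------------

#' Objective, gradient, constraint, Jacobian and Hessian evaluators
#'
#' Builds the NLP callbacks in either derivative mode. In `"ad"` mode the
#' objective gradient costs a single reverse sweep over the integrand tape
#' (vectorized over mesh intervals) and the constraint Jacobian is assembled
#' blockwise from per-interval tape sweeps; in `"fd"` mode the gradient uses
#' `n + 1` objective evaluations and the nonlinear blocks are forward
#' differenced. The exact Hessian (forward-over-reverse) is available in
#' `"ad"` mode for problems without a global objective post-map.
#'
#' @param nlp a `tt_nlp`.
#' @param mode `"ad"` or `"fd"`.
#' @param fd_h finite-difference step on the scaled variables.
#' @return List of callbacks `f`, `grad`, `con`, `jac`, `hess` (or `NULL`),
#'   plus bounds and dimensions, as consumed by [ip_solve()].
#' @export
nlp_callbacks <- function(nlp, mode = c("ad", "fd"), fd_h = 1e-6) {
  mode <- match.arg(mode)
  N <- nlp$N; nx <- nlp$nx; d <- nlp$d
  env <- nlp$counters

  obj_parts <- function(z) {
    cols <- nlp_gather_blocks(nlp, z, "obj")
    o <- replay(nlp$obj_tape, cols)
    S <- sum(o)
    if (is.null(nlp$post_tape)) list(val = S, S = S) else {
      zp <- c(S, z[nlp$IX[, 1]], z[nlp$IX[, N + 1L]],
              if (nlp$np) z[nlp$ip] else numeric(0))
      list(val = replay(nlp$post_tape, zp), S = S, zp = zp)
    }
  }

  f_fun <- function(z) {
    t0 <- proc.time()[3]
    env$neval["f"] <- env$neval["f"] + 1L
    .bump("fn_evals")
    v <- obj_parts(z)$val
    env$time["f"] <- env$time["f"] + proc.time()[3] - t0
    v
  }

  grad_ad <- function(z) {
    t0 <- proc.time()[3]
    env$neval["grad"] <- env$neval["grad"] + 1L
    cols <- nlp_gather_blocks(nlp, z, "obj")
    V <- tape_eval(nlp$obj_tape, cols)
    P <- tape_partials(nlp$obj_tape, V)
    B <- rev_prop(nlp$obj_tape, P, 1, ncol(cols))   # one reverse sweep
    .bump("reverse_sweeps")
    Bz <- B[, nlp$obj_tape$input_ids[seq_len(nlp$nzb)], drop = FALSE]
    g <- numeric(nlp$ntot)
    acc <- rowsum(as.vector(t(Bz)), group = as.vector(nlp$objcols))
    idx <- as.integer(rownames(acc))
    if (is.null(nlp$post_tape)) {
      g[idx] <- g[idx] + acc
    } else {
      S <- sum(t(V[, nlp$obj_tape$output_ids, drop = FALSE]))
      zp <- c(S, z[nlp$IX[, 1]], z[nlp$IX[, N + 1L]],
              if (nlp$np) z[nlp$ip] else numeric(0))
      Jp <- tape_jacobian(nlp$post_tape, at = zp)    # 1 x (1 + 2 nx + np)
      g[idx] <- g[idx] + Jp[1] * acc
      bidx <- c(nlp$IX[, 1], nlp$IX[, N + 1L],
                if (nlp$np) nlp$ip else integer(0))
      g[bidx] <- g[bidx] + Jp[-1]
    }
    env$time["grad"] <- env$time["grad"] + proc.time()[3] - t0
    g
  }

  grad_fd <- function(z) {
    t0 <- proc.time()[3]
    env$neval["grad"] <- env$neval["grad"] + 1L
    J <- fd_jacobian(function(zz) obj_parts(zz)$val, z, h = fd_h)
    env$time["grad"] <- env$time["grad"] + proc.time()[3] - t0
    as.numeric(J)
  }

  con_fun <- function(z) {
    t0 <- proc.time()[3]
    env$neval["con"] <- env$neval["con"] + 1L
    cvec <- numeric(nlp$mtot)
    h <- nlp_h(nlp, z)
    Fk <- nlp_dyn_values(nlp, z)
    XT <- matrix(z[nlp$IX], nx, N + 1L)
    Ztil <- lapply(nlp$IZ, function(I) matrix(z[I], nx, N))
    Dm <- nlp$scheme$D
    for (k in seq_len(d)) {
      R <- Dm[k, 1] * XT[, 1:N, drop = FALSE]
      for (c in seq_len(d)) R <- R + Dm[k, c + 1L] * Ztil[[c]]
      R <- R - (h / nlp$sc$x) * Fk[[k]]
      cvec[nlp$RC[[k]]] <- R
    }
    cvec[nlp$RCONT] <- XT[, 2:(N + 1L), drop = FALSE] - Ztil[[d]]
    if (nlp$npe) {
      cols <- nlp_gather_blocks(nlp, z, "pe")
      cvec[nlp$RPE] <- replay(nlp$pe_tape, cols)
    }
    if (nlp$npi) {
      iAs <- nlp$ocp$ineq_A * rep(c(nlp$sc$x, nlp$sc$u, nlp$sc$p),
                                  each = nlp$npi)
      U <- if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) else matrix(0, 0, N)
      P <- if (nlp$np) matrix(rep(z[nlp$ip], N), nlp$np, N) else
        matrix(0, 0, N)
      gi <- (iAs %*% rbind(XT[, 1:N, drop = FALSE], U, P) +
               nlp$ocp$ineq_b) / nlp$ocp$ineq_scale
      cvec[nlp$RPI] <- gi - matrix(z[nlp$IS], nlp$npi, N)
    }
    if (nlp$nb) {
      bsc <- c(nlp$sc$x, nlp$sc$x, nlp$sc$p)
      zb <- c(z[nlp$IX[, 1]], z[nlp$IX[, N + 1L]],
              if (nlp$np) z[nlp$ip] else numeric(0))
      cvec[nlp$rb] <- (nlp$ocp$bnd_A %*% (zb * bsc) + nlp$ocp$bnd_b) /
        nlp$ocp$bnd_scale
    }
    env$time["con"] <- env$time["con"] + proc.time()[3] - t0
    cvec
  }

  pe_block_jac <- function(z) {
    cols <- nlp_gather_blocks(nlp, z, "pe")
    if (mode == "ad") {
      Jm <- tape_jacobian_multi(nlp$pe_tape, cols, mode = "reverse")
      Jm[seq_len(nlp$npe * nlp$nzpe), , drop = FALSE]
    } else {
      m <- nlp$npe
      base <- replay(nlp$pe_tape, cols)
      .bump("fn_evals")
      Jm <- matrix(0, m * nlp$nzpe, ncol(cols))
      for (j in seq_len(nlp$nzpe)) {
        colsp <- cols
        colsp[j, ] <- colsp[j, ] + fd_h
        Jm[(j - 1L) * m + seq_len(m), ] <-
          (replay(nlp$pe_tape, colsp) - base) / fd_h
        .bump("fn_evals")
      }
      Jm
    }
  }

  jac_fun <- function(z) {
    t0 <- proc.time()[3]
    env$neval["jac"] <- env$neval["jac"] + 1L
    ti <- nlp$const_trip$i; tj <- nlp$const_trip$j; tv <- nlp$const_trip$v
    if (!is.null(nlp$ft_pos)) {
      h <- nlp_h(nlp, z)
      fp <- nlp$ft_pos
      vals <- -h * nlp$dyn_As[nlp$dynpat[fp$r, , drop = FALSE]] /
        nlp$sc$x[nlp$dynpat[fp$r, 1]]
      ti <- c(ti, fp$i); tj <- c(tj, fp$j); tv <- c(tv, vals)
      # derivative of the collocation rows w.r.t. the free final time
      Fk <- nlp_dyn_values(nlp, z)
      spN <- nlp$sc$p[1] / nlp$N
      for (k in seq_len(d)) {
        ti <- c(ti, as.vector(nlp$RC[[k]]))
        tj <- c(tj, rep(nlp$ip[1], nx * N))
        tv <- c(tv, as.vector(-spN * Fk[[k]] / nlp$sc$x))
      }
    }
    if (nlp$npe) {
      Jm <- pe_block_jac(z)
      ti <- c(ti, nlp$pe_pos$i); tj <- c(tj, nlp$pe_pos$j)
      tv <- c(tv, as.vector(Jm))
    }
    J <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                              dims = c(nlp$mtot, nlp$ntot))
    env$time["jac"] <- env$time["jac"] + proc.time()[3] - t0
    J
  }

  hess_fun <- NULL
  if (mode == "ad") {
    vjp_env <- new.env(parent = emptyenv())
    get_vjp <- function(which) {
      if (is.null(vjp_env[[which]]))
        vjp_env[[which]] <- record_vjp(
          if (which == "obj") nlp$obj_tape else nlp$pe_tape)
      vjp_env[[which]]
    }
    hess_fun <- function(z, sigma, lambda) {
      vjp_obj <- get_vjp("obj")
      vjp_pe <- if (nlp$npe) get_vjp("pe") else NULL
      t0 <- proc.time()[3]
      env$neval["hess"] <- env$neval["hess"] + 1L
      if (!is.null(nlp$post_tape))
        stop("exact Hessian unavailable with a global objective post-map; ",
             "use hessian = 'lbfgs'")
      ti <- integer(0); tj <- integer(0); tv <- numeric(0)
      # objective blocks: seed only dimensions that can yield nonzero columns
      cols <- nlp_gather_blocks(nlp, z, "obj")
      colsw <- rbind(cols, rep(sigma, N))
      dob <- intersect(tape_relevant_inputs(vjp_obj), seq_len(nlp$nzb))
      Hm <- tape_jacobian_multi_fwd(vjp_obj, colsw, dims = dob)
      # rows of Hm: (out dim = nzb + ne + 1 adjoints) x seeds; keep decision
      mvjp <- vjp_obj$m
      keep <- as.vector(outer(seq_len(nlp$nzb), seq_along(dob),
                              function(i, jj) (jj - 1L) * mvjp + i))
      Hm <- Hm[keep, , drop = FALSE]
      ti <- c(ti, as.vector(nlp$objcols[rep(seq_len(nlp$nzb),
                                            times = length(dob)), ]))
      tj <- c(tj, as.vector(nlp$objcols[rep(dob, each = nlp$nzb), ]))
      tv <- c(tv, as.vector(Hm))
      # path-equality blocks
      if (nlp$npe) {
        pcols <- nlp_gather_blocks(nlp, z, "pe")
        lam <- matrix(lambda[nlp$RPE], nlp$npe, N)
        pcolsw <- rbind(pcols, lam)
        dpe <- intersect(tape_relevant_inputs(vjp_pe), seq_len(nlp$nzpe))
        Hp <- tape_jacobian_multi_fwd(vjp_pe, pcolsw, dims = dpe)
        mv <- vjp_pe$m
        keep <- as.vector(outer(seq_len(nlp$nzpe), seq_along(dpe),
                                function(i, jj) (jj - 1L) * mv + i))
        Hp <- Hp[keep, , drop = FALSE]
        ti <- c(ti, as.vector(nlp$pe_pos$cols[rep(seq_len(nlp$nzpe),
                                                  times = length(dpe)), ]))
        tj <- c(tj, as.vector(nlp$pe_pos$cols[rep(dpe, each = nlp$nzpe), ]))
        tv <- c(tv, as.vector(Hp))
      }
      # free-time bilinear coupling of the collocation rows
      if (nlp$ocp$free_time) {
        spN <- nlp$sc$p[1] / nlp$N
        for (k in seq_len(d)) {
          lamk <- matrix(lambda[nlp$RC[[k]]], nx, N)
          # cross term d^2 / (dp dz_l) = -spN * dyn_As[j, l] / sx_j
          W <- t(nlp$dyn_As / nlp$sc$x) %*% lamk * (-spN)  # (nx+nu+np) x N
          for (l in seq_len(nrow(W))) {
            colsl <- if (l <= nx) nlp$IZ[[k]][l, ]
                     else if (l <= nx + nlp$nu) nlp$IU[l - nx, ]
                     else rep(nlp$ip[l - nx - nlp$nu], N)
            ti <- c(ti, colsl, rep(nlp$ip[1], N))
            tj <- c(tj, rep(nlp$ip[1], N), colsl)
            tv <- c(tv, W[l, ], W[l, ])
          }
        }
      }
      H <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                                dims = c(nlp$ntot, nlp$ntot))
      H <- (H + Matrix::t(H)) / 2
      env$time["hess"] <- env$time["hess"] + proc.time()[3] - t0
      H
    }
  }

  list(n = nlp$ntot, m = nlp$mtot,
       f = f_fun,
       grad = if (mode == "ad") grad_ad else grad_fd,
       con = con_fun, jac = jac_fun, hess = hess_fun,
       lb = nlp$lb, ub = nlp$ub, mode = mode, nlp = nlp)
}

## ---- packing / unpacking -----------------------------------------------------

#' Pack physical trajectories into the scaled decision vector
#'
#' @param nlp a `tt_nlp`.
#' @param X physical mesh states, `nx x (N+1)`.
#' @param U physical controls, `nu x N`.
#' @param P physical parameters.
#' @param Z optional physical collocation states (`nx x d x N` array);
#'   interpolated linearly between mesh states when omitted.
#' @return Numeric decision vector (scaled), with inequality slacks set to
#'   their constraint values clamped into bounds.
#' @export
nlp_pack <- function(nlp, X, U = NULL, P = numeric(0), Z = NULL) {
  z <- numeric(nlp$ntot)
  N <- nlp$N; nx <- nlp$nx
  Xs <- X / nlp$sc$x
  z[nlp$IX] <- Xs
  for (k in seq_len(nlp$d)) {
    tau <- nlp$scheme$points[k]
    Zk <- if (is.null(Z)) (1 - tau) * Xs[, 1:N, drop = FALSE] +
      tau * Xs[, 2:(N + 1L), drop = FALSE] else Z[, k, ] / nlp$sc$x
    z[nlp$IZ[[k]]] <- Zk
  }
  if (nlp$nu) z[nlp$IU] <- U / nlp$sc$u
  if (nlp$np) z[nlp$ip] <- P / nlp$sc$p
  if (nlp$npi) {
    iAs <- nlp$ocp$ineq_A * rep(c(nlp$sc$x, nlp$sc$u, nlp$sc$p),
                                each = nlp$npi)
    XT <- matrix(z[nlp$IX], nx, N + 1L)
    Um <- if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) else matrix(0, 0, N)
    Pm <- if (nlp$np) matrix(rep(z[nlp$ip], N), nlp$np, N) else
      matrix(0, 0, N)
    gi <- (iAs %*% rbind(XT[, 1:N, drop = FALSE], Um, Pm) +
             nlp$ocp$ineq_b) / nlp$ocp$ineq_scale
    gi <- pmin(pmax(gi, nlp$ocp$ineq_lb / nlp$ocp$ineq_scale),
               nlp$ocp$ineq_ub / nlp$ocp$ineq_scale)
    z[nlp$IS] <- gi
  }
  pmin(pmax(z, nlp$lb), nlp$ub)
}

#' Unpack a decision vector into physical trajectories
#'
#' @param nlp a `tt_nlp`.
#' @param z scaled decision vector.
#' @return List with mesh times `t`, `X` (`nx x (N+1)`), collocation states
#'   `Z` (`nx x d x N` array) and times `t_c`, controls `U`, parameters `P`.
#' @export
nlp_unpack <- function(nlp, z) {
  N <- nlp$N; nx <- nlp$nx
  P <- if (nlp$np) z[nlp$ip] * nlp$sc$p else numeric(0)
  tf <- if (nlp$ocp$free_time) P[1] else nlp$ocp$horizon
  h <- tf / N
  X <- matrix(z[nlp$IX], nx, N + 1L) * nlp$sc$x
  Z <- array(0, c(nx, nlp$d, N))
  for (k in seq_len(nlp$d))
    Z[, k, ] <- matrix(z[nlp$IZ[[k]]], nx, N) * nlp$sc$x
  U <- if (nlp$nu) matrix(z[nlp$IU], nlp$nu, N) * nlp$sc$u else NULL
  tc <- as.vector(vapply(seq_len(N), function(i)
    (i - 1) * h + h * nlp$scheme$points, numeric(nlp$d)))
  list(t = seq(0, tf, length.out = N + 1L), X = X, Z = Z, t_c = tc,
       U = U, P = P,
       x_names = nlp$ocp$x_names, u_names = nlp$ocp$u_names)
}
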