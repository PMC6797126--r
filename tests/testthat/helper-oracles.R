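# Shared test helpers: random tape generation and complex-step /
# Lagrangian-form oracles independent of the tape sweeps they check.

# random smooth expression recorded on a tape; returns the tape plus a plain
# numeric reference implementation of the same expression
random_tape <- function(n_in = 3, n_ops = 20, seed = 1) {
  set.seed(seed)
  ops_bin <- c("+", "-", "*")
  ops_un <- c("sin", "cos", "tanh", "atan", "exp")
  steps <- list()
  navail <- n_in
  for (k in seq_len(n_ops)) {
    if (stats::runif(1) < 0.5) {
      steps[[k]] <- list(kind = "bin", op = sample(ops_bin, 1),
                         a = sample(navail, 1), b = sample(navail, 1))
    } else {
      steps[[k]] <- list(kind = "un", op = sample(ops_un, 1),
                         a = sample(navail, 1))
    }
    navail <- navail + 1L
  }
  n_out <- sample(1:3, 1)
  out_idx <- sample(navail, n_out)
  buildfn <- function(x) {
    vals <- vector("list", n_in + length(steps))
    for (i in seq_len(n_in)) vals[[i]] <- x[i]
    for (k in seq_along(steps)) {
      s <- steps[[k]]
      vals[[n_in + k]] <- if (s$kind == "bin")
        get(s$op)(vals[[s$a]], vals[[s$b]])
      else get(s$op, mode = "function")(vals[[s$a]] * 0.5)
    }
    out <- vals[[out_idx[1]]]
    for (j in out_idx[-1]) out <- c(out, vals[[j]])
    out
  }
  x0 <- stats::rnorm(n_in)
  list(tape = record(buildfn, x0),
       fn = function(x) { # plain numeric path
         v <- buildfn(x)
         if (inherits(v, "adnum")) stop("numeric path only")
         v
       },
       x0 = x0, n_in = n_in, n_out = n_out)
}

# complex-step derivative of a scalar- or vector-valued numeric function
cstep_jac <- function(fn, x, h = 1e-30) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xc <- x + 0i
    xc[j] <- xc[j] + 1i * h
    J[, j] <- Im(fn(xc)) / h
  }
  J
}

# Lagrangian-form inverse-dynamics oracle from kinetic/potential energy:
#   T = M(q) udv + (d/dq (M v)) v - dKE/dq + dPE/dq,
# with the quadratic-form identity (M w)_k = KE(q, w + e_k) - KE(q, w) -
# KE(q, e_k) and all q-derivatives by complex step (machine precision). The
# Coriolis term (d/dq (M v)) v is a directional derivative along v and needs
# a single complex direction. Independent of planar_id_core.
lagrangian_id_oracle <- function(model, q, v, udv, accel_offset,
                                 h = 1e-30) {
  n <- model$ncoord
  KE <- function(qq, vv)
    tapetraj:::planar_energies(model, qq, vv, accel_offset)$kinetic
  PE <- function(qq)
    tapetraj:::planar_energies(model, qq, rep(0, n), accel_offset)$potential
  Mw <- function(qq, w) {
    kew <- KE(qq, w)
    vapply(seq_len(n), function(k) {
      e <- rep(0, n); e[k] <- 1
      KE(qq, w + e) - kew - KE(qq, e)
    }, if (is.complex(qq)) complex(1) else 0)
  }
  qc <- q + 1i * h * v
  cor_term <- Im(Mw(qc, v)) / h            # (d/dq (M v)) v
  Mu <- Re(Mw(q, udv))
  dKE <- vapply(seq_len(n), function(k) {
    e <- rep(0, n) + 0i; e[k] <- 1i * h
    Im(KE(q + e, v)) / h
  }, 0)
  dPE <- vapply(seq_len(n), function(k) {
    e <- rep(0, n) + 0i; e[k] <- 1i * h
    Im(PE(q + e)) / h
  }, 0)
  Mu + cor_term - dKE + dPE
}

pendulum_id_oracle <- function(chain, t, q, v, udv, h = 1e-30) {
  A <- chain$base_motion(t)
  lagrangian_id_oracle(chain$model, q, v, udv, c(A, chain$gravity), h)
}

# gait skeleton: same oracle plus the contact forces mapped through
# complex-step position Jacobians of the sphere centers
skeleton_id_oracle <- function(gait, q, v, udv, h = 1e-30) {
  n <- gait$ncoord
  Tk <- lagrangian_id_oracle(gait$model, q, v, udv, c(0, gait$gravity), h)
  cf <- gait_contact_forces(gait, q, v)
  spos <- function(qq) {
    pk <- tapetraj:::gait_sphere_kinematics(gait, qq, rep(0, n))
    unlist(lapply(pk, function(p) c(p$x, p$y)))
  }
  Jp <- cstep_jac(spos, q, h)
  for (s in seq_along(cf))
    Tk <- Tk - cf[[s]]$fx * Jp[2 * s - 1, ] - cf[[s]]$fy * Jp[2 * s, ]
  Tk
}

# cached gait fixture (geometry fitting is moderately expensive)
gait_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- planar_gait_skeleton()
      cache <<- list(gait = g, geom = fit_gait_geometry(g))
    }
    cache
  }
})
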