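# Muscle and actuator dynamics: Raasch-style activation-rate inequality
# constraints, the implicit Hill-type contraction residual with the normalized
# tendon force as a state, first-order ideal torque-actuator dynamics, and
# polynomial muscle-tendon geometry with derivative-consistent moment arms.

#' Activation dynamics constants
#'
#' Activation/deactivation time constants of the activation-rate (Raasch)
#' model and the scale of the activation-rate control.
#'
#' @param tau_a activation time constant (s).
#' @param tau_d deactivation time constant (s); must exceed `tau_a`.
#' @param s_da scale of the activation-rate control `u_da`.
#' @return List of class `tt_activation`.
#' @export
activation_constants <- function(tau_a = 0.015, tau_d = 0.060, s_da = 100) {
  stopifnot(tau_a > 0, tau_a < tau_d)
  structure(list(tau_a = tau_a, tau_d = tau_d, s_da = s_da),
            class = "tt_activation")
}

#' Raasch activation-rate residuals
#'
#' The activation rate `da/dt = s_da * u_da` is admissible when both
#' `r_lo = s_da u_da + a / tau_d >= 0` (bounded deactivation) and
#' `r_hi = s_da u_da + a / tau_a - 1 / tau_a <= 0` (bounded activation).
#'
#' @param a activation in `[0, 1]`.
#' @param u_da scaled activation-rate control.
#' @param c a `tt_activation`.
#' @return List with `r_lo` and `r_hi` (taped scalars in, taped out).
#' @export
raasch_bounds <- function(a, u_da, c = activation_constants()) {
  list(r_lo = c$s_da * u_da + a / c$tau_d,
       r_hi = c$s_da * u_da + a / c$tau_a - 1 / c$tau_a)
}

#' Ideal torque-actuator parameters
#' @param tau excitation-to-activation time constant (s).
#' @param scale torque scale (N m): joint torque = activation * scale.
#' @return List of class `tt_torque_actuator`.
#' @export
torque_actuator_params <- function(tau = 0.035, scale = 150) {
  stopifnot(tau > 0, scale > 0)
  structure(list(tau = tau, scale = scale), class = "tt_torque_actuator")
}

#' First-order torque-actuator activation rate
#' @param e excitation in `[-1, 1]`.
#' @param act activation state.
#' @param p a `tt_torque_actuator`.
#' @return `(e - act) / tau`.
#' @export
torque_actuator_rate <- function(e, act, p = torque_actuator_params()) {
  (e - act) / p$tau
}

## ---- Hill-type contraction dynamics (implicit, tendon-force state) ---------

#' Hill-type muscle parameters
#'
#' The contraction-dynamics curve constants default to a widely used
#' twice-differentiable set: exponential tendon force-length, sum-of-Gaussians
#' active force-length, logistic-type force-velocity, exponential passive
#' curve, plus a small fiber damping. All constants are overridable.
#'
#' @param F_max maximal isometric force (N).
#' @param l_M_opt optimal fiber length (m).
#' @param l_T_slack tendon slack length (m).
#' @param v_M_max maximal shortening velocity (optimal fiber lengths per s).
#' @param alpha_opt optimal pennation angle (rad).
#' @param k_T tendon stiffness shape parameter.
#' @param F_t_ub upper bound of the normalized tendon force state.
#' @param tendon_c1,tendon_c2,tendon_c3 tendon force-length constants.
#' @param fl_b 4 x 3 matrix of active force-length Gaussian constants.
#' @param fv_d force-velocity constants (length 4).
#' @param kpe,e0 passive force-length constants.
#' @param damping fiber damping on the normalized fiber velocity.
#' @return List of class `tt_muscle`.
#' @export
muscle_params <- function(F_max, l_M_opt, l_T_slack, v_M_max = 10,
                          alpha_opt = 0, k_T = 35, F_t_ub = 5,
                          tendon_c1 = 0.2, tendon_c2 = 0.995,
                          tendon_c3 = 0.25,
                          fl_b = cbind(
                            c(0.814483478343008, 1.055033428970575,
                              0.162384573599574, 0.063303448465465),
                            c(0.433004984392647, 0.716775413397760,
                              -0.029947116970696, 0.200356847296188),
                            c(0.1, 1.0, 0.353553390593274, 0.0)),
                          fv_d = c(-0.318323436899127, -8.149156043475250,
                                   -0.374121508647863, 0.885644059915004),
                          kpe = 4, e0 = 0.6, damping = 0.1) {
  stopifnot(F_max > 0, l_M_opt > 0, l_T_slack > 0, v_M_max > 0,
            alpha_opt >= 0, alpha_opt < pi / 2, F_t_ub > 0)
  structure(list(F_max = F_max, l_M_opt = l_M_opt, l_T_slack = l_T_slack,
                 v_M_max = v_M_max, alpha_opt = alpha_opt, k_T = k_T,
                 F_t_ub = F_t_ub, tendon_c1 = tendon_c1,
                 tendon_c2 = tendon_c2, tendon_c3 = tendon_c3,
                 fl_b = fl_b, fv_d = fv_d, kpe = kpe, e0 = e0,
                 damping = damping), class = "tt_muscle")
}

#' Muscle characteristic curves
#'
#' Normalized active force-length, force-velocity, passive force-length and
#' tendon force-length curves, all twice continuously differentiable.
#'
#' @param p a `tt_muscle`.
#' @param lm_tilde normalized fiber length.
#' @param vm_tilde normalized fiber velocity (fraction of `v_M_max`).
#' @param lt_tilde normalized tendon length.
#' @name muscle_curves
NULL

#' @rdname muscle_curves
#' @export
force_length_active <- function(lm_tilde, p) {
  b <- p$fl_b
  f <- 0
  for (j in 1:3) {
    den <- b[3, j] + b[4, j] * lm_tilde
    z <- (lm_tilde - b[2, j]) / den
    f <- f + b[1, j] * exp(-0.5 * z^2)
  }
  f
}

#' @rdname muscle_curves
#' @export
force_velocity <- function(vm_tilde, p) {
  d <- p$fv_d
  z <- d[2] * vm_tilde + d[3]
  d[1] * log(z + sqrt(z^2 + 1)) + d[4]
}

#' @rdname muscle_curves
#' @export
force_length_passive <- function(lm_tilde, p) {
  (exp(p$kpe * (lm_tilde - 1) / p$e0) - 1) / (exp(p$kpe) - 1)
}

#' @rdname muscle_curves
#' @export
tendon_force_length <- function(lt_tilde, p) {
  p$tendon_c1 * exp(p$k_T * (lt_tilde - p$tendon_c2)) - p$tendon_c3
}

# inverse of the tendon force-length curve: normalized tendon length at a
# given normalized tendon force
tendon_length_from_force <- function(ft, p) {
  p$tendon_c2 + log((ft + p$tendon_c3) / p$tendon_c1) / p$k_T
}

#' Implicit Hill-type contraction residual
#'
#' The normalized tendon force `F_t` is a state and its scaled rate `u_dFt`
#' a control (`dF_t/dt = s_dFt * u_dFt`). Fiber kinematics are recovered from
#' the invertible tendon curve and a constant-thickness pennation model; the
#' residual is the normalized fiber-force projection minus the tendon force,
#'
#' `r = a f_act(lM~) f_v(vM~) + f_pas(lM~) + beta vM~ - F_t / cos(alpha)`,
#'
#' which vanishes exactly at fiber-tendon force equilibrium and is twice
#' continuously differentiable in all arguments.
#'
#' @param a activation in `[0, 1]`.
#' @param l_MT muscle-tendon length (m).
#' @param v_MT muscle-tendon lengthening velocity (m/s).
#' @param F_t normalized tendon force state (tendon force / `F_max`).
#' @param u_dFt scaled tendon-force-rate control.
#' @param p a `tt_muscle`.
#' @param s_dFt scale of `u_dFt` (1/s).
#' @return Scalar residual (taped scalars in, taped out).
#' @export
hill_residual <- function(a, l_MT, v_MT, F_t, u_dFt, p, s_dFt = 100) {
  lt_tilde <- tendon_length_from_force(F_t, p)
  lt <- lt_tilde * p$l_T_slack
  w <- p$l_M_opt * sin(p$alpha_opt)
  proj <- l_MT - lt                     # fiber length along the tendon line
  if (is.numeric(proj) && any(Re(proj) <= 0))
    stop("pennation geometry impossible: fiber projection non-positive")
  lm <- sqrt(proj^2 + w^2)
  lm_tilde <- lm / p$l_M_opt
  cos_a <- proj / lm
  # tendon velocity from the force-rate state, via the tendon curve slope
  vt <- s_dFt * u_dFt * p$l_T_slack / (p$k_T * (F_t + p$tendon_c3))
  vm <- (v_MT - vt) * cos_a
  vm_tilde <- vm / (p$v_M_max * p$l_M_opt)
  a * force_length_active(lm_tilde, p) * force_velocity(vm_tilde, p) +
    force_length_passive(lm_tilde, p) + p$damping * vm_tilde -
    F_t / cos_a
}

## ---- polynomial muscle-tendon geometry -------------------------------------

# exponent tuples with total degree <= order in nv variables
monomial_exponents <- function(nv, order) {
  grid <- do.call(expand.grid, rep(list(0:order), nv))
  grid <- as.matrix(grid[rowSums(grid) <= order, , drop = FALSE])
  dimnames(grid) <- NULL
  grid[order(rowSums(grid)), , drop = FALSE]
}

poly_design <- function(Q, expts) {
  A <- matrix(1, nrow(Q), nrow(expts))
  for (v in seq_len(ncol(Q))) {
    e <- expts[, v]
    nz <- which(e > 0)
    if (length(nz)) A[, nz] <- A[, nz, drop = FALSE] *
        outer(Q[, v], e[nz], `^`)
  }
  A
}

# derivative of the design matrix w.r.t. variable v
poly_design_deriv <- function(Q, expts, v) {
  e <- expts[, v]
  D <- matrix(0, nrow(Q), nrow(expts))
  nz <- which(e > 0)
  if (!length(nz)) return(D)
  em <- expts[nz, , drop = FALSE]
  em[, v] <- em[, v] - 1L
  D[, nz] <- poly_design(Q, em) * rep(e[nz], each = nrow(Q))
  D
}

#' Fit polynomial muscle-tendon geometry
#'
#' Least-squares fit of a multivariate polynomial `l_MT(q)` per muscle,
#' jointly penalizing the muscle-tendon-length mismatch and the moment-arm
#' mismatch (moment arm = `-d l_MT / d q_k`). The lowest total order whose
#' length RMS deviation meets `rms_tol` is selected, capped at `max_order`.
#'
#' @param samples list, one entry per muscle:
#'   `list(name, coords, Q, lmt, ma)` with `Q` an n x k matrix of spanned
#'   joint angles (rad), `lmt` length samples (m) and `ma` an n x k matrix of
#'   moment arms (m).
#' @param max_order maximal total polynomial order (<= 9).
#' @param rms_tol maximal admissible RMS length deviation (m; default 3 mm).
#' @param ma_weight relative weight of the moment-arm rows in the fit.
#' @return Object of class `tt_polygeom`: per muscle the exponent tuples,
#'   coefficients, selected order and RMS deviations (length and moment arm).
#' @export
fit_polynomials <- function(samples, max_order = 9, rms_tol = 0.003,
                            ma_weight = 2) {
  stopifnot(max_order >= 1, max_order <= 9)
  fits <- lapply(samples, function(s) {
    Q <- as.matrix(s$Q)
    k <- ncol(Q)
    for (ord in seq_len(max_order)) {
      expts <- monomial_exponents(k, ord)
      if (nrow(Q) < 10 * nrow(expts))
        stop("need at least 10x more samples than coefficients for muscle ",
             s$name, " at order ", ord)
      A <- poly_design(Q, expts)
      rows <- A; rhs <- s$lmt
      for (v in seq_len(k)) {
        Dv <- poly_design_deriv(Q, expts, v)
        rows <- rbind(rows, -ma_weight * Dv)
        rhs <- c(rhs, ma_weight * s$ma[, v])
      }
      cf <- qr.coef(qr(rows), rhs)
      cf[is.na(cf)] <- 0
      rms_len <- sqrt(mean((A %*% cf - s$lmt)^2))
      rms_ma <- vapply(seq_len(k), function(v)
        sqrt(mean((-poly_design_deriv(Q, expts, v) %*% cf - s$ma[, v])^2)), 0)
      ok <- rms_len <= rms_tol && max(rms_ma) <= rms_tol
      if (ok || ord == max_order) {
        if (rms_len > rms_tol)
          stop("polynomial fit failure: muscle ", s$name, " has RMS ",
               signif(rms_len * 1000, 4), " mm at order ", max_order)
        return(list(name = s$name, coords = s$coords, expts = expts,
                    coef = as.numeric(cf), order = ord,
                    rms_len = rms_len, rms_ma = rms_ma))
      }
    }
  })
  names(fits) <- vapply(fits, `[[`, "", "name")
  structure(list(muscles = fits), class = "tt_polygeom")
}

#' @export
print.tt_polygeom <- function(x, ...) {
  cat("<tt_polygeom>", length(x$muscles), "muscles; orders:",
      paste(vapply(x$muscles, `[[`, 0L, "order"), collapse = " "),
      "\n  max RMS length dev:",
      signif(1000 * max(vapply(x$muscles, `[[`, 0, "rms_len")), 4), "mm\n")
  invisible(x)
}

# polymorphic monomial-polynomial evaluation for one muscle at scalar inputs
# qsub: list of spanned coordinate scalars. Returns the scalar value.
poly_eval_scalar <- function(expts, coef, qsub) {
  val <- 0
  for (t in seq_len(nrow(expts))) {
    term <- coef[t]
    for (v in seq_len(ncol(expts))) {
      e <- expts[t, v]
      if (e == 1) term <- term * qsub[[v]]
      else if (e > 1) term <- term * qsub[[v]]^e
    }
    val <- zadd(val, term)
  }
  val
}

# coefficients of the derivative polynomial w.r.t. spanned variable v
poly_deriv_coef <- function(expts, coef, v) {
  e <- expts[, v]
  keep <- e > 0
  em <- expts[keep, , drop = FALSE]
  em[, v] <- em[, v] - 1L
  list(expts = em, coef = coef[keep] * e[keep])
}

# per-muscle evaluation usable on the tape: returns list(lmt, vmt, ma=list)
muscle_geom_eval <- function(fit, qsub, vsub) {
  k <- length(fit$coords)
  lmt <- poly_eval_scalar(fit$expts, fit$coef, qsub)
  ma <- vector("list", k)
  vmt <- 0
  for (v in seq_len(k)) {
    dv <- poly_deriv_coef(fit$expts, fit$coef, v)
    dl <- poly_eval_scalar(dv$expts, dv$coef, qsub)
    ma[[v]] <- -dl
    vmt <- zadd(vmt, zmul(dl, vsub[[v]]))
  }
  list(lmt = lmt, vmt = vmt, ma = ma)
}

#' Evaluate fitted muscle-tendon geometry
#'
#' Muscle-tendon lengths, lengthening velocities and moment arms from the
#' fitted polynomials: `v_MT = sum_k (d l_MT / d q_k) v_k` and moment arm
#' `MA_k = -d l_MT / d q_k` (derivatives of the fitted polynomial, identical
#' to an AD sweep over the polynomial tape).
#'
#' @param geom a `tt_polygeom`.
#' @param q full coordinate vector (rad); each muscle picks its spanned
#'   coordinates by index.
#' @param v coordinate velocities.
#' @param warn_range optional k x 2 matrix of fitted ranges; values outside
#'   trigger a warning.
#' @return List with `lmt` (named vector), `vmt` (named vector) and `ma`
#'   (list of per-muscle moment-arm vectors over their spanned coordinates).
#' @export
eval_lmt_vmt_ma <- function(geom, q, v, warn_range = NULL) {
  out_l <- numeric(0); out_v <- numeric(0); out_ma <- list()
  for (fit in geom$muscles) {
    qs <- as.list(q[fit$coords]); vs <- as.list(v[fit$coords])
    if (!is.null(warn_range)) {
      qq <- unlist(qs)
      if (any(qq < warn_range[fit$coords, 1] - 1e-9) ||
          any(qq > warn_range[fit$coords, 2] + 1e-9))
        warning("coordinates outside fitted range for muscle ", fit$name)
    }
    ev <- muscle_geom_eval(fit, qs, vs)
    out_l[fit$name] <- ev$lmt
    out_v[fit$name] <- if (identical(ev$vmt, 0)) 0 else ev$vmt
    out_ma[[fit$name]] <- unlist(lapply(ev$ma, function(z)
      if (identical(z, 0)) 0 else z))
  }
  list(lmt = out_l, vmt = out_v, ma = out_ma)
}
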