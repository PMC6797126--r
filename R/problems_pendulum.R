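# Perturbed-balance pendulum problems: an ndof inverted pendulum chain on a
# base that accelerates backward must return to (and stop at) the upright
# configuration within one second, minimizing squared scaled joint torques
# plus a small acceleration penalty to avoid singular arcs. Implicit
# formulation: accelerations u_dv are controls, joint torques u_T are
# controls, and the skeleton dynamics enter as the algebraic path constraint
# T(q, v, u_dv) = u_T imposed once per mesh interval.

default_pendulum_mesh <- function(ndof) {
  if (ndof <= 6) 25L else if (ndof <= 9) 50L else 100L
}

#' Build the perturbed-balance pendulum optimal control problem
#'
#' States `q` (rad) and `v` (rad/s), controls `u_dv` (rad/s^2) and `u_T`
#' (N m). Bounds `|q| <= 3 pi`, `|v| <= 20`, `|u_dv| <= 500`,
#' `|u_T| <= 1000`; scales `s_q = 3`, `s_t = 0.2` (so velocities scale by
#' `s_q / s_t` and accelerations by `s_q / s_t^2`) and `s_T = 500`. Objective
#' integrand: squared scaled torques plus `0.1` times squared scaled
#' accelerations. Zero boundary conditions at both ends; horizon 1 s.
#'
#' @param ndof degrees of freedom (2-10).
#' @param chain optional `tt_pendulum` overriding the default chain.
#' @param peak,duration base-acceleration pulse parameters (m/s^2, s),
#'   forwarded to [base_pulse()] when `chain` is not given.
#' @param horizon task horizon (s).
#' @return A `tt_ocp`; the chain is attached as attribute `"chain"`.
#' @export
build_pendulum <- function(ndof, chain = NULL, peak = 2, duration = 0.2,
                           horizon = 1) {
  stopifnot(ndof >= 2, ndof <= 10)
  if (is.null(chain))
    chain <- pendulum_chain(ndof, base_motion = base_pulse(peak, duration))
  n <- ndof
  nx <- 2L * n; nu <- 2L * n
  s_q <- 3; s_t <- 0.2; s_T <- 500
  sx <- c(rep(s_q, n), rep(s_q / s_t, n))
  su <- c(rep(s_q / s_t^2, n), rep(s_T, n))
  dyn_A <- matrix(0, nx, nx + nu)
  dyn_A[seq_len(n), n + seq_len(n)] <- diag(n)          # dq/dt = v
  dyn_A[n + seq_len(n), nx + seq_len(n)] <- diag(n)     # dv/dt = u_dv
  integrand <- function(x, u, p, e) {
    uT <- u[n + seq_len(n)] / s_T
    udv <- u[seq_len(n)] / (s_q / s_t^2)
    sum(uT^2) + 0.1 * sum(udv^2)
  }
  path_eq <- function(x, u, p, e) {
    q <- x[seq_len(n)]; v <- x[n + seq_len(n)]
    udv <- u[seq_len(n)]; uT <- u[n + seq_len(n)]
    tl <- planar_id_core(chain$model, q, v, udv,
                         accel_offset = c(e[1], chain$gravity))
    lapply(seq_len(n), function(j) tl[[j]] - uT[j])
  }
  bnd_A <- matrix(0, 2L * nx, 2L * nx)
  bnd_A[seq_len(nx), seq_len(nx)] <- diag(nx)            # x(0) = 0
  bnd_A[nx + seq_len(nx), nx + seq_len(nx)] <- diag(nx)  # x(tf) = 0
  ocp <- optimal_control_problem(
    nx = nx, nu = nu, np = 0L,
    x_names = c(paste0("q", seq_len(n)), paste0("v", seq_len(n))),
    u_names = c(paste0("udv", seq_len(n)), paste0("uT", seq_len(n))),
    x_lb = c(rep(-3 * pi, n), rep(-20, n)),
    x_ub = c(rep(3 * pi, n), rep(20, n)),
    u_lb = c(rep(-500, n), rep(-1000, n)),
    u_ub = c(rep(500, n), rep(1000, n)),
    scaling = scaling_set(sx, su),
    horizon = horizon,
    dyn_A = dyn_A,
    integrand = integrand,
    path_eq = path_eq,
    path_eq_scale = rep(s_T, n),
    bnd_A = bnd_A, bnd_b = rep(0, 2L * nx),
    bnd_scale = c(sx, sx),
    exog = function(N, tf) matrix(chain$base_motion(seq_len(N) * tf / N),
                                  1, N),
    nominal = list(x = c(rep(0.1, n), rep(0, n)), u = rep(0, nu),
                   p = numeric(0)))
  attr(ocp, "chain") <- chain
  attr(ocp, "canonical_guess") <- function(nlp) {
    nlp_pack(nlp, X = matrix(0, nx, nlp$N + 1L),
             U = matrix(0, nu, nlp$N))
  }
  attr(ocp, "problem_id") <- paste0("pendulum", ndof)
  ocp
}

#' Solve a perturbed-balance pendulum problem
#'
#' Builds, transcribes and solves the `ndof` pendulum balance problem with
#' the default mesh for its size (25 intervals up to 6 dof, 50 up to 9, 100
#' for 10).
#'
#' @param ndof degrees of freedom (2-10).
#' @param N mesh intervals (default by `ndof`).
#' @param derivative `"ad"` or `"fd"`.
#' @param hessian `"exact"` or `"lbfgs"`.
#' @param guess initial decision vector (default: the canonical zero guess).
#' @param ... passed to [solve_ocp()] (e.g. `tol`, `max_iter`, `verbose`,
#'   `peak`).
#' @param peak,duration perturbation pulse parameters.
#' @return A `tt_solution`.
#' @export
pendulum_balance <- function(ndof, N = NULL, derivative = "ad",
                             hessian = "exact", guess = NULL,
                             peak = 2, duration = 0.2, ...) {
  ocp <- build_pendulum(ndof, peak = peak, duration = duration)
  if (is.null(N)) N <- default_pendulum_mesh(ndof)
  solve_ocp(ocp, N, derivative = derivative, hessian = hessian,
            guess = guess, ...)
}
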