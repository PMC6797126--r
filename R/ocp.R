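# Optimal control problem container. The problem is posed in the implicit
# formulation: state derivatives are controls and the dynamic constraints
# x' = f(x, u, p) entering the collocation equations are affine in (x, u, p)
# (the nonlinear dynamics residuals are algebraic path constraints). This is
# what makes the transcription's collocation block linear and puts all
# nonlinearity into the taped path-equality block.

#' Per-variable scaling set
#'
#' Maps physical variables to the scaled variables the NLP optimizes:
#' `scaled = physical / scale`. Scales must be nonzero; applying then
#' inverting is the identity to machine precision.
#'
#' @param x_scale,u_scale,p_scale numeric vectors of scale factors.
#' @return List of class `tt_scaling`.
#' @export
scaling_set <- function(x_scale, u_scale, p_scale = numeric(0)) {
  stopifnot(all(x_scale != 0), all(u_scale != 0), all(p_scale != 0))
  structure(list(x = x_scale, u = u_scale, p = p_scale),
            class = "tt_scaling")
}

#' Scale / unscale variables
#' @param scaling a `tt_scaling`.
#' @param x,u,p physical (for [ocp_scale()]) or scaled (for [ocp_unscale()])
#'   variables.
#' @return List with scaled (resp. physical) `x`, `u`, `p`.
#' @export
ocp_scale <- function(scaling, x, u = numeric(0), p = numeric(0)) {
  list(x = x / scaling$x, u = if (length(u)) u / scaling$u else u,
       p = if (length(p)) p / scaling$p else p)
}

#' @rdname ocp_scale
#' @export
ocp_unscale <- function(scaling, x, u = numeric(0), p = numeric(0)) {
  list(x = x * scaling$x, u = if (length(u)) u * scaling$u else u,
       p = if (length(p)) p * scaling$p else p)
}

#' Define an optimal control problem (implicit formulation)
#'
#' @param nx,nu,np dimensions of states, controls and time-independent
#'   parameters (at most one parameter, the free final time, is currently
#'   meaningful).
#' @param x_names,u_names,p_names variable names.
#' @param x_lb,x_ub,u_lb,u_ub,p_lb,p_ub bounds in physical units.
#' @param scaling a `tt_scaling`.
#' @param horizon fixed final time (numeric), or the string `"free"` when the
#'   final time is the (single) parameter; the mesh width is then `p / N`.
#' @param dyn_A,dyn_b affine dynamics `xdot = dyn_A %*% c(x, u, p) + dyn_b`
#'   in physical units.
#' @param integrand function `L(x, u, p, e)` (physical arguments, taped
#'   scalars in/out); integrated with Radau quadrature.
#' @param obj_post optional function `(S, x0, xf, p)` mapping the integral
#'   `S` and the boundary states to the objective (e.g. distance
#'   normalisation); identity when `NULL`. Exact Hessians require `NULL`.
#' @param path_eq optional function `(x, u, p, e)` returning a list of
#'   equality residuals (physical), imposed once per mesh interval at the
#'   interval-end collocation state; `path_eq_scale` divides each row.
#' @param path_eq_scale row scales of the equality path constraints.
#' @param ineq_A,ineq_b,ineq_lb,ineq_ub affine inequality path constraints
#'   `ineq_lb <= ineq_A %*% c(x, u, p) + ineq_b <= ineq_ub` imposed once per
#'   mesh interval at the mesh state; `ineq_scale` divides each row.
#' @param ineq_scale row scales of the inequality path constraints.
#' @param bnd_A,bnd_b affine boundary rows
#'   `bnd_A %*% c(x0, xf, p) + bnd_b = 0` (physical); `bnd_scale` divides
#'   each row.
#' @param bnd_scale row scales of the boundary constraints.
#' @param exog function `(N, tf)` returning an `ne x N` matrix of exogenous
#'   per-interval data (e.g. the prescribed base acceleration at the
#'   interval-end times), or `NULL`.
#' @param nominal list with physical `x`, `u`, `p` used as the tape recording
#'   point (must be free of singularities).
#' @return Object of class `tt_ocp`.
#' @export
optimal_control_problem <- function(nx, nu, np = 0L,
                                    x_names = NULL, u_names = NULL,
                                    p_names = NULL,
                                    x_lb, x_ub, u_lb, u_ub,
                                    p_lb = numeric(0), p_ub = numeric(0),
                                    scaling,
                                    horizon,
                                    dyn_A, dyn_b = rep(0, nx),
                                    integrand,
                                    obj_post = NULL,
                                    path_eq = NULL,
                                    path_eq_scale = numeric(0),
                                    ineq_A = NULL, ineq_b = numeric(0),
                                    ineq_lb = numeric(0),
                                    ineq_ub = numeric(0),
                                    ineq_scale = numeric(0),
                                    bnd_A = NULL, bnd_b = numeric(0),
                                    bnd_scale = numeric(0),
                                    exog = NULL,
                                    nominal) {
  stopifnot(length(x_lb) == nx, length(x_ub) == nx,
            length(u_lb) == nu, length(u_ub) == nu,
            all(x_lb <= x_ub), all(u_lb <= u_ub))
  if (length(p_lb)) stopifnot(all(p_lb <= p_ub))
  free_time <- identical(horizon, "free")
  if (free_time && np < 1L)
    stop("free final time requires a parameter")
  stopifnot(nrow(dyn_A) == nx, ncol(dyn_A) == nx + nu + np)
  if (!is.null(ineq_A))
    stopifnot(ncol(ineq_A) == nx + nu + np,
              all(ineq_lb <= ineq_ub))
  structure(list(nx = nx, nu = nu, np = np,
                 x_names = x_names %||% paste0("x", seq_len(nx)),
                 u_names = u_names %||% paste0("u", seq_len(nu)),
                 p_names = p_names %||%
                   (if (np) paste0("p", seq_len(np)) else character(0)),
                 x_lb = x_lb, x_ub = x_ub, u_lb = u_lb, u_ub = u_ub,
                 p_lb = p_lb, p_ub = p_ub,
                 scaling = scaling, horizon = horizon,
                 free_time = free_time,
                 dyn_A = dyn_A, dyn_b = dyn_b,
                 integrand = integrand, obj_post = obj_post,
                 path_eq = path_eq, path_eq_scale = path_eq_scale,
                 ineq_A = ineq_A, ineq_b = ineq_b,
                 ineq_lb = ineq_lb, ineq_ub = ineq_ub,
                 ineq_scale = ineq_scale,
                 bnd_A = bnd_A, bnd_b = bnd_b, bnd_scale = bnd_scale,
                 exog = exog, nominal = nominal),
            class = "tt_ocp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tt_ocp <- function(x, ...) {
  cat("<tt_ocp>", x$nx, "states,", x$nu, "controls,", x$np, "parameters;",
      if (x$free_time) "free" else paste0("fixed (", x$horizon, " s)"),
      "horizon\n")
  invisible(x)
}
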