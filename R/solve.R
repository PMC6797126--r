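# High-level solve interface returning a classed solution object with the
# usual methods (print, summary, plot, residuals, coef).

#' Transcribe and solve an optimal control problem
#'
#' @param ocp a `tt_ocp` (typically from [build_pendulum()] or
#'   [build_gait2d()]).
#' @param N mesh intervals.
#' @param scheme a `tt_radau` (default third order).
#' @param derivative `"ad"` (tape sweeps) or `"fd"` (finite differences).
#' @param hessian `"exact"` (forward-over-reverse) or `"lbfgs"`
#'   (limited-memory quasi-Newton). `"fd"` derivatives force `"lbfgs"`.
#' @param guess initial decision vector (scaled), or `NULL` for the problem's
#'   canonical guess.
#' @param tol NLP relative error tolerance.
#' @param max_iter iteration cap.
#' @param verbose print iteration log.
#' @param control extra solver control entries (see [ip_solve()]).
#' @return Object of class `tt_solution`.
#' @export
solve_ocp <- function(ocp, N, scheme = make_radau(3),
                      derivative = c("ad", "fd"),
                      hessian = c("exact", "lbfgs"),
                      guess = NULL, tol = 1e-6, max_iter = 500L,
                      verbose = FALSE, control = list()) {
  derivative <- match.arg(derivative)
  hessian <- match.arg(hessian)
  if (derivative == "fd") hessian <- "lbfgs"
  if (!is.null(ocp$obj_post) && hessian == "exact") hessian <- "lbfgs"
  nlp <- transcribe(ocp, N, scheme)
  cb <- nlp_callbacks(nlp, mode = derivative)
  z0 <- guess %||% attr(ocp, "canonical_guess")(nlp)
  ctl <- utils::modifyList(list(tol = tol, max_iter = max_iter,
                                verbose = verbose), control)
  t0 <- proc.time()[3]
  res <- ip_solve(cb, z0, hessian = hessian, control = ctl)
  wall <- proc.time()[3] - t0
  traj <- nlp_unpack(nlp, res$z)
  sol <- list(ocp = ocp, nlp = nlp, result = res, trajectories = traj,
              objective = res$objective, status = res$status,
              iterations = res$iterations, wall_time = wall,
              derivative = derivative, hessian = hessian,
              evals = nlp$counters$neval, times = nlp$counters$time,
              problem_id = attr(ocp, "problem_id") %||% "ocp")
  class(sol) <- "tt_solution"
  sol
}

#' @export
print.tt_solution <- function(x, ...) {
  cat("<tt_solution> ", x$problem_id, ": ", x$status,
      " in ", x$iterations, " iterations (",
      sprintf("%.2f", x$wall_time), " s, ", x$derivative, "/",
      x$hessian, ")\n  objective ", format(x$objective, digits = 8),
      ", max |c| ", format(x$result$c_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tt_solution <- function(object, ...) {
  traj <- object$trajectories
  cat("Problem:       ", object$problem_id, "\n")
  cat("Status:        ", object$status, " (", object$iterations,
      " iterations, ", sprintf("%.2f s", object$wall_time), ")\n", sep = "")
  cat("Objective:     ", format(object$objective, digits = 8), "\n")
  cat("KKT error:     ", format(object$result$kkt_error, digits = 3), "\n")
  cat("Max |c|:       ", format(object$result$c_norm, digits = 3), "\n")
  cat("Derivatives:   ", object$derivative, "; Hessian: ", object$hessian,
      "\n", sep = "")
  ev <- object$evals
  cat("Evaluations:    f ", ev["f"], ", grad ", ev["grad"], ", con ",
      ev["con"], ", jac ", ev["jac"], ", hess ", ev["hess"], "\n", sep = "")
  if (length(traj$P))
    cat("Parameters:    ", paste(signif(traj$P, 6), collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.tt_solution <- function(object, ...) object$trajectories$P

#' Constraint residuals of a solution
#' @param object a `tt_solution`.
#' @param ... unused.
#' @return Numeric vector of scaled constraint values at the solution.
#' @export
residuals.tt_solution <- function(object, ...) {
  cb <- nlp_callbacks(object$nlp, mode = "ad")
  cb$con(object$result$z)
}

#' @export
plot.tt_solution <- function(x, which = c("states", "controls"), ...) {
  which <- match.arg(which)
  traj <- x$trajectories
  if (which == "states") {
    graphics::matplot(traj$t, t(traj$X), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "states",
                      main = x$problem_id, ...)
    graphics::legend("topright", legend = traj$x_names, lty = 1,
                     col = seq_len(nrow(traj$X)), cex = 0.6, bty = "n")
  } else {
    tu <- traj$t[-length(traj$t)]
    graphics::matplot(tu, t(traj$U), type = "s", lty = 1,
                      xlab = "time (s)", ylab = "controls",
                      main = x$problem_id, ...)
    graphics::legend("topright", legend = traj$u_names, lty = 1,
                     col = seq_len(nrow(traj$U)), cex = 0.6, bty = "n")
  }
  invisible(x)
}

# deterministic fingerprint of a converged trajectory: round scaled decision
# variables to 1e-3 and hash (runs converging to the same optimum match)
traj_fingerprint <- function(z, digits = 3) {
  v <- round(z, digits)
  v[v == 0] <- 0               # normalise -0
  s <- paste(sprintf("%.3f", v), collapse = ",")
  r <- as.integer(charToRaw(s))
  h <- 5381
  for (b in r) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Fingerprint of a solution
#'
#' Trajectories are rounded to `1e-3` in scaled units and hashed; two runs
#' are regarded as having converged to the same optimum iff their
#' fingerprints match (the screening rule of the benchmark harness).
#' @param sol a `tt_solution`.
#' @return Character hash.
#' @export
solution_fingerprint <- function(sol) traj_fingerprint(sol$result$z)

#' Interpolate a solution onto a finer (or coarser) transcription
#'
#' Builds a warm-start decision vector for `nlp` from the mesh trajectories
#' of a previous solution: states by linear interpolation at the new mesh
#' times, controls piecewise-constant, parameters copied.
#'
#' @param sol a `tt_solution`.
#' @param nlp the target `tt_nlp` (same problem, different mesh).
#' @return Decision vector usable as `guess` in [solve_ocp()].
#' @export
refine_guess <- function(sol, nlp) {
  tr <- sol$trajectories
  tf <- if (length(tr$P)) tr$P[1] else sol$ocp$horizon
  tnew <- seq(0, tf, length.out = nlp$N + 1L)
  X <- t(vapply(seq_len(nrow(tr$X)), function(j)
    stats::approx(tr$t, tr$X[j, ], xout = tnew, rule = 2)$y,
    numeric(nlp$N + 1L)))
  U <- NULL
  if (!is.null(tr$U)) {
    tu <- tr$t[-length(tr$t)]
    tun <- tnew[-length(tnew)]
    U <- t(vapply(seq_len(nrow(tr$U)), function(j)
      stats::approx(tu, tr$U[j, ], xout = tun, rule = 2,
                    method = "constant")$y, numeric(nlp$N)))
  }
  nlp_pack(nlp, X = X, U = U, P = tr$P)
}

#' Mesh-refinement self-check
#'
#' Solves the problem at `N` and `factor * N` intervals and reports the
#' maximum discrepancy of the mesh states (physical units, the coarse mesh
#' states compared against the fine solution at the same times by linear
#' interpolation).
#'
#' @param ocp a `tt_ocp`.
#' @param N coarse mesh size.
#' @param factor refinement factor.
#' @param threshold flag discrepancies above this value.
#' @param ... passed to [solve_ocp()].
#' @return List with `discrepancy`, `pass`, and both solutions.
#' @export
mesh_refine_check <- function(ocp, N, factor = 2, threshold = 1e-2, ...) {
  s1 <- solve_ocp(ocp, N, ...)
  s2 <- solve_ocp(ocp, factor * N, ...)
  t1 <- s1$trajectories$t
  disc <- 0
  for (j in seq_len(nrow(s1$trajectories$X))) {
    fine <- stats::approx(s2$trajectories$t, s2$trajectories$X[j, ],
                          xout = t1)$y
    disc <- max(disc, max(abs(fine - s1$trajectories$X[j, ])))
  }
  list(discrepancy = disc, pass = disc <= threshold,
       coarse = s1, fine = s2)
}
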