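# Radau scheme construction, transcription layout, scaling, callbacks and
# the interior-point solver on small control problems.

test_that("Radau IIA points, weights and differentiation matrix", {
  r1 <- make_radau(1)
  expect_equal(r1$points, 1)            # implicit Euler
  expect_equal(r1$w, 1)
  r3 <- make_radau(3)
  expect_equal(r3$points, c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1),
               tolerance = 1e-12)
  expect_equal(r3$points[3], 1)
  expect_true(all(diff(r3$points) > 0))
  # quadrature exact to degree 2d - 2 = 4
  expect_equal(radau_quadrature(r3, function(t) t^4), 1 / 5,
               tolerance = 1e-14)
  expect_equal(radau_quadrature(r3, function(t) 3 * t^2 - t + 2), 2.5,
               tolerance = 1e-14)
  # the differentiation matrix is exact for the degree-3 interpolant
  vals <- c(0, r3$points)^3
  expect_equal(as.numeric(r3$D %*% vals), 3 * r3$points^2,
               tolerance = 1e-12)
  expect_error(make_radau(10), "unsupported")
  # order check for all supported degrees
  for (d in 2:9) {
    rd <- make_radau(d)
    expect_equal(rd$points[d], 1)
    expect_equal(radau_quadrature(rd, function(t) t^(2 * d - 2)),
                 1 / (2 * d - 1), tolerance = 1e-10)
  }
})

test_that("scaling round-trips to machine precision", {
  sc <- scaling_set(c(3, 15), c(75, 500), 1.7)
  x <- c(-2.3, 11); u <- c(40, -800); p <- 0.4
  s <- ocp_scale(sc, x, u, p)
  b <- ocp_unscale(sc, s$x, s$u, s$p)
  expect_identical(b$x, x)
  expect_equal(b$u, u, tolerance = 1e-15)
  expect_equal(b$p, p, tolerance = 1e-15)
  expect_error(scaling_set(c(1, 0), 1), "0")
})

test_that("transcription counts follow the closed-form layout", {
  # minimal problem: one state, no controls, N = 1, d = 1; the layout keeps
  # the mesh state, one collocation state, one collocation row and one
  # continuity row
  ocp <- optimal_control_problem(
    nx = 1L, nu = 0L, x_lb = -10, x_ub = 10,
    u_lb = numeric(0), u_ub = numeric(0),
    scaling = scaling_set(1, numeric(0)),
    horizon = 1,
    dyn_A = matrix(0, 1, 1),
    integrand = function(x, u, p, e) x[1]^2,
    nominal = list(x = 0.5, u = numeric(0), p = numeric(0)))
  nlp <- transcribe(ocp, 1, make_radau(1))
  expect_equal(nlp$n_var, 3L)
  expect_equal(nlp$n_eq, 2L)
  expect_equal(nlp$n_ineq, 0L)
  # pendulum sizes: variables nx(N+1) + nx N d + nu N; equalities
  # nx N d (collocation) + nx N (continuity) + n N (torque) + 4n (boundary)
  for (nd in c(3, 6)) {
    N <- 25
    nlp <- transcribe(build_pendulum(nd), N)
    expect_equal(nlp$n_var, 2 * nd * (N + 1) + 2 * nd * N * 3 + 2 * nd * N)
    expect_equal(nlp$n_eq, 2 * nd * N * 3 + 2 * nd * N + nd * N + 4 * nd)
  }
})

test_that("quadrature objective of a constant integrand equals the horizon", {
  ocp <- optimal_control_problem(
    nx = 1L, nu = 0L, x_lb = -10, x_ub = 10,
    u_lb = numeric(0), u_ub = numeric(0),
    scaling = scaling_set(1, numeric(0)),
    horizon = 2.5,
    dyn_A = matrix(0, 1, 1),
    integrand = function(x, u, p, e) 1 + 0 * x[1],
    nominal = list(x = 0.5, u = numeric(0), p = numeric(0)))
  for (N in c(1, 7)) {
    nlp <- transcribe(ocp, N)
    cbk <- nlp_callbacks(nlp, "ad")
    z <- stats::runif(nlp$ntot, -1, 1)
    expect_equal(cbk$f(z), 2.5, tolerance = 1e-12)
    expect_equal(max(abs(cbk$grad(z))), 0)
  }
})

test_that("AD and FD callbacks agree on the pendulum NLP", {
  nlp <- transcribe(build_pendulum(2), 25)
  expect_equal(nlp$n_var, 504L)
  cba <- nlp_callbacks(nlp, "ad")
  cbf <- nlp_callbacks(nlp, "fd")
  set.seed(21)
  z <- stats::runif(nlp$ntot, -0.1, 0.1)
  J <- cba$jac(z)
  Jf <- cbf$jac(z)
  expect_lt(max(abs(J - Jf)), 1e-5 * (1 + max(abs(J))))
  expect_lt(max(abs(cba$grad(z) - cbf$grad(z))),
            1e-5 * (1 + max(abs(cba$grad(z)))))
  # AD Jacobian against central differences of the constraint function
  Jc <- fd_jacobian(cba$con, z, h = 1e-7, method = "central")
  expect_lt(max(abs(as.matrix(J) - Jc)), 1e-6 * (1 + max(abs(J))))
})

test_that("gradient costs one reverse sweep in ad mode, n+1 evals in fd", {
  nlp <- transcribe(build_pendulum(2), 25)
  cba <- nlp_callbacks(nlp, "ad")
  z <- numeric(nlp$ntot)
  reset_ad_counters()
  cba$grad(z)
  cnt <- ad_counters()
  expect_equal(cnt$reverse_sweeps, 1L)
  expect_equal(cnt$fn_evals, 0L)
  cbf <- nlp_callbacks(nlp, "fd")
  reset_ad_counters()
  cbf$grad(z)
  cnt <- ad_counters()
  expect_equal(cnt$fn_evals, nlp$n_var + 1L)   # 505 for the 504-variable NLP
  expect_equal(cnt$reverse_sweeps, 0L)
})

test_that("exact NLP Hessian matches finite differences of the gradient", {
  nlp <- transcribe(build_pendulum(2), 10)
  cb <- nlp_callbacks(nlp, "ad")
  set.seed(4)
  z <- stats::runif(nlp$ntot, -0.1, 0.1)
  lam <- stats::rnorm(nlp$mtot, sd = 0.2)
  H <- cb$hess(z, 1, lam)
  expect_lt(max(abs(H - Matrix::t(H))), 1e-12)
  gL <- function(zz) cb$grad(zz) +
    as.numeric(Matrix::crossprod(cb$jac(zz), lam))
  Hfd <- fd_jacobian(gL, z, h = 1e-6, method = "central")
  expect_lt(max(abs(as.matrix(H) - Hfd)), 1e-4 * (1 + max(abs(H))))
})

# double integrator with a free velocity endpoint: the optimum has constant
# acceleration, which piecewise-constant controls represent exactly, so the
# collocation solution is exact at any mesh
toy_ocp <- function() {
  optimal_control_problem(
    nx = 2L, nu = 1L,
    x_names = c("pos", "vel"), u_names = "acc",
    x_lb = c(-10, -10), x_ub = c(10, 10), u_lb = -10, u_ub = 10,
    scaling = scaling_set(c(1, 1), 1),
    horizon = 1,
    dyn_A = rbind(c(0, 1, 0), c(0, 0, 1)),
    integrand = function(x, u, p, e) u[1]^2,
    bnd_A = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 1)),
    bnd_b = c(0, 0, -1),            # x(0) = 0, vel(1) = 1
    bnd_scale = c(1, 1, 1),
    nominal = list(x = c(0.1, 0.1), u = 0.1, p = numeric(0)))
}

test_that("linear-dynamics toy problem is solved exactly at any mesh", {
  ocp <- toy_ocp()
  attr(ocp, "canonical_guess") <- function(nlp)
    nlp_pack(nlp, X = matrix(0, 2, nlp$N + 1), U = matrix(0, 1, nlp$N))
  sols <- lapply(c(1, 2, 5), function(N)
    solve_ocp(ocp, N, hessian = "exact", tol = 1e-10))
  for (s in sols) {
    expect_equal(s$status, "solved")
    # analytic optimum: u = 1, vel = t, pos = t^2/2, objective 1
    expect_equal(s$objective, 1, tolerance = 1e-9)
    expect_equal(as.numeric(s$trajectories$U), rep(1, s$nlp$N),
                 tolerance = 1e-7)
    tt <- s$trajectories$t
    expect_equal(s$trajectories$X[2, ], tt, tolerance = 1e-8)
    expect_equal(s$trajectories$X[1, ], tt^2 / 2, tolerance = 1e-8)
  }
  # N = 1 and N = 2 agree to machine-level precision (both exact)
  expect_equal(sols[[1]]$objective, sols[[2]]$objective, tolerance = 1e-10)
})

test_that("mesh refinement check passes on the toy problem", {
  ocp <- toy_ocp()
  attr(ocp, "canonical_guess") <- function(nlp)
    nlp_pack(nlp, X = matrix(0, 2, nlp$N + 1), U = matrix(0, 1, nlp$N))
  mr <- mesh_refine_check(ocp, 2, factor = 2, threshold = 1e-6,
                          hessian = "exact", tol = 1e-10)
  expect_true(mr$pass)
  expect_lt(mr$discrepancy, 1e-7)
})

test_that("solving twice with identical options is deterministic", {
  s1 <- pendulum_balance(2)
  s2 <- pendulum_balance(2)
  expect_equal(s1$iterations, s2$iterations)
  expect_equal(s1$objective, s2$objective, tolerance = 1e-12)
  expect_identical(solution_fingerprint(s1), solution_fingerprint(s2))
})

test_that("initial guesses are clamped into bounds with a warning", {
  nlp <- transcribe(build_pendulum(2), 5)
  cb <- nlp_callbacks(nlp, "ad")
  z0 <- rep(100, nlp$ntot)             # far outside the scaled bounds
  expect_warning(ip_solve(cb, z0, hessian = "exact",
                          control = list(max_iter = 1)), "clamped")
})
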