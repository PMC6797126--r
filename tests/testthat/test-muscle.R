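# Activation-rate bounds, Hill contraction residual, torque actuator and
# polynomial muscle-tendon geometry.

test_that("activation-rate residuals match direct substitution", {
  cns <- activation_constants()          # tau_a 15 ms, tau_d 60 ms
  r <- raasch_bounds(0.5, 0, cns)
  expect_equal(r$r_lo, 0.5 / 0.060, tolerance = 1e-12)
  expect_gte(r$r_lo, 0)
  expect_equal(r$r_hi, 0.5 / 0.015 - 1 / 0.015, tolerance = 1e-12)
  expect_lte(r$r_hi, 0)
  r0 <- raasch_bounds(0, 0, cns)        # rest: lower boundary active
  expect_equal(r0$r_lo, 0)
  expect_equal(r0$r_hi, -1 / cns$tau_a)
  r1 <- raasch_bounds(1, 0, cns)        # saturation: upper boundary active
  expect_equal(r1$r_hi, 0)
})

test_that("a feasible activation-rate band exists for any activation", {
  cns <- activation_constants()
  for (a in seq(0, 1, by = 0.05)) {
    # u_da interval [lo, hi] where both residuals are feasible
    lo <- -a / cns$tau_d / cns$s_da
    hi <- (1 - a) / cns$tau_a / cns$s_da
    expect_lte(lo, hi)
    mid <- (lo + hi) / 2
    r <- raasch_bounds(a, mid, cns)
    expect_gte(r$r_lo, -1e-12)
    expect_lte(r$r_hi, 1e-12)
  }
})

test_that("torque-actuator rate is first order", {
  p <- torque_actuator_params()          # tau = 35 ms
  expect_equal(torque_actuator_rate(0.3, 0.3, p), 0)
  expect_equal(torque_actuator_rate(1, 0, p), 1 / 0.035)
  expect_equal(torque_actuator_rate(-1, 1, p), -2 / 0.035)
})

hillp <- muscle_params(F_max = 1000, l_M_opt = 0.1, l_T_slack = 0.2)

test_that("Hill residual vanishes at force equilibria", {
  p <- hillp
  # zero activation, fiber at optimal length (no passive force at lm~ = 1),
  # tendon force consistent with zero total fiber force
  ft0 <- force_length_passive(1, p)      # = 0 by construction
  lt0 <- tapetraj:::tendon_length_from_force(0, p) * p$l_T_slack
  lmt0 <- lt0 + p$l_M_opt                # alpha = 0
  expect_equal(hill_residual(0, lmt0, 0, 0 + ft0, 0, p), 0,
               tolerance = 1e-12)
  # full activation, isometric, lm~ = 1: equilibrium iff
  # Ft = f_act(1) * f_v(0) + f_pas(1)
  ftiso <- force_length_active(1, p) * force_velocity(0, p) +
    force_length_passive(1, p)
  ltiso <- tapetraj:::tendon_length_from_force(ftiso, p) * p$l_T_slack
  lmtiso <- ltiso + p$l_M_opt
  expect_equal(hill_residual(1, lmtiso, 0, ftiso, 0, p), 0,
               tolerance = 1e-12)
  # residual sign flips when the tendon force state is perturbed
  rp <- hill_residual(1, lmtiso, 0, ftiso + 0.05, 0, p)
  rm <- hill_residual(1, lmtiso, 0, ftiso - 0.05, 0, p)
  expect_lt(rp, 0)
  expect_gt(rm, 0)
})

test_that("Hill residual is twice continuously differentiable", {
  p <- hillp
  base <- list(a = 0.6, lmt = 0.305, vmt = 0.02, ft = 0.4, udft = 0.1)
  f_of <- function(nm) function(s) {
    b <- base; b[[nm]] <- s
    hill_residual(b$a, b$lmt, b$vmt, b$ft, b$udft, p)
  }
  for (nm in names(base)) {
    f <- f_of(nm)
    s0 <- base[[nm]]
    h <- 1e-4 * max(1, abs(s0))
    grid <- seq(s0 - 20 * h, s0 + 20 * h, by = h)
    vals <- vapply(grid, f, 0)
    d2 <- diff(vals, differences = 2) / h^2
    # second difference varies smoothly: no jumps between neighbours
    expect_lt(max(abs(diff(d2))), 1e-2 * (1 + max(abs(d2))))
  }
})

test_that("pennation geometry error is raised", {
  p <- muscle_params(F_max = 100, l_M_opt = 0.1, l_T_slack = 0.2)
  # muscle-tendon length shorter than the tendon alone
  expect_error(hill_residual(0.5, 0.15, 0, 1, 0, p), "pennation")
})

test_that("linear geometry is fitted exactly at order 1", {
  r <- 0.04; l0 <- 0.3
  q <- seq(-1, 1, length.out = 120)
  s <- list(name = "lin", coords = 1L, Q = matrix(q),
            lmt = l0 - r * q, ma = matrix(rep(r, 120)))
  fit <- fit_polynomials(list(s), max_order = 3)
  expect_equal(fit$muscles$lin$order, 1L)
  ev <- eval_lmt_vmt_ma(fit, 0.3, 2.0)
  expect_equal(unname(ev$lmt), l0 - r * 0.3, tolerance = 1e-12)
  expect_equal(unname(ev$vmt), -r * 2, tolerance = 1e-12)
  expect_equal(unname(ev$ma[["lin"]]), r, tolerance = 1e-12)
})

test_that("fit failure names the worst muscle", {
  set.seed(4)
  q <- seq(-1, 1, length.out = 400)
  s <- list(name = "rough", coords = 1L, Q = matrix(q),
            lmt = 0.3 + 0.05 * sin(25 * q), ma = matrix(-1.25 * cos(25 * q)))
  expect_error(fit_polynomials(list(s), max_order = 9), "rough")
})

test_that("via-point gait geometry fits within 3 mm and AD moment arms are exact", {
  fx <- gait_fixture()
  geom <- fx$geom
  rms <- vapply(geom$muscles, `[[`, 0, "rms_len")
  expect_lt(max(rms), 0.003)
  orders <- vapply(geom$muscles, `[[`, 0L, "order")
  expect_true(all(orders <= 9))
  # AD on the polynomial tape reproduces the analytic polynomial derivative
  fit <- geom$muscles$hamstrings_r
  q0 <- c(0.2, -0.4)
  tp <- record(function(z)
    tapetraj:::poly_eval_scalar(fit$expts, fit$coef, list(z[1], z[2])), q0)
  g_ad <- reverse_sweep(tp, 1)
  ev <- tapetraj:::muscle_geom_eval(fit, list(q0[1], q0[2]), list(0, 0))
  expect_equal(-g_ad, unlist(ev$ma), tolerance = 1e-14)
  # fitted moment arm vs analytic via-point moment arm on a grid: <= 5 mm
  gait <- fx$gait
  mu <- gait$muscles$hamstrings_r
  qbase <- c(0, gait$standing_ty, 0, rep(0, 7))
  worst <- 0
  for (qh in seq(-0.8, 0.8, length.out = 7))
    for (qk in seq(-1.8, 0.05, length.out = 7)) {
      q <- qbase; q[4] <- qh; q[5] <- qk
      ev <- tapetraj:::muscle_geom_eval(fit, list(qh, qk), list(0, 0))
      for (v in 1:2) {
        qc <- q + 0i
        qc[mu$coords[v]] <- qc[mu$coords[v]] + 1e-30i
        ma_true <- -Im(tapetraj:::muscle_tendon_length(gait, mu, qc)) / 1e-30
        worst <- max(worst, abs(unlist(ev$ma)[v] - ma_true))
      }
    }
  expect_lt(worst, 0.005)
})

test_that("polynomial velocity matches a finite-difference along a path", {
  fx <- gait_fixture()
  geom <- fx$geom
  set.seed(8)
  q <- c(0, 0.99, 0, stats::runif(6, -0.4, 0.02), 0)
  v <- stats::runif(10, -1, 1)
  ev <- eval_lmt_vmt_ma(geom, q, v)
  dt <- 1e-6
  evp <- eval_lmt_vmt_ma(geom, q + dt * v, v)
  evm <- eval_lmt_vmt_ma(geom, q - dt * v, v)
  vfd <- (evp$lmt - evm$lmt) / (2 * dt)
  expect_equal(unname(ev$vmt), unname(vfd), tolerance = 1e-6)
  # zero velocities give zero lengthening rate
  ev0 <- eval_lmt_vmt_ma(geom, q, rep(0, 10))
  expect_true(all(ev0$vmt == 0))
})
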