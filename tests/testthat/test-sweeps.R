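# Forward/reverse sweeps, Jacobians, exact Hessians, source emission and the
# finite-difference comparator.

test_that("forward and reverse sweeps give analytic directional derivatives", {
  tp <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
  # d/dx1 = -x2, d/dx2 = -sin x2 - x1
  expect_equal(forward_sweep(tp, c(1, 0)), -pi / 2)
  expect_equal(forward_sweep(tp, c(0, 1)), -sin(pi / 2) - 1)
  expect_equal(reverse_sweep(tp, 1), c(-pi / 2, -2))
  expect_equal(reverse_sweep(tp, 0), c(0, 0))
  tp20 <- record(function(x) cos(x[2]) - x[2] * x[1], c(2, 0))
  expect_equal(forward_sweep(tp20, c(1, 0)), 0)    # -x2 vanishes
  # dimension errors
  expect_error(forward_sweep(tp, c(1, 0, 0)), "dimension")
  expect_error(reverse_sweep(tp, c(1, 1)), "dimension")
})

test_that("jacobian picks the cheaper mode and matches hand results", {
  tp <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
  reset_ad_counters()
  expect_equal(tape_jacobian(tp), matrix(c(-pi / 2, -2), 1))
  cnt <- ad_counters()
  expect_equal(cnt$reverse_sweeps, 1L)   # m = 1 < n = 2
  expect_equal(cnt$forward_sweeps, 0L)
  tpi <- record(function(x) x, c(1, 2, 3))
  expect_equal(tape_jacobian(tpi), diag(3))
  tp2 <- record(function(x) c(x[1] + x[2], x[1] * x[2]), c(2, 3))
  expect_equal(tape_jacobian(tp2), matrix(c(1, 3, 1, 2), 2))
})

test_that("adjoint identity holds on 200 random tapes", {
  for (s in 1:200) {
    rt <- random_tape(n_in = sample(2:5, 1), n_ops = sample(5:40, 1),
                      seed = s)
    tp <- rt$tape
    set.seed(1000 + s)
    xd <- stats::rnorm(tp$n)
    yb <- stats::rnorm(tp$m)
    yd <- forward_sweep(tp, xd)
    xb <- reverse_sweep(tp, yb)
    scale <- max(1, abs(sum(yb * yd)), abs(sum(xb * xd)))
    expect_lt(abs(sum(yb * yd) - sum(xb * xd)), 1e-12 * scale)
  }
})

test_that("AD Jacobians match central differences on random tapes", {
  for (s in 1:50) {
    rt <- random_tape(n_in = 3, n_ops = 25, seed = 300 + s)
    J <- tape_jacobian(rt$tape)
    Jfd <- fd_jacobian(rt$fn, rt$x0, h = 1e-6, method = "central")
    expect_lt(max(abs(J - Jfd)), 1e-6 * (1 + max(abs(J))))
  }
})

test_that("exact Hessians match analytic second derivatives", {
  tp <- record(function(x) x[1]^2, 1.7)
  expect_equal(hessian_lagrangian(list(tp)), matrix(2, 1, 1))
  tpf <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
  H <- hessian_lagrangian(list(tpf))
  expect_equal(H, matrix(c(0, -1, -1, -cos(pi / 2)), 2), tolerance = 1e-14)
  # x1 * x2 as a weighted constraint: off-diagonal = weight
  tpc <- record(function(x) x[1] * x[2], c(0.4, -1.1))
  Hc <- hessian_lagrangian(list(tpc), obj_weight = 2)
  expect_equal(Hc, matrix(c(0, 2, 2, 0), 2))
  # symmetry and FD-of-gradient agreement on a mixed expression
  g <- record(function(x) {
    y <- x[1] * sin(x[2]) + exp(x[3] / 3) * x[1] - tanh(x[4] * x[2])
    y
  }, c(0.5, 1.2, -0.3, 0.8))
  Hs <- hessian_lagrangian(list(g))
  expect_lt(max(abs(Hs - t(Hs))), 1e-10)
  Hfd <- fd_jacobian(function(x) reverse_sweep(g, 1, at = x),
                     g$nominal_in, h = 1e-6, method = "central")
  expect_lt(max(abs(Hs - Hfd)), 1e-4 * (1 + max(abs(Hs))))
})

test_that("emitted source agrees with the tape interpreter", {
  tp <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
  fns <- emit_compile(emit_source(tp, "f1"), "f1")
  expect_equal(fns$replay(c(1, pi / 2)), -pi / 2)
  expect_equal(fns$reverse(c(1, pi / 2), 1), c(-pi / 2, -2))
  # identity: emitted forward returns the seed
  tpi <- record(function(x) x, c(1, 2))
  fi <- emit_compile(emit_source(tpi, "idf"), "idf")
  expect_equal(fi$forward(c(5, 5), c(0.3, -2)), c(0.3, -2))
  # a ~50-node random tape on 100 random inputs
  rt <- random_tape(n_in = 3, n_ops = 50, seed = 99)
  fr <- emit_compile(emit_source(rt$tape, "g"), "g")
  for (k in 1:100) {
    x <- stats::rnorm(3)
    a <- replay(rt$tape, x)
    b <- fr$replay(x)
    expect_lt(max(abs(a - b)), 1e-14 * (1 + max(abs(a))))
    yb <- stats::rnorm(rt$tape$m)
    expect_equal(fr$reverse(x, yb),
                 reverse_sweep(rt$tape, yb, at = x), tolerance = 1e-13)
  }
})

test_that("fd_jacobian counts evaluations and shows forward-difference bias", {
  reset_ad_counters()
  J <- fd_jacobian(function(x) x[1]^2, 1, h = 1e-6)
  expect_equal(attr(J, "evals"), 2L)      # n + 1
  expect_equal(J[1, 1], 2 + 1e-6, tolerance = 1e-9)  # truncation bias ~ h
  Jc <- fd_jacobian(function(x) c(5, -1), c(1, 2, 3), h = 1e-6)
  expect_true(all(Jc == 0))
  expect_equal(attr(Jc, "evals"), 4L)
  expect_error(suppressWarnings(
    fd_jacobian(function(x) sqrt(x[1]), -1e-7, h = 1e-6)), "non-finite")
})
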