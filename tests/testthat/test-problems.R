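# Problem builders, initial guesses and the benchmark harness.

test_that("zero-perturbation balance is optimally torque-free", {
  sol <- pendulum_balance(2, peak = 0)
  expect_equal(sol$status, "solved")
  expect_lt(sol$objective, 1e-10)
  expect_lt(max(abs(sol$trajectories$U)), 1e-3)
  expect_lt(max(abs(sol$trajectories$X)), 1e-4)
})

test_that("solved 2-dof balance satisfies boundary conditions and bounds", {
  sol <- pendulum_balance(2)
  expect_equal(sol$status, "solved")
  tr <- sol$trajectories
  n <- 2
  sx <- c(rep(3, n), rep(15, n))
  expect_lt(max(abs(tr$X[, 1] / sx)), 1e-6)
  expect_lt(max(abs(tr$X[, ncol(tr$X)] / sx)), 1e-6)
  expect_true(all(abs(tr$X[1:n, ]) <= 3 * pi + 1e-9))
  expect_true(all(abs(tr$X[n + 1:n, ]) <= 20 + 1e-9))
  expect_true(all(abs(tr$U[1:n, ]) <= 500 + 1e-6))
  expect_true(all(abs(tr$U[n + 1:n, ]) <= 1000 + 1e-6))
  # the torque controls reproduce the inverse dynamics at the interval ends
  ch <- attr(sol$ocp, "chain")
  N <- sol$nlp$N
  for (i in c(3, 12, 25)) {
    tq <- pendulum_inverse_dynamics(ch, i / N,
      list(q = tr$Z[1:n, 3, i], v = tr$Z[n + 1:n, 3, i],
           udv = tr$U[1:n, i]))
    expect_lt(max(abs(tq - tr$U[n + 1:n, i])), 1e-3)
  }
  # perturbation strong enough to demand meaningful torques
  expect_gt(max(abs(tr$U[n + 1:n, ])), 1)
})

test_that("initial guesses are deterministic and within bounds", {
  ocp <- build_pendulum(3)
  nlp <- transcribe(ocp, 10)
  g1 <- make_initial_guesses(ocp, nlp, count = 5, seed = 0)
  g2 <- make_initial_guesses(ocp, nlp, count = 5, seed = 0)
  expect_identical(g1, g2)
  g3 <- make_initial_guesses(ocp, nlp, count = 5, seed = 1)
  expect_false(identical(g1[[2]], g3[[2]]))
  expect_identical(g1[[1]], g3[[1]])     # canonical guess is seed-free
  for (g in g1) {
    expect_true(all(g >= nlp$lb - 1e-12))
    expect_true(all(g <= nlp$ub + 1e-12))
  }
})

test_that("perturbed guesses converge to the canonical fingerprint", {
  ocp <- build_pendulum(2)
  nlp <- transcribe(ocp, 25)
  guesses <- make_initial_guesses(ocp, nlp, count = 3, seed = 0)
  fps <- vapply(guesses, function(g) {
    s <- solve_ocp(ocp, 25, hessian = "exact", guess = g)
    expect_equal(s$status, "solved")
    solution_fingerprint(s)
  }, "")
  expect_true(all(fps == fps[1]))
})

test_that("benchmark harness screens by fingerprint and reports ratios", {
  ocp <- build_pendulum(2)
  bench <- run_benchmark(ocp, N = 25, scenarios = c("ad", "fd"),
                         hessians = c("exact", "lbfgs"), n_guesses = 2,
                         seed = 0, max_iter = 400)
  rec <- bench$records
  expect_true(all(c("problem", "scenario", "hessian", "guess", "status",
                    "iterations", "time_s", "grad_time_share",
                    "jac_time_share", "objective", "fingerprint")
                  %in% names(rec)))
  expect_true(all(rec$status == "solved"))
  # fd spends at least n+1 function evaluations per gradient call, while ad
  # spends one reverse sweep per gradient call (factor >= n on counters)
  ad <- rec[rec$scenario == "ad" & rec$hessian == "lbfgs" & rec$guess == 1, ]
  fd <- rec[rec$scenario == "fd" & rec$guess == 1, ]
  expect_gte(fd$fn_evals / fd$grad_calls, transcribe(ocp, 25)$n_var)
  expect_gte(ad$reverse_sweeps, ad$grad_calls)   # 1 sweep per gradient
  expect_true(!is.null(bench$ratios))
  expect_true(all(bench$ratios$n + bench$ratios$excluded >= 1))
  # identical scenario compared against itself gives unit ratios
  base <- rec[rec$scenario == "ad" & rec$hessian == "lbfgs", ]
  selfr <- merge(base, base, by = "guess", suffixes = c("", ".b"))
  expect_true(all(selfr$time_s / selfr$time_s.b == 1))
  csv <- tempfile(fileext = ".csv")
  benchmark_csv(bench, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(rec))
})

test_that("gait problem assembles the documented constraint layout", {
  fx <- gait_fixture()
  ocp <- build_gait2d(gait = fx$gait, geom = fx$geom)
  N <- 50
  nlp <- transcribe(ocp, N)
  # one Hill equality per muscle and interval; two activation-rate
  # inequalities per muscle and interval; torque rows per interval;
  # collocation + continuity rows per state; symmetry + speed + anchor
  expect_equal(nlp$npe, 18 + 10)
  expect_equal(nlp$n_ineq, 2 * 18 * N)
  expect_equal(nlp$n_eq, 57 * 3 * N + 57 * N + 28 * N + 56 + 2)
  expect_equal(nlp$n_var, 57 * (N + 1) + 57 * 3 * N + 47 * N + 1)
  # symmetry map is an involution
  sym <- tapetraj:::gait_symmetry_map()
  expect_identical(sym[sym], seq_len(57L))
})
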