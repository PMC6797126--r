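# Recording, replay and the branch signature of the AD tape.

test_that("recording and replay reproduce direct evaluation", {
  tp <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
  expect_equal(replay(tp, c(1, pi / 2)), -pi / 2)
  expect_equal(tp$nominal_out, -pi / 2)
  expect_equal(replay(tp, c(2, 0)), 1)        # cos 0 - 0
  # multi-point replay equals direct evaluation columnwise (m x K matrix)
  X <- matrix(stats::runif(20, -2, 2), 2)
  expect_equal(as.numeric(replay(tp, X)), cos(X[2, ]) - X[2, ] * X[1, ],
               tolerance = 1e-15)
})

test_that("identity tape has input node equal to output node", {
  tp <- record(function(x) x, 3.7)
  expect_identical(tp$input_ids, tp$output_ids)
  expect_equal(replay(tp, 42), 42)
  expect_equal(length(tp$op), 1L)
})

test_that("elementary-operation count matches a hand count", {
  tp <- record(function(x) tanh(x[1]) + x[1]^2, 0)
  expect_equal(replay(tp, 0), 0)
  # input, tanh, square, add (constants are not elementary operations)
  expect_equal(sum(tp$op != "const"), 4L)
})

test_that("unsupported operations and non-finite nominals error", {
  expect_error(record(function(x) abs(x[1]), 1), "unsupported")
  expect_error(record(function(x) max(x[1], 0), 1), "unsupported")
  expect_error(record(function(x) floor(x[1]), 1), "unsupported")
  expect_error(suppressWarnings(record(function(x) log(x[1]), -1)),
               "recording error")
  expect_error(record(function(x) x[1] / 0, 1), "recording error")
})

test_that("branch signature is recorded and replay rejects stale tapes", {
  f <- function(x) if (x[1] > 0) x[1]^2 else -x[1]
  tp <- record(f, 2)
  expect_length(tp$branch, 1L)
  expect_equal(replay(tp, 3), 9)
  expect_error(replay(tp, -1), "stale tape")
  tp2 <- record(function(x) x[1]^2, 2)
  expect_length(tp2$branch, 0L)
})

test_that("replay is deterministic bit-for-bit", {
  rt <- random_tape(n_in = 4, n_ops = 30, seed = 7)
  x <- stats::rnorm(4)
  expect_identical(replay(rt$tape, x), replay(rt$tape, x))
})

test_that("tape JSON serialization round-trips", {
  tp <- record(function(x) sin(x[1]) * x[2] + exp(x[2] / 4), c(0.3, 1.2))
  tp2 <- tape_from_json(tape_to_json(tp))
  x <- c(-0.5, 2)
  expect_identical(replay(tp, x), replay(tp2, x))
  expect_identical(tape_jacobian(tp), tape_jacobian(tp2))
})
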