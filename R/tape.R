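# Tape-based algorithmic differentiation: an operator-overloaded scalar/vector
# type records an expression graph ("tape") while the function is evaluated at
# a nominal point; forward and reverse sweeps over the tape then yield exact
# directional derivatives.

.tt_ops <- c("const", "input", "add", "sub", "mul", "div", "neg", "pow",
             "sqrt", "exp", "log", "sin", "cos", "tan", "tanh", "atan")

.tt_state <- new.env(parent = emptyenv())
.tt_state$rec <- NULL
.tt_state$counters <- list(forward_sweeps = 0L, reverse_sweeps = 0L,
                           fn_evals = 0L)

#' Reset the AD/FD evaluation counters
#'
#' The package counts forward sweeps, reverse sweeps and plain function
#' evaluations (used by the finite-difference fallback). The counters expose
#' the cost mechanism of reverse-mode AD: one reverse sweep yields a full
#' gradient regardless of the input dimension, whereas forward differencing
#' needs n+1 function evaluations.
#' @return Invisibly, the zeroed counter list.
#' @export
reset_ad_counters <- function() {
  .tt_state$counters <- list(forward_sweeps = 0L, reverse_sweeps = 0L,
                             fn_evals = 0L)
  invisible(.tt_state$counters)
}

#' Read the AD/FD evaluation counters
#' @return Named list with `forward_sweeps`, `reverse_sweeps`, `fn_evals`.
#' @export
ad_counters <- function() .tt_state$counters

.bump <- function(which, by = 1L) {
  .tt_state$counters[[which]] <- .tt_state$counters[[which]] + as.integer(by)
}

## ---- recorder -------------------------------------------------------------

new_recorder <- function(cap = 256L) {
  rec <- new.env(parent = emptyenv())
  rec$n <- 0L
  rec$op <- character(cap)
  rec$p1 <- integer(cap)
  rec$p2 <- integer(cap)
  rec$val <- numeric(cap)
  rec$branch <- list()
  rec
}

rec_grow <- function(rec, need) {
  cap <- length(rec$op)
  if (rec$n + need <= cap) return(invisible(NULL))
  newcap <- max(2L * cap, rec$n + need)
  length(rec$op) <- newcap
  length(rec$p1) <- newcap
  length(rec$p2) <- newcap
  length(rec$val) <- newcap
  invisible(NULL)
}

add_nodes <- function(rec, op, p1, p2, val) {
  k <- length(val)
  rec_grow(rec, k)
  ids <- rec$n + seq_len(k)
  rec$op[ids] <- op
  rec$p1[ids] <- as.integer(p1)
  rec$p2[ids] <- as.integer(p2)
  rec$val[ids] <- val
  rec$n <- rec$n + k
  ids
}

active_rec <- function() {
  rec <- .tt_state$rec
  if (is.null(rec)) stop("no active tape recording", call. = FALSE)
  rec
}

## ---- adnum: the recorded scalar/vector type -------------------------------

adnum <- function(ids) structure(list(ids = as.integer(ids)), class = "adnum")

#' @export
length.adnum <- function(x) length(x$ids)

#' @export
`[.adnum` <- function(x, i) adnum(x$ids[i])

#' @export
c.adnum <- function(...) {
  parts <- list(...)
  rec <- active_rec()
  ids <- unlist(lapply(parts, function(p) {
    if (inherits(p, "adnum")) p$ids
    else if (is.numeric(p)) add_nodes(rec, "const", 0L, 0L, as.numeric(p))
    else stop("cannot combine object of class ", class(p)[1], " with adnum")
  }))
  adnum(ids)
}

#' @export
print.adnum <- function(x, ...) {
  rec <- .tt_state$rec
  vals <- if (!is.null(rec)) rec$val[x$ids] else rep(NA_real_, length(x$ids))
  cat("<adnum> length", length(x$ids), "nominal:",
      paste(signif(vals, 6), collapse = " "), "\n")
  invisible(x)
}

as_ids <- function(e, rec, len = NULL) {
  if (inherits(e, "adnum")) {
    ids <- e$ids
  } else if (is.numeric(e)) {
    ids <- add_nodes(rec, "const", 0L, 0L, as.numeric(e))
  } else stop("unsupported operand of class ", class(e)[1], " on tape")
  if (!is.null(len) && length(ids) != len) {
    if (length(ids) == 1L) ids <- rep(ids, len)
    else if (len == 1L) stop("length mismatch in taped operation")
    else stop("length mismatch in taped operation")
  }
  ids
}

.tt_binary <- c("+" = "add", "-" = "sub", "*" = "mul", "/" = "div",
                "^" = "pow")
.tt_compare <- c("==", "!=", "<", "<=", ">", ">=")

#' @export
Ops.adnum <- function(e1, e2) {
  rec <- active_rec()
  if (missing(e2)) { # unary
    if (.Generic == "+") return(e1)
    if (.Generic == "-") {
      ids <- e1$ids
      return(adnum(add_nodes(rec, "neg", ids, 0L, -rec$val[ids])))
    }
    stop("unsupported unary operation '", .Generic, "' on tape")
  }
  if (.Generic %in% names(.tt_binary)) {
    n1 <- if (inherits(e1, "adnum")) length(e1$ids) else length(e1)
    n2 <- if (inherits(e2, "adnum")) length(e2$ids) else length(e2)
    len <- max(n1, n2)
    i1 <- as_ids(e1, rec, len)
    i2 <- as_ids(e2, rec, len)
    v1 <- rec$val[i1]; v2 <- rec$val[i2]
    v <- switch(.Generic,
                "+" = v1 + v2, "-" = v1 - v2, "*" = v1 * v2,
                "/" = v1 / v2, "^" = v1 ^ v2)
    return(adnum(add_nodes(rec, .tt_binary[[.Generic]], i1, i2, v)))
  }
  if (.Generic %in% .tt_compare) {
    # Comparisons are evaluated numerically at the nominal point and their
    # outcomes recorded as a branch signature; replay must reproduce them.
    a_ad <- inherits(e1, "adnum"); b_ad <- inherits(e2, "adnum")
    av <- if (a_ad) rec$val[e1$ids] else as.numeric(e1)
    bv <- if (b_ad) rec$val[e2$ids] else as.numeric(e2)
    out <- do.call(.Generic, list(av, bv))
    rec$branch[[length(rec$branch) + 1L]] <- list(
      op = .Generic,
      aid = if (a_ad) e1$ids else NA_integer_, aval = if (a_ad) NA_real_ else av,
      bid = if (b_ad) e2$ids else NA_integer_, bval = if (b_ad) NA_real_ else bv,
      outcome = out)
    return(out)
  }
  stop("unsupported operation '", .Generic, "' on tape")
}

.tt_math <- c("sqrt", "exp", "log", "sin", "cos", "tan", "tanh", "atan")

#' @export
Math.adnum <- function(x, ...) {
  if (!(.Generic %in% .tt_math))
    stop("unsupported operation '", .Generic,
         "' on tape (closed smooth op set)")
  rec <- active_rec()
  ids <- x$ids
  v <- get(.Generic, mode = "function")(rec$val[ids])
  adnum(add_nodes(rec, .Generic, ids, 0L, v))
}

#' @export
Summary.adnum <- function(..., na.rm = FALSE) {
  if (!(.Generic %in% c("sum", "prod")))
    stop("unsupported operation '", .Generic,
         "' on tape (closed smooth op set)")
  rec <- active_rec()
  ids <- unlist(lapply(list(...), function(p) as_ids(p, rec)))
  opname <- if (.Generic == "sum") "add" else "mul"
  # balanced pairwise reduction keeps the graph shallow
  while (length(ids) > 1L) {
    k <- length(ids)
    half <- k %/% 2L
    a <- ids[seq_len(half)]
    b <- ids[half + seq_len(half)]
    v1 <- rec$val[a]; v2 <- rec$val[b]
    v <- if (opname == "add") v1 + v2 else v1 * v2
    red <- add_nodes(rec, opname, a, b, v)
    ids <- if (k %% 2L == 1L) c(red, ids[k]) else red
  }
  adnum(ids)
}

#' @export
mean.adnum <- function(x, ...) sum(x) / length(x$ids)

## ---- recording ------------------------------------------------------------

#' Record a function's expression graph onto a tape
#'
#' Evaluates `fn` at `nominal_in` with an operator-overloaded numeric type;
#' every elementary operation (from the closed smooth set: arithmetic, `sqrt`,
#' `exp`, `log`, `sin`, `cos`, `tan`, `tanh`, `atan`) is appended to a tape.
#' Comparison outcomes encountered during recording form the tape's branch
#' signature; [replay()] refuses evaluation points whose comparison outcomes
#' differ (the recorded graph is then stale).
#'
#' @param fn function taking one argument, an overloaded vector of length
#'   `length(nominal_in)`, returning an overloaded vector (or plain numerics,
#'   treated as constants).
#' @param nominal_in numeric vector; the recording point.
#' @return An object of class `tt_tape`.
#' @examples
#' tp <- record(function(x) cos(x[2]) - x[2] * x[1], c(1, pi / 2))
#' replay(tp, c(1, pi / 2))   # -pi/2
#' reverse_sweep(tp, 1)       # full gradient in one sweep
#' @export
record <- function(fn, nominal_in) {
  if (!is.null(.tt_state$rec))
    stop("a tape recording is already active; nested recording is not supported")
  nominal_in <- as.numeric(nominal_in)
  if (any(!is.finite(nominal_in)))
    stop("recording error: non-finite nominal input")
  rec <- new_recorder()
  .tt_state$rec <- rec
  on.exit(.tt_state$rec <- NULL, add = TRUE)
  n <- length(nominal_in)
  x <- adnum(add_nodes(rec, "input", 0L, 0L, nominal_in))
  out <- fn(x)
  if (is.numeric(out)) out <- adnum(add_nodes(rec, "const", 0L, 0L, out))
  if (!inherits(out, "adnum"))
    stop("recorded function must return a taped (or numeric) vector")
  nn <- rec$n
  vals <- rec$val[seq_len(nn)]
  if (any(!is.finite(vals)))
    stop("recording error: non-finite value at node ",
         which(!is.finite(vals))[1], " (op '",
         rec$op[which(!is.finite(vals))[1]], "')")
  tape <- list(op = rec$op[seq_len(nn)],
               p1 = rec$p1[seq_len(nn)],
               p2 = rec$p2[seq_len(nn)],
               val = vals,
               input_ids = x$ids,
               output_ids = out$ids,
               n = n, m = length(out$ids),
               nominal_in = nominal_in,
               nominal_out = vals[out$ids],
               branch = rec$branch,
               cache = new.env(parent = emptyenv()))
  class(tape) <- "tt_tape"
  tape
}

#' @export
print.tt_tape <- function(x, ...) {
  cat("<tt_tape> ", x$n, " inputs -> ", x$m, " outputs, ",
      length(x$op), " nodes, ", length(x$branch),
      " recorded branch(es)\n", sep = "")
  invisible(x)
}

## ---- evaluation plan: nodes grouped by (level, op) ------------------------

tape_plan <- function(tape) {
  if (!is.null(tape$cache$plan)) return(tape$cache$plan)
  nn <- length(tape$op)
  lev <- integer(nn)
  p1 <- tape$p1; p2 <- tape$p2; op <- tape$op
  leaf <- op %in% c("const", "input")
  for (i in seq_len(nn)) {
    if (leaf[i]) next
    l1 <- lev[p1[i]]
    l2 <- if (p2[i] > 0L) lev[p2[i]] else 0L
    lev[i] <- 1L + max(l1, l2)
  }
  idx <- which(!leaf)
  key <- paste(lev[idx], op[idx])
  groups <- split(idx, key)
  ord <- order(vapply(groups, function(g) lev[g[1]], integer(1)))
  groups <- groups[ord]
  is_const <- op == "const"
  steps <- lapply(groups, function(ids) {
    pp1 <- p1[ids]
    pp2 <- pmax(p2[ids], 1L)           # placeholder for unary ops
    list(op = op[ids[1]], ids = ids, p1 = pp1, p2 = pp2,
         c1 = is_const[pp1],
         c2 = is_const[pp2] | p2[ids] == 0L)
  })
  plan <- list(steps = steps, nn = nn,
               const_ids = which(is_const),
               const_vals = tape$val[is_const])
  tape$cache$plan <- plan
  plan
}

# Evaluate tape at columns of X (n x K). Returns list(V = K x nn node values).
tape_eval <- function(tape, X, check_branch = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  stopifnot(nrow(X) == tape$n)
  K <- ncol(X)
  plan <- tape_plan(tape)
  V <- matrix(0, K, plan$nn)
  if (length(plan$const_ids))
    V[, plan$const_ids] <- rep(plan$const_vals, each = K)
  V[, tape$input_ids] <- t(X)
  for (s in plan$steps) {
    a <- V[, s$p1, drop = FALSE]
    V[, s$ids] <- switch(s$op,
      add = a + V[, s$p2, drop = FALSE],
      sub = a - V[, s$p2, drop = FALSE],
      mul = a * V[, s$p2, drop = FALSE],
      div = a / V[, s$p2, drop = FALSE],
      pow = a ^ V[, s$p2, drop = FALSE],
      neg = -a,
      sqrt = sqrt(a), exp = exp(a), log = log(a),
      sin = sin(a), cos = cos(a), tan = tan(a),
      tanh = tanh(a), atan = atan(a),
      stop("corrupt tape: op ", s$op))
  }
  if (check_branch && length(tape$branch)) check_branches(tape, V)
  V
}

check_branches <- function(tape, V) {
  for (b in tape$branch) {
    av <- if (!is.na(b$aid[1])) V[, b$aid, drop = TRUE] else b$aval
    bv <- if (!is.na(b$bid[1])) V[, b$bid, drop = TRUE] else b$bval
    out <- do.call(b$op, list(av, bv))
    if (!all(out == b$outcome))
      stop("stale tape: branch outcome at replay differs from the recorded ",
           "signature; re-record the function at the new point", call. = FALSE)
  }
  invisible(TRUE)
}

# Local partial derivatives at given node values. Partials toward constant
# parents are zeroed (their seeds are identically zero).
tape_partials <- function(tape, V) {
  plan <- tape_plan(tape)
  K <- nrow(V)
  D1 <- matrix(0, K, plan$nn)
  D2 <- matrix(0, K, plan$nn)
  for (s in plan$steps) {
    a <- V[, s$p1, drop = FALSE]
    b <- V[, s$p2, drop = FALSE]
    y <- V[, s$ids, drop = FALSE]
    d <- switch(s$op,
      add = list(1 + 0 * a, 1 + 0 * a),
      sub = list(1 + 0 * a, -1 + 0 * a),
      mul = list(b, a),
      div = list(1 / b, -y / b),
      pow = list(b * a ^ (b - 1),
                 if (all(s$c2)) NULL else y * log(a)),
      neg = list(-1 + 0 * a, NULL),
      sqrt = list(0.5 / y, NULL),
      exp = list(y, NULL),
      log = list(1 / a, NULL),
      sin = list(cos(a), NULL),
      cos = list(-sin(a), NULL),
      tan = list(1 + y ^ 2, NULL),
      tanh = list(1 - y ^ 2, NULL),
      atan = list(1 / (1 + a ^ 2), NULL))
    d1 <- d[[1]]; d1[, s$c1] <- 0
    D1[, s$ids] <- d1
    if (!is.null(d[[2]])) {
      d2 <- d[[2]]; d2[, s$c2] <- 0
      D2[, s$ids] <- d2
    }
  }
  list(D1 = D1, D2 = D2)
}

fwd_prop <- function(tape, P, Xdot, K) {
  plan <- tape_plan(tape)
  S <- matrix(0, K, plan$nn)
  S[, tape$input_ids] <- if (is.null(dim(Xdot))) rep(Xdot, each = K) else t(Xdot)
  for (s in plan$steps) {
    S[, s$ids] <- P$D1[, s$ids, drop = FALSE] * S[, s$p1, drop = FALSE] +
      P$D2[, s$ids, drop = FALSE] * S[, s$p2, drop = FALSE]
  }
  S
}

rev_prop <- function(tape, P, Ybar, K) {
  plan <- tape_plan(tape)
  B <- matrix(0, K, plan$nn)
  yb <- if (is.null(dim(Ybar))) matrix(rep(Ybar, each = K), K) else t(Ybar)
  for (j in seq_along(tape$output_ids)) {
    oid <- tape$output_ids[j]
    B[, oid] <- B[, oid] + yb[, j]
  }
  for (s in rev(plan$steps)) {
    bb <- B[, s$ids, drop = FALSE]
    cc <- P$D1[, s$ids, drop = FALSE] * bb
    acc <- rowsum(t(cc), group = s$p1)
    tgt <- as.integer(rownames(acc))
    B[, tgt] <- B[, tgt] + t(acc)
    if (any(P$D2[, s$ids] != 0)) {
      cc2 <- P$D2[, s$ids, drop = FALSE] * bb
      acc2 <- rowsum(t(cc2), group = s$p2)
      tgt2 <- as.integer(rownames(acc2))
      B[, tgt2] <- B[, tgt2] + t(acc2)
    }
  }
  B
}

## ---- user-facing sweeps ---------------------------------------------------

#' Replay a tape at new inputs
#'
#' Re-evaluates the recorded expression graph. Replaying at the nominal point
#' reproduces the recorded outputs exactly. If the tape recorded comparison
#' outcomes (branch signature), replay errors when any outcome differs at the
#' new point.
#'
#' @param tape a `tt_tape`.
#' @param x numeric vector of length `tape$n`, or an `n x K` matrix to
#'   evaluate at K points simultaneously.
#' @return m-vector, or `m x K` matrix when `x` is a matrix.
#' @export
replay <- function(tape, x) {
  mat <- !is.null(dim(x))
  if (!mat) x <- matrix(as.numeric(x), ncol = 1L)
  if (any(!is.finite(x))) stop("replay requires finite inputs")
  V <- tape_eval(tape, x)
  out <- t(V[, tape$output_ids, drop = FALSE])
  if (!mat) drop(out) else out
}

#' Forward derivative sweep: J %*% xdot
#'
#' Propagates a forward seed from inputs to outputs in a single pass over the
#' tape; the cost is proportional to one function evaluation.
#'
#' @param tape a `tt_tape`.
#' @param xdot forward seed, length `tape$n`.
#' @param at evaluation point (default: the tape's nominal input).
#' @return Forward sensitivity `J %*% xdot`, length `tape$m`.
#' @export
forward_sweep <- function(tape, xdot, at = NULL) {
  if (length(xdot) != tape$n)
    stop("seed length ", length(xdot), " does not match input dimension ",
         tape$n)
  x <- if (is.null(at)) tape$nominal_in else at
  V <- tape_eval(tape, matrix(x, ncol = 1L))
  P <- tape_partials(tape, V)
  S <- fwd_prop(tape, P, as.numeric(xdot), 1L)
  .bump("forward_sweeps")
  drop(S[, tape$output_ids])
}

#' Reverse derivative sweep: t(J) %*% ybar
#'
#' Propagates a reverse seed from outputs to inputs in a single pass; for a
#' scalar function, seeding with 1 yields the full gradient in one sweep
#' regardless of the number of inputs.
#'
#' @param tape a `tt_tape`.
#' @param ybar reverse seed, length `tape$m`.
#' @param at evaluation point (default: nominal input).
#' @return Reverse sensitivity `t(J) %*% ybar`, length `tape$n`.
#' @export
reverse_sweep <- function(tape, ybar, at = NULL) {
  if (length(ybar) != tape$m)
    stop("seed length ", length(ybar), " does not match output dimension ",
         tape$m)
  x <- if (is.null(at)) tape$nominal_in else at
  V <- tape_eval(tape, matrix(x, ncol = 1L))
  P <- tape_partials(tape, V)
  B <- rev_prop(tape, P, as.numeric(ybar), 1L)
  .bump("reverse_sweeps")
  drop(B[, tape$input_ids])
}

#' Full Jacobian of a tape
#'
#' Assembled from `n` forward sweeps when `n <= m`, otherwise from `m` reverse
#' sweeps (mode chosen purely by dimensions).
#'
#' @param tape a `tt_tape`.
#' @param at evaluation point (default: nominal input).
#' @return `m x n` Jacobian matrix.
#' @export
tape_jacobian <- function(tape, at = NULL) {
  x <- if (is.null(at)) tape$nominal_in else at
  V <- tape_eval(tape, matrix(x, ncol = 1L))
  P <- tape_partials(tape, V)
  n <- tape$n; m <- tape$m
  J <- matrix(0, m, n)
  if (n <= m) {
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      J[, j] <- drop(fwd_prop(tape, P, e, 1L)[, tape$output_ids])
      .bump("forward_sweeps")
    }
  } else {
    for (i in seq_len(m)) {
      e <- numeric(m); e[i] <- 1
      J[i, ] <- drop(rev_prop(tape, P, e, 1L)[, tape$input_ids])
      .bump("reverse_sweeps")
    }
  }
  J
}

# Batched sweeps: several seed directions are propagated simultaneously by
# folding them into the evaluation-point dimension (seed block jj occupies
# rows (jj-1)*K + 1:K). This turns per-seed plan traversals into a single
# traversal on wider matrices, which is much faster in R. Chunking bounds
# the memory of the replicated partial matrices.
.sweep_chunk <- function(nn, K, budget = 4e8) {
  max(1L, as.integer(budget / (8 * 3 * max(1, K) * max(1, nn))))
}

fwd_prop_batch <- function(tape, P, seed_dims, K) {
  plan <- tape_plan(tape)
  nn <- plan$nn
  ns <- length(seed_dims)
  rep_idx <- rep(seq_len(K), times = ns)
  D1r <- P$D1[rep_idx, , drop = FALSE]
  D2r <- P$D2[rep_idx, , drop = FALSE]
  S <- matrix(0, K * ns, nn)
  for (jj in seq_len(ns))
    S[(jj - 1L) * K + seq_len(K), tape$input_ids[seed_dims[jj]]] <- 1
  for (s in plan$steps) {
    S[, s$ids] <- D1r[, s$ids, drop = FALSE] * S[, s$p1, drop = FALSE] +
      D2r[, s$ids, drop = FALSE] * S[, s$p2, drop = FALSE]
  }
  .bump("forward_sweeps", ns)
  S
}

rev_prop_batch <- function(tape, P, seed_outs, K) {
  plan <- tape_plan(tape)
  nn <- plan$nn
  ns <- length(seed_outs)
  rep_idx <- rep(seq_len(K), times = ns)
  D1r <- P$D1[rep_idx, , drop = FALSE]
  D2r <- P$D2[rep_idx, , drop = FALSE]
  B <- matrix(0, K * ns, nn)
  for (jj in seq_len(ns))
    B[(jj - 1L) * K + seq_len(K), tape$output_ids[seed_outs[jj]]] <-
      B[(jj - 1L) * K + seq_len(K), tape$output_ids[seed_outs[jj]]] + 1
  for (s in rev(plan$steps)) {
    bb <- B[, s$ids, drop = FALSE]
    cc <- D1r[, s$ids, drop = FALSE] * bb
    acc <- rowsum(t(cc), group = s$p1)
    tgt <- as.integer(rownames(acc))
    B[, tgt] <- B[, tgt] + t(acc)
    if (any(D2r[, s$ids] != 0)) {
      cc2 <- D2r[, s$ids, drop = FALSE] * bb
      acc2 <- rowsum(t(cc2), group = s$p2)
      tgt2 <- as.integer(rownames(acc2))
      B[, tgt2] <- B[, tgt2] + t(acc2)
    }
  }
  .bump("reverse_sweeps", ns)
  B
}

# Vectorized multi-point Jacobians for the NLP callbacks: evaluates the tape
# at the K columns of X and returns all K Jacobians as an (m*n) x K matrix
# (column k = vec of the k-th Jacobian, row-major over (i,j) = (out, in)).
tape_jacobian_multi <- function(tape, X, mode = c("auto", "forward", "reverse")) {
  mode <- match.arg(mode)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  K <- ncol(X)
  V <- tape_eval(tape, X)
  P <- tape_partials(tape, V)
  n <- tape$n; m <- tape$m
  if (mode == "auto") mode <- if (n <= m) "forward" else "reverse"
  out <- matrix(0, m * n, K)
  chunk <- .sweep_chunk(length(tape$op), K)
  if (mode == "forward") {
    for (grp in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
      S <- fwd_prop_batch(tape, P, grp, K)
      for (jj in seq_along(grp)) {
        rows <- (jj - 1L) * K + seq_len(K)
        out[(grp[jj] - 1L) * m + seq_len(m), ] <-
          t(S[rows, tape$output_ids, drop = FALSE])
      }
    }
  } else {
    for (grp in split(seq_len(m), ceiling(seq_len(m) / chunk))) {
      B <- rev_prop_batch(tape, P, grp, K)
      for (jj in seq_along(grp)) {
        rows <- (jj - 1L) * K + seq_len(K)
        idx <- grp[jj] + (seq_len(n) - 1L) * m
        out[idx, ] <- t(B[rows, tape$input_ids, drop = FALSE])
      }
    }
  }
  out
}

# Forward sweeps seeded on a subset of input dimensions, vectorized over the
# K columns of X. Returns an (m * length(dims)) x K matrix, column-major over
# (out, dim) per evaluation point.
tape_jacobian_multi_fwd <- function(tape, X, dims) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  K <- ncol(X)
  V <- tape_eval(tape, X)
  P <- tape_partials(tape, V)
  m <- tape$m
  out <- matrix(0, m * length(dims), K)
  chunk <- .sweep_chunk(length(tape$op), K)
  for (grp in split(seq_along(dims), ceiling(seq_along(dims) / chunk))) {
    S <- fwd_prop_batch(tape, P, dims[grp], K)
    for (jj in seq_along(grp)) {
      rows <- (jj - 1L) * K + seq_len(K)
      out[(grp[jj] - 1L) * m + seq_len(m), ] <-
        t(S[rows, tape$output_ids, drop = FALSE])
    }
  }
  out
}

# Input dimensions that are ancestors of at least one output node; seeds on
# other dimensions produce identically-zero columns and can be skipped.
tape_relevant_inputs <- function(tape) {
  if (!is.null(tape$cache$relevant)) return(tape$cache$relevant)
  nn <- length(tape$op)
  mark <- logical(nn)
  mark[tape$output_ids] <- TRUE
  for (i in rev(seq_len(nn))) {
    if (!mark[i]) next
    if (tape$p1[i] > 0L) mark[tape$p1[i]] <- TRUE
    if (tape$p2[i] > 0L) mark[tape$p2[i]] <- TRUE
  }
  rel <- which(mark[tape$input_ids])
  tape$cache$relevant <- rel
  rel
}

## ---- taped reverse sweep (forward-over-reverse Hessians) ------------------

# Interpret `tape` with overloaded inputs inside the currently active
# recording, then perform reverse accumulation with overloaded arithmetic.
# `w` are the output weights (numeric or adnum). Returns the adnum gradient
# of sum(w * outputs) w.r.t. the tape inputs. This records the reverse sweep
# itself, so a forward sweep of the resulting tape yields exact second
# derivatives.
taped_vjp <- function(tape, xad, w) {
  op <- tape$op; p1 <- tape$p1; p2 <- tape$p2
  nn <- length(op)
  vals <- vector("list", nn)
  isc <- op == "const"
  for (i in which(isc)) vals[[i]] <- tape$val[i]
  for (j in seq_along(tape$input_ids)) vals[[tape$input_ids[j]]] <- xad[j]
  for (i in seq_len(nn)) {
    o <- op[i]
    if (o == "const" || o == "input") next
    a <- vals[[p1[i]]]
    vals[[i]] <- switch(o,
      add = a + vals[[p2[i]]], sub = a - vals[[p2[i]]],
      mul = a * vals[[p2[i]]], div = a / vals[[p2[i]]],
      pow = a ^ vals[[p2[i]]], neg = -a,
      sqrt = sqrt(a), exp = exp(a), log = log(a), sin = sin(a),
      cos = cos(a), tan = tan(a), tanh = tanh(a), atan = atan(a))
  }
  bar <- vector("list", nn)
  live <- rep(FALSE, nn)
  for (j in seq_along(tape$output_ids)) {
    oid <- tape$output_ids[j]
    wj <- w[j]
    bar[[oid]] <- if (live[oid]) bar[[oid]] + wj else wj
    live[oid] <- TRUE
  }
  addbar <- function(id, term) {
    if (isc[id]) return(invisible(NULL))
    if (live[id]) bar[[id]] <<- bar[[id]] + term
    else { bar[[id]] <<- term; live[id] <<- TRUE }
    invisible(NULL)
  }
  for (i in rev(seq_len(nn))) {
    if (!live[i]) next
    o <- op[i]
    if (o == "const" || o == "input") next
    b <- bar[[i]]
    a1 <- p1[i]; a2 <- p2[i]
    switch(o,
      add = { addbar(a1, b); addbar(a2, b) },
      sub = { addbar(a1, b); addbar(a2, -b) },
      mul = { addbar(a1, b * vals[[a2]]); addbar(a2, b * vals[[a1]]) },
      div = { addbar(a1, b / vals[[a2]])
              addbar(a2, -b * vals[[i]] / vals[[a2]]) },
      pow = { addbar(a1, b * vals[[a2]] * vals[[a1]] ^ (vals[[a2]] - 1))
              if (!isc[a2]) addbar(a2, b * vals[[i]] * log(vals[[a1]])) },
      neg = addbar(a1, -b),
      sqrt = addbar(a1, b * 0.5 / vals[[i]]),
      exp = addbar(a1, b * vals[[i]]),
      log = addbar(a1, b / vals[[a1]]),
      sin = addbar(a1, b * cos(vals[[a1]])),
      cos = addbar(a1, -b * sin(vals[[a1]])),
      tan = addbar(a1, b * (1 + vals[[i]] ^ 2)),
      tanh = addbar(a1, b * (1 - vals[[i]] ^ 2)),
      atan = addbar(a1, b / (1 + vals[[a1]] ^ 2)))
  }
  g <- vector("list", tape$n)
  for (j in seq_along(tape$input_ids)) {
    id <- tape$input_ids[j]
    g[[j]] <- if (live[id]) bar[[id]] else 0
  }
  # combine into one adnum vector (numeric entries become constant nodes)
  rec <- active_rec()
  ids <- unlist(lapply(g, function(p) {
    if (inherits(p, "adnum")) p$ids
    else add_nodes(rec, "const", 0L, 0L, as.numeric(p))
  }))
  adnum(ids)
}

#' Record the reverse sweep of a tape as a new tape
#'
#' Produces a tape with inputs `(x, w)` (length `n + m`) and outputs
#' `t(J(x)) %*% w` (length `n`). Forward sweeps over this tape give exact
#' second derivatives of `sum(w * f(x))` (forward-over-reverse).
#'
#' @param tape a `tt_tape`.
#' @param at recording point for `x` (default: the tape's nominal input).
#' @param w0 nominal output weights (default: ones).
#' @return A `tt_tape` of the vector-Jacobian product.
#' @export
record_vjp <- function(tape, at = NULL, w0 = NULL) {
  x0 <- if (is.null(at)) tape$nominal_in else at
  if (is.null(w0)) w0 <- rep(1, tape$m)
  n <- tape$n; m <- tape$m
  record(function(z) taped_vjp(tape, z[seq_len(n)], z[n + seq_len(m)]),
         c(x0, w0))
}

#' Exact Hessian of a Lagrangian by forward-over-reverse sweeps
#'
#' Computes the symmetric matrix of second derivatives of
#' `obj_weight * f + sum(multipliers * g)` where `f` is the (scalar-output)
#' first tape and `g` the concatenated outputs of the remaining tapes. The
#' reverse sweep is itself recorded as a tape, then differentiated by forward
#' sweeps.
#'
#' @param tapes list of `tt_tape`s sharing the same input vector; the first is
#'   the objective (one output), the rest constraints.
#' @param multipliers numeric vector matching the concatenated outputs of
#'   `tapes[-1]`.
#' @param obj_weight scalar weight on the first tape.
#' @param at evaluation point (default: nominal input of the first tape).
#' @return `n x n` symmetric matrix.
#' @export
hessian_lagrangian <- function(tapes, multipliers = numeric(0),
                               obj_weight = 1, at = NULL) {
  if (inherits(tapes, "tt_tape")) tapes <- list(tapes)
  n <- tapes[[1]]$n
  if (any(vapply(tapes, function(t) t$n, 0L) != n))
    stop("all tapes must share the same input vector")
  if (tapes[[1]]$m != 1L) stop("objective tape must have one output")
  mrest <- sum(vapply(tapes[-1], function(t) t$m, 0L))
  if (length(multipliers) != mrest)
    stop("multiplier length does not match constraint outputs")
  x0 <- if (is.null(at)) tapes[[1]]$nominal_in else as.numeric(at)
  gt <- record(function(xad) {
    g <- taped_vjp(tapes[[1]], xad, obj_weight)
    off <- 0L
    for (tp in tapes[-1]) {
      g <- g + taped_vjp(tp, xad, multipliers[off + seq_len(tp$m)])
      off <- off + tp$m
    }
    g
  }, x0)
  H <- tape_jacobian(gt, at = x0)
  asym <- max(abs(H - t(H)))
  if (asym > 1e-8 * (1 + max(abs(H))))
    warning("Hessian asymmetry ", signif(asym, 3))
  (H + t(H)) / 2
}

## ---- finite differences ---------------------------------------------------

#' Finite-difference Jacobian
#'
#' Forward differences use `n + 1` function evaluations; central differences
#' (`2n`) are available as a higher-accuracy oracle. Evaluations are counted
#' in [ad_counters()].
#'
#' @param fn plain numeric function of an n-vector returning an m-vector.
#' @param x evaluation point.
#' @param h step size on the (scaled) variables.
#' @param method `"forward"` (default) or `"central"`.
#' @return `m x n` matrix with attribute `"evals"`, the evaluation count.
#' @export
fd_jacobian <- function(fn, x, h = 1e-6, method = c("forward", "central")) {
  method <- match.arg(method)
  stopifnot(h > 0)
  x <- as.numeric(x)
  n <- length(x)
  evals <- 0L
  f <- function(z) {
    evals <<- evals + 1L
    .bump("fn_evals")
    v <- fn(z)
    if (any(!is.finite(v))) stop("non-finite function value in fd_jacobian")
    v
  }
  if (method == "forward") {
    f0 <- f(x)
    J <- matrix(0, length(f0), n)
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - f0) / h
    }
  } else {
    f0 <- NULL
    J <- NULL
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      col <- (f(xp) - f(xm)) / (2 * h)
      if (is.null(J)) J <- matrix(0, length(col), n)
      J[, j] <- col
    }
  }
  attr(J, "evals") <- evals
  J
}

## ---- serialization --------------------------------------------------------

#' Serialize a tape to JSON
#'
#' Writes the node table (ops, parents, nominal values), the input/output ids
#' and the branch signature in a documented JSON schema, for fixtures and
#' debugging.
#'
#' @param tape a `tt_tape`.
#' @param path optional file path; when `NULL`, the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
tape_to_json <- function(tape, path = NULL) {
  obj <- list(schema = "tapetraj-tape-v1",
              op = tape$op, p1 = tape$p1, p2 = tape$p2,
              val = tape$val,
              input_ids = tape$input_ids, output_ids = tape$output_ids,
              nominal_in = tape$nominal_in, nominal_out = tape$nominal_out,
              branch = lapply(tape$branch, function(b)
                list(op = b$op, aid = b$aid, aval = b$aval,
                     bid = b$bid, bval = b$bval, outcome = b$outcome)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize a tape from JSON
#' @param x JSON string or file path produced by [tape_to_json()].
#' @return A `tt_tape`.
#' @export
tape_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  stopifnot(identical(obj$schema, "tapetraj-tape-v1"))
  tape <- list(op = as.character(obj$op), p1 = as.integer(obj$p1),
               p2 = as.integer(obj$p2), val = as.numeric(obj$val),
               input_ids = as.integer(obj$input_ids),
               output_ids = as.integer(obj$output_ids),
               n = length(obj$input_ids), m = length(obj$output_ids),
               nominal_in = as.numeric(obj$nominal_in),
               nominal_out = as.numeric(obj$nominal_out),
               branch = lapply(obj$branch, function(b)
                 list(op = b$op, aid = as.integer(b$aid),
                      aval = as.numeric(b$aval), bid = as.integer(b$bid),
                      bval = as.numeric(b$bval), outcome = as.logical(b$outcome))),
               cache = new.env(parent = emptyenv()))
  class(tape) <- "tt_tape"
  tape
}
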