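# Benchmark harness: solves problems under the derivative-scenario x Hessian
# grid from multiple seeded initial guesses, screens runs by solution
# fingerprint (only runs that converged to the same optimum are compared) and
# reports per-problem ratios. Wall-clock ratios are hardware-dependent and
# reported informationally; the sweep/evaluation counters expose the cost
# mechanism independently of hardware.

#' Deterministic seeded initial guesses
#'
#' The first guess is always the problem's canonical one (zeros for the
#' pendulum, the quasi-static forward sweep for gait); the rest perturb it
#' uniformly within 10% of the (finite) scaled bound widths.
#'
#' @param ocp a `tt_ocp`.
#' @param nlp its transcription.
#' @param count number of guesses.
#' @param seed RNG seed.
#' @param frac perturbation fraction of the bound width.
#' @return List of decision vectors, all within bounds.
#' @export
make_initial_guesses <- function(ocp, nlp, count = 10, seed = 0,
                                 frac = 0.1) {
  stopifnot(count >= 1)
  z0 <- attr(ocp, "canonical_guess")(nlp)
  out <- list(z0)
  if (count > 1) {
    set.seed(seed)
    w <- nlp$ub - nlp$lb
    fin <- is.finite(w)
    for (k in 2:count) {
      dzm <- numeric(nlp$ntot)
      dzm[fin] <- stats::runif(sum(fin), -frac, frac) * w[fin]
      out[[k]] <- pmin(pmax(z0 + dzm, nlp$lb), nlp$ub)
    }
  }
  out
}

#' Run the derivative-scenario / Hessian-mode benchmark
#'
#' @param problems list of `tt_ocp`s (or a single one).
#' @param N mesh intervals (scalar or per problem).
#' @param scenarios character vector from `"ad"`, `"fd"`.
#' @param hessians character vector from `"exact"`, `"lbfgs"`.
#' @param n_guesses number of seeded initial guesses per problem.
#' @param seed RNG seed for the guesses.
#' @param ... passed to [solve_ocp()].
#' @return List of class `tt_benchmark` with the per-run record table
#'   (`records`) and the fingerprint-screened ratio summary (`ratios`).
#' @export
run_benchmark <- function(problems, N, scenarios = c("ad", "fd"),
                          hessians = c("exact", "lbfgs"),
                          n_guesses = 3, seed = 0, ...) {
  if (inherits(problems, "tt_ocp")) problems <- list(problems)
  if (length(N) == 1L) N <- rep(N, length(problems))
  rec <- list()
  for (pi in seq_along(problems)) {
    ocp <- problems[[pi]]
    pid <- attr(ocp, "problem_id") %||% paste0("problem", pi)
    nlp0 <- transcribe(ocp, N[pi])
    guesses <- make_initial_guesses(ocp, nlp0, n_guesses, seed)
    for (sc in scenarios) for (hs in hessians) {
      if (hs == "exact" && (sc == "fd" || !is.null(ocp$obj_post))) next
      for (gi in seq_along(guesses)) {
        reset_ad_counters()
        sol <- solve_ocp(ocp, N[pi], derivative = sc, hessian = hs,
                         guess = guesses[[gi]], ...)
        cnt <- ad_counters()
        rec[[length(rec) + 1L]] <- data.frame(
          problem = pid, mesh = N[pi], scenario = sc, hessian = hs,
          seed = seed, guess = gi, status = sol$status,
          iterations = sol$iterations, time_s = sol$wall_time,
          grad_time_share = unname(sol$times["grad"]) /
            max(1e-9, sum(sol$times)),
          jac_time_share = unname(sol$times["jac"]) /
            max(1e-9, sum(sol$times)),
          reverse_sweeps = cnt$reverse_sweeps,
          forward_sweeps = cnt$forward_sweeps,
          fn_evals = cnt$fn_evals,
          grad_calls = unname(sol$evals["grad"]),
          objective = sol$objective,
          fingerprint = solution_fingerprint(sol),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  structure(list(records = records,
                 ratios = benchmark_ratios(records)),
            class = "tt_benchmark")
}

# fingerprint-screened ratios of scenario pairs per problem: runs from the
# same initial guess are compared only when they converged to the same
# optimum (matching fingerprints); mismatches are counted and excluded
benchmark_ratios <- function(records) {
  out <- list()
  base <- records[records$scenario == "ad" & records$hessian == "lbfgs", ]
  for (pid in unique(records$problem)) {
    rp <- records[records$problem == pid & records$status == "solved", ]
    bp <- base[base$problem == pid & base$status == "solved", ]
    for (sc in unique(rp$scenario)) for (hs in unique(rp$hessian)) {
      if (sc == "ad" && hs == "lbfgs") next
      cmp <- rp[rp$scenario == sc & rp$hessian == hs, ]
      if (!nrow(cmp) || !nrow(bp)) next
      mg <- merge(cmp, bp, by = "guess", suffixes = c("", ".base"))
      match_fp <- mg$fingerprint == mg$fingerprint.base
      excluded <- sum(!match_fp)
      mg <- mg[match_fp, , drop = FALSE]
      if (!nrow(mg)) {
        out[[length(out) + 1L]] <- data.frame(
          problem = pid, scenario = sc, hessian = hs,
          n = 0L, excluded = excluded, time_ratio = NA, time_ratio_sd = NA,
          iter_ratio = NA, iter_ratio_sd = NA,
          time_per_iter_ratio = NA, stringsAsFactors = FALSE)
        next
      }
      tr <- mg$time_s / mg$time_s.base
      ir <- mg$iterations / mg$iterations.base
      out[[length(out) + 1L]] <- data.frame(
        problem = pid, scenario = sc, hessian = hs,
        n = nrow(mg), excluded = excluded,
        time_ratio = mean(tr), time_ratio_sd = stats::sd(tr),
        iter_ratio = mean(ir), iter_ratio_sd = stats::sd(ir),
        time_per_iter_ratio = mean(tr / ir),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' @export
print.tt_benchmark <- function(x, ...) {
  cat("<tt_benchmark>", nrow(x$records), "runs\n")
  print(x$records[, c("problem", "scenario", "hessian", "guess", "status",
                      "iterations", "time_s", "fn_evals",
                      "reverse_sweeps", "fingerprint")],
        row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\nRatios vs ad/lbfgs (fingerprint-matched runs only):\n")
    print(x$ratios, row.names = FALSE)
  }
  invisible(x)
}

#' Write benchmark records to CSV
#' @param bench a `tt_benchmark`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
benchmark_csv <- function(bench, path) {
  utils::write.csv(bench$records, path, row.names = FALSE)
  invisible(path)
}
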