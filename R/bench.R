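#' Benchmark kernel implementations on a given problem shape
#'
#' Builds a synthetic problem of exactly the requested dimensions (random
#' tree, simulated nucleotide data), runs the identical full wavefront
#' traversal plus root log-likelihood workload under each candidate
#' implementation, and ranks candidates by median wall time over `reps`
#' repetitions after one discarded warm-up run. Before any ranking is
#' returned, all candidates must agree on the log-likelihood bitwise —
#' correctness precedes speed, and selection can never change results.
#'
#' @param patterns,states,categories,tips,subsets problem dimensions.
#'   (Synthetic data generation is nucleotide-based, so `states` must be
#'   4 here; the engine itself is state-count generic.)
#' @param candidates implementations to time.
#' @param reps timed repetitions per candidate (>= 3).
#' @param seed seed for the synthetic problem.
#' @param timer timing function `function(thunk) seconds`; the default
#'   measures elapsed wall time. Injectable for testing.
#' @return an object of class `pw_ranking`: a data frame `entries`
#'   (implementation, median seconds, reps) sorted ascending by time, and
#'   `chosen`, the fastest implementation.
#' @export
benchmark_implementations <- function(patterns, states = 4L,
                                      categories = 4L, tips = 16L,
                                      subsets = 1L,
                                      candidates = c("serial", "vectorized",
                                                     "threaded"),
                                      reps = 5L, seed = 1L, timer = NULL) {
  if (!length(candidates)) pw_stop("candidates must be nonempty")
  if (reps < 3L) pw_stop("reps must be >= 3")
  if (states != 4L)
    pw_stop("benchmark data generation supports 4-state problems")
  if (is.null(timer))
    timer <- function(thunk) {
      t0 <- proc.time()[["elapsed"]]
      thunk()
      proc.time()[["elapsed"]] - t0
    }
  set.seed(seed)
  tree <- random_tree(tips, branch_mean = 0.1)
  model <- build_model("HKY", kappa = 2,
                       frequencies = c(0.3, 0.2, 0.2, 0.3))
  rates <- discretize_gamma(0.5, categories)
  aln <- simulate_alignment(tree, model, rates,
                            site_count = max(patterns, subsets))
  sos <- sort(rep_len(seq_len(subsets), aln$site_count))
  ctx <- likelihood_context(aln, model, rates, partitions = sos)
  workload <- function(impl) context_loglik(ctx, tree, impl = impl)$total

  lnl <- setNames(numeric(length(candidates)), candidates)
  med <- setNames(numeric(length(candidates)), candidates)
  for (cand in candidates) {
    lnl[cand] <- workload(cand)  # warm-up, value kept for the cross-check
    med[cand] <- median(vapply(seq_len(reps),
                               function(i) timer(function() workload(cand)),
                               numeric(1)))
  }
  if (!all(lnl == lnl[[1]]))
    pw_stop("implementations disagree on the log-likelihood; ",
            "refusing to rank")
  ord <- order(med)
  entries <- data.frame(implementation = candidates[ord],
                        median_seconds = unname(med[ord]),
                        reps = reps, row.names = NULL)
  structure(list(entries = entries, chosen = entries$implementation[1],
                 lnl = unname(lnl[[1]])),
            class = "pw_ranking")
}

#' @export
print.pw_ranking <- function(x, ...) {
  cat("<pw_ranking> chosen:", x$chosen, "\n")
  print(x$entries)
  invisible(x)
}

#' Automatic implementation selection
#'
#' Resolves `implementation = "auto"` by benchmarking the available
#' kernels on the exact problem dimensions of the configuration and
#' returning the fastest; the answer is cached per dimension signature
#' for the process lifetime, and any benchmarking failure falls back to
#' the serial kernel.
#'
#' @param config an [instance_config()].
#' @return an implementation id string.
#' @export
auto_select <- function(config) {
  if (config$implementation != "auto") return(config$implementation)
  key <- paste(config$pattern_count, config$state_count,
               config$category_count, config$tip_count,
               config$subset_count, sep = "/")
  hit <- .pw_cache[[key]]
  if (!is.null(hit)) return(hit)
  chosen <- tryCatch(
    benchmark_implementations(patterns = config$pattern_count,
                              states = config$state_count,
                              categories = config$category_count,
                              tips = config$tip_count,
                              subsets = config$subset_count,
                              reps = 5L)$chosen,
    error = function(e) "serial")
  .pw_cache[[key]] <- chosen
  chosen
}
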