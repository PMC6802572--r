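#' Engine instance configuration
#'
#' An instance owns every buffer the likelihood kernels touch: tip data,
#' internal partials, eigensystems, transition-matrix sets, per-subset
#' rate categories and frequencies, pattern weights and per-pattern scale
#' accumulators, all addressed by integer indices. One instance is shared
#' by all partition-defined subsets, whose patterns occupy contiguous
#' ranges of the pattern axis.
#'
#' @param tip_count number of tips.
#' @param pattern_count total site patterns across subsets.
#' @param state_count states per character (4 for nucleotides).
#' @param category_count rate categories per subset.
#' @param subset_count partition-defined subsets sharing the instance.
#' @param partials_buffer_count internal partials buffers (>= tips - 1).
#' @param matrix_buffer_count transition-matrix buffers; default one per
#'   (node, subset).
#' @param scale_buffer_count per-pattern scale accumulators; default one
#'   per internal node plus one accumulation slot.
#' @param implementation `"auto"`, `"serial"`, `"vectorized"`,
#'   `"threaded"`. `"auto"` defers to [auto_select()]. All kernels
#'   produce bitwise-identical double-precision results.
#' @param max_workers `"auto"` (scale with pattern count up to the core
#'   count) or an integer cap for the threaded kernel.
#' @return an `pw_config` list.
#' @export
instance_config <- function(tip_count, pattern_count,
                            state_count = 4L, category_count = 1L,
                            subset_count = 1L,
                            partials_buffer_count = tip_count - 1L,
                            matrix_buffer_count =
                              (2L * tip_count - 1L) * subset_count,
                            scale_buffer_count = tip_count,
                            implementation = c("auto", "serial",
                                               "vectorized", "threaded"),
                            max_workers = "auto") {
  implementation <- match.arg(implementation)
  cfg <- list(tip_count = as.integer(tip_count),
              pattern_count = as.integer(pattern_count),
              state_count = as.integer(state_count),
              category_count = as.integer(category_count),
              subset_count = as.integer(subset_count),
              partials_buffer_count = as.integer(partials_buffer_count),
              matrix_buffer_count = as.integer(matrix_buffer_count),
              scale_buffer_count = as.integer(scale_buffer_count),
              implementation = implementation,
              max_workers = max_workers)
  with(cfg, {
    if (tip_count < 2) pw_stop("tip_count must be >= 2")
    if (pattern_count < 1) pw_stop("pattern_count must be >= 1")
    if (state_count < 2) pw_stop("state_count must be >= 2")
    if (category_count < 1) pw_stop("category_count must be >= 1")
    if (subset_count < 1) pw_stop("subset_count must be >= 1")
    if (partials_buffer_count < tip_count - 1L)
      pw_stop("partials_buffer_count must be >= tip_count - 1")
  })
  structure(cfg, class = "pw_config")
}

#' Create an engine instance
#'
#' Allocates and zeroes every buffer described by the configuration.
#' Buffers are mutated in place by the kernels; an instance is therefore
#' an environment, not a value.
#' @param config an [instance_config()].
#' @return an object of class `pw_instance`.
#' @export
create_instance <- function(config) {
  stopifnot(inherits(config, "pw_config"))
  S <- config$state_count; C <- config$category_count
  P <- config$pattern_count
  inst <- new.env(parent = emptyenv())
  inst$config <- config
  inst$tips <- vector("list", config$tip_count)
  inst$tip_type <- rep(NA_integer_, config$tip_count)
  inst$partials <- lapply(seq_len(config$partials_buffer_count),
                          function(i) numeric(S * C * P))
  inst$partials_written <- logical(config$partials_buffer_count)
  inst$eigens <- vector("list", config$subset_count)
  inst$rates <- vector("list", config$subset_count)
  inst$freqs <- vector("list", config$subset_count)
  inst$matrices <- vector("list", config$matrix_buffer_count)
  inst$pattern_weights <- rep(1, P)
  inst$subset_ranges <- matrix(c(1L, P), 1)
  inst$scales <- lapply(seq_len(config$scale_buffer_count),
                        function(i) numeric(P))
  inst$matrix_stride <- 2L * config$tip_count - 1L
  class(inst) <- "pw_instance"
  inst
}

#' @export
print.pw_instance <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pw_instance: %d tips, %d patterns, S=%d, C=%d, %d subset(s), impl=%s>\n",
    cfg$tip_count, cfg$pattern_count, cfg$state_count,
    cfg$category_count, cfg$subset_count, cfg$implementation))
  invisible(x)
}

#' Populate an instance's data slots
#'
#' Sets tip buffers, per-subset eigensystems, rate categories and
#' frequencies, pattern weights and the subset layout. Re-setting an
#' eigensystem or rate slot invalidates the transition matrices that
#' depended on it.
#'
#' @param instance a `pw_instance`.
#' @param tips list of encoded tip payloads (see [encode_tip()]), indexed
#'   by tip id.
#' @param eigen a `pw_eigen` or a list of one per subset.
#' @param rates a `pw_rates` or a list of one per subset.
#' @param frequencies a frequency vector or a list of one per subset.
#' @param pattern_weights numeric vector of per-pattern site counts.
#' @param subset_ranges `K x 2` matrix of 1-based inclusive pattern
#'   ranges, one row per subset.
#' @return the instance, invisibly.
#' @export
set_instance_data <- function(instance, tips = NULL, eigen = NULL,
                              rates = NULL, frequencies = NULL,
                              pattern_weights = NULL,
                              subset_ranges = NULL) {
  cfg <- instance$config
  S <- cfg$state_count; P <- cfg$pattern_count; K <- cfg$subset_count
  if (!is.null(tips)) {
    if (length(tips) != cfg$tip_count)
      pw_stop("tips: expected ", cfg$tip_count, " payloads")
    for (k in seq_along(tips)) {
      tp <- tips[[k]]
      if (is.matrix(tp)) {
        if (nrow(tp) != S || ncol(tp) != P)
          pw_stop("tips: payload ", k, " must be ", S, " x ", P)
        instance$tip_type[k] <- 1L
      } else {
        tp <- as.integer(tp)
        if (length(tp) != P)
          pw_stop("tips: payload ", k, " must have length ", P)
        instance$tip_type[k] <- 0L
      }
      instance$tips[[k]] <- tp
    }
  }
  as_per_subset <- function(x, what) {
    if (is.null(x)) return(NULL)
    lst <- if (inherits(x, c("pw_eigen", "pw_rates")) || !is.list(x))
      rep(list(x), K) else x
    if (length(lst) != K) pw_stop(what, ": expected one per subset (", K, ")")
    lst
  }
  reset_matrices <- FALSE
  ei <- as_per_subset(eigen, "eigen")
  if (!is.null(ei)) { instance$eigens <- ei; reset_matrices <- TRUE }
  ra <- as_per_subset(rates, "rates")
  if (!is.null(ra)) {
    if (any(vapply(ra, function(r) length(r$rates), 1L) != cfg$category_count))
      pw_stop("rates: category count must be ", cfg$category_count)
    instance$rates <- ra
    reset_matrices <- TRUE
  }
  fr <- if (is.list(frequencies) && !is.null(frequencies)) frequencies
        else if (!is.null(frequencies)) rep(list(frequencies), K)
  if (!is.null(fr)) {
    if (length(fr) != K) pw_stop("frequencies: expected one per subset")
    if (any(vapply(fr, length, 1L) != S))
      pw_stop("frequencies: each must have length ", S)
    instance$freqs <- fr
  }
  if (!is.null(pattern_weights)) {
    if (length(pattern_weights) != P)
      pw_stop("pattern_weights: expected length ", P)
    instance$pattern_weights <- as.numeric(pattern_weights)
  }
  if (!is.null(subset_ranges)) {
    sr <- matrix(as.integer(subset_ranges), ncol = 2)
    if (nrow(sr) != K) pw_stop("subset_ranges: expected ", K, " rows")
    if (sr[1, 1] != 1L || sr[nrow(sr), 2] != P ||
        (K > 1 && any(sr[-1, 1] != sr[-K, 2] + 1L)))
      pw_stop("subset_ranges must be contiguous and cover all patterns")
    instance$subset_ranges <- sr
  }
  if (reset_matrices)
    instance$matrices <- vector("list", cfg$matrix_buffer_count)
  invisible(instance)
}

#' Fill transition-matrix buffers for one subset
#'
#' Computes `P(t, c)` (and optionally first/second derivative matrices)
#' for the given branch lengths from the subset's eigensystem and rate
#' categories, storing them in the named matrix buffers.
#'
#' @param instance a `pw_instance`.
#' @param subset_index subset whose eigensystem/rates to use.
#' @param edge_lengths branch lengths (>= 0).
#' @param matrix_indices destination buffer index per edge.
#' @param want_derivatives also fill `dP/dt`, `d2P/dt2`.
#' @export
update_transition_matrices <- function(instance, subset_index,
                                       edge_lengths, matrix_indices,
                                       want_derivatives = FALSE) {
  cfg <- instance$config
  ei <- instance$eigens[[subset_index]]
  if (is.null(ei)) pw_stop("eigen slot ", subset_index, " is unset")
  ra <- instance$rates[[subset_index]]
  if (is.null(ra)) pw_stop("rate slot ", subset_index, " is unset")
  if (any(matrix_indices < 1 | matrix_indices > cfg$matrix_buffer_count))
    pw_stop("matrix index out of range")
  tm <- compute_transition_matrices(ei, ra, edge_lengths,
                                    want_derivatives = want_derivatives)
  for (j in seq_along(matrix_indices))
    instance$matrices[[matrix_indices[j]]] <- tm[[j]]
  invisible(instance)
}

# Resolve a node id to (type, data) for the kernels.
resolve_buffer <- function(instance, node) {
  n <- instance$config$tip_count
  if (node <= n) {
    tp <- instance$tips[[node]]
    if (is.null(tp)) pw_stop("tip buffer ", node, " is unset")
    list(type = instance$tip_type[node], data = tp)
  } else {
    k <- node - n
    if (!instance$partials_written[k])
      pw_stop("reading unwritten partials buffer for node ", node)
    list(type = 2L, data = instance$partials[[k]])
  }
}

resolve_workers <- function(pattern_count, max_workers) {
  base <- max(1L, as.integer(ceiling(pattern_count / 512)))
  cap <- if (identical(max_workers, "auto"))
    parallel::detectCores() else as.integer(max_workers)
  max(1L, min(base, cap))
}

resolve_implementation <- function(instance) {
  impl <- instance$config$implementation
  if (impl == "auto") {
    if (is.null(instance$impl_resolved))
      instance$impl_resolved <- auto_select(instance$config)
    impl <- instance$impl_resolved
  }
  impl
}

#' Execute partial-likelihood operations
#'
#' Runs a traversal plan (a [plan_postorder()] operation list or a
#' [plan_wavefront()]/[plan_partitioned()] wave plan) against the
#' instance. Each operation combines its two children through their
#' transition matrices into the destination partials. With
#' `rescale = "always"`, after each operation the destination partials of
#' every pattern are divided by their maximum entry across states and
#' categories (when positive) and the log of that maximum is accumulated
#' in the destination's scale buffer. Results are identical — bitwise —
#' whichever kernel implementation executes the plan.
#'
#' @param instance a `pw_instance`.
#' @param plan operation list or `pw_waveplan`.
#' @param rescale `"none"` or `"always"`.
#' @export
update_partials <- function(instance, plan, rescale = c("none", "always")) {
  rescale <- match.arg(rescale)
  cfg <- instance$config
  S <- cfg$state_count; C <- cfg$category_count
  K <- cfg$subset_count
  n <- cfg$tip_count
  impl <- resolve_implementation(instance)
  workers <- if (impl == "threaded")
    resolve_workers(cfg$pattern_count, cfg$max_workers) else 1L
  ops <- flatten_plan(plan)
  do_scale <- rescale == "always"
  if (do_scale) {
    dests <- unique(vapply(ops, function(op) op$dest, 1L)) - n
    for (k in dests) instance$scales[[k]] <- numeric(cfg$pattern_count)
  }
  for (op in ops) {
    subsets <- if (identical(op$subset, "all")) seq_len(K) else op$subset
    dk <- op$dest - n
    dest <- instance$partials[[dk]]
    scale_buf <- if (do_scale) instance$scales[[dk]] else NULL
    for (s in subsets) {
      off <- (s - 1L) * instance$matrix_stride
      m1 <- instance$matrices[[off + op$child1_matrix]]
      m2 <- instance$matrices[[off + op$child2_matrix]]
      if (is.null(m1) || is.null(m2))
        pw_stop("transition matrices unset for operation at node ", op$dest,
                " (subset ", s, ")")
      c1 <- resolve_buffer(instance, op$child1)
      c2 <- resolve_buffer(instance, op$child2)
      rg <- instance$subset_ranges[s, ]
      update_partials_cpp(dest, c1$type, c1$data, m1$P,
                          c2$type, c2$data, m2$P,
                          S, C, rg[1] - 1L, rg[2],
                          do_scale, scale_buf, impl, workers)
    }
    instance$partials_written[dk] <- TRUE
  }
  invisible(instance)
}

#' Sum per-pattern log scale factors
#'
#' Writes `destination[p] = sum` of the listed scale buffers at pattern
#' `p`; with an empty list the destination is zeroed.
#' @param instance a `pw_instance`.
#' @param scale_indices buffers to accumulate (may be empty).
#' @param destination destination buffer index.
#' @export
accumulate_scale_factors <- function(instance, scale_indices, destination) {
  cfg <- instance$config
  idx <- as.integer(scale_indices)
  if (any(idx < 1 | idx > cfg$scale_buffer_count) ||
      destination < 1 || destination > cfg$scale_buffer_count)
    pw_stop("scale buffer index out of range")
  acc <- numeric(cfg$pattern_count)
  for (k in idx) acc <- acc + instance$scales[[k]]
  instance$scales[[destination]] <- acc
  invisible(instance)
}

#' Root log-likelihood
#'
#' Per pattern, the site likelihood integrates the root partials over
#' rate categories and equilibrium frequencies:
#' `L_p = sum_i pi_i sum_c w_c root[p,c,i]`; the site log-likelihood adds
#' the accumulated log scale factor. Subset log-likelihoods are the
#' pattern-weighted sums over each subset's range, and the total is their
#' sum. A zero site likelihood yields `-Inf` with the offending patterns
#' reported in `$underflow`, not an error.
#'
#' @param instance a `pw_instance`.
#' @param root_node the root's node id (its partials buffer is used).
#' @param scale_index accumulated scale buffer index, or `NA` for none.
#' @param want_site_lnl also return per-pattern site log-likelihoods.
#' @return an object of class `pw_lik`: `total`, `per_subset`, optional
#'   `site_lnl`, `underflow` (pattern indices with zero likelihood).
#' @export
calculate_root_log_likelihood <- function(instance, root_node,
                                          scale_index = NA,
                                          want_site_lnl = FALSE) {
  cfg <- instance$config
  n <- cfg$tip_count
  root <- instance$partials[[root_node - n]]
  scale <- if (is.na(scale_index)) NULL else instance$scales[[scale_index]]
  K <- cfg$subset_count
  per_subset <- numeric(K)
  site <- numeric(cfg$pattern_count)
  for (s in seq_len(K)) {
    rg <- instance$subset_ranges[s, ]
    sl <- root_site_lnl_cpp(root, cfg$state_count, cfg$category_count,
                            rg[1] - 1L, rg[2],
                            instance$freqs[[s]],
                            instance$rates[[s]]$weights, scale)
    site[rg[1]:rg[2]] <- sl
    per_subset[s] <- sum(instance$pattern_weights[rg[1]:rg[2]] * sl)
  }
  structure(list(total = sum(per_subset), per_subset = per_subset,
                 site_lnl = if (want_site_lnl) site else NULL,
                 underflow = which(is.infinite(site) & site < 0)),
            class = "pw_lik")
}

#' @export
print.pw_lik <- function(x, ...) {
  cat(sprintf("<pw_lik: total lnL = %.6f>\n", x$total))
  if (length(x$per_subset) > 1)
    cat("  per subset:", paste(sprintf("%.4f", x$per_subset),
                               collapse = " "), "\n")
  if (!is.null(x$d1)) cat(sprintf("  d1 = %.6g, d2 = %.6g\n", x$d1, x$d2))
  invisible(x)
}

#' Edge log-likelihood with branch-length derivatives
#'
#' Evaluates the likelihood factorised across one edge:
#' `L_p = sum_c w_c sum_i pi_i parent[p,c,i] (sum_j P[c,i,j] child[p,c,j])`,
#' where `parent` holds the partials of the tree minus the child subtree
#' (formed by the caller rerooting toward the edge; see [edge_loglik()]).
#' The first and second derivatives with respect to the edge length
#' replace `P` with its derivative matrices and combine per pattern as
#' `d1 = sum_p w_p L'_p/L_p` and
#' `d2 = sum_p w_p (L''_p/L_p - (L'_p/L_p)^2)`.
#'
#' @param instance a `pw_instance`.
#' @param parent_node node whose partials hold the complement ("outside")
#'   of the child subtree.
#' @param child_node the child-side node (tip or internal).
#' @param matrix_node base matrix buffer index for the edge (offset per
#'   subset internally).
#' @param scale_index accumulated scale buffer or `NA`.
#' @param want_derivatives compute `d1`, `d2` (requires derivative
#'   matrices in the buffers).
#' @return a `pw_lik` with `d1` and `d2` fields when requested.
#' @export
calculate_edge_log_likelihood <- function(instance, parent_node, child_node,
                                          matrix_node, scale_index = NA,
                                          want_derivatives = TRUE) {
  cfg <- instance$config
  n <- cfg$tip_count
  parent <- instance$partials[[parent_node - n]]
  child <- resolve_buffer(instance, child_node)
  scale <- if (is.na(scale_index)) NULL else instance$scales[[scale_index]]
  K <- cfg$subset_count
  per_subset <- numeric(K)
  d1 <- 0; d2 <- 0
  for (s in seq_len(K)) {
    off <- (s - 1L) * instance$matrix_stride
    m <- instance$matrices[[off + matrix_node]]
    if (is.null(m)) pw_stop("transition matrices unset for edge buffer")
    if (want_derivatives && (is.null(m$d1) || is.null(m$d2)))
      pw_stop("derivative matrices missing; recompute with want_derivatives")
    rg <- instance$subset_ranges[s, ]
    res <- edge_site_terms_cpp(parent, child$type, child$data,
                               m$P, m$d1, m$d2,
                               cfg$state_count, cfg$category_count,
                               rg[1] - 1L, rg[2],
                               instance$freqs[[s]],
                               instance$rates[[s]]$weights,
                               scale, want_derivatives)
    w <- instance$pattern_weights[rg[1]:rg[2]]
    per_subset[s] <- sum(w * res$site_lnl)
    if (want_derivatives) {
      d1 <- d1 + sum(w * res$r1)
      d2 <- d2 + sum(w * (res$r2 - res$r1^2))
    }
  }
  structure(list(total = sum(per_subset), per_subset = per_subset,
                 d1 = if (want_derivatives) d1 else NULL,
                 d2 = if (want_derivatives) d2 else NULL),
            class = "pw_lik")
}
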