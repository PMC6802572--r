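#' Assemble a likelihood evaluation context
#'
#' Bundles everything that does not depend on the tree: compressed
#' patterns, per-subset models, eigensystems, rate categories and
#' frequencies, and encoded tip buffers. The same context can then be
#' evaluated against any tree over the same taxa (e.g. rerootings), which
#' is how the engine is meant to be driven by tree-search clients.
#'
#' Tips whose sequences contain partial-ambiguity IUPAC codes (e.g. `R`)
#' are automatically encoded as tip partials; fully resolved or fully
#' missing characters use the compact state-index fast path.
#'
#' @param data a `pw_alignment` or `pw_patterns`.
#' @param models a `pw_model` or list of one per subset.
#' @param rates a `pw_rates` or list of one per subset (default: a single
#'   unit-rate category).
#' @param partitions optional site-to-subset assignment: an integer
#'   vector (one subset id per site) or the result of
#'   [read_partition_config()]. Ignored when `data` is already compressed.
#' @param subset_rates optional relative rate multiplier per subset
#'   (branch lengths are scaled by it for that subset's matrices).
#' @param frequencies optional root/equilibrium frequencies overriding
#'   the model's (a vector or list per subset).
#' @return an object of class `pw_context`.
#' @export
likelihood_context <- function(data, models, rates = NULL,
                               partitions = NULL, subset_rates = NULL,
                               frequencies = NULL) {
  if (inherits(data, "pw_alignment")) {
    sos <- if (is.list(partitions)) partitions$subset_of_site else partitions
    patterns <- compress_patterns(data, sos)
  } else if (inherits(data, "pw_patterns")) {
    patterns <- data
  } else pw_stop("data must be a pw_alignment or pw_patterns")

  K <- nrow(patterns$subset_ranges)
  as_list <- function(x, what) {
    lst <- if (is.list(x) && !inherits(x, c("pw_model", "pw_rates"))) x
           else rep(list(x), K)
    if (length(lst) != K) pw_stop(what, ": expected one per subset (", K, ")")
    lst
  }
  models <- as_list(models, "models")
  rates <- as_list(if (is.null(rates)) rate_categories(1) else rates, "rates")
  freqs <- if (is.null(frequencies))
    lapply(models, `[[`, "frequencies") else as_list(frequencies, "frequencies")
  if (is.null(subset_rates)) subset_rates <- rep(1, K)
  if (length(subset_rates) != K) pw_stop("subset_rates: expected one per subset")
  eigens <- lapply(models, eigendecompose)

  n <- nrow(patterns$patterns)
  tips <- vector("list", n)
  for (k in seq_len(n)) {
    seqk <- patterns$patterns[k, ]
    mode <- if (needs_partials(paste(seqk, collapse = ""),
                               patterns$alphabet)) "partial" else "compact"
    tips[[k]] <- encode_tip(seqk, mode, patterns$alphabet)
  }
  structure(list(patterns = patterns, models = models, rates = rates,
                 freqs = freqs, eigens = eigens,
                 subset_rates = as.numeric(subset_rates), tips = tips,
                 n_subsets = K),
            class = "pw_context")
}

# Build and populate an instance for a context + tree; fills transition
# matrices for every non-root node (per subset).
context_instance <- function(ctx, tree, impl = "serial",
                             max_workers = "auto",
                             want_derivatives = FALSE) {
  pat <- ctx$patterns
  if (!identical(tree$tip_labels, pat$taxon_names))
    pw_stop("tree taxa do not match the alignment taxon order")
  n <- tree$n_tips
  K <- ctx$n_subsets
  C <- length(ctx$rates[[1]]$rates)
  S <- length(pat$alphabet$states)
  cfg <- instance_config(tip_count = n, pattern_count = ncol(pat$patterns),
                         state_count = S, category_count = C,
                         subset_count = K,
                         scale_buffer_count = n, # n-1 internals + 1 accumulator
                         implementation = impl, max_workers = max_workers)
  inst <- create_instance(cfg)
  set_instance_data(inst, tips = ctx$tips, eigen = ctx$eigens,
                    rates = ctx$rates, frequencies = ctx$freqs,
                    pattern_weights = pat$weights,
                    subset_ranges = pat$subset_ranges)
  nodes <- seq_len(2L * n - 2L)
  for (s in seq_len(K))
    update_transition_matrices(
      inst, s,
      edge_lengths = tree$edge_length[nodes] * ctx$subset_rates[s],
      matrix_indices = (s - 1L) * inst$matrix_stride + nodes,
      want_derivatives = want_derivatives)
  inst
}

#' Tree log-likelihood
#'
#' One-call evaluation of the pruning-algorithm log-likelihood of an
#' alignment on a tree: compresses site patterns (per partition subset),
#' encodes tips, schedules the traversal, runs the partials kernels and
#' integrates at the root. This is the main user entry point; the
#' buffer-level API ([create_instance()] and friends) exposes every
#' intermediate step for clients that manage their own traversals.
#'
#' @inheritParams likelihood_context
#' @param data a `pw_alignment` or `pw_patterns`.
#' @param tree a `pw_tree` over the same taxa (in the same order).
#' @param rescale `"none"` or `"always"` (per-pattern rescaling with log
#'   scale-factor bookkeeping; needed for large trees where raw partials
#'   underflow).
#' @param plan `"wavefront"` (reverse level-order batches) or
#'   `"postorder"`; both give identical results.
#' @param impl kernel implementation (`"auto"` benchmarks and picks).
#' @param max_workers worker cap for the threaded kernel.
#' @param want_site_lnl return per-pattern site log-likelihoods.
#' @return a `pw_lik` (see [calculate_root_log_likelihood()]).
#' @examples
#' aln <- alignment(c("A", "B", "C"), c("ACGT", "ACGA", "ACTA"))
#' tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.2);", taxa = aln$taxon_names)
#' tree_loglik(aln, tr, build_model("JC"))$total
#' @export
tree_loglik <- function(data, tree, models, rates = NULL,
                        partitions = NULL, subset_rates = NULL,
                        frequencies = NULL,
                        rescale = c("none", "always"),
                        plan = c("wavefront", "postorder"),
                        impl = c("serial", "auto", "vectorized", "threaded"),
                        max_workers = "auto",
                        want_site_lnl = FALSE) {
  ctx <- if (inherits(data, "pw_context")) data
         else likelihood_context(data, models, rates, partitions,
                                 subset_rates, frequencies)
  context_loglik(ctx, tree, rescale = match.arg(rescale),
                 plan = match.arg(plan), impl = match.arg(impl),
                 max_workers = max_workers, want_site_lnl = want_site_lnl)
}

#' Evaluate a context on a tree
#' @param ctx a [likelihood_context()].
#' @inheritParams tree_loglik
#' @export
context_loglik <- function(ctx, tree, rescale = c("none", "always"),
                           plan = c("wavefront", "postorder"),
                           impl = "serial", max_workers = "auto",
                           want_site_lnl = FALSE) {
  rescale <- match.arg(rescale)
  plan <- match.arg(plan)
  inst <- context_instance(ctx, tree, impl = impl, max_workers = max_workers)
  n <- tree$n_tips
  pl <- if (plan == "wavefront") plan_partitioned(tree, ctx$n_subsets)
        else plan_postorder(tree)
  update_partials(inst, pl, rescale = rescale)
  scale_index <- NA
  if (rescale == "always") {
    scale_index <- n # accumulator slot
    accumulate_scale_factors(inst, seq_len(n - 1L), scale_index)
  }
  calculate_root_log_likelihood(inst, root_node = 2L * n - 1L,
                                scale_index = scale_index,
                                want_site_lnl = want_site_lnl)
}

# Expand a tip payload to the internal (state, category, pattern) layout.
tip_as_internal <- function(payload, type, S, C) {
  m <- if (type == 0L) {
    out <- matrix(0, S, length(payload))
    for (p in seq_along(payload)) {
      s <- payload[p]
      if (s >= 0L && s < S) out[s + 1L, p] <- 1 else out[, p] <- 1
    }
    out
  } else payload
  as.numeric(m[, rep(seq_len(ncol(m)), each = C)])
}

#' Edge log-likelihood and branch-length derivatives
#'
#' Computes the total log-likelihood factorised across the (unrooted)
#' edge above `node`, together with the first and second derivatives of
#' the log-likelihood with respect to that edge's length. The tree is
#' rerooted at the parent end of the edge (placing the full edge length
#' on the child side), a traversal computes the child-subtree partials
#' and the complement ("outside") partials, and the edge kernel combines
#' them through `P(t)`, `dP/dt` and `d2P/dt2`. If `node`'s parent is the
#' root, the edge is the merged root edge and the derivative is with
#' respect to its total length.
#'
#' @inheritParams tree_loglik
#' @param node the child-end node of the edge (any non-root node).
#' @param want_derivatives compute `d1`, `d2`.
#' @return a `pw_lik` with `d1`/`d2` and the edge length used (`$t`).
#' @export
edge_loglik <- function(data, tree, models, rates = NULL,
                        partitions = NULL, subset_rates = NULL,
                        frequencies = NULL, node,
                        rescale = c("none", "always"),
                        impl = "serial", max_workers = "auto",
                        want_derivatives = TRUE) {
  rescale <- match.arg(rescale)
  ctx <- if (inherits(data, "pw_context")) data
         else likelihood_context(data, models, rates, partitions,
                                 subset_rates, frequencies)
  n <- tree$n_tips
  rk <- tree$children[tree$root, ]
  t_edge <- if (node %in% rk)
    sum(tree$edge_length[rk]) else tree$edge_length[node]
  rtree <- reroot_tree(tree, node, split = c(t_edge, 0))
  # after rerooting, root child 1 is the queried subtree, child 2 the rest
  inst <- context_instance(ctx, rtree, impl = impl,
                           max_workers = max_workers,
                           want_derivatives = want_derivatives)
  update_partials(inst, plan_partitioned(rtree, ctx$n_subsets),
                  rescale = rescale)
  scale_index <- NA
  if (rescale == "always") {
    scale_index <- n
    # every internal node except the root contributes to one side
    accumulate_scale_factors(inst, setdiff(seq_len(n - 1L), n - 1L),
                             scale_index)
  }
  ch <- rtree$children[rtree$root, ]
  child_node <- ch[1]; parent_node <- ch[2]
  cfg <- inst$config
  if (parent_node <= n) {
    # complement side is a bare tip: expand it to the internal layout
    pb <- tip_as_internal(inst$tips[[parent_node]],
                          inst$tip_type[parent_node],
                          cfg$state_count, cfg$category_count)
    k <- cfg$partials_buffer_count
    inst$partials[[k]] <- pb
    inst$partials_written[k] <- TRUE
    parent_node <- n + k
  }
  res <- calculate_edge_log_likelihood(inst, parent_node, child_node,
                                       matrix_node = child_node,
                                       scale_index = scale_index,
                                       want_derivatives = want_derivatives)
  res$t <- t_edge
  res
}
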