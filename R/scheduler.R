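#' Traversal plans for partial-likelihood operations
#'
#' A partial-likelihood operation computes one internal node's partials
#' from its two children. `plan_postorder()` emits the classic one-at-a-
#' time postorder sequence. `plan_wavefront()` groups operations into
#' reverse level-order *waves*: wave `k` holds exactly the internal nodes
#' at height `k` above the tips (height = longest path to a descendant
#' tip, counting internal nodes), so every operation in a wave has all its
#' inputs ready and the waves are batches of mutually independent work.
#' Executing the waves in order is a valid dependency-respecting schedule,
#' and the number of waves equals the internal-node height of the tree.
#'
#' Each operation is a list with `dest` (internal node id; its partials
#' buffer and scale buffer), `child1`/`child2` (node ids), `child1_matrix`/
#' `child2_matrix` (transition-matrix indices = child node ids, offset per
#' subset at execution), and `subset` (subset index or `"all"`).
#'
#' @param tree a `pw_tree`.
#' @return `plan_postorder()`: a list of operations. `plan_wavefront()`
#'   and `plan_partitioned()`: an object of class `pw_waveplan` whose
#'   `waves` element is an ordered list of operation batches.
#' @examples
#' tr <- balanced_tree(4)
#' length(plan_wavefront(tr)$waves)   # 2
#' @export
plan_postorder <- function(tree) {
  lapply(postorder_internal(tree), function(v) make_op(tree, v, "all"))
}

make_op <- function(tree, v, subset) {
  k <- tree$children[v, ]
  list(dest = v, child1 = k[1], child2 = k[2],
       child1_matrix = k[1], child2_matrix = k[2],
       subset = subset)
}

#' @rdname plan_postorder
#' @export
plan_wavefront <- function(tree) {
  plan_partitioned(tree, 1L)
}

#' @rdname plan_postorder
#' @param subset_count number of partition-defined subsets; the per-subset
#'   operations of a node level are merged into one wave (subset-major
#'   order), so subsets are evaluated concurrently rather than in
#'   sequence.
#' @export
plan_partitioned <- function(tree, subset_count = 1L) {
  if (subset_count < 1) pw_stop("subset_count must be >= 1")
  h <- node_heights(tree)
  internal <- (tree$n_tips + 1L):(2L * tree$n_tips - 1L)
  waves <- lapply(seq_len(max(h)), function(k) {
    nodes <- sort(internal[h[internal] == k])
    ops <- list()
    for (s in seq_len(subset_count))
      for (v in nodes)
        ops[[length(ops) + 1L]] <- make_op(tree, v, if (subset_count == 1L) "all" else s)
    ops
  })
  structure(list(waves = waves, n_tips = tree$n_tips,
                 subset_count = subset_count),
            class = "pw_waveplan")
}

#' @export
print.pw_waveplan <- function(x, ...) {
  sizes <- vapply(x$waves, length, integer(1))
  cat(sprintf("<pw_waveplan: %d waves, sizes [%s]>\n",
              length(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}

flatten_plan <- function(plan) {
  if (inherits(plan, "pw_waveplan")) do.call(c, plan$waves) else plan
}

#' Serialise a wave plan as JSON
#' @param plan a `pw_waveplan`.
#' @export
waveplan_json <- function(plan) {
  jsonlite::toJSON(lapply(plan$waves, function(w) {
    lapply(w, function(op) op[c("dest", "child1", "child2",
                                "child1_matrix", "child2_matrix", "subset")])
  }), auto_unbox = TRUE, pretty = TRUE)
}

#' Reroot a tree to minimise the number of traversal waves
#'
#' For a reversible model the likelihood does not depend on where the
#' (unrooted) tree is rooted, but the wavefront schedule does: the wave
#' count is the internal-node height of the rooted tree. This searches all
#' `2n-3` edge rootings exhaustively (each candidate's height is computed
#' in linear time), returning the rooting with the fewest waves; ties go
#' to the lowest candidate edge index (candidates enumerated in node-id
#' order). A caterpillar rooted at one end, for example, drops from `n-1`
#' waves to about `n/2`.
#'
#' @param tree a `pw_tree`.
#' @return the rerooted `pw_tree` (possibly an equivalent rerooting with
#'   the same wave count as the input if no rooting improves on it).
#' @export
reroot_for_concurrency <- function(tree) {
  cands <- candidate_edge_nodes(tree)
  best <- NULL
  best_h <- Inf
  for (v in cands) {
    tr2 <- reroot_tree(tree, v)
    h <- max(node_heights(tr2))
    if (h < best_h) {
      best_h <- h
      best <- tr2
    }
  }
  best
}

# Candidate edge representatives: one node per unrooted edge, in node-id
# order. The second root child duplicates the first's merged edge.
candidate_edge_nodes <- function(tree) {
  rk <- tree$children[tree$root, ]
  setdiff(seq_len(2L * tree$n_tips - 2L), rk[2])
}
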