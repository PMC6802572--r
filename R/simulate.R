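#' Uniform random trees
#'
#' Grows a rooted binary topology by attaching each successive tip to a
#' uniformly chosen attachment point (any existing edge, or above the
#' root). Every rooted labeled topology on `n` tips is produced with
#' equal probability `1/(2n-3)!!`, and since each unrooted topology has
#' exactly `2n-3` rootings this induces the uniform distribution over
#' labeled unrooted topologies as well. Branch lengths are i.i.d.
#' exponential with the given mean. Fully deterministic for a fixed seed.
#'
#' @param otu_count number of tips (>= 2).
#' @param branch_mean mean branch length (expected substitutions/site).
#' @param seed optional integer seed.
#' @return a `pw_tree` with tip labels `t1..tN`.
#' @export
random_tree <- function(otu_count, branch_mean = 0.1, seed = NULL) {
  n <- as.integer(otu_count)
  if (is.na(n) || n < 2) pw_stop("otu_count must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  nxt <- n + 1L
  parent <- c(nxt, nxt); child <- c(1L, 2L)  # cherry on tips 1, 2
  root <- nxt
  for (k in seq_len(n - 2L) + 2L) {
    pick <- sample.int(length(parent) + 1L, 1L)
    nxt <- nxt + 1L
    if (pick <= length(parent)) {
      # split edge `pick`: new node nxt takes its child slot
      parent <- c(parent, nxt, nxt)
      child <- c(child, child[pick], k)
      child[pick] <- nxt
    } else {
      # attach above the root
      parent <- c(parent, nxt, nxt)
      child <- c(child, root, k)
      root <- nxt
    }
  }
  len <- rexp(length(parent), rate = 1 / branch_mean)
  tree_from_edges(parent, child, len, seq_len(n), paste0("t", seq_len(n)))
}

#' Simulate sequences along a tree
#'
#' For each site a rate category is drawn from the category weights and a
#' root state from the equilibrium frequencies; states then propagate
#' from the root towards the tips, each edge transition sampled from the
#' row of `P(t * r_c)` for the site's category. Deterministic per seed.
#'
#' @param tree a `pw_tree`.
#' @param model a `pw_model`.
#' @param rates a `pw_rates` (default: single unit rate).
#' @param site_count number of sites.
#' @param seed optional integer seed.
#' @return a `pw_alignment` over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, model, rates = NULL, site_count,
                               seed = NULL) {
  stopifnot(inherits(tree, "pw_tree"), inherits(model, "pw_model"))
  L <- as.integer(site_count)
  if (is.na(L) || L < 1) pw_stop("site_count must be >= 1")
  if (tree$n_tips < 2) pw_stop("simulation needs at least 2 tips")
  if (is.null(rates)) rates <- rate_categories(1)
  if (!is.null(seed)) set.seed(seed)
  S <- model$state_count
  C <- length(rates$rates)
  eig <- eigendecompose(model)
  n <- tree$n_tips
  nn <- 2L * n - 1L
  cat_of_site <- sample.int(C, L, replace = TRUE, prob = rates$weights)
  states <- matrix(0L, nn, L)
  states[nn, ] <- sample.int(S, L, replace = TRUE, prob = model$frequencies)
  tm <- compute_transition_matrices(eig, rates,
                                    tree$edge_length[seq_len(nn - 1L)])
  # root-to-tips: visit parents before children (root is last id)
  for (v in seq(nn - 1L, 1L)) {
    p <- tree$parent[v]
    P <- tm[[v]]$P
    for (c in seq_len(C)) {
      for (s in seq_len(S)) {
        idx <- which(cat_of_site == c & states[p, ] == s)
        if (length(idx))
          states[v, idx] <- sample.int(S, length(idx), replace = TRUE,
                                       prob = P[s, , c])
      }
    }
  }
  letters_ <- nucleotide_alphabet()$states
  if (S != length(letters_)) letters_ <- as.character(seq_len(S))
  seqs <- vapply(seq_len(n), function(k)
    paste(letters_[states[k, ]], collapse = ""), character(1))
  alignment(tree$tip_labels, seqs)
}

# One random nearest-neighbour interchange across an internal edge of the
# unrooted topology (edge lengths travel with their subtrees). Candidate
# edges: (parent(v), v) for internal v with internal non-root parent, plus
# the merged root edge when both root children are internal. A pivot whose
# parent is the root is NOT a candidate: swapping around it only rotates
# the star at the root and leaves the unrooted topology unchanged.
nni_tree <- function(tree) {
  n <- tree$n_tips
  root <- tree$root
  rk <- tree$children[root, ]
  internal <- (n + 1L):(2L * n - 1L)
  std <- internal[!is.na(tree$parent[internal])]
  std <- std[tree$parent[std] != root]
  n_ops <- length(std) + (rk[1] > n && rk[2] > n)
  if (!n_ops) return(tree)
  pick <- sample.int(n_ops, 1L)
  if (pick <= length(std)) {
    v <- std[pick]
    p <- tree$parent[v]
    a <- tree$children[v, sample.int(2L, 1L)]  # swap a child of v ...
    b <- setdiff(tree$children[p, ], v)        # ... with v's sibling
    new_parent_of <- c(p, v)
  } else {
    # merged root edge: exchange one child of each root child
    a <- tree$children[rk[1], sample.int(2L, 1L)]
    b <- tree$children[rk[2], sample.int(2L, 1L)]
    new_parent_of <- c(rk[2], rk[1])
  }
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  for (w in seq_len(2L * n - 2L)) {
    pw <- tree$parent[w]
    if (w == a) pw <- new_parent_of[1] else if (w == b) pw <- new_parent_of[2]
    parent <- c(parent, pw); child <- c(child, w)
    len <- c(len, tree$edge_length[w])
  }
  tree_from_edges(parent, child, len, seq_len(n), tree$tip_labels)
}

# Jitter helpers for benchmark variations.
jitter_lengths <- function(tree) {
  idx <- !is.na(tree$edge_length)
  tree$edge_length[idx] <- tree$edge_length[idx] *
    runif(sum(idx), 0.8, 1.25)
  tree
}

jitter_rates <- function(rates) {
  r <- rates$rates * runif(length(rates$rates), 0.8, 1.25)
  w <- rates$weights * runif(length(rates$weights), 0.8, 1.25)
  rate_categories(r, w / sum(w))
}

#' Synthetic benchmark inputs
#'
#' Reproduces the structure of a scaling experiment: for each requested
#' pattern count, a base problem (random tree over `otu_count` tips,
#' simulated nucleotide alignment under HKY with discretized-gamma rates,
#' compressed to weighted site patterns) plus `n_variations` perturbed
#' parameter sets. Each variation applies one random
#' nearest-neighbour interchange to the topology, jitters branch lengths
#' by `U(0.8, 1.25)`, jitters category rates and weights (renormalised),
#' and redraws the pattern weights.
#'
#' @param pattern_counts target pattern counts; the simulated alignment
#'   has this many sites, so the realised unique-pattern count can be
#'   smaller and is reported alongside.
#' @param otu_count tips in the simulated tree.
#' @param seed integer seed.
#' @param n_variations perturbed parameter sets per size.
#' @param kappa,frequencies,alpha,category_count generating HKY+gamma
#'   parameters.
#' @param branch_mean mean branch length of the random tree.
#' @return a list with one element per size: `tree`, `patterns`,
#'   `model`, `rates`, and `variations` (each with `tree`, `rates`,
#'   `pattern_weights`).
#' @export
synthetic_benchmark_inputs <- function(pattern_counts, otu_count, seed = 1,
                                       n_variations = 10L,
                                       kappa = 2,
                                       frequencies = c(0.3, 0.2, 0.2, 0.3),
                                       alpha = 0.5, category_count = 4L,
                                       branch_mean = 0.1) {
  if (any(pattern_counts < 1)) pw_stop("pattern_counts must be positive")
  model <- build_model("HKY", kappa = kappa, frequencies = frequencies)
  rates <- discretize_gamma(alpha, category_count)
  set.seed(seed)
  lapply(pattern_counts, function(N) {
    tree <- random_tree(otu_count, branch_mean = branch_mean)
    aln <- simulate_alignment(tree, model, rates, site_count = N)
    patterns <- compress_patterns(aln)
    vars <- lapply(seq_len(n_variations), function(i) {
      list(tree = jitter_lengths(nni_tree(tree)),
           rates = jitter_rates(rates),
           pattern_weights = sample.int(5L, ncol(patterns$patterns),
                                        replace = TRUE))
    })
    list(size = N, tree = tree, patterns = patterns, model = model,
         rates = rates, variations = vars)
  })
}

#' Run the synthetic scaling harness
#'
#' Simulates data over a range of pattern counts, evaluates the base
#' problem and every parameter variation with each requested kernel
#' implementation, times the evaluations and verifies that all
#' implementations agree on every log-likelihood bitwise.
#'
#' @inheritParams synthetic_benchmark_inputs
#' @param replicates independent replicate seeds per size.
#' @param impls kernel implementations to compare.
#' @param rescale rescaling mode passed to the engine.
#' @return a data frame with one row per (size, replicate, variation,
#'   implementation): realised pattern count, log-likelihood, evaluation
#'   seconds, and whether all implementations matched bitwise.
#' @export
run_synthetictest <- function(otu_count = 128L,
                              pattern_counts = c(100L, 1000L, 10000L),
                              n_variations = 10L, replicates = 3L,
                              seed = 1L,
                              impls = c("serial", "threaded"),
                              rescale = "none") {
  rows <- list()
  for (si in seq_along(pattern_counts)) {
    N <- pattern_counts[si]
    for (rep in seq_len(replicates)) {
      rep_seed <- seed + 1000L * (si - 1L) + rep
      inp <- synthetic_benchmark_inputs(N, otu_count, seed = rep_seed,
                                        n_variations = n_variations)[[1]]
      cases <- c(list(list(tree = inp$tree, rates = inp$rates,
                           pattern_weights = inp$patterns$weights)),
                 inp$variations)
      base_ctx <- likelihood_context(inp$patterns, inp$model, inp$rates)
      for (vi in seq_along(cases)) {
        cs <- cases[[vi]]
        ctx <- base_ctx
        ctx$rates <- rep(list(cs$rates), ctx$n_subsets)
        ctx$patterns$weights <- cs$pattern_weights
        lnls <- numeric(length(impls))
        secs <- numeric(length(impls))
        for (ii in seq_along(impls)) {
          t0 <- proc.time()[["elapsed"]]
          lnls[ii] <- context_loglik(ctx, cs$tree, rescale = rescale,
                                     impl = impls[ii])$total
          secs[ii] <- proc.time()[["elapsed"]] - t0
        }
        agree <- all(lnls == lnls[1])
        for (ii in seq_along(impls))
          rows[[length(rows) + 1L]] <- data.frame(
            size = N, patterns = ncol(ctx$patterns$patterns), replicate = rep,
            variation = vi - 1L, impl = impls[ii], lnl = lnls[ii],
            seconds = secs[ii], impls_agree = agree)
      }
    }
  }
  do.call(rbind, rows)
}
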