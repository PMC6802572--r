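# Independent oracles used across the test suite. These deliberately avoid
# the package's computational paths: transition probabilities come from
# Matrix::expm, likelihoods from explicit marginalisation over ancestral
# state assignments, and closed forms are hand-derived.

# Brute-force tree log-likelihood: sum over all ancestral state
# assignments of pi(root) * prod over edges of P(edge)[parent, child],
# tips summed over their compatible states, mixed over rate categories.
oracle_loglik <- function(patterns, pattern_weights, tree, Q, freqs,
                          cat_rates, cat_weights,
                          alphabet = nucleotide_alphabet()) {
  n <- tree$n_tips
  S <- length(freqs)
  C <- length(cat_rates)
  nn <- 2L * n - 1L
  Pm <- lapply(seq_len(nn - 1L), function(v)
    lapply(seq_len(C), function(c)
      as.matrix(Matrix::expm(Q * cat_rates[c] * tree$edge_length[v]))))
  internals <- (n + 1L):nn
  nI <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nI)))
  total <- 0
  for (p in seq_len(ncol(patterns))) {
    allowed <- lapply(seq_len(n), function(k)
      alphabet$ambiguity[[patterns[k, p]]])
    Lsite <- 0
    for (c in seq_len(C)) {
      lik <- freqs[grid[, nI]]          # root is the last internal
      for (v in seq_len(nn - 1L)) {
        ps <- grid[, match(tree$parent[v], internals)]
        f <- if (v <= n) {
          rowSums(matrix(Pm[[v]][[c]][ps, allowed[[v]]],
                         nrow = nrow(grid)))
        } else {
          Pm[[v]][[c]][cbind(ps, grid[, match(v, internals)])]
        }
        lik <- lik * f
      }
      Lsite <- Lsite + cat_weights[c] * sum(lik)
    }
    total <- total + pattern_weights[p] * log(Lsite)
  }
  total
}

# Closed-form two-taxon JC quantities at total separation t, for m
# matching and k mismatching sites: lnL and its first two t-derivatives.
# Derivation: P(same) = 1/4 + 3/4 e^{-4t/3}, site likelihoods
# Lm = (1 + 3e)/16, Lx = (1 - e)/16 with e = exp(-4t/3).
jc_two_taxon <- function(t, m, k) {
  e <- exp(-4 * t / 3)
  Lm <- (1 + 3 * e) / 16
  Lx <- (1 - e) / 16
  dLm <- -e / 4          # d/dt (3e)/16 = (-4e)/16
  dLx <- e / 12          # d/dt (-e)/16 = (4e/3)/16
  d2Lm <- e / 3
  d2Lx <- -e / 9
  list(
    lnl = m * log(Lm) + k * log(Lx),
    d1 = m * dLm / Lm + k * dLx / Lx,
    d2 = m * (d2Lm / Lm - (dLm / Lm)^2) + k * (d2Lx / Lx - (dLx / Lx)^2)
  )
}

# Canonical unrooted-topology signature (sorted nontrivial splits,
# normalised to the side not containing tip 1).
topology_key <- function(tr) {
  n <- tr$n_tips
  desc <- vector("list", 2L * n - 1L)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in (n + 1L):(2L * n - 1L))
    desc[[v]] <- sort(c(desc[[tr$children[v, 1]]], desc[[tr$children[v, 2]]]))
  sp <- lapply((n + 1L):(2L * n - 2L), function(v) {
    s <- desc[[v]]
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    if (length(s) >= 2 && length(s) <= n - 2) paste(s, collapse = ",")
    else NA_character_
  })
  paste(sort(unique(unlist(sp[!is.na(sp)]))), collapse = "|")
}

# Independent recursive height-above-tips oracle.
height_oracle <- function(tr) {
  rec <- function(v) {
    if (v <= tr$n_tips) return(0L)
    1L + max(rec(tr$children[v, 1]), rec(tr$children[v, 2]))
  }
  rec(tr$root)
}

# Random reversible model for property tests.
random_gtr <- function() {
  f <- runif(4, 0.5, 2); f <- f / sum(f)
  build_model("GTR", frequencies = f,
              exchangeabilities = runif(6, 0.2, 3))
}

# Random alignment with occasional missing data.
random_patterns_alignment <- function(n_taxa, n_sites, p_missing = 0.05) {
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_taxa), function(i) {
    s <- sample(chars, n_sites, replace = TRUE)
    miss <- runif(n_sites) < p_missing
    s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  alignment(paste0("t", seq_len(n_taxa)), seqs)
}
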