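# Build a ready instance for a hand-made case via the buffer-level API.
cherry_instance <- function(tipA, tipB, t1, t2, model = build_model("JC"),
                            rates = rate_categories(1), P = NULL) {
  aln <- alignment(c("A", "B"), c(tipA, tipB))
  ps <- compress_patterns(aln)
  cfg <- instance_config(tip_count = 2, pattern_count = ncol(ps$patterns),
                         category_count = length(rates$rates),
                         implementation = "serial")
  inst <- create_instance(cfg)
  set_instance_data(inst,
                    tips = list(encode_tip(ps$patterns[1, ], "compact"),
                                encode_tip(ps$patterns[2, ], "compact")),
                    eigen = eigendecompose(model), rates = rates,
                    frequencies = model$frequencies,
                    pattern_weights = ps$weights)
  update_transition_matrices(inst, 1, c(t1, t2), 1:2)
  inst
}

test_that("instance configuration validates counts", {
  expect_error(instance_config(2, 0), "pattern_count")
  expect_error(instance_config(1, 5), "tip_count")
  cfg <- instance_config(2, 1, category_count = 1)
  expect_s3_class(create_instance(cfg), "pw_instance")
})

test_that("set_instance_data rejects mismatched shapes by slot name", {
  cfg <- instance_config(4, 10)
  inst <- create_instance(cfg)
  expect_error(set_instance_data(inst, pattern_weights = rep(1, 9)),
               "pattern_weights")
  expect_error(set_instance_data(inst, tips = list(1:10)), "tips")
})

test_that("cherry partials: identical tips at t = 0 give a one-hot parent", {
  inst <- cherry_instance("A", "A", 0, 0)
  update_partials(inst, plan_postorder(caterpillar_tree(2)))
  expect_equal(inst$partials[[1]], c(1, 0, 0, 0))
})

test_that("fully ambiguous tips give unit partials and zero log-likelihood", {
  inst <- cherry_instance("N", "N", 0.3, 0.7)
  tr <- caterpillar_tree(2)
  update_partials(inst, plan_postorder(tr))
  expect_equal(inst$partials[[1]], rep(1, 4))
  res <- calculate_root_log_likelihood(inst, 3)
  expect_equal(res$total, 0)
})

test_that("unwritten internal buffers are a state error; unset matrices too", {
  cfg <- instance_config(4, 1)
  inst <- create_instance(cfg)
  set_instance_data(inst,
                    tips = lapply(1:4, function(i) encode_tip("A", "compact")),
                    eigen = eigendecompose(build_model("JC")),
                    rates = rate_categories(1), frequencies = rep(0.25, 4),
                    pattern_weights = 1)
  tr <- balanced_tree(4)
  ops <- plan_postorder(tr)
  expect_error(update_partials(inst, ops), "matrices unset")
  update_transition_matrices(inst, 1, tr$edge_length[1:6], 1:6)
  expect_error(update_partials(inst, ops[3]), "unwritten")
})

test_that("engine log-likelihood matches the brute-force marginalisation oracle", {
  set.seed(51)
  for (i in 1:12) {
    n <- sample(3:6, 1)
    C <- sample(1:3, 1)
    tr <- random_tree(n, branch_mean = 0.3)
    m <- random_gtr()
    g <- if (C == 1) rate_categories(1) else discretize_gamma(runif(1, 0.3, 2), C)
    aln <- random_patterns_alignment(n, sample(3:8, 1))
    lik <- tree_loglik(aln, tr, m, g)$total
    ps <- compress_patterns(aln)
    orc <- oracle_loglik(ps$patterns, ps$weights, tr, m$Q, m$frequencies,
                         g$rates, g$weights)
    expect_equal(lik, orc, tolerance = 1e-10)
  }
})

test_that("two-taxon JC log-likelihood matches the closed form", {
  aln <- alignment(c("A", "B"), c("AAAC", "AAAT"))  # m = 3, k = 1
  tr <- read_newick("(A:0.12,B:0.08);", taxa = c("A", "B"))
  r <- tree_loglik(aln, tr, build_model("JC"))
  expect_equal(r$total, jc_two_taxon(0.2, 3, 1)$lnl, tolerance = 1e-12)
})

test_that("likelihood on compressed patterns equals uncompressed", {
  set.seed(52)
  tr <- random_tree(8, seed = 99)
  m <- build_model("HKY", kappa = 3, frequencies = c(0.4, 0.1, 0.2, 0.3))
  g <- discretize_gamma(0.6, 4)
  aln <- simulate_alignment(tr, m, g, 200, seed = 100)
  compressed <- tree_loglik(aln, tr, m, g)$total
  ps <- compress_patterns(aln)
  # uncompressed: every site its own pattern with weight 1
  unc <- ps
  unc$patterns <- ps$patterns[, ps$pattern_of_site, drop = FALSE]
  unc$weights <- rep(1, aln$site_count)
  unc$subset_ranges <- matrix(c(1L, aln$site_count), 1)
  unc$pattern_of_site <- seq_len(aln$site_count)
  uncompressed <- tree_loglik(unc, tr, m, g)$total
  expect_equal(compressed, uncompressed, tolerance = 1e-10)
})

test_that("log-likelihood is invariant under rerooting (reversible model)", {
  set.seed(53)
  tr <- random_tree(10, seed = 7)
  m <- random_gtr()
  g <- discretize_gamma(0.8, 4)
  aln <- simulate_alignment(tr, m, g, 150, seed = 8)
  ctx <- likelihood_context(aln, m, g)
  base <- context_loglik(ctx, tr)$total
  for (v in prunewave:::candidate_edge_nodes(tr)) {
    lv <- context_loglik(ctx, reroot_tree(tr, v))$total
    expect_equal(lv, base, tolerance = 1e-10)
  }
})

test_that("postorder and wavefront plans give bitwise-identical results", {
  set.seed(54)
  tr <- random_tree(32, seed = 12)
  m <- build_model("HKY", kappa = 2.5, frequencies = c(0.3, 0.2, 0.2, 0.3))
  g <- discretize_gamma(0.5, 4)
  aln <- simulate_alignment(tr, m, g, 300, seed = 13)
  ctx <- likelihood_context(aln, m, g)
  expect_identical(context_loglik(ctx, tr, plan = "postorder")$total,
                   context_loglik(ctx, tr, plan = "wavefront")$total)
})

test_that("serial, vectorized and threaded kernels agree bitwise for any worker count", {
  set.seed(55)
  tr <- random_tree(16, seed = 21)
  m <- build_model("HKY", kappa = 2, frequencies = c(0.35, 0.15, 0.2, 0.3))
  g <- discretize_gamma(0.4, 4)
  aln <- simulate_alignment(tr, m, g, 2500, seed = 22)
  ctx <- likelihood_context(aln, m, g)
  ref <- context_loglik(ctx, tr, impl = "serial", want_site_lnl = TRUE)
  for (impl in c("vectorized", "threaded")) {
    for (w in if (impl == "threaded") c(1, 2, 4) else 1) {
      r <- context_loglik(ctx, tr, impl = impl, max_workers = w,
                          want_site_lnl = TRUE)
      expect_identical(r$total, ref$total)
      expect_identical(r$site_lnl, ref$site_lnl)
    }
  }
})

test_that("multi-subset totals decompose as sums of per-subset evaluations", {
  set.seed(56)
  K <- 10
  tr <- random_tree(12, seed = 31)
  models <- lapply(1:K, function(s)
    build_model("HKY", kappa = runif(1, 1, 6), frequencies = {
      f <- runif(4, 0.5, 2); f / sum(f)
    }))
  rates <- lapply(1:K, function(s) discretize_gamma(runif(1, 0.3, 1.5), 4))
  rel <- runif(K, 0.5, 2)
  alns <- lapply(1:K, function(s)
    simulate_alignment(tr, models[[s]], rates[[s]], 60, seed = 400 + s))
  joint <- alignment(tr$tip_labels,
                     vapply(seq_along(tr$tip_labels), function(k)
                       paste(vapply(alns, function(a) a$sequences[k],
                                    character(1)), collapse = ""),
                       character(1)))
  sos <- rep(1:K, each = 60)
  shared <- tree_loglik(joint, tr, models, rates, partitions = sos,
                        subset_rates = rel)
  separate <- vapply(1:K, function(s)
    tree_loglik(alns[[s]], tr, models[[s]], rates[[s]],
                subset_rates = rel[s])$total, numeric(1))
  expect_equal(shared$total, sum(separate), tolerance = 1e-10)
  expect_equal(shared$per_subset, separate, tolerance = 1e-10)
  expect_equal(shared$total, sum(shared$per_subset), tolerance = 1e-12)
})

test_that("edge factorisation reproduces the root likelihood at any edge", {
  set.seed(57)
  tr <- random_tree(9, seed = 61)
  m <- random_gtr()
  g <- discretize_gamma(0.9, 3)
  aln <- simulate_alignment(tr, m, g, 120, seed = 62)
  ctx <- likelihood_context(aln, m, g)
  base <- context_loglik(ctx, tr)$total
  for (v in c(1L, 5L, tr$n_tips + 2L)) {
    ed <- edge_loglik(ctx, tr, node = v)
    expect_equal(ed$total, base, tolerance = 1e-10)
  }
})

test_that("edge derivatives match the closed form and finite differences", {
  # closed-form two-taxon JC
  aln <- alignment(c("A", "B"), c("AAAC", "AAAT"))
  tr <- read_newick("(A:0.2,B:0.0);", taxa = c("A", "B"))
  ed <- edge_loglik(aln, tr, build_model("JC"), node = 1)
  cf <- jc_two_taxon(0.2, 3, 1)
  expect_equal(ed$d1, cf$d1, tolerance = 1e-9)
  expect_equal(ed$d2, cf$d2, tolerance = 1e-9)

  # identical sequences: d1 < 0 for all t > 0
  aln2 <- alignment(c("A", "B"), c("ACGT", "ACGT"))
  for (t in c(0.05, 0.5, 2)) {
    tr2 <- read_newick(sprintf("(A:%g,B:0.0);", t), taxa = c("A", "B"))
    expect_lt(edge_loglik(aln2, tr2, build_model("JC"), node = 1)$d1, 0)
  }
})

test_that("scale factor accumulation: empty list zeroes, one buffer copies", {
  cfg <- instance_config(4, 5)
  inst <- create_instance(cfg)
  inst$scales[[1]] <- c(1, 2, 3, 4, 5)
  inst$scales[[2]] <- rep(0.5, 5)
  accumulate_scale_factors(inst, integer(0), 4)
  expect_equal(inst$scales[[4]], rep(0, 5))
  accumulate_scale_factors(inst, 1, 4)
  expect_equal(inst$scales[[4]], c(1, 2, 3, 4, 5))
  accumulate_scale_factors(inst, 1:2, 4)
  expect_equal(inst$scales[[4]], c(1.5, 2.5, 3.5, 4.5, 5.5))
  expect_error(accumulate_scale_factors(inst, 9, 4), "out of range")
})

test_that("rescaling is neutral on moderate trees and rescues deep ones", {
  set.seed(58)
  tr <- random_tree(16, seed = 71)
  m <- build_model("HKY", kappa = 2, frequencies = c(0.3, 0.2, 0.2, 0.3))
  g <- discretize_gamma(0.5, 4)
  aln <- simulate_alignment(tr, m, g, 500, seed = 72)
  ctx <- likelihood_context(aln, m, g)
  l0 <- context_loglik(ctx, tr, rescale = "none")$total
  l1 <- context_loglik(ctx, tr, rescale = "always")$total
  expect_equal(l1, l0, tolerance = 1e-8)

  # deep tree, saturated data, skewed evaluation frequencies: raw partials
  # hit exact zero, rescaled bookkeeping stays finite
  deep <- random_tree(500, branch_mean = 2, seed = 73)
  alnd <- simulate_alignment(deep, build_model("JC"), site_count = 30,
                             seed = 74)
  skew <- build_model("HKY", kappa = 2,
                      frequencies = c(0.01, 0.49, 0.49, 0.01))
  ctxd <- likelihood_context(alnd, skew)
  raw <- context_loglik(ctxd, deep, rescale = "none")
  expect_true(is.infinite(raw$total) && raw$total < 0)
  expect_gt(length(raw$underflow), 0)
  scaled <- context_loglik(ctxd, deep, rescale = "always")
  expect_true(is.finite(scaled$total))
})
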