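test_that("F3x4 frequencies normalize and track compositional bias", {
  code <- genetic_code()
  set.seed(43)
  aln <- random_codon_aln(c("a", "b"), 200, code)
  fr <- suppressWarnings(f3x4_frequencies(aln, code))
  expect_equal(sum(fr), 1)
  expect_equal(length(fr), length(code$sense_codons))
  # AT-rich data over-weights AT-ending codons
  at_aln <- c(x = paste(rep("ATTTTATTAAAT", 50), collapse = ""))
  # G absent from some positions: the documented floor kicks in with a warning
  expect_warning(fr_at <- f3x4_frequencies(at_aln, code), "floored")
  at_end <- substr(names(fr_at), 3, 3) %in% c("A", "T")
  expect_gt(sum(fr_at[at_end]), 0.9)
  expect_error(f3x4_frequencies(character(0)), "empty")
})

test_that("GY94 generator is a reversible rate matrix", {
  code <- genetic_code()
  set.seed(47)
  aln <- random_codon_aln(c("a", "b", "c"), 100, code)
  fr <- suppressWarnings(f3x4_frequencies(aln, code))
  Q <- gy94_matrix(kappa = 3, omega = 0.4, fr, code)
  expect_equal(unname(rowSums(Q)), rep(0, nrow(Q)), tolerance = 1e-12)
  pi <- fr[rownames(Q)]
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12) # detailed balance: pi_i q_ij = pi_j q_ji
  expect_equal(-sum(pi * diag(Q)), 1) # unit mean rate
  # multi-nucleotide changes have rate zero
  expect_equal(Q["TTT", "AAT"], 0)
  expect_equal(Q["TTT", "ACT"], 0)
})

test_that("transition probabilities match a series-expansion matrix exponential", {
  code <- genetic_code()
  fr <- stats::setNames(
    rep(1 / length(code$sense_codons), length(code$sense_codons)),
    code$sense_codons
  )
  Q <- gy94_matrix(kappa = 2, omega = 0.5, fr, code)
  for (t in c(0.01, 0.1, 0.7)) {
    P <- codon_pmatrix(Q, fr, t)
    P_oracle <- expm_series(Q * t)
    expect_equal(unname(P), unname(P_oracle), tolerance = 1e-8)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
  }
})

test_that("pruning log-likelihood equals exhaustive enumeration on tiny trees", {
  code <- genetic_code()
  set.seed(53)
  for (rep in 1:3) {
    tree <- ape::rtree(3)
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
    aln <- random_codon_aln(tree$tip.label, 2, code)
    fr <- suppressWarnings(f3x4_frequencies(aln, code))
    kappa <- runif(1, 1, 4)
    omega <- runif(1, 0.05, 2)
    lnl <- site_log_likelihoods(aln, tree, list(kappa = kappa, omega = omega),
      code = code, freqs = fr
    )
    Q <- gy94_matrix(kappa, omega, fr, code)
    sense <- code$sense_codons
    for (site in 1:2) {
      st <- vapply(aln, function(s) {
        match(substr(s, 3 * site - 2, 3 * site), sense)
      }, integer(1))
      expect_equal(lnl[site], oracle_enum_loglik(st, tree, Q, fr[sense]), tolerance = 1e-8)
    }
  }
})

test_that("total branch-site mixture likelihood decomposes per site", {
  cfg <- simulation_config(seed = 59, n_taxa = 4, n_codons = 40, omega2 = 2)
  sim <- simulate_codon_alignment(cfg)
  lnl <- site_log_likelihoods(
    sim$alignment, sim$tree,
    list(kappa = 2, omega0 = 0.1, omega2 = 2, p0 = 0.7, p1 = 0.2),
    foreground = sim$foreground
  )
  expect_length(lnl, 40)
  expect_true(all(is.finite(lnl)))
  # mixture with omega2 = 1 equals the null parameterization regardless of weights
  lnl_a <- site_log_likelihoods(
    sim$alignment, sim$tree,
    list(kappa = 2, omega0 = 0.1, omega2 = 1, p0 = 0.6, p1 = 0.4),
    foreground = sim$foreground
  )
  lnl_b <- site_log_likelihoods(
    sim$alignment, sim$tree,
    list(kappa = 2, omega0 = 0.1, omega2 = 1, p0 = 0.6, p1 = 0.4),
    foreground = integer(0)
  )
  expect_equal(lnl_a, lnl_b, tolerance = 1e-9)
})

test_that("taxon mismatches between tree and alignment are reported by name", {
  cfg <- simulation_config(seed = 61, n_taxa = 4, n_codons = 20)
  sim <- simulate_codon_alignment(cfg)
  aln <- sim$alignment
  names(aln)[1] <- "intruder"
  expect_error(
    site_log_likelihoods(aln, sim$tree, list(kappa = 2, omega = 1)),
    "intruder"
  )
})

test_that("foreground marks parse from Newick tags and clade specs", {
  parsed <- read_foreground_tree("((a:1,b:1)#1:0.5,(c:1,d:1):0.5);")
  expect_length(parsed$foreground, 1)
  marked_child <- parsed$tree$edge[parsed$foreground, 2]
  clade <- ape::extract.clade(parsed$tree, marked_child)
  expect_setequal(clade$tip.label, c("a", "b"))
  # tip mark
  parsed2 <- read_foreground_tree("((a:1,b#1:1):0.5,c:1);")
  expect_equal(parsed2$tree$edge[parsed2$foreground, 2], which(parsed2$tree$tip.label == "b"))
  # stem-branch spec agrees with the Newick tag
  expect_equal(foreground_stem(parsed$tree, c("a", "b")), parsed$foreground)
})

test_that("branch-site fit recovers selection and respects nesting", {
  cfg <- simulation_config(seed = 67, n_taxa = 6, n_codons = 300, omega2 = 8)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_branch_site(sim$alignment, sim$tree, sim$foreground)
  expect_gte(fit$alt$lnL, fit$null$lnL - 1e-4) # nested-model dominance
  expect_gte(fit$twoDeltaL, 0)
  expect_gt(fit$alt$omega2, 1)
  expect_equal(sum(fit$alt$proportions), 1, tolerance = 1e-9)
  # Model A constraint on the dependent proportions
  p <- fit$alt$proportions
  expect_equal(p[3], (1 - p[1] - p[2]) * p[1] / (p[1] + p[2]), tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$twoDeltaL, fit$twoDeltaL)
  td <- tidy(fit)
  expect_equal(nrow(td), 14)
  expect_equal(td$estimate[td$model == "null" & td$term == "omega2"], 1)
})

test_that("likelihood ratio test follows its reference distributions", {
  expect_equal(lrt(0), 1)
  expect_equal(lrt(3.841), 0.05, tolerance = 1e-3)
  expect_equal(lrt(8.25), stats::pchisq(8.25, 1, lower.tail = FALSE))
  expect_lt(lrt(8.25), 0.05)
  expect_equal(lrt(3.841, reference = "mixture"), 0.025, tolerance = 1e-3)
  expect_equal(lrt(0, reference = "mixture"), 1)
})

test_that("BEB posteriors are probabilities that rank planted sites first", {
  cfg <- simulation_config(seed = 71, n_taxa = 6, n_codons = 250, omega2 = 8)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_branch_site(sim$alignment, sim$tree, sim$foreground)
  bt <- beb(fit)
  expect_equal(nrow(bt), 250)
  expect_true(all(bt$pp >= 0 & bt$pp <= 1))
  planted <- sim$classes >= 3
  expect_gt(mean(bt$pp[planted]), mean(bt$pp[!planted]))
  expect_true(all(bt$stars[bt$pp > 0.99] == "**"))
  expect_true(all(bt$stars[bt$pp <= 0.95] == ""))
})

test_that("RELL topology tests separate trees by their site support", {
  set.seed(73)
  # identical trees: all p = 1, equal weights
  base <- matrix(rnorm(2 * 100), nrow = 2)
  base[2, ] <- base[1, ]
  res <- rell_tests(base, n_resamples = 500)
  expect_equal(res$p_KH, c(1, 1))
  expect_equal(res$elw, c(0.5, 0.5), tolerance = 1e-9)
  # one tree better by 2 lnL per site over 100 sites: competitor rejected
  m <- rbind(rep(0, 100), rep(-2, 100) + rnorm(100, sd = 0.1))
  res2 <- rell_tests(m, n_resamples = 1000)
  expect_lt(res2$p_KH[2], 0.05)
  expect_lt(res2$p_SH[2], 0.05)
  expect_gt(res2$elw[1], 0.99)
  expect_equal(sum(res2$elw), 1)
  # single tree: trivial output
  res1 <- rell_tests(matrix(rnorm(50), nrow = 1))
  expect_equal(res1$p_KH, 1)
  expect_equal(res1$elw, 1)
})
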