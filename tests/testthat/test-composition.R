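test_that("composition profiles match closed forms and exclude N", {
  p <- base_composition("AATT")
  expect_equal(p$AT_pct, 100)
  expect_equal(p$AT_skew, 0)
  expect_equal(base_composition("AAAT")$AT_skew, 0.5) # (3 - 1)/4
  pn <- base_composition("AANNT")
  expect_equal(pn$n_counted, 3L)
  expect_equal(pn$AT_pct, 100)
  expect_error(base_composition("NNN"), "countable")
})

test_that("reverse complement negates both skews", {
  set.seed(11)
  for (i in 1:15) {
    s <- random_seq(200, at = runif(1, 0.3, 0.8))
    fwd <- base_composition(s)
    rev <- base_composition(revcomp(s))
    expect_equal(rev$AT_skew, -fwd$AT_skew)
    expect_equal(rev$GC_skew, -fwd$GC_skew)
    expect_equal(rev$AT_pct, fwd$AT_pct)
  }
})

test_that("codon-position profiles separate positions and respect AT3 bias", {
  pp <- per_position_composition(c("ATAATA"))
  expect_equal(pp$AT_pct[pp$scope == "pos3"], 100)
  # synthetic third-position bias shows up only at position 3
  set.seed(3)
  cds <- vapply(1:5, function(i) {
    cod <- replicate(60, paste0(
      sample(c("A", "C", "G", "T"), 1),
      sample(c("A", "C", "G", "T"), 1),
      sample(c("A", "T"), 1) # AT-only third positions
    ))
    paste(cod, collapse = "")
  }, character(1))
  pp2 <- per_position_composition(cds)
  expect_equal(pp2$AT_pct[pp2$scope == "pos3"], 100)
  expect_lt(pp2$AT_pct[pp2$scope == "pos1"], 70)
  expect_error(per_position_composition(c("AC")), "no complete codons")
})

test_that("whole-genome AT equals the length-weighted average of its parts", {
  set.seed(5)
  parts <- c(random_seq(300, 0.8), random_seq(200, 0.6), random_seq(100, 0.4))
  whole <- base_composition(paste(parts, collapse = ""))
  per <- base_composition(parts)
  weighted <- sum(per$AT_pct * per$n_counted) / sum(per$n_counted)
  expect_equal(whole$AT_pct, weighted)
})

test_that("group comparisons use Welch's t-test with star conventions", {
  set.seed(21)
  df <- data.frame(
    at = c(rnorm(20, 0), rnorm(20, 5), rnorm(20, 0.2)),
    habitat = rep(c("aquatic", "terrestrial", "semi_aquatic"), each = 20)
  )
  res <- group_compare(df, "at", "habitat")
  expect_equal(nrow(res), 3L) # all pairwise contrasts
  strong <- res[res$group1 == "aquatic" & res$group2 == "terrestrial", ]
  expect_lt(strong$p_value, 0.001)
  expect_equal(strong$stars, "***")
  same <- res[res$group2 == "semi_aquatic" & res$group1 == "aquatic", ]
  expect_equal(same$stars, "ns")
  # identical groups: p ~ 1
  df2 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("x", "y"), each = 3))
  expect_gt(group_compare(df2, "v", "g")$p_value, 0.99)
  expect_error(
    group_compare(data.frame(v = 1:3, g = c("a", "a", "b")), "v", "g"),
    "fewer than 2"
  )
})

test_that("Welch p agrees with a permutation p within Monte-Carlo error", {
  set.seed(33)
  x <- rnorm(12, 0, 1)
  y <- rnorm(12, 0.8, 1)
  df <- data.frame(v = c(x, y), g = rep(c("a", "b"), each = 12))
  welch_p <- group_compare(df, "v", "g")$p_value
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  perm <- replicate(10000, {
    idx <- sample(24, 12)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  perm_p <- mean(perm >= obs)
  expect_lt(abs(welch_p - perm_p), 0.05)
})

test_that("correlation reports r, R-squared and the fitted line", {
  df <- data.frame(x = 1:10, y = 2 * (1:10))
  res <- correlate(df, "x", "y")
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  set.seed(2)
  df2 <- data.frame(x = 1:50)
  df2$y <- -df2$x + rnorm(50, sd = 1e-4)
  expect_lt(correlate(df2, "x", "y")$r, -0.999)
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"), "zero variance")
})
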