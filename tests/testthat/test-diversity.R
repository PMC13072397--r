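test_that("nucleotide diversity matches closed forms and a brute-force oracle", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste0(paste(rep("A", 99), collapse = ""), "T")
  expect_equal(nucleotide_diversity(c(s1 = a, s2 = b)), 0.01)
  expect_equal(nucleotide_diversity(c(s1 = a, s2 = a, s3 = a)), 0)
  expect_error(nucleotide_diversity(c(s1 = a)), "at least 2")
  # random alignment vs all-pairs oracle, with gaps
  set.seed(13)
  for (rep in 1:5) {
    n <- 5
    L <- 60
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L,
      replace = TRUE, prob = c(rep(0.225, 4), 0.05, 0.05)
    ), nrow = n)
    oracle <- {
      tot <- 0
      np <- 0
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          ok <- !(m[i, ] %in% c("-", "N")) & !(m[j, ] %in% c("-", "N"))
          tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
          np <- np + 1
        }
      }
      tot / np
    }
    expect_equal(nucleotide_diversity(m), oracle)
  }
  # order invariance
  aln <- c(x = "ACGTACGTAA", y = "ACGAACGTAT", z = "ACGTACCTAA")
  expect_equal(nucleotide_diversity(aln), nucleotide_diversity(rev(aln)))
})

test_that("sliding windows follow the count formula and tile to the global Pi", {
  set.seed(19)
  aln <- stats::setNames(replicate(4, random_seq(200)), paste0("s", 1:4))
  win <- sliding_window_pi(aln, window = 100, step = 25)
  expect_equal(nrow(win), floor((200 - 100) / 25) + 1) # 5 windows
  expect_equal(win$start, c(1, 26, 51, 76, 101))
  const <- stats::setNames(rep(paste(rep("ACGT", 50), collapse = ""), 3), paste0("c", 1:3))
  expect_true(all(sliding_window_pi(const, 100, 25)$pi == 0))
  # step = window: window Pi values average exactly to the global value
  tiles <- sliding_window_pi(aln, window = 50, step = 50)
  expect_equal(mean(tiles$pi), nucleotide_diversity(aln))
  expect_error(sliding_window_pi(aln, window = 500), "exceeds")
})

test_that("haplotype diversity matches the small-sample formula", {
  four <- c(h1 = "AAAA", h2 = "AAAT", h3 = "AATT", h4 = "ATTT")
  expect_equal(haplotype_diversity(four)$hd, 1)
  split22 <- c(h1 = "AAAA", h2 = "AAAA", h3 = "TTTT", h4 = "TTTT")
  res <- haplotype_diversity(split22)
  expect_equal(res$hd, (4 / 3) * (1 - 0.5)) # 0.6667
  expect_equal(res$n_haplotypes, 2L)
  same <- c(h1 = "ACGT", h2 = "ACGT", h3 = "ACGT")
  expect_equal(haplotype_diversity(same)$hd, 0)
  # sequences differing only at masked positions share a haplotype
  masked <- c(h1 = "ACGT", h2 = "ACGN", h3 = "ACTT")
  expect_equal(haplotype_diversity(masked)$n_haplotypes, 2L)
})

test_that("pairwise identity counts matches over included columns", {
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste0(substr(a, 1, 999), "T")
  expect_equal(pairwise_identity(c(x = a, y = a)), 100)
  expect_equal(pairwise_identity(c(x = a, y = b)), 99.9)
  # amino-acid level: one nonsynonymous change in 10 codons
  cds1 <- "ATTATACCTAAAGGAATTCATCTTACAGGA"
  cds2 <- sub("CAT", "GAT", cds1)
  expect_equal(pairwise_identity(c(x = cds1, y = cds2), level = "aa"), 90)
})

test_that("segregating sites count polymorphic included columns", {
  aln <- c(s1 = "AAC-T", s2 = "ATCNT", s3 = "AACGT")
  expect_equal(segregating_sites(aln), 1L)
})

test_that("Nei-Gojobori sites, pathways and correction behave per the counting rules", {
  code <- genetic_code()
  r <- ka_ks("ATTATACCT", "ATTATACCT", code)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$S_sites + r$N_sites, 9) # 3 x codons, always
  # single synonymous third-position change
  r2 <- ka_ks("GGAGGAGGA", "GGAGGAGGT", code)
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
  expect_equal(r2$Sd, 1)
  # pathway averaging equals the recursive ordering oracle for 2-3 differences
  set.seed(29)
  sense <- code$sense_codons
  checked <- 0
  for (i in 1:400) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (nd < 2) next
    est <- mitocomp:::codon_path_differences(c1, c2, code)
    orc <- oracle_path_counts(c1, c2, code)
    expect_equal(est[["sd"]], orc[["sd"]])
    expect_equal(est[["nd"]], orc[["nd"]])
    checked <- checked + 1
  }
  expect_gt(checked, 50)
  # symmetry (exact)
  c1 <- "ATTACAGGTCCTAAA"
  c2 <- "ATAACCGGTCCAAAA"
  expect_equal(ka_ks(c1, c2, code), ka_ks(c2, c1, code))
  expect_error(ka_ks("ATTATA", "ATT"), "length")
})

test_that("Jukes-Cantor correction errors at saturation", {
  expect_equal(jukes_cantor(0), 0)
  expect_error(jukes_cantor(0.8), "saturation")
})

test_that("clade Ka/Ks under purifying simulation stays below 1", {
  cfg <- simulation_config(
    seed = 37, n_taxa = 5, n_codons = 200,
    p0 = 1, p1 = 0, omega0 = 0.1, omega2 = 1
  )
  sim <- simulate_codon_alignment(cfg)
  kk <- ka_ks_matrix(sim$alignment)
  expect_true(all(kk$ka_ks < 1, na.rm = TRUE))
})

test_that("diversity profile bundles summary statistics consistently", {
  set.seed(41)
  aln <- stats::setNames(replicate(5, random_seq(150)), paste0("p", 1:5))
  prof <- diversity_profile(aln)
  expect_equal(prof$summary$n, 5L)
  expect_equal(prof$summary$pi, nucleotide_diversity(aln))
  expect_equal(prof$summary$S, segregating_sites(aln))
  expect_equal(nrow(prof$windows), floor((150 - 100) / 25) + 1)
})
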