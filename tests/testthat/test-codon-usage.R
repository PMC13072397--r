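test_that("RSCU closed forms and per-family bookkeeping hold", {
  code <- genetic_code()
  counts <- stats::setNames(rep(3L, length(code$sense_codons)), code$sense_codons)
  r <- rscu(counts, code)
  expect_true(all(r$rscu == 1)) # uniform usage in every family
  # one codon used exclusively in a 4-fold family
  counts2 <- stats::setNames(rep(0L, length(code$sense_codons)), code$sense_codons)
  counts2[c("GTT", "GTA")] <- c(8L, 0L)
  counts2["GTT"] <- 8L
  r2 <- rscu(counts2, code)
  val <- r2[r2$aa == "V", ]
  expect_equal(val$rscu[val$codon == "GTT"], 4)
  expect_equal(sum(val$rscu), 4) # family sum equals family size
  expect_true(all(is.na(r2$rscu[r2$aa == "K"]))) # unused family: undefined, not 0
  # random counts: per-family sums equal family sizes
  set.seed(9)
  counts3 <- stats::setNames(
    rpois(length(code$sense_codons), 10) + 1L, code$sense_codons
  )
  r3 <- rscu(counts3, code)
  sums <- tapply(r3$rscu, r3$aa, sum)
  sizes <- tapply(r3$family_size, r3$aa, unique)
  expect_equal(as.numeric(sums), as.numeric(sizes))
})

test_that("ENC hits its closed-form bounds and matches a direct-formula oracle", {
  code <- genetic_code()
  n_sense <- length(code$sense_codons)
  uniform <- stats::setNames(rep(50L, n_sense), code$sense_codons)
  expect_equal(as.numeric(enc(uniform, code)), n_sense) # 62 under this code
  # standard code: 61 sense codons
  std <- genetic_code("standard")
  uni_std <- stats::setNames(rep(50L, 61L), std$sense_codons)
  expect_equal(as.numeric(enc(uni_std, std)), 61)
  # exactly one codon per amino acid -> ENC = number of amino acids
  one_per <- stats::setNames(rep(0L, n_sense), code$sense_codons)
  for (fam in code$families) one_per[fam[1]] <- 40L
  expect_equal(as.numeric(enc(one_per, code)), length(code$families))
  # random counts vs an independently coded Wright estimator
  oracle_enc <- function(counts, code) {
    fams <- code$families[vapply(code$families, length, integer(1)) > 1]
    k <- vapply(fams, length, integer(1))
    Fv <- vapply(fams, function(cd) {
      n <- sum(counts[cd])
      (n * sum((counts[cd] / n)^2) - 1) / (n - 1)
    }, numeric(1))
    tot <- 0
    for (ksz in unique(k)) tot <- tot + sum(k == ksz) / mean(Fv[k == ksz])
    min(tot + sum(vapply(code$families, length, integer(1)) == 1), length(code$sense_codons))
  }
  set.seed(17)
  for (i in 1:10) {
    counts <- stats::setNames(rpois(n_sense, 20) + 2L, code$sense_codons)
    expect_equal(as.numeric(enc(counts, code)), oracle_enc(counts, code), tolerance = 1e-9)
  }
})

test_that("ENC decreases as usage concentrates within families", {
  code <- genetic_code()
  n_sense <- length(code$sense_codons)
  base <- stats::setNames(rep(100, n_sense), code$sense_codons)
  encs <- vapply(seq(0, 0.95, by = 0.05), function(alpha) {
    counts <- base
    for (fam in code$families) {
      if (length(fam) > 1) {
        tot <- sum(counts[fam])
        conc <- rep((1 - alpha) * tot / length(fam), length(fam))
        conc[1] <- conc[1] + alpha * tot
        counts[fam] <- conc
      }
    }
    as.numeric(enc(counts, code))
  }, numeric(1))
  expect_true(all(diff(encs) < 1e-9))
  expect_lt(encs[length(encs)], 25)
})

test_that("expected-ENC curve is exact and symmetric", {
  expect_equal(enc_expected(0.5), 60.5) # 2 + 0.5 + 29/0.5
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(enc_expected(0.5 - s) - (0.5 - s), enc_expected(0.5 + s) - (0.5 + s))
})

test_that("strongly biased usage plots below the expected ENC curve", {
  code <- genetic_code()
  # AT-ending codons used exclusively: severe bias at moderate GC3
  aln <- list(tx = c(paste(rep("GGATTACTAAAT", 40), collapse = "")))
  usage <- codon_usage(aln, code)
  expect_lt(usage$ENC, enc_expected(usage$GC3_pct / 100))
})

test_that("CBI closed forms and expected-count bookkeeping hold", {
  code <- genetic_code()
  n_sense <- length(code$sense_codons)
  opt <- optimal_codons(
    stats::setNames(seq_len(n_sense), code$sense_codons), code
  )
  # only optimal codons used -> CBI = 1
  counts <- stats::setNames(rep(0L, n_sense), code$sense_codons)
  counts[opt] <- 30L
  expect_equal(cbi(counts, code, opt), 1)
  # uniform synonymous usage -> CBI = 0
  uniform <- stats::setNames(rep(12L, n_sense), code$sense_codons)
  expect_equal(cbi(uniform, code, opt), 0)
  # random counts vs independent expected-count computation
  set.seed(23)
  counts3 <- stats::setNames(rpois(n_sense, 15), code$sense_codons)
  fams <- code$families[vapply(code$families, length, integer(1)) > 1]
  n_opt <- sum(vapply(fams, function(f) sum(counts3[intersect(opt, f)]), numeric(1)))
  n_tot <- sum(vapply(fams, function(f) sum(counts3[f]), numeric(1)))
  n_ran <- sum(vapply(fams, function(f) {
    sum(counts3[f]) * length(intersect(opt, f)) / length(f)
  }, numeric(1)))
  expect_equal(cbi(counts3, code, opt), (n_opt - n_ran) / (n_tot - n_ran))
})

test_that("AT3-biased usage prefers AT-ending codons and shifts ENC/CBI with composition", {
  set.seed(31)
  code <- genetic_code()
  make_taxon <- function(at3) {
    cod <- replicate(400, {
      repeat {
        c3 <- sample(c("A", "T", "G", "C"), 1,
          prob = c(at3 / 2, at3 / 2, (1 - at3) / 2, (1 - at3) / 2)
        )
        cd <- paste0(sample(c("A", "C", "G", "T"), 1), sample(c("A", "C", "G", "T"), 1), c3)
        if (cd %in% code$sense_codons) break
      }
      cd
    })
    paste(cod, collapse = "")
  }
  ats <- seq(0.55, 0.95, by = 0.1)
  cds <- lapply(ats, make_taxon)
  names(cds) <- paste0("t", seq_along(ats))
  usage <- codon_usage(lapply(cds, identity), code)
  # RSCU of AT-ending codons exceeds 1 for the most biased taxon
  r <- rscu(codon_counts(cds[[length(cds)]], code), code)
  at_end <- substr(r$codon, 3, 3) %in% c("A", "T")
  expect_gt(mean(r$rscu[at_end & r$family_size > 1], na.rm = TRUE), 1)
  # ENC rises with GC3; CBI falls (composition-driven bias)
  expect_gt(cor(usage$GC3_pct, usage$ENC), 0)
  expect_lt(cor(usage$GC3_pct, usage$CBI), 0)
})
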