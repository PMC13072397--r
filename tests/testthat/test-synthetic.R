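test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 101)
  m1 <- simulate_mitogenome(cfg)
  m2 <- simulate_mitogenome(cfg)
  expect_identical(m1$sequence, m2$sequence)
  expect_identical(m1$features, m2$features)
  s1 <- simulate_codon_alignment(simulation_config(seed = 102, n_taxa = 5, n_codons = 50))
  s2 <- simulate_codon_alignment(simulation_config(seed = 102, n_taxa = 5, n_codons = 50))
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$classes, s2$classes)
  p1 <- simulate_population(simulation_config(seed = 103))
  p2 <- simulate_population(simulation_config(seed = 103))
  expect_identical(p1$haplotypes, p2$haplotypes)
})

test_that("simulated mitogenomes are complete, ordered, and hit the AT target", {
  cfg <- simulation_config(seed = 107, at_target = 0.78)
  m <- simulate_mitogenome(cfg)
  census <- gene_census(m)
  expect_equal(census$n[census$kind == "PCG"], 13L)
  expect_equal(census$n[census$kind == "tRNA"], 22L)
  expect_equal(census$n[census$kind == "rRNA"], 2L)
  expect_true(is_complete_mitogenome(m))
  at <- base_composition(m$sequence)$AT_pct
  expect_gte(at, 76)
  expect_lte(at, 80)
  # CR sits between rrnS and trnI across the origin-free layout
  feats <- m$features
  expect_equal(feats$name[nrow(feats)], "CR")
  expect_equal(feats$name[1], "trnI")
  expect_equal(feats$name[which(feats$name == "CR") - 1], "rrnS")
  # conserved short intergenic spacer between trnS2 and nad1
  gap <- feats$start[feats$name == "nad1"] - feats$end[feats$name == "trnS2"]
  expect_gte(gap, 17L)
  expect_lte(gap, 42L)
  # every PCG is a translatable ORF under the invertebrate mito code
  for (g in feats$name[feats$kind == "PCG"]) {
    expect_no_error(translate_cds(extract_gene(m, g)))
  }
  # infeasible composition target is a config error
  expect_error(simulation_config(at_target = 0.99))
})

test_that("planted control-region repeats are recovered by the detector", {
  cfg <- simulation_config(seed = 109, cr_motif = "TATTA", cr_copies = 8)
  m <- simulate_mitogenome(cfg)
  truth <- attr(m, "truth")
  reps <- annotate_cr(m)$repeats
  expect_gt(nrow(reps), 0)
  best <- reps[which.max(reps$score), ]
  expect_equal(best$period, 5L)
  expect_equal(best$copy_number, 8)
})

test_that("simulated codon alignments are stop-free with F3x4-consistent frequencies", {
  code <- genetic_code()
  cfg <- simulation_config(seed = 113, n_taxa = 6, n_codons = 800, omega2 = 1)
  sim <- simulate_codon_alignment(cfg)
  for (s in sim$alignment) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cod %in% code$stop_codons))
  }
  # empirical codon frequencies approach the F3x4 target
  cod_all <- unlist(lapply(sim$alignment, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  emp <- table(factor(cod_all, levels = code$sense_codons)) / length(cod_all)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(sim$freqs))), 0.02)
  # degenerate mixture (omega2 = 1, p2 = 0) reduces to single-class data
  cfg0 <- simulation_config(seed = 113, n_taxa = 6, n_codons = 100, p0 = 1, p1 = 0)
  sim0 <- simulate_codon_alignment(cfg0)
  expect_true(all(sim0$classes == 1))
})

test_that("population simulator bookkeeping matches the realized sample", {
  cfg0 <- simulation_config(seed = 127, pop_mut_prob = 0)
  pop0 <- simulate_population(cfg0)
  expect_equal(pop0$true_S, 0L)
  expect_equal(nucleotide_diversity(pop0$haplotypes), 0)
  expect_equal(haplotype_diversity(pop0$haplotypes)$hd, 0)
  cfg <- simulation_config(seed = 131, pop_mut_prob = 0.01)
  pop <- simulate_population(cfg)
  expect_equal(segregating_sites(pop$haplotypes), pop$true_S)
  # Pi across replicates matches the 2p(1-1/n)-scaled expectation:
  # two haplotypes differ at a site when at least one mutated (to distinct bases)
  set.seed(1)
  p <- 0.01
  pis <- vapply(1:40, function(i) {
    nucleotide_diversity(
      simulate_population(simulation_config(
        seed = 1000 + i,
        pop_n = 10, pop_mut_prob = p, pop_len = 500
      ))$haplotypes
    )
  }, numeric(1))
  expected <- 2 * p * (1 - p) + p^2 * (2 / 3)
  expect_lt(abs(mean(pis) - expected) / expected, 0.15)
})

test_that("simulated panels vary metadata and seeds per genome", {
  cfg <- simulation_config(seed = 137)
  panel <- simulate_panel(cfg, n = 3, at_targets = c(0.76, 0.78, 0.80),
    habitats = c("aquatic", "terrestrial", "unknown")
  )
  expect_length(panel, 3)
  expect_false(identical(panel[[1]]$sequence, panel[[2]]$sequence))
  expect_equal(vapply(panel, function(m) m$habitat, character(1)),
    c("aquatic", "terrestrial", "unknown")
  )
})
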