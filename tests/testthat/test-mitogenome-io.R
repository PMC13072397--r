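test_that("translation follows the invertebrate mitochondrial code with incomplete-stop handling", {
  expect_equal(as.character(translate_cds("ATTATA")), "IM") # ATA is Met, not Ile
  expect_equal(as.character(translate_cds("TGATCTAGA")), "WSS") # TGA = Trp, AGA = Ser
  out <- translate_cds("TTTT")
  expect_equal(as.character(out), "F")
  expect_true(attr(out, "incomplete_stop"))
  expect_error(translate_cds("ATTTAAATT"), "internal stop")
  # property: random stop-free CDS translates to floor(len/3) residues
  set.seed(42)
  code <- genetic_code()
  for (i in 1:20) {
    n <- sample(5:40, 1)
    cds <- paste(sample(code$sense_codons, n, replace = TRUE), collapse = "")
    extra <- sample(0:2, 1)
    if (extra > 0) cds <- paste0(cds, substr("TA", 1, extra))
    expect_equal(nchar(translate_cds(cds)), n)
  }
})

test_that("gene extraction respects strand and circular wraparound", {
  m <- tiny_mitogenome()
  expect_equal(extract_gene(m, "cox1"), "ATTATACCTAAAGGATTTTAA")
  expect_equal(extract_gene(m, "nad5"), "ATTTTAGGAAAACATCTTTAA")
  cr <- extract_gene(m, "CR")
  expect_equal(nchar(cr), (m$length - 102) + 4) # (L - start) + end for a wrap
  expect_equal(cr, "AATTAATTTT")
  expect_error(extract_gene(m, "nad99"), "no feature named")
  # minus-strand extraction equals reverse complement of the forward slice
  set.seed(7)
  for (i in 1:10) {
    s <- random_seq(60)
    feats <- tibble::tibble(
      name = "cob", kind = "PCG", start = 10L, end = 40L,
      strand = "-", wraps_origin = FALSE
    )
    g <- mitogenome("X", s, feats)
    expect_equal(extract_gene(g, "cob"), revcomp(substr(s, 11, 40)))
  }
})

test_that("GenBank writing and reparsing round-trips annotation and sequence", {
  m <- tiny_mitogenome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(m, path)
  back <- read_genbank(path)[[1]]
  expect_equal(back$sequence, m$sequence)
  expect_equal(back$id, m$id)
  expect_equal(back$taxon, m$taxon)
  expect_equal(
    back$features[c("name", "kind", "start", "end", "strand", "wraps_origin")],
    m$features[c("name", "kind", "start", "end", "strand", "wraps_origin")]
  )
})

test_that("GenBank gene names map through the synonym table", {
  gb <- c(
    "LOCUS       MINI01 12 bp    DNA     circular INV",
    "DEFINITION  minimal record.",
    "  ORGANISM  Testus parvus",
    "FEATURES             Location/Qualifiers",
    "     source          1..12",
    "     CDS             1..9",
    "                     /gene=\"COI\"",
    "     tRNA            10..12",
    "                     /product=\"tRNA-Leu(UUR)\"",
    "ORIGIN",
    "        1 attataccta aa",
    "//"
  )
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  m <- read_genbank(path)[[1]]
  expect_equal(m$features$name, c("cox1", "trnL2"))
  expect_equal(m$features$kind, c("PCG", "tRNA"))
  expect_equal(m$features$start, c(0L, 9L)) # 1-based inclusive -> 0-based half-open
  expect_equal(m$features$end, c(9L, 12L))
  # unmappable names are kept as intergenic with a warning
  gb2 <- sub("COI", "mystery-orf", gb)
  writeLines(gb2, path)
  expect_warning(m2 <- read_genbank(path)[[1]], "cannot map")
  expect_equal(m2$features$kind[1], "intergenic")
})

test_that("supermatrix concatenation records disjoint covering partitions", {
  taxa <- c("a", "b", "c")
  blocks <- list(
    cox1 = stats::setNames(replicate(3, random_seq(300)), taxa),
    nad5 = stats::setNames(replicate(3, random_seq(150)), taxa)
  )
  sm <- concatenate_genes(blocks)
  expect_equal(unname(nchar(sm$supermatrix)), rep(450L, 3))
  expect_equal(sm$partitions$gene, c("cox1", "nad5")) # canonical PCG order
  expect_equal(sm$partitions$start, c(1L, 301L))
  expect_equal(sm$partitions$end, c(300L, 450L))
  # partitions are disjoint and cover all columns
  cols <- unlist(Map(seq, sm$partitions$start, sm$partitions$end))
  expect_equal(sort(cols), 1:450)
  # 13 synthetic blocks: widths sum to supermatrix width
  blocks13 <- lapply(stats::setNames(nm = pcg_order()), function(g) {
    stats::setNames(replicate(3, random_seq(30)), taxa)
  })
  sm13 <- concatenate_genes(blocks13)
  expect_equal(unname(nchar(sm13$supermatrix))[1], 13L * 30L)
  expect_error(
    concatenate_genes(list(g1 = c(a = "AAA"), g2 = c(b = "TTT"))),
    "taxon sets differ"
  )
})

test_that("fasta round trip preserves names and gaps", {
  seqs <- c(s1 = "ACGT-NACGT", s2 = "TTTTAAAACC")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})

test_that("ambiguity codes other than N are rejected at construction", {
  expect_error(
    mitogenome("B", "ACGTRY", tibble::tibble(
      name = "cox1", kind = "PCG", start = 0L, end = 6L,
      strand = "+", wraps_origin = FALSE
    )),
    "ambiguity"
  )
})
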