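# Shared fixtures and independent oracles used across the suite.

random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE,
    prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  ), collapse = "")
}

# A small hand-built mitogenome: two PCGs (one minus-strand), a tRNA, an rRNA
# and a CR that wraps the circular origin.
tiny_mitogenome <- function() {
  cox1 <- "ATTATACCTAAAGGATTTTAA" # 21 bp, stop-free body
  nad5_fwd <- "ATTTTAGGAAAACATCTTTAA"
  trn <- paste(rep("ACGT", 4), collapse = "")
  rrn <- strrep("AGTT", 10)
  cr_tail <- "TTTT" # wraps: last 6 bp + first 4 bp
  cr_head <- "AATTAA"
  body <- paste0(cox1, revcomp(nad5_fwd), trn, rrn)
  genome <- paste0(cr_tail, body, cr_head)
  L <- nchar(genome)
  start_cox1 <- 4L
  features <- tibble::tibble(
    name = c("cox1", "nad5", "trnM", "rrnS", "CR"),
    kind = c("PCG", "PCG", "tRNA", "rRNA", "control_region"),
    start = c(
      start_cox1, start_cox1 + 21L, start_cox1 + 42L,
      start_cox1 + 42L + 16L, L - 6L
    ),
    end = c(
      start_cox1 + 21L, start_cox1 + 42L, start_cox1 + 42L + 16L,
      start_cox1 + 42L + 16L + 40L, 4L
    ),
    strand = c("+", "-", "+", "+", "+"),
    wraps_origin = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  mitogenome("TINY01", genome, features, taxon = "Testus minimus", habitat = "aquatic")
}

# Independent Nei-Gojobori pathway oracle: recursive enumeration of all
# orderings of the differing positions, with stop-free pathway preference.
oracle_path_counts <- function(c1, c2, code) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd, stop = through_stop)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      syn <- code$aa[[cur]] == code$aa[[nxt]] && code$aa[[nxt]] != "*"
      walk(
        nxt, setdiff(remaining, pos),
        sd + as.integer(syn), nd + as.integer(!syn),
        through_stop || (code$aa[[nxt]] == "*" && nxt != c2)
      )
    }
  }
  walk(c1, diff_pos, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(
    sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd"))
  )
}

# Exhaustive-enumeration likelihood oracle for small trees: sums the joint
# probability over all internal-node state assignments, with transition
# matrices from a plain series-expansion matrix exponential (independent of
# the engine's eigendecomposition path).
expm_series <- function(M) {
  n <- nrow(M)
  # scaling and squaring with a Taylor series
  k <- max(0L, ceiling(log2(max(1, norm(M, "1")))) + 4L)
  A <- M / 2^k
  P <- diag(n)
  term <- diag(n)
  for (i in 1:30) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

oracle_enum_loglik <- function(states_by_taxon, tree, Q, freqs) {
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(po$tip.label)
  nnode <- max(po$edge)
  internals <- (n + 1L):nnode
  P <- lapply(seq_len(nrow(po$edge)), function(e) expm_series(Q * po$edge.length[e]))
  pi <- as.numeric(freqs)
  nstate <- length(pi)
  root <- po$edge[nrow(po$edge), 1L]
  grid <- as.matrix(expand.grid(rep(list(seq_len(nstate)), length(internals))))
  total <- rep(0, nrow(grid))
  st <- matrix(0L, nrow = nrow(grid), ncol = nnode)
  for (i in seq_len(n)) st[, i] <- states_by_taxon[po$tip.label[i]]
  st[, internals] <- grid
  p <- pi[st[, root]]
  for (e in seq_len(nrow(po$edge))) {
    p <- p * P[[e]][cbind(st[, po$edge[e, 1L]], st[, po$edge[e, 2L]])]
  }
  log(sum(p))
}

# A motif is primitive when it is not itself a repetition of a shorter unit;
# only primitive motifs define arrays whose minimal period equals the nominal
# one (planting "TTT" x 6 really plants "T" x 18).
primitive_motif <- function(period) {
  repeat {
    motif <- random_seq(period)
    ok <- TRUE
    for (d in seq_len(period - 1)) {
      if (period %% d == 0 && motif == strrep(substr(motif, 1, d), period / d)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(motif)
  }
}

# Independent re-implementation of the "plant an array with periodicity
# breakers" construction: each of the 4 boundary bases is forced to differ
# from the base one period before and after it.
plant_with_breakers <- function(left, array, right, period) {
  v <- strsplit(paste0(left, strrep("?", 4), array, strrep("?", 4), right), "")[[1]]
  for (j in which(v == "?")) {
    bad <- c(
      if (j - period >= 1) v[j - period],
      if (j + period <= length(v)) v[j + period]
    )
    v[j] <- setdiff(c("A", "C", "G", "T"), bad[bad != "?"])[1]
  }
  list(seq = paste(v, collapse = ""), start = nchar(left) + 4L)
}

# Random in-frame stop-free codon alignment over the code's sense codons.
random_codon_aln <- function(taxa, n_codons, code) {
  sense <- code$sense_codons
  stats::setNames(
    vapply(taxa, function(t) {
      paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    }, character(1)),
    taxa
  )
}
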