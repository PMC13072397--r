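# Synthetic mitogenome and alignment generator -------------------------------
#
# Generates fixtures with the statistical structure the comparative analysis
# assumes: 37-gene AT-biased mitogenomes with a repeat-bearing control region,
# low-diversity population haplotype samples, and codon alignments evolved on
# a tree under a branch-site class mixture. A single integer seed drives one
# root generator; identical config + seed gives byte-identical output.

#' Simulation configuration
#'
#' Collects and validates all generator parameters. Defaults emulate an
#' AT-biased beetle mitogenome panel: whole-genome AT fraction 0.78 (the
#' middle of the published hydrophiloid range), a Model A site-class mixture
#' dominated by purifying selection, and a low-diversity population sample.
#'
#' @param seed Integer seed for the root generator.
#' @param n_taxa Number of taxa for simulated alignments/trees.
#' @param at_target Whole-genome AT fraction target (0-1).
#' @param p0,p1 Model A free class proportions (classes 2a/2b follow the
#'   Model A constraint).
#' @param omega0 Purifying-class omega (0 < omega0 < 1).
#' @param omega2 Foreground-selected-class omega (>= 1; 1 collapses to the
#'   null model).
#' @param kappa Transition/transversion ratio.
#' @param n_codons Codon alignment length.
#' @param cr_motif,cr_copies,cr_mut_rate Control-region tandem array: motif,
#'   copy number, per-base substitution rate applied per copy after
#'   construction.
#' @param cr_length Total control-region length (>= array + flanking motifs).
#' @param pop_n,pop_mut_prob,pop_len Population sample: haplotype count,
#'   per-site mutation probability, fragment length.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L, n_taxa = 8L, at_target = 0.78,
                              p0 = 0.75, p1 = 0.15, omega0 = 0.1, omega2 = 5,
                              kappa = 2, n_codons = 500L,
                              cr_motif = "TATTA", cr_copies = 8L, cr_mut_rate = 0,
                              cr_length = 800L,
                              pop_n = 10L, pop_mut_prob = 0.001, pop_len = 600L) {
  stopifnot(
    at_target > 0.05, at_target < 0.95,
    p0 >= 0, p1 >= 0, p0 + p1 <= 1,
    omega0 > 0, omega0 < 1, omega2 >= 1, kappa > 0,
    n_codons >= 10L, cr_copies >= 1L, cr_mut_rate >= 0, cr_mut_rate < 1,
    pop_n >= 2L, pop_mut_prob >= 0, pop_mut_prob < 1
  )
  if (nchar(cr_motif) * cr_copies + 48L > cr_length) {
    stop("cr_length too short for the requested repeat array", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_taxa = as.integer(n_taxa), at_target = at_target,
      p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2, kappa = kappa,
      n_codons = as.integer(n_codons),
      cr_motif = toupper(cr_motif), cr_copies = as.integer(cr_copies),
      cr_mut_rate = cr_mut_rate, cr_length = as.integer(cr_length),
      pop_n = as.integer(pop_n), pop_mut_prob = pop_mut_prob,
      pop_len = as.integer(pop_len)
    ),
    class = "simulation_config"
  )
}

# Typical insect mitochondrial gene lengths (bp) and the ancestral gene order
# with strands; CR sits between rrnS and trnI.
mito_gene_table <- function() {
  pcg_len <- c(
    nad2 = 1023L, cox1 = 1539L, cox2 = 684L, atp8 = 162L, atp6 = 678L,
    cox3 = 789L, nad3 = 354L, nad5 = 1719L, nad4 = 1341L, nad4L = 297L,
    nad6 = 498L, cob = 1137L, nad1 = 936L
  )
  order <- tibble::tribble(
    ~name, ~kind, ~strand,
    "trnI", "tRNA", "+", "trnQ", "tRNA", "-", "trnM", "tRNA", "+",
    "nad2", "PCG", "+", "trnW", "tRNA", "+", "trnC", "tRNA", "-",
    "trnY", "tRNA", "-", "cox1", "PCG", "+", "trnL2", "tRNA", "+",
    "cox2", "PCG", "+", "trnK", "tRNA", "+", "trnD", "tRNA", "+",
    "atp8", "PCG", "+", "atp6", "PCG", "+", "cox3", "PCG", "+",
    "trnG", "tRNA", "+", "nad3", "PCG", "+", "trnA", "tRNA", "+",
    "trnR", "tRNA", "+", "trnN", "tRNA", "+", "trnS1", "tRNA", "+",
    "trnE", "tRNA", "+", "trnF", "tRNA", "-", "nad5", "PCG", "-",
    "trnH", "tRNA", "-", "nad4", "PCG", "-", "nad4L", "PCG", "-",
    "trnT", "tRNA", "+", "trnP", "tRNA", "-", "nad6", "PCG", "+",
    "cob", "PCG", "+", "trnS2", "tRNA", "+", "nad1", "PCG", "-",
    "trnL1", "tRNA", "-", "rrnL", "rRNA", "-", "trnV", "tRNA", "-",
    "rrnS", "rRNA", "-", "CR", "control_region", "+"
  )
  order$length <- dplyr::case_when(
    order$kind == "PCG" ~ pcg_len[order$name],
    order$name == "rrnL" ~ 1290L,
    order$name == "rrnS" ~ 780L,
    order$kind == "tRNA" ~ 66L,
    TRUE ~ NA_integer_
  )
  order
}

random_bases <- function(n, at) {
  sample(NUC, n, replace = TRUE, prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
}

# Random stop-free CDS: ATT start, TAA stop, body codons drawn from a
# position-biased product distribution (third position most AT-rich).
random_cds <- function(n_bp, at, code) {
  stopifnot(n_bp %% 3L == 0L, n_bp >= 9L)
  at_pos <- pmin(pmax(c(at, at - 0.08, at + 0.08), 0.05), 0.95)
  n_body <- n_bp / 3L - 2L
  pos_bases <- vapply(1:3, function(p) random_bases(n_body, at_pos[p]), character(n_body))
  if (n_body == 1L) pos_bases <- matrix(pos_bases, nrow = 1L)
  cod <- apply(pos_bases, 1L, paste, collapse = "")
  stops <- cod %in% code$stop_codons
  while (any(stops)) {
    # redraw third position of stop codons (TAA/TAG -> TAT/TAC etc.)
    for (i in which(stops)) substr(cod[i], 3L, 3L) <- sample(c("T", "C"), 1L)
    stops <- cod %in% code$stop_codons
  }
  paste0("ATT", paste(cod, collapse = ""), "TAA")
}

mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(NUC, v[i]), 1L)
  paste(v, collapse = "")
}

# Control region: AT-rich flanks, a poly-T and poly-A stretch, and the planted
# tandem array (per-copy mutation applied after construction so the planted
# period is known). Flanking bases are forced to break the array periodicity.
build_cr <- function(cfg) {
  p <- nchar(cfg$cr_motif)
  copies <- vapply(seq_len(cfg$cr_copies), function(i) {
    if (i == 1L) cfg$cr_motif else mutate_bases(cfg$cr_motif, cfg$cr_mut_rate)
  }, character(1))
  array <- paste(copies, collapse = "")
  polyt <- strrep("T", 9L)
  polya <- strrep("A", 11L)
  pad <- cfg$cr_length - nchar(array) - nchar(polyt) - nchar(polya) - 8L
  left_n <- pad %/% 2L
  right_n <- pad - left_n
  left <- paste(random_bases(left_n, min(cfg$at_target + 0.05, 0.92)), collapse = "")
  right <- paste(random_bases(right_n, min(cfg$at_target + 0.05, 0.92)), collapse = "")
  planted <- plant_tandem_array(paste0(left, polyt), array, paste0(polya, right), p)
  list(seq = planted$seq, array_start = planted$start, array_len = nchar(array))
}

# Embed a tandem array between flanks with 4-base periodicity breakers on each
# side, so the array's boundaries cannot be extended by chance lag-p matches
# and the planted period/copy number stay exactly recoverable.
plant_tandem_array <- function(left, array, right, period) {
  seq <- paste0(left, strrep("?", 4L), array, strrep("?", 4L), right)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  holes <- which(v == "?")
  for (j in holes) {
    forbidden <- character(0)
    if (j - period >= 1L && v[j - period] != "?") forbidden <- c(forbidden, v[j - period])
    if (j + period <= length(v) && v[j + period] != "?") forbidden <- c(forbidden, v[j + period])
    v[j] <- setdiff(NUC, forbidden)[1L]
  }
  list(seq = paste(v, collapse = ""), start = nchar(left) + 4L)
}

#' Simulate an annotated mitogenome
#'
#' Builds a complete 37-gene mitogenome in the ancestral insect gene order
#' (no rearrangement): stop-free protein-coding genes with AT-biased,
#' position-structured composition; tRNAs and rRNAs; a conserved short
#' intergenic spacer between trnS2 and nad1; and a control region between
#' rrnS and trnI carrying a planted tandem-repeat array plus poly-A/poly-T
#' stretches. Realized whole-genome AT lands within about two points of the
#' target.
#'
#' @param cfg A [simulation_config()].
#' @param id,taxon,habitat Metadata for the generated record.
#' @return A [mitogenome()] with attribute `truth` (list: control-region
#'   repeat period, copy number and array span).
#' @export
simulate_mitogenome <- function(cfg, id = "SYN0001", taxon = "Syntheticus exemplum",
                                habitat = "unknown") {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  code <- genetic_code()
  plan <- mito_gene_table()
  pieces <- character(nrow(plan))
  cr_truth <- NULL
  for (i in seq_len(nrow(plan))) {
    g <- plan[i, ]
    fwd <- if (g$kind == "PCG") {
      random_cds(g$length, cfg$at_target, code)
    } else if (g$kind == "control_region") {
      built <- build_cr(cfg)
      cr_truth <- list(
        period = nchar(cfg$cr_motif), copy_number = cfg$cr_copies,
        array_start = built$array_start, array_len = built$array_len
      )
      built$seq
    } else {
      paste(random_bases(g$length, cfg$at_target), collapse = "")
    }
    pieces[i] <- if (g$strand == "-") revcomp(fwd) else fwd
  }
  lens <- nchar(pieces)
  # conserved 17-42 bp intergenic spacer between trnS2 and nad1
  spacer_after <- which(plan$name == "trnS2")
  spacer <- paste(random_bases(25L, cfg$at_target), collapse = "")
  seq_parts <- character(0)
  starts <- integer(nrow(plan))
  pos <- 0L
  for (i in seq_len(nrow(plan))) {
    starts[i] <- pos
    seq_parts <- c(seq_parts, pieces[i])
    pos <- pos + lens[i]
    if (i == spacer_after) {
      seq_parts <- c(seq_parts, spacer)
      pos <- pos + nchar(spacer)
    }
  }
  genome <- paste(seq_parts, collapse = "")
  features <- tibble::tibble(
    name = plan$name, kind = plan$kind,
    start = starts, end = starts + lens,
    strand = plan$strand, wraps_origin = FALSE
  )
  m <- mitogenome(
    id = id, sequence = genome, features = features,
    taxon = taxon, habitat = habitat
  )
  attr(m, "truth") <- cr_truth
  m
}

#' Simulate a panel of mitogenomes
#'
#' Independent draws of [simulate_mitogenome()] with per-genome seeds derived
#' from the root seed.
#'
#' @param cfg A [simulation_config()].
#' @param n Number of genomes.
#' @param at_targets Optional vector of per-genome AT targets (recycled).
#' @param habitats Optional vector of habitat labels (recycled).
#' @return List of [mitogenome()] objects.
#' @export
simulate_panel <- function(cfg, n = 6L, at_targets = NULL, habitats = "unknown") {
  if (is.null(at_targets)) at_targets <- cfg$at_target
  at_targets <- rep_len(at_targets, n)
  habitats <- rep_len(habitats, n)
  lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed * 1000L + i
    cfg_i$at_target <- at_targets[i]
    simulate_mitogenome(
      cfg_i,
      id = sprintf("SYN%04d", i),
      taxon = sprintf("Syntheticus sp%d", i),
      habitat = habitats[i]
    )
  })
}

# F3x4 target codon frequencies implied by the config's AT bias
config_codon_freqs <- function(cfg, code) {
  at_pos <- pmin(pmax(c(cfg$at_target, cfg$at_target - 0.08, cfg$at_target + 0.08), 0.05), 0.95)
  freq <- rbind(
    c(at_pos[1] / 2, (1 - at_pos[1]) / 2, (1 - at_pos[1]) / 2, at_pos[1] / 2),
    c(at_pos[2] / 2, (1 - at_pos[2]) / 2, (1 - at_pos[2]) / 2, at_pos[2] / 2),
    c(at_pos[3] / 2, (1 - at_pos[3]) / 2, (1 - at_pos[3]) / 2, at_pos[3] / 2)
  )
  colnames(freq) <- NUC
  pi <- vapply(code$sense_codons, function(cd) {
    freq[1L, substr(cd, 1L, 1L)] * freq[2L, substr(cd, 2L, 2L)] * freq[3L, substr(cd, 3L, 3L)]
  }, numeric(1))
  pi / sum(pi)
}

#' Simulate a codon alignment under the branch-site model
#'
#' Evolves codon sites on a tree under the Model A site-class mixture: each
#' site draws a class from (p0, p1, p2a, p2b); background branches use the
#' class's background omega and the foreground branch uses the class's
#' foreground omega (omega2 for classes 2a/2b). Transition probabilities come
#' from the same GY94 generator and scaling used by the fitting engine, so
#' fits to simulated data are internally consistent. No stop codons can occur
#' (the state space is the sense codons).
#'
#' @param cfg A [simulation_config()].
#' @param tree Optional `ape::phylo` with branch lengths (expected
#'   substitutions per codon); default: random topology on `cfg$n_taxa` tips
#'   with uniform(0.05, 0.3) branch lengths.
#' @param foreground Optional integer edge index/indices; default: a random
#'   internal edge (or a terminal edge when none exists).
#' @return List: `alignment` (named character vector), `classes` (true
#'   per-site class, 1-4 for 0/1/2a/2b), `tree`, `foreground`, `freqs`,
#'   `weights`.
#' @export
simulate_codon_alignment <- function(cfg, tree = NULL, foreground = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  code <- genetic_code()
  if (is.null(tree)) {
    tree <- ape::rtree(cfg$n_taxa, br = NULL)
    tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.3)
  }
  if (is.null(foreground)) {
    internal <- which(tree$edge[, 2L] > length(tree$tip.label))
    foreground <- if (length(internal) > 0L) sample(internal, 1L) else sample(nrow(tree$edge), 1L)
  }
  weights <- model_a_weights(cfg$p0, cfg$p1)
  if (sum(weights[3:4]) > 0 && length(foreground) == 0L) {
    stop("selected site classes require a marked foreground branch", call. = FALSE)
  }
  freqs <- config_codon_freqs(cfg, code)
  Qs <- bs_scaled_generators(cfg$kappa, cfg$omega0, cfg$omega2, freqs, code, weights)
  eng <- tree_engine_data(tree, foreground)
  edge <- eng$edge + 1L
  nnode <- max(edge)
  ntip <- length(eng$tips)
  classes <- sample.int(4L, cfg$n_codons, replace = TRUE, prob = weights)
  # background/foreground generator index per class (1 = omega0, 2 = omega1, 3 = omega2)
  bg_of <- c(1L, 2L, 1L, 2L)
  fg_of <- c(1L, 2L, 3L, 3L)
  # per-edge transition matrices per generator, cached
  pmats <- vector("list", nrow(edge) * 3L)
  getP <- function(e, w) {
    k <- (e - 1L) * 3L + w
    if (is.null(pmats[[k]])) {
      pmats[[k]] <<- cpp_pmat(Qs[[w]], as.numeric(freqs), eng$elen[e])
    }
    pmats[[k]]
  }
  nstate <- length(code$sense_codons)
  states <- matrix(0L, nrow = nnode, ncol = cfg$n_codons)
  root <- edge[nrow(edge), 1L]
  states[root, ] <- sample.int(nstate, cfg$n_codons, replace = TRUE, prob = freqs)
  for (e in rev(seq_len(nrow(edge)))) { # reverse postorder = parents first
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    for (cl in 1:4) {
      sites <- which(classes == cl)
      if (length(sites) == 0L) next
      P <- getP(e, if (eng$fg[e] == 1L) fg_of[cl] else bg_of[cl])
      cur <- states[parent, sites]
      nxt <- integer(length(sites))
      for (s in unique(cur)) { # vectorized draw per distinct parent state
        at <- which(cur == s)
        nxt[at] <- sample.int(nstate, length(at), replace = TRUE, prob = P[s, ])
      }
      states[child, sites] <- nxt
    }
  }
  sense <- code$sense_codons
  aln <- vapply(seq_len(ntip), function(i) {
    paste(sense[states[i, ]], collapse = "")
  }, character(1))
  names(aln) <- eng$tips
  list(
    alignment = aln, classes = classes, tree = tree, foreground = foreground,
    freqs = freqs, weights = weights
  )
}

#' Simulate a low-diversity population haplotype sample
#'
#' Mutates `pop_n` haplotypes independently from a common random reference at
#' a per-site substitution probability, emulating the near-zero variation of
#' high-altitude conspecific samples.
#'
#' @param cfg A [simulation_config()].
#' @return List: `haplotypes` (named character vector), `reference`, `true_S`
#'   (segregating-site count computed from the constructed matrix).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ref <- random_bases(cfg$pop_len, cfg$at_target)
  haps <- matrix(rep(ref, cfg$pop_n), nrow = cfg$pop_n, byrow = TRUE)
  for (i in seq_len(cfg$pop_n)) {
    hit <- which(stats::runif(cfg$pop_len) < cfg$pop_mut_prob)
    for (j in hit) haps[i, j] <- sample(setdiff(NUC, haps[i, j]), 1L)
  }
  true_S <- sum(apply(haps, 2L, function(col) length(unique(col)) > 1L))
  seqs <- apply(haps, 1L, paste, collapse = "")
  names(seqs) <- sprintf("hap%02d", seq_len(cfg$pop_n))
  list(haplotypes = seqs, reference = paste(ref, collapse = ""), true_S = true_S)
}
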