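# Codon state space ---------------------------------------------------------

# Single-nucleotide-difference structure of the sense-codon space: for every
# ordered pair of sense codons differing at exactly one position, whether the
# change is a transition and whether it is synonymous. Cached per code id.
codon_pair_table <- local({
  cache <- new.env(parent = emptyenv())
  function(code) {
    code <- as_code(code)
    key <- code$id
    if (!is.null(cache[[key]])) return(cache[[key]])
    sense <- code$sense_codons
    n <- length(sense)
    mat <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
    ii <- jj <- integer(0)
    ts <- syn <- logical(0)
    purines <- c("A", "G")
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- which(mat[i, ] != mat[j, ])
        if (length(d) == 1L) {
          b1 <- mat[i, d]
          b2 <- mat[j, d]
          ii <- c(ii, i)
          jj <- c(jj, j)
          ts <- c(ts, (b1 %in% purines) == (b2 %in% purines))
          syn <- c(syn, code$aa[[sense[i]]] == code$aa[[sense[j]]])
        }
      }
    }
    out <- list(i = ii, j = jj, ts = ts, syn = syn, sense = sense)
    cache[[key]] <- out
    out
  }
})

#' F3x4 codon equilibrium frequencies
#'
#' Estimates codon frequencies as products of position-specific nucleotide
#' frequencies observed in the alignment, renormalized over sense codons after
#' removing stops — the standard companion of codon substitution models.
#' A nucleotide absent from some codon position is floored at a small value
#' (with a warning) so no sense codon gets zero frequency.
#'
#' @param aln Named character vector of in-frame aligned coding sequences
#'   (gaps and Ns ignored in the counts).
#' @param code A [genetic_code()].
#' @param floor Minimum position-specific nucleotide frequency.
#' @return Named numeric vector over the code's sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(aln, code = genetic_code(), floor = 1e-4) {
  code <- as_code(code)
  if (length(aln) == 0L) stop("empty alignment", call. = FALSE)
  freq <- matrix(0, nrow = 3L, ncol = 4L, dimnames = list(NULL, NUC))
  for (s in aln) {
    s <- toupper(s)
    n <- nchar(s) - (nchar(s) %% 3L)
    if (n == 0L) next
    v <- strsplit(substr(s, 1L, n), "", fixed = TRUE)[[1L]]
    pos <- rep_len(1:3, n)
    for (p in 1:3) {
      t <- table(factor(v[pos == p], levels = NUC))
      freq[p, ] <- freq[p, ] + as.numeric(t)
    }
  }
  if (sum(freq) == 0) stop("no countable codons in alignment", call. = FALSE)
  freq <- freq / rowSums(freq)
  if (any(freq < floor)) {
    warning("zero or near-zero nucleotide frequency at a codon position; floored at ", floor, call. = FALSE)
    freq <- pmax(freq, floor)
    freq <- freq / rowSums(freq)
  }
  sense <- code$sense_codons
  pi <- vapply(sense, function(cd) {
    freq[1L, substr(cd, 1L, 1L)] * freq[2L, substr(cd, 2L, 2L)] * freq[3L, substr(cd, 3L, 3L)]
  }, numeric(1))
  pi / sum(pi)
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the instantaneous rate generator of the GY94 codon model over sense
#' codons: zero for multi-nucleotide changes, and rate proportional to the
#' target codon frequency times 1 (synonymous transversion), kappa
#' (synonymous transition), omega (nonsynonymous transversion) or kappa*omega
#' (nonsynonymous transition). The chain is reversible with stationary
#' distribution `freqs`.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Codon equilibrium frequencies over sense codons (e.g. from
#'   [f3x4_frequencies()]).
#' @param code A [genetic_code()].
#' @param scale `"unit"` (default) rescales so the mean rate
#'   `-sum(pi_i q_ii)` is 1; `"none"` leaves the raw generator.
#' @return Square rate matrix with sense-codon dimnames.
#' @export
gy94_matrix <- function(kappa, omega, freqs, code = genetic_code(), scale = c("unit", "none")) {
  scale <- match.arg(scale)
  stopifnot(kappa > 0, omega >= 0)
  code <- as_code(code)
  pt <- codon_pair_table(code)
  n <- length(pt$sense)
  freqs <- freqs[pt$sense]
  Q <- matrix(0, n, n, dimnames = list(pt$sense, pt$sense))
  rate <- ifelse(pt$ts, kappa, 1) * ifelse(pt$syn, 1, omega)
  Q[cbind(pt$i, pt$j)] <- rate * freqs[pt$j]
  Q[cbind(pt$j, pt$i)] <- rate * freqs[pt$i]
  diag(Q) <- -rowSums(Q)
  if (scale == "unit") {
    mr <- -sum(freqs * diag(Q))
    if (mr > 0) Q <- Q / mr
  }
  Q
}

# Mean substitution rate of an unscaled GY94 generator
gy94_rate <- function(kappa, omega, freqs, code) {
  Q <- gy94_matrix(kappa, omega, freqs, code, scale = "none")
  -sum(freqs[rownames(Q)] * diag(Q))
}

#' Codon transition-probability matrix
#'
#' `P(t) = exp(Q t)` computed by symmetric eigendecomposition of the
#' reversible generator; the same routine drives both the simulator and the
#' likelihood engine.
#'
#' @param Q Rate matrix from [gy94_matrix()].
#' @param freqs Stationary codon frequencies (same order as `Q`).
#' @param t Branch length (expected substitutions per codon when `Q` has unit
#'   mean rate).
#' @return Transition-probability matrix.
#' @export
codon_pmatrix <- function(Q, freqs, t) {
  P <- cpp_pmat(Q, as.numeric(freqs[rownames(Q)]), t)
  dimnames(P) <- dimnames(Q)
  P
}

# Trees with foreground branch marks ----------------------------------------

#' Read a Newick tree with "#1"-style foreground marks
#'
#' Accepts the codeml convention of tagging foreground branches with `#1`
#' after a tip label or a closing parenthesis. Marks are removed before
#' parsing; the edges leading to the tagged tips/clades become the foreground
#' set.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Treat `text` as a path.
#' @return List with `tree` (an `ape::phylo`) and `foreground` (integer edge
#'   indices into `tree$edge`).
#' @export
read_foreground_tree <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  sentinel <- "XFGMARKX"
  marked <- gsub("#\\s*1", sentinel, text)
  tree <- ape::read.tree(text = marked)
  if (is.null(tree)) stop("cannot parse Newick string", call. = FALSE)
  fg_nodes <- integer(0)
  tip_hits <- grepl(sentinel, tree$tip.label, fixed = TRUE)
  if (any(tip_hits)) {
    fg_nodes <- c(fg_nodes, which(tip_hits))
    tree$tip.label <- sub(sentinel, "", tree$tip.label, fixed = TRUE)
  }
  if (!is.null(tree$node.label)) {
    node_hits <- grepl(sentinel, tree$node.label, fixed = TRUE)
    if (any(node_hits)) {
      fg_nodes <- c(fg_nodes, length(tree$tip.label) + which(node_hits))
      tree$node.label <- sub(sentinel, "", tree$node.label, fixed = TRUE)
    }
  }
  fg_edges <- which(tree$edge[, 2L] %in% fg_nodes)
  list(tree = tree, foreground = fg_edges)
}

#' Mark the stem branch of a clade as foreground
#'
#' Returns the index (into `tree$edge`) of the branch subtending the most
#' recent common ancestor of the given taxa — e.g. the ancestral branch of a
#' subfamily designated as the selection foreground. With a single taxon the
#' terminal branch is returned.
#'
#' @param tree An `ape::phylo`.
#' @param taxa Character vector of tip labels.
#' @return Integer edge index (length 1).
#' @export
foreground_stem <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  node <- if (length(taxa) == 1L) {
    which(tree$tip.label == taxa)
  } else {
    ape::getMRCA(tree, taxa)
  }
  edge <- which(tree$edge[, 2L] == node)
  if (length(edge) == 0L) {
    stop("the MRCA of the given taxa is the root; its stem branch does not exist", call. = FALSE)
  }
  edge
}

# Convert a phylo + foreground edge set into the 0-based postorder structure
# the C++ engine consumes.
tree_engine_data <- function(tree, foreground = integer(0)) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  po <- ape::reorder.phylo(tree, "postorder")
  # map foreground edge indices (original order) to postorder rows
  key_orig <- paste(tree$edge[, 1L], tree$edge[, 2L])
  key_po <- paste(po$edge[, 1L], po$edge[, 2L])
  fg_po <- match(key_orig[foreground], key_po)
  fg_flag <- integer(nrow(po$edge))
  fg_flag[fg_po] <- 1L
  list(
    edge = po$edge - 1L,
    elen = po$edge.length,
    fg = fg_flag,
    tips = po$tip.label
  )
}

# Codon alignment -> compressed pattern representation -----------------------

# States are 0-based indices into code$sense_codons; gapped, ambiguous or
# stop-containing codons become missing data (-1) so site indices stay aligned
# with per-site outputs.
codon_patterns <- function(aln, code = genetic_code()) {
  code <- as_code(code)
  if (is.null(names(aln))) stop("alignment must be named by taxon", call. = FALSE)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length", call. = FALSE)
  if (lens[1L] %% 3L != 0L) stop("alignment length ", lens[1L], " is not a multiple of 3", call. = FALSE)
  states <- t(vapply(aln, function(s) {
    cod <- split_codons(s, partial = FALSE)
    idx <- match(cod, code$sense_codons)
    idx[is.na(idx)] <- 0L
    idx - 1L
  }, integer(lens[1L] / 3L)))
  nsites <- ncol(states)
  key <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  site2pat <- match(key, key[upat])
  list(
    states = states[, upat, drop = FALSE],
    counts = as.numeric(table(factor(site2pat, levels = seq_len(sum(upat))))),
    site2pat = site2pat,
    nsites = nsites,
    taxa = rownames(states)
  )
}

match_tree_alignment <- function(pat, eng) {
  missing <- setdiff(eng$tips, pat$taxa)
  extra <- setdiff(pat$taxa, eng$tips)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop(
      "taxon mismatch between tree and alignment",
      if (length(missing) > 0L) paste0("; missing from alignment: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0L) paste0("; absent from tree: ", paste(extra, collapse = ", ")),
      call. = FALSE
    )
  }
  pat$states[eng$tips, , drop = FALSE]
}

#' Per-site log-likelihoods under a codon model
#'
#' Felsenstein pruning over codon columns. `model` is either a single-ratio
#' (M0) description `list(kappa =, omega =)` or a branch-site Model A
#' description `list(kappa =, omega0 =, omega2 =, p0 =, p1 =)`; for the
#' branch-site case `foreground` must name at least one edge and each site's
#' likelihood is the class-proportion-weighted mixture over the four site
#' classes. Gapped or ambiguous codons are treated as missing data.
#'
#' @param aln Named character vector of in-frame aligned CDSs.
#' @param tree `ape::phylo` with branch lengths in expected substitutions per
#'   codon.
#' @param model Model description (see above).
#' @param foreground Integer edge indices (into `tree$edge`) of foreground
#'   branches.
#' @param code A [genetic_code()].
#' @param freqs Codon frequencies; default F3x4 from the alignment.
#' @return Numeric vector of per-site log-likelihoods (one per codon column).
#' @export
site_log_likelihoods <- function(aln, tree, model, foreground = integer(0),
                                 code = genetic_code(), freqs = NULL) {
  code <- as_code(code)
  pat <- codon_patterns(aln, code)
  eng <- tree_engine_data(tree, foreground)
  states <- match_tree_alignment(pat, eng)
  if (is.null(freqs)) freqs <- f3x4_frequencies(aln, code)
  pi <- as.numeric(freqs[code$sense_codons])
  if (!is.null(model$omega0)) {
    w <- model_a_weights(model$p0, model$p1)
    Qs <- bs_scaled_generators(model$kappa, model$omega0, model$omega2, freqs, code, w)
    f_hk <- cpp_bs_class_loglik(states, eng$edge, eng$elen, eng$fg, Qs, pi)
    mx <- apply(f_hk, 1L, max)
    lnl_pat <- mx + log(as.numeric(exp(f_hk - mx) %*% w))
  } else {
    Q <- gy94_matrix(model$kappa, model$omega, freqs, code, scale = "unit")
    lnl_pat <- as.numeric(cpp_site_loglik(
      states, eng$edge, eng$elen, eng$fg, list(Q), pi, 0L, 0L
    ))
  }
  lnl_pat[pat$site2pat]
}

# Model A class weights (p0, p1, p2a, p2b) from the free proportions
model_a_weights <- function(p0, p1) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1)
  rest <- 1 - p0 - p1
  if (p0 + p1 == 0) {
    c(0, 0, rest / 2, rest / 2)
  } else {
    c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
  }
}

# The three class generators (omega0, 1, omega2) under the common
# mixture-weighted scaling: branch lengths are expected substitutions per
# codon averaged over site classes on background branches.
bs_scaled_generators <- function(kappa, omega0, omega2, freqs, code, weights) {
  r0 <- gy94_rate(kappa, omega0, freqs, code)
  r1 <- gy94_rate(kappa, 1, freqs, code)
  # background omega of the classes: w0, w1, w0, w1
  cfac <- sum(weights * c(r0, r1, r0, r1))
  if (cfac <= 0) cfac <- 1
  list(
    gy94_matrix(kappa, omega0, freqs, code, scale = "none") / cfac,
    gy94_matrix(kappa, 1, freqs, code, scale = "none") / cfac,
    gy94_matrix(kappa, omega2, freqs, code, scale = "none") / cfac
  )
}
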