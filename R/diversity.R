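# Alignment utilities -------------------------------------------------------

aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

# TRUE where a character takes part in comparisons (not a gap and not N)
included_mask <- function(m) {
  m != "-" & m != "N" & m != "?" & m != "."
}

#' Segregating sites
#'
#' Number of alignment columns with more than one distinct base among the
#' included (non-gap, non-N) characters.
#'
#' @param aln Named character vector of aligned sequences (or a character
#'   matrix).
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  m <- aln_matrix(aln)
  inc <- included_mask(m)
  sum(vapply(seq_len(ncol(m)), function(j) {
    b <- m[inc[, j], j]
    length(unique(b)) > 1L
  }, logical(1)))
}

#' Nucleotide diversity (Pi)
#'
#' Mean pairwise proportion of differing sites over all unordered sequence
#' pairs. Gap handling is per pair ("pairwise deletion", the default): a
#' column is excluded for a pair when either member carries a gap or N there;
#' with `gaps = "complete"` any column containing a gap or N in any sequence
#' is excluded for all pairs.
#'
#' @param aln Named character vector of aligned sequences (>= 2) or matrix.
#' @param gaps `"pairwise"` (default) or `"complete"`.
#' @return Pi (numeric scalar in \[0, 1\]).
#' @export
nucleotide_diversity <- function(aln, gaps = c("pairwise", "complete")) {
  gaps <- match.arg(gaps)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  inc <- included_mask(m)
  if (gaps == "complete") {
    keep <- colSums(inc) == n
    m <- m[, keep, drop = FALSE]
    inc <- inc[, keep, drop = FALSE]
  }
  tot <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- inc[i, ] & inc[j, ]
      L <- sum(ok)
      if (L == 0L) next
      tot <- tot + sum(m[i, ok] != m[j, ok]) / L
      np <- np + 1L
    }
  }
  if (np == 0L) stop("no comparable columns in any pair", call. = FALSE)
  tot / np
}

#' Sliding-window nucleotide diversity
#'
#' Computes Pi in windows of alignment columns (default 100 bp window, 25 bp
#' step, the convention used for per-gene diversity scans). Windows are in
#' alignment coordinates; a final partial window is dropped.
#'
#' @param aln Named character vector of aligned sequences or matrix.
#' @param window,step Window length and step in alignment columns.
#' @param gaps Gap handling, see [nucleotide_diversity()].
#' @return Tibble: `start`, `end` (1-based inclusive columns), `midpoint`,
#'   `pi`.
#' @export
sliding_window_pi <- function(aln, window = 100L, step = 25L, gaps = "pairwise") {
  m <- aln_matrix(aln)
  L <- ncol(m)
  if (window > L) stop("window (", window, ") exceeds alignment length (", L, ")", call. = FALSE)
  starts <- seq(1L, L - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    w <- m[, s:(s + window - 1L), drop = FALSE]
    tibble::tibble(
      start = s, end = s + window - 1L,
      midpoint = s + (window - 1) / 2,
      pi = nucleotide_diversity(w, gaps = gaps)
    )
  })
  dplyr::bind_rows(rows)
}

#' Haplotype diversity (Hd)
#'
#' Hd = n/(n-1) * (1 - sum(p_i^2)) over haplotype frequencies p_i, the
#' small-sample-corrected probability that two sampled haplotypes differ.
#' Sequences are grouped into the same haplotype when they are identical at
#' every column where both carry an included (non-gap, non-N) base.
#'
#' @param seqs Named character vector of aligned sequences (>= 2).
#' @return List with `hd`, `n_haplotypes`, and `haplotype` (integer
#'   assignment per sequence).
#' @export
haplotype_diversity <- function(seqs) {
  m <- aln_matrix(seqs)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  inc <- included_mask(m)
  hap <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ok <- inc[i, ] & inc[j, ]
        if (!any(m[i, ok] != m[j, ok])) {
          hap[i] <- hap[j]
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      next_id <- next_id + 1L
      hap[i] <- next_id
    }
  }
  p <- as.numeric(table(hap)) / n
  hd <- n / (n - 1) * (1 - sum(p^2))
  list(hd = hd, n_haplotypes = next_id, haplotype = hap)
}

#' Mean pairwise sequence identity
#'
#' Mean over unordered pairs of the percentage of matching included columns,
#' at the nucleotide level or after translation to amino acids.
#'
#' @param aln Named character vector of aligned sequences (>= 2). For
#'   `level = "aa"`, in-frame nucleotide alignments are translated first
#'   (codons containing gaps become `X` and are excluded).
#' @param level `"nucleotide"` (default) or `"aa"`.
#' @param code Genetic code used for `level = "aa"`.
#' @return Mean identity in percent.
#' @export
pairwise_identity <- function(aln, level = c("nucleotide", "aa"), code = genetic_code()) {
  level <- match.arg(level)
  if (level == "aa") {
    aln <- vapply(aln, function(s) {
      cod <- split_codons(s, partial = TRUE)
      aa <- as_code(code)$aa[cod]
      aa[is.na(aa)] <- "X"
      aa[aa == "*"] <- "X"
      paste(aa, collapse = "")
    }, character(1))
  }
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  inc <- if (level == "aa") m != "-" & m != "X" & m != "?" else included_mask(m)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- inc[i, ] & inc[j, ]
      L <- sum(ok)
      if (L == 0L) {
        warning("pair (", i, ",", j, ") has no comparable columns; skipped", call. = FALSE)
        next
      }
      vals <- c(vals, 100 * sum(m[i, ok] == m[j, ok]) / L)
    }
  }
  mean(vals)
}

#' Per-gene diversity profile
#'
#' Bundles the population summaries reported per gene: number of sequences,
#' segregating sites S, nucleotide diversity Pi, haplotype diversity Hd, and
#' the sliding-window Pi track.
#'
#' @param aln Named character vector of aligned sequences (>= 2).
#' @param window,step Sliding-window settings; windows are skipped when the
#'   alignment is shorter than `window`.
#' @return List with `summary` (one-row tibble: `n`, `S`, `pi`, `hd`,
#'   `n_haplotypes`) and `windows` (tibble from [sliding_window_pi()], possibly
#'   empty).
#' @export
diversity_profile <- function(aln, window = 100L, step = 25L) {
  m <- aln_matrix(aln)
  hap <- haplotype_diversity(aln)
  windows <- if (ncol(m) >= window) {
    sliding_window_pi(aln, window = window, step = step)
  } else {
    tibble::tibble(start = integer(0), end = integer(0), midpoint = numeric(0), pi = numeric(0))
  }
  list(
    summary = tibble::tibble(
      n = nrow(m), S = segregating_sites(aln),
      pi = nucleotide_diversity(aln), hd = hap$hd,
      n_haplotypes = hap$n_haplotypes
    ),
    windows = windows
  )
}
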