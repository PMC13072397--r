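NUC <- c("A", "C", "G", "T")

# Fraction of synonymous single-nucleotide changes per codon (Nei-Gojobori).
# Each position contributes (synonymous changes)/3; changes creating a stop
# codon count as nonsynonymous, so synonymous + nonsynonymous sites per codon
# always total 3.
syn_sites_codon <- function(codon, code) {
  aa0 <- code$aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(NUC, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!is.na(code$aa[mut]) && code$aa[[mut]] == aa0 && code$aa[[mut]] != "*") {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal mutational pathways (orderings of the differing positions);
# pathways passing through a stop codon are excluded when any stop-free
# pathway exists.
codon_path_differences <- function(c1, c2, code) {
  diff_pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(diff_pos)
  path_counts <- matrix(NA_real_, nrow = nrow(perms), ncol = 2L)
  via_stop <- logical(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    cur <- c1
    sd <- 0
    nd <- 0
    for (pos in perms[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code$aa[[nxt]] == "*" && nxt != c2) via_stop[p] <- TRUE
      if (code$aa[[cur]] == code$aa[[nxt]] && code$aa[[nxt]] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    path_counts[p, ] <- c(sd, nd)
  }
  use <- if (all(via_stop)) rep(TRUE, nrow(perms)) else !via_stop
  c(
    sd = mean(path_counts[use, 1L]),
    nd = mean(path_counts[use, 2L])
  )
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, nrow = 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` applied to a proportion of differing
#' sites. Undefined (saturated) at `p >= 3/4`.
#'
#' @param p Proportion of sites differing.
#' @return Corrected distance.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75)) {
    stop("substitution saturation: proportion >= 3/4, Jukes-Cantor correction undefined", call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame coding sequences, with fractional site counts averaged between
#' the sequences, differences averaged over all minimal mutational pathways
#' (stop-bearing pathways excluded when avoidable), and Jukes-Cantor
#' correction of both proportions. Ka/Ks < 1 indicates purifying selection,
#' > 1 positive selection.
#'
#' @param cds1,cds2 Equal-length in-frame stop-free CDSs. Codons containing
#'   gaps or ambiguity characters in either sequence are skipped.
#' @param code A [genetic_code()].
#' @return One-row tibble: `S_sites`, `N_sites`, `Sd`, `Nd`, `ps`, `pn`, `Ks`,
#'   `Ka`, `ka_ks` (`NA` when Ks = 0).
#' @export
ka_ks <- function(cds1, cds2, code = genetic_code()) {
  code <- as_code(code)
  if (nchar(cds1) != nchar(cds2)) {
    stop("sequences differ in length (", nchar(cds1), " vs ", nchar(cds2), ")", call. = FALSE)
  }
  cod1 <- split_codons(cds1, partial = TRUE)
  cod2 <- split_codons(cds2, partial = TRUE)
  sense <- code$sense_codons
  keep <- cod1 %in% sense & cod2 %in% sense
  cod1 <- cod1[keep]
  cod2 <- cod2[keep]
  if (length(cod1) == 0L) stop("no comparable sense codons", call. = FALSE)
  syn_cache <- new.env(parent = emptyenv())
  syn_of <- function(cd) {
    if (is.null(syn_cache[[cd]])) syn_cache[[cd]] <- syn_sites_codon(cd, code)
    syn_cache[[cd]]
  }
  s1 <- vapply(cod1, syn_of, numeric(1))
  s2 <- vapply(cod2, syn_of, numeric(1))
  S_sites <- (sum(s1) + sum(s2)) / 2
  N_sites <- 3 * length(cod1) - S_sites
  sd_tot <- 0
  nd_tot <- 0
  for (i in seq_along(cod1)) {
    if (cod1[i] != cod2[i]) {
      d <- codon_path_differences(cod1[i], cod2[i], code)
      sd_tot <- sd_tot + d[["sd"]]
      nd_tot <- nd_tot + d[["nd"]]
    }
  }
  ps <- if (S_sites > 0) sd_tot / S_sites else 0
  pn <- nd_tot / N_sites
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  tibble::tibble(
    S_sites = S_sites, N_sites = N_sites, Sd = sd_tot, Nd = nd_tot,
    ps = ps, pn = pn, Ks = Ks, Ka = Ka,
    ka_ks = if (Ks > 0) Ka / Ks else NA_real_
  )
}

#' All-pairs Ka/Ks for a set of coding sequences
#'
#' @param cds_set Named character vector of equal-length in-frame CDSs.
#' @param code A [genetic_code()].
#' @return Tibble with one row per unordered pair (`id1`, `id2`) plus the
#'   [ka_ks()] columns.
#' @export
ka_ks_matrix <- function(cds_set, code = genetic_code()) {
  ids <- names(cds_set)
  if (is.null(ids)) ids <- paste0("seq", seq_along(cds_set))
  n <- length(cds_set)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      est <- ka_ks(cds_set[[i]], cds_set[[j]], code)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(id1 = ids[i], id2 = ids[j]), est
      )
    }
  }
  dplyr::bind_rows(rows)
}
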