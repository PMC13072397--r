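#' Count codon usage over sense codons
#'
#' Tallies codon occurrences across one or more in-frame coding sequences.
#' Stop codons (including a completed terminal stop) and codons containing
#' ambiguity characters are excluded.
#'
#' @param cds_set Character vector of in-frame CDSs.
#' @param code A [genetic_code()].
#' @return Named integer vector over the code's sense codons.
#' @export
codon_counts <- function(cds_set, code = genetic_code()) {
  code <- as_code(code)
  counts <- stats::setNames(integer(length(code$sense_codons)), code$sense_codons)
  for (s in cds_set) {
    cod <- split_codons(s, partial = TRUE)
    cod <- cod[cod %in% code$sense_codons]
    if (length(cod) > 0L) {
      t <- table(cod)
      counts[names(t)] <- counts[names(t)] + as.integer(t)
    }
  }
  counts
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family, so values above 1 mark preferred codons. In AT-biased
#' mitogenomes, AT-ending codons typically carry RSCU > 1. Families with zero
#' total usage get `NA` (undefined), not 0.
#'
#' @param counts Named counts over sense codons (from [codon_counts()]).
#' @param code A [genetic_code()].
#' @return Tibble: `codon`, `aa`, `family_size`, `count`, `rscu`. Within each
#'   used family the RSCU values sum to the family size.
#' @export
rscu <- function(counts, code = genetic_code()) {
  code <- as_code(code)
  rows <- purrr::imap(code$families, function(codons, aa) {
    n <- counts[codons]
    tot <- sum(n)
    tibble::tibble(
      codon = codons, aa = aa, family_size = length(codons),
      count = as.integer(n),
      rscu = if (tot == 0L) NA_real_ else as.numeric(n) / (tot / length(codons))
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$aa, .data$codon)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC estimator generalized to the synonymous-family structure of
#' the active genetic code. For each family with total usage n and codon
#' proportions p, the codon homozygosity is F = (n * sum(p^2) - 1)/(n - 1);
#' families are grouped by size k and ENC = sum over size classes of
#' a_k / mean(F_k) where a_k is the number of families of size k. Under the
#' invertebrate mitochondrial code the classes are 13 two-fold, 5 four-fold,
#' one six-fold and one eight-fold family (max ENC = 62). A size class whose
#' families are all uninformative (n < 2 or F <= 0) is imputed from the mean
#' of the neighbouring classes' mean F (flagged in the `imputed` attribute);
#' the estimate is capped at the number of sense codons.
#'
#' @param counts Named counts over sense codons.
#' @param code A [genetic_code()].
#' @return ENC (numeric scalar) with attribute `imputed` (character vector of
#'   imputed family sizes, empty when none).
#' @export
enc <- function(counts, code = genetic_code()) {
  code <- as_code(code)
  fams <- code$families
  sizes <- vapply(fams, length, integer(1))
  fams <- fams[sizes > 1L] # single-codon families carry no usage information
  sizes <- sizes[sizes > 1L]
  f_hat <- vapply(seq_along(fams), function(i) {
    n_c <- counts[fams[[i]]]
    n <- sum(n_c)
    if (n < 2L) return(NA_real_)
    p <- n_c / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- sort(unique(sizes))
  fbar <- vapply(classes, function(k) {
    vals <- f_hat[sizes == k & !is.na(f_hat) & f_hat > 0]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, numeric(1))
  names(fbar) <- as.character(classes)
  imputed <- character(0)
  if (anyNA(fbar)) {
    for (i in which(is.na(fbar))) {
      neigh <- fbar[!is.na(fbar)]
      if (length(neigh) == 0L) {
        stop("ENC undefined: no informative synonymous family", call. = FALSE)
      }
      # mean of the nearest informative classes on either side (Wright's rule)
      ks <- as.integer(names(neigh))
      k0 <- classes[i]
      lower <- neigh[ks < k0]
      upper <- neigh[ks > k0]
      fbar[i] <- mean(c(
        if (length(lower) > 0L) lower[length(lower)],
        if (length(upper) > 0L) upper[1L]
      ))
      imputed <- c(imputed, names(fbar)[i])
    }
  }
  a_k <- vapply(classes, function(k) sum(sizes == k), numeric(1))
  singletons <- sum(vapply(code$families, length, integer(1)) == 1L)
  est <- singletons + sum(a_k / fbar)
  est <- min(est, length(code$sense_codons))
  structure(est, imputed = imputed)
}

#' Expected ENC under mutation bias alone
#'
#' The null expectation of ENC as a function of third-position GC content
#' (s = GC3): `2 + s + 29 / (s^2 + (1 - s)^2)`. Species plotting below this
#' curve show codon bias beyond what composition alone explains.
#'
#' @param gc3 Numeric vector of GC3 fractions in (0, 1) (endpoints evaluated
#'   literally).
#' @return Expected ENC values.
#' @examples
#' enc_expected(0.5) # 60.5
#' @export
enc_expected <- function(gc3) {
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Codon bias index (CBI)
#'
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_opt counts occurrences of
#' "optimal" codons, N_tot the total codons in degenerate families, and N_ran
#' the expected optimal count under uniform synonymous usage. CBI is 1 when
#' only optimal codons are used and 0 under uniform usage.
#'
#' @param counts Named counts over sense codons.
#' @param code A [genetic_code()].
#' @param optimal Character vector with at least one codon per degenerate
#'   family; defaults to [optimal_codons()] computed from `counts` itself.
#' @return CBI (numeric scalar).
#' @export
cbi <- function(counts, code = genetic_code(), optimal = NULL) {
  code <- as_code(code)
  fams <- code$families
  fams <- fams[vapply(fams, length, integer(1)) > 1L]
  if (is.null(optimal)) optimal <- optimal_codons(counts, code)
  n_opt <- 0
  n_tot <- 0
  n_ran <- 0
  for (codons in fams) {
    n_fam <- sum(counts[codons])
    opt_here <- intersect(optimal, codons)
    if (length(opt_here) == 0L) {
      stop("no optimal codon supplied for family {", paste(codons, collapse = ","), "}", call. = FALSE)
    }
    n_tot <- n_tot + n_fam
    n_opt <- n_opt + sum(counts[opt_here])
    n_ran <- n_ran + n_fam * length(opt_here) / length(codons)
  }
  if (n_tot == n_ran) stop("CBI undefined: no synonymous degeneracy in usage", call. = FALSE)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Default optimal-codon set: the most frequent synonym per family
#'
#' @param counts Named counts over sense codons (typically pooled over the
#'   whole dataset).
#' @param code A [genetic_code()].
#' @return Character vector, one codon per degenerate family (alphabetical
#'   tie-break).
#' @export
optimal_codons <- function(counts, code = genetic_code()) {
  code <- as_code(code)
  fams <- code$families
  fams <- fams[vapply(fams, length, integer(1)) > 1L]
  vapply(fams, function(codons) {
    n <- counts[codons]
    sort(codons[n == max(n)])[1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Per-taxon codon-usage summary
#'
#' Computes the codon-usage bias indices reported per species: ENC, CBI, GC%
#' and GC3% of the pooled protein-coding genes.
#'
#' @param cds_by_taxon Named list; each element a character vector of in-frame
#'   CDSs for one taxon.
#' @param code A [genetic_code()].
#' @param optimal Optional optimal-codon set for CBI; defaults to the most
#'   frequent synonyms over the pooled dataset.
#' @return Tibble: `id`, `n_codons`, `ENC`, `CBI`, `GC_pct`, `GC3_pct`.
#' @export
codon_usage <- function(cds_by_taxon, code = genetic_code(), optimal = NULL) {
  code <- as_code(code)
  if (is.null(optimal)) {
    pooled <- codon_counts(unlist(cds_by_taxon, use.names = FALSE), code)
    optimal <- optimal_codons(pooled, code)
  }
  rows <- purrr::imap(cds_by_taxon, function(cds, id) {
    counts <- codon_counts(cds, code)
    comp <- base_composition(paste(cds, collapse = ""))
    pp <- per_position_composition(cds)
    tibble::tibble(
      id = id,
      n_codons = sum(counts),
      ENC = as.numeric(enc(counts, code)),
      CBI = cbi(counts, code, optimal),
      GC_pct = comp$GC_pct,
      GC3_pct = pp$GC_pct[pp$scope == "pos3"]
    )
  })
  dplyr::bind_rows(rows)
}
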