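#' Nucleotide composition and strand skews
#'
#' Computes base counts, AT/GC content and the strand-asymmetry skews
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C) for one or more
#' sequences, as profiled for whole mitogenomes, individual genes and the
#' control region. `N` and gap characters are excluded from all numerators and
#' denominators. Skews are computed on the sequence as given, i.e. on the
#' majority (J-) strand when the input is a forward-strand genome.
#'
#' @param seqs Character vector of nucleotide sequences (named or not).
#' @param scope Optional scope label(s) recycled across sequences (e.g.
#'   `"whole_genome"`, a gene name, `"CR"`).
#' @return Tibble with one row per sequence: `id`, `scope`, counts `A,C,G,T`,
#'   `n_counted`, `AT_pct`, `GC_pct`, `AT_skew`, `GC_skew`.
#' @examples
#' base_composition("AAAT") # AT_skew = 0.5
#' @export
base_composition <- function(seqs, scope = NA_character_) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  scope <- rep_len(scope, length(seqs))
  rows <- purrr::map2(unname(seqs), seq_along(seqs), function(s, i) {
    cnt <- base_counts(s)
    tot <- sum(cnt)
    if (tot == 0L) {
      stop("sequence '", ids[i], "' has no countable (A/C/G/T) bases", call. = FALSE)
    }
    at <- cnt[["A"]] + cnt[["T"]]
    gc <- cnt[["G"]] + cnt[["C"]]
    tibble::tibble(
      id = ids[i], scope = scope[i],
      A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
      n_counted = tot,
      AT_pct = 100 * at / tot,
      GC_pct = 100 * gc / tot,
      AT_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
      GC_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

base_counts <- function(s) {
  s <- toupper(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  c(
    A = sum(v == "A"), C = sum(v == "C"),
    G = sum(v == "G"), T = sum(v == "T")
  )
}

#' Composition by codon position
#'
#' Profiles first, second and third codon positions separately, pooled across
#' a set of in-frame coding sequences. In AT-biased mitogenomes the third
#' position typically shows the highest AT content.
#'
#' @param cds_set Character vector of in-frame CDSs (a trailing incomplete
#'   codon of 1-2 bases per gene is trimmed before pooling).
#' @return Tibble with three rows (`scope` = `"pos1"`, `"pos2"`, `"pos3"`).
#' @export
per_position_composition <- function(cds_set) {
  pooled <- c(p1 = "", p2 = "", p3 = "")
  for (s in cds_set) {
    s <- toupper(s)
    n <- nchar(s)
    n <- n - (n %% 3L)
    if (n == 0L) next
    v <- strsplit(substr(s, 1L, n), "", fixed = TRUE)[[1L]]
    pos <- rep_len(1:3, n)
    pooled["p1"] <- paste0(pooled["p1"], paste(v[pos == 1L], collapse = ""))
    pooled["p2"] <- paste0(pooled["p2"], paste(v[pos == 2L], collapse = ""))
    pooled["p3"] <- paste0(pooled["p3"], paste(v[pos == 3L], collapse = ""))
  }
  if (all(nchar(pooled) == 0L)) stop("no complete codons in input", call. = FALSE)
  base_composition(stats::setNames(pooled, c("pos1", "pos2", "pos3")),
    scope = c("pos1", "pos2", "pos3")
  )
}

#' Composition profile of a whole mitogenome and its parts
#'
#' Convenience wrapper producing the per-taxon composition report: whole
#' genome, each annotated feature, the control region, and the three pooled
#' codon positions of the protein-coding genes.
#'
#' @param mito A [mitogenome()].
#' @return Tibble in [base_composition()] format (plus a `taxon` column).
#' @export
composition_report <- function(mito) {
  rows <- list(base_composition(stats::setNames(mito$sequence, mito$id), scope = "whole_genome"))
  for (i in seq_len(nrow(mito$features))) {
    f <- mito$features[i, ]
    rows[[length(rows) + 1L]] <- base_composition(
      stats::setNames(extract_gene(mito, f$name), mito$id),
      scope = f$name
    )
  }
  pcgs <- mito$features$name[mito$features$kind == "PCG"]
  if (length(pcgs) > 0L) {
    cds <- vapply(pcgs, function(g) extract_gene(mito, g), character(1))
    pp <- per_position_composition(cds)
    pp$id <- mito$id
    rows[[length(rows) + 1L]] <- pp
  }
  out <- dplyr::bind_rows(rows)
  out$taxon <- mito$taxon
  dplyr::relocate(out, "taxon", .after = "id")
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pairwise group comparisons of a numeric variable
#'
#' Runs Welch's two-sample t-test for every unordered pair of groups (e.g. AT
#' content across habitat classes or families), reporting the statistic,
#' p-value and conventional significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise). Welch's unequal-variance form is used for
#' robustness to the small, unbalanced groups typical of taxon panels; an
#' optional Benjamini-Hochberg adjustment is available.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the numeric variable and the
#'   grouping factor.
#' @param adjust `"none"` (default, raw p-values as usually reported) or
#'   `"BH"`.
#' @return Tibble with one row per group pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
group_compare <- function(data, value, group, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  groups <- unique(g)
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  small <- groups[vapply(groups, function(x) sum(g == x) < 2L, logical(1))]
  if (length(small) > 0L) {
    stop(
      "groups with fewer than 2 observations: ", paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  pairs <- utils::combn(groups, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- v[g == pr[1L]]
    y <- v[g == pr[2L]]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(
      group1 = pr[1L], group2 = pr[2L], n1 = length(x), n2 = length(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- significance_stars(out$p_value)
  out
}

#' Pearson correlation with least-squares fit
#'
#' Correlation analysis as used to relate Ka/Ks or codon-bias indices to GC
#' content: Pearson's r, R-squared, the two-sided p-value for r, and the
#' fitted least-squares line.
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @return One-row tibble: `n`, `r`, `r_squared`, `p_value`, `intercept`,
#'   `slope`.
#' @export
correlate <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined: zero variance in '", if (stats::sd(xv) == 0) x else y, "'", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv)
  fit <- stats::lm(yv ~ xv)
  tibble::tibble(
    n = length(xv),
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L])
  )
}
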