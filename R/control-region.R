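# Control-region architecture ------------------------------------------------

#' Find tandem repeats in a nucleotide sequence
#'
#' Detects tandem repeat arrays by exact k-mer recurrence seeding followed by
#' verification of each candidate period: positions where the sequence equals
#' itself shifted by the period are scored (+match weight / -mismatch weight)
#' and maximal positive-scoring segments become candidate arrays. Overlapping
#' reports from different periods are merged keeping the best score (smaller
#' period wins ties, so a period-4 array is not also reported at period 8).
#' The consensus motif is the column-majority over copies. The detector
#' models substitutional divergence between copies; the indel weight is
#' accepted for interface compatibility but indels within an array are not
#' aligned around.
#'
#' @param seq Nucleotide string.
#' @param weights Named vector `c(match = 2, mismatch = 7, indel = 7)`.
#' @param min_score Minimum segment score (match minus mismatch weighted);
#'   the default of 8 keeps a perfect 3-copy period-2 array detectable.
#' @param min_period,max_period Period search range.
#' @param min_copies Minimum (fractional) copy number to report.
#' @return Tibble with 0-based half-open `start`, `end`, plus `period`,
#'   `copy_number`, `consensus`, `percent_matches`, `score`; zero rows when
#'   nothing is found.
#' @export
find_tandem_repeats <- function(seq, weights = c(match = 2, mismatch = 7, indel = 7),
                                min_score = 8, min_period = 2L, max_period = 2000L,
                                min_copies = 1.9) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- tibble::tibble(
    start = integer(0), end = integer(0), period = integer(0),
    copy_number = numeric(0), consensus = character(0),
    percent_matches = numeric(0), score = numeric(0)
  )
  if (n < 2L * min_period) return(empty)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  # k-mer recurrence seeding: distances between successive occurrences of the
  # same 3-mer are the candidate periods
  k <- 3L
  cands <- integer(0)
  if (n >= k + min_period) {
    kmers <- substring(seq, 1:(n - k + 1L), k:n)
    occ <- split(seq_along(kmers), kmers)
    # consecutive-occurrence distances miss the nominal period when a k-mer
    # recurs within one copy (or in homopolymer runs), so distances to the
    # first occurrence are included as well
    d <- unlist(lapply(occ, function(p) {
      if (length(p) > 1L) c(diff(p), p[-1L] - p[1L]) else integer(0)
    }), use.names = FALSE)
    cands <- sort(unique(d[d >= min_period & d <= min(max_period, n %/% 2L)]))
  }
  if (length(cands) == 0L) return(empty)
  hits <- list()
  for (p in cands) {
    m <- v[seq_len(n - p)] == v[(p + 1L):n]
    sc <- ifelse(m, weights[["match"]], -weights[["mismatch"]])
    # maximal positive-scoring segments (one best segment per positive run)
    cur <- 0
    seg_start <- 1L
    best <- -Inf
    best_end <- 0L
    flush <- function(i_end) {
      if (best >= min_score) {
        a <- seg_start # match-vector coords: array spans [a, best_end + p]
        len <- best_end + p - a + 1L
        cn <- len / p
        if (cn >= min_copies) {
          span <- v[a:(best_end + p)]
          cols <- ((seq_along(span) - 1L) %% p) + 1L
          consensus <- vapply(seq_len(p), function(cc) {
            names(which.max(table(span[cols == cc])))
          }, character(1))
          hits[[length(hits) + 1L]] <<- tibble::tibble(
            start = a - 1L, end = best_end + p, period = p, copy_number = cn,
            consensus = paste(consensus, collapse = ""),
            percent_matches = 100 * mean(m[a:best_end]),
            score = best
          )
        }
      }
    }
    for (i in seq_along(sc)) {
      if (cur <= 0) {
        flush(i)
        cur <- 0
        seg_start <- i
        best <- -Inf
      }
      cur <- cur + sc[i]
      if (cur > best) {
        best <- cur
        best_end <- i
      }
    }
    flush(length(sc) + 1L)
  }
  if (length(hits) == 0L) return(empty)
  out <- dplyr::bind_rows(hits)
  out <- out[order(-out$score, out$period), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1L):nrow(out)) {
        if (!keep[j]) next
        ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
        shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
        if (ov > 0.5 * shorter) keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, ]
  out[order(out$start), ]
}

#' Conserved blocks of a multiple alignment
#'
#' Maximal runs of gap-free, 100%-identical alignment columns of length at
#' least `min_len`, as used to segment aligned control regions into conserved
#' and variable regions.
#'
#' @param aln Named character vector of aligned sequences (>= 2) or matrix.
#' @param min_len Minimum block length (default 3, i.e. "longer than 2 bp").
#' @return Tibble: `block`, `start`, `end` (1-based inclusive alignment
#'   columns), `length`.
#' @export
conserved_blocks <- function(aln, min_len = 3L) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences", call. = FALSE)
  identical_col <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    !any(col %in% c("-", "N", "?")) && length(unique(col)) == 1L
  }, logical(1))
  r <- rle(identical_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(
    block = seq_len(sum(keep)),
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}

find_motif_runs <- function(seq, pattern, class) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(tibble::tibble(
      class = character(0), start = integer(0), end = integer(0)
    ))
  }
  tibble::tibble(
    class = class,
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}

#' Annotate control-region architecture
#'
#' Composes tandem-repeat detection with motif scans over the control region:
#' poly-A / poly-T runs, (TA)n microsatellite stretches, and a windowed AT%
#' track, then assembles an ordered feature list (repeat arrays, motif runs,
#' and the spacers between them).
#'
#' @param mito A [mitogenome()] with a `CR` feature (or a raw CR string).
#' @param min_polyrun Minimum poly-A/poly-T run length.
#' @param ta_min_units Minimum (TA) unit count for a microsatellite run.
#' @param at_window Window (and step = window/2) for the AT% track.
#' @param ... Passed to [find_tandem_repeats()].
#' @return List with `repeats`, `motifs`, `features` (ordered segmentation,
#'   0-based half-open) and `at_track` tibbles, plus `cr_length`.
#' @export
annotate_cr <- function(mito, min_polyrun = 6L, ta_min_units = 3L, at_window = 50L, ...) {
  cr <- if (inherits(mito, "mitogenome")) extract_gene(mito, "CR") else toupper(mito)
  n <- nchar(cr)
  reps <- find_tandem_repeats(cr, ...)
  motifs <- dplyr::bind_rows(
    find_motif_runs(cr, sprintf("A{%d,}", min_polyrun), "polyA"),
    find_motif_runs(cr, sprintf("T{%d,}", min_polyrun), "polyT"),
    find_motif_runs(cr, sprintf("(?:TA){%d,}T?", ta_min_units), "TA_microsat")
  )
  annotated <- dplyr::bind_rows(
    if (nrow(reps) > 0L) {
      tibble::tibble(
        class = "tandem_repeat", start = reps$start, end = reps$end,
        attribute = sprintf("period=%d;copies=%.2f", reps$period, reps$copy_number)
      )
    },
    if (nrow(motifs) > 0L) {
      tibble::tibble(class = motifs$class, start = motifs$start, end = motifs$end, attribute = "")
    }
  )
  features <- if (!is.null(annotated) && nrow(annotated) > 0L) {
    annotated <- annotated[order(annotated$start, -annotated$end), ]
    # drop motif runs fully inside an already-claimed segment; fill spacers
    kept <- list()
    cursor <- 0L
    for (i in seq_len(nrow(annotated))) {
      a <- annotated[i, ]
      if (a$start < cursor) next
      if (a$start > cursor) {
        kept[[length(kept) + 1L]] <- tibble::tibble(
          class = "spacer", start = cursor, end = a$start, attribute = ""
        )
      }
      kept[[length(kept) + 1L]] <- a
      cursor <- a$end
    }
    if (cursor < n) {
      kept[[length(kept) + 1L]] <- tibble::tibble(
        class = "spacer", start = cursor, end = n, attribute = ""
      )
    }
    dplyr::bind_rows(kept)
  } else {
    tibble::tibble(class = "spacer", start = 0L, end = n, attribute = "")
  }
  step <- max(1L, at_window %/% 2L)
  at_track <- if (n >= at_window) {
    starts <- seq(1L, n - at_window + 1L, by = step)
    tibble::tibble(
      midpoint = starts + (at_window - 1) / 2,
      at_pct = vapply(starts, function(s) {
        base_composition(substr(cr, s, s + at_window - 1L))$AT_pct
      }, numeric(1))
    )
  } else {
    tibble::tibble(midpoint = numeric(0), at_pct = numeric(0))
  }
  list(
    repeats = reps, motifs = motifs, features = features,
    at_track = at_track, cr_length = n
  )
}
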