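#' Construct an annotated mitogenome object
#'
#' A `mitogenome` holds a circular mitochondrial sequence together with its
#' gene annotation and sample metadata. Insect mitogenomes carry a typical set
#' of 37 genes (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus the
#' non-coding control region between `rrnS` and `trnI`. Feature coordinates
#' are stored 0-based half-open on the forward (majority, "J") strand;
#' user-facing reports and GenBank output convert back to 1-based inclusive.
#'
#' @param id Accession or sample identifier.
#' @param sequence Nucleotide string over `A,C,G,T,N` (other ambiguity codes
#'   are rejected).
#' @param features Data frame with columns `name`, `kind` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control_region`, `intergenic`), `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), and optionally `wraps_origin`
#'   (logical). A feature spanning the origin keeps `end > length` semantics
#'   via `wraps_origin = TRUE` with `end` < `start`.
#' @param taxon,family,subfamily Taxonomy strings.
#' @param habitat One of `"aquatic"`, `"semi_aquatic"`, `"terrestrial"`,
#'   `"unknown"`.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features,
                       taxon = NA_character_, family = NA_character_,
                       subfamily = NA_character_, habitat = "unknown") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", sequence), "")[[1L]])
    stop(
      "sequence of '", id, "' contains unsupported ambiguity codes: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  habitat <- match.arg(habitat, c("aquatic", "semi_aquatic", "terrestrial", "unknown"))
  features <- tibble::as_tibble(features)
  if (!"wraps_origin" %in% names(features)) features$wraps_origin <- FALSE
  features$wraps_origin[is.na(features$wraps_origin)] <- FALSE
  needed <- c("name", "kind", "start", "end", "strand", "wraps_origin")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0L) {
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features <- features[, union(needed, names(features))]
  len <- nchar(sequence)
  ok <- features$wraps_origin |
    (features$end > features$start & features$start >= 0L & features$end <= len)
  if (!all(ok)) {
    stop(
      "feature coordinates out of range for '", id, "': ",
      paste(features$name[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      id = id, taxon = taxon, family = family, subfamily = subfamily,
      habitat = habitat, sequence = sequence, features = features,
      length = len
    ),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  census <- gene_census(x)
  cat(sprintf(
    "<mitogenome> %s (%s), %d bp, %d features [PCG %d | tRNA %d | rRNA %d], habitat: %s\n",
    x$id, ifelse(is.na(x$taxon), "?", x$taxon), x$length, nrow(x$features),
    census$n[census$kind == "PCG"], census$n[census$kind == "tRNA"],
    census$n[census$kind == "rRNA"], x$habitat
  ))
  invisible(x)
}

#' Count annotated features by kind
#'
#' A complete insect mitogenome reports 13 PCGs, 22 tRNAs and 2 rRNAs.
#'
#' @param mito A [mitogenome()].
#' @return Tibble with columns `kind` and `n` (all five kinds always present).
#' @export
gene_census <- function(mito) {
  kinds <- c("PCG", "tRNA", "rRNA", "control_region", "intergenic")
  n <- vapply(kinds, function(k) sum(mito$features$kind == k), integer(1))
  tibble::tibble(kind = kinds, n = unname(n))
}

#' Is a mitogenome annotation complete?
#'
#' @param mito A [mitogenome()].
#' @return `TRUE` when exactly 13 PCG, 22 tRNA and 2 rRNA features are present.
#' @export
is_complete_mitogenome <- function(mito) {
  cen <- gene_census(mito)
  get <- function(k) cen$n[cen$kind == k]
  get("PCG") == 13L && get("tRNA") == 22L && get("rRNA") == 2L
}

#' Extract a gene sequence in reading orientation
#'
#' Slices the named feature out of the genome sequence. Minus-strand features
#' are returned reverse-complemented; features that wrap the circular origin
#' are concatenated across it.
#'
#' @param mito A [mitogenome()].
#' @param name Canonical gene symbol (e.g. `"cox1"`, `"nad5"`, `"CR"`).
#' @return Nucleotide string in the gene's reading orientation.
#' @export
extract_gene <- function(mito, name) {
  idx <- which(mito$features$name == name)
  if (length(idx) == 0L) {
    stop("no feature named '", name, "' in mitogenome '", mito$id, "'", call. = FALSE)
  }
  f <- mito$features[idx[1L], ]
  s <- if (isTRUE(f$wraps_origin)) {
    paste0(
      substr(mito$sequence, f$start + 1L, mito$length),
      substr(mito$sequence, 1L, f$end)
    )
  } else {
    substr(mito$sequence, f$start + 1L, f$end)
  }
  if (identical(f$strand, "-")) revcomp(s) else s
}

#' Length of a feature under circular wraparound
#' @keywords internal
feature_length <- function(f, genome_length) {
  ifelse(f$wraps_origin, (genome_length - f$start) + f$end, f$end - f$start)
}

#' Canonical order of the 13 mitochondrial protein-coding genes
#'
#' Gene order of the ancestral insect mitogenome (shared by hydrophiloid
#' beetles, which show no rearrangement); used for supermatrix concatenation.
#'
#' @return Character vector of 13 gene symbols.
#' @export
pcg_order <- function() {
  c(
    "nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
    "nad5", "nad4", "nad4L", "nad6", "cob", "nad1"
  )
}

#' Concatenate aligned gene blocks into a supermatrix
#'
#' Builds a concatenated alignment from per-gene aligned blocks (e.g. the 13
#' protein-coding genes, optionally plus the two rRNAs), in canonical gene
#' order, together with a partition table mapping each gene to its column
#' range.
#'
#' @param blocks Named list of aligned blocks; each block is a named character
#'   vector (taxon -> aligned sequence) with equal lengths within a block. All
#'   blocks must cover the same taxon set.
#' @param order Gene order to use; defaults to the blocks in [pcg_order()]
#'   order followed by any remaining blocks (e.g. rRNAs) in given order.
#' @return List with `supermatrix` (named character vector), `partitions`
#'   (tibble: `gene`, `start`, `end`, 1-based inclusive columns) and
#'   `charsets` (NEXUS-style charset lines).
#' @export
concatenate_genes <- function(blocks, order = NULL) {
  stopifnot(is.list(blocks), length(blocks) > 0L, !is.null(names(blocks)))
  if (is.null(order)) {
    order <- c(intersect(pcg_order(), names(blocks)), setdiff(names(blocks), pcg_order()))
  }
  stopifnot(all(order %in% names(blocks)))
  taxa <- sort(names(blocks[[order[1L]]]))
  for (g in order) {
    b <- blocks[[g]]
    if (is.null(names(b))) stop("block '", g, "' has no taxon names", call. = FALSE)
    missing <- setdiff(taxa, names(b))
    extra <- setdiff(names(b), taxa)
    if (length(missing) > 0L || length(extra) > 0L) {
      stop(
        "taxon sets differ in block '", g, "'",
        if (length(missing) > 0L) paste0("; missing: ", paste(missing, collapse = ", ")),
        if (length(extra) > 0L) paste0("; extra: ", paste(extra, collapse = ", ")),
        call. = FALSE
      )
    }
    if (length(unique(nchar(b))) != 1L) {
      stop("block '", g, "' is not aligned (unequal lengths)", call. = FALSE)
    }
  }
  widths <- vapply(order, function(g) nchar(blocks[[g]][[1L]]), integer(1), USE.NAMES = FALSE)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  supermatrix <- vapply(taxa, function(tx) {
    paste(vapply(order, function(g) unname(blocks[[g]][[tx]]), character(1)), collapse = "")
  }, character(1))
  partitions <- tibble::tibble(gene = order, start = starts, end = ends)
  charsets <- sprintf("charset %s = %d-%d;", order, starts, ends)
  list(supermatrix = supermatrix, partitions = partitions, charsets = charsets)
}

#' Alias retained for the protein-coding-gene supermatrix workflow
#' @rdname concatenate_genes
#' @export
concatenate_pcgs <- concatenate_genes
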