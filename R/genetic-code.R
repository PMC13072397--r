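#' Genetic code tables for mitochondrial sequence analysis
#'
#' Wraps an NCBI translation table as the single genetic-code object used by
#' every downstream stage (translation, codon-usage statistics, Ka/Ks and the
#' codon substitution models). The default is the invertebrate mitochondrial
#' code (NCBI table 5), the code used by insect mitochondrial protein-coding
#' genes: `ATA` encodes Met, `TGA` Trp, and `AGA`/`AGG` Ser, leaving `TAA` and
#' `TAG` as the only stops (62 sense codons).
#'
#' @param table NCBI translation table identifier (character or integer, e.g.
#'   `"5"`), or one of the names `"invertebrate_mitochondrial"` /
#'   `"standard"`.
#' @return An object of class `genetic_code`: a list with elements
#'   `id`, `codons` (the 64 codons), `aa` (named amino-acid letters, `"*"` for
#'   stop), `sense_codons`, `stop_codons`, and `families` (a named list
#'   partitioning the sense codons into synonymous families by amino acid).
#' @examples
#' code <- genetic_code()
#' code$aa[["ATA"]] # "M" under the invertebrate mitochondrial code
#' @export
genetic_code <- local({
  cache <- new.env(parent = emptyenv())
  function(table = "invertebrate_mitochondrial") {
    id <- switch(as.character(table),
      invertebrate_mitochondrial = "5",
      standard = "1",
      as.character(table)
    )
    if (!is.null(cache[[id]])) return(cache[[id]])
    cache[[id]] <- build_genetic_code(id)
    cache[[id]]
  }
})

build_genetic_code <- function(id) {
  aa <- Biostrings::getGeneticCode(id)
  codons <- names(aa)
  sense <- codons[aa != "*"]
  stops <- codons[aa == "*"]
  fam <- split(sense, aa[sense])
  structure(
    list(
      id = id,
      codons = codons,
      aa = aa,
      sense_codons = sense,
      stop_codons = stops,
      families = fam
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "<genetic_code> NCBI table %s: %d sense codons, stops: %s\n",
    x$id, length(x$sense_codons), paste(x$stop_codons, collapse = ", ")
  ))
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

as_code <- function(code) {
  if (is_genetic_code(code)) code else genetic_code(code)
}

#' Split an in-frame coding sequence into codons
#'
#' @param seq Single nucleotide string, length a multiple of 3 (a trailing
#'   incomplete codon of 1-2 bases is dropped with `partial = TRUE`).
#' @param partial Allow (and drop) a trailing incomplete codon.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(seq, partial = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rem <- n %% 3L
  if (rem != 0L) {
    if (!partial) {
      stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
    }
    seq <- substr(seq, 1L, n - rem)
    n <- n - rem
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate an in-frame coding sequence
#'
#' Translates a mitochondrial CDS, handling the truncated stop codons common in
#' insect mitogenomes: a trailing incomplete codon of one or two bases is
#' treated as a stop completed by polyadenylation and excluded from the
#' peptide, as is a complete terminal stop codon. An internal stop is an error
#' (it indicates a frame or annotation problem) unless `internal_stop =
#' "warn"`.
#'
#' @param seq Nucleotide string (in frame; trailing incomplete codon allowed).
#' @param code A [genetic_code()] object (default invertebrate mitochondrial).
#' @param internal_stop `"error"` (default) or `"warn"`; with `"warn"` internal
#'   stops are translated as `"*"`.
#' @return Single amino-acid string. The attribute `incomplete_stop` is `TRUE`
#'   when a trailing partial codon was completed as a stop.
#' @examples
#' translate_cds("ATTATA") # "IM": ATA is Met in the invertebrate mito code
#' translate_cds("TTTT") # "F", with an incomplete terminal stop
#' @export
translate_cds <- function(seq, code = genetic_code(), internal_stop = c("error", "warn")) {
  internal_stop <- match.arg(internal_stop)
  code <- as_code(code)
  seq <- toupper(seq)
  n <- nchar(seq)
  incomplete <- (n %% 3L) != 0L
  codons <- split_codons(seq, partial = TRUE)
  aa <- unname(code$aa[codons])
  aa[is.na(aa)] <- "X" # codons containing N or gaps
  stop_idx <- which(aa == "*")
  if (length(stop_idx) > 0L) {
    internal <- stop_idx[stop_idx < length(aa)]
    if (length(internal) > 0L) {
      msg <- sprintf(
        "internal stop codon%s at codon position%s %s",
        if (length(internal) > 1L) "s" else "",
        if (length(internal) > 1L) "s" else "",
        paste(internal, collapse = ", ")
      )
      if (internal_stop == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    aa[aa == "*"] <- "*"
  }
  structure(paste(aa, collapse = ""), incomplete_stop = incomplete)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over `A,C,G,T,N` (case-insensitive; `-` kept).
#' @return Reverse-complemented string (upper case).
#' @export
revcomp <- function(seq) {
  s <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
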