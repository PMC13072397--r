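#' Gene-name synonym table
#'
#' Maps the gene-name spellings found in public mitogenome records (e.g.
#' `COI`, `ND5`, `16S ribosomal RNA`, `tRNA-Leu(UUR)`) to the canonical
#' symbols used throughout the package (`cox1`, `nad5`, `rrnL`, `trnL2`, ...).
#' The shipped table can be extended with user entries.
#'
#' @param extra Optional data frame with columns `alias`, `canonical` appended
#'   to (and taking precedence over) the shipped table.
#' @return Tibble with columns `alias` (lower case) and `canonical`.
#' @export
gene_synonyms <- function(extra = NULL) {
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)[, c("alias", "canonical")]
    extra$alias <- tolower(extra$alias)
    tab <- rbind(extra, tab)
    tab <- tab[!duplicated(tab$alias), ]
  }
  tibble::as_tibble(tab)
}

canonical_gene_name <- function(raw, synonyms) {
  key <- tolower(trimws(raw))
  hit <- match(key, synonyms$alias)
  ifelse(is.na(hit), NA_character_, synonyms$canonical[hit])
}

# Parse a GenBank location string into 0-based half-open internal coordinates.
# Supports "a..b", "complement(...)", and "join(a..L,1..b)" origin wraps;
# partial markers (< >) are stripped.
parse_gb_location <- function(loc, genome_length) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(body, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1L]]))
    if (length(rng) == 2L && rng[[1L]][2L] == genome_length && rng[[2L]][1L] == 1L) {
      wraps <- TRUE
      start <- rng[[1L]][1L] - 1L
      end <- rng[[2L]][2L]
    } else {
      # non-wrapping join: take the overall span
      start <- min(vapply(rng, `[`, integer(1), 1L)) - 1L
      end <- max(vapply(rng, `[`, integer(1), 2L))
    }
  } else {
    nums <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums)) stop("cannot parse location '", loc, "'", call. = FALSE)
    start <- nums[1L] - 1L
    end <- nums[2L]
  }
  list(start = start, end = end, strand = strand, wraps_origin = wraps)
}

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one or more GenBank records into [mitogenome()] objects. CDS, tRNA,
#' rRNA and D-loop features are retained; gene names are mapped to canonical
#' symbols via [gene_synonyms()] (an unmappable name is kept with a warning
#' as `kind = "intergenic"`). GenBank 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention, including
#' `join()`-style origin wraps.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param synonyms Synonym table from [gene_synonyms()].
#' @param metadata Optional tibble (from [read_metadata()]) with columns `id`,
#'   `taxon`, `family`, `subfamily`, `habitat` used to fill sample metadata.
#' @return List of [mitogenome()] objects.
#' @export
read_genbank <- function(path, synonyms = gene_synonyms(), metadata = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS line found in '", path, "'", call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    out[[k]] <- parse_gb_record(lines[starts[k]:ends[k]], synonyms, path)
  }
  if (!is.null(metadata)) {
    out <- lapply(out, function(m) {
      row <- metadata[metadata$id == m$id, ]
      if (nrow(row) == 1L) {
        for (fld in intersect(c("taxon", "family", "subfamily", "habitat"), names(row))) {
          if (!is.na(row[[fld]])) m[[fld]] <- row[[fld]]
        }
      }
      m
    })
  }
  out
}

parse_gb_record <- function(rec, synonyms, path) {
  locus_tokens <- strsplit(trimws(rec[1L]), "\\s+")[[1L]]
  id <- locus_tokens[2L]
  if (is.na(id)) stop("malformed LOCUS line in '", path, "'", call. = FALSE)
  org_line <- grep("^\\s{2}ORGANISM", rec, value = TRUE)
  taxon <- if (length(org_line) > 0L) trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1L])) else NA_character_

  ori <- grep("^ORIGIN", rec)
  if (length(ori) == 0L) stop("record '", id, "': no ORIGIN section", call. = FALSE)
  seq_lines <- rec[(ori[1L] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome_length <- nchar(sequence)

  feat_start <- grep("^FEATURES", rec)
  if (length(feat_start) == 0L) stop("record '", id, "': no FEATURES table", call. = FALSE)
  feat_lines <- rec[(feat_start[1L] + 1L):(ori[1L] - 1L)]
  # a new feature starts with a key at column 6
  is_key <- grepl("^\\s{5}\\S", feat_lines)
  idx <- which(is_key)
  feats <- list()
  for (i in seq_along(idx)) {
    block <- feat_lines[idx[i]:(if (i < length(idx)) idx[i + 1L] - 1L else length(feat_lines))]
    header <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    key <- header[1L]
    loc <- paste(header[-1L], collapse = "")
    # location may continue on following lines before the first qualifier
    qual_start <- grep("^\\s+/", block)
    loc_extra <- if (length(qual_start) > 0L && qual_start[1L] > 2L) {
      block[2L:(qual_start[1L] - 1L)]
    } else if (length(qual_start) == 0L && length(block) > 1L) {
      block[-1L]
    } else {
      character(0)
    }
    loc <- paste0(loc, paste(trimws(loc_extra), collapse = ""))
    kind <- switch(key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      `D-loop` = "control_region", misc_feature = "misc", NULL
    )
    if (is.null(kind)) next
    quals <- paste(block[grepl("^\\s+/", block)], collapse = " ")
    get_qual <- function(q) {
      m <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1L]]
      if (length(m) == 2L) m[2L] else NA_character_
    }
    raw_name <- get_qual("gene")
    if (is.na(raw_name)) raw_name <- get_qual("product")
    if (is.na(raw_name)) raw_name <- get_qual("note")
    pos <- tryCatch(parse_gb_location(loc, genome_length), error = function(e) {
      stop("record '", id, "', feature '", key, "': ", conditionMessage(e), call. = FALSE)
    })
    cname <- if (!is.na(raw_name)) canonical_gene_name(raw_name, synonyms) else NA_character_
    if (kind == "misc") {
      kind <- if (!is.na(cname) && cname == "CR") "control_region" else "intergenic"
    }
    if (kind == "control_region") cname <- "CR"
    if (is.na(cname)) {
      warning(
        "record '", id, "': cannot map gene name '", raw_name,
        "'; keeping as intergenic", call. = FALSE
      )
      cname <- if (is.na(raw_name)) key else raw_name
      kind <- "intergenic"
    }
    feats[[length(feats) + 1L]] <- tibble::tibble(
      name = cname, kind = kind,
      start = pos$start, end = pos$end, strand = pos$strand,
      wraps_origin = pos$wraps_origin
    )
  }
  features <- if (length(feats) > 0L) {
    dplyr::bind_rows(feats)
  } else {
    tibble::tibble(
      name = character(0), kind = character(0), start = integer(0),
      end = integer(0), strand = character(0), wraps_origin = logical(0)
    )
  }
  mitogenome(id = id, sequence = sequence, features = features, taxon = taxon)
}

#' Write mitogenomes to a GenBank flat file
#'
#' Serializes [mitogenome()] objects back to GenBank format (reversing the
#' coordinate conversion performed by [read_genbank()], including origin
#' wraps). `read_genbank(write_genbank(x))` reproduces the annotation.
#'
#' @param mitos A [mitogenome()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(mitos, path) {
  if (inherits(mitos, "mitogenome")) mitos <- list(mitos)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mitos) {
    writeLines(sprintf(
      "LOCUS       %s %d bp    DNA     circular INV",
      m$id, m$length
    ), con)
    writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.", ifelse(is.na(m$taxon), m$id, m$taxon)), con)
    writeLines("SOURCE      mitochondrion", con)
    if (!is.na(m$taxon)) writeLines(sprintf("  ORGANISM  %s", m$taxon), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", m$length), con)
    for (i in seq_len(nrow(m$features))) {
      f <- m$features[i, ]
      loc <- if (isTRUE(f$wraps_origin)) {
        sprintf("join(%d..%d,1..%d)", f$start + 1L, m$length, f$end)
      } else {
        sprintf("%d..%d", f$start + 1L, f$end)
      }
      if (identical(f$strand, "-")) loc <- sprintf("complement(%s)", loc)
      key <- switch(f$kind,
        PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
        control_region = "D-loop", "misc_feature"
      )
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(m$sequence)
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (plain or aligned; gaps preserved).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1L, nchar(s), width), pmin(seq(width, nchar(s) + width - 1L, width), nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `id`, `taxon`, `family`, `subfamily`, `habitat`
#' (habitat one of aquatic / semi_aquatic / terrestrial / unknown; missing
#' values become `"unknown"`).
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!"id" %in% names(tab)) stop("metadata must have an 'id' column", call. = FALSE)
  if ("habitat" %in% names(tab)) {
    tab$habitat[is.na(tab$habitat) | tab$habitat == ""] <- "unknown"
    bad <- setdiff(unique(tab$habitat), c("aquatic", "semi_aquatic", "terrestrial", "unknown"))
    if (length(bad) > 0L) {
      stop("unknown habitat values: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    tab$habitat <- "unknown"
  }
  tab
}
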