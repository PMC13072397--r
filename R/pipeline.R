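# End-to-end pipeline ---------------------------------------------------------

#' Validate pipeline inputs
#'
#' Diagnostic checks across a set of mitogenomes, an optional tree and
#' optional metadata: taxa concordance, duplicate ids, missing habitat
#' labels, protein-coding genes whose length is not a multiple of 3 (after
#' incomplete-stop trimming) and internal stop codons.
#'
#' @param mitos List of [mitogenome()] objects.
#' @param tree Optional `ape::phylo`.
#' @param metadata Optional metadata tibble (see [read_metadata()]).
#' @param strict Escalate any diagnostic to an error.
#' @param code A [genetic_code()].
#' @return Tibble of diagnostics: `level` (`warning`), `item`, `message`
#'   (zero rows when clean).
#' @export
validate_inputs <- function(mitos, tree = NULL, metadata = NULL, strict = FALSE,
                            code = genetic_code()) {
  code <- as_code(code)
  rows <- list()
  note <- function(item, message) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      level = "warning", item = item, message = message
    )
  }
  ids <- vapply(mitos, function(m) m$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note(d, "duplicate mitogenome id")
  for (m in mitos) {
    if (m$habitat == "unknown") note(m$id, "habitat label missing (unknown)")
    pcgs <- m$features$name[m$features$kind == "PCG"]
    for (g in pcgs) {
      s <- extract_gene(m, g)
      n <- nchar(s)
      if (n < 6L) note(m$id, sprintf("%s: PCG shorter than 6 bp", g))
      cod <- split_codons(s, partial = TRUE)
      aa <- code$aa[cod]
      internal <- which(aa == "*")
      internal <- internal[internal < length(cod)]
      if (length(internal) > 0L) {
        note(m$id, sprintf("%s: internal stop codon at codon %d", g, internal[1L]))
      }
    }
  }
  if (!is.null(tree)) {
    missing <- setdiff(tree$tip.label, ids)
    for (t in missing) note(t, "tree taxon absent from genomes")
    extra <- setdiff(ids, tree$tip.label)
    for (t in extra) note(t, "genome absent from tree")
  }
  if (!is.null(metadata)) {
    missing <- setdiff(ids, metadata$id)
    for (t in missing) note(t, "genome absent from metadata")
  }
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(level = character(0), item = character(0), message = character(0))
  }
  if (strict && nrow(out) > 0L) {
    stop("validation failed:\n", paste(out$message, collapse = "\n"), call. = FALSE)
  }
  out
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = ""
  )
}

#' Run the comparative-mitogenomics pipeline
#'
#' Executes the analysis stages over a set of mitogenomes and writes one TSV
#' per stage plus a machine-readable JSON summary (seed, parameters, stage
#' status) into `out_dir`:
#' `composition` (per-taxon/per-scope composition profiles), `codon_usage`
#' (ENC/CBI/GC/GC3 per taxon plus a pooled RSCU table), `diversity` (per-gene
#' S/Pi/Hd and the sliding-window Pi track), `kaks` (per-gene all-pairs
#' Nei-Gojobori estimates), `selection` (branch-site fit and BEB table;
#' needs `tree` and `foreground`), and `cr` (control-region repeat
#' architecture). A stage failure halts downstream stages; partial outputs
#' are kept and a `MANIFEST.txt` records the failure.
#'
#' @param mitos List of [mitogenome()] objects (e.g. from [read_genbank()] or
#'   [simulate_panel()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in fixed order.
#' @param tree,foreground Inputs for the selection stage: an `ape::phylo`
#'   whose tip labels are genome ids, and a foreground specification
#'   ([fit_branch_site()]).
#' @param genes Genes analyzed by the diversity/kaks/selection stages
#'   (default: all PCGs shared by every genome with equal lengths, treated as
#'   aligned; supply pre-aligned data for real, indel-containing sets).
#' @param window,step Sliding-window parameters.
#' @param seed Seed recorded in the summary and set before any stage runs.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(mitos, out_dir,
                         stages = c("composition", "codon_usage", "diversity", "kaks", "selection", "cr"),
                         tree = NULL, foreground = NULL, genes = NULL,
                         window = 100L, step = 25L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  code <- genetic_code()
  ids <- vapply(mitos, function(m) m$id, character(1))
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(mitos, function(m) m$features$name[m$features$kind == "PCG"]))
  }
  gene_seqs <- function(g) {
    s <- vapply(mitos, function(m) extract_gene(m, g), character(1))
    names(s) <- ids
    s
  }
  summary <- list(
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp")),
    seed = seed,
    parameters = list(window = window, step = step, genes = genes),
    stages = list()
  )
  stage_order <- c("composition", "codon_usage", "diversity", "kaks", "selection", "cr")
  stages <- stage_order[stage_order %in% stages]
  failed <- FALSE
  for (st in stages) {
    if (failed) {
      summary$stages[[st]] <- list(status = "skipped")
      next
    }
    res <- tryCatch(
      {
        switch(st,
          composition = {
            comp <- dplyr::bind_rows(lapply(mitos, composition_report))
            write_tsv_file(comp, file.path(out_dir, "composition.tsv"))
          },
          codon_usage = {
            cds_by_taxon <- lapply(mitos, function(m) {
              vapply(
                m$features$name[m$features$kind == "PCG"],
                function(g) extract_gene(m, g), character(1)
              )
            })
            names(cds_by_taxon) <- ids
            usage <- codon_usage(cds_by_taxon, code)
            write_tsv_file(usage, file.path(out_dir, "codon_usage.tsv"))
            pooled <- codon_counts(unlist(cds_by_taxon, use.names = FALSE), code)
            write_tsv_file(rscu(pooled, code), file.path(out_dir, "rscu.tsv"))
          },
          diversity = {
            rows <- list()
            wins <- list()
            for (g in genes) {
              s <- gene_seqs(g)
              if (length(unique(nchar(s))) != 1L) next
              prof <- diversity_profile(s, window = window, step = step)
              rows[[g]] <- dplyr::bind_cols(tibble::tibble(gene = g), prof$summary)
              if (nrow(prof$windows) > 0L) {
                wins[[g]] <- dplyr::bind_cols(tibble::tibble(gene = g), prof$windows)
              }
            }
            write_tsv_file(dplyr::bind_rows(rows), file.path(out_dir, "diversity.tsv"))
            write_tsv_file(dplyr::bind_rows(wins), file.path(out_dir, "diversity_windows.tsv"))
          },
          kaks = {
            rows <- list()
            for (g in genes) {
              s <- gene_seqs(g)
              if (length(unique(nchar(s))) != 1L) next
              rows[[g]] <- dplyr::bind_cols(tibble::tibble(gene = g), ka_ks_matrix(s, code))
            }
            write_tsv_file(dplyr::bind_rows(rows), file.path(out_dir, "kaks.tsv"))
          },
          selection = {
            if (is.null(tree) || is.null(foreground)) {
              stop("selection stage needs 'tree' and 'foreground'", call. = FALSE)
            }
            rows <- list()
            beb_rows <- list()
            for (g in genes) {
              s <- gene_seqs(g)
              if (length(unique(nchar(s))) != 1L) next
              fit <- fit_branch_site(s, tree, foreground, code)
              rows[[g]] <- dplyr::bind_cols(tibble::tibble(gene = g), glance(fit))
              bt <- beb(fit)
              bt$gene <- g
              beb_rows[[g]] <- bt
            }
            write_tsv_file(dplyr::bind_rows(rows), file.path(out_dir, "selection.tsv"))
            write_tsv_file(dplyr::bind_rows(beb_rows), file.path(out_dir, "beb.tsv"))
          },
          cr = {
            rows <- list()
            for (m in mitos) {
              if (!"CR" %in% m$features$name) next
              rep <- annotate_cr(m)
              f <- rep$features
              f$id <- m$id
              rows[[m$id]] <- f
            }
            write_tsv_file(dplyr::bind_rows(rows), file.path(out_dir, "cr_architecture.tsv"))
          }
        )
        list(status = "ok")
      },
      error = function(e) list(status = "failed", error = conditionMessage(e))
    )
    summary$stages[[st]] <- res
    if (identical(res$status, "failed")) {
      failed <- TRUE
      writeLines(
        c(
          sprintf("stage '%s' FAILED: %s", st, res$error),
          "downstream stages skipped; outputs above this stage are complete"
        ),
        file.path(out_dir, "MANIFEST.txt")
      )
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(summary)
}
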