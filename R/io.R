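#' Read a 12-column tabular hit file (BLAST outfmt-6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore, optionally followed by `subject_taxon_domain` and
#' `subject_taxon_phylum`.
#'
#' @param path file path (tab-separated, no header).
#' @return data.frame with named columns.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(x) < 12L)
    stop("expected >= 12 tab-separated columns, got ", ncol(x))
  names(x)[1:12] <- cols
  if (ncol(x) >= 13L) names(x)[13L] <- "subject_taxon_domain"
  if (ncol(x) >= 14L) names(x)[14L] <- "subject_taxon_phylum"
  for (col in c("pident", "length", "evalue", "bitscore")) {
    if (!is.numeric(x[[col]]))
      stop("malformed hit file: non-numeric '", col, "'")
  }
  x
}

#' Read a genome metadata table
#'
#' Tab-separated with header: `genome_id completeness contamination size_bp`
#' (completeness and contamination in percent).
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("genome_id", "completeness", "contamination")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Completeness fractions from a percent-scale metadata table
#' @param metadata data.frame with `genome_id` and `completeness` (percent).
#' @return named numeric vector of fractions in (0, 1].
#' @export
completeness_fractions <- function(metadata)
  stats::setNames(metadata$completeness / 100, metadata$genome_id)

#' Read per-genome protein FASTA files into a protein table
#'
#' Headers are `genome_id|gene_id|family_id` (family optional). Sequences
#' are returned with lengths so the family filters can run.
#'
#' @param paths FASTA file path(s).
#' @return data.frame `gene_id`, `genome_id`, `family_id`, `length`,
#'   `sequence`.
#' @export
read_proteins_fasta <- function(paths) {
  res <- lapply(paths, function(p) {
    ss <- Biostrings::readAAStringSet(p)
    parts <- strsplit(names(ss), "|", fixed = TRUE)
    data.frame(
      gene_id = vapply(parts, function(z) z[min(2L, length(z))], ""),
      genome_id = vapply(parts, `[`, "", 1L),
      family_id = vapply(parts, function(z)
        if (length(z) >= 3L) z[3L] else NA_character_, ""),
      length = Biostrings::width(ss),
      sequence = as.character(ss), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to a directory
#'
#' Emits the species tree and per-family gene trees as Newick, proteins as
#' FASTA (headers `genome|gene|family`), metadata and the true per-branch
#' event tallies as TSV, and (if present) a hit table.
#'
#' @param dataset a `sim_dataset`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(dataset$species_tree, file.path(out_dir, "species.nwk"))
  gt_dir <- file.path(out_dir, "gene_trees")
  dir.create(gt_dir, showWarnings = FALSE)
  for (f in names(dataset$gene_trees)) {
    gt <- dataset$gene_trees[[f]]
    if (is.null(gt)) next
    path <- file.path(gt_dir, paste0(f, ".nwk"))
    if (is.character(gt)) writeLines(paste0("(", gt, ");"), path)
    else ape::write.tree(gt, path)
  }
  if (!is.null(dataset$alignments)) {
    fa <- file.path(out_dir, "proteins.faa")
    con <- file(fa, "w")
    for (f in names(dataset$alignments)) {
      aln <- dataset$alignments[[f]]
      writeLines(paste0(">", names(aln), "\n", unname(aln)), con)
    }
    close(con)
  }
  utils::write.table(dataset$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$branch, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Write a branch event table as TSV
#' @param table data.frame from [aggregate_events()].
#' @param path output path.
#' @export
write_branch_table <- function(table, path)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

#' Write reconciliations as JSON
#'
#' One object per family: cost, origination branch, events and per-branch
#' tallies.
#' @param reconciliations list of `reconciliation` objects.
#' @param path output path.
#' @export
write_reconciliations_json <- function(reconciliations, path) {
  payload <- lapply(reconciliations, function(r) {
    list(family_id = r$family_id, cost = r$cost, origination = r$origination,
         n_dup = r$n_dup, n_transfer = r$n_transfer, n_loss = r$n_loss,
         events = r$events,
         tallies = r$tallies[r$tallies$dup + r$tallies$transfer +
                               r$tallies$loss + r$tallies$orig > 0, ,
                             drop = FALSE])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
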