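#' Filter homology hits on e-value, identity, alignment length and bitscore
#'
#' A hit qualifies iff `evalue <= max_evalue`, `pident >= min_pct_id`,
#' `length >= min_aln_len` and `bitscore >= min_bitscore`; boundary values
#' are kept (the removal conditions are strict). With `best_hit = TRUE` only
#' the best qualifying hit per query is retained (bitscore desc, then
#' e-value asc, then subject id). An optional `posterior` column can be
#' thresholded with `min_posterior` (for HMM-style hits).
#'
#' @param hits hit table (see [read_hits()]).
#' @param max_evalue default 1e-5.
#' @param min_pct_id percent, default 35.
#' @param min_aln_len columns, default 80.
#' @param min_bitscore bits, default 100.
#' @param best_hit keep only the best qualifying hit per query.
#' @param min_posterior optional floor on a `posterior` column.
#' @return the qualifying subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_pct_id = 35,
                        min_aln_len = 80, min_bitscore = 100,
                        best_hit = FALSE, min_posterior = NULL) {
  need <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("pident", "length", "evalue", "bitscore")) {
    if (anyNA(hits[[col]]))
      stop("malformed hit row(s): NA in '", col, "' at line(s) ",
           paste(utils::head(which(is.na(hits[[col]])), 5L), collapse = ", "))
  }
  keep <- hits$evalue <= max_evalue & hits$pident >= min_pct_id &
    hits$length >= min_aln_len & hits$bitscore >= min_bitscore
  if (!is.null(min_posterior)) {
    if (is.null(hits$posterior)) stop("no 'posterior' column to threshold")
    keep <- keep & hits$posterior >= min_posterior
  }
  out <- hits[keep, , drop = FALSE]
  if (best_hit && nrow(out)) {
    o <- order(out$qseqid, -out$bitscore, out$evalue, out$sseqid)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$qseqid), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Proteome novelty per genome
#'
#' Novelty is the percentage of a genome's proteins that lack any qualifying
#' homology hit (apply [filter_hits()] with the reference database's
#' thresholds first).
#'
#' @param proteins data.frame with `gene_id` and `genome_id`.
#' @param qualifying_hits hit table already filtered; only `qseqid` is used.
#' @return data.frame `genome_id`, `n_proteins`, `n_with_hit`, `novelty_pct`.
#' @export
proteome_novelty <- function(proteins, qualifying_hits) {
  genomes <- sort(unique(proteins$genome_id))
  if (!length(genomes)) stop("no proteins given")
  with_hit <- unique(qualifying_hits$qseqid)
  res <- lapply(genomes, function(g) {
    genes <- proteins$gene_id[proteins$genome_id == g]
    if (!length(genes)) stop("genome ", g, " has zero proteins")
    nh <- sum(genes %in% with_hit)
    data.frame(genome_id = g, n_proteins = length(genes), n_with_hit = nh,
               novelty_pct = 100 * (length(genes) - nh) / length(genes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify origination sources from medoid homology searches
#'
#' For each originating family, hits of its medoid against an external
#' database are examined after discarding hits to the focal phylum itself.
#' Families with no remaining hits are putative de novo genes; otherwise the
#' donor is the domain of the best remaining hit (highest bitscore, ties by
#' lowest e-value then lexicographically smallest subject).
#'
#' @param medoids named character vector: family id -> medoid gene id.
#' @param external_hits pre-filtered hit table with columns
#'   `subject_taxon_domain` and `subject_taxon_phylum` appended.
#' @param self_phylum phylum label whose matches are excluded.
#' @return data.frame `family_id`, `medoid`, `origin` (`"lateral"` or
#'   `"putative de novo"`), `donor_domain` (NA for de novo), plus attribute
#'   `donor_percentages` (percent per domain among lateral families).
#' @export
classify_origination <- function(medoids, external_hits, self_phylum) {
  need <- c("qseqid", "sseqid", "bitscore", "evalue",
            "subject_taxon_domain", "subject_taxon_phylum")
  miss <- setdiff(need, names(external_hits))
  if (length(miss))
    stop("external hits lack column(s): ", paste(miss, collapse = ", "))
  hits <- external_hits[external_hits$subject_taxon_phylum != self_phylum, ,
                        drop = FALSE]
  res <- lapply(names(medoids), function(f) {
    h <- hits[hits$qseqid == medoids[[f]], , drop = FALSE]
    if (!nrow(h)) {
      if (!medoids[[f]] %in% external_hits$qseqid)
        warning("medoid ", medoids[[f]], " (family ", f,
                ") has no search results; counted as putative de novo")
      return(data.frame(family_id = f, medoid = medoids[[f]],
                        origin = "putative de novo",
                        donor_domain = NA_character_,
                        stringsAsFactors = FALSE))
    }
    o <- order(-h$bitscore, h$evalue, h$sseqid)
    data.frame(family_id = f, medoid = medoids[[f]], origin = "lateral",
               donor_domain = h$subject_taxon_domain[o[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  lat <- out$donor_domain[out$origin == "lateral"]
  attr(out, "donor_percentages") <-
    if (length(lat)) 100 * table(lat) / length(lat) else table(character(0))
  out
}

#' Gained and lost functional terms between adjacent ancestral nodes
#'
#' A term is present at a node iff at least one family carrying it has copy
#' number >= 1 there. Gains are terms present at the child but not the
#' parent; losses the reverse.
#'
#' @param content ancestral content matrix from [ancestral_content()].
#' @param species_tree the species tree (adjacency check).
#' @param term_map data.frame `family_id`, `term_id` (possibly partial).
#' @param parent,child adjacent node labels.
#' @return list with character vectors `gained` and `lost`.
#' @export
ancestral_function_changes <- function(content, species_tree, term_map,
                                       parent, child) {
  idx <- species_index(species_tree)
  pv <- node_of_label(idx, parent); cv <- node_of_label(idx, child)
  if (idx$parent[cv] != pv)
    stop("'", parent, "' is not the immediate ancestor of '", child, "'")
  present_terms <- function(node) {
    fams <- colnames(content)[content[node, ] >= 1L]
    sort(unique(term_map$term_id[term_map$family_id %in% fams]))
  }
  pt <- present_terms(parent); ct <- present_terms(child)
  list(gained = setdiff(ct, pt), lost = setdiff(pt, ct))
}
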