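#' Filter genomes on completeness and contamination
#'
#' A genome is kept iff its completeness is strictly greater than
#' `min_completeness` and its contamination strictly below
#' `max_contamination` (both in percent).
#'
#' @param metadata data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (percent scale).
#' @param min_completeness percent, default 45.
#' @param max_contamination percent, default 10.
#' @return character vector of kept genome ids.
#' @export
filter_genomes <- function(metadata, min_completeness = 45,
                           max_contamination = 10) {
  need <- c("genome_id", "completeness", "contamination")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("completeness", "contamination")) {
    bad <- metadata$genome_id[is.na(metadata[[col]])]
    if (length(bad))
      stop("missing ", col, " for genome(s): ", paste(bad, collapse = ", "))
  }
  keep <- metadata$completeness > min_completeness &
    metadata$contamination < max_contamination
  metadata$genome_id[keep]
}

# Markov clustering (expansion 2) on a column-stochastic matrix; returns an
# integer membership vector. Deterministic for a fixed input matrix.
mcl_cluster <- function(adj, inflation = 1.5, max_iter = 200L,
                        tol = 1e-8, prune = 1e-10) {
  n <- nrow(adj)
  diag(adj) <- pmax(diag(adj), apply(adj, 1L, max), 1e-12)  # self loops
  M <- sweep(adj, 2L, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                 # expansion
    M2 <- M2^inflation            # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  # attractors: rows with mass; cluster = union of columns served by a row,
  # merging overlapping attractor systems
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (j in seq_len(n)) {
    rows <- which(M[, j] > 1e-6)
    if (!length(rows)) rows <- j
    for (r in rows) union_(r, j)
  }
  vapply(seq_len(n), find, 0L)
}

#' Cluster proteins into families by Markov clustering of a similarity graph
#'
#' Discards hit edges below a percent-identity floor, builds a symmetrized,
#' self-loop-augmented bitscore-weighted adjacency over all proteins, and
#' runs Markov clustering (expansion 2, configurable inflation). Every
#' protein is assigned to exactly one family; proteins without qualifying
#' edges become singletons. Output is deterministic: proteins are processed
#' in sorted id order and family ids are numbered by each family's smallest
#' member id.
#'
#' @param edges hit table with at least `qseqid`, `sseqid`, `pident`,
#'   `bitscore` (12-column tabular dialect, see [read_hits()]).
#' @param proteins data.frame with `gene_id` and `genome_id` for every
#'   protein (endpoints of edges must be known proteins).
#' @param min_pct_id percent-identity floor (default 35; use 50 for
#'   core-marker stringency).
#' @param inflation MCL inflation (default 1.5).
#' @return data.frame `family_id`, `gene_id`, `genome_id`, one row per
#'   protein, sorted by family then gene id.
#' @export
cluster_families <- function(edges, proteins, min_pct_id = 35,
                             inflation = 1.5) {
  ids <- sort(unique(proteins$gene_id))
  genome_of <- stats::setNames(proteins$genome_id, proteins$gene_id)
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$qseqid, edges$sseqid)), ids)
    if (length(unknown))
      stop("edge endpoint(s) not in protein table: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  edges <- edges[edges$pident >= min_pct_id &
                   edges$qseqid != edges$sseqid, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no qualifying edges: every protein is its own family")
    member <- seq_along(ids)
  } else {
    n <- length(ids)
    adj <- matrix(0, n, n, dimnames = list(ids, ids))
    qi <- match(edges$qseqid, ids); si <- match(edges$sseqid, ids)
    for (k in seq_len(nrow(edges))) {
      w <- edges$bitscore[k]
      if (w > adj[qi[k], si[k]]) {
        adj[qi[k], si[k]] <- w
        adj[si[k], qi[k]] <- w
      }
    }
    member <- mcl_cluster(adj, inflation = inflation)
  }
  fam_rank <- match(member, sort(unique(member)))
  fam_id <- sprintf("FAM%05d", fam_rank)
  out <- data.frame(family_id = fam_id, gene_id = ids,
                    genome_id = unname(genome_of[ids]),
                    stringsAsFactors = FALSE)
  out[order(out$family_id, out$gene_id), , drop = FALSE]
}

#' Apply the family length and size filters
#'
#' Members shorter than `min_len` amino acids are removed first; families
#' left with fewer than `min_members` members are then removed entirely.
#' The order matters and is fixed.
#'
#' @param families membership data.frame (`family_id`, `gene_id`,
#'   `genome_id`).
#' @param proteins data.frame with `gene_id` and `length` (amino acids).
#' @param min_len minimum member length (default 30).
#' @param min_members minimum family size after length filtering (default 4).
#' @return the filtered membership data.frame.
#' @export
filter_families <- function(families, proteins, min_len = 30,
                            min_members = 4) {
  len <- stats::setNames(proteins$length, proteins$gene_id)
  keep_len <- len[families$gene_id] >= min_len
  if (anyNA(keep_len))
    stop("protein length missing for gene(s): ",
         paste(utils::head(families$gene_id[is.na(keep_len)], 5L),
               collapse = ", "))
  fam <- families[keep_len, , drop = FALSE]
  sizes <- table(fam$family_id)
  keep_fam <- names(sizes)[sizes >= min_members]
  out <- fam[fam$family_id %in% keep_fam, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag single-copy core marker families
#'
#' A family is core iff (a) it is single-copy in every genome where it is
#' present at all, and (b) it is present in at least `presence_fraction` of
#' the near-complete genomes (completeness at or above
#' `near_complete_cutoff` percent).
#'
#' @param families membership data.frame (`family_id`, `gene_id`,
#'   `genome_id`).
#' @param kept_genomes character vector of genomes under consideration
#'   (e.g. from [filter_genomes()]).
#' @param metadata data.frame with `genome_id` and `completeness` (percent).
#' @param near_complete_cutoff percent completeness defining "near complete"
#'   (default 90, the conventional high-quality MAG boundary).
#' @param presence_fraction required presence among near-complete genomes
#'   (default 0.85).
#' @return data.frame `family_id`, `is_core`, `n_near_complete_present`.
#' @export
select_core_markers <- function(families, kept_genomes, metadata,
                                near_complete_cutoff = 90,
                                presence_fraction = 0.85) {
  comp <- stats::setNames(metadata$completeness, metadata$genome_id)
  nc <- kept_genomes[comp[kept_genomes] >= near_complete_cutoff]
  if (!length(nc))
    stop("no genome reaches completeness ", near_complete_cutoff,
         "%; lower 'near_complete_cutoff'")
  fam <- families[families$genome_id %in% kept_genomes, , drop = FALSE]
  fam_ids <- sort(unique(families$family_id))
  res <- lapply(fam_ids, function(f) {
    rows <- fam[fam$family_id == f, , drop = FALSE]
    copies <- table(rows$genome_id)
    single <- nrow(rows) > 0 && all(copies == 1L)
    n_nc <- sum(nc %in% names(copies))
    data.frame(family_id = f,
               is_core = single && n_nc >= presence_fraction * length(nc),
               n_near_complete_present = n_nc, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' BLOSUM62 medoid of an aligned protein family
#'
#' Pairwise distance `d(i, j) = 1 - S(i, j) / max(S(i, i), S(j, j))`, where
#' `S` is the summed BLOSUM62 score over aligned columns (columns where
#' either sequence has a gap are skipped for that pair). Returns the member
#' minimising the summed distance to all others; ties break to the
#' lexicographically smallest id.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @return the medoid sequence id.
#' @export
compute_medoid <- function(alignment) {
  if (!length(alignment)) stop("empty family: no medoid")
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length")
  if (length(alignment) == 1L) return(names(alignment))
  ids <- names(alignment)
  sub <- blosum62_matrix()
  chars <- strsplit(alignment, "")
  n <- length(ids)
  D <- matrix(0, n, n)
  self <- vapply(chars, function(a) {
    ok <- a != "-"
    sum(sub[cbind(a[ok], a[ok])])
  }, 0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "-" & b != "-"
    s <- if (any(ok)) sum(sub[cbind(a[ok], b[ok])]) else 0
    d <- 1 - s / max(self[i], self[j])
    D[i, j] <- D[j, i] <- d
  }
  tot <- rowSums(D)
  cand <- ids[tot <= min(tot) + 1e-12]
  sort(cand)[1L]
}

# BLOSUM62 from Biostrings, cached
blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
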