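#' Average amino acid identity from a similarity-hit table
#'
#' For each ordered genome pair, the best hit per query protein is chosen by
#' bitscore (ties: lowest e-value, then lexicographically smallest subject);
#' reciprocal best hits (RBH) between the two genomes are identified, and
#' the directed AAI is the mean percent identity over RBH pairs. The matrix
#' is symmetrized by averaging the two directions; the diagonal is 100.
#' Pairs with no RBH are `NA` and listed in the `missing_pairs` attribute.
#'
#' @param hits 12-column hit table (`qseqid`, `sseqid`, `pident`,
#'   `bitscore`, `evalue`, ...).
#' @param gene2genome named character vector mapping gene id to genome id.
#' @return symmetric numeric AAI matrix (percent) over the genomes that have
#'   proteins; attribute `missing_pairs` lists genome pairs without RBHs.
#' @export
compute_aai <- function(hits, gene2genome) {
  genomes <- sort(unique(unname(gene2genome)))
  qg <- gene2genome[hits$qseqid]
  sg <- gene2genome[hits$sseqid]
  if (anyNA(qg) || anyNA(sg))
    stop("hit endpoints missing from gene2genome mapping")
  hits <- hits[qg != sg, , drop = FALSE]
  qg <- gene2genome[hits$qseqid]; sg <- gene2genome[hits$sseqid]
  n <- length(genomes)
  aai <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  diag(aai) <- 100
  best_map <- function(sub) {
    # best subject per query: bitscore desc, evalue asc, subject lex
    o <- order(sub$qseqid, -sub$bitscore, sub$evalue, sub$sseqid)
    sub <- sub[o, , drop = FALSE]
    sub[!duplicated(sub$qseqid), , drop = FALSE]
  }
  missing <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    g1 <- genomes[i]; g2 <- genomes[j]
    fwd <- best_map(hits[qg == g1 & sg == g2, , drop = FALSE])
    rev_ <- best_map(hits[qg == g2 & sg == g1, , drop = FALSE])
    back <- stats::setNames(rev_$sseqid, rev_$qseqid)
    rbh <- fwd[!is.na(back[fwd$sseqid]) &
                 back[fwd$sseqid] == fwd$qseqid, , drop = FALSE]
    if (nrow(rbh)) {
      rev_id <- stats::setNames(rev_$pident, rev_$qseqid)
      a12 <- mean(rbh$pident)
      a21 <- mean(rev_id[rbh$sseqid])
      aai[i, j] <- aai[j, i] <- (a12 + a21) / 2
    } else {
      missing <- c(missing, paste(g1, g2, sep = "|"))
    }
  }
  attr(aai, "missing_pairs") <- missing
  aai
}

# connected components of an undirected adjacency (single linkage at a
# strict threshold); labels numbered by first member in lex order
threshold_components <- function(adj, node_names) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in order(node_names)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Genus and species clusters from AAI thresholds
#'
#' Single-linkage clustering at strict AAI thresholds: two genomes share a
#' species iff they are connected by a chain of pairs with AAI strictly
#' above `species_cut`, and a genus likewise above `genus_cut`. Species
#' clusters nest inside genus clusters by construction.
#'
#' @param aai AAI matrix from [compute_aai()].
#' @param genus_cut percent AAI for genus (default 70, strict).
#' @param species_cut percent AAI for species (default 95, strict).
#' @return data.frame `genome`, `genus`, `species` (labels `G1..`, `S1..`).
#' @export
assign_species_genus <- function(aai, genus_cut = 70, species_cut = 95) {
  genomes <- rownames(aai)
  off <- upper.tri(aai)
  if (anyNA(aai[off])) {
    bad <- which(is.na(aai) & off, arr.ind = TRUE)
    stop("missing AAI for pair(s): ",
         paste(paste(genomes[bad[, 1L]], genomes[bad[, 2L]], sep = "|"),
               collapse = ", "))
  }
  a <- aai; diag(a) <- 100
  genus <- threshold_components(a > genus_cut, genomes)
  species <- threshold_components(a > species_cut, genomes)
  data.frame(genome = genomes, genus = paste0("G", genus),
             species = paste0("S", species), stringsAsFactors = FALSE)
}

#' Class, order and family clusters from phylogenetic-distance profiles
#'
#' Each genome's profile is its row of the patristic distance matrix.
#' The Pearson distance between two genomes is `1 - r` computed over all
#' other genomes (the two self-entries are excluded). Single-linkage
#' clusters are cut at strict Pearson-distance thresholds: below 0.34
#' (class), 0.13 (order) and 0.015 (family) by default; nesting of the three
#' ranks is guaranteed by single linkage at nested thresholds.
#'
#' @param species_tree rooted tree with branch lengths covering all genomes.
#' @param cuts named numeric vector `c(class=, order=, family=)`.
#' @return data.frame `genome`, `class`, `order`, `family` (labels `C1..`,
#'   `O1..`, `F1..`), with the Pearson distance matrix as attribute
#'   `pearson_dist`.
#' @export
assign_upper_ranks <- function(species_tree,
                               cuts = c(class = 0.34, order = 0.13,
                                        family = 0.015)) {
  stopifnot(all(c("class", "order", "family") %in% names(cuts)))
  pd <- patristic_distances(species_tree)
  genomes <- rownames(pd)
  n <- length(genomes)
  if (n < 3L) stop("need at least 3 genomes to correlate distance profiles")
  pdist <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    pi_ <- pd[i, keep]; pj_ <- pd[j, keep]
    if (stats::sd(pi_) == 0 || stats::sd(pj_) == 0) {
      # flat profiles: correlation undefined; identical profiles are at
      # distance 0, anything else maximally uninformative (r treated as 0)
      r <- if (max(abs(pi_ - pj_)) < 1e-12) 1 else 0
    } else {
      r <- stats::cor(pi_, pj_)
    }
    pdist[i, j] <- pdist[j, i] <- 1 - r
  }
  cls <- threshold_components(pdist < cuts[["class"]], genomes)
  ord <- threshold_components(pdist < cuts[["order"]], genomes)
  fam <- threshold_components(pdist < cuts[["family"]], genomes)
  out <- data.frame(genome = genomes, class = paste0("C", cls),
                    order = paste0("O", ord), family = paste0("F", fam),
                    stringsAsFactors = FALSE)
  attr(out, "pearson_dist") <- pdist
  out
}

#' Maximum divergence of a genome group
#'
#' 100 minus the lowest AAI between any two members of the group; a
#' singleton group has maximum divergence 0 by convention.
#'
#' @param aai AAI matrix.
#' @param group character vector of genome ids (subset of the matrix).
#' @return percent maximum divergence.
#' @export
max_divergence <- function(aai, group) {
  if (!length(group)) stop("empty group")
  miss <- setdiff(group, rownames(aai))
  if (length(miss))
    stop("genome(s) not in AAI matrix: ", paste(miss, collapse = ", "))
  if (length(group) == 1L) return(0)
  sub <- aai[group, group]
  100 - min(sub[upper.tri(sub)])
}
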