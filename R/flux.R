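#' Aggregate reconciliation events into a per-branch table
#'
#' Sums duplications, losses, intra-LGT receipts and originations over
#' families for every species-tree branch, and reports the reconstructed
#' proteome size (gene copies surviving at the branch's child node).
#'
#' @param reconciliations list of [reconcile_undated()] results sharing one
#'   species tree.
#' @param species_tree the shared rooted species tree.
#' @return data.frame `branch_id`, `dup`, `loss`, `intra_lgt`, `orig`,
#'   `proteome_size`, one row per branch (the root stem included).
#' @export
aggregate_events <- function(reconciliations, species_tree) {
  idx <- species_index(species_tree)
  labs <- idx$labels
  dup <- loss <- lgt <- orig <- size <- integer(length(labs))
  for (r in reconciliations) {
    if (!identical(r$species_labels, labs))
      stop("reconciliation does not match the given species tree")
    dup <- dup + r$tallies$dup
    loss <- loss + r$tallies$loss
    lgt <- lgt + r$tallies$transfer
    orig <- orig + r$tallies$orig
    size <- size + r$presence
  }
  data.frame(branch_id = labs, dup = as.integer(dup), loss = as.integer(loss),
             intra_lgt = as.integer(lgt), orig = as.integer(orig),
             proteome_size = as.integer(size), stringsAsFactors = FALSE)
}

#' Ancestral proteome content matrix
#'
#' Copy number of each family at each species-tree node: the number of
#' gene-tree lineages of the family surviving at that node under the
#' reconciliation.
#'
#' @inheritParams aggregate_events
#' @return integer matrix, nodes (rows, by label) x families (columns).
#' @export
ancestral_content <- function(reconciliations, species_tree) {
  idx <- species_index(species_tree)
  fams <- vapply(reconciliations, function(r) as.character(r$family_id), "")
  if (anyNA(fams) || anyDuplicated(fams))
    fams <- make.unique(ifelse(is.na(fams), "family", fams))
  m <- matrix(0L, idx$n_node, length(reconciliations),
              dimnames = list(idx$labels, fams))
  for (i in seq_along(reconciliations)) {
    r <- reconciliations[[i]]
    if (!identical(r$species_labels, idx$labels))
      stop("reconciliation does not match the given species tree")
    m[, i] <- r$presence
  }
  m
}

#' Detect fold-change family expansions and contractions between two nodes
#'
#' A family is expanded iff `child > fold * parent` with `parent >= 1`, and
#' contracted iff `parent > fold * child` with `child >= 1` (strict
#' inequalities). Families appearing from zero copies are reported separately
#' as `novel` — a fold change from zero is undefined and such gains are
#' origination/transfer-driven rather than expansions.
#'
#' @param content matrix from [ancestral_content()].
#' @param species_tree the species tree (for the adjacency check).
#' @param parent,child node labels; `parent` must be the immediate ancestor.
#' @param fold fold-change threshold (default 10).
#' @return list with character vectors `expanded`, `contracted`, `novel`.
#' @export
detect_expansions <- function(content, species_tree, parent, child,
                              fold = 10) {
  idx <- species_index(species_tree)
  pv <- node_of_label(idx, parent); cv <- node_of_label(idx, child)
  if (idx$parent[cv] != pv)
    stop("'", parent, "' is not the immediate ancestor of '", child, "'")
  p <- content[parent, ]; k <- content[child, ]
  fams <- colnames(content)
  list(expanded = fams[p >= 1 & k > fold * p],
       contracted = fams[k >= 1 & p > fold * k],
       novel = fams[p == 0 & k > 0])
}

#' Completeness-corrected loss/duplication fractions from copy numbers
#'
#' Given observed copy numbers of a family set in extant genomes and the
#' genomes' completeness, returns raw and corrected percentages of families
#' lost (zero copies) and duplicated (two or more copies). A family present
#' in a genome of completeness `c` is falsely scored absent with probability
#' `1 - c` under independent gene observation, so the corrected loss
#' fraction is `(raw - (1 - c)) / c`; observed duplications are scaled as
#' `raw / c`. Both are clipped to [0, 1] and reported as percentages.
#'
#' @param copies integer matrix, families (rows) x genomes (columns).
#' @param completeness named numeric vector of fractions in (0, 1].
#' @return data.frame `genome`, `n_families`, `pct_lost_raw`, `pct_lost`,
#'   `pct_dup_raw`, `pct_dup`.
#' @export
fate_from_copies <- function(copies, completeness) {
  if (nrow(copies) == 0L) stop("undefined fate: no families")
  genomes <- colnames(copies)
  cc <- rep(1, length(genomes))
  names(cc) <- genomes
  cc[names(completeness)[names(completeness) %in% genomes]] <-
    completeness[names(completeness) %in% genomes]
  if (any(cc <= 0) || any(cc > 1))
    stop("completeness values must lie in (0, 1]")
  raw_l <- colMeans(copies == 0L)
  raw_d <- colMeans(copies >= 2L)
  corr_l <- pmin(pmax((raw_l - (1 - cc)) / cc, 0), 1)
  corr_d <- pmin(pmax(raw_d / cc, 0), 1)
  data.frame(genome = genomes, n_families = nrow(copies),
             pct_lost_raw = 100 * raw_l, pct_lost = 100 * corr_l,
             pct_dup_raw = 100 * raw_d, pct_dup = 100 * corr_d,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fate of the families originating on a branch
#'
#' Selects the families whose origination maps to `origin_branch` and scores,
#' for every extant genome descending from that branch (or for pooled genome
#' groups), the completeness-corrected percentage of those families that were
#' lost or duplicated (see [fate_from_copies()]).
#'
#' @param origin_branch species-tree branch label.
#' @param reconciliations list of [reconcile_undated()] results.
#' @param species_tree the shared species tree.
#' @param completeness named numeric vector of fractions in (0, 1].
#' @param groups optional named character vector mapping genome to group
#'   (e.g. genus); copies are pooled by maximum over members and group
#'   completeness is the probability that at least one member observes a
#'   present gene, `1 - prod(1 - c_i)`.
#' @return a `fate_from_copies()` data.frame, plus attribute `origin_branch`
#'   and `families`.
#' @export
fate_of_families <- function(origin_branch, reconciliations, species_tree,
                             completeness = NULL, groups = NULL) {
  idx <- species_index(species_tree)
  node_of_label(idx, origin_branch)
  sel <- Filter(function(r) r$origination == origin_branch, reconciliations)
  if (!length(sel))
    stop("undefined fate: no family originates on branch '", origin_branch,
         "'")
  tips <- descendant_tips(idx, origin_branch)
  copies <- do.call(rbind, lapply(sel, function(r) r$presence[tips]))
  colnames(copies) <- tips
  rownames(copies) <- vapply(sel, function(r) as.character(r$family_id), "")
  cc <- stats::setNames(rep(1, length(tips)), tips)
  if (!is.null(completeness)) {
    keep <- names(completeness)[names(completeness) %in% tips]
    cc[keep] <- completeness[keep]
  }
  if (!is.null(groups)) {
    gl <- groups[tips]
    if (anyNA(gl)) stop("groups must cover every descendant genome")
    glev <- unique(gl)
    pooled <- matrix(0L, nrow(copies), length(glev),
                     dimnames = list(rownames(copies), glev))
    for (g in glev)
      pooled[, g] <- apply(copies[, gl == g, drop = FALSE], 1L, max)
    cc <- vapply(glev, function(g) 1 - prod(1 - cc[gl == g]), 0)
    names(cc) <- glev
    copies <- pooled
  }
  out <- fate_from_copies(copies, cc)
  attr(out, "origin_branch") <- origin_branch
  attr(out, "families") <- rownames(copies)
  out
}

#' Permutation test comparing event rates inside vs outside a clade
#'
#' Statistic: mean per-branch event count over the clade branches minus the
#' mean over the remaining branches. The null distribution reassigns the
#' clade label set uniformly among branches; the two-sided p-value uses the
#' add-one correction `p = (1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`
#' and therefore never reports zero.
#'
#' @param table branch event table from [aggregate_events()].
#' @param clade_branches character vector of branch ids (non-empty proper
#'   subset of the table's branches).
#' @param event_class one of `"all"`, `"dup"`, `"loss"`, `"intra_lgt"`,
#'   `"orig"`; `"all"` sums the four classes.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed; results are deterministic given the seed.
#' @return the two-sided p-value, with attributes `statistic` and `n_perm`.
#' @export
compare_clade_rates <- function(table, clade_branches,
                                event_class = c("all", "dup", "loss",
                                                "intra_lgt", "orig"),
                                n_perm = 9999, seed = 1) {
  event_class <- match.arg(event_class)
  counts <- if (event_class == "all")
    table$dup + table$loss + table$intra_lgt + table$orig
  else table[[event_class]]
  names(counts) <- table$branch_id
  inset <- table$branch_id %in% clade_branches
  if (!any(inset) || all(inset))
    stop("clade_branches must be a non-empty proper subset of all branches")
  k <- sum(inset)
  stat <- function(m) mean(counts[m]) - mean(counts[!m])
  obs <- stat(inset)
  set.seed(as.integer(seed))
  n <- length(counts)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    m <- logical(n)
    m[sample.int(n, k)] <- TRUE
    if (abs(stat(m)) >= abs(obs) - 1e-9) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + n_perm)
  attr(p, "statistic") <- obs
  attr(p, "n_perm") <- n_perm
  p
}

#' Completeness-corrected predicted genome size
#'
#' @param measured_size measured (assembled) genome size in bp.
#' @param completeness fraction in (0, 1].
#' @return `measured_size / completeness`, vectorized.
#' @export
predicted_genome_size <- function(measured_size, completeness) {
  if (any(completeness <= 0))
    stop("completeness must be > 0")
  if (any(completeness > 1))
    stop("completeness must be given as a fraction in (0, 1]")
  measured_size / completeness
}
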