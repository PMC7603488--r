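AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parameters of the gene-family evolution simulator
#'
#' Bundles the rates of the generative model: each family originates once on
#' a branch drawn proportional to branch length, after which every gene copy
#' independently undergoes duplication, transfer and loss as competing
#' exponential processes along the species tree. Transfers re-insert the copy
#' at a uniformly chosen incomparable (contemporaneous) branch. Sequences
#' evolve by uniform 20-state amino-acid replacement.
#'
#' @param n_families number of gene families to simulate (>= 1).
#' @param dup_rate duplication rate, events per gene per unit branch length.
#' @param transfer_rate transfer rate, events per gene per unit branch length.
#' @param loss_rate loss rate, events per gene per unit branch length.
#' @param origination_rate nominal origination intensity per branch; each
#'   family realises exactly one origination, so this parameter is retained
#'   for interface completeness and validated but does not alter counts.
#' @param seq_length protein length in amino acids (>= 1).
#' @param subst_rate substitutions per site per unit branch length.
#' @param seed integer seed; identical seeds give identical outputs.
#' @return an object of class `evol_params`.
#' @export
evol_params <- function(n_families, dup_rate = 0, transfer_rate = 0,
                        loss_rate = 0, origination_rate = 1,
                        seq_length = 200, subst_rate = 1, seed = 1) {
  stopifnot(is.numeric(n_families), length(n_families) == 1L)
  if (n_families < 1) stop("n_families must be >= 1")
  rates <- c(dup_rate = dup_rate, transfer_rate = transfer_rate,
             loss_rate = loss_rate, origination_rate = origination_rate,
             subst_rate = subst_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (seq_length < 1) stop("seq_length must be >= 1")
  structure(list(n_families = as.integer(n_families), dup_rate = dup_rate,
                 transfer_rate = transfer_rate, loss_rate = loss_rate,
                 origination_rate = origination_rate,
                 seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, seed = as.integer(seed)),
            class = "evol_params")
}

#' Simulate a rooted binary species tree
#'
#' Constant-rate birth-death tree conditioned on the number of extant taxa
#' (via [ape::rphylo()]); tips are relabelled `g01, g02, ...` and internal
#' nodes `N1..Nk` in preorder.
#'
#' @param n_taxa number of extant leaves (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed integer seed.
#' @return a rooted binary `phylo` with positive branch lengths and labelled
#'   internal nodes.
#' @export
simulate_species_tree <- function(n_taxa, birth = 1, death = 0, seed = 1) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2)
    stop("invalid parameter: n_taxa must be >= 2")
  if (!(birth > death) || death < 0)
    stop("invalid parameter: need birth > death >= 0")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth, death, fossils = FALSE)
  w <- max(2L, nchar(as.character(n_taxa)))
  tr$tip.label <- paste0("g", formatC(seq_len(n_taxa), width = w, flag = "0"))
  species_index(tr)$tree
}

# internal: join two simulated gene subtrees after `elapsed` time on the
# current lineage; survivors of a dead sibling are passed through.
join_subtrees <- function(a, b, elapsed) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) { b$stem <- b$stem + elapsed; return(b) }
  if (is.null(b)) { a$stem <- a$stem + elapsed; return(a) }
  list(node = list(kind = "node", left = a, right = b), stem = elapsed)
}

# internal: evolve one gene copy from the top of the branch above species
# node x with `pos` branch length remaining; st is the mutable family state.
sim_copy <- function(x, pos, st) {
  elapsed <- 0
  repeat {
    rtot <- st$dup + st$tra + st$los
    tev <- if (rtot > 0) stats::rexp(1L, rtot) else Inf
    if (tev < pos) {
      elapsed <- elapsed + tev
      pos <- pos - tev
      u <- stats::runif(1L) * rtot
      if (u < st$los) {
        st$l[x] <- st$l[x] + 1L
        return(NULL)
      } else if (u < st$los + st$dup) {
        st$d[x] <- st$d[x] + 1L
        a <- sim_copy(x, pos, st)
        b <- sim_copy(x, pos, st)
        return(join_subtrees(a, b, elapsed))
      } else {
        cand <- st$incomp[[x]]
        y <- cand[sample.int(length(cand), 1L)]
        st$t[y] <- st$t[y] + 1L
        a <- sim_copy(x, pos, st)            # donor lineage continues
        b <- sim_copy(y, st$brlen[y], st)    # recipient from branch top
        return(join_subtrees(a, b, elapsed))
      }
    } else {
      elapsed <- elapsed + pos
      st$pres[x] <- st$pres[x] + 1L
      if (st$is_tip[x]) {
        st$k <- st$k + 1L
        gid <- sprintf("%s_%04d", st$family_id, st$k)
        lab <- paste(st$labels[x], gid, st$family_id, sep = "|")
        return(list(node = list(kind = "leaf", label = lab,
                                genome = st$labels[x], gene = gid),
                    stem = elapsed))
      }
      ch <- st$children[[x]]
      a <- sim_copy(ch[1L], st$brlen[ch[1L]], st)
      b <- sim_copy(ch[2L], st$brlen[ch[2L]], st)
      return(join_subtrees(a, b, elapsed))
    }
  }
}

# internal: nested gene genealogy -> ape phylo (>= 2 tips) or the single
# tip label (1 tip)
genealogy_to_phylo <- function(root) {
  tips <- character(0); tip_len <- numeric(0)
  count_tips <- function(nd) {
    if (nd$kind == "leaf") 1L
    else count_tips(nd$left$node) + count_tips(nd$right$node)
  }
  ntip <- count_tips(root$node)
  if (ntip == 1L) {
    grab <- function(nd) if (nd$kind == "leaf") nd$label else grab(nd$left$node)
    return(grab(root$node))
  }
  edge <- matrix(0L, 2L * ntip - 2L, 2L)
  edge_len <- numeric(2L * ntip - 2L)
  tip_lab <- character(ntip)
  e <- 0L; tip_i <- 0L; node_i <- ntip
  assign_ids <- function(sub) {
    nd <- sub$node
    if (nd$kind == "leaf") {
      tip_i <<- tip_i + 1L
      tip_lab[tip_i] <<- nd$label
      tip_i
    } else {
      node_i <<- node_i + 1L
      my <- node_i
      for (child in list(nd$left, nd$right)) {
        cid <- assign_ids(child)
        e <<- e + 1L
        edge[e, ] <<- c(my, cid)
        edge_len[e] <<- child$stem
      }
      my
    }
  }
  assign_ids(list(node = root$node, stem = root$stem))
  tr <- list(edge = edge, edge.length = edge_len, tip.label = tip_lab,
             Nnode = ntip - 1L, root.edge = root$stem)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate gene-family histories with exact event ground truth
#'
#' Evolves `params$n_families` gene families along a rooted species tree
#' under an origination/duplication/transfer/loss model and records the full
#' genealogy of every surviving copy together with exact per-branch event
#' tallies (the `TrueHistory`). Transfers land on branches incomparable to
#' the donor branch and are credited to the receiving branch. Each family is
#' conditioned on leaving at least one extant copy (histories that go extinct
#' are redrawn), so every family in the output has exactly one origination
#' and a non-empty gene tree.
#'
#' @param tree rooted binary species tree with positive branch lengths.
#' @param params an [evol_params()] object.
#' @param origin_branch optional branch label (or `"root"` for the root stem)
#'   forcing the origination of every family; by default the branch is drawn
#'   proportional to branch length.
#' @param max_tries redraw cap per family for the survival condition.
#' @return an object of class `sim_dataset`: species tree, per-family gene
#'   trees, protein table, metadata and `truth` (per-branch `o/d/t/l` counts
#'   and the node-by-family copy-number matrix).
#' @export
simulate_gene_content <- function(tree, params, origin_branch = NULL,
                                  max_tries = 1000L) {
  stopifnot(inherits(params, "evol_params"))
  idx <- species_index(tree)
  if (any(idx$brlen[-idx$root] <= 0)) stop("all branch lengths must be > 0")
  if (params$dup_rate == 0 && params$transfer_rate == 0 &&
      params$loss_rate == 0 && params$origination_rate == 0)
    warning("all event rates are zero: dataset carries no evolutionary signal")
  set.seed(params$seed)
  n_node <- idx$n_node
  real <- setdiff(seq_len(n_node), idx$root)   # branches with length
  incomp <- lapply(seq_len(n_node), function(x) {
    y <- real[!(idx$anc[x, real] | idx$anc[real, x])]
    y
  })
  fam_ids <- sprintf("F%03d", seq_len(params$n_families))
  o_cnt <- d_cnt <- t_cnt <- l_cnt <- integer(n_node)
  copy_num <- matrix(0L, n_node, params$n_families,
                     dimnames = list(idx$labels, fam_ids))
  gene_trees <- vector("list", params$n_families)
  names(gene_trees) <- fam_ids
  proteins <- vector("list", params$n_families)
  forced <- if (!is.null(origin_branch) && origin_branch != "root")
    node_of_label(idx, origin_branch) else NULL

  for (f in seq_len(params$n_families)) {
    for (try in seq_len(max_tries)) {
      st <- new.env(parent = emptyenv())
      st$dup <- params$dup_rate; st$tra <- params$transfer_rate
      st$los <- params$loss_rate
      st$incomp <- incomp; st$brlen <- idx$brlen
      st$children <- idx$children; st$is_tip <- idx$is_tip
      st$labels <- idx$labels
      st$d <- st$t <- st$l <- st$pres <- integer(n_node)
      st$k <- 0L; st$family_id <- fam_ids[f]
      if (!is.null(origin_branch) && origin_branch == "root") {
        ob <- idx$root
        st$pres[idx$root] <- 1L
        ch <- idx$children[[idx$root]]
        a <- sim_copy(ch[1L], idx$brlen[ch[1L]], st)
        b <- sim_copy(ch[2L], idx$brlen[ch[2L]], st)
        res <- join_subtrees(a, b, 0)
      } else {
        ob <- if (is.null(forced))
          real[sample.int(length(real), 1L, prob = idx$brlen[real])]
        else forced
        res <- sim_copy(ob, idx$brlen[ob], st)
      }
      if (!is.null(res)) break
      res <- NULL
    }
    if (is.null(res))
      stop("family ", fam_ids[f], " went extinct in every of ", max_tries,
           " redraws; lower loss_rate")
    o_cnt[ob] <- o_cnt[ob] + 1L
    d_cnt <- d_cnt + st$d; t_cnt <- t_cnt + st$t; l_cnt <- l_cnt + st$l
    copy_num[, f] <- st$pres
    gene_trees[[f]] <- genealogy_to_phylo(res)
    labs <- if (is.character(gene_trees[[f]])) gene_trees[[f]]
            else gene_trees[[f]]$tip.label
    parts <- do.call(rbind, strsplit(labs, "|", fixed = TRUE))
    proteins[[f]] <- data.frame(gene_id = parts[, 2L], genome_id = parts[, 1L],
                                family_id = fam_ids[f],
                                stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, proteins)
  rownames(proteins) <- NULL
  genomes <- idx$labels[idx$is_tip]
  n_genes <- vapply(genomes, function(g) sum(proteins$genome_id == g), 0L)
  metadata <- data.frame(genome_id = genomes, completeness = 100,
                         contamination = 0,
                         size_bp = as.integer(n_genes) * 1000L,
                         stringsAsFactors = FALSE)
  structure(list(
    species_tree = idx$tree, params = params, gene_trees = gene_trees,
    proteins = proteins, metadata = metadata,
    truth = list(
      branch = data.frame(branch_id = idx$labels, o = o_cnt, d = d_cnt,
                          t = t_cnt, l = l_cnt, stringsAsFactors = FALSE),
      copy_number = copy_num),
    alignments = NULL, observed = FALSE
  ), class = "sim_dataset")
}

#' Degrade a simulated dataset to mimic MAG incompleteness
#'
#' Retains each gene of genome `g` independently with probability
#' `completeness_map[g]`, prunes the gene trees accordingly, and records the
#' assigned completeness in the metadata. The `TrueHistory` is left unchanged
#' (the truth is pre-degradation).
#'
#' @param dataset a `sim_dataset`.
#' @param completeness_map named numeric vector (fractions in (0, 1]) by
#'   genome; genomes not named keep completeness 1.
#' @param seed integer seed.
#' @return the observed `sim_dataset`.
#' @export
degrade_completeness <- function(dataset, completeness_map, seed = 1) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (any(completeness_map <= 0) || any(completeness_map > 1))
    stop("invalid parameter: completeness values must lie in (0, 1]")
  genomes <- dataset$metadata$genome_id
  cmap <- stats::setNames(rep(1, length(genomes)), genomes)
  cmap[names(completeness_map)] <- completeness_map
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(dataset$proteins)) <=
    cmap[dataset$proteins$genome_id]
  kept <- dataset$proteins[keep, , drop = FALSE]
  out <- dataset
  out$proteins <- kept
  out$gene_trees <- lapply(names(dataset$gene_trees), function(f) {
    gt <- dataset$gene_trees[[f]]
    labs <- if (is.character(gt)) gt else gt$tip.label
    genes <- vapply(strsplit(labs, "|", fixed = TRUE), `[`, "", 2L)
    ok <- genes %in% kept$gene_id[kept$family_id == f]
    if (!any(ok)) return(NULL)
    if (is.character(gt)) return(gt)
    if (sum(ok) == 1L) return(labs[ok])
    ape::keep.tip(gt, labs[ok])
  })
  names(out$gene_trees) <- names(dataset$gene_trees)
  if (!is.null(dataset$alignments)) {
    out$alignments <- lapply(names(dataset$alignments), function(f) {
      aln <- dataset$alignments[[f]]
      genes <- vapply(strsplit(names(aln), "|", fixed = TRUE), `[`, "", 2L)
      aln[genes %in% kept$gene_id[kept$family_id == f]]
    })
    names(out$alignments) <- names(dataset$alignments)
    out$alignments <- Filter(function(a) length(a) > 0, out$alignments)
  }
  n_genes <- vapply(genomes, function(g) sum(kept$genome_id == g), 0L)
  out$metadata$completeness <- 100 * cmap[genomes]
  out$metadata$size_bp <- as.integer(round(n_genes * 1000L))
  out$observed <- TRUE
  out
}

# internal: uniform 20-state replacement of a sequence (integer codes) over
# evolutionary distance d. P(unchanged | k events) = 1/20 + (19/20)(-1/19)^k.
mutate_seq <- function(s, d) {
  if (d <= 0) return(s)
  k <- stats::rpois(length(s), d)
  hit <- which(k > 0L)
  if (!length(hit)) return(s)
  stay_p <- 1 / 20 + (19 / 20) * (-1 / 19)^k[hit]
  moved <- hit[stats::runif(length(hit)) >= stay_p]
  if (length(moved))
    s[moved] <- ((s[moved] - 1L +
                    sample.int(19L, length(moved), replace = TRUE)) %% 20L) + 1L
  s
}

#' Simulate protein sequences along the gene trees
#'
#' Evolves a uniform-replacement amino-acid sequence (each substitution picks
#' uniformly among the 19 alternative residues) down every gene tree. The
#' expected pairwise identity between two leaves at total distance d is
#' `0.05 + 0.95 * exp(-(20/19) * d * subst_rate)`. Output alignments are
#' gap-free and positionally homologous within a family.
#'
#' @param dataset a `sim_dataset` with gene trees.
#' @param params an [evol_params()] (uses `seq_length`, `subst_rate`, `seed`).
#' @return the dataset with `$alignments`: per family a named character
#'   vector of aligned sequences, names matching gene-tree leaf labels.
#' @export
simulate_sequences <- function(dataset, params = dataset$params) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (is.null(dataset$gene_trees)) stop("dataset has no gene trees")
  set.seed(params$seed + 1L)
  L <- params$seq_length
  mu <- params$subst_rate
  dataset$alignments <- lapply(dataset$gene_trees, function(gt) {
    root_seq <- sample.int(20L, L, replace = TRUE)
    if (is.null(gt)) return(NULL)
    if (is.character(gt)) {
      out <- paste(AA_ALPHABET20[root_seq], collapse = "")
      return(stats::setNames(out, gt))
    }
    ntip <- length(gt$tip.label)
    seqs <- vector("list", ntip + gt$Nnode)
    seqs[[ntip + 1L]] <- root_seq
    ord <- ape::reorder.phylo(gt, "cladewise")$edge
    lens <- ape::reorder.phylo(gt, "cladewise")$edge.length
    out <- character(ntip)
    for (i in seq_len(nrow(ord))) {
      p <- ord[i, 1L]; ch <- ord[i, 2L]
      seqs[[ch]] <- mutate_seq(seqs[[p]], mu * lens[i])
      if (ch <= ntip)
        out[ch] <- paste(AA_ALPHABET20[seqs[[ch]]], collapse = "")
    }
    stats::setNames(out, gt$tip.label)
  })
  dataset$alignments <- Filter(Negate(is.null), dataset$alignments)
  dataset
}

#' Derive an all-vs-all similarity-hit table from simulated sequences
#'
#' Computes full-length pairwise percent identity between every pair of
#' simulated proteins and reports pairs at or above a reporting floor as
#' 12-column tabular hits (BLAST outfmt-6 dialect), both directions. Bitscore
#' is a monotone transform of identity; e-value a monotone transform of
#' bitscore. Unrelated families drift to ~5% identity and fall below any
#' sensible floor.
#'
#' @param dataset a `sim_dataset` with `$alignments`.
#' @param min_report_pct reporting floor on percent identity.
#' @return data.frame with the 12 outfmt-6 columns.
#' @export
simulate_hits <- function(dataset, min_report_pct = 25) {
  if (is.null(dataset$alignments))
    stop("run simulate_sequences() first")
  seqs <- unlist(unname(dataset$alignments))
  ids <- names(seqs)
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("simulated sequences must share one length")
  X <- matrix(match(unlist(strsplit(seqs, "")), AA_ALPHABET20), nrow = n,
              byrow = TRUE)
  idm <- matrix(0, n, n)
  for (a in seq_len(20L)) {
    Ia <- (X == a) * 1
    idm <- idm + tcrossprod(Ia)
  }
  pid <- 100 * idm / L
  ut <- which(upper.tri(pid) & pid >= min_report_pct, arr.ind = TRUE)
  if (!nrow(ut)) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  q <- c(ut[, 1L], ut[, 2L]); s <- c(ut[, 2L], ut[, 1L])
  pident <- round(pid[cbind(q, s)], 2)
  bits <- round(2 * L * pident / 100, 1)
  data.frame(
    qseqid = ids[q], sseqid = ids[s], pident = pident, length = L,
    mismatch = as.integer(round(L * (1 - pident / 100))), gapopen = 0L,
    qstart = 1L, qend = L, sstart = 1L, send = L,
    evalue = 10^(-bits / 10), bitscore = bits, stringsAsFactors = FALSE)
}
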