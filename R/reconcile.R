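#' Event costs for undated DTL parsimony
#'
#' @param dup cost of a duplication (> 0).
#' @param transfer cost of a transfer (> 0).
#' @param loss cost of a loss (> 0); speciations are free.
#' @return an object of class `event_costs`.
#' @export
event_costs <- function(dup = 2, transfer = 3, loss = 1) {
  if (any(c(dup, transfer, loss) <= 0))
    stop("event costs must all be > 0")
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "event_costs")
}

# lexicographic (cost, transfers, dups) comparison with numeric tolerance
.better <- function(c1, t1, d1, c2, t2, d2, eps = 1e-9) {
  if (c1 < c2 - eps) return(TRUE)
  if (c1 > c2 + eps) return(FALSE)
  if (t1 < t2) return(TRUE)
  if (t1 > t2) return(FALSE)
  d1 < d2
}

# internal gene-tree structure: children list, tip -> species node id map,
# postorder. Built from a rooted binary phylo, a single tip label, or one
# rooting of an unrooted tree.
gene_struct_from_phylo <- function(gt, idx) {
  ntip <- length(gt$tip.label)
  n <- ntip + gt$Nnode
  children <- vector("list", n)
  for (i in seq_len(nrow(gt$edge))) {
    p <- gt$edge[i, 1L]
    children[[p]] <- c(children[[p]], gt$edge[i, 2L])
  }
  if (any(lengths(children[(ntip + 1L):n]) != 2L))
    stop("non-binary gene tree")
  tip_sp <- rep(NA_integer_, n)
  tip_sp[seq_len(ntip)] <- map_leaf_genomes(gt$tip.label, idx)
  post <- integer(0)
  stack <- ntip + 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(post, v)
    stack <- c(stack, children[[v]])
  }
  list(n = n, ntip = ntip, children = children, tip_sp = tip_sp,
       post = rev(post), root = ntip + 1L, tip_label = gt$tip.label)
}

# leaf labels "genome|gene|family" or plain genome ids -> species tip ids
map_leaf_genomes <- function(labels, idx) {
  genomes <- vapply(strsplit(labels, "|", fixed = TRUE), `[`, "", 1L)
  sp <- match(genomes, idx$labels[idx$is_tip])
  if (anyNA(sp))
    stop("gene-tree leaf genome(s) not in species tree: ",
         paste(unique(genomes[is.na(sp)]), collapse = ", "))
  sp
}

# all rootings of an unrooted binary phylo, as gene_structs
unrooted_rootings <- function(gt, idx) {
  ntip <- length(gt$tip.label)
  n <- ntip + gt$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(gt$edge))) {
    a <- gt$edge[i, 1L]; b <- gt$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  if (any(deg[(ntip + 1L):n] != 3L) || any(deg[seq_len(ntip)] != 1L))
    stop("non-binary gene tree")
  tip_sp_base <- map_leaf_genomes(gt$tip.label, idx)
  lapply(seq_len(nrow(gt$edge)), function(i) {
    a <- gt$edge[i, 1L]; b <- gt$edge[i, 2L]
    root <- n + 1L
    children <- vector("list", root)
    children[[root]] <- c(a, b)
    orient <- function(v, from) {
      kids <- setdiff(adj[[v]], from)
      children[[v]] <<- kids
      for (k in kids) orient(k, v)
    }
    orient(a, b); orient(b, a)
    post <- integer(0)
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      post <- c(post, v)
      stack <- c(stack, children[[v]])
    }
    tip_sp <- rep(NA_integer_, root)
    tip_sp[seq_len(ntip)] <- tip_sp_base
    list(n = root, ntip = ntip, children = children, tip_sp = tip_sp,
         post = rev(post), root = root, tip_label = gt$tip.label)
  })
}

# core dynamic program; returns cost/tie tuples plus traceback tables
dp_reconcile <- function(gs, idx, costs, losscost) {
  S <- idx$n_node
  lexS <- idx$lex
  sp_post <- postorder_nodes(idx)
  incomp <- lapply(seq_len(S), function(x) {
    y <- which(!(idx$anc[x, ] | idx$anc[, x]) & seq_len(S) != idx$root)
    y[order(idx$labels[y])]
  })
  M <- gs$n
  INF <- Inf
  Ac <- matrix(INF, M, S); At <- matrix(0L, M, S); Ad <- matrix(0L, M, S)
  Ic <- matrix(INF, M, S); It <- matrix(0L, M, S); Id <- matrix(0L, M, S)
  Oc <- matrix(INF, M, S); Ot <- matrix(0L, M, S); Od <- matrix(0L, M, S)
  Ach <- matrix(0L, M, S)      # A choice code
  Ich <- matrix(0L, M, S)      # IN choice: 0 stay, 1/2 descend
  Oarg <- matrix(0L, M, S)     # OUT argmin branch
  for (u in gs$post) {
    kids <- gs$children[[u]]
    if (!length(kids)) {
      Ac[u, gs$tip_sp[u]] <- 0
    } else {
      v <- kids[1L]; w <- kids[2L]
      for (x in lexS) {
        bc <- INF; bt <- 0L; bd <- 0L; bch <- 0L
        cand <- function(cc, tt, dd, code) {
          if (is.finite(cc) && .better(cc, tt, dd, bc, bt, bd)) {
            bc <<- cc; bt <<- tt; bd <<- dd; bch <<- code
          }
        }
        if (!idx$is_tip[x]) {
          ch <- idx$children[[x]]
          l <- ch[1L]; r <- ch[2L]
          cand(Ic[v, l] + Ic[w, r], It[v, l] + It[w, r],
               Id[v, l] + Id[w, r], 1L)
          cand(Ic[v, r] + Ic[w, l], It[v, r] + It[w, l],
               Id[v, r] + Id[w, l], 2L)
        }
        cand(costs$dup + Ic[v, x] + Ic[w, x], It[v, x] + It[w, x],
             Id[v, x] + Id[w, x] + 1L, 3L)
        cand(costs$transfer + Ic[v, x] + Oc[w, x],
             It[v, x] + Ot[w, x] + 1L, Id[v, x] + Od[w, x], 4L)
        cand(costs$transfer + Ic[w, x] + Oc[v, x],
             It[w, x] + Ot[v, x] + 1L, Id[w, x] + Od[v, x], 5L)
        Ac[u, x] <- bc; At[u, x] <- bt; Ad[u, x] <- bd; Ach[u, x] <- bch
      }
    }
    # IN: species postorder so children are ready
    for (x in sp_post) {
      bc <- Ac[u, x]; bt <- At[u, x]; bd <- Ad[u, x]; bch <- 0L
      if (!idx$is_tip[x]) {
        ch <- idx$children[[x]]
        if (idx$labels[ch[2L]] < idx$labels[ch[1L]]) ch <- rev(ch)
        for (k in 1:2) {
          into <- ch[k]; lost <- ch[3L - k]
          cc <- Ic[u, into] + losscost[lost]
          if (is.finite(cc) &&
              .better(cc, It[u, into], Id[u, into], bc, bt, bd)) {
            bc <- cc; bt <- It[u, into]; bd <- Id[u, into]
            bch <- if (into == idx$children[[x]][1L]) 1L else 2L
          }
        }
      }
      Ic[u, x] <- bc; It[u, x] <- bt; Id[u, x] <- bd; Ich[u, x] <- bch
    }
    # OUT: best IN over incomparable branches, lex scan
    for (x in seq_len(S)) {
      bc <- INF; bt <- 0L; bd <- 0L; barg <- 0L
      for (y in incomp[[x]]) {
        if (is.finite(Ic[u, y]) && .better(Ic[u, y], It[u, y], Id[u, y],
                                           bc, bt, bd)) {
          bc <- Ic[u, y]; bt <- It[u, y]; bd <- Id[u, y]; barg <- y
        }
      }
      Oc[u, x] <- bc; Ot[u, x] <- bt; Od[u, x] <- bd; Oarg[u, x] <- barg
    }
  }
  list(Ac = Ac, At = At, Ad = Ad, Ic = Ic, It = It, Id = Id,
       Oc = Oc, Ach = Ach, Ich = Ich, Oarg = Oarg)
}

# follow the stored DP choices, emitting events, tallies and node presence
traceback_reconciliation <- function(gs, idx, dp, root_branch) {
  S <- idx$n_node
  acc <- new.env(parent = emptyenv())
  acc$d <- acc$t <- acc$l <- acc$pres <- integer(S)
  acc$events <- list()
  emit <- function(type, branch, donor = NA_character_, gene_node = NA_integer_)
    acc$events[[length(acc$events) + 1L]] <-
      data.frame(type = type, branch = idx$labels[branch],
                 donor = if (is.na(donor)) NA_character_ else donor,
                 gene_node = gene_node, stringsAsFactors = FALSE)
  tb_A <- function(u, x) {
    kids <- gs$children[[u]]
    if (!length(kids)) {
      acc$pres[x] <- acc$pres[x] + 1L
      return(invisible())
    }
    v <- kids[1L]; w <- kids[2L]
    code <- dp$Ach[u, x]
    ch <- if (!idx$is_tip[x]) idx$children[[x]] else NULL
    if (code == 1L || code == 2L) {
      acc$pres[x] <- acc$pres[x] + 1L
      emit("speciation", x, gene_node = u)
      if (code == 1L) { tb_IN(v, ch[1L]); tb_IN(w, ch[2L]) }
      else { tb_IN(v, ch[2L]); tb_IN(w, ch[1L]) }
    } else if (code == 3L) {
      acc$d[x] <- acc$d[x] + 1L
      emit("duplication", x, gene_node = u)
      tb_IN(v, x); tb_IN(w, x)
    } else if (code == 4L || code == 5L) {
      stay <- if (code == 4L) v else w
      move <- if (code == 4L) w else v
      y <- dp$Oarg[move, x]
      acc$t[y] <- acc$t[y] + 1L
      emit("transfer", y, donor = idx$labels[x], gene_node = u)
      tb_IN(stay, x); tb_IN(move, y)
    } else stop("internal error: unset A choice")
    invisible()
  }
  tb_IN <- function(u, x) {
    code <- dp$Ich[u, x]
    if (code == 0L) return(tb_A(u, x))
    ch <- idx$children[[x]]
    into <- ch[code]; lost <- ch[3L - code]
    acc$pres[x] <- acc$pres[x] + 1L
    acc$l[lost] <- acc$l[lost] + 1L
    emit("loss", lost, gene_node = u)
    tb_IN(u, into)
  }
  tb_A(gs$root, root_branch)
  acc
}

#' Reconcile a gene tree with a species tree under undated DTL parsimony
#'
#' Computes the minimum-cost mapping of a gene tree into a rooted species
#' tree under an undated duplication-transfer-loss model: transfers are only
#' allowed between incomparable species branches, the family's origination
#' branch is the branch the gene-tree root maps to, and the absence of a
#' family member at a leaf with completeness `c` is charged `loss * c`
#' instead of the full loss cost (an expected-cost discount for genes that
#' are missing only because the assembly is incomplete). Ties are broken in
#' favour of fewer transfers, then fewer duplications, then the
#' lexicographically smallest species-branch label. Unrooted gene trees are
#' rooted by minimum reconciliation cost over all edges.
#'
#' @param gene_tree a `phylo` gene tree (rooted binary, or unrooted with a
#'   basal trifurcation), or a single leaf label for one-member families.
#'   Leaf labels are genome ids, optionally `genome|gene|family`.
#' @param species_tree rooted binary `phylo`; unlabelled internal nodes are
#'   auto-labelled `N1..Nk` in preorder.
#' @param costs an [event_costs()] object.
#' @param completeness named numeric vector of fractions in (0, 1] by genome
#'   (missing genomes default to 1).
#' @param family_id identifier carried into the result.
#' @return an object of class `reconciliation`: total `cost`, `origination`
#'   branch label, per-event `events` data.frame, per-branch `tallies`
#'   (`branch_id`, `dup`, `transfer`, `loss`, `orig`), `presence` (copies
#'   surviving at each species node) and event totals.
#' @export
reconcile_undated <- function(gene_tree, species_tree, costs = event_costs(),
                              completeness = NULL, family_id = NA_character_) {
  idx <- species_index(species_tree)
  stopifnot(inherits(costs, "event_costs"))
  comp <- rep(1, idx$n_node)
  if (!is.null(completeness)) {
    if (any(completeness <= 0) || any(completeness > 1))
      stop("completeness values must lie in (0, 1]")
    tipn <- match(names(completeness), idx$labels)
    bad <- names(completeness)[is.na(tipn)]
    if (length(bad))
      stop("completeness given for unknown genome(s): ",
           paste(bad, collapse = ", "))
    comp[tipn] <- completeness
  }
  losscost <- ifelse(idx$is_tip, costs$loss * comp, costs$loss)

  if (is.character(gene_tree) && length(gene_tree) == 1L) {
    sp <- map_leaf_genomes(gene_tree, idx)
    pres <- integer(idx$n_node); pres[sp] <- 1L
    return(new_reconciliation(idx, family_id, cost = 0,
                              origination = idx$labels[sp],
                              events = empty_events(),
                              d = integer(idx$n_node), t = integer(idx$n_node),
                              l = integer(idx$n_node), pres = pres))
  }
  if (!inherits(gene_tree, "phylo")) stop("gene_tree must be phylo or a label")

  structs <- if (ape::is.rooted(gene_tree))
    list(gene_struct_from_phylo(gene_tree, idx))
  else unrooted_rootings(gene_tree, idx)

  best <- NULL
  for (gs in structs) {
    dp <- dp_reconcile(gs, idx, costs, losscost)
    bc <- Inf; bt <- 0L; bd <- 0L; bx <- 0L
    for (x in idx$lex) {
      if (is.finite(dp$Ac[gs$root, x]) &&
          .better(dp$Ac[gs$root, x], dp$At[gs$root, x], dp$Ad[gs$root, x],
                  bc, bt, bd)) {
        bc <- dp$Ac[gs$root, x]; bt <- dp$At[gs$root, x]
        bd <- dp$Ad[gs$root, x]; bx <- x
      }
    }
    if (is.null(best) || .better(bc, bt, bd, best$bc, best$bt, best$bd))
      best <- list(gs = gs, dp = dp, bc = bc, bt = bt, bd = bd, bx = bx)
  }
  if (!is.finite(best$bc)) stop("no feasible reconciliation found")
  acc <- traceback_reconciliation(best$gs, idx, best$dp, best$bx)
  events <- if (length(acc$events)) do.call(rbind, acc$events)
            else empty_events()
  new_reconciliation(idx, family_id, cost = best$bc,
                     origination = idx$labels[best$bx], events = events,
                     d = acc$d, t = acc$t, l = acc$l, pres = acc$pres)
}

empty_events <- function()
  data.frame(type = character(0), branch = character(0),
             donor = character(0), gene_node = integer(0),
             stringsAsFactors = FALSE)

new_reconciliation <- function(idx, family_id, cost, origination, events,
                               d, t, l, pres) {
  tallies <- data.frame(
    branch_id = idx$labels, dup = as.integer(d), transfer = as.integer(t),
    loss = as.integer(l),
    orig = as.integer(idx$labels == origination), stringsAsFactors = FALSE)
  structure(list(
    family_id = family_id, cost = cost, origination = origination,
    events = events, tallies = tallies,
    presence = stats::setNames(as.integer(pres), idx$labels),
    n_dup = sum(d), n_transfer = sum(t), n_loss = sum(l),
    species_labels = idx$labels
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf(
    "reconciliation%s: cost %.3f | %d dup, %d transfer, %d loss | origin %s\n",
    if (is.na(x$family_id)) "" else paste0(" [", x$family_id, "]"),
    x$cost, x$n_dup, x$n_transfer, x$n_loss, x$origination))
  invisible(x)
}

#' Decompose per-branch gene gains into duplication / intra-LGT / origination
#'
#' Every duplication event is a duplication gain on its branch; every
#' transfer-receive is an intra-LGT gain on the receiving branch (transfers
#' within the sampled genome set are intra-LGT by definition); each family
#' contributes exactly one origination gain on the branch its gene-tree root
#' maps to. The three classes partition the gains exactly.
#'
#' @param reconciliations list of [reconcile_undated()] results against one
#'   shared species tree.
#' @param sampled_genome_set optional character vector of genomes (the
#'   sampled set); retained for interface symmetry — all in-tree transfers
#'   are classed intra-LGT.
#' @return data.frame `branch_id`, `duplication`, `intra_lgt`, `origination`
#'   with attribute `totals` (named numeric, including the grand total).
#' @export
classify_gains <- function(reconciliations, sampled_genome_set = NULL) {
  stopifnot(length(reconciliations) > 0)
  labs <- reconciliations[[1L]]$species_labels
  for (r in reconciliations)
    if (!identical(r$species_labels, labs))
      stop("reconciliations computed against different species trees")
  dup <- lgt <- orig <- stats::setNames(integer(length(labs)), labs)
  for (r in reconciliations) {
    dup <- dup + r$tallies$dup
    lgt <- lgt + r$tallies$transfer
    orig <- orig + r$tallies$orig
  }
  out <- data.frame(branch_id = labs, duplication = as.integer(dup),
                    intra_lgt = as.integer(lgt),
                    origination = as.integer(orig), stringsAsFactors = FALSE)
  attr(out, "totals") <- c(duplication = sum(dup), intra_lgt = sum(lgt),
                           origination = sum(orig),
                           total = sum(dup) + sum(lgt) + sum(orig))
  out
}

#' Percentage report for a gain decomposition
#'
#' Shared reporting path for gain decompositions: given class totals, returns
#' the grand total and integer-rounded percentages per mechanism.
#'
#' @param duplication,intra_lgt,origination class totals (counts).
#' @return list with `total` and `pct` (named integer vector).
#' @export
gain_percentages <- function(duplication, intra_lgt, origination) {
  total <- duplication + intra_lgt + origination
  if (total <= 0) stop("no gains to report")
  pct <- round(100 * c(duplication = duplication, intra_lgt = intra_lgt,
                       origination = origination) / total)
  list(total = total, pct = pct)
}
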