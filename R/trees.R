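#' Indexed view of a rooted species tree
#'
#' Builds the lookup tables used throughout the package from a rooted, binary
#' `ape::phylo` tree: node labels (internal nodes are auto-labelled
#' `N1..Nk` in preorder when unlabelled), parent/child pointers, the
#' ancestor-or-equal relation, and branch lengths. Every node identifies the
#' branch above it; the root node identifies the root stem.
#'
#' @param tree a rooted binary `phylo` object.
#' @return an object of class `species_index`: a list with elements `tree`,
#'   `labels`, `parent`, `children`, `is_tip`, `brlen`, `anc` (logical matrix,
#'   `anc[i, j]` is TRUE iff node i is an ancestor of j or equal to it),
#'   `root`, `n_tip`, and `lex` (node ids in lexicographic label order).
#' @export
species_index <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    ord <- preorder_nodes(tree)
    internal_preorder <- ord[ord > n_tip]
    lab <- tree$node.label
    if (is.null(lab)) lab <- character(tree$Nnode)
    for (i in seq_along(internal_preorder)) {
      k <- internal_preorder[i] - n_tip
      if (!nzchar(lab[k])) lab[k] <- paste0("N", i)
    }
    tree$node.label <- lab
  }
  labels <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labels)) {
    stop("duplicate node labels in species tree: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  parent <- integer(n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- n_tip + 1L
  brlen <- numeric(n_node)
  if (!is.null(tree$edge.length)) brlen[tree$edge[, 2L]] <- tree$edge.length
  anc <- matrix(FALSE, n_node, n_node)
  ord <- preorder_nodes(tree)
  for (v in ord) {
    anc[v, v] <- TRUE
    if (v != root) anc[, v] <- anc[, v] | anc[, parent[v]]
  }
  structure(list(
    tree = tree, labels = labels, parent = parent, children = children,
    is_tip = seq_len(n_node) <= n_tip, brlen = brlen, anc = anc,
    root = root, n_tip = n_tip, n_node = n_node,
    lex = order(labels)
  ), class = "species_index")
}

# preorder node ids (root first), parents before children
preorder_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[v]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  out
}

# postorder (children before parents)
postorder_nodes <- function(idx) rev(preorder_nodes(idx$tree))

#' Node id for a branch label
#' @keywords internal
node_of_label <- function(idx, label) {
  i <- match(label, idx$labels)
  if (is.na(i)) stop("label '", label, "' not found in species tree")
  i
}

#' Descendant tip labels of a node/branch
#' @param idx a [species_index()].
#' @param label a node (branch) label.
#' @return character vector of tip labels below (and including) the node.
#' @export
descendant_tips <- function(idx, label) {
  v <- node_of_label(idx, label)
  idx$labels[which(idx$anc[v, ] & idx$is_tip)]
}

#' Patristic distance matrix of a tree
#'
#' Thin wrapper over [ape::cophenetic.phylo()] returning a matrix with rows
#' and columns ordered by tip label.
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric numeric matrix of summed branch-length path distances.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  d[ord, ord, drop = FALSE]
}

#' Write a species tree with per-branch event counts as comments
#'
#' Annotates each branch with `[&dup=..,loss=..,intra_lgt=..,orig=..]`
#' comments readable by common tree viewers.
#' @param tree rooted species tree (`phylo`).
#' @param table a branch event table as returned by [aggregate_events()].
#' @param path output file path.
#' @return the annotated Newick string, invisibly.
#' @export
write_annotated_newick <- function(tree, table, path) {
  idx <- species_index(tree)
  build_annotated <- function(v) {
    lab <- idx$labels[v]
    row <- table[table$branch_id == lab, , drop = FALSE]
    com <- if (nrow(row) == 1L) {
      sprintf("[&dup=%d,loss=%d,intra_lgt=%d,orig=%d]",
              row$dup, row$loss, row$intra_lgt, row$orig)
    } else ""
    bl <- if (v == idx$root) "" else sprintf(":%g", idx$brlen[v])
    if (idx$is_tip[v]) return(paste0(lab, com, bl))
    ch <- idx$children[[v]]
    paste0("(", build_annotated(ch[1]), ",", build_annotated(ch[2]), ")",
           lab, com, bl)
  }
  s <- paste0(build_annotated(idx$root), ";")
  writeLines(s, path)
  invisible(s)
}
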