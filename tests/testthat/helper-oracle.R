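# Independent oracles used to check the package's algorithms.

# Exhaustive undated-DTL enumeration. Gene trees are nested lists (leaves are
# genome labels, internal nodes two-element lists); recursion explores every
# event history (duplication, transfer to each incomparable branch,
# speciation, stepwise pass-through losses) without memoisation.
naive_dtl_cost <- function(gtree, idx, costs, losscost = NULL) {
  if (is.null(losscost))
    losscost <- ifelse(idx$is_tip, costs$loss, costs$loss)
  S <- idx$n_node
  incomp <- lapply(seq_len(S), function(x)
    which(!(idx$anc[x, ] | idx$anc[, x]) & seq_len(S) != idx$root))
  enter <- function(u, x) {
    best <- Inf
    if (is.character(u)) {
      if (idx$is_tip[x] && idx$labels[x] == u) best <- 0
    } else {
      best <- min(best, costs$dup + enter(u[[1]], x) + enter(u[[2]], x))
      for (y in incomp[[x]]) {
        best <- min(best,
                    costs$transfer + enter(u[[1]], x) + enter(u[[2]], y),
                    costs$transfer + enter(u[[1]], y) + enter(u[[2]], x))
      }
      if (!idx$is_tip[x]) {
        ch <- idx$children[[x]]
        best <- min(best,
                    enter(u[[1]], ch[1]) + enter(u[[2]], ch[2]),
                    enter(u[[1]], ch[2]) + enter(u[[2]], ch[1]))
      }
    }
    if (!idx$is_tip[x]) {
      ch <- idx$children[[x]]
      best <- min(best,
                  losscost[ch[2]] + enter(u, ch[1]),
                  losscost[ch[1]] + enter(u, ch[2]))
    }
    best
  }
  min(vapply(seq_len(S), function(x) enter(gtree, x), 0))
}

# random nested binary topology over a label multiset
rand_topology <- function(labels) {
  if (length(labels) == 1L) return(labels[[1L]])
  k <- sample.int(length(labels) - 1L, 1L)
  pick <- sample.int(length(labels), k)
  list(rand_topology(labels[pick]), rand_topology(labels[-pick]))
}

nested_to_newick <- function(u) {
  go <- function(v) if (is.character(v)) v
    else paste0("(", go(v[[1]]), ",", go(v[[2]]), ")")
  paste0(go(u), ";")
}

# one random reconciliation instance: rooted species tree of 2..4 leaves,
# gene tree of 1..5 leaves over those genomes, costs in [1, 5]
rand_dtl_instance <- function() {
  ns <- sample(2:4, 1L)
  sp <- ape::rtree(ns, rooted = TRUE, tip.label = LETTERS[seq_len(ns)])
  ng <- sample(1:5, 1L)
  leaves <- sample(sp$tip.label, ng, replace = TRUE)
  gt <- rand_topology(leaves)
  costs <- event_costs(dup = runif(1, 1, 5), transfer = runif(1, 1, 5),
                       loss = runif(1, 1, 5))
  list(species = sp, gene_nested = gt,
       gene_phylo = if (ng == 1L) leaves else
         ape::read.tree(text = nested_to_newick(gt)),
       costs = costs)
}

# Reference Markov clustering, coded independently of mcl_cluster():
# explicit column-by-column normalisation and loop-based interpretation.
ref_mcl <- function(adj, inflation) {
  n <- nrow(adj)
  for (i in seq_len(n)) adj[i, i] <- max(adj[i, ], 1e-12)
  M <- adj
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  repeat {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      E[i, j] <- sum(M[i, ] * M[, j])
    E <- E^inflation
    E[E < 1e-10] <- 0
    for (j in seq_len(n)) {
      s <- sum(E[, j])
      if (s > 0) E[, j] <- E[, j] / s
    }
    if (max(abs(E - M)) < 1e-8) { M <- E; break }
    M <- E
  }
  # connected components of the attractor graph
  edge <- (M > 1e-6) | t(M > 1e-6)
  diag(edge) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      if (comp[v]) next
      comp[v] <- cur
      q <- c(q, which(edge[v, ] & comp == 0L))
    }
  }
  comp
}

# brute-force medoid: summed BLOSUM62 distances with plain loops
brute_medoid <- function(alignment) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  B <- BLOSUM62
  ids <- names(alignment)
  n <- length(ids)
  score <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    s <- 0
    for (k in seq_along(ca))
      if (ca[k] != "-" && cb[k] != "-") s <- s + B[ca[k], cb[k]]
    s
  }
  self <- vapply(alignment, function(a) score(a, a), 0)
  tot <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- score(alignment[[i]], alignment[[j]])
    tot[i] <- tot[i] + (1 - s / max(self[i], self[j]))
  }
  sort(ids[tot <= min(tot) + 1e-12])[1L]
}
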