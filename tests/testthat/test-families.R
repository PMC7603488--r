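meta3 <- data.frame(genome_id = c("g1", "g2", "g3"),
                    completeness = c(63, 45, 80),
                    contamination = c(1, 1, 10),
                    stringsAsFactors = FALSE)

test_that("genome filters use strict inequalities", {
  expect_equal(filter_genomes(meta3), "g1")           # 45 and 10 excluded
  expect_true("g1" %in% filter_genomes(meta3))        # 63% / 1% kept
  broken <- meta3; broken$contamination[2] <- NA
  expect_error(filter_genomes(broken), "g2")
  expect_error(filter_genomes(meta3[, 1:2]), "contamination")
})

clique_edges <- function(ids, pident = 90, bitscore = 200) {
  do.call(rbind, lapply(utils::combn(ids, 2, simplify = FALSE), function(p)
    hit_row(p[1], p[2], pident = pident, bitscore = bitscore)))
}

test_that("disconnected cliques are never merged; weak edges are dropped", {
  prot <- data.frame(gene_id = paste0("p", 1:8),
                     genome_id = rep(c("g1", "g2"), 4),
                     stringsAsFactors = FALSE)
  e <- rbind(clique_edges(paste0("p", 1:4)), clique_edges(paste0("p", 5:8)))
  fam <- cluster_families(e, prot)
  expect_equal(length(unique(fam$family_id)), 2L)
  expect_equal(nrow(fam), 8L)  # partition property
  # an inter-clique edge below the identity floor changes nothing
  e2 <- rbind(e, hit_row("p1", "p5", pident = 20, bitscore = 40))
  fam2 <- cluster_families(e2, prot, min_pct_id = 35)
  expect_identical(fam2$family_id, fam$family_id)
  expect_error(cluster_families(hit_row("p1", "zz"), prot), "zz")
  expect_warning(fam3 <- cluster_families(e[0, ], prot), "own family")
  expect_equal(length(unique(fam3$family_id)), 8L)
})

test_that("barbell graph clustering matches an independent MCL run", {
  prot <- data.frame(gene_id = paste0("n", 1:6), genome_id = "g1",
                     stringsAsFactors = FALSE)
  e <- rbind(clique_edges(paste0("n", 1:3), bitscore = 100),
             clique_edges(paste0("n", 4:6), bitscore = 100),
             hit_row("n3", "n4", pident = 40, bitscore = 10))
  fam <- cluster_families(e, prot, inflation = 1.5)
  got <- split(fam$gene_id, fam$family_id)
  adj <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (k in seq_len(nrow(e))) {
    adj[e$qseqid[k], e$sseqid[k]] <- e$bitscore[k]
    adj[e$sseqid[k], e$qseqid[k]] <- e$bitscore[k]
  }
  ref <- ref_mcl(adj, 1.5)
  ref_parts <- split(paste0("n", 1:6), ref)
  expect_setequal(lapply(unname(got), sort), lapply(unname(ref_parts), sort))
  # the weak bridge must not fuse the triangles
  expect_equal(length(got), 2L)
})

test_that("length filter precedes the family-size filter", {
  prot <- data.frame(gene_id = paste0("q", 1:9),
                     genome_id = "g1",
                     length = c(50, 29, 29, 50, 50, 50, 50, 50, 50),
                     stringsAsFactors = FALSE)
  fam <- fam_table(list("FA", paste0("q", 1:5), "g1"),
                   list("FB", paste0("q", 6:9), "g1"))
  out <- filter_families(fam, prot)
  # FA: 5 members, 2 short -> 3 left -> removed; FB: 4 long members -> kept
  expect_setequal(unique(out$family_id), "FB")
  expect_equal(nrow(out), 4L)
  # family of 3 long members removed outright
  fam3 <- fam_table(list("FC", paste0("q", 4:6), "g1"))
  expect_equal(nrow(filter_families(fam3, prot)), 0L)
  # idempotence
  expect_identical(filter_families(out, prot), out)
})

test_that("core markers demand single copy and 85% near-complete presence", {
  genomes <- paste0("g", 1:10)
  meta <- data.frame(genome_id = genomes, completeness = 95,
                     contamination = 0, stringsAsFactors = FALSE)
  single9 <- fam_table(list("FX", paste0("x", 1:9), genomes[1:9]))
  dup1 <- rbind(fam_table(list("FY", paste0("y", 1:9), genomes[1:9])),
                fam_table(list("FY", "y10", genomes[1])))
  single8 <- fam_table(list("FZ", paste0("z", 1:8), genomes[1:8]))
  core <- select_core_markers(rbind(single9, dup1, single8), genomes, meta)
  flag <- stats::setNames(core$is_core, core$family_id)
  expect_true(flag[["FX"]])    # 9/10 >= 0.85, single copy
  expect_false(flag[["FY"]])   # copy count 2 in g1
  expect_false(flag[["FZ"]])   # 8/10 < 0.85
  lowmeta <- meta; lowmeta$completeness <- 50
  expect_error(select_core_markers(single9, genomes, lowmeta), "lower")
})

test_that("medoid selection matches brute force and breaks ties lexically", {
  expect_equal(compute_medoid(c(only = "MKV")), "only")
  aln <- c(b2 = "MKVLA", a1 = "MKVLA", zz = "WWWWW")
  expect_equal(compute_medoid(aln), "a1")
  set.seed(99)
  for (i in 1:5) {
    rnd <- vapply(1:4, function(j)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                   replace = TRUE), collapse = ""), "")
    names(rnd) <- paste0("s", 1:4)
    expect_equal(compute_medoid(rnd), brute_medoid(rnd))
  }
  expect_error(compute_medoid(character(0)), "empty")
})

test_that("families recovered from simulated data match the truth", {
  tr <- simulate_species_tree(6, seed = 21)
  p <- evol_params(n_families = 15, dup_rate = 0.05, loss_rate = 0.05,
                   seq_length = 120, subst_rate = 0.05, seed = 21)
  ds <- simulate_sequences(simulate_gene_content(tr, p))
  hits <- simulate_hits(ds, min_report_pct = 25)
  prot <- ds$proteins
  prot$gene_id <- paste(prot$genome_id, prot$gene_id, prot$family_id,
                        sep = "|")
  fam <- cluster_families(hits, prot, min_pct_id = 35)
  expect_equal(nrow(fam), nrow(prot))            # partition property
  truth <- vapply(strsplit(fam$gene_id, "|", fixed = TRUE), `[`, "", 3L)
  agree <- mean(vapply(split(truth, fam$family_id), function(z)
    length(unique(z)) == 1L, TRUE))
  # recovered families must be pure and cover >= 95% of proteins correctly
  tab <- table(fam$family_id, truth)
  purity <- sum(apply(tab, 1L, max)) / nrow(fam)
  expect_gte(purity, 0.95)
  expect_gte(agree, 0.95)
})
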