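test_that("simulate_species_tree gives labelled binary trees, deterministically", {
  expect_error(simulate_species_tree(1), "n_taxa")
  t2 <- simulate_species_tree(2, seed = 1)
  expect_s3_class(t2, "phylo")
  expect_length(t2$tip.label, 2L)
  t16 <- simulate_species_tree(16, seed = 1)
  expect_length(t16$tip.label, 16L)
  expect_equal(nrow(t16$edge), 2L * 16L - 2L)
  expect_true(all(t16$edge.length > 0))
  expect_identical(ape::write.tree(simulate_species_tree(16, seed = 1)),
                   ape::write.tree(t16))
  expect_false(identical(ape::write.tree(simulate_species_tree(16, seed = 2)),
                         ape::write.tree(t16)))
})

test_that("no-event limit: root origination reaches every leaf single-copy", {
  tr <- simulate_species_tree(8, seed = 3)
  p <- evol_params(n_families = 5, seed = 1)
  ds <- simulate_gene_content(tr, p, origin_branch = "root")
  cn <- ds$truth$copy_number
  expect_true(all(cn == 1L))
  expect_equal(sum(ds$truth$branch$d), 0L)
  expect_equal(sum(ds$truth$branch$t), 0L)
  expect_equal(sum(ds$truth$branch$l), 0L)
  expect_equal(ds$truth$branch$o[ds$truth$branch$branch_id == "N1"], 5L)
})

test_that("truth tallies are conserved and every family originates once", {
  tr <- simulate_species_tree(10, seed = 4)
  p <- evol_params(n_families = 40, dup_rate = 0.3, transfer_rate = 0.15,
                   loss_rate = 0.3, seed = 7)
  ds <- simulate_gene_content(tr, p)
  expect_equal(sum(ds$truth$branch$o), 40L)
  # leaf copy numbers match the surviving gene tallies
  tips <- ds$metadata$genome_id
  for (f in names(ds$gene_trees)) {
    genes <- ds$proteins[ds$proteins$family_id == f, ]
    for (g in tips)
      expect_identical(ds$truth$copy_number[g, f],
                       sum(genes$genome_id == g))
  }
  # gene-tree leaves map to exactly the surviving proteins
  all_leaves <- unlist(lapply(ds$gene_trees, function(gt)
    if (is.character(gt)) gt else gt$tip.label))
  expect_setequal(vapply(strsplit(all_leaves, "|", fixed = TRUE), `[`, "", 2L),
                  ds$proteins$gene_id)
  # determinism
  ds2 <- simulate_gene_content(tr, p)
  expect_identical(ds$truth, ds2$truth)
})

test_that("absorbing-loss limit empties the leaves", {
  tr <- simulate_species_tree(6, seed = 5)
  p <- evol_params(n_families = 4, loss_rate = 100, seed = 2)
  # survival conditioning cannot rescue rate-100 losses over deep branches
  expect_error(simulate_gene_content(tr, p, max_tries = 20L), "extinct")
})

test_that("pure duplication matches the Yule mean on a single branch", {
  tr <- ape::read.tree(text = "(g01:1,g02:1)N1;")
  p <- evol_params(n_families = 1000, dup_rate = 0.5, seed = 11)
  ds <- simulate_gene_content(tr, p, origin_branch = "g01",
                              max_tries = 1L)  # no loss: survival certain
  counts <- ds$truth$copy_number["g01", ]
  expect_true(all(ds$truth$copy_number["g02", ] == 0L))
  mean_expected <- exp(0.5 * 1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mean_expected), 3 * se)
})

test_that("degrade_completeness follows the binomial and keeps truth fixed", {
  tr <- ape::read.tree(text = "(g01:1,g02:1)N1;")
  p <- evol_params(n_families = 1000, seed = 8)
  ds <- simulate_gene_content(tr, p, origin_branch = "root")
  expect_error(degrade_completeness(ds, c(g01 = 0)), "invalid parameter")
  same <- degrade_completeness(ds, c(g01 = 1, g02 = 1), seed = 1)
  expect_identical(same$proteins, ds$proteins)
  obs <- degrade_completeness(ds, c(g01 = 0.5), seed = 2)
  kept <- sum(obs$proteins$genome_id == "g01")
  expect_lt(abs(kept - 500), 3 * sqrt(1000 * 0.25))
  expect_identical(obs$truth, ds$truth)
  expect_equal(obs$metadata$completeness[obs$metadata$genome_id == "g01"], 50)
  obs2 <- degrade_completeness(ds, c(g01 = 0.5), seed = 2)
  expect_identical(obs$proteins, obs2$proteins)
})

test_that("sequence evolution follows the uniform-model identity decay", {
  tr <- ape::read.tree(text = "(g01:0.25,g02:0.25)N1;")
  p <- evol_params(n_families = 300, seq_length = 200, subst_rate = 1,
                   seed = 13)
  ds <- simulate_gene_content(tr, p, origin_branch = "root")
  ds <- simulate_sequences(ds, p)
  # zero-rate limit
  p0 <- evol_params(n_families = 3, seq_length = 50, subst_rate = 0, seed = 1)
  ds0 <- simulate_gene_content(tr, p0, origin_branch = "root")
  ds0 <- simulate_sequences(ds0, p0)
  for (aln in ds0$alignments) expect_length(unique(unname(aln)), 1L)
  # closed-form identity at total distance d = 0.5
  ident <- vapply(ds$alignments, function(aln) {
    a <- strsplit(aln[[1]], "")[[1]]; b <- strsplit(aln[[2]], "")[[1]]
    mean(a == b)
  }, 0)
  d <- 0.5
  p_exp <- 0.05 + 0.95 * exp(-(20 / 19) * d * 1)
  se <- sqrt(p_exp * (1 - p_exp) / (300 * 200))
  expect_lt(abs(mean(ident) - p_exp), 3 * se)
  # determinism
  ds2 <- simulate_sequences(ds, p)
  expect_identical(ds$alignments, ds2$alignments)
})

test_that("simulated hit tables look like outfmt-6 and respect the floor", {
  tr <- simulate_species_tree(4, seed = 6)
  p <- evol_params(n_families = 5, seq_length = 100, subst_rate = 0.2,
                   seed = 3)
  ds <- simulate_sequences(simulate_gene_content(tr, p, origin_branch = "root"))
  h <- simulate_hits(ds, min_report_pct = 30)
  expect_named(h, c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                    "bitscore"))
  expect_true(all(h$pident >= 30))
  expect_true(all(h$qseqid != h$sseqid))
  # symmetric reporting
  key <- paste(h$qseqid, h$sseqid); rev_key <- paste(h$sseqid, h$qseqid)
  expect_setequal(key, rev_key)
})

test_that("evol_params validates its invariants", {
  expect_error(evol_params(0), "n_families")
  expect_error(evol_params(5, dup_rate = -1), "rates")
  expect_error(evol_params(5, seq_length = 0), "seq_length")
  expect_warning(
    simulate_gene_content(simulate_species_tree(4, seed = 1),
                          evol_params(2, origination_rate = 0, seed = 1)),
    "zero")
})
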