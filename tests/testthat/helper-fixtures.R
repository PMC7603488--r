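# Shared miniature fixtures, built in code.

sp4 <- function() ape::read.tree(text = "((A:1,B:1)AB:1,C:2)R;")
sp4b <- function() ape::read.tree(text = "((A:1,B:1)AB:1,(C:1,D:1)CD:1)R;")

# planted two-level species tree: 3 clades x 2 subclades x 2 genomes, branch
# lengths tuned so within-subclade AAI > 95, within-clade 70-95, between
# clades < 70 at subst_rate 1
planted_tree <- function() {
  sub <- function(a, b) sprintf("(%s:0.02,%s:0.02):0.105", a, b)
  clade <- function(i) {
    g <- sprintf("c%d%s", i, c("a", "b", "c", "d"))
    sprintf("(%s,%s):0.35", sub(g[1], g[2]), sub(g[3], g[4]))
  }
  ape::read.tree(text = sprintf("(%s,(%s,%s):0.01);",
                                clade(1), clade(2), clade(3)))
}

# small membership table for the family filters
fam_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(family_id = r[[1]], gene_id = r[[2]], genome_id = r[[3]],
               stringsAsFactors = FALSE)))
}

# minimal hit row with sane defaults
hit_row <- function(q, s, pident = 90, length = 150, evalue = 1e-30,
                    bitscore = 250, domain = NA, phylum = NA) {
  d <- data.frame(qseqid = q, sseqid = s, pident = pident, length = length,
                  mismatch = 0L, gapopen = 0L, qstart = 1L, qend = length,
                  sstart = 1L, send = length, evalue = evalue,
                  bitscore = bitscore, stringsAsFactors = FALSE)
  if (!is.na(domain)) d$subject_taxon_domain <- domain
  if (!is.na(phylum)) d$subject_taxon_phylum <- phylum
  d
}
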