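#!/usr/bin/env Rscript
# RBH synteny on a synthetic proteome pair: score proteins both ways,
# compute reciprocal best hits and ranks, write the dot-plot table, type
# outliers, and anchor shredded scaffolds back to chromosomes with AGP
# output. One gene is relocated and one duplicated to exercise the
# real/random outlier typing.
source("analysis/00_config.R")

set.seed(SEED + 8L)
aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
rand_prot <- function(n) paste(sample(aas, n, replace = TRUE), collapse = "")
n_genes <- 60

base <- vapply(rep(120, n_genes), rand_prot, character(1))
prot_a <- setNames(base, sprintf("ga%02d", 1:n_genes))
prot_b <- setNames(base, sprintf("gb%02d", 1:n_genes))
# a point-mutated copy keeps RBHs reciprocal but not identical
mutate1 <- function(p) {
  ch <- strsplit(p, "")[[1]]
  i <- sample(length(ch), 3)
  ch[i] <- sample(aas, 3, replace = TRUE)
  paste(ch, collapse = "")
}
prot_b[] <- vapply(prot_b, mutate1, character(1))

genes_a <- data.frame(id = names(prot_a), seq_id = "chrA",
                      start = seq(0, by = 4000, length.out = n_genes))
genes_a$end <- genes_a$start + 1200
genes_b <- genes_a
genes_b$id <- names(prot_b)
genes_b$seq_id <- "chrB"
# relocate one gene far away: a "real" outlier
genes_b$start[10] <- genes_b$start[50] + 2000
genes_b$end[10] <- genes_b$start[10] + 1200

hits_ab <- score_proteins(prot_a, prot_b)
hits_ba <- score_proteins(prot_b, prot_a)
rbhs <- compute_rbhs(best_hits(hits_ab), best_hits(hits_ba),
                     genes_a, genes_b)
write_tsv(rbhs, file.path(OUT, "rbh_pairs.tsv"))
dot_plot_data(rbhs, file.path(OUT, "rbh_dotplot.tsv"))
cat("RBH pairs:", nrow(rbhs), "of", n_genes, "genes (",
    round(100 * nrow(rbhs) / n_genes, 1), "% )\n")

out <- detect_outliers(rbhs, rbh_params(outlier_rank_dev = 10))
if (nrow(out) > 0) {
  typed <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    classify_outlier(out[i, ], hits_ab, hits_ba)
  }))
  write_tsv(typed, file.path(OUT, "rbh_outliers.tsv"))
  cat("outliers:", nrow(typed), "(", sum(typed$kind == "random"), "random,",
      sum(typed$kind == "real"), "real )\n")
} else {
  cat("outliers: 0\n")
}

# shred a 2-chromosome reference into scaffolds and anchor them back
n_frag <- 30
frag_len <- 40000L
chr_of <- rep(c("chr1", "chr2"), each = 15)
offset <- rep(seq(0, by = frag_len, length.out = 15), 2)
flip <- sample(c(TRUE, FALSE), n_frag, replace = TRUE)
ev <- do.call(rbind, lapply(seq_len(n_frag), function(i) {
  k <- sample(3:6, 1)
  gpos <- sort(sample(1000:(frag_len - 1000), k))
  data.frame(scaffold = sprintf("scf%02d", i),
             scaffold_pos = if (flip[i]) frag_len - gpos else gpos,
             chr = chr_of[i], chr_pos = offset[i] + gpos, weight = 1200)
}))
lens <- setNames(rep(frag_len, n_frag), sprintf("scf%02d", 1:n_frag))
anch <- anchor_scaffolds(ev, lens,
                         agp_path = file.path(OUT, "anchored.agp"))
write_tsv(anch$assignments, file.path(OUT, "scaffold_assignments.tsv"))
ok <- anch$assignments$chr == chr_of &
  anch$assignments$strand == ifelse(flip, "-", "+")
cat("scaffold anchoring: chromosome+orientation correct for",
    sum(ok), "of", n_frag, "\n")

# chimeric scaffold split hint
chim <- data.frame(scaffold = "chimera", pos = (1:10) * 2000,
                   counterpart_seq = rep(c("chr1", "chr2"), each = 5),
                   rank = c(1:5, 400:404))
hints <- scaffold_split_hints(chim)
write_tsv(hints, file.path(OUT, "split_hints.tsv"))
cat("split hints on the planted chimera:", nrow(hints),
    "at", hints$break_start[1], "-", hints$break_end[1], "\n")
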