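make_colinear_sets <- function(n, len = 80, seed = 1) {
  set.seed(seed)
  prots <- setNames(vapply(rep(len, n), rand_protein, character(1)),
                    paste0("g", seq_len(n)))
  genes <- data.frame(id = names(prots), seq_id = "chr1",
                      start = seq(0, by = 5000, length.out = n),
                      end = seq(0, by = 5000, length.out = n) + 1000,
                      stringsAsFactors = FALSE)
  list(prots = prots, genes = genes)
}

# score table where every protein matches its namesake strongly
toy_hits <- function(ids_a, ids_b, strong = 500) {
  expand <- expand.grid(query_id = ids_a, subject_id = ids_b,
                        stringsAsFactors = FALSE)
  expand$score <- ifelse(expand$query_id == expand$subject_id, strong,
                         30 + 5 * (match(expand$subject_id, ids_b) %% 3))
  expand$evalue <- 2^(-(0.267 * expand$score - log(0.041)) / log(2)) * 1e4
  expand
}

test_that("protein scoring: self-score dominates; random pairs are null", {
  set.seed(2)
  p <- rand_protein(100)
  set_a <- c(x = p, y = rand_protein(100))
  set_b <- c(x2 = p, z = rand_protein(100))
  sc <- score_proteins(set_a, set_b)
  self <- sc$score[sc$query_id == "x" & sc$subject_id == "x2"]
  expect_equal(self, max(sc$score))

  # unrelated random proteins are almost never significant at E <= 0.001
  set.seed(3)
  n_trials <- 60
  qs <- setNames(vapply(rep(100, n_trials), rand_protein, character(1)),
                 paste0("q", 1:n_trials))
  ss <- setNames(vapply(rep(100, n_trials), rand_protein, character(1)),
                 paste0("s", 1:n_trials))
  sc <- score_proteins(qs, ss)
  sig <- sc$evalue <= 0.001
  expect_gte(mean(!sig), 0.95)
})

test_that("best hits honour the e-value cutoff and tie-breaks", {
  h <- data.frame(query_id = "q", subject_id = "s1", score = 100,
                  evalue = 0.01)
  expect_equal(nrow(best_hits(h)), 0L)

  ties <- data.frame(query_id = "q", subject_id = c("sB", "sA"),
                     score = c(50, 50), evalue = c(1e-10, 1e-10))
  expect_equal(best_hits(ties)$subject_id, "sA")

  set.seed(4)
  big <- data.frame(
    query_id = rep(paste0("q", 1:30), each = 8),
    subject_id = sample(paste0("s", 1:12), 240, replace = TRUE),
    score = sample(20:200, 240, replace = TRUE),
    evalue = 10^-sample(4:30, 240, replace = TRUE))
  got <- best_hits(big)
  for (q in unique(big$query_id)) {
    sub <- big[big$query_id == q & big$evalue <= 0.001, ]
    if (nrow(sub) == 0) {
      expect_false(q %in% got$query_id)
    } else {
      best <- sub[order(-sub$score, sub$evalue, sub$subject_id), ][1, ]
      expect_equal(got$subject_id[got$query_id == q], best$subject_id)
    }
  }
})

test_that("RBH pairing equals brute-force reciprocal intersection", {
  cs <- make_colinear_sets(15)
  hits_ab <- toy_hits(names(cs$prots), names(cs$prots))
  rbhs <- compute_rbhs(best_hits(hits_ab), best_hits(hits_ab),
                       cs$genes, cs$genes)
  expect_equal(nrow(rbhs), 15L)
  expect_equal(rbhs$rank_a, rbhs$rank_b)
  expect_equal(sort(rbhs$rank_a), 0:14)

  # a's best is b, but b's best is c (another A gene): no pair for a
  ab <- data.frame(query_id = "a", subject_id = "b",
                   score = 100, evalue = 1e-20)
  ba <- data.frame(query_id = "b", subject_id = "c",
                   score = 100, evalue = 1e-20)
  genes <- data.frame(id = c("a", "b", "c"), seq_id = "s",
                      start = c(0, 100, 200), end = c(50, 150, 250))
  expect_equal(nrow(compute_rbhs(ab, ba, genes, genes)), 0L)

  # random best-hit maps vs brute force
  set.seed(5)
  for (rep in 1:10) {
    ids_a <- paste0("A", 1:12); ids_b <- paste0("B", 1:12)
    best_ab <- data.frame(query_id = ids_a,
                          subject_id = sample(ids_b, 12, replace = TRUE),
                          score = 100, evalue = 1e-10)
    best_ba <- data.frame(query_id = ids_b,
                          subject_id = sample(ids_a, 12, replace = TRUE),
                          score = 100, evalue = 1e-10)
    ga <- data.frame(id = ids_a, seq_id = "c", start = 1:12 * 10,
                     end = 1:12 * 10 + 5)
    gb <- data.frame(id = ids_b, seq_id = "c", start = 1:12 * 10,
                     end = 1:12 * 10 + 5)
    got <- compute_rbhs(best_ab, best_ba, ga, gb)
    want <- 0L
    for (i in 1:12) {
      b <- best_ab$subject_id[i]
      if (best_ba$subject_id[best_ba$query_id == b] == ids_a[i]) {
        want <- want + 1L
      }
    }
    expect_equal(nrow(got), want)
    # symmetry: swapping roles gives the same pair set
    swapped <- compute_rbhs(best_ba, best_ab, gb, ga)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(swapped$gene_b, swapped$gene_a))
  }
})

test_that("dot plot table conserves pairs and round trips through TSV", {
  cs <- make_colinear_sets(10)
  hits <- toy_hits(names(cs$prots), names(cs$prots))
  rbhs <- compute_rbhs(best_hits(hits), best_hits(hits), cs$genes, cs$genes)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  dp <- dot_plot_data(rbhs, tmp)
  expect_equal(nrow(dp), nrow(rbhs))
  expect_true(all(dp$rank_a == dp$rank_b))
  back <- utils::read.delim(tmp)
  expect_equal(back$rank_a, dp$rank_a)
  expect_equal(back$rank_b, dp$rank_b)
})

test_that("outlier detection: colinear clean, injected relocations found", {
  n <- 200
  rbhs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                     score_ab = 500, score_ba = 500,
                     rank_a = 0:(n - 1), rank_b = 0:(n - 1))
  expect_equal(nrow(detect_outliers(rbhs)), 0L)

  # every single-gene relocation beyond the threshold is detected
  set.seed(6)
  for (rep in 1:25) {
    r <- rbhs
    i <- sample(30:170, 1)
    shift <- sample(c(-1, 1), 1) * sample(25:150, 1)
    r$rank_b[i] <- r$rank_b[i] + shift
    out <- detect_outliers(r)
    expect_true(r$gene_a[i] %in% out$gene_a)
    expect_equal(nrow(out), 1L)
  }
})

test_that("outlier typing separates ambiguous (random) from real", {
  cs <- make_colinear_sets(30)
  ids <- names(cs$prots)
  hits <- toy_hits(ids, ids)
  cand <- data.frame(gene_a = "g5", gene_b = "g5", rank_a = 4, rank_b = 40)
  got <- classify_outlier(cand, hits, hits)
  expect_equal(got$kind, "real")

  # give g5 a second near-best subject
  dup <- data.frame(query_id = "g5", subject_id = "g9dup", score = 495,
                    evalue = 1e-30)
  got2 <- classify_outlier(cand, rbind(hits, dup), hits)
  expect_equal(got2$kind, "random")
})

test_that("split hints localise chimeric junctions to one gene", {
  # colinear scaffold: no hints
  clean <- data.frame(scaffold = "scf1", pos = (1:10) * 1000,
                      counterpart_seq = "chr1", rank = 1:10)
  expect_equal(nrow(scaffold_split_hints(clean)), 0L)

  # chimeric scaffold: first half chr1, second half chr3
  chim <- data.frame(scaffold = "scf2", pos = (1:10) * 1000,
                     counterpart_seq = rep(c("chr1", "chr3"), each = 5),
                     rank = c(1:5, 500:504))
  hints <- scaffold_split_hints(chim)
  expect_equal(nrow(hints), 1L)
  expect_equal(hints$break_start, 5000)
  expect_equal(hints$break_end, 6000)

  # random chimeras: hint within one gene of the truth junction
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(8:20, 1)
    cut <- sample(3:(n - 3), 1)
    df <- data.frame(scaffold = "s", pos = (1:n) * 500,
                     counterpart_seq = c(rep("chrA", cut),
                                         rep("chrB", n - cut)),
                     rank = c(seq_len(cut), 1000 + seq_len(n - cut)))
    h <- scaffold_split_hints(df)
    expect_equal(nrow(h), 1L)
    expect_equal(h$left_index, cut)
  }

  # a lone stray gene does not produce a hint (no consistent run after it)
  stray <- data.frame(scaffold = "s", pos = (1:9) * 500,
                      counterpart_seq = c(rep("chr1", 4), "chr9",
                                          rep("chr1", 4)),
                      rank = c(1:4, 900, 6:9))
  expect_equal(nrow(scaffold_split_hints(stray)), 0L)
})

test_that("scaffold anchoring recovers order and orientation of a shredded reference", {
  set.seed(8)
  # a reference of 2 chromosomes with evenly spaced genes, shredded into 50
  # fragments; evidence = gene positions
  n_frag <- 50
  frag_len <- 20000L
  genes_per_frag <- sample(0:6, n_frag, replace = TRUE)
  chr_of <- rep(c("chr1", "chr2"), each = 25)
  offset <- c(seq(0, by = frag_len, length.out = 25),
              seq(0, by = frag_len, length.out = 25))
  flip <- sample(c(TRUE, FALSE), n_frag, replace = TRUE)
  ev <- list()
  for (i in seq_len(n_frag)) {
    if (genes_per_frag[i] == 0) next
    gpos <- sort(sample(500:(frag_len - 500), genes_per_frag[i]))
    spos <- if (flip[i]) frag_len - gpos else gpos
    ev[[i]] <- data.frame(scaffold = sprintf("f%02d", i),
                          scaffold_pos = spos, chr = chr_of[i],
                          chr_pos = offset[i] + gpos, weight = 1000)
  }
  evidence <- do.call(rbind, ev)
  lens <- setNames(rep(frag_len, n_frag), sprintf("f%02d", 1:n_frag))
  res <- anchor_scaffolds(evidence, lens)
  a <- res$assignments
  informative <- sprintf("f%02d", which(genes_per_frag >= 3))
  sub <- a[a$scaffold %in% informative, ]
  truth_chr <- chr_of[match(sub$scaffold, sprintf("f%02d", 1:n_frag))]
  truth_strand <- ifelse(flip[match(sub$scaffold,
                                    sprintf("f%02d", 1:n_frag))], "-", "+")
  ok <- sub$chr == truth_chr & sub$strand == truth_strand
  expect_gte(mean(ok), 0.95)
  # order along each chromosome follows the reference offsets
  for (ch in c("chr1", "chr2")) {
    s <- sub[sub$chr == ch, ]
    idx <- match(s$scaffold, sprintf("f%02d", 1:n_frag))
    expect_equal(order(s$order_pos), order(offset[idx]))
  }

  # AGP round trip reproduces the placements exactly
  tmp <- withr::local_tempfile(fileext = ".agp")
  res2 <- anchor_scaffolds(evidence, lens, agp_path = tmp)
  back <- read_agp(tmp)
  expect_equal(back[, c("object", "component_id", "start", "end", "strand")],
               res2$placements[, c("object", "component_id", "start", "end",
                                   "strand")], ignore_attr = TRUE)

  # conflicting evidence below 60% majority stays unplaced
  conflict <- data.frame(scaffold = "fx", scaffold_pos = c(100, 200),
                         chr = c("chr1", "chr2"), chr_pos = c(1, 2),
                         weight = c(500, 500))
  rx <- anchor_scaffolds(conflict, c(fx = 1000L))
  expect_true(is.na(rx$assignments$chr))
  expect_match(rx$assignments$reason, "60%")
})

test_that("genic coverage flags only >= 2x non-RBH genes", {
  genes <- data.frame(id = paste0("g", 1:5), seq_id = "s",
                      start = c(0, 200, 400, 600, 800),
                      end = c(100, 300, 500, 700, 900))
  depth <- rep(100L, 1000)
  gc <- genic_coverage(list(s = depth), genes, paste0("g", 1:4))
  expect_equal(gc$mean_depth, rep(100, 5))
  expect_false(any(gc$collapsed_candidate))

  depth[801:900] <- 250L
  gc2 <- genic_coverage(list(s = depth), genes, paste0("g", 1:4))
  expect_equal(attr(gc2, "reference_level"), 100)
  expect_true(gc2$collapsed_candidate[5])

  expect_error(genic_coverage(list(s = depth),
                              within(genes, end[1] <- start[1]),
                              "g2"), "zero-length")
})

test_that("a collapsed duplicate is flagged from simulated coverage", {
  # two identical copies in the read source, one in the target: the target
  # copy collects both copies' reads (about 2x depth)
  set.seed(9)
  gene <- rand_dna(1500)
  target <- setNames(paste0(rand_dna(8000), gene, rand_dna(8000)), "t")
  source_g <- setNames(paste0(rand_dna(4000), gene, rand_dna(6000), gene,
                              rand_dna(4000)), "src")
  sim <- simulate_reads(source_g,
                        read_sim_config(read_length = 100, coverage = 30,
                                        insert_mean = 350, insert_sd = 30,
                                        seed = 10))
  pl <- map_reads(sim$reads, target)
  trk <- compute_coverage(pl, target)
  genes <- data.frame(id = c("bg1", "dup", "bg2"), seq_id = "t",
                      start = c(2000L, 8000L, 14000L),
                      end = c(3500L, 9500L, 15500L))
  gc <- genic_coverage(trk, genes, c("bg1", "bg2"))
  expect_true(gc$collapsed_candidate[2])
  expect_gt(gc$mean_depth[2], 1.7 * attr(gc, "reference_level"))
})

test_that("TE and organelle genes are excluded before RBH pairing", {
  prots <- c(g1 = "MKV", te1 = "MLL", g2 = "MAA", chl1 = "MCC")
  feats <- data.frame(
    seq_id = c("chr1", "chr1", "chr2", "plastome"),
    start = c(0L, 100L, 0L, 0L), end = c(50L, 150L, 50L, 50L),
    strand = "+",
    type = c("gene", "transposable_element", "gene", "gene"),
    id = c("g1", "te1", "g2", "chl1"))
  kept <- filter_rbh_input(prots, feats, organelle_seqs = "plastome")
  expect_setequal(names(kept), c("g1", "g2"))
})
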