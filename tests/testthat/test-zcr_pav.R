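test_that("ZCR detection matches a brute-force zero-run scan", {
  set.seed(1)
  for (rep in 1:20) {
    len <- sample(200:1000, 1)
    depth <- sample(0:3, len, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    g <- setNames(rand_dna(len), "s")
    params <- zcr_params(min_zcr_len = sample(1:8, 1))
    got <- detect_zcrs(list(s = depth), g, params)
    want <- brute_zero_runs(depth, params$min_zcr_len)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("the 5 bp lower cutoff and the ambiguity filter are enforced", {
  g <- setNames(paste0(strrep("A", 100)), "s")
  d4 <- rep(1L, 100); d4[11:14] <- 0L
  expect_equal(nrow(detect_zcrs(list(s = d4), g)), 0L)
  d5 <- rep(1L, 100); d5[11:15] <- 0L
  z <- detect_zcrs(list(s = d5), g)
  expect_equal(z$length, 5L)
  expect_false(z$at_edge)

  # >10% ambiguity inside the run discards it
  gn <- setNames(paste0(strrep("A", 10), strrep("N", 2), strrep("A", 88)), "s")
  dz <- rep(1L, 100); dz[6:20] <- 0L   # 15 bp run containing 2 Ns (13.3%)
  expect_equal(nrow(detect_zcrs(list(s = dz), gn)), 0L)
  dz2 <- rep(1L, 100); dz2[6:30] <- 0L # 25 bp run, 2 Ns (8%) kept
  expect_equal(nrow(detect_zcrs(list(s = dz2), gn)), 1L)

  expect_error(detect_zcrs(list(s = rep(1L, 50)), g), "length")

  d_all <- rep(2L, 100)
  expect_equal(nrow(detect_zcrs(list(s = d_all), g)), 0L)
})

test_that("ZCRs are maximal: never adjacent to another zero base", {
  set.seed(2)
  depth <- sample(0:1, 3000, replace = TRUE)
  g <- setNames(rand_dna(3000), "s")
  z <- detect_zcrs(list(s = depth), g, zcr_params(min_zcr_len = 1))
  for (i in seq_len(nrow(z))) {
    if (z$start[i] > 0) expect_gt(depth[z$start[i]], 0)
    if (z$end[i] < 3000) expect_gt(depth[z$end[i] + 1], 0)
    expect_true(all(depth[(z$start[i] + 1):z$end[i]] == 0))
  }
})

test_that("flank extraction clips at boundaries and returns true substrings", {
  g <- setNames(rand_dna(8000), "s")
  zcr <- data.frame(seq_id = "s", start = 5000L, end = 5500L, length = 500L,
                    at_edge = FALSE)
  fl <- extract_flanks(zcr, g)
  expect_identical(fl$left, unname(substr(g, 4001, 5000)))
  expect_identical(fl$right, unname(substr(g, 5501, 6500)))
  expect_false(fl$left_clipped || fl$right_clipped)
  expect_true(grepl(fl$left, g[[1]], fixed = TRUE))

  near <- data.frame(seq_id = "s", start = 300L, end = 600L, length = 300L,
                     at_edge = FALSE)
  fn <- extract_flanks(near, g)
  expect_identical(fn$left, unname(substr(g, 1, 300)))
  expect_true(fn$left_clipped)
  expect_false(fn$right_clipped)
})

test_that("flank anchoring equals the exhaustive Smith-Waterman oracle", {
  set.seed(3)
  for (rep in 1:6) {
    subject <- setNames(rand_dna(5000), "ctg")
    # flank = a diverged copy of a subject region
    s0 <- sample(1000:3000, 1)
    q <- substr(subject, s0, s0 + 499)
    ch <- strsplit(q, "")[[1]]
    mut <- sample(500, 15)
    for (p in mut) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    q <- paste(ch, collapse = "")
    if (rep %% 2 == 0) q <- revcomp(q)
    hit <- align_best(q, subject)
    oracle <- oracle_local_hit(q, subject[[1]])
    expect_equal(hit$score, oracle$score)
    expect_equal(hit$strand, oracle$strand)
    expect_equal(hit$s_start, oracle$s_start)
  }

  expect_null(align_best(strrep("N", 500), setNames(rand_dna(2000), "c")))

  # identical flank: perfect-identity hit at the exact region
  subject <- setNames(rand_dna(4000), "ctg")
  q <- substr(subject, 2001, 2400)
  hit <- align_best(q, subject)
  expect_equal(hit$identity, 1)
  expect_equal(hit$s_start, 2000L)
  expect_equal(hit$s_end, 2400L)
})

test_that("classification follows the adjacency and tolerance rules", {
  zcr <- data.frame(seq_id = "t", start = 10000L, end = 10500L,
                    length = 500L, at_edge = FALSE)
  mk <- function(s_start, s_end, strand = "+", subject = "c1") {
    data.frame(subject_id = subject, s_start = s_start, s_end = s_end,
               strand = strand, score = 900, identity = 0.99, q_cov = 1)
  }
  # exact adjacency: pav
  call <- classify_zcr(zcr, mk(4000, 5000), mk(5000, 6000))
  expect_equal(call$classification, "pav")
  expect_equal(call$inner_end_distance, 0)

  # inner distance 500 on a 500 bp ZCR: > 100 bp tolerance, hdr
  call <- classify_zcr(zcr, mk(4000, 5000), mk(5500, 6500))
  expect_equal(call$classification, "hdr")

  # relative tolerance above 1 kbp: distance 450 on a 5 kbp ZCR is within 10%
  big <- within(zcr, { end <- start + 5000L; length <- 5000L })
  call <- classify_zcr(big, mk(4000, 5000), mk(5450, 6450))
  expect_equal(call$classification, "pav")
  call <- classify_zcr(big, mk(4000, 5000), mk(5600, 6600))
  expect_equal(call$classification, "hdr")

  # different subjects, opposite strands, wrong order: hdr
  expect_equal(classify_zcr(zcr, mk(4000, 5000),
                            mk(5000, 6000, subject = "c2"))$classification,
               "hdr")
  expect_equal(classify_zcr(zcr, mk(4000, 5000),
                            mk(5000, 6000, strand = "-"))$classification,
               "hdr")
  expect_equal(classify_zcr(zcr, mk(5000, 6000), mk(4000, 5000))$classification,
               "hdr")

  # minus-strand adjacency in reversed order: pav
  call <- classify_zcr(zcr, mk(5000, 6000, strand = "-"),
                       mk(4000, 5000, strand = "-"))
  expect_equal(call$classification, "pav")

  # missing hits: hdr; edge: unresolved
  expect_equal(classify_zcr(zcr, NULL, mk(5000, 6000))$classification, "hdr")
  edge <- within(zcr, at_edge <- TRUE)
  expect_equal(classify_zcr(edge, mk(4000, 5000),
                            mk(5000, 6000))$classification, "unresolved")
})

test_that("mate-distance validation distinguishes deviating spanning pairs", {
  call <- data.frame(seq_id = "t", start = 5000L, end = 5500L, length = 500L,
                     at_edge = FALSE, classification = "pav")
  gs <- list(mean = 200, sd = 30, n = 1000)
  none <- data.frame(pair_id = character(), seq_id = character(),
                     inner_distance = numeric(), left_end = numeric(),
                     right_start = numeric())
  v <- validate_by_pair_distance(call, none, gs)
  expect_equal(v$pair_distance_supported, "indeterminate")

  near <- data.frame(pair_id = paste0("p", 1:5), seq_id = "t",
                     inner_distance = c(195, 205, 200, 210, 190),
                     left_end = 4950, right_start = 5520)
  v <- validate_by_pair_distance(call, near, gs)
  expect_equal(v$pair_distance_supported, "unsupported")

  far <- within(near, inner_distance <- inner_distance + 500)
  v <- validate_by_pair_distance(call, far, gs)
  expect_equal(v$pair_distance_supported, "supported")
})

test_that("an implanted deletion is recovered end to end with mate support", {
  # one 6.8 kbp deletion in the derived accession, mirroring a known
  # flowering-locus deletion scale
  anc <- generate_ancestor(80000, seed = 61)
  reg <- data.frame(type = "deletion", start_a = 40000L, end_a = 46800L,
                    alt = "", stringsAsFactors = FALSE)
  der <- apply_registry(anc, reg)
  asm_a <- setNames(anc[1], "accA")
  sim <- simulate_reads(setNames(der$genome[1], "accB"),
                        read_sim_config(read_length = 250, coverage = 25,
                                        insert_mean = 700, insert_sd = 50,
                                        seed = 62))
  res <- run_direction(sim$reads, asm_a, setNames(der$genome[1], "accB"))
  pav <- res$calls[res$calls$classification == "pav", ]
  expect_equal(nrow(pav), 1L)
  expect_lt(abs(pav$start - 40000), 700)
  expect_lt(abs(pav$length - 6800), 0.1 * 6800)
  expect_equal(pav$pair_distance_supported, "supported")
})

test_that("identical accessions give zero reportable calls (null control)", {
  g <- generate_ancestor(60000, seed = 71)
  asm <- setNames(g[1], "acc")
  sim <- simulate_reads(asm, read_sim_config(read_length = 250,
                                             coverage = 20,
                                             insert_mean = 700,
                                             insert_sd = 50, seed = 72))
  res <- run_direction(sim$reads, asm, asm)
  expect_equal(sum(res$calls$classification %in% c("pav", "hdr")), 0L)
})

test_that("every reported ZCR gets exactly one classification", {
  pair <- make_test_pair(seed = 81)
  sim <- simulate_reads(pair$asm_b,
                        read_sim_config(read_length = 200, coverage = 20,
                                        insert_mean = 600, insert_sd = 50,
                                        seed = 82))
  res <- run_direction(sim$reads, pair$asm_a, pair$asm_b)
  expect_true(all(res$calls$classification %in%
                    c("pav", "hdr", "unresolved")))
  expect_equal(nrow(res$calls),
               sum(res$zcrs$length >= zcr_params()$report_min_len))
})

test_that("coverage titration is nested and saturates at full coverage", {
  pair <- make_test_pair(seed = 91, len = 40000, n_del = 1, n_ins = 1)
  sim <- simulate_reads(pair$asm_b,
                        read_sim_config(read_length = 150, coverage = 25,
                                        insert_mean = 500, insert_sd = 40,
                                        seed = 92))
  tit <- coverage_titration(sim$reads, pair$asm_a, pair$asm_b,
                            fractions = c(0.02, 0.5, 1.0), seed = 93)
  expect_equal(tit$fraction, c(0.02, 0.5, 1.0))
  # at ~0.5x expected depth most of the genome is uncovered
  expect_gt(tit$zcr_bp[1], 0.5 * 40000)
  # full fraction reproduces the direct run exactly
  full <- run_direction(sim$reads, pair$asm_a, pair$asm_b)
  expect_equal(tit$n_zcr[3], nrow(full$zcrs))
  expect_equal(tit$n_pav[3], sum(full$calls$classification == "pav"))
  # spurious coverage-gap length shrinks with coverage
  expect_true(all(diff(tit$zcr_bp) <= 0))
})

test_that("size-bin summary reproduces brute-force binning", {
  expect_error(summarize_bins(c(99, 200)), "below 100")

  empty <- summarize_bins(integer(0))
  expect_true(all(empty$count == 0))
  expect_true(all(empty$bp == 0))

  set.seed(4)
  lens <- sample(100:40000, 1000, replace = TRUE)
  got <- summarize_bins(lens)
  edges <- c(100, 200, 400, 800, 1600, 3200, 6400, 12800, 25600, Inf)
  for (b in seq_len(9)) {
    lo <- ifelse(b == 1, 100, edges[b] + 1)
    hi <- edges[b + 1]
    sel <- lens >= lo & lens <= hi
    expect_equal(got$count[b], sum(sel))
    expect_equal(got$bp[b], sum(lens[sel]))
  }
  expect_equal(got$count[10], 1000L)
  expect_equal(got$bp[10], sum(lens))
})

test_that("flank anchoring accepts an external hit table", {
  hits <- data.frame(
    query_id = c("left", "left", "right"),
    subject_id = c("scf2", "scf1", "scf1"),
    s_start = c(9000L, 4000L, 5020L), s_end = c(9900L, 5000L, 6020L),
    strand = "+", score = c(400, 950, 940), identity = 0.98, q_cov = 1)
  anch <- anchor_flanks(NULL, hits)
  expect_equal(anch$left$subject_id, "scf1")   # highest score wins
  expect_equal(anch$right$s_start, 5020L)
  zcr <- data.frame(seq_id = "t", start = 2000L, end = 2500L,
                    length = 500L, at_edge = FALSE)
  call <- classify_zcr(zcr, anch$left, anch$right)
  expect_equal(call$classification, "pav")   # inner distance 20 <= 100
  expect_null(anchor_flanks(NULL, hits[0, ])$left)
})
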