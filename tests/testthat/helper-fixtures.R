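# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately naive (per-base loops, full scans) so they cannot share a bug
# with the vectorised/seeded implementation paths they check.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# brute force: maximal zero runs of a depth vector
brute_zero_runs <- function(depth, min_len) {
  runs <- list()
  i <- 1
  n <- length(depth)
  while (i <= n) {
    if (depth[i] == 0) {
      j <- i
      while (j < n && depth[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_len) {
        runs[[length(runs) + 1]] <- c(start = i - 1, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, runs))
}

# brute force: per-base coverage by counting every placement at every base
brute_coverage <- function(starts, ends, len) {
  depth <- integer(len)
  for (i in seq_along(starts)) {
    for (p in seq(starts[i] + 1, ends[i])) depth[p] <- depth[p] + 1L
  }
  depth
}

# brute force: k-mer canonical counting via R hashing
brute_kmer_hist <- function(reads, k) {
  all <- character(0)
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- pavscape::revcomp(km)
      all <- c(all, if (km <= rc) km else rc)
    }
  }
  tab <- table(table(all))
  data.frame(multiplicity = as.integer(names(tab)),
             count = as.integer(tab))
}

# reference genome-scale local aligner used as the Smith-Waterman oracle:
# a single full-sequence pairwiseAlignment, no seeding
oracle_local_hit <- function(query, subject_str) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  best <- NULL
  for (st in c("+", "-")) {
    q <- if (st == "+") query else pavscape::revcomp(query)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject_str),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      subj <- Biostrings::subject(aln)
      best <- list(score = sc, strand = st,
                   s_start = Biostrings::start(subj) - 1L,
                   s_end = Biostrings::end(subj))
    }
  }
  best
}

# a tiny deterministic accession pair used by several classification tests
make_test_pair <- function(seed = 101, len = 60000, n_del = 2, n_ins = 2,
                           snp_rate = 1 / 500) {
  anc <- generate_ancestor(len, gc = 0.4, seed = seed)
  cfg <- divergence_config(snp_rate = snp_rate, small_indel_rate = 0,
                           n_insertions = n_ins, n_deletions = n_del,
                           event_len_range = c(300, 2000), seed = seed + 1)
  der <- derive_accession(anc, cfg)
  asm_a <- stats::setNames(anc[1], "accA")
  attr(asm_a, "repeats") <- NULL
  list(asm_a = asm_a, asm_b = stats::setNames(der$genome[1], "accB"),
       registry = der$registry)
}
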