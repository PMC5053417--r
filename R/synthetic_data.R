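# Synthetic accession pairs with a ground-truth variant registry. The
# generator emulates the divergence structure the detection pipeline assumes:
# background SNPs and small InDels, large (>= 100 bp) insertions/deletions,
# locally hyper-diverged (HDR) blocks, tandem repeat arrays and an optional
# collapsed-duplicate (CNV) locus.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param seqs character vector (IUPAC codes allowed).
#' @return character vector.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Divergence configuration for a synthetic accession pair
#'
#' Defaults follow the divergence observed between two typical *A. thaliana*
#' accessions: one SNP per 292 bp, one small InDel (1-20 bp) per ~1.5 kbp,
#' large events with log-uniform lengths spanning the doubling size bins
#' 100 bp-25.6 kbp, and HDR blocks modelled as contiguous segments with a
#' 10x elevated SNP/InDel density.
#'
#' @param snp_rate substitutions per bp.
#' @param small_indel_rate small InDels per bp (lengths 1-`small_indel_max`).
#' @param small_indel_max largest small-InDel length, bp.
#' @param n_insertions,n_deletions counts of large events (novel-sequence
#'   insertions in the derived accession / deletions of ancestral sequence).
#' @param event_len_range large-event length range, sampled log-uniformly.
#' @param n_hdr_blocks number of hyper-diverged blocks.
#' @param hdr_len_range HDR block length range, sampled log-uniformly.
#' @param hdr_multiplier SNP/InDel density multiplier inside HDR blocks.
#' @param collapsed_duplicate NULL or list(gene_length =) — writes two
#'   identical copies of a gene-sized segment into the derived accession and
#'   leaves one in the ancestor (a collapsed-duplicate CNV locus).
#' @param min_separation minimum gap between large-event footprints, bp.
#' @param seed integer; fixes the whole genome pair.
#' @return list of class "divergence_config".
#' @export
divergence_config <- function(snp_rate = 1 / 292,
                              small_indel_rate = 1 / 1500,
                              small_indel_max = 20L,
                              n_insertions = 20L, n_deletions = 20L,
                              event_len_range = c(100, 25600),
                              n_hdr_blocks = 0L,
                              hdr_len_range = c(100, 10000),
                              hdr_multiplier = 10,
                              collapsed_duplicate = NULL,
                              min_separation = 2000L,
                              seed = 1L) {
  stopifnot(snp_rate >= 0, snp_rate < 1, small_indel_rate >= 0,
            small_indel_rate < 1, n_insertions >= 0, n_deletions >= 0,
            n_hdr_blocks >= 0, hdr_multiplier >= 1, min_separation >= 0)
  structure(as.list(environment()), class = "divergence_config")
}

#' Generate a random ancestor genome with embedded tandem repeat arrays
#'
#' @param length genome length in bp (>= 10 kbp recommended).
#' @param gc target GC fraction of the i.i.d. background.
#' @param repeat_specs list of lists with fields `unit_len` and `copies`
#'   (e.g. a 180 bp centromere-like unit or a 10 kbp rDNA-like unit); each
#'   array is embedded at a recorded position.
#' @param seed integer.
#' @return single-element named character vector; attribute "repeats" is a
#'   data.frame of the embedded array positions (0-based half-open).
#' @export
generate_ancestor <- function(length, gc = 0.36, repeat_specs = list(),
                              seed = 1L) {
  total_rep <- sum(vapply(repeat_specs, function(s) s$unit_len * s$copies, 0))
  if (total_rep > 0.5 * length) {
    stop("repeat arrays exceed half the genome length")
  }
  with_seed(seed, {
    g <- random_dna(length, gc)
    reps <- data.frame(start = integer(), end = integer(),
                       unit_len = integer(), copies = integer())
    occupied <- matrix(numeric(0), ncol = 2)
    for (spec in repeat_specs) {
      arr_len <- spec$unit_len * spec$copies
      unit <- random_dna(spec$unit_len, gc)
      for (try in 1:1000) {
        s <- sample.int(length - arr_len - 2000L, 1) + 1000L
        ok <- nrow(reps) == 0 ||
          all(s + arr_len + 1000 < reps$start | s - 1000 > reps$end)
        if (ok) break
        if (try == 1000) stop("could not place repeat array")
      }
      g <- paste0(substr(g, 1, s), strrep(unit, spec$copies),
                  substr(g, s + arr_len + 1, length))
      reps <- rbind(reps, data.frame(start = s, end = s + arr_len,
                                     unit_len = spec$unit_len,
                                     copies = spec$copies))
    }
    g <- substr(g, 1, length)
    out <- c(ancestor = g)
    attr(out, "repeats") <- reps
    out
  })
}

mutate_dna <- function(seq, snp_rate, indel_rate, indel_max, gc = 0.36) {
  # SNPs + small indels applied i.i.d.; used for HDR block interiors.
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  snp_pos <- which(stats::runif(n) < snp_rate)
  for (p in snp_pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  indel_pos <- which(stats::runif(n) < indel_rate)
  if (length(indel_pos) > 0) {
    lens <- sample.int(indel_max, length(indel_pos), replace = TRUE)
    ins <- stats::runif(length(indel_pos)) < 0.5
    out <- character(0)
    prev <- 1L
    drop_to <- 0L
    for (i in seq_along(indel_pos)) {
      p <- indel_pos[i]
      if (p <= drop_to) next
      out <- c(out, paste(chars[prev:p], collapse = ""))
      if (ins[i]) {
        out <- c(out, random_dna(lens[i], gc))
        prev <- p + 1L
      } else {
        drop_to <- min(n, p + lens[i])
        prev <- drop_to + 1L
      }
    }
    if (prev <= n) out <- c(out, paste(chars[prev:n], collapse = ""))
    paste(out, collapse = "")
  } else {
    paste(chars, collapse = "")
  }
}

#' Derive a diverged accession from an ancestor, with a truth registry
#'
#' Large events (deletions of ancestral sequence, novel-sequence insertions,
#' HDR blocks, an optional collapsed duplicate) are placed non-overlapping,
#' separated by at least `min_separation` bp, and away from tandem repeat
#' arrays and sequence ends. Background SNPs and small InDels are sprinkled
#' outside the large-event footprints. The registry is a list of replacement
#' operations on the ancestor; replaying it reproduces the derived genome
#' exactly.
#'
#' @param ancestor output of [generate_ancestor()] (or any single named
#'   sequence).
#' @param config a [divergence_config()].
#' @return list with elements `genome` (named character vector, id
#'   "derived") and `registry` (data.frame: type, start_a, end_a, start_b,
#'   end_b, length, alt).
#' @export
derive_accession <- function(ancestor, config) {
  stopifnot(inherits(config, "divergence_config"))
  A <- unname(ancestor[[1]])
  L <- nchar(A)
  reps <- attr(ancestor, "repeats")
  if (is.null(reps)) reps <- data.frame(start = integer(), end = integer())
  with_seed(config$seed, {
    loglen <- function(n, range) {
      round(exp(stats::runif(n, log(range[1]), log(range[2]))))
    }
    ev <- data.frame(type = character(), len_a = integer(), len_b = integer(),
                     stringsAsFactors = FALSE)
    add <- function(ev, type, n, la, lb) {
      if (n > 0) rbind(ev, data.frame(type = type, len_a = la, len_b = lb)) else ev
    }
    del_len <- loglen(config$n_deletions, config$event_len_range)
    ins_len <- loglen(config$n_insertions, config$event_len_range)
    hdr_len <- loglen(config$n_hdr_blocks, config$hdr_len_range)
    ev <- add(ev, "deletion", config$n_deletions, del_len, 0L)
    ev <- add(ev, "insertion", config$n_insertions, 0L, ins_len)
    ev <- add(ev, "hdr", config$n_hdr_blocks, hdr_len, hdr_len)
    if (!is.null(config$collapsed_duplicate)) {
      gl <- config$collapsed_duplicate$gene_length
      ev <- add(ev, "cnv_collapse", 1L, gl, 2L * gl)
    }
    if (sum(ev$len_a) > 0.2 * L) {
      stop("large events would cover more than 20% of the ancestor")
    }
    # place footprints (on A) non-overlapping with separation, away from
    # repeat arrays and from the sequence ends (1.5 kbp margin keeps flanks
    # classifiable)
    margin <- 1500L
    sep <- config$min_separation
    placed <- data.frame(start = reps$start - sep, end = reps$end + sep)
    starts <- integer(nrow(ev))
    if (nrow(ev) > 0) {
      for (i in order(ev$len_a, decreasing = TRUE)) {
        la <- ev$len_a[i]
        ok <- FALSE
        for (try in 1:2000) {
          s <- sample.int(L - la - 2L * margin, 1) + margin
          if (nrow(placed) == 0 ||
              all(s + la + sep <= placed$start | s - sep >= placed$end)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place non-overlapping events after retries")
        starts[i] <- s
        placed <- rbind(placed, data.frame(start = s, end = s + la))
      }
    }
    reg <- data.frame(type = ev$type, start_a = starts,
                      end_a = starts + ev$len_a,
                      alt = rep(NA_character_, nrow(ev)),
                      stringsAsFactors = FALSE)
    if (nrow(reg) > 0) {
      for (i in seq_len(nrow(reg))) {
        seg <- substr(A, reg$start_a[i] + 1L, reg$end_a[i])
        reg$alt[i] <- switch(reg$type[i],
          deletion = "",
          insertion = random_dna(ev$len_b[i]),
          hdr = mutate_dna(seg, config$hdr_multiplier * config$snp_rate,
                           config$hdr_multiplier * config$small_indel_rate,
                           config$small_indel_max),
          cnv_collapse = paste0(seg, seg))
      }
    }
    # Background SNPs sit anywhere outside large-event footprints (they are
    # the realistic flank divergence the anchoring must tolerate). Small
    # InDels are additionally kept one read span away from large events: a
    # >= 14 bp InDel within a read length of an event junction merges its
    # own mapping dead zone with the event's ZCR and corrupts the flank
    # adjacency distance — the events are meant to be isolated test cases.
    free_snp <- rep(TRUE, L)
    free_ind <- rep(TRUE, L)
    ind_buffer <- 300L
    if (nrow(reg) > 0) {
      for (i in seq_len(nrow(reg))) {
        lo <- max(1L, reg$start_a[i] - 25L)
        hi <- min(L, reg$end_a[i] + 25L)
        free_snp[lo:hi] <- FALSE
        lo2 <- max(1L, reg$start_a[i] - ind_buffer)
        hi2 <- min(L, reg$end_a[i] + ind_buffer)
        free_ind[lo2:hi2] <- FALSE
      }
    }
    free_pos <- which(free_snp)
    achars <- strsplit(A, "")[[1]]
    n_snp <- stats::rbinom(1, length(free_pos), config$snp_rate)
    snp_pos <- sort(sample(free_pos, n_snp))
    snp_alt <- vapply(snp_pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), achars[p]), 1)
    }, character(1))
    free_ind_pos <- which(free_ind)
    n_ind <- stats::rbinom(1, length(free_ind_pos), config$small_indel_rate)
    ind_pos <- sort(sample(free_ind_pos, n_ind))
    # keep small indels clear of each other, of SNPs, and of footprints
    keep <- rep(TRUE, length(ind_pos))
    if (length(ind_pos) > 1) keep[-1] <- diff(ind_pos) > 50
    ind_pos <- ind_pos[keep]
    ind_len <- sample.int(config$small_indel_max, length(ind_pos),
                          replace = TRUE)
    ind_ins <- stats::runif(length(ind_pos)) < 0.5
    small <- data.frame(type = character(), start_a = integer(),
                        end_a = integer(), alt = character(),
                        stringsAsFactors = FALSE)
    if (length(snp_pos) > 0) {
      small <- rbind(small, data.frame(type = "snp", start_a = snp_pos - 1L,
                                       end_a = snp_pos, alt = snp_alt,
                                       stringsAsFactors = FALSE))
    }
    if (length(ind_pos) > 0) {
      ind_alt <- character(length(ind_pos))
      ind_end <- integer(length(ind_pos))
      for (i in seq_along(ind_pos)) {
        if (ind_ins[i]) {
          ind_alt[i] <- random_dna(ind_len[i])
          ind_end[i] <- ind_pos[i] - 1L
        } else {
          ind_alt[i] <- ""
          ind_end[i] <- min(L, ind_pos[i] - 1L + ind_len[i])
        }
      }
      small <- rbind(small, data.frame(type = "small_indel",
                                       start_a = ind_pos - 1L,
                                       end_a = ind_end, alt = ind_alt,
                                       stringsAsFactors = FALSE))
    }
    # drop small variants colliding with each other after interval expansion
    reg <- rbind(reg, small)
    reg <- reg[order(reg$start_a, reg$end_a), , drop = FALSE]
    if (nrow(reg) > 1) {
      keep <- c(TRUE, reg$start_a[-1] >= cummax(reg$end_a[-nrow(reg)]))
      reg <- reg[keep, , drop = FALSE]
    }
    rownames(reg) <- NULL
    res <- apply_registry(stats::setNames(A, "ancestor"), reg)
    list(genome = res$genome, registry = res$registry)
  })
}

#' Replay a truth registry against the ancestor
#'
#' Applies the registry's replacement operations left to right and fills in
#' the derived-genome coordinates (start_b/end_b) of every variant. The
#' derived genome equals [derive_accession()]'s output exactly — this is the
#' recovery-testing oracle.
#'
#' @param ancestor named character vector of length 1.
#' @param registry data.frame with type, start_a, end_a, alt.
#' @return list(genome, registry) with registry gaining start_b, end_b,
#'   length.
#' @export
apply_registry <- function(ancestor, registry) {
  A <- unname(ancestor[[1]])
  reg <- registry[order(registry$start_a, registry$end_a), , drop = FALSE]
  if (nrow(reg) > 1 && any(reg$start_a[-1] < reg$end_a[-nrow(reg)])) {
    stop("registry intervals overlap")
  }
  pieces <- character(0)
  prev <- 0L
  start_b <- end_b <- integer(nrow(reg))
  blen <- 0L
  for (i in seq_len(nrow(reg))) {
    gap <- substr(A, prev + 1L, reg$start_a[i])
    blen <- blen + nchar(gap)
    start_b[i] <- blen
    blen <- blen + nchar(reg$alt[i])
    end_b[i] <- blen
    pieces <- c(pieces, gap, reg$alt[i])
    prev <- reg$end_a[i]
  }
  pieces <- c(pieces, substr(A, prev + 1L, nchar(A)))
  reg$start_b <- start_b
  reg$end_b <- end_b
  reg$length <- pmax(reg$end_a - reg$start_a, reg$end_b - reg$start_b)
  list(genome = c(derived = paste(pieces, collapse = "")), registry = reg)
}

#' Read-simulation configuration
#'
#' `insert_mean` is the outer fragment length (the library insert); the inner
#' mate distance is `insert - 2 * read_length`, truncated at zero. Defaults
#' mirror a 2 x 250 nt paired-end MiSeq library with a 700 bp insert.
#'
#' @param read_length read length, nt.
#' @param coverage fold coverage of the genome.
#' @param layout "paired_end" (inward-facing) or "mate_pair" (outward).
#' @param insert_mean,insert_sd fragment-length distribution, bp.
#' @param error_rate i.i.d. per-base substitution error rate.
#' @param seed integer.
#' @export
read_sim_config <- function(read_length = 250L, coverage = 30,
                            layout = c("paired_end", "mate_pair"),
                            insert_mean = 700, insert_sd = 50,
                            error_rate = 0, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(coverage > 0, insert_mean > 2 * read_length, error_rate >= 0,
            error_rate < 1)
  structure(as.list(environment()), class = "read_sim_config")
}

#' Simulate paired reads from a genome
#'
#' Fragment starts are uniform; fragment lengths are Normal(insert_mean,
#' insert_sd) truncated at 2 x read_length. Paired-end reads face inward
#' (forward/reverse-complement); mate-pair reads face outward. Substitution
#' errors are i.i.d. The truth placement of every read is returned.
#'
#' @param genome named character vector of length 1.
#' @param config a [read_sim_config()].
#' @return list(reads = named character vector (ids end in /1, /2),
#'   truth = data.frame(read_id, start, end, strand, pair_id, mate),
#'   config).
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "read_sim_config"))
  g <- unname(genome[[1]])
  L <- nchar(g)
  rl <- config$read_length
  if (L <= config$insert_mean + 6 * config$insert_sd) {
    stop("genome too short for the configured insert distribution")
  }
  with_seed(config$seed, {
    n_pairs <- round(config$coverage * L / (2 * rl))
    frag <- pmax(2L * rl,
                 round(stats::rnorm(n_pairs, config$insert_mean,
                                    config$insert_sd)))
    frag <- pmin(frag, L)
    start <- floor(stats::runif(n_pairs) * (L - frag + 1))
    left <- substring(g, start + 1L, start + rl)
    right_start <- start + frag - rl
    right <- substring(g, right_start + 1L, right_start + rl)
    if (config$layout == "paired_end") {
      r1 <- left; r2 <- revcomp(right)
      strand1 <- "+"; strand2 <- "-"
    } else {
      r1 <- revcomp(left); r2 <- right
      strand1 <- "-"; strand2 <- "+"
    }
    if (config$error_rate > 0) {
      r1 <- add_seq_errors(r1, config$error_rate)
      r2 <- add_seq_errors(r2, config$error_rate)
    }
    ids <- sprintf("r%06d", seq_len(n_pairs))
    reads <- stats::setNames(c(rbind(r1, r2)),
                             c(rbind(paste0(ids, "/1"), paste0(ids, "/2"))))
    truth <- data.frame(
      read_id = names(reads),
      start = c(rbind(start, right_start)),
      end = c(rbind(start + rl, right_start + rl)),
      strand = c(rbind(rep(strand1, n_pairs), rep(strand2, n_pairs))),
      pair_id = c(rbind(ids, ids)),
      mate = c(rbind(rep(1L, n_pairs), rep(2L, n_pairs))),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, config = config)
  })
}

add_seq_errors <- function(reads, rate) {
  n <- nchar(reads[1])
  mat <- matrix(unlist(strsplit(reads, "")), nrow = n)
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit) > 0) {
    mat[hit] <- vapply(mat[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  apply(mat, 2, paste, collapse = "")
}
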