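# Assembly statistics, k-mer genome-size estimation, read-depth repeat copy
# number, genome-composition reconciliation, and the exon/EST completeness
# filters.

#' Assembly statistics (N-values, GC, lengths)
#'
#' Nxx is the length of the shortest sequence in the smallest set of longest
#' sequences whose summed length reaches xx% of the assembly total. GC is
#' computed over unambiguous bases only.
#'
#' @param sequences named character vector.
#' @return list: n_sequences, total_bp, mean/min/max length, gc, N25, N50,
#'   N75, N90.
#' @export
assembly_stats <- function(sequences) {
  if (length(sequences) == 0) stop("empty sequence set")
  lens <- sort(nchar(sequences), decreasing = TRUE)
  total <- sum(lens)
  nxx <- function(xx) unname(lens[which(cumsum(lens) >= xx / 100 * total)[1]])
  comp <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unname(sequences))))
  gc <- (comp[["G"]] + comp[["C"]]) /
    (comp[["A"]] + comp[["C"]] + comp[["G"]] + comp[["T"]])
  list(n_sequences = length(sequences), total_bp = total,
       mean_length = mean(lens), min_length = min(lens),
       max_length = max(lens), gc = gc,
       N25 = nxx(25), N50 = nxx(50), N75 = nxx(75), N90 = nxx(90))
}

#' Canonical k-mer histogram of a read set
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement); k-mers containing ambiguity characters and reads shorter
#' than k contribute nothing.
#'
#' @param reads character vector of read sequences.
#' @param k k-mer length (default 25).
#' @return data.frame(multiplicity, count) sorted by multiplicity; attribute
#'   "k".
#' @export
kmer_histogram <- function(reads, k = 25L) {
  if (k < 1) stop("k must be >= 1")
  m <- .kmer_histogram_cpp(toupper(reads), as.integer(k))
  out <- data.frame(multiplicity = m[, 1], count = m[, 2])
  out <- out[order(out$multiplicity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  out
}

#' Genome size from a k-mer histogram
#'
#' The error tail is separated at the first local minimum of the (3-bin
#' moving-average smoothed) counts scanning up from multiplicity 1; the
#' coverage peak is the modal multiplicity above that boundary, refined by a
#' count-weighted centroid over mode +/- 2 so the estimate does not jump by
#' a full 1/mode when sampling noise shifts the modal bin. Genome size =
#' total k-mer observations above the boundary divided by the peak depth.
#'
#' @param hist data.frame(multiplicity, count) from [kmer_histogram()].
#' @return list(genome_size, peak_depth, error_boundary).
#' @export
estimate_genome_size <- function(hist) {
  mults <- seq_len(max(hist$multiplicity))
  counts <- numeric(length(mults))
  counts[hist$multiplicity] <- hist$count
  M <- length(counts)
  if (M < 2) stop("error tail not separable: histogram has no coverage peak")
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(counts[1:2])
  sm[M] <- mean(counts[(M - 1):M])
  boundary <- NA_integer_
  for (m in seq_len(M - 1)) {
    if (sm[m] <= sm[m + 1]) { boundary <- m; break }
  }
  if (is.na(boundary)) {
    stop("error tail not separable: counts decrease monotonically")
  }
  above <- boundary:M
  mode_m <- above[which.max(sm[above])]
  win <- intersect((mode_m - 2):(mode_m + 2), above)
  peak <- sum(win * counts[win]) / sum(counts[win])
  total <- sum(as.numeric(mults[above]) * counts[above])
  list(genome_size = total / peak, peak_depth = peak,
       error_boundary = boundary)
}

#' Repeat copy number from read depth
#'
#' copies = (mean depth over the repeat reference x reference length /
#' unit length) / single-copy depth. With a multi-copy (e.g. three adjacent
#' copies) reference, the mean over the whole reference is the robust
#' measurement: every array-derived read is placed somewhere on it, so the
#' total placed bases are conserved regardless of how the random
#' multi-mapper spreads them; the multi-copy layout also lets reads spanning
#' unit junctions be placed full length.
#'
#' @param repeat_depth mean read depth over the repeat reference (or its
#'   central portion).
#' @param single_copy_depth single-copy reference depth (e.g. the RBH genic
#'   level from [genic_coverage()]).
#' @param repeat_ref_len length of the repeat reference the depth was
#'   measured over, bp.
#' @param unit_len repeat unit length, bp.
#' @return list(copies, total_bp).
#' @export
repeat_copy_number <- function(repeat_depth, single_copy_depth,
                               repeat_ref_len, unit_len) {
  if (single_copy_depth <= 0) stop("single-copy depth must be positive")
  copies <- repeat_depth * repeat_ref_len / unit_len / single_copy_depth
  list(copies = copies, total_bp = copies * unit_len)
}

#' Reconcile assembly length, repeat content and genome-size estimate
#'
#' The shortfall of the assembly against the k-mer genome-size estimate is
#' attributed first to the rDNA repeat arrays (NOR) and the remainder to
#' centromeric sequence, assumed equally distributed over five centromeres.
#'
#' @param genome_size_est estimated genome size, bp.
#' @param assembly_len assembly total, bp.
#' @param nor_size rDNA (NOR) repeat total, bp.
#' @param n_centromeres number of centromeres.
#' @return list(genome_size_est, assembly_len, nor_size, unassembled,
#'   centromeric_total, per_centromere).
#' @export
composition_reconcile <- function(genome_size_est, assembly_len, nor_size,
                                  n_centromeres = 5L) {
  unassembled <- genome_size_est - assembly_len
  centromeric <- genome_size_est - (assembly_len + nor_size)
  if (unassembled < 0 || centromeric < 0) {
    stop("inconsistent inputs: assembly plus NOR exceeds the size estimate")
  }
  list(genome_size_est = genome_size_est, assembly_len = assembly_len,
       nor_size = nor_size, unassembled = unassembled,
       centromeric_total = centromeric,
       per_centromere = centromeric / n_centromeres)
}

#' Exon presence filter against a counterpart assembly
#'
#' An exon counts as detected when its best hit in the assembly scores at
#' least half of its self-score (its score against its own source genome),
#' under a greedy one-hit-per-region rule: hits are taken in decreasing
#' score order and a region once claimed is closed to overlapping later
#' hits.
#'
#' @param hits data.frame(query_id, subject_id, s_start, s_end, score) of
#'   exon-vs-assembly hits (best may be recovered from many rows).
#' @param self_scores named numeric vector: each exon's self-score.
#' @return data.frame(query_id, detected) for every exon with a self-score;
#'   exons missing a self-score are dropped with a warning. Attribute
#'   "fraction_detected".
#' @export
exon_presence <- function(hits, self_scores) {
  exons <- names(self_scores)
  h <- hits[hits$query_id %in% exons, , drop = FALSE]
  missing <- setdiff(unique(hits$query_id), exons)
  if (length(missing) > 0) {
    warning(length(missing), " exon(s) without a self-score skipped")
  }
  h <- h[order(-h$score), , drop = FALSE]
  claimed <- list()
  detected <- stats::setNames(rep(FALSE, length(exons)), exons)
  for (i in seq_len(nrow(h))) {
    q <- h$query_id[i]
    if (detected[[q]]) next
    if (h$score[i] < 0.5 * self_scores[[q]]) next
    sid <- h$subject_id[i]
    prior <- claimed[[sid]]
    overlaps <- !is.null(prior) &&
      any(h$s_start[i] < prior[, 2] & h$s_end[i] > prior[, 1])
    if (overlaps) next
    claimed[[sid]] <- rbind(prior, c(h$s_start[i], h$s_end[i]))
    detected[[q]] <- TRUE
  }
  out <- data.frame(query_id = exons, detected = unname(detected),
                    stringsAsFactors = FALSE)
  attr(out, "fraction_detected") <- mean(out$detected)
  out
}

#' EST mapped/unmapped filter
#'
#' An EST counts as mapped when some hit covers at least 95% of the query
#' at 90% identity or better.
#'
#' @param hits data.frame(query_id, q_cov, identity) — one row per hit.
#' @param est_ids character vector of all ESTs considered.
#' @param min_cov,min_identity the coverage and identity cutoffs.
#' @return named logical vector over `est_ids`.
#' @export
est_mapping_filter <- function(hits, est_ids, min_cov = 0.95,
                               min_identity = 0.90) {
  ok <- hits[hits$q_cov >= min_cov & hits$identity >= min_identity, ,
             drop = FALSE]
  stats::setNames(est_ids %in% ok$query_id, est_ids)
}

#' Transposable-element overlap of scaffold-end anchor positions
#'
#' The terminal 2 kbp windows of every scaffold longer than 4 kbp are
#' assumed pre-anchored to the counterpart reference (`end_anchor_hits`);
#' each anchored interval is flagged when it intersects a TE feature.
#'
#' @param scaffold_lengths named integer vector.
#' @param end_anchor_hits data.frame(scaffold, end ("left"/"right"), seq_id,
#'   s_start, s_end) — anchor positions of the terminal windows on the
#'   counterpart.
#' @param te_features data.frame(seq_id, start, end) of TE annotations.
#' @param min_scaffold_len scaffolds at or below this length are excluded.
#' @return list(per_end = data.frame(scaffold, end, te_overlap),
#'   fraction_scaffolds_with_te_end).
#' @export
scaffold_end_te_overlap <- function(scaffold_lengths, end_anchor_hits,
                                    te_features, min_scaffold_len = 4000L) {
  eligible <- names(scaffold_lengths)[scaffold_lengths > min_scaffold_len]
  h <- end_anchor_hits[end_anchor_hits$scaffold %in% eligible, , drop = FALSE]
  flag <- logical(nrow(h))
  for (sid in unique(h$seq_id)) {
    te <- te_features[te_features$seq_id == sid, , drop = FALSE]
    sel <- which(h$seq_id == sid)
    if (nrow(te) == 0) next
    flag[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(h$s_start[sel] + 1L, h$s_end[sel]),
      IRanges::IRanges(te$start + 1L, te$end))
  }
  per_end <- data.frame(scaffold = h$scaffold, end = h$end,
                        te_overlap = flag, stringsAsFactors = FALSE)
  with_te <- unique(per_end$scaffold[per_end$te_overlap])
  list(per_end = per_end,
       fraction_scaffolds_with_te_end =
         if (length(eligible) > 0) length(with_te) / length(eligible) else
           NA_real_)
}
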