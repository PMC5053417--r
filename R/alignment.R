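# Seeded best-local-hit search. Candidate windows come from exact k-mer
# seeding; the dynamic programming inside each window is Smith-Waterman
# (Biostrings::pairwiseAlignment). Nucleotide scoring: match +1, mismatch -2,
# affine gaps open 5 / extend 2 — protein scoring: BLOSUM62, open 11 /
# extend 1.

nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

#' Best local alignment of one query against a sequence set
#'
#' Seeds the query against an exact k-mer index of the subject set (both
#' query orientations), clusters seed hits into candidate windows, runs
#' Smith-Waterman in each window and returns the single best-scoring hit.
#' Ties are broken by lowest subject id, then lowest subject coordinate.
#'
#' @param query single character string.
#' @param subjects named character vector, or NULL when `index` is given.
#' @param index optional prebuilt [build_seed_index()] of `subjects`.
#' @param min_coverage minimum fraction of the query that must be aligned
#'   for a hit to be reported.
#' @param k seed length.
#' @param max_windows cap on candidate windows examined (by seed support).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return one-row data.frame (query aligned coords, subject_id, s_start,
#'   s_end 0-based half-open, strand, score, identity, q_cov) or NULL when
#'   no window yields a qualifying hit.
#' @export
align_best <- function(query, subjects, index = NULL, min_coverage = 0.5,
                       k = 15L, max_windows = 8L,
                       gap_opening = 5, gap_extension = 2) {
  if (is.null(index)) index <- build_seed_index(subjects, k)
  k <- attr(index, "k")
  seq_names <- attr(index, "seq_names")
  qlen <- nchar(query)
  if (qlen < k || ambiguity_fraction(query) == 1) return(NULL)
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    offs <- seq(1L, qlen - k + 1L, by = max(1L, min(25L, qlen - k)))
    qt <- data.table::data.table(kmer = substring(q, offs, offs + k - 1L),
                                 off = offs)
    hits <- index[qt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0) next
    hits[, diag_start := pos - off + 1L]
    # cluster candidate starts within one query length
    for (si in unique(hits$seq)) {
      d <- sort(unique(hits$diag_start[hits$seq == si]))
      grp <- cumsum(c(1L, diff(d) > qlen))
      support <- tabulate(grp)
      centers <- vapply(split(d, grp), stats::median, numeric(1))
      cands[[length(cands) + 1L]] <- data.table::data.table(
        seq = si, center = centers, support = support, strand = strand,
        q = q)
    }
  }
  if (length(cands) == 0) return(NULL)
  cand <- data.table::rbindlist(cands)
  data.table::setorder(cand, -support)
  cand <- utils::head(cand, max_windows)
  mat <- nuc_submat()
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    si <- cand$seq[i]
    slen <- nchar(subjects[[si]])
    w0 <- max(1L, as.integer(cand$center[i]) - qlen)
    w1 <- min(slen, as.integer(cand$center[i]) + 2L * qlen)
    win <- substr(subjects[[si]], w0, w1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cand$q[i]), Biostrings::DNAString(win),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    sc <- Biostrings::score(aln)
    pat <- Biostrings::pattern(aln)
    subj <- Biostrings::subject(aln)
    q_cov <- (Biostrings::end(pat) - Biostrings::start(pat) + 1L) / qlen
    if (q_cov < min_coverage) next
    width <- nchar(as.character(subj))
    idy <- Biostrings::nmatch(aln) / width
    s_start0 <- w0 + Biostrings::start(subj) - 2L  # 0-based
    s_end0 <- w0 + Biostrings::end(subj) - 1L      # exclusive
    hit <- data.frame(subject_id = seq_names[si], s_start = s_start0,
                      s_end = s_end0, strand = cand$strand[i], score = sc,
                      identity = idy, q_cov = q_cov, stringsAsFactors = FALSE)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && (hit$subject_id < best$subject_id ||
          (hit$subject_id == best$subject_id && s_start0 < best$s_start)))) {
      best <- hit
    }
  }
  best
}

#' All-vs-all protein similarity scores
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (open 11, extend 1), plus a
#' Karlin-Altschul e-value surrogate E = m n 2^(-bits) with
#' bits = (lambda S - ln K) / ln 2 at the ungapped BLOSUM62 defaults
#' (lambda = 0.267, K = 0.041). m and n are the total residue counts of the
#' two sets. Only the <= e-value-cutoff decision is meant to be calibrated,
#' not absolute e-values.
#'
#' @param set_a,set_b named character vectors of protein sequences.
#' @return data.frame(query_id, subject_id, score, evalue) with one row per
#'   ordered pair, queries from `set_a`.
#' @export
score_proteins <- function(set_a, set_b) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  keep_a <- nchar(set_a) > 0
  keep_b <- nchar(set_b) > 0
  if (!all(keep_a) || !all(keep_b)) {
    warning(sum(!keep_a) + sum(!keep_b), " empty protein sequence(s) skipped")
    set_a <- set_a[keep_a]; set_b <- set_b[keep_b]
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- sum(nchar(set_a)); n <- sum(nchar(set_b))
  aa <- Biostrings::AAStringSet(set_a)
  rows <- vector("list", length(set_b))
  for (j in seq_along(set_b)) {
    sc <- Biostrings::pairwiseAlignment(
      aa, Biostrings::AAString(set_b[[j]]), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    rows[[j]] <- data.frame(query_id = names(set_a),
                            subject_id = names(set_b)[j],
                            score = sc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  bits <- (0.267 * out$score - log(0.041)) / log(2)
  out$evalue <- m * n * 2^(-bits)
  rownames(out) <- NULL
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}
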