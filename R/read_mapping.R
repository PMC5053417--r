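# Desk-scale seed-and-extend read mapper. Only the two acceptance fractions
# (length fraction 0.9, similarity fraction 0.95) are treated as the mapping
# contract; the engine is exact 15-mer seeding, ungapped verification, and a
# banded gapped fallback. Reads are aligned end to end (glocal), so partial
# placements are never emitted and the aligned fraction of an accepted
# placement is 1 by construction.

#' Read-mapping parameters
#'
#' @param length_fraction minimum fraction of the read that must be aligned.
#' @param similarity_fraction minimum identity over aligned columns.
#' @param multi_mapper_policy "random" (place tied reads uniformly at random,
#'   flagged non-unique) or "unique" (discard tied reads).
#' @param seed integer seed for random tie placement.
#' @param seed_k exact-seed length for the index.
#' @param band band half-width of the gapped fallback; must exceed the
#'   largest InDel expected inside a single read.
#' @export
mapping_params <- function(length_fraction = 0.9, similarity_fraction = 0.95,
                           multi_mapper_policy = c("random", "unique"),
                           seed = 1L, seed_k = 15L, band = 25L) {
  multi_mapper_policy <- match.arg(multi_mapper_policy)
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1,
            seed_k >= 4, band >= 1)
  structure(as.list(environment()), class = "mapping_params")
}

#' Build an exact k-mer seed index of a genome
#'
#' @param genome named character vector of sequences.
#' @param k seed length.
#' @return data.table with columns kmer, seq (integer index into
#'   `names(genome)`), pos (1-based seed start); attribute "seq_names".
#' @export
build_seed_index <- function(genome, k = 15L) {
  tabs <- lapply(seq_along(genome), function(i) {
    L <- nchar(genome[[i]])
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(genome[[i]], starts,
                                            starts + k - 1L),
                           seq = i, pos = starts)
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  attr(idx, "seq_names") <- names(genome)
  attr(idx, "k") <- k
  idx
}

#' Map reads to a genome
#'
#' Seed-and-extend: exact k-mer seeds at up to four offsets per read and
#' strand, ungapped verification at each candidate diagonal, banded gapped
#' fallback for reads that fail ungapped. A placement is accepted iff its
#' identity over aligned columns is at least `similarity_fraction` and the
#' aligned fraction of the read is at least `length_fraction`. Score ties are
#' resolved by the multi-mapper policy.
#'
#' @param reads named character vector.
#' @param genome named character vector, or a prebuilt [build_seed_index()]
#'   passed via `index`.
#' @param params a [mapping_params()].
#' @param index optional prebuilt seed index for `genome`.
#' @return data.frame of placements: read_id, seq_id, start, end (0-based
#'   half-open), strand, identity, aligned_fraction, score, n_best,
#'   is_unique. Attribute "summary" holds mapped/unmapped/multi counts.
#' @export
map_reads <- function(reads, genome, params = mapping_params(), index = NULL) {
  stopifnot(inherits(params, "mapping_params"))
  k <- params$seed_k
  if (is.null(index)) index <- build_seed_index(genome, k)
  seq_names <- attr(index, "seq_names")
  n_reads <- length(reads)
  rlens <- nchar(reads)
  cand_all <- list()
  for (st in c("+", "-")) {
    oriented <- if (st == "+") unname(reads) else revcomp(unname(reads))
    for (len in unique(rlens)) {
      if (len < k) next
      sel <- which(rlens == len)
      offs <- unique(round(seq(1L, len - k + 1L, length.out = 4L)))
      qt <- data.table::rbindlist(lapply(offs, function(o) {
        data.table::data.table(ridx = sel,
                               kmer = substring(oriented[sel], o, o + k - 1L),
                               off = o)
      }))
      hits <- index[qt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0) next
      hits[, cpos := pos - off + 1L]
      cand <- unique(hits[, .(ridx, seq, cpos)])
      cand[, strand := st]
      cand_all[[length(cand_all) + 1L]] <- cand
    }
  }
  empty <- data.frame(read_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), aligned_fraction = numeric(),
                      score = numeric(), n_best = integer(),
                      is_unique = logical(), stringsAsFactors = FALSE)
  if (length(cand_all) == 0) {
    attr(empty, "summary") <- list(total = n_reads, mapped = 0L,
                                   unmapped = n_reads, multi = 0L)
    return(empty)
  }
  cand <- data.table::rbindlist(cand_all)
  # ungapped verification per sequence/strand
  acc <- list()
  need_gapped <- list()
  cand_df <- as.data.frame(cand)
  for (si in unique(cand_df$seq)) {
    for (st in c("+", "-")) {
      sub <- cand_df[cand_df$seq == si & cand_df$strand == st, , drop = FALSE]
      if (nrow(sub) == 0) next
      oriented <- if (st == "+") unname(reads[sub$ridx]) else
        revcomp(unname(reads[sub$ridx]))
      mm <- .mismatch_count_at(genome[[si]], oriented, sub$cpos)
      len <- rlens[sub$ridx]
      max_mm <- floor(len * (1 - params$similarity_fraction))
      ok <- mm >= 0 & mm <= max_mm
      if (any(ok)) {
        a <- sub[ok, , drop = FALSE]
        lena <- len[ok]
        acc[[length(acc) + 1L]] <- data.table::data.table(
          ridx = a$ridx, seq = a$seq, start = a$cpos - 1L,
          end = a$cpos - 1L + lena, strand = a$strand,
          identity = (lena - mm[ok]) / lena, aligned_fraction = 1,
          score = lena - 3 * mm[ok])
      }
      fail <- sub[!ok, , drop = FALSE]
      if (nrow(fail) > 0) {
        need_gapped[[length(need_gapped) + 1L]] <- fail
      }
    }
  }
  acc_dt <- data.table::rbindlist(acc)
  # gapped fallback only for reads with no ungapped acceptance anywhere
  if (length(need_gapped) > 0) {
    ng <- do.call(rbind, need_gapped)
    if (nrow(acc_dt) > 0) ng <- ng[!ng$ridx %in% unique(acc_dt$ridx), , drop = FALSE]
    if (nrow(ng) > 0) {
      for (si in unique(ng$seq)) {
        for (st in c("+", "-")) {
          sub <- ng[ng$seq == si & ng$strand == st, , drop = FALSE]
          if (nrow(sub) == 0) next
          oriented <- if (st == "+") unname(reads[sub$ridx]) else
            revcomp(unname(reads[sub$ridx]))
          res <- .banded_align_batch(genome[[si]], oriented, sub$cpos,
                                     params$band, 1, -2, -3)
          len <- rlens[sub$ridx]
          idy <- ifelse(res[, "columns"] > 0,
                        res[, "matches"] / res[, "columns"], 0)
          ok <- res[, "ref_start"] > 0 & idy >= params$similarity_fraction
          if (any(ok)) {
            acc_dt <- rbind(acc_dt, data.table::data.table(
              ridx = sub$ridx[ok], seq = sub$seq[ok],
              start = as.integer(res[ok, "ref_start"]) - 1L,
              end = as.integer(res[ok, "ref_end"]),
              strand = sub$strand[ok], identity = idy[ok],
              aligned_fraction = 1, score = res[ok, "score"]))
          }
        }
      }
    }
  }
  if (nrow(acc_dt) == 0) {
    attr(empty, "summary") <- list(total = n_reads, mapped = 0L,
                                   unmapped = n_reads, multi = 0L)
    return(empty)
  }
  acc_dt <- unique(acc_dt, by = c("ridx", "seq", "start", "strand"))
  # best placement per read; ties per multi-mapper policy
  acc_dt[, best := max(score), by = ridx]
  top <- acc_dt[score == best]
  top[, n_best := .N, by = ridx]
  sel <- with_seed(params$seed, {
    top[, rnd := stats::runif(.N)]
    data.table::setorder(top, ridx, rnd)
    top[, head := seq_len(.N) == 1L, by = ridx]
    top[head == TRUE]
  })
  if (params$multi_mapper_policy == "unique") sel <- sel[n_best == 1L]
  out <- data.frame(read_id = names(reads)[sel$ridx],
                    seq_id = seq_names[sel$seq],
                    start = sel$start, end = sel$end, strand = sel$strand,
                    identity = sel$identity,
                    aligned_fraction = sel$aligned_fraction,
                    score = sel$score, n_best = sel$n_best,
                    is_unique = sel$n_best == 1L, stringsAsFactors = FALSE)
  attr(out, "summary") <- list(total = n_reads, mapped = nrow(out),
                               unmapped = n_reads - nrow(out),
                               multi = sum(out$n_best > 1L))
  out
}

#' Per-base coverage track from read placements
#'
#' @param placements data.frame from [map_reads()].
#' @param genome named character vector (defines sequence lengths).
#' @return named list of integer depth vectors.
#' @export
compute_coverage <- function(placements, genome) {
  track <- lapply(genome, function(s) integer(nchar(s)))
  for (sid in unique(placements$seq_id)) {
    sub <- placements[placements$seq_id == sid, , drop = FALSE]
    if (any(sub$end > nchar(genome[[sid]]) | sub$start < 0)) {
      stop("placement outside sequence bounds on ", sid)
    }
    cov <- IRanges::coverage(IRanges::IRanges(start = sub$start + 1L,
                                              end = sub$end),
                             width = nchar(genome[[sid]]))
    track[[sid]] <- as.integer(cov)
  }
  track
}

#' Proper mate pairs and their inner distances
#'
#' A proper pair maps both mates to the same sequence on opposite strands.
#' The inner distance is the signed gap between the inner ends of the two
#' placements (negative when they overlap).
#'
#' @param placements data.frame from [map_reads()]; read ids must end in
#'   /1 and /2.
#' @return data.frame(pair_id, seq_id, inner_distance, left_end,
#'   right_start).
#' @export
mate_pairs <- function(placements) {
  p <- placements[grepl("/[12]$", placements$read_id), , drop = FALSE]
  p$pair_id <- sub("/[12]$", "", p$read_id)
  p$mate <- as.integer(sub(".*/", "", p$read_id))
  dt <- data.table::as.data.table(p)
  both <- dt[, .N, by = pair_id][N == 2]$pair_id
  dt <- dt[pair_id %in% both]
  w <- data.table::dcast(dt, pair_id ~ mate,
                         value.var = c("seq_id", "start", "end", "strand"))
  proper <- w$seq_id_1 == w$seq_id_2 & w$strand_1 != w$strand_2
  w <- w[proper]
  left_end <- pmin(w$end_1, w$end_2)
  right_start <- pmax(w$start_1, w$start_2)
  data.frame(pair_id = w$pair_id, seq_id = w$seq_id_1,
             inner_distance = right_start - left_end,
             left_end = left_end, right_start = right_start,
             stringsAsFactors = FALSE)
}

#' Global mate-distance statistics
#'
#' @param placements data.frame from [map_reads()] (or a precomputed
#'   [mate_pairs()] table).
#' @return list(mean, sd, n) of proper-pair inner distances.
#' @export
pair_distance_stats <- function(placements) {
  pairs <- if (!is.null(placements$inner_distance)) placements
           else mate_pairs(placements)
  if (nrow(pairs) < 2) {
    stop("fewer than 2 proper pairs: insufficient data for distance stats")
  }
  list(mean = mean(pairs$inner_distance),
       sd = stats::sd(pairs$inner_distance),
       n = nrow(pairs))
}
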