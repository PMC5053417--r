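# Core PAV/HDR procedure: zero-coverage regions (ZCRs) on the mapping-target
# assembly are classified by anchoring their 1 kbp flanks in the read-source
# assembly. Directly adjacent anchors on one subject sequence, in order and
# orientation, mean the region is absent from the read source (PAV);
# non-adjacent anchors mean the region is present but too diverged for reads
# to map (HDR).

#' ZCR detection and classification parameters
#'
#' @param min_zcr_len minimum zero-run length recorded (5 bp).
#' @param report_min_len minimum length for PAV/HDR classification (100 bp).
#' @param max_ambiguity maximum fraction of ambiguity characters in a ZCR.
#' @param flank_len flank length anchored in the counterpart assembly.
#' @param pav_min_len minimum PAV length (separates PAV from InDels).
#' @param base_adjacency_tol anchor adjacency tolerance for ZCRs <= 1 kbp.
#' @param rel_tol relative tolerance (fraction of ZCR length) above 1 kbp.
#' @param pair_dev_cutoff mate-distance deviation supporting a PAV, bp.
#' @param min_spanning_pairs below this count the distance check is
#'   indeterminate.
#' @export
zcr_params <- function(min_zcr_len = 5L, report_min_len = 100L,
                       max_ambiguity = 0.10, flank_len = 1000L,
                       pav_min_len = 100L, base_adjacency_tol = 100L,
                       rel_tol = 0.10, pair_dev_cutoff = 100,
                       min_spanning_pairs = 3L) {
  stopifnot(min_zcr_len >= 1, max_ambiguity >= 0, max_ambiguity <= 1,
            base_adjacency_tol > 0, rel_tol > 0, pair_dev_cutoff > 0)
  structure(as.list(environment()), class = "zcr_params")
}

#' Detect zero-coverage regions on a target assembly
#'
#' Maximal runs of depth 0 of at least `min_zcr_len` bp. Runs whose target
#' sequence contains more than `max_ambiguity` ambiguity characters are
#' discarded (assembly gaps, not biology). Runs touching a sequence end are
#' flagged.
#'
#' @param track coverage track (named list of integer vectors).
#' @param target named character vector of target sequences.
#' @param params a [zcr_params()].
#' @return data.frame(seq_id, start, end, length, ambiguity_fraction,
#'   at_edge).
#' @export
detect_zcrs <- function(track, target, params = zcr_params()) {
  out <- list()
  for (sid in names(track)) {
    depth <- track[[sid]]
    if (length(depth) != nchar(target[[sid]])) {
      stop("coverage track length does not match sequence length for ", sid)
    }
    r <- rle(depth == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    zero <- r$values & r$lengths >= params$min_zcr_len
    if (!any(zero)) next
    s <- starts[zero]; e <- ends[zero]
    amb <- ambiguity_fraction(substring(target[[sid]], s + 1L, e))
    keep <- amb <= params$max_ambiguity
    if (!any(keep)) next
    out[[sid]] <- data.frame(seq_id = sid, start = s[keep], end = e[keep],
                             length = (e - s)[keep],
                             ambiguity_fraction = amb[keep],
                             at_edge = (s[keep] == 0L) |
                               (e[keep] == length(depth)),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      ambiguity_fraction = numeric(), at_edge = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the flanking sequences of a ZCR
#'
#' @param zcr one-row data.frame from [detect_zcrs()].
#' @param target named character vector.
#' @param params a [zcr_params()].
#' @return list(left, right, left_clipped, right_clipped); flanks are plain
#'   strings (possibly empty at a sequence end).
#' @export
extract_flanks <- function(zcr, target, params = zcr_params()) {
  fl <- params$flank_len
  s <- zcr$start; e <- zcr$end
  L <- nchar(target[[zcr$seq_id]])
  left_start <- max(0L, s - fl)
  right_end <- min(L, e + fl)
  list(left = substr(target[[zcr$seq_id]], left_start + 1L, s),
       right = substr(target[[zcr$seq_id]], e + 1L, right_end),
       left_clipped = left_start > s - fl,
       right_clipped = right_end < e + fl)
}

#' Anchor ZCR flanks in the read-source assembly
#'
#' Per flank, the single best local alignment hit (see [align_best()]);
#' absent when no hit covers at least half the flank. Instead of the
#' assembly, a precomputed hit table (e.g. from [read_tabular_hits()]) may
#' be supplied; the best row per flank id is then selected (highest score,
#' ties by lowest subject id then coordinate).
#'
#' @param flanks list from [extract_flanks()].
#' @param counterpart named character vector (read-source assembly), or a
#'   hit data.frame with query_id, subject_id, s_start, s_end, strand,
#'   score columns.
#' @param index optional prebuilt seed index of `counterpart`.
#' @param flank_ids query ids of the left and right flank in an external
#'   hit table.
#' @return list(left, right) of one-row hit data.frames or NULL.
#' @export
anchor_flanks <- function(flanks, counterpart, index = NULL,
                          flank_ids = c("left", "right")) {
  if (is.data.frame(counterpart)) {
    pick <- function(id) {
      h <- counterpart[counterpart$query_id == id, , drop = FALSE]
      if (nrow(h) == 0) return(NULL)
      h <- h[order(-h$score, h$subject_id, h$s_start), , drop = FALSE]
      h[1, setdiff(names(h), "query_id"), drop = FALSE]
    }
    return(list(left = pick(flank_ids[1]), right = pick(flank_ids[2])))
  }
  list(left = align_best(flanks$left, counterpart, index),
       right = align_best(flanks$right, counterpart, index))
}

adjacency_tolerance <- function(len, params) {
  if (len > 1000) params$rel_tol * len else params$base_adjacency_tol
}

#' Classify a ZCR as PAV, HDR or unresolved
#'
#' PAV requires both flank anchors on the same subject sequence, same
#' strand, in the expected order, with the signed distance between the inner
#' anchor ends within tolerance (100 bp, or 10% of the ZCR length above
#' 1 kbp), and a ZCR of at least `pav_min_len`. ZCRs at a sequence edge or
#' with a clipped flank are unresolved; everything else that fails the
#' adjacency test is HDR.
#'
#' @param zcr one-row data.frame from [detect_zcrs()].
#' @param left_hit,right_hit hit rows from [anchor_flanks()] (or NULL).
#' @param flanks the [extract_flanks()] list (for clipped flags); optional.
#' @param params a [zcr_params()].
#' @return one-row data.frame: the zcr columns plus classification,
#'   anchor_subject, anchor_strand, inner_end_distance.
#' @export
classify_zcr <- function(zcr, left_hit, right_hit, flanks = NULL,
                         params = zcr_params()) {
  call <- zcr
  call$classification <- "hdr"
  call$anchor_subject <- NA_character_
  call$anchor_strand <- NA_character_
  call$inner_end_distance <- NA_real_
  clipped <- !is.null(flanks) && (flanks$left_clipped || flanks$right_clipped)
  if (zcr$at_edge || clipped) {
    call$classification <- "unresolved"
    return(call)
  }
  if (!is.null(left_hit) && !is.null(right_hit) &&
      left_hit$subject_id == right_hit$subject_id &&
      left_hit$strand == right_hit$strand) {
    d <- if (left_hit$strand == "+") {
      right_hit$s_start - left_hit$s_end
    } else {
      left_hit$s_start - right_hit$s_end
    }
    ordered <- if (left_hit$strand == "+") {
      left_hit$s_start <= right_hit$s_start
    } else {
      right_hit$s_start <= left_hit$s_start
    }
    call$anchor_subject <- left_hit$subject_id
    call$anchor_strand <- left_hit$strand
    call$inner_end_distance <- d
    tol <- adjacency_tolerance(zcr$length, params)
    if (ordered && abs(d) <= tol && zcr$length >= params$pav_min_len) {
      call$classification <- "pav"
    }
  }
  call
}

#' Validate a PAV call by mate-distance deviation
#'
#' Proper pairs spanning the ZCR (one mate ending at or before the ZCR
#' start within one insert span, the other starting at or after the ZCR
#' end) should show an inner distance inflated by the missing sequence. The
#' call is supported when the mean spanning-pair distance deviates from the
#' global mean by more than `pair_dev_cutoff` (two-sided), unsupported when
#' it does not, and indeterminate with fewer than `min_spanning_pairs`
#' spanning pairs.
#'
#' @param call one-row data.frame from [classify_zcr()].
#' @param pairs [mate_pairs()] table for the same mapping.
#' @param global_stats [pair_distance_stats()] result.
#' @param params a [zcr_params()].
#' @return the call with pair_distance_supported and n_spanning_pairs added.
#' @export
validate_by_pair_distance <- function(call, pairs, global_stats,
                                      params = zcr_params()) {
  span <- global_stats$mean + 3 * global_stats$sd
  sp <- pairs[pairs$seq_id == call$seq_id &
                pairs$left_end <= call$start &
                pairs$left_end >= call$start - span &
                pairs$right_start >= call$end, , drop = FALSE]
  call$n_spanning_pairs <- nrow(sp)
  call$pair_distance_supported <-
    if (nrow(sp) < params$min_spanning_pairs) {
      "indeterminate"
    } else if (abs(mean(sp$inner_distance) - global_stats$mean) >
               params$pair_dev_cutoff) {
      "supported"
    } else {
      "unsupported"
    }
  call
}

#' Run one mapping direction of the PAV/HDR pipeline
#'
#' Maps reads from one accession onto the other accession's assembly,
#' detects ZCRs, classifies each ZCR of reportable length, and validates
#' calls by mate distances. A PAV here is sequence absent from the read
#' source: a deletion in the read-source accession and equally an insertion
#' in the mapping-target accession.
#'
#' @param reads named character vector (read-source accession reads).
#' @param target named character vector (mapping-target assembly).
#' @param source named character vector (read-source assembly, for flank
#'   anchoring).
#' @param map_params a [mapping_params()].
#' @param params a [zcr_params()].
#' @return list(calls, zcrs, track, pair_stats, map_summary). `calls` holds
#'   one row per ZCR >= report_min_len; `zcrs` is the raw >= 5 bp set.
#' @export
run_direction <- function(reads, target, source,
                          map_params = mapping_params(),
                          params = zcr_params()) {
  placements <- map_reads(reads, target, map_params)
  track <- compute_coverage(placements, target)
  zcrs <- detect_zcrs(track, target, params)
  pairs <- mate_pairs(placements)
  stats <- if (nrow(pairs) >= 2) pair_distance_stats(pairs) else NULL
  report <- zcrs[zcrs$length >= params$report_min_len, , drop = FALSE]
  src_index <- if (nrow(report) > 0) {
    build_seed_index(source, map_params$seed_k)
  } else NULL
  calls <- vector("list", nrow(report))
  for (i in seq_len(nrow(report))) {
    zcr <- report[i, , drop = FALSE]
    flanks <- extract_flanks(zcr, target, params)
    hits <- anchor_flanks(flanks, source, src_index)
    call <- classify_zcr(zcr, hits$left, hits$right, flanks, params)
    if (!is.null(stats)) {
      call <- validate_by_pair_distance(call, pairs, stats, params)
    } else {
      call$n_spanning_pairs <- 0L
      call$pair_distance_supported <- "indeterminate"
    }
    calls[[i]] <- call
  }
  calls <- if (length(calls) > 0) do.call(rbind, calls) else report
  rownames(calls) <- NULL
  list(calls = calls, zcrs = zcrs, track = track, pair_stats = stats,
       map_summary = attr(placements, "summary"))
}

#' Run both mapping directions (reciprocal PAV/HDR detection)
#'
#' Direction "a_on_b" maps accession A's reads onto assembly B: a PAV there
#' is sequence missing from A — a deletion in A and an insertion in B.
#' Direction "b_on_a" is the mirror image.
#'
#' @param reads_a,reads_b named character vectors of reads.
#' @param asm_a,asm_b assemblies (named character vectors).
#' @param map_params a [mapping_params()].
#' @param params a [zcr_params()].
#' @return list(a_on_b, b_on_a, calls); `calls` row-binds both directions
#'   with direction, deletion_in and insertion_in labels.
#' @export
run_reciprocal <- function(reads_a, reads_b, asm_a, asm_b,
                           map_params = mapping_params(),
                           params = zcr_params()) {
  dir_ab <- run_direction(reads_a, asm_b, asm_a, map_params, params)
  dir_ba <- run_direction(reads_b, asm_a, asm_b, map_params, params)
  lab <- function(res, direction, del_in, ins_in) {
    calls <- res$calls
    if (nrow(calls) == 0) return(cbind(calls, direction = character(0),
                                       deletion_in = character(0),
                                       insertion_in = character(0)))
    calls$direction <- direction
    calls$deletion_in <- del_in
    calls$insertion_in <- ins_in
    calls
  }
  calls <- rbind(lab(dir_ab, "a_on_b", "a", "b"),
                 lab(dir_ba, "b_on_a", "b", "a"))
  list(a_on_b = dir_ab, b_on_a = dir_ba, calls = calls)
}

#' Variant detection as a function of read coverage
#'
#' Subsamples read pairs to each fraction (nested: smaller fractions are
#' subsets of larger ones), reruns one mapping direction and reports
#' detected-variant counts and cumulative lengths per fraction — the
#' coverage-titration control showing detection has reached its plateau.
#'
#' @param reads named character vector (/1-/2 paired ids).
#' @param target,source assemblies.
#' @param fractions increasing fractions in (0, 1].
#' @param seed integer for the nested subsampling order.
#' @param map_params,params see [run_direction()].
#' @return data.frame(fraction, n_reads, n_zcr, zcr_bp, n_pav, pav_bp,
#'   n_hdr, hdr_bp).
#' @export
coverage_titration <- function(reads, target, source, fractions, seed = 1L,
                               map_params = mapping_params(),
                               params = zcr_params()) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions))
  pair_ids <- unique(sub("/[12]$", "", names(reads)))
  order_ids <- with_seed(seed, sample(pair_ids))
  rows <- lapply(fractions, function(f) {
    take <- order_ids[seq_len(max(1L, round(f * length(order_ids))))]
    sel <- reads[sub("/[12]$", "", names(reads)) %in% take]
    res <- run_direction(sel, target, source, map_params, params)
    calls <- res$calls
    data.frame(fraction = f, n_reads = length(sel),
               n_zcr = nrow(res$zcrs), zcr_bp = sum(res$zcrs$length),
               n_pav = sum(calls$classification == "pav"),
               pav_bp = sum(calls$length[calls$classification == "pav"]),
               n_hdr = sum(calls$classification == "hdr"),
               hdr_bp = sum(calls$length[calls$classification == "hdr"]))
  })
  do.call(rbind, rows)
}

#' Doubling size-bin summary of variant lengths
#'
#' Bins 100-200, 201-400, ..., 12801-25600, >25600 with per-bin counts and
#' cumulative bp plus a totals row. Lengths below 100 bp are an error —
#' variants that size are InDels, not SV.
#'
#' @param lengths integer vector of event lengths (bp), all >= 100.
#' @return data.frame(bin, count, bp) whose last row is the total.
#' @export
summarize_bins <- function(lengths) {
  if (any(lengths < 100)) stop("summarize_bins: lengths below 100 bp")
  breaks <- c(100, 200, 400, 800, 1600, 3200, 6400, 12800, 25600, Inf)
  labels <- c("100-200", "201-400", "401-800", "801-1600", "1601-3200",
              "3201-6400", "6401-12800", "12801-25600", ">25600")
  bin <- cut(lengths, breaks = c(99.5, breaks[-1] + 0.5), labels = labels)
  count <- as.integer(table(bin))
  bp <- vapply(levels(bin), function(l) sum(lengths[bin == l]), numeric(1))
  out <- data.frame(bin = c(labels, "Total"),
                    count = c(count, length(lengths)),
                    bp = c(unname(bp), sum(lengths)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
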