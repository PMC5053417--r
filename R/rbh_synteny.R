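# Reciprocal-best-hit (RBH) protein synteny: best-hit computation with an
# e-value cutoff, reciprocal pairing, position ranks for the synteny dot
# plot, random/real outlier typing, scaffold split hints, reference-guided
# scaffold anchoring with AGP output, and genic read-coverage flags for
# collapsed-duplicate candidates.

#' RBH and outlier parameters
#'
#' @param evalue_max e-value cutoff for a hit to count.
#' @param near_best_ratio score ratio defining an "equally good" hit when
#'   typing outliers as random (ambiguous) vs real.
#' @param outlier_window number of nearest rank-neighbours used for the
#'   local rank median.
#' @param outlier_rank_dev rank deviation beyond which a pair is an outlier.
#' @export
rbh_params <- function(evalue_max = 0.001, near_best_ratio = 0.95,
                       outlier_window = 5L, outlier_rank_dev = 20L) {
  stopifnot(evalue_max > 0, near_best_ratio > 0, near_best_ratio <= 1,
            outlier_window >= 1, outlier_rank_dev >= 1)
  structure(as.list(environment()), class = "rbh_params")
}

#' Drop transposable-element and organelle genes before RBH pairing
#'
#' When annotations are available, proteins from genes typed as
#' transposable elements, or located on organelle sequences, are excluded
#' so multi-copy mobile elements cannot masquerade as orthologs.
#'
#' @param proteins named character vector (names are gene ids).
#' @param features annotation data.frame as from [read_annotation()].
#' @param te_types feature types treated as transposable elements.
#' @param organelle_seqs sequence ids holding organelle genomes.
#' @return the filtered protein vector.
#' @export
filter_rbh_input <- function(proteins, features,
                             te_types = "transposable_element",
                             organelle_seqs = character(0)) {
  drop <- unique(c(
    features$id[features$type %in% te_types],
    features$id[features$seq_id %in% organelle_seqs]))
  proteins[!names(proteins) %in% drop]
}

#' Best hit per query under the e-value cutoff
#'
#' Highest score wins; ties broken by lowest e-value, then lexicographically
#' smallest subject id.
#'
#' @param hits data.frame(query_id, subject_id, score, evalue).
#' @param params an [rbh_params()].
#' @return data.frame(query_id, subject_id, score, evalue), one row per
#'   query with at least one qualifying hit.
#' @export
best_hits <- function(hits, params = rbh_params()) {
  h <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h <- h[order(h$query_id, -h$score, h$evalue, h$subject_id), , drop = FALSE]
  out <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gene_ranks <- function(genes, seq_order, ids) {
  g <- genes[genes$id %in% ids, , drop = FALSE]
  key <- match(g$seq_id, seq_order)
  if (anyNA(key)) key[is.na(key)] <- length(seq_order) + 1L
  g <- g[order(key, g$start), , drop = FALSE]
  stats::setNames(seq_len(nrow(g)) - 1L, g$id)
}

#' Reciprocal best hits with synteny ranks
#'
#' A pair (a, b) is an RBH when a's best hit is b and b's best hit is a.
#' Ranks are 0-based positions of each RBH gene in its assembly's
#' position-sorted RBH gene list; sequences are ordered by `seq_order_*`
#' (chromosome order; unplaced scaffolds are appended last).
#'
#' @param best_ab,best_ba [best_hits()] tables for the two directions.
#' @param genes_a,genes_b data.frame(id, seq_id, start, end) gene positions.
#' @param seq_order_a,seq_order_b character vectors giving sequence order;
#'   default the order of first appearance in the gene table.
#' @return data.frame(gene_a, gene_b, score_ab, score_ba, rank_a, rank_b).
#' @export
compute_rbhs <- function(best_ab, best_ba, genes_a, genes_b,
                         seq_order_a = unique(genes_a$seq_id),
                         seq_order_b = unique(genes_b$seq_id)) {
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  recip <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  pairs <- best_ab[recip, , drop = FALSE]
  score_ba <- stats::setNames(best_ba$score, best_ba$query_id)
  rank_a <- gene_ranks(genes_a, seq_order_a, pairs$query_id)
  rank_b <- gene_ranks(genes_b, seq_order_b, pairs$subject_id)
  out <- data.frame(gene_a = pairs$query_id, gene_b = pairs$subject_id,
                    score_ab = pairs$score,
                    score_ba = unname(score_ba[pairs$subject_id]),
                    rank_a = unname(rank_a[pairs$query_id]),
                    rank_b = unname(rank_b[pairs$subject_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-plot table of RBH ranks
#'
#' One row per RBH pair; optionally written as TSV for plotting.
#'
#' @param rbhs [compute_rbhs()] table.
#' @param path optional TSV output path.
#' @return data.frame(gene_a, gene_b, rank_a, rank_b), invisibly written to
#'   `path` when given.
#' @export
dot_plot_data <- function(rbhs, path = NULL) {
  out <- rbhs[, c("gene_a", "gene_b", "rank_a", "rank_b")]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Detect synteny outliers from RBH ranks
#'
#' A pair is a candidate outlier when its rank in assembly B deviates from
#' the median rank-B of its `outlier_window` nearest rank-A neighbours by
#' more than `outlier_rank_dev` ranks.
#'
#' @param rbhs [compute_rbhs()] table.
#' @param params an [rbh_params()].
#' @return subset of `rbhs` with a rank_deviation column.
#' @export
detect_outliers <- function(rbhs, params = rbh_params()) {
  n <- nrow(rbhs)
  r <- rbhs[order(rbhs$rank_a), , drop = FALSE]
  dev <- numeric(n)
  w <- params$outlier_window
  for (i in seq_len(n)) {
    others <- setdiff(order(abs(r$rank_a - r$rank_a[i])), i)
    nb <- utils::head(others, w)
    dev[i] <- abs(r$rank_b[i] - stats::median(r$rank_b[nb]))
  }
  out <- r[dev > params$outlier_rank_dev, , drop = FALSE]
  out$rank_deviation <- dev[dev > params$outlier_rank_dev]
  rownames(out) <- NULL
  out
}

#' Type an outlier as "random" (ambiguous hits) or "real"
#'
#' Random: at least one member of the pair has two or more qualifying hits
#' scoring within `near_best_ratio` of its best hit — the pairing was a
#' coin toss among near-identical copies. Real: both members have exactly
#' one qualifying near-best hit, so the positional deviation is genuine.
#'
#' @param candidate one row of [detect_outliers()] output.
#' @param hits_ab,hits_ba full hit tables for the two directions.
#' @param params an [rbh_params()].
#' @return the row with a `kind` column ("random" or "real").
#' @export
classify_outlier <- function(candidate, hits_ab, hits_ba,
                             params = rbh_params()) {
  near_best_n <- function(hits, id) {
    h <- hits[hits$query_id == id & hits$evalue <= params$evalue_max, ,
              drop = FALSE]
    if (nrow(h) == 0) return(0L)
    sum(h$score >= params$near_best_ratio * max(h$score))
  }
  n_a <- near_best_n(hits_ab, candidate$gene_a)
  n_b <- near_best_n(hits_ba, candidate$gene_b)
  candidate$kind <- if (n_a >= 2 || n_b >= 2) "random" else "real"
  candidate
}

#' Scaffold split hints from RBH synteny breaks
#'
#' Flags the junction between consecutive RBH genes on one scaffold whose
#' counterpart positions jump chromosomes or more than `outlier_rank_dev`
#' ranks, provided at least two genes on each side form internally
#' consistent runs — the signature of a chimeric scaffold rather than a
#' stray outlier gene.
#'
#' @param rbh_map data.frame(scaffold, pos, counterpart_seq, rank) — one row
#'   per RBH gene on the scaffolds of interest, `pos` the gene start on its
#'   scaffold, `rank` the counterpart synteny rank.
#' @param params an [rbh_params()].
#' @return data.frame(scaffold, break_start, break_end, left_seq,
#'   right_seq, left_index) — one row per hinted junction; break_start/end
#'   bracket the junction between the two gene positions.
#' @export
scaffold_split_hints <- function(rbh_map, params = rbh_params()) {
  out <- list()
  consistent_run <- function(sub, idx) {
    length(idx) >= 2 &&
      length(unique(sub$counterpart_seq[idx])) == 1 &&
      all(abs(diff(sub$rank[idx])) <= params$outlier_rank_dev)
  }
  for (sc in unique(rbh_map$scaffold)) {
    sub <- rbh_map[rbh_map$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      jump <- sub$counterpart_seq[i] != sub$counterpart_seq[i + 1] ||
        abs(sub$rank[i + 1] - sub$rank[i]) > params$outlier_rank_dev
      if (!jump) next
      left <- max(1, i - 1):i
      right <- (i + 1):min(nrow(sub), i + 2)
      if (consistent_run(sub, left) && consistent_run(sub, right)) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, break_start = sub$pos[i],
          break_end = sub$pos[i + 1],
          left_seq = sub$counterpart_seq[i],
          right_seq = sub$counterpart_seq[i + 1],
          left_index = i, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(scaffold = character(), break_start = integer(),
                      break_end = integer(), left_seq = character(),
                      right_seq = character(), left_index = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Anchor scaffolds to chromosomes and emit AGP placements
#'
#' Each scaffold is assigned the chromosome holding the weighted majority of
#' its evidence (RBH gene positions and/or alignment blocks, weighted by
#' bp), oriented by the sign of the rank correlation between scaffold and
#' chromosome coordinates, and ordered along the chromosome by the median
#' counterpart coordinate. Scaffolds whose best chromosome holds less than
#' 60% of the evidence weight are left unplaced with a reason.
#'
#' @param evidence data.frame(scaffold, scaffold_pos, chr, chr_pos, weight).
#' @param scaffold_lengths named integer vector.
#' @param gap_len gap inserted between consecutive scaffolds in the AGP.
#' @param agp_path optional path; when given the AGP v2.0 file is written.
#' @return list(assignments, placements); `placements` is the
#'   [write_agp()] input.
#' @export
anchor_scaffolds <- function(evidence, scaffold_lengths, gap_len = 100L,
                             agp_path = NULL) {
  rows <- lapply(unique(evidence$scaffold), function(sc) {
    e <- evidence[evidence$scaffold == sc, , drop = FALSE]
    wt <- tapply(e$weight, e$chr, sum)
    best <- names(wt)[which.max(wt)]
    if (max(wt) / sum(wt) < 0.6) {
      return(data.frame(scaffold = sc, chr = NA_character_,
                        strand = NA_character_, order_pos = NA_real_,
                        reason = "conflicting evidence below 60% majority",
                        stringsAsFactors = FALSE))
    }
    eb <- e[e$chr == best, , drop = FALSE]
    strand <- if (nrow(eb) >= 2) {
      rho <- suppressWarnings(stats::cor(eb$scaffold_pos, eb$chr_pos,
                                         method = "spearman"))
      if (!is.na(rho) && rho < 0) "-" else "+"
    } else "+"
    data.frame(scaffold = sc, chr = best, strand = strand,
               order_pos = stats::median(eb$chr_pos), reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  placed <- assignments[!is.na(assignments$chr), , drop = FALSE]
  placements <- NULL
  if (nrow(placed) > 0) {
    placed <- placed[order(placed$chr, placed$order_pos), , drop = FALSE]
    parts <- lapply(unique(placed$chr), function(ch) {
      sub <- placed[placed$chr == ch, , drop = FALSE]
      lens <- unname(scaffold_lengths[sub$scaffold])
      starts <- cumsum(c(0L, utils::head(lens + gap_len, -1)))
      data.frame(object = ch, component_id = sub$scaffold,
                 start = starts, end = starts + lens, strand = sub$strand,
                 stringsAsFactors = FALSE)
    })
    placements <- do.call(rbind, parts)
    rownames(placements) <- NULL
    if (!is.null(agp_path)) write_agp(placements, agp_path)
  }
  list(assignments = assignments, placements = placements)
}

#' Mean read depth per gene with collapsed-duplicate flags
#'
#' The genome-wide single-copy reference level is the median of the RBH
#' genes' mean depths; a non-RBH gene whose mean depth is at least twice
#' that level is flagged as a collapsed-duplicate candidate.
#'
#' @param track coverage track (named list of integer vectors).
#' @param genes data.frame(id, seq_id, start, end).
#' @param rbh_ids character vector of RBH gene ids.
#' @return data.frame(id, mean_depth, is_rbh, collapsed_candidate);
#'   attribute "reference_level".
#' @export
genic_coverage <- function(track, genes, rbh_ids) {
  if (any(genes$end <= genes$start)) stop("zero-length gene interval")
  means <- numeric(nrow(genes))
  for (sid in unique(genes$seq_id)) {
    cs <- cumsum(c(0, track[[sid]]))
    sel <- which(genes$seq_id == sid)
    means[sel] <- (cs[genes$end[sel] + 1L] - cs[genes$start[sel] + 1L]) /
      (genes$end[sel] - genes$start[sel])
  }
  is_rbh <- genes$id %in% rbh_ids
  ref <- stats::median(means[is_rbh])
  out <- data.frame(id = genes$id, mean_depth = means, is_rbh = is_rbh,
                    collapsed_candidate = !is_rbh & means >= 2 * ref,
                    stringsAsFactors = FALSE)
  attr(out, "reference_level") <- ref
  out
}
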