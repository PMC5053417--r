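# Orchestration: the synthetic recovery benchmark (generate a pair with a
# known truth registry, run reciprocal detection, score recall/precision)
# and the consolidated run report.

stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter) %% (2^31 - 1))
}

match_calls_to_truth <- function(calls, registry, slop = 1000L,
                                 explain_span = 300L) {
  # A PAV call matches a truth large event when call and truth intervals on
  # the mapping-target assembly overlap (after slop expansion). Deletions
  # (sequence absent from the derived accession B) surface as ZCRs on A in
  # the b_on_a direction; insertions (novel in B) as ZCRs on B in a_on_b.
  # A call matching no large event can still be explained by smaller truth
  # variation: clustered small InDels within one read span produce genuine
  # mapping dead zones with adjacent flanks. Only calls with no truth
  # variant nearby are false.
  pav <- calls[calls$classification == "pav", , drop = FALSE]
  truth <- registry[registry$type %in% c("deletion", "insertion"), ,
                    drop = FALSE]
  if (nrow(truth) > 0) {
    truth$direction <- ifelse(truth$type == "deletion", "b_on_a", "a_on_b")
    truth$t_start <- ifelse(truth$type == "deletion", truth$start_a,
                            truth$start_b)
    truth$t_end <- ifelse(truth$type == "deletion", truth$end_a,
                          truth$end_b)
  }
  other <- registry[registry$type %in% c("small_indel", "hdr",
                                         "cnv_collapse"), , drop = FALSE]
  truth_hit <- logical(nrow(truth))
  call_hit <- logical(nrow(pav))
  call_dir_ok <- logical(nrow(pav))
  for (i in seq_len(nrow(pav))) {
    same_dir <- truth$direction == pav$direction[i]
    ov <- same_dir & truth$t_start - slop < pav$end[i] &
      truth$t_end + slop > pav$start[i]
    any_dir_ov <- (truth$t_start - slop < pav$end[i]) &
      (truth$t_end + slop > pav$start[i])
    if (any(ov)) {
      call_hit[i] <- TRUE
      call_dir_ok[i] <- TRUE
      truth_hit[ov] <- TRUE
      next
    }
    if (any(any_dir_ov)) {
      call_hit[i] <- TRUE  # right locus, wrong direction label
      next
    }
    if (nrow(other) > 0) {
      o_start <- if (pav$direction[i] == "b_on_a") other$start_a else
        other$start_b
      o_end <- if (pav$direction[i] == "b_on_a") other$end_a else
        other$end_b
      explained <- o_start - explain_span < pav$end[i] &
        o_end + explain_span > pav$start[i]
      if (any(explained)) {
        call_hit[i] <- TRUE
        call_dir_ok[i] <- TRUE
      }
    }
  }
  list(truth = truth, truth_recovered = truth_hit, call_matched = call_hit,
       call_direction_ok = call_dir_ok)
}

#' Synthetic recovery benchmark
#'
#' Generates an accession pair with a known truth registry, simulates
#' error-free paired reads from both accessions, runs reciprocal PAV/HDR
#' detection, and scores recovery against the registry. Defaults are the
#' package's standard recovery experiment: a 1 Mbp pair with 20 implanted
#' deletions and 20 insertions (100 bp - 10 kbp, isolated from repeats),
#' background SNP/InDel divergence at realistic accession-pair rates, and
#' 30x 2 x 250 nt paired-end reads.
#'
#' @param genome_length ancestor length, bp.
#' @param div_config a [divergence_config()]; its seed is overridden by the
#'   fan-out of `seed`.
#' @param sim_config a [read_sim_config()]; seed likewise overridden.
#' @param map_params,params mapping and ZCR parameters.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param slop interval slop when matching calls to truth, bp.
#' @return list: registry, calls, recall, precision, n_truth, n_pav,
#'   direction_labels_correct, bins (size-bin summaries), seeds, and the
#'   per-direction results.
#' @export
run_benchmark <- function(genome_length = 1e6,
                          div_config = divergence_config(
                            event_len_range = c(100, 10000)),
                          sim_config = read_sim_config(),
                          map_params = mapping_params(),
                          params = zcr_params(),
                          seed = 1L, slop = 1000L) {
  seeds <- list(ancestor = stage_seed(seed, 1), derive = stage_seed(seed, 2),
                reads_a = stage_seed(seed, 3), reads_b = stage_seed(seed, 4),
                mapping = stage_seed(seed, 5))
  anc <- generate_ancestor(genome_length, gc = 0.36, seed = seeds$ancestor)
  div_config$seed <- seeds$derive
  der <- derive_accession(anc, div_config)
  asm_a <- stats::setNames(anc[1], "accA")
  attr(asm_a, "repeats") <- NULL
  asm_b <- stats::setNames(der$genome[1], "accB")
  cfg_a <- sim_config; cfg_a$seed <- seeds$reads_a
  cfg_b <- sim_config; cfg_b$seed <- seeds$reads_b
  sim_a <- simulate_reads(asm_a, cfg_a)
  sim_b <- simulate_reads(asm_b, cfg_b)
  names(sim_a$reads) <- paste0("a", names(sim_a$reads))
  names(sim_b$reads) <- paste0("b", names(sim_b$reads))
  map_params$seed <- seeds$mapping
  rec <- run_reciprocal(sim_a$reads, sim_b$reads, asm_a, asm_b,
                        map_params, params)
  m <- match_calls_to_truth(rec$calls, der$registry, slop)
  n_truth <- nrow(m$truth)
  n_pav <- sum(rec$calls$classification == "pav")
  pav_lens <- rec$calls$length[rec$calls$classification == "pav"]
  list(registry = der$registry, calls = rec$calls,
       recall = if (n_truth > 0) mean(m$truth_recovered) else NA_real_,
       precision = if (n_pav > 0) mean(m$call_matched) else NA_real_,
       n_truth = n_truth, n_pav = n_pav,
       direction_labels_correct = all(m$call_direction_ok[m$call_matched]),
       n_false_pav = sum(!m$call_matched),
       bins = if (n_pav > 0) summarize_bins(pav_lens) else NULL,
       truth_recovered = m$truth_recovered,
       seeds = seeds, a_on_b = rec$a_on_b, b_on_a = rec$b_on_a)
}

#' Consolidated run report
#'
#' Aggregates whichever stage outputs are present into one list and
#' optionally writes it as JSON: assembly statistics, size-bin tables, RBH
#' and outlier tallies, genome-composition estimate, benchmark recovery.
#'
#' @param stats [assembly_stats()] output, or NULL.
#' @param bins [summarize_bins()] output, or NULL.
#' @param rbhs [compute_rbhs()] table, or NULL.
#' @param outliers typed outlier table (with `kind`), or NULL.
#' @param composition [composition_reconcile()] output, or NULL.
#' @param benchmark [run_benchmark()] output, or NULL.
#' @param path optional JSON output path.
#' @return the report list, invisibly written to `path` when given.
#' @export
run_report <- function(stats = NULL, bins = NULL, rbhs = NULL,
                       outliers = NULL, composition = NULL,
                       benchmark = NULL, path = NULL) {
  report <- list()
  if (!is.null(stats)) report$assembly <- stats
  if (!is.null(bins)) report$size_bins <- bins
  if (!is.null(rbhs)) {
    report$rbh <- list(n_pairs = nrow(rbhs))
  }
  if (!is.null(outliers)) {
    report$outliers <- list(n = nrow(outliers),
                            n_random = sum(outliers$kind == "random"),
                            n_real = sum(outliers$kind == "real"))
  }
  if (!is.null(composition)) report$composition <- composition
  if (!is.null(benchmark)) {
    report$benchmark <- benchmark[c("recall", "precision", "n_truth",
                                    "n_pav", "n_false_pav",
                                    "direction_labels_correct")]
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  report
}
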