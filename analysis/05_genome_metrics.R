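#!/usr/bin/env Rscript
# Genome metrics: assembly statistics of the simulated assemblies, k-mer
# genome-size estimation from reads, tandem-repeat copy number from read
# depth, and the genome-composition reconciliation — including the
# published-scale worked example (146 Mbp estimate, 117 Mbp assembly,
# 4 Mbp rDNA).
source("analysis/00_config.R")

asm_b <- read_sequences(file.path(SIM_DIR, "accB.fasta"))
reads_b <- read_sequences(file.path(SIM_DIR, "reads_B.fastq"))

st <- assembly_stats(asm_b)
cat("assembly:", st$n_sequences, "sequence(s),", st$total_bp, "bp, GC",
    round(st$gc, 4), ", N50", st$N50, "\n")

hist_b <- kmer_histogram(reads_b, k = 25)
utils::write.table(hist_b, file.path(OUT, "kmer_histogram.txt"),
                   sep = " ", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
est <- estimate_genome_size(hist_b)
cat("k-mer genome size estimate:", round(est$genome_size), "bp",
    "(truth", nchar(asm_b[[1]]), "bp; peak depth",
    round(est$peak_depth, 2), ")\n")

# tandem-repeat copy number on a dedicated array genome
anc <- generate_ancestor(100000, gc = 0.36,
                         repeat_specs = list(list(unit_len = 180L,
                                                  copies = 50L)),
                         seed = SEED + 9L)
reps <- attr(anc, "repeats")
unit <- substr(anc[[1]], reps$start + 1, reps$start + 180)
ref <- setNames(strrep(unit, 3), "ref3")
simr <- simulate_reads(setNames(anc[1], "g"),
                       read_sim_config(read_length = 100, coverage = 30,
                                       insert_mean = 350, insert_sd = 25,
                                       seed = SEED + 10L))
mp <- mapping_params(seed = SEED + 11L)
trk_rep <- compute_coverage(map_reads(simr$reads, ref, mp), ref)
gref <- setNames(anc[1], "g")
trk_g <- compute_coverage(map_reads(simr$reads, gref, mp), gref)
cn <- repeat_copy_number(mean(trk_rep$ref3),
                         mean(trk_g$g[5000:25000]), 540, 180)
cat("tandem repeat copies (truth 50):", round(cn$copies, 1), "\n")

# published-scale composition worked example
comp <- composition_reconcile(146e6, 117e6, 4e6)
cat("composition: unassembled", comp$unassembled / 1e6, "Mbp,",
    "centromeric", comp$centromeric_total / 1e6, "Mbp,",
    "per centromere", comp$per_centromere / 1e6, "Mbp\n")

report <- run_report(stats = st, composition = comp,
                     path = file.path(OUT, "metrics.json"))
cat("metrics written to", file.path(OUT, "metrics.json"), "\n")
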