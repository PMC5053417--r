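#!/usr/bin/env Rscript
# Generate the synthetic accession pair (ancestor "A" and derived "B" with
# 20 implanted deletions, 20 insertions and realistic background SNP/InDel
# divergence) plus 30x error-free paired reads from both accessions, and
# persist genomes, reads and the truth registry.
source("analysis/00_config.R")

anc <- generate_ancestor(GENOME_LENGTH, gc = 0.36, seed = SEED + 1L)
der <- derive_accession(anc, div_cfg)
asm_a <- setNames(anc[1], "accA")
asm_b <- setNames(der$genome[1], "accB")

write_sequences(asm_a, file.path(SIM_DIR, "accA.fasta"))
write_sequences(asm_b, file.path(SIM_DIR, "accB.fasta"))
write_tsv(der$registry[, c("type", "start_a", "end_a", "start_b", "end_b",
                           "length")],
          file.path(SIM_DIR, "truth_registry.tsv"))

cfg_a <- sim_cfg; cfg_a$seed <- SEED + 3L
cfg_b <- sim_cfg; cfg_b$seed <- SEED + 4L
sim_a <- simulate_reads(asm_a, cfg_a)
sim_b <- simulate_reads(asm_b, cfg_b)
names(sim_a$reads) <- paste0("a", names(sim_a$reads))
names(sim_b$reads) <- paste0("b", names(sim_b$reads))
write_sequences(sim_a$reads, file.path(SIM_DIR, "reads_A.fastq"),
                format = "fastq")
write_sequences(sim_b$reads, file.path(SIM_DIR, "reads_B.fastq"),
                format = "fastq")

tab <- table(der$registry$type)
cat("accession pair written:", GENOME_LENGTH, "bp ancestor;",
    nchar(asm_b), "bp derived\n")
cat("truth registry:", paste(names(tab), tab, collapse = ", "), "\n")
cat("reads:", length(sim_a$reads), "from A,", length(sim_b$reads),
    "from B\n")
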