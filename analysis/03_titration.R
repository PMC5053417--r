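#!/usr/bin/env Rscript
# Coverage titration: subsample one accession's reads to increasing
# fractions (nested subsets) and rerun the detection direction, showing
# that variant discovery has reached its plateau at full coverage. Run on
# a dedicated 150 kbp pair: at the lowest fractions most of the genome is
# a coverage gap, so every gap-flank gets anchored and the cost of a
# titration scales with genome size, not with the variant count.
source("analysis/00_config.R")

anc <- generate_ancestor(150000, gc = 0.36, seed = SEED + 20L)
cfg <- divergence_config(n_insertions = 5, n_deletions = 5,
                         event_len_range = c(200, 5000), seed = SEED + 21L)
der <- derive_accession(anc, cfg)
asm_a <- setNames(anc[1], "accA")
asm_b <- setNames(der$genome[1], "accB")
sim_b <- simulate_reads(asm_b, read_sim_config(seed = SEED + 22L))

fractions <- c(0.02, 0.1, 0.25, 0.5, 0.75, 1.0)
tit <- coverage_titration(sim_b$reads, asm_a, asm_b, fractions,
                          seed = SEED + 23L,
                          map_params = mapping_params(seed = SEED + 24L))
write_tsv(tit, file.path(OUT, "titration.tsv"))
print(tit, row.names = FALSE)
cat("plateau check: pav count at 0.75x vs 1.0x:",
    tit$n_pav[5], "vs", tit$n_pav[6], "\n")
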