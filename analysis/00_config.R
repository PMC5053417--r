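# Shared configuration for the analysis drivers. Scales are desk-sized: a
# 1 Mbp accession pair at 30x coverage exercises every stage in minutes.
suppressMessages(library(pavscape))

SEED <- as.integer(Sys.getenv("PAVSCAPE_SEED", "1"))
OUT <- "results"
SIM_DIR <- file.path(OUT, "sim")
GENOME_LENGTH <- 1e6

dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

div_cfg <- divergence_config(event_len_range = c(100, 10000),
                             seed = SEED + 2L)
sim_cfg <- read_sim_config(read_length = 250L, coverage = 30,
                           insert_mean = 700, insert_sd = 50)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
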