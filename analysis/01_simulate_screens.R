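#!/usr/bin/env Rscript
# Simulate the two screening regimes the analysis distinguishes: a linear
# epitope (small SID expected) and a conformational sensor that needs the
# whole folding core (full-core SID expected). Writes reference FASTA and
# clone tables under results/sim/.

suppressPackageStartupMessages({
  library(sidmap)
  library(Biostrings)
})
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

write_refs <- function(refs, path) {
  ss <- DNAStringSet(setNames(refs$mrna_seq, refs$id))
  writeXStringSet(ss, path)
  utils::write.table(refs[, c("id", "cds_start", "cds_stop")],
                     sub("\\.fa$", "_cds.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# linear epitope, 21 aa, background at 5%
cfg_lin <- sim_config(epitope = c(200, 220), n_clones_retained = 32L,
                      background_rate = 0.05, seed = 101L)
refs_lin <- simulate_transcriptome(cfg_lin)
scr_lin <- simulate_screen(cfg_lin, refs_lin)
write_refs(refs_lin, "results/sim/linear_ref.fa")
write_clone_table(scr_lin, "results/sim/linear_clones.tsv")

# conformational sensor: the Rab-like core (residues 13..174 of a 208-aa
# GTPase) must be intact for binding
cfg_conf <- sim_config(mode = "conformational", core = c(13, 174),
                       epitope = c(13, 174), n_clones_retained = 25L,
                       background_rate = 0.05, seed = 202L)
refs_conf <- simulate_transcriptome(cfg_conf)
scr_conf <- simulate_screen(cfg_conf, refs_conf)
write_refs(refs_conf, "results/sim/conformational_ref.fa")
write_clone_table(scr_conf, "results/sim/conformational_clones.tsv")

jsonlite::write_json(
  list(linear = list(epitope = cfg_lin$epitope, seed = cfg_lin$seed),
       conformational = list(core = cfg_conf$core, seed = cfg_conf$seed)),
  "results/sim/truth.json", auto_unbox = TRUE
)
cat("Simulated screens written to results/sim/:\n")
cat(sprintf("  linear: %d clones, planted epitope %d-%d\n",
            nrow(scr_lin$records), cfg_lin$epitope[1], cfg_lin$epitope[2]))
cat(sprintf("  conformational: %d clones, folding core %d-%d\n",
            nrow(scr_conf$records), cfg_conf$core[1], cfg_conf$core[2]))
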