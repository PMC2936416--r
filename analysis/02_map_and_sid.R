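#!/usr/bin/env Rscript
# Map the simulated screens of 01 back from their files, cluster fragments
# and compute SIDs. The linear screen should give a small SID containing
# the planted epitope; the conformational screen a SID spanning at least
# the whole folding core.

suppressPackageStartupMessages(library(sidmap))
dir.create("results", showWarnings = FALSE)

truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)

for (kind in c("linear", "conformational")) {
  refs <- read_reference_fasta(
    sprintf("results/sim/%s_ref.fa", kind),
    cds_table = sprintf("results/sim/%s_ref_cds.tsv", kind)
  )
  scr <- read_clone_table(sprintf("results/sim/%s_clones.tsv", kind))
  rep <- sid_report(scr, refs)
  utils::write.table(rep, sprintf("results/sid_%s.tsv", kind),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- rep[1, ]
  planted <- if (kind == "linear") truth$linear$epitope else
    truth$conformational$core
  cat(sprintf(
    "%s screen: top gene %s, SID %d-%d (%d aa, support %d); planted %d-%d %s\n",
    kind, top$gene, top$sid_start, top$sid_stop, top$sid_length,
    top$sid_support, planted[1], planted[2],
    ifelse(top$sid_start <= planted[1] & top$sid_stop >= planted[2],
           "contained in SID", "NOT contained")
  ))
  sid_iv <- data.frame(orf_id = top$sid_orf, aa_start = top$sid_start,
                       aa_stop = top$sid_stop, name = "SID")
  write_intervals(sid_iv, "bed", sprintf("results/sid_%s.bed", kind))
}
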