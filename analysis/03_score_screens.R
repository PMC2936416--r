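#!/usr/bin/env Rscript
# Confidence scoring across the bundled synthetic screen suite: every prey
# gene gets an e-value under the competition-for-bait null and a category
# A-F, with the cross-screen registry flagging sticky prey (E) and the
# artifact list overriding to F. Writes per-screen score tables.

suppressPackageStartupMessages(library(sidmap))
dir.create("results/scores", showWarnings = FALSE, recursive = TRUE)

suite <- synthetic_screen_suite()
conn <- connectivity_index(suite$registry)
cfg <- pipeline_config(artifacts = suite$artifacts, connectivity = conn,
                       seed = 11L)

targets <- list(AA2_human = "RAB6A", AA2_fly = "RAB6_DM", ROF7 = "RAB1A",
                TA10 = "GOLGB1", SF9 = "MYH9")
for (nm in names(suite$screens)) {
  rep <- run_pipeline(suite$references, suite$screens[[nm]], cfg)
  utils::write.table(rep$scores, sprintf("results/scores/%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- rep$scores[1, ]
  tg <- rep$scores[rep$scores$gene == targets[[nm]], ]
  cat(sprintf(paste0("%-10s best evalue %-8s (%.3g, cat %s); ",
                     "known target %-8s n_ind %3d evalue %.3g cat %s\n"),
              nm, top$gene, top$evalue, top$category,
              tg$gene, tg$n_independent, tg$evalue, tg$category))
}
cat("\nNote: full-core (conformational) clusters collapse to few distinct\n",
    "5' starts, so their count term is weak; the e-value rewards many\n",
    "independent starts, as in the SF9 and simulated linear screens.\n", sep = "")

cat("\nCategory E genes (highly connected across screens):",
    paste(names(conn)[conn >= cfg$tau], collapse = ", "), "\n")
cat("Category F genes (known artifacts):",
    paste(suite$artifacts, collapse = ", "), "\n")
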