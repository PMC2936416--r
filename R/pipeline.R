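#' Pipeline configuration
#'
#' @param thresholds E-value thresholds `c(tA, tB, tC)` for categories
#'   A/B/C.
#' @param tau Connectivity threshold for category E.
#' @param artifacts Known-artifact gene ids (category F).
#' @param connectivity Named connectivity indices (see
#'   [connectivity_index()]).
#' @param pbs_min Optional category filter for SID computation.
#' @param mc_draws,seed Monte-Carlo settings for the overlap probability.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = c(1e-10, 1e-5, 1e-2), tau = 0.25,
                            artifacts = character(),
                            connectivity = numeric(),
                            pbs_min = NULL, mc_draws = 10000L, seed = 1L) {
  structure(list(thresholds = thresholds, tau = tau, artifacts = artifacts,
                 connectivity = connectivity, pbs_min = pbs_min,
                 mc_draws = as.integer(mc_draws), seed = seed),
            class = "pipeline_config")
}

#' Run the whole screen-analysis pipeline
#'
#' map -> cluster -> SID -> confidence score -> report. The report combines
#' the per-gene SID table ([sid_report()]) with the per-ORF score table
#' ([score_screen()]); deterministic for a given config seed.
#'
#' @param references A [reference_orfs()] set.
#' @param screen A [screen_table()].
#' @param config A [pipeline_config()].
#' @return A `screen_report`: list with `screen_id`, `bait_name`, `totals`
#'   (all/IF/OOF/antisense clone counts), `genes` (SID table joined with
#'   score columns `n_independent`, `evalue`, `category`), `scores`
#'   (per-ORF score table) and `mapped` (the mapping output, for sketches).
#' @export
run_pipeline <- function(references, screen, config = pipeline_config()) {
  mapped <- map_screen(screen, references)
  genes <- sid_report(screen, references, pbs_min = config$pbs_min)
  scores <- score_screen(
    mapped$intervals, references, n_clones = max(1L, nrow(screen$records)),
    artifacts = config$artifacts, connectivity = config$connectivity,
    thresholds = config$thresholds, tau = config$tau,
    mc_draws = config$mc_draws, seed = config$seed
  )
  idx <- match(genes$sid_orf, scores$gene)
  genes$n_independent <- scores$n_independent[idx]
  genes$evalue <- scores$evalue[idx]
  genes$category <- scores$category[idx]
  structure(list(
    screen_id = screen$screen_id,
    bait_name = screen$bait_name,
    totals = list(
      all = nrow(screen$records),
      if_clones = sum(mapped$records$frame == "IF"),
      oof_clones = sum(mapped$records$frame == "OOF"),
      antisense = sum(screen$records$sense == "antisense")
    ),
    genes = genes,
    scores = scores,
    mapped = mapped,
    references = references
  ), class = "screen_report")
}

# Text ruler of fragments under the ORF, with the SID marked: the classic
# schematic of a fragment screen figure, at terminal width.
fragment_sketch <- function(orf, intervals, sid = NULL, width = 60L) {
  L <- orf$protein_length
  scale_pos <- function(aa) pmax(1L, pmin(width, ceiling(aa / L * width)))
  lines <- c(sprintf("%-10s 1%s%d", orf$id,
                     paste(rep("=", width - 2L), collapse = ""), L))
  for (i in seq_len(nrow(intervals))) {
    a <- scale_pos(intervals$aa_start[i])
    b <- scale_pos(intervals$aa_stop[i])
    row <- rep(" ", width)
    row[a:b] <- "-"
    lines <- c(lines, sprintf("%-10s %s [%d-%d]",
                              substr(intervals$clone_id[i], 1, 10),
                              paste(row, collapse = ""),
                              intervals$aa_start[i], intervals$aa_stop[i]))
  }
  if (!is.null(sid)) {
    a <- scale_pos(sid$aa_start); b <- scale_pos(sid$aa_stop)
    row <- rep(" ", width)
    row[a:b] <- "#"
    lines <- c(lines, sprintf("%-10s %s SID [%d-%d] (%d aa)", "SID",
                              paste(row, collapse = ""),
                              sid$aa_start, sid$aa_stop,
                              sid$aa_stop - sid$aa_start + 1L))
  }
  lines
}

#' @export
print.screen_report <- function(x, max_genes = 5L, ...) {
  cat(sprintf("Screen %s (bait %s): %d clones (%d IF, %d OOF)\n",
              x$screen_id, x$bait_name, x$totals$all,
              x$totals$if_clones, x$totals$oof_clones))
  show <- utils::head(x$genes, max_genes)
  for (i in seq_len(nrow(show))) {
    g <- show[i, ]
    cat(sprintf("  %-12s %4d clones (%3d%%)  cat %-2s SID %s\n",
                g$gene, g$clones, g$percent,
                ifelse(is.na(g$category), "-", g$category),
                if (is.na(g$sid_start)) "-" else
                  sprintf("%s:%d-%d (%d aa%s)", g$sid_orf, g$sid_start,
                          g$sid_stop, g$sid_length,
                          ifelse(g$sid_complete, "", ", partial"))))
  }
  top <- x$genes[1, ]
  if (nrow(x$genes) >= 1 && !is.na(top$sid_orf)) {
    orf <- x$references[match(top$sid_orf, x$references$id), , drop = FALSE]
    iv <- x$mapped$intervals[x$mapped$intervals$orf_id == top$sid_orf, ,
                             drop = FALSE]
    sid <- list(aa_start = top$sid_start, aa_stop = top$sid_stop)
    cat("\n", paste(fragment_sketch(orf, utils::head(iv, 12L), sid),
                    collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Write a screen report's tables to disk
#'
#' Deterministic TSV + JSON emission (`genes.tsv`, `scores.tsv`,
#' `report.json`); re-running on identical inputs yields byte-identical
#' files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(screen_id = report$screen_id, bait_name = report$bait_name,
         totals = report$totals, genes = report$genes),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
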