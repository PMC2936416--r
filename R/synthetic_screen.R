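codons_no_stop <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

#' Configuration of a synthetic two-hybrid screen
#'
#' The generator emulates the statistical structure of an scFv bait screen
#' against a saturated random-primed cDNA library: genes compete for the
#' bait in proportion to length, fragment starts are uniform along the
#' transcript, and insert lengths follow a truncated lognormal with a mean
#' around the 700-800 bp printed for such libraries. Selection is a hard
#' containment rule: a specifically retained clone must be in frame on the
#' target and its residue interval must contain the epitope (`linear` mode)
#' or the whole folding core (`conformational` mode); with probability
#' `background_rate` a clone is instead a nonspecific fragment of another
#' gene.
#'
#' @param n_genes Number of reference genes.
#' @param gene_length_range Protein lengths (aa), uniform.
#' @param target_orf_id Id given to the planted target gene.
#' @param epitope `c(aa_start, aa_stop)` of the planted linear epitope on
#'   the target.
#' @param mode `"linear"` or `"conformational"`.
#' @param core `c(aa_start, aa_stop)` folding core (conformational mode;
#'   defaults to `epitope`).
#' @param n_clones_retained Retained clones to emit.
#' @param background_rate Probability a retained clone is background, in
#'   `[0, 1)`.
#' @param insert_len_mean_nt,insert_len_sigma,insert_len_bounds Truncated
#'   lognormal insert-length model (nt). Defaults 750 / 0.5 / c(150, 3000).
#' @param frame_random If `TRUE` the vector frame of each insert is drawn
#'   uniformly over the three phases instead of being read off the start
#'   offset.
#' @param seed RNG seed; the whole simulation is deterministic under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L,
                       gene_length_range = c(150L, 500L),
                       target_orf_id = "TARGET01",
                       epitope = c(200L, 220L),
                       mode = c("linear", "conformational"),
                       core = NULL,
                       n_clones_retained = 100L,
                       background_rate = 0.05,
                       insert_len_mean_nt = 750,
                       insert_len_sigma = 0.5,
                       insert_len_bounds = c(150L, 3000L),
                       frame_random = FALSE,
                       seed = 1L) {
  mode <- match.arg(mode)
  epitope <- as.integer(epitope)
  if (length(epitope) != 2 || epitope[1] > epitope[2] || epitope[1] < 1) {
    stop_usage("epitope must be c(aa_start, aa_stop) with start <= stop")
  }
  core <- as.integer(core %||% epitope)
  if (background_rate < 0 || background_rate >= 1) {
    stop_usage("background_rate must lie in [0, 1)")
  }
  if (insert_len_bounds[1] > insert_len_bounds[2]) {
    stop_usage("insert_len_bounds must be ordered")
  }
  need <- if (mode == "linear") epitope else core
  if (3L * (need[2] - need[1] + 1L) > insert_len_bounds[2]) {
    stop_usage("retention rule unsatisfiable: region longer than the largest insert")
  }
  if (need[2] > gene_length_range[2]) {
    stop_usage("epitope/core stop exceeds the maximum gene length")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    target_orf_id = target_orf_id,
    epitope = epitope, mode = mode, core = core,
    n_clones_retained = as.integer(n_clones_retained),
    background_rate = background_rate,
    insert_len_mean_nt = insert_len_mean_nt,
    insert_len_sigma = insert_len_sigma,
    insert_len_bounds = as.integer(insert_len_bounds),
    frame_random = isTRUE(frame_random),
    seed = as.integer(seed)
  ), class = "sim_config")
}

random_orf_seq <- function(aa_len) {
  paste(sample(codons_no_stop, aa_len, replace = TRUE), collapse = "")
}

#' Simulate a reference transcriptome
#'
#' Random-codon ORFs (no internal stops) with lengths uniform in the
#' configured range, short random UTRs and a stop codon after the CDS. The
#' planted target is drawn long enough to hold the epitope/core.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A [reference_orfs()] set of `n_genes` ORFs; the first is the
#'   target.
#' @export
simulate_transcriptome <- function(config) {
  with_seed(config$seed, {
    rng <- config$gene_length_range
    need <- if (config$mode == "linear") config$epitope else config$core
    lens <- sample(rng[1]:rng[2], config$n_genes, replace = TRUE)
    lens[1] <- sample(max(rng[1], need[2]):rng[2], 1)
    ids <- c(config$target_orf_id,
             sprintf("GENE%03d", seq_len(config$n_genes - 1L)))
    utr5 <- sample(0:30, config$n_genes, replace = TRUE)
    utr3 <- sample(0:30, config$n_genes, replace = TRUE)
    seqs <- character(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      seqs[i] <- paste0(
        paste(sample(c("A", "C", "G", "T"), utr5[i], replace = TRUE),
              collapse = ""),
        random_orf_seq(lens[i]),
        "TAA",
        paste(sample(c("A", "C", "G", "T"), utr3[i], replace = TRUE),
              collapse = "")
      )
    }
    reference_orfs(
      id = ids, mrna_seq = seqs,
      cds_start = utr5 + 1L,
      cds_stop = utr5 + 3L * lens
    )
  })
}

#' Draw insert lengths from the library-size model
#'
#' Truncated lognormal parameterized so the untruncated mean equals
#' `insert_len_mean_nt`; draws outside the bounds are rejected and redrawn.
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Integer vector of insert lengths (nt).
#' @export
draw_insert_lengths <- function(n, config) {
  sigma <- config$insert_len_sigma
  meanlog <- log(config$insert_len_mean_nt) - sigma^2 / 2
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n, meanlog, sigma))
    x <- x[x >= config$insert_len_bounds[1] & x <= config$insert_len_bounds[2]]
    out <- c(out, x)
  }
  as.integer(out[seq_len(n)])
}

draw_fragments <- function(n, gene_idx, references, config) {
  mlen <- nchar(references$mrna_seq[gene_idx])
  start <- vapply(mlen, function(l) sample.int(l, 1L), integer(1))
  len <- draw_insert_lengths(n, config)
  stop <- pmin(start + len - 1L, mlen)
  cs <- references$cds_start[gene_idx]
  ce <- references$cds_stop[gene_idx]
  in_cds <- stop >= cs & start <= ce
  if (config$frame_random) {
    iff <- in_cds & sample.int(3L, n, replace = TRUE) == 1L
  } else {
    iff <- in_cds & (pmax(start, cs) - cs) %% 3L == 0L
  }
  data.frame(gene_idx = gene_idx, nt_start = start, nt_stop = stop,
             frame = ifelse(iff, "IF", "OOF"), stringsAsFactors = FALSE)
}

#' Simulate a saturated two-hybrid screen
#'
#' Emits exactly `n_clones_retained` clone records in the clone-table
#' schema. Specific clones are rejection-sampled target fragments satisfying
#' the retention rule (in frame, residue interval containing the epitope or
#' core); background clones are unconstrained fragments of the non-target
#' genes, drawn length-weighted. PBS is left `NA` (it is recomputed by the
#' scoring stage).
#'
#' @param config A [sim_config()].
#' @param references The [simulate_transcriptome()] output (or any
#'   reference set containing `target_orf_id`).
#' @return A [screen_table()].
#' @export
simulate_screen <- function(config, references) {
  t_idx <- match(config$target_orf_id, references$id)
  if (is.na(t_idx)) stop_usage("references do not contain the target ORF")
  need <- if (config$mode == "linear") config$epitope else config$core
  if (references$protein_length[t_idx] < need[2]) {
    stop_usage("target ORF too short for the configured epitope/core")
  }
  with_seed(config$seed + 1L, {
    n <- config$n_clones_retained
    is_bg <- stats::runif(n) < config$background_rate
    n_bg <- sum(is_bg)
    n_on <- n - n_bg

    on_rows <- NULL
    orf <- references[t_idx, , drop = FALSE]
    while (is.null(on_rows) || nrow(on_rows) < n_on) {
      cand <- draw_fragments(max(64L, 4L * n_on), rep(t_idx, max(64L, 4L * n_on)),
                             references, config)
      ok <- cand$frame == "IF"
      if (any(ok)) {
        cs <- orf$cds_start
        s <- pmax(cand$nt_start[ok], cs)
        e <- pmin(cand$nt_stop[ok], orf$cds_stop)
        aa_s <- (s - cs) %/% 3L + 1L
        aa_e <- aa_s + (e - s + 1L) %/% 3L - 1L
        hit <- aa_s <= need[1] & aa_e >= need[2]
        on_rows <- rbind(on_rows, cand[ok, , drop = FALSE][hit, , drop = FALSE])
      }
    }
    on_rows <- on_rows[seq_len(n_on), , drop = FALSE]

    bg_rows <- NULL
    if (n_bg > 0) {
      bg_pool <- setdiff(seq_len(nrow(references)), t_idx)
      w <- references$protein_length[bg_pool]
      gidx <- bg_pool[sample.int(length(bg_pool), n_bg, replace = TRUE,
                                 prob = w / sum(w))]
      bg_rows <- draw_fragments(n_bg, gidx, references, config)
    }

    rows <- rbind(on_rows, bg_rows)
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    screen_table(
      data.frame(
        clone_id = sprintf("C%04d", seq_len(n)),
        prey_name = references$id[rows$gene_idx],
        accession = references$accession[rows$gene_idx],
        nt_start = rows$nt_start,
        nt_stop = rows$nt_stop,
        frame = rows$frame,
        sense = "sense",
        pbs = NA_character_,
        stringsAsFactors = FALSE
      ),
      screen_id = sprintf("sim_%s_%d", config$mode, config$seed),
      bait_name = "synthetic-scFv"
    )
  })
}
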