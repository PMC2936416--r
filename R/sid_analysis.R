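#' Cluster overlapping fragments
#'
#' Overlapping prey fragments originating from the same gene form a
#' cluster: a connected component under pairwise interval overlap, where
#' overlap means at least one shared residue (abutting intervals such as
#' 1..10 and 11..20 do *not* cluster). Clusters are ordered by
#' `(orf_id, min aa_start)`.
#'
#' @param intervals Fragment-interval data frame (`orf_id`, `aa_start`,
#'   `aa_stop`, `clone_id`).
#' @return List of clusters, each `list(orf_id, members)` with `members` a
#'   subset of `intervals`.
#' @export
cluster_fragments <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(list())
  out <- list()
  for (g in sort(unique(intervals$orf_id))) {
    iv <- intervals[intervals$orf_id == g, , drop = FALSE]
    iv <- iv[order(iv$aa_start, iv$aa_stop), , drop = FALSE]
    # scan line: a new component starts where aa_start exceeds the max stop
    # seen so far (shared-residue overlap, so strict >)
    run_max <- cummax(iv$aa_stop)
    comp <- cumsum(c(TRUE, iv$aa_start[-1] > run_max[-nrow(iv)]))
    for (cid in unique(comp)) {
      out[[length(out) + 1L]] <- list(
        orf_id = g,
        members = iv[comp == cid, , drop = FALSE]
      )
    }
  }
  out
}

#' Compute the Selected Interacting Domain of a cluster
#'
#' The SID is the region shared by all fragments of the cluster: the
#' interval `[max(aa_start), min(aa_stop)]` when that intersection is
#' non-empty (`complete = TRUE`, support = cluster size). For chained
#' clusters whose global intersection is empty, the fall-back is the
#' deepest-coverage plateau (leftmost if tied), flagged `complete = FALSE`
#' with support equal to the coverage depth.
#'
#' @param cluster One element of [cluster_fragments()] output.
#' @return List `orf_id`, `aa_start`, `aa_stop`, `support`, `complete`,
#'   `n_members`.
#' @export
compute_sid <- function(cluster) {
  m <- cluster$members
  if (is.null(m) || nrow(m) == 0) stop_usage("empty cluster")
  lo <- max(m$aa_start)
  hi <- min(m$aa_stop)
  if (lo <= hi) {
    return(list(orf_id = cluster$orf_id, aa_start = lo, aa_stop = hi,
                support = nrow(m), complete = TRUE, n_members = nrow(m)))
  }
  # empty intersection: deepest plateau via coverage difference array
  offset <- min(m$aa_start) - 1L
  width <- max(m$aa_stop) - offset
  delta <- integer(width + 1L)
  s <- m$aa_start - offset
  e <- m$aa_stop - offset
  for (i in seq_len(nrow(m))) {
    delta[s[i]] <- delta[s[i]] + 1L
    delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
  }
  cov <- cumsum(delta[seq_len(width)])
  depth <- max(cov)
  r <- rle(cov == depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first <- which(r$values)[1]  # leftmost deepest plateau
  list(orf_id = cluster$orf_id,
       aa_start = starts[first] + offset,
       aa_stop = ends[first] + offset,
       support = depth, complete = FALSE, n_members = nrow(m))
}

#' Per-gene SID report for a screen
#'
#' Maps the screen, groups clones by prey gene (the table's `prey_name`, so
#' closely related paralogues listed under one prey name are counted
#' together, the way screen tables report them) and gives, per gene: total
#' retained clones, in-frame clones, percent of the screen
#' (`round(100 * gene clones / total clones)`, halves up, so 2 of 3 clones
#' report as 67%), and the SID of the group's largest fragment cluster
#' (SIDs stay in the coordinates of the single ORF the cluster maps to).
#'
#' @param screen A [screen_table()].
#' @param references A [reference_orfs()] set.
#' @param pbs_min Optional PBS category letter; when given, only clones of
#'   that category or better (closer to "A") contribute fragments to SIDs.
#' @return Data frame sorted by clone count (ties by gene id): one row per
#'   prey gene with columns `gene`, `clones`, `if_clones`, `percent`,
#'   `sid_orf`, `sid_start`, `sid_stop`, `sid_length`, `sid_support`,
#'   `sid_complete`.
#' @export
sid_report <- function(screen, references, pbs_min = NULL) {
  rec <- screen$records
  total <- nrow(rec)
  mapped <- map_screen(screen, references)
  gene_of <- mapped$records$prey_name
  intervals <- mapped$intervals
  if (!is.null(pbs_min)) {
    if (!pbs_min %in% LETTERS[1:6]) stop_usage("pbs_min must be 'A'..'F'")
    keep_ids <- rec$clone_id[!is.na(rec$pbs) & rec$pbs <= pbs_min]
    intervals <- intervals[intervals$clone_id %in% keep_ids, , drop = FALSE]
  }
  genes <- sort(unique(gene_of))
  rows <- lapply(genes, function(g) {
    in_gene <- gene_of == g
    iv_g <- intervals[intervals$clone_id %in% rec$clone_id[in_gene], ,
                      drop = FALSE]
    cl_g <- cluster_fragments(iv_g)
    sid <- NULL
    if (length(cl_g)) {
      sizes <- vapply(cl_g, function(cl) nrow(cl$members), integer(1))
      sid <- compute_sid(cl_g[[which.max(sizes)]])
    }
    data.frame(
      gene = g,
      clones = sum(in_gene),
      if_clones = sum(in_gene & mapped$records$frame == "IF"),
      percent = if (total > 0) round_half_up(100 * sum(in_gene) / total) else 0,
      sid_orf = if (is.null(sid)) NA_character_ else sid$orf_id,
      sid_start = if (is.null(sid)) NA_integer_ else sid$aa_start,
      sid_stop = if (is.null(sid)) NA_integer_ else sid$aa_stop,
      sid_length = if (is.null(sid)) NA_integer_ else
        sid$aa_stop - sid$aa_start + 1L,
      sid_support = if (is.null(sid)) NA_integer_ else sid$support,
      sid_complete = if (is.null(sid)) NA else sid$complete,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), clones = integer(),
                      if_clones = integer(), percent = numeric(),
                      sid_orf = character(), sid_start = integer(),
                      sid_stop = integer(), sid_length = integer(),
                      sid_support = integer(), sid_complete = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$clones, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
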