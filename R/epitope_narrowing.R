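#' Narrow a binding region from tiling interaction calls
#'
#' Deconvolution of a gap-repair tiling experiment: every positive
#' sub-fragment must contain the binding region, so the region lies in the
#' intersection of all positives; every negative sub-fragment must miss it,
#' so residues covered by any negative are subtracted. The longest remaining
#' contiguous run (leftmost if tied) is returned.
#'
#' @param calls Data frame with columns `orf_id`, `aa_start`, `aa_stop`,
#'   `outcome` (`"positive"`/`"negative"`), all on one ORF, at least one
#'   positive.
#' @return List `orf_id`, `aa_start`, `aa_stop`, `length`, `n_positive`,
#'   `n_negative`.
#' @export
narrow_domain <- function(calls) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (length(unique(calls$orf_id)) != 1) {
    stop_usage("tiling calls must all lie on one ORF")
  }
  if (!all(calls$outcome %in% c("positive", "negative"))) {
    stop_validation("outcome must be 'positive' or 'negative'")
  }
  pos <- calls[calls$outcome == "positive", , drop = FALSE]
  neg <- calls[calls$outcome == "negative", , drop = FALSE]
  if (nrow(pos) == 0) stop_usage("need at least one positive call")
  lo <- max(pos$aa_start)
  hi <- min(pos$aa_stop)
  if (lo > hi) {
    stop_validation("inconsistent positives: their intersection is empty")
  }
  keep <- rep(TRUE, hi - lo + 1L)
  for (i in seq_len(nrow(neg))) {
    a <- max(neg$aa_start[i], lo)
    b <- min(neg$aa_stop[i], hi)
    if (a <= b) keep[(a - lo + 1L):(b - lo + 1L)] <- FALSE
  }
  if (!any(keep)) {
    stop_validation("inconsistent negatives: they cover the whole positive intersection")
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]  # which.max is leftmost on ties
  list(orf_id = calls$orf_id[1],
       aa_start = lo + starts[best] - 1L,
       aa_stop = lo + ends[best] - 1L,
       length = r$lengths[best],
       n_positive = nrow(pos), n_negative = nrow(neg))
}

#' Design a tiling of sub-fragments over a region
#'
#' Generates `n_tiles` intervals of varied length whose union covers the
#' region exactly, emulating the PCR sub-fragments of a gap-repair
#' narrowing experiment. Deterministic under `seed`.
#'
#' @param region List or one-row data frame with `orf_id`, `aa_start`,
#'   `aa_stop`.
#' @param n_tiles Number of tiles (>= 2).
#' @param min_len Minimum tile length (default `max(5, L %/% n_tiles)`).
#' @param overlap_frac Target fractional overlap between neighbours.
#' @param seed RNG seed.
#' @return Fragment-interval data frame with `n_tiles` rows covering the
#'   region.
#' @export
design_tiling <- function(region, n_tiles, min_len = NULL,
                          overlap_frac = 0.25, seed = NULL) {
  lo <- as.integer(region$aa_start)
  hi <- as.integer(region$aa_stop)
  L <- hi - lo + 1L
  if (!is_count(n_tiles) || n_tiles < 2) stop_usage("n_tiles must be >= 2")
  min_len <- as.integer(min_len %||% max(5L, L %/% n_tiles))
  if (min_len > L) stop_usage("min_len exceeds the region length")
  with_seed(seed, {
    base <- max(min_len, ceiling(L * (1 + overlap_frac) / n_tiles))
    lens <- pmin(L, pmax(min_len, round(stats::runif(
      n_tiles, base * 0.6, base * 1.6
    ))))
    starts <- round(seq(lo, hi - lens[n_tiles] + 1L, length.out = n_tiles))
    starts <- starts + c(0L, round(stats::runif(n_tiles - 2, -base / 4, base / 4)), 0L)
    starts <- pmin(pmax(as.integer(starts), lo), hi - lens + 1L)
    ord <- order(starts)
    starts <- starts[ord]; lens <- lens[ord]
    starts[1] <- lo
    # close any coverage gap by pulling the next tile back
    for (i in 2:n_tiles) {
      prev_end <- starts[i - 1L] + lens[i - 1L] - 1L
      if (starts[i] > prev_end + 1L) starts[i] <- prev_end + 1L
    }
    last_end <- starts[n_tiles] + lens[n_tiles] - 1L
    if (last_end < hi) {
      lens[n_tiles] <- hi - starts[n_tiles] + 1L
    } else if (last_end > hi) {
      starts[n_tiles] <- hi - lens[n_tiles] + 1L
      # pulling the last tile left cannot open a gap (it moves left)
    }
    tiles <- data.frame(
      orf_id = region$orf_id,
      aa_start = starts,
      aa_stop = pmin(starts + lens - 1L, hi),
      clone_id = sprintf("tile%02d", seq_len(n_tiles)),
      stringsAsFactors = FALSE
    )
    covered <- rep(FALSE, L)
    for (i in seq_len(n_tiles)) {
      covered[(tiles$aa_start[i] - lo + 1L):(tiles$aa_stop[i] - lo + 1L)] <- TRUE
    }
    if (!all(covered)) {
      stop_usage("infeasible tiling constraints: region not coverable")
    }
    tiles
  })
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

pair_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  mat <- matrix(mismatch, 20, 20, dimnames = list(aa_alphabet, aa_alphabet))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

pair_identity <- function(pa) {
  ca <- strsplit(pa$a, "")[[1]]
  cb <- strsplit(pa$b, "")[[1]]
  cols <- !(ca == "-" & cb == "-")
  round_half_up(100 * sum(ca == cb & ca != "-" & cols) / sum(cols), 1)
}

# Merge one pairwise alignment (center-with-gaps pc, other ps) into the
# running master alignment ("once a gap, always a gap").
merge_into_master <- function(master, others, pc, ps) {
  mi <- 1L; pj <- 1L
  nm <- length(master); np <- length(pc)
  new_master <- character(0)
  new_others <- lapply(others, function(x) character(0))
  new_seq <- character(0)
  while (mi <= nm || pj <= np) {
    take_m <- mi <= nm && master[mi] == "-"
    take_p <- pj <= np && pc[pj] == "-"
    if (take_m && !take_p) {
      new_master <- c(new_master, master[mi])
      for (k in seq_along(others)) new_others[[k]] <- c(new_others[[k]], others[[k]][mi])
      new_seq <- c(new_seq, "-")
      mi <- mi + 1L
    } else if (take_p) {
      new_master <- c(new_master, "-")
      for (k in seq_along(others)) new_others[[k]] <- c(new_others[[k]], "-")
      new_seq <- c(new_seq, ps[pj])
      pj <- pj + 1L
    } else {
      new_master <- c(new_master, master[mi])
      for (k in seq_along(others)) new_others[[k]] <- c(new_others[[k]], others[[k]][mi])
      new_seq <- c(new_seq, ps[pj])
      mi <- mi + 1L; pj <- pj + 1L
    }
  }
  list(master = new_master, others = c(new_others, list(new_seq)))
}

#' Align SID peptide sequences and compute pairwise identities
#'
#' Global alignment with linear gap costs (defaults: match +1, mismatch -1,
#' gap -2). For more than two sequences a center-star progressive alignment
#' is built from the pairwise alignments (center = sequence with the
#' highest total pairwise score). Percent identity is computed per pair
#' from its own global alignment as matches over aligned columns (dual-gap
#' columns excluded), reported to one decimal.
#'
#' @param seqs Named character vector of peptide sequences (standard
#'   20-letter alphabet), length >= 2.
#' @param match,mismatch,gap Scoring parameters.
#' @return List `alignment` (named character vector of equal-length gapped
#'   sequences), `identity` (percent matrix), `center`.
#' @export
align_sids <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  if (length(seqs) < 2) stop_usage("need at least two sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet, collapse = "")), seqs)
  if (any(bad)) {
    stop_validation(sprintf("sequence '%s' contains non-amino-acid symbols",
                            names(seqs)[bad][1]))
  }
  n <- length(seqs)
  ident <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  scores <- matrix(0, n, n)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- pair_align(seqs[[i]], seqs[[j]], match, mismatch, gap)
      pairs[[paste(i, j)]] <- pa
      ident[i, j] <- ident[j, i] <- pair_identity(pa)
      scores[i, j] <- scores[j, i] <- pa$score
    }
  }
  center <- which.max(rowSums(scores))
  rest <- setdiff(seq_len(n), center)
  master <- strsplit(seqs[[center]], "")[[1]]
  others <- list()
  for (j in rest) {
    key <- paste(min(center, j), max(center, j))
    pa <- pairs[[key]]
    if (center < j) {
      pc <- strsplit(pa$a, "")[[1]]; ps <- strsplit(pa$b, "")[[1]]
    } else {
      pc <- strsplit(pa$b, "")[[1]]; ps <- strsplit(pa$a, "")[[1]]
    }
    merged <- merge_into_master(master, others, pc, ps)
    master <- merged$master
    others <- merged$others
  }
  aln <- character(n)
  aln[center] <- paste(master, collapse = "")
  aln[rest] <- vapply(others, paste, character(1), collapse = "")
  names(aln) <- names(seqs)
  list(alignment = aln, identity = ident, center = names(seqs)[center])
}

#' Common SID block of a multiple alignment
#'
#' The longest run of alignment columns in which every sequence has a
#' residue, with pairwise percent identities computed inside that block.
#' This is the cross-homologue narrowing step: homologue SIDs of different
#' lengths reduce to the conserved region they all share.
#'
#' @param aln An [align_sids()] result.
#' @return List `block_start`, `block_stop`, `block_length` (alignment
#'   columns) and `identity` (percent matrix within the block).
#' @export
common_sid_block <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$alignment, ""))
  all_res <- colSums(mat == "-") == 0
  if (!any(all_res)) {
    return(list(block_start = NA_integer_, block_stop = NA_integer_,
                block_length = 0L, identity = NULL))
  }
  r <- rle(all_res)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  b0 <- starts[best]; b1 <- ends[best]
  n <- nrow(mat)
  ident <- matrix(100, n, n,
                  dimnames = list(names(aln$alignment), names(aln$alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ident[i, j] <- ident[j, i] <- round_half_up(
        100 * sum(mat[i, b0:b1] == mat[j, b0:b1]) / (b1 - b0 + 1L), 1
      )
    }
  }
  list(block_start = b0, block_stop = b1, block_length = b1 - b0 + 1L,
       identity = ident)
}

#' Intersection of SID intervals in a shared coordinate system
#'
#' @param intervals Data frame with `aa_start`, `aa_stop` (>= 2 rows), all
#'   expressed in one coordinate system (e.g. alignment columns, or residue
#'   positions of one homologue).
#' @return List `aa_start`, `aa_stop`, `length`, or `NULL` when the
#'   intervals share no position.
#' @export
common_sid <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) < 2) stop_usage("need at least two intervals")
  lo <- max(intervals$aa_start)
  hi <- min(intervals$aa_stop)
  if (lo > hi) return(NULL)
  list(aa_start = lo, aa_stop = hi, length = hi - lo + 1L)
}
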