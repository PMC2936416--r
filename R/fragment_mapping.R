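#' Mapping policy for placing prey fragments on references
#'
#' @param mode `"coordinates"` (trust the clone table's nt coordinates),
#'   `"exact_match"` (longest exact substring placement) or `"seeded_match"`
#'   (15-mer seeds with ungapped extension, tolerating isolated mismatches).
#' @param min_match_nt Minimum placed length to call a fragment mapped
#'   (>= 30).
#' @param allow_antisense Also search the reverse complement.
#' @return A `mapping_policy` list.
#' @export
mapping_policy <- function(mode = c("coordinates", "exact_match", "seeded_match"),
                           min_match_nt = 30L, allow_antisense = FALSE) {
  mode <- match.arg(mode)
  if (!is_count(min_match_nt) || min_match_nt < 30) {
    stop_usage("min_match_nt must be an integer >= 30")
  }
  structure(list(mode = mode, min_match_nt = as.integer(min_match_nt),
                 allow_antisense = isTRUE(allow_antisense)),
            class = "mapping_policy")
}

ref_row <- function(references, orf_id) {
  i <- match(orf_id, references$id)
  if (is.na(i)) stop_usage(sprintf("unknown reference ORF '%s'", orf_id))
  references[i, , drop = FALSE]
}

#' Classify the reading frame of a clone on its reference ORF
#'
#' A fragment fused downstream of the Gal4 activation domain translates in
#' the source ORF's frame only if it is in sense orientation and its first
#' base inside the CDS sits at a codon boundary: `IF` iff
#' `(max(nt_start, cds_start) - cds_start) %% 3 == 0`. Antisense inserts are
#' always `OOF`. Frame is invariant under +3 nt shifts of the start within
#' the CDS.
#'
#' @param record A clone record (list or one-row data frame with `nt_start`,
#'   `nt_stop`, `sense`).
#' @param orf One row of a [reference_orfs()] set.
#' @return `"IF"` or `"OOF"`.
#' @export
classify_frame <- function(record, orf) {
  nt_start <- as.integer(record$nt_start)
  nt_stop <- as.integer(record$nt_stop)
  if (nt_stop < orf$cds_start || nt_start > orf$cds_stop) {
    stop_validation(sprintf(
      "clone [%d, %d] lies entirely outside the CDS [%d, %d] of '%s'",
      nt_start, nt_stop, orf$cds_start, orf$cds_stop, orf$id
    ))
  }
  if (!identical(as.character(record$sense), "sense")) return("OOF")
  off <- (max(nt_start, orf$cds_start) - orf$cds_start) %% 3L
  if (off == 0L) "IF" else "OOF"
}

#' Translate a clone's nucleotide span into a residue interval
#'
#' The span is clamped to the CDS (fragments reaching into the UTRs or over
#' the stop codon contribute only their coding part) and partial codons at
#' either end are dropped: only fully encoded residues can contribute to an
#' epitope. With `o = clamped_start - cds_start`, the interval is
#' `aa_start = o/3 + 1`, `aa_stop = aa_start + floor(clamped_len/3) - 1`.
#'
#' @inheritParams classify_frame
#' @return A one-row data frame (`orf_id`, `aa_start`, `aa_stop`,
#'   `clone_id`): a fragment interval in 1-based inclusive residue
#'   coordinates.
#' @export
to_residue_interval <- function(record, orf) {
  if (classify_frame(record, orf) != "IF") {
    stop_usage("cannot project an out-of-frame clone onto residues")
  }
  s <- max(as.integer(record$nt_start), orf$cds_start)
  e <- min(as.integer(record$nt_stop), orf$cds_stop)
  n_codons <- (e - s + 1L) %/% 3L
  if (n_codons < 1L) {
    stop_validation(sprintf(
      "clone '%s' encodes no complete codon after clamping to the CDS",
      record$clone_id %||% "?"
    ))
  }
  aa_start <- (s - orf$cds_start) %/% 3L + 1L
  data.frame(
    orf_id = orf$id,
    aa_start = aa_start,
    aa_stop = aa_start + n_codons - 1L,
    clone_id = as.character(record$clone_id %||% NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Map a whole screen onto a reference set
#'
#' Matches each clone to a reference (by accession, then by prey name),
#' recomputes its reading frame from the coordinates and projects every
#' in-frame sense clone into residue space. Out-of-frame and antisense
#' clones are kept in the annotated record table (they count in totals) but
#' yield no fragment interval, so they never shape a SID.
#'
#' @param screen A [screen_table()].
#' @param references A [reference_orfs()] set.
#' @return List with `records` (annotated clone table: `orf_id`, computed
#'   `frame`) and `intervals` (fragment intervals of the IF clones).
#' @export
map_screen <- function(screen, references) {
  rec <- screen$records
  idx <- match(rec$accession, references$accession)
  idx[is.na(idx)] <- match(rec$prey_name, references$id)[is.na(idx)]
  rec$orf_id <- references$id[idx]
  frame <- character(nrow(rec))
  ivs <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (is.na(idx[i])) {
      frame[i] <- rec$frame[i]  # unmatched prey: keep the table's call
      next
    }
    orf <- references[idx[i], , drop = FALSE]
    # clones entirely in a UTR encode nothing of the ORF: report them OOF
    frame[i] <- tryCatch(classify_frame(rec[i, ], orf),
                         sidmap_validation_error = function(e) "OOF")
    if (frame[i] == "IF") {
      ivs[[i]] <- tryCatch(to_residue_interval(rec[i, ], orf),
                           sidmap_validation_error = function(e) NULL)
      if (is.null(ivs[[i]])) frame[i] <- "OOF"  # no complete codon
    }
  }
  rec$frame <- frame
  intervals <- do.call(rbind, ivs[!vapply(ivs, is.null, logical(1))])
  if (is.null(intervals)) {
    intervals <- data.frame(orf_id = character(), aa_start = integer(),
                            aa_stop = integer(), clone_id = character(),
                            stringsAsFactors = FALSE)
  }
  list(records = rec, intervals = intervals)
}

# Maximal exact extension of a seed hit: grow [qs,qe] on the query and
# [rs,re] on the reference while the flanking bases agree.
extend_exact <- function(q, r, qs, qe, rs, re) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  while (qs > 1 && rs > 1 && qc[qs - 1] == rc[rs - 1]) {
    qs <- qs - 1; rs <- rs - 1
  }
  nq <- length(qc); nr <- length(rc)
  while (qe < nq && re < nr && qc[qe + 1] == rc[re + 1]) {
    qe <- qe + 1; re <- re + 1
  }
  c(qs, qe, rs, re)
}

# X-drop ungapped extension scoring +1 match / -1 mismatch, stopping when
# the running score falls `drop` below its maximum; returns the span that
# attained the maximum.
extend_xdrop <- function(q, r, qs, qe, rs, re, drop = 10L) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  best <- qe - qs + 1L; cur <- best
  bqs <- qs; brs <- rs
  i <- qs - 1L; j <- rs - 1L
  while (i >= 1 && j >= 1 && cur > best - drop) {
    cur <- cur + if (qc[i] == rc[j]) 1L else -1L
    if (cur > best) { best <- cur; bqs <- i; brs <- j }
    i <- i - 1L; j <- j - 1L
  }
  qs <- bqs; rs <- brs
  cur <- best; bqe <- qe; bre <- re
  i <- qe + 1L; j <- re + 1L
  nq <- length(qc); nr <- length(rc)
  while (i <= nq && j <= nr && cur > best - drop) {
    cur <- cur + if (qc[i] == rc[j]) 1L else -1L
    if (cur > best) { best <- cur; bqe <- i; bre <- j }
    i <- i + 1L; j <- j + 1L
  }
  c(qs, bqe, rs, bre)
}

#' Place a prey fragment sequence on a reference set
#'
#' Local stand-in for the database search step of a screen analysis: the
#' fragment is seeded onto each reference with non-overlapping 15-mers and
#' extended. `exact_match` extends exactly (longest exact substring
#' placement); `seeded_match` extends ungapped with an X-drop rule, so
#' isolated mismatches do not break a placement. The best placement is the
#' longest; ties break to the lowest `orf_id`, then the lowest `nt_start`.
#' Placements shorter than `policy$min_match_nt` are reported unmapped.
#'
#' @param record_seq Nucleotide string of the insert.
#' @param references A [reference_orfs()] set.
#' @param policy A [mapping_policy()] with mode `exact_match` or
#'   `seeded_match`.
#' @return List `orf_id` (NA if unmapped), `nt_start`, `nt_stop` (reference
#'   forward-strand coordinates), `sense`, `matched_nt`.
#' @export
assign_prey <- function(record_seq, references, policy) {
  if (nrow(references) == 0) stop_usage("empty reference set")
  if (policy$mode == "coordinates") {
    stop_usage("assign_prey requires an alignment mode, not 'coordinates'")
  }
  k <- 15L
  q_fwd <- toupper(record_seq)
  strands <- list(sense = q_fwd)
  if (policy$allow_antisense) {
    strands$antisense <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(q_fwd))
    )
  }
  best <- NULL
  ord <- order(references$id)
  for (ri in ord) {
    r <- references$mrna_seq[ri]
    for (sn in names(strands)) {
      q <- strands[[sn]]
      nq <- nchar(q)
      if (nq < k) next
      seed_starts <- unique(c(seq(1L, nq - k + 1L, by = k), nq - k + 1L))
      for (ss in seed_starts) {
        seed <- substr(q, ss, ss + k - 1L)
        hits <- Biostrings::matchPattern(seed, Biostrings::DNAString(r))
        for (h in seq_along(hits)) {
          rs <- Biostrings::start(hits)[h]
          span <- if (policy$mode == "exact_match") {
            extend_exact(q, r, ss, ss + k - 1L, rs, rs + k - 1L)
          } else {
            extend_xdrop(q, r, ss, ss + k - 1L, rs, rs + k - 1L)
          }
          len <- span[4] - span[3] + 1L
          cand <- list(orf_id = references$id[ri],
                       nt_start = span[3], nt_stop = span[4],
                       sense = sn, matched_nt = len)
          if (is.null(best) || len > best$matched_nt ||
              (len == best$matched_nt &&
               (cand$orf_id < best$orf_id ||
                (cand$orf_id == best$orf_id &&
                 cand$nt_start < best$nt_start)))) {
            best <- cand
          }
        }
      }
    }
  }
  if (is.null(best) || best$matched_nt < policy$min_match_nt) {
    return(list(orf_id = NA_character_, nt_start = NA_integer_,
                nt_stop = NA_integer_, sense = NA_character_,
                matched_nt = if (is.null(best)) 0L else best$matched_nt))
  }
  best
}
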