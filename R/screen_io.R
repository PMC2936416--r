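#' Construct a set of reference ORFs
#'
#' A reference ORF is the coordinate system every prey fragment is mapped
#' onto: an mRNA (or cDNA) sequence together with the 1-based nucleotide
#' positions of its first codon (`cds_start`) and last coding base
#' (`cds_stop`). The stop codon is excluded by convention, so
#' `protein_length == (cds_stop - cds_start + 1) / 3`.
#'
#' @param id Character vector of unique ORF identifiers.
#' @param mrna_seq Character vector of nucleotide sequences (A/C/G/T/N).
#' @param cds_start,cds_stop 1-based inclusive coding-region bounds on the
#'   mRNA. Defaults: the whole record codes (`cds_start = 1`,
#'   `cds_stop = nchar(mrna_seq)`).
#' @param accession Optional accession strings (defaults to `id`).
#' @return A `reference_set`: a data frame with one row per ORF and columns
#'   `id`, `accession`, `mrna_seq`, `cds_start`, `cds_stop`,
#'   `protein_length`.
#' @export
reference_orfs <- function(id, mrna_seq, cds_start = NULL, cds_stop = NULL,
                           accession = NULL) {
  id <- as.character(id)
  mrna_seq <- toupper(as.character(mrna_seq))
  n <- length(id)
  if (length(mrna_seq) != n) {
    stop_usage("`id` and `mrna_seq` must have the same length")
  }
  if (anyDuplicated(id)) stop_validation("duplicate reference ORF ids")
  cds_start <- as.integer(cds_start %||% rep(1L, n))
  cds_stop <- as.integer(cds_stop %||% nchar(mrna_seq))
  refs <- data.frame(
    id = id,
    accession = as.character(accession %||% id),
    mrna_seq = mrna_seq,
    cds_start = cds_start,
    cds_stop = cds_stop,
    protein_length = (cds_stop - cds_start + 1L) %/% 3L,
    stringsAsFactors = FALSE
  )
  validate_reference_set(refs)
  class(refs) <- c("reference_set", "data.frame")
  refs
}

validate_reference_set <- function(refs) {
  len <- nchar(refs$mrna_seq)
  for (i in seq_len(nrow(refs))) {
    if (refs$cds_start[i] < 1L || refs$cds_stop[i] > len[i] ||
        refs$cds_start[i] > refs$cds_stop[i]) {
      stop_validation(sprintf(
        "reference '%s': CDS [%d, %d] outside mRNA of length %d",
        refs$id[i], refs$cds_start[i], refs$cds_stop[i], len[i]
      ))
    }
    span <- refs$cds_stop[i] - refs$cds_start[i] + 1L
    if (span %% 3L != 0L) {
      stop_validation(sprintf(
        "reference '%s': CDS length %d not divisible by 3", refs$id[i], span
      ))
    }
  }
  invisible(refs)
}

#' Read reference ORFs from a FASTA file
#'
#' Without a CDS table each record is taken to be entirely coding and its
#' length must be a multiple of 3. A CDS table (TSV with columns `id`,
#' `cds_start` and optionally `cds_stop`) supplies offsets for records with
#' untranslated ends; when `cds_stop` is absent the coding region is
#' truncated to the last complete codon before the record end.
#'
#' @param path FASTA file.
#' @param cds_table Optional path to the CDS offset TSV.
#' @return A [reference_orfs()] `reference_set`, in file order.
#' @export
read_reference_fasta <- function(path, cds_table = NULL) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop_format(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(seqs) == 0) stop_format(sprintf("no records in FASTA '%s'", path))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_format(sprintf(
      "duplicate record id '%s' in FASTA '%s'", ids[anyDuplicated(ids)], path
    ))
  }
  acc <- vapply(strsplit(headers, "[ \t]+"), function(x) {
    if (length(x) >= 2) x[2] else x[1]
  }, character(1))
  len <- Biostrings::width(seqs)
  cds_start <- rep(1L, length(seqs))
  cds_stop <- as.integer(len)
  if (!is.null(cds_table)) {
    tab <- utils::read.delim(cds_table, stringsAsFactors = FALSE,
                             comment.char = "#", quote = "")
    if (!all(c("id", "cds_start") %in% names(tab))) {
      stop_format("CDS table needs columns 'id' and 'cds_start'")
    }
    hit <- match(tab$id, ids)
    if (anyNA(hit)) {
      stop_format(sprintf("CDS table id '%s' not in FASTA",
                          tab$id[which(is.na(hit))[1]]))
    }
    cds_start[hit] <- as.integer(tab$cds_start)
    if ("cds_stop" %in% names(tab) && !all(is.na(tab$cds_stop))) {
      given <- !is.na(tab$cds_stop)
      cds_stop[hit[given]] <- as.integer(tab$cds_stop[given])
      open <- hit[!given]
    } else {
      open <- hit
    }
    # truncate open-ended CDS to the last complete codon
    cds_stop[open] <- cds_start[open] +
      3L * ((len[open] - cds_start[open] + 1L) %/% 3L) - 1L
  }
  reference_orfs(
    id = ids,
    mrna_seq = as.character(seqs),
    cds_start = cds_start,
    cds_stop = cds_stop,
    accession = acc
  )
}

clone_columns <- c("clone_id", "prey_name", "accession",
                   "nt_start", "nt_stop", "frame", "sense", "pbs")

#' Construct a screen table
#'
#' One retained prey clone per row, mirroring the per-screen supplementary
#' tables of scFv bait screens: prey identity, nucleotide start/stop of the
#' insert, reading frame relative to the source ORF (`IF`/`OOF`), sense of
#' the insert in the prey vector and PBS category (`A`..`F` or `NA`).
#'
#' @param records Data frame with columns `clone_id`, `prey_name`,
#'   `accession`, `nt_start`, `nt_stop`, `frame`, `sense`, `pbs`.
#' @param screen_id,bait_name Screen metadata.
#' @return A `screen_table` object.
#' @export
screen_table <- function(records, screen_id = "screen", bait_name = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(clone_columns, names(records))
  if (length(missing_cols)) {
    stop_format(paste0("missing clone-table column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  records <- records[clone_columns]
  records$nt_start <- as.integer(records$nt_start)
  records$nt_stop <- as.integer(records$nt_stop)
  records$pbs <- as.character(records$pbs)
  bad <- which(records$nt_start > records$nt_stop)
  if (length(bad)) {
    stop_validation(sprintf("row %d: nt_start (%d) > nt_stop (%d)",
                            bad[1], records$nt_start[bad[1]],
                            records$nt_stop[bad[1]]))
  }
  bad <- which(!records$frame %in% c("IF", "OOF"))
  if (length(bad)) {
    stop_validation(sprintf("row %d: frame must be 'IF' or 'OOF'", bad[1]))
  }
  bad <- which(!records$sense %in% c("sense", "antisense"))
  if (length(bad)) {
    stop_validation(sprintf("row %d: sense must be 'sense' or 'antisense'",
                            bad[1]))
  }
  unknown <- !is.na(records$pbs) & !records$pbs %in% c(LETTERS[1:6], "NA")
  if (any(unknown)) {
    warning(sprintf("%d unknown PBS value(s) set to NA (e.g. '%s')",
                    sum(unknown), records$pbs[which(unknown)[1]]),
            call. = FALSE)
    records$pbs[unknown] <- NA_character_
  }
  records$pbs[records$pbs == "NA"] <- NA_character_
  if (anyDuplicated(records$clone_id)) {
    stop_validation(sprintf("duplicate clone_id '%s'",
                            records$clone_id[anyDuplicated(records$clone_id)]))
  }
  structure(
    list(screen_id = as.character(screen_id),
         bait_name = as.character(bait_name),
         records = records),
    class = "screen_table"
  )
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("<screen_table> %s (bait %s): %d clones, %d IF / %d OOF\n",
              x$screen_id, x$bait_name, nrow(x$records),
              sum(x$records$frame == "IF"), sum(x$records$frame == "OOF")))
  invisible(x)
}

#' Read a clone table (TSV)
#'
#' Tab-separated, UTF-8, `#` comment lines ignored. Header must contain
#' `clone_id`, `prey_name`, `accession`, `nt_start`, `nt_stop`, `frame`,
#' `sense`, `pbs`. Metadata comments of the form `# screen_id: X` and
#' `# bait_name: Y` are honoured. Out-of-frame rows are retained (they count
#' in screen totals even though they never support a SID); unknown PBS
#' values become `NA` with a warning.
#'
#' @param path TSV file.
#' @param screen_id,bait_name Override metadata (default: from file comments
#'   or the file name).
#' @return A [screen_table()].
#' @export
read_clone_table <- function(path, screen_id = NULL, bait_name = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s\\s*:", key), lines, value = TRUE)
    if (length(hit)) sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", hit[1]) else NULL
  }
  screen_id <- screen_id %||% meta("screen_id") %||%
    sub("\\.[^.]*$", "", basename(path))
  bait_name <- bait_name %||% meta("bait_name") %||% NA_character_
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 1) stop_format(sprintf("no header line in '%s'", path))
  tab <- utils::read.delim(text = body, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (nrow(tab) > 0 && any(is.na(tab$nt_start) | is.na(tab$nt_stop))) {
    stop_format(sprintf("non-numeric nt coordinates in '%s'", path))
  }
  screen_table(tab, screen_id = screen_id, bait_name = bait_name)
}

#' Write a screen table as TSV
#'
#' Inverse of [read_clone_table()]: the written file round-trips every field
#' bit-exactly, including screen metadata (as `#` comments).
#'
#' @param screen A [screen_table()].
#' @param path Output path.
#' @export
write_clone_table <- function(screen, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# screen_id: %s", screen$screen_id),
    sprintf("# bait_name: %s", screen$bait_name)
  ), con)
  rec <- screen$records
  rec$pbs[is.na(rec$pbs)] <- "NA"
  utils::write.table(rec, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write residue intervals (fragment intervals or SIDs)
#'
#' Residue coordinates are 1-based inclusive everywhere inside the package;
#' BED output is the single place converted to the standard 0-based
#' half-open convention, so a SID spanning residues 13..174 becomes the BED
#' line `orf 12 174`. TSV and JSON keep 1-based inclusive coordinates and a
#' `length` field (`aa_stop - aa_start + 1`).
#'
#' @param intervals Data frame with columns `orf_id`, `aa_start`, `aa_stop`
#'   and optionally `name` (falls back to `clone_id`, then `"SID"`).
#' @param format One of `"tsv"`, `"bed"`, `"json"`.
#' @param path Output path.
#' @export
write_intervals <- function(intervals, format = c("tsv", "bed", "json"), path) {
  if (length(format) != 1 || !format %in% c("tsv", "bed", "json")) {
    stop_usage("format must be one of 'tsv', 'bed', 'json'")
  }
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals) > 0 &&
      !all(c("orf_id", "aa_start", "aa_stop") %in% names(intervals))) {
    stop_usage("intervals need columns orf_id, aa_start, aa_stop")
  }
  nm <- intervals$name %||% intervals$clone_id %||%
    rep("SID", nrow(intervals))
  if (format == "bed") {
    out <- sprintf("%s\t%d\t%d\t%s", intervals$orf_id,
                   as.integer(intervals$aa_start) - 1L,
                   as.integer(intervals$aa_stop), nm)
    writeLines(out, path)
  } else if (format == "tsv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("# coordinates: 1-based inclusive amino-acid positions", con)
    out <- data.frame(orf_id = intervals$orf_id, name = nm,
                      aa_start = as.integer(intervals$aa_start),
                      aa_stop = as.integer(intervals$aa_stop),
                      length = as.integer(intervals$aa_stop) -
                        as.integer(intervals$aa_start) + 1L)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    out <- list(
      coordinates = "1-based inclusive amino-acid positions",
      intervals = data.frame(
        orf_id = intervals$orf_id, name = nm,
        aa_start = as.integer(intervals$aa_start),
        aa_stop = as.integer(intervals$aa_stop),
        length = as.integer(intervals$aa_stop) -
          as.integer(intervals$aa_start) + 1L
      )
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
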