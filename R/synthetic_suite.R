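#' Extract the peptide encoded by a residue interval of a reference ORF
#'
#' @param references A [reference_orfs()] set.
#' @param orf_id Reference id.
#' @param aa_start,aa_stop 1-based inclusive residue bounds.
#' @return Peptide string.
#' @export
orf_peptide <- function(references, orf_id, aa_start, aa_stop) {
  orf <- ref_row(references, orf_id)
  if (aa_start < 1 || aa_stop > orf$protein_length || aa_start > aa_stop) {
    stop_usage("residue interval outside the protein")
  }
  nt <- substr(orf$mrna_seq,
               orf$cds_start + 3L * (aa_start - 1L),
               orf$cds_start + 3L * aa_stop - 1L)
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

# nt coordinates of an in-frame clone covering residues [aa_start, aa_stop]
# on an ORF with cds_start = 1
aa_to_nt <- function(aa_start, aa_stop) {
  c(3L * (aa_start - 1L) + 1L, 3L * aa_stop)
}

suite_clones <- function(prey, acc, aa_start, aa_stop, frame = "IF",
                         sense = "sense") {
  data.frame(prey_name = prey, accession = acc,
             nt_start = 3L * (aa_start - 1L) + 1L + ifelse(frame == "OOF", 1L, 0L),
             nt_stop = 3L * aa_stop,
             frame = frame, sense = sense, pbs = NA_character_,
             stringsAsFactors = FALSE)
}

# n clones whose residue intervals all contain [sid_lo, sid_hi], with both
# SID boundaries attained so the cluster intersection is exactly the SID
containing_clones <- function(prey, acc, sid_lo, sid_hi, n, prot_len,
                              max_flank = 120L) {
  starts <- pmax(1L, sid_lo - sample.int(max_flank, n, replace = TRUE) + 1L)
  stops <- pmin(prot_len, sid_hi + sample.int(max_flank, n, replace = TRUE) - 1L)
  starts[1] <- sid_lo
  stops[min(2L, n)] <- sid_hi
  suite_clones(prey, acc, starts, stops)
}

scatter_clones <- function(prey, acc, n, prot_len, n_oof = 0L) {
  starts <- sample.int(max(1L, prot_len - 80L), n, replace = TRUE)
  stops <- pmin(prot_len, starts + sample(40:200, n, replace = TRUE))
  frame <- rep("IF", n)
  if (n_oof > 0) frame[seq_len(n_oof)] <- "OOF"
  suite_clones(prey, acc, starts, stops, frame = frame)
}

#' Synthetic suite of published-scale scFv screens
#'
#' A fully synthetic reference set and five screen tables whose summary
#' structure matches the screens of the anti-Rab6 (AA2), anti-Rab1 (ROF7),
#' anti-giantin (TA10) and anti-myosin (SF9) scFv baits: clone totals of
#' 3 / 8 / 191 / 60 / 352; full-core SIDs spanning residues 13-174 of the
#' 208-aa Rab6a and 2-178 of the 205-aa Rab1a; a single 7-clone giantin
#' cluster with a 250-aa SID; and three myosin-homologue SIDs of 35, 33 and
#' 70 residues sharing a 29-residue, >93%-identical common block. All
#' sequences are random-codon stand-ins (the three myosins share a designed
#' 120-residue tail window); no real accession is reproduced.
#'
#' @param seed Internal RNG seed fixing the suite (default 59).
#' @return List with `references` ([reference_orfs()]), `screens` (named
#'   list of [screen_table()]), `artifacts` (known-artifact gene ids) and
#'   `registry` (screen x gene table for connectivity flagging).
#' @export
synthetic_screen_suite <- function(seed = 59L) {
  with_seed(seed, {
    lens <- c(
      RAB6A = 208L, RAB6B = 208L, RAB6_DM = 208L,
      RAB1A = 205L, RAB1B = 201L,
      GOLGB1 = 3259L,
      MYH9 = 1960L, MYH10 = 1976L, MYH11 = 1938L,
      HSBG01 = 650L, HSBG02 = 540L, HSBG03 = 430L, HSBG04 = 380L,
      HSBG05 = 520L, HSBG06 = 610L,
      DMBG01 = 450L, DMBG02 = 360L, DMBG03 = 560L
    )
    seqs <- vapply(lens, function(l) {
      paste(sample(codons_no_stop, l, replace = TRUE), collapse = "")
    }, character(1))

    # shared 120-codon myosin tail window; one substitution each inside the
    # future 29-residue common block (window positions 36..64)
    win <- list(MYH9 = 1611L, MYH10 = 1617L, MYH11 = 1582L)
    w_codons <- sample(codons_no_stop, 120L, replace = TRUE)
    sub_codon <- function(codons, pos) {
      aa_of <- function(cd) as.character(
        Biostrings::translate(Biostrings::DNAString(cd))
      )
      repeat {
        cand <- sample(codons_no_stop, 1)
        if (aa_of(cand) != aa_of(codons[pos])) break
      }
      codons[pos] <- cand
      codons
    }
    windows <- list(
      MYH9 = w_codons,
      MYH10 = sub_codon(w_codons, 45L),
      MYH11 = sub_codon(w_codons, 50L)
    )
    for (g in names(win)) {
      s <- seqs[[g]]
      a <- 3L * (win[[g]] - 1L) + 1L
      substr(s, a, a + 360L - 1L) <- paste(windows[[g]], collapse = "")
      seqs[[g]] <- s
    }

    refs <- reference_orfs(id = names(lens), mrna_seq = unname(seqs))
    stopifnot(identical(unname(refs$protein_length), unname(as.integer(lens))))

    # --- AA2, human library: 3 clones, 2 on Rab6 (67%) ---------------------
    aa2_h <- rbind(
      suite_clones("Rab6", "RAB6A", 13L, 174L),
      suite_clones("Rab6", "RAB6B", 8L, 180L),
      scatter_clones("BG-h01", "HSBG01", 1L, lens[["HSBG01"]])
    )

    # --- AA2, fly library: 8 clones, 4 on dRab6 (50%) ----------------------
    aa2_d <- rbind(
      containing_clones("dRab6", "RAB6_DM", 13L, 174L, 4L, lens[["RAB6_DM"]],
                        max_flank = 13L),
      scatter_clones("BG-d01", "DMBG01", 2L, lens[["DMBG01"]]),
      scatter_clones("BG-d02", "DMBG02", 1L, lens[["DMBG02"]]),
      scatter_clones("BG-d03", "DMBG03", 1L, lens[["DMBG03"]], n_oof = 1L)
    )

    # --- ROF7: 191 clones, 152 on Rab1 (80%), full core 2-178 --------------
    rof7 <- rbind(
      containing_clones("Rab1", "RAB1A", 2L, 178L, 100L, lens[["RAB1A"]],
                        max_flank = 2L),
      containing_clones("Rab1", "RAB1B", 2L, 174L, 52L, lens[["RAB1B"]],
                        max_flank = 2L),
      scatter_clones("BG-h01", "HSBG01", 12L, lens[["HSBG01"]], n_oof = 3L),
      scatter_clones("BG-h02", "HSBG02", 9L, lens[["HSBG02"]], n_oof = 2L),
      scatter_clones("BG-h03", "HSBG03", 7L, lens[["HSBG03"]]),
      scatter_clones("BG-h04", "HSBG04", 6L, lens[["HSBG04"]], n_oof = 1L),
      scatter_clones("BG-h06", "HSBG06", 5L, lens[["HSBG06"]])
    )

    # --- TA10: 60 clones, one 7-clone giantin cluster, 250-aa SID ----------
    g_sid <- c(1399L, 1648L)
    giantin_starts <- c(1399L, 1210L, 1300L, 1350L, 1280L, 1390L, 1340L)
    giantin_stops <- c(1648L, 1700L, 1810L, 1680L, 1750L, 1648L, 1720L)
    ta10 <- rbind(
      suite_clones("giantin", "GOLGB1", giantin_starts, giantin_stops),
      scatter_clones("BG-h01", "HSBG01", 12L, lens[["HSBG01"]], n_oof = 3L),
      scatter_clones("BG-h02", "HSBG02", 10L, lens[["HSBG02"]], n_oof = 2L),
      scatter_clones("BG-h03", "HSBG03", 9L, lens[["HSBG03"]]),
      scatter_clones("BG-h04", "HSBG04", 8L, lens[["HSBG04"]], n_oof = 2L),
      scatter_clones("BG-h05", "HSBG05", 8L, lens[["HSBG05"]]),
      scatter_clones("BG-h06", "HSBG06", 6L, lens[["HSBG06"]], n_oof = 1L)
    )

    # --- SF9: 352 clones; myosin SIDs of 35/33/70 aa -----------------------
    sf9 <- rbind(
      containing_clones("MYH9", "MYH9", 1640L, 1674L, 196L, lens[["MYH9"]]),
      containing_clones("MYH10", "MYH10", 1652L, 1684L, 55L, lens[["MYH10"]]),
      containing_clones("MYH11", "MYH11", 1591L, 1660L, 61L, lens[["MYH11"]]),
      scatter_clones("BG-h01", "HSBG01", 14L, lens[["HSBG01"]], n_oof = 4L),
      scatter_clones("BG-h02", "HSBG02", 10L, lens[["HSBG02"]], n_oof = 2L),
      scatter_clones("BG-h05", "HSBG05", 9L, lens[["HSBG05"]]),
      scatter_clones("BG-h06", "HSBG06", 7L, lens[["HSBG06"]], n_oof = 1L)
    )

    finish <- function(df, screen_id, bait) {
      df$clone_id <- sprintf("%s-%03d", screen_id, seq_len(nrow(df)))
      screen_table(df, screen_id = screen_id, bait_name = bait)
    }
    screens <- list(
      AA2_human = finish(aa2_h, "AA2h", "AA2"),
      AA2_fly = finish(aa2_d, "AA2d", "AA2"),
      ROF7 = finish(rof7, "ROF7", "ROF7"),
      TA10 = finish(ta10, "TA10", "TA10"),
      SF9 = finish(sf9, "SF9", "SF9")
    )

    registry <- do.call(rbind, lapply(names(screens), function(nm) {
      sc <- screens[[nm]]
      data.frame(screen_id = nm,
                 orf_id = unique(sc$records$accession),
                 stringsAsFactors = FALSE)
    }))
    list(references = refs, screens = screens,
         artifacts = "HSBG06", registry = registry)
  })
}
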