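# Independent brute-force oracles; deliberately naive residue-by-residue
# scans, sharing no code with the package implementation.

# SID of a set of fragment intervals: residues covered by all members, or
# failing that the leftmost longest run of residues at maximal coverage.
sid_oracle <- function(aa_start, aa_stop) {
  n <- length(aa_start)
  residues <- min(aa_start):max(aa_stop)
  depth <- sapply(residues, function(r) sum(aa_start <= r & r <= aa_stop))
  target <- if (max(depth) == n) n else max(depth)
  at <- depth == target
  # leftmost run at maximal depth
  first <- which(at)[1]
  last <- first
  while (last < length(at) && at[last + 1]) last <- last + 1
  list(aa_start = residues[first],
       aa_stop = residues[last],
       support = target, complete = max(depth) == n)
}

# P(all n intervals share a residue) by full enumeration with an explicit
# residue membership check.
overlap_oracle <- function(lengths, L) {
  S <- L - lengths + 1L
  combos <- expand.grid(lapply(S, seq_len))
  hit <- 0
  for (i in seq_len(nrow(combos))) {
    starts <- as.integer(combos[i, ])
    shared <- FALSE
    for (r in 1:L) {
      if (all(starts <= r & r <= starts + lengths - 1L)) { shared <- TRUE; break }
    }
    if (shared) hit <- hit + 1
  }
  hit / nrow(combos)
}

# Upper binomial tail by direct summation.
binom_tail_oracle <- function(k, N, p) {
  sum(sapply(k:N, function(j) choose(N, j) * p^j * (1 - p)^(N - j)))
}

# Remaining-region oracle for tiling deconvolution: residue sets.
narrow_oracle <- function(pos, neg) {
  inter <- Reduce(intersect, lapply(seq_len(nrow(pos)),
                                    function(i) pos$aa_start[i]:pos$aa_stop[i]))
  if (nrow(neg) > 0) {
    bad <- unlist(lapply(seq_len(nrow(neg)),
                         function(i) neg$aa_start[i]:neg$aa_stop[i]))
    inter <- setdiff(inter, bad)
  }
  inter
}

tiny_refs <- function() {
  reference_orfs(
    id = c("ORF1", "ORF2"),
    mrna_seq = c(
      paste(rep("ATGGCTGCA", 8), collapse = ""),      # 24 codons
      paste0("GGGGG", paste(rep("ATGGCTGCA", 4), collapse = ""), "TT")
    ),
    cds_start = c(1L, 6L),
    cds_stop = c(72L, 41L)
  )
}

make_intervals <- function(orf_id, aa_start, aa_stop,
                           clone_id = sprintf("c%02d", seq_along(aa_start))) {
  data.frame(orf_id = orf_id, aa_start = as.integer(aa_start),
             aa_stop = as.integer(aa_stop), clone_id = clone_id,
             stringsAsFactors = FALSE)
}

make_screen <- function(prey, acc, nt_start, nt_stop, frame = "IF",
                        sense = "sense", pbs = NA_character_,
                        screen_id = "t") {
  screen_table(data.frame(
    clone_id = sprintf("%s-%02d", screen_id, seq_along(nt_start)),
    prey_name = prey, accession = acc,
    nt_start = nt_start, nt_stop = nt_stop,
    frame = frame, sense = sense, pbs = pbs,
    stringsAsFactors = FALSE
  ), screen_id = screen_id)
}

# Tiling-call simulation used by the narrowing properties: the tiled region
# (smallest positive prey clone) is a baseline positive; tiles are positive
# iff they contain the epitope, negative iff disjoint from it, and
# boundary-straddling tiles are excluded as uninterpretable hard calls.
simulate_tiling_calls <- function(region, epitope, n_tiles = 17L, seed = 1L) {
  tiles <- design_tiling(region, n_tiles = n_tiles, seed = seed)
  contains <- tiles$aa_start <= epitope[1] & tiles$aa_stop >= epitope[2]
  disjoint <- tiles$aa_stop < epitope[1] | tiles$aa_start > epitope[2]
  keep <- contains | disjoint
  rbind(
    data.frame(orf_id = region$orf_id, aa_start = region$aa_start,
               aa_stop = region$aa_stop, outcome = "positive",
               stringsAsFactors = FALSE),
    data.frame(orf_id = tiles$orf_id[keep], aa_start = tiles$aa_start[keep],
               aa_stop = tiles$aa_stop[keep],
               outcome = ifelse(contains[keep], "positive", "negative"),
               stringsAsFactors = FALSE)
  )
}
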