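#' Null model for the confidence score
#'
#' Under the null, retained clones are drawn independently with per-gene
#' probability proportional to coding length (longer ORFs present more
#' fragment starts to the bait), and fragment placements are uniform. The
#' confidence score of a prey gene combines how many independent fragments
#' it collected against this competition and how improbably those fragments
#' all share residues.
#'
#' @param references A [reference_orfs()] set (defines gene weights and the
#'   gene count `G`).
#' @param n_clones Total retained clones `N` in the screen.
#' @param mc_draws Monte-Carlo sample size for the overlap probability
#'   (>= 1000).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return A `null_model` list: `w` (named weights summing to 1), `N`, `G`,
#'   `mc_draws`, `seed`, `protein_length` (named).
#' @export
null_model <- function(references, n_clones, mc_draws = 10000L, seed = NULL) {
  if (!is_count(n_clones) || n_clones < 1) stop_usage("n_clones must be >= 1")
  if (!is_count(mc_draws) || mc_draws < 1000) {
    stop_usage("mc_draws must be an integer >= 1000")
  }
  w <- references$protein_length / sum(references$protein_length)
  names(w) <- references$id
  stopifnot(abs(sum(w) - 1) < 1e-9)
  pl <- references$protein_length
  names(pl) <- references$id
  structure(list(w = w, N = as.integer(n_clones),
                 G = nrow(references), mc_draws = as.integer(mc_draws),
                 seed = seed, protein_length = pl),
            class = "null_model")
}

#' Count independent fragments of a cluster
#'
#' In a random-primed library, clones sharing the same 5' start are likely
#' replication/PCR duplicates of one priming event, so independence is
#' proxied by the number of distinct `aa_start` values.
#'
#' @param members Fragment-interval data frame.
#' @return Integer count.
#' @export
count_independent <- function(members) {
  length(unique(members$aa_start))
}

#' Probability that random fragments share a common residue
#'
#' Null probability that `n` intervals of the given lengths, with starts
#' uniform on `1..L - l + 1`, all share at least one residue. Solved by
#' exhaustive enumeration of start combinations when the state space is at
#' most 1e6, otherwise by Monte Carlo (Laplace-smoothed so the estimate is
#' strictly positive). A single fragment trivially overlaps itself
#' (probability 1).
#'
#' @param lengths Interval lengths (residues), each <= `L`.
#' @param L Protein length of the gene.
#' @param mc_draws Monte-Carlo sample size.
#' @param seed RNG seed (Monte-Carlo branch only).
#' @return Probability in (0, 1].
#' @export
overlap_probability <- function(lengths, L, mc_draws = 10000L, seed = NULL) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1) stop_usage("need at least one length")
  if (any(lengths < 1)) stop_validation("interval lengths must be >= 1")
  if (any(lengths > L)) {
    stop_validation(sprintf("interval length %d exceeds protein length %d",
                            max(lengths), L))
  }
  n <- length(lengths)
  if (n == 1) return(1.0)
  S <- L - lengths + 1L
  if (prod(as.numeric(S)) <= 1e6) {
    grid <- as.matrix(expand.grid(lapply(S, seq_len)))
    ends <- sweep(grid, 2, lengths - 1L, `+`)
    hits <- apply(grid, 1, max) <= apply(ends, 1, min)
    return(mean(hits))
  }
  with_seed(seed, {
    starts <- vapply(S, function(s) sample.int(s, mc_draws, replace = TRUE),
                     integer(mc_draws))
    ends <- sweep(starts, 2, lengths - 1L, `+`)
    hits <- sum(apply(starts, 1, max) <= apply(ends, 1, min))
    (hits + 1) / (mc_draws + 2)
  })
}

#' Score one prey-gene cluster under the null model
#'
#' The count term is the exact upper binomial tail
#' `p_count = P(X >= n_d)`, `X ~ Binomial(N, w_g)`, with `n_d` the number of
#' independent fragments. The placement term `p_overlap` is the probability
#' that the `n_d` representative fragments (longest per distinct start)
#' would share a residue by chance. The e-value Bonferroni-scales their
#' product over the `G` reference genes:
#' `evalue = G * p_count * p_overlap`.
#'
#' @param cluster One element of [cluster_fragments()] output.
#' @param null A [null_model()].
#' @return List `orf_id`, `n_independent`, `p_count`, `p_overlap`, `evalue`.
#' @export
score_gene <- function(cluster, null) {
  g <- cluster$orf_id
  if (!g %in% names(null$w)) {
    stop_usage(sprintf("gene '%s' absent from the null model's reference set", g))
  }
  m <- cluster$members
  n_d <- count_independent(m)
  # longest fragment per distinct 5' start represents that priming event
  reps <- do.call(rbind, lapply(split(m, m$aa_start), function(d) {
    d[which.max(d$aa_stop - d$aa_start), , drop = FALSE]
  }))
  p_count <- stats::pbinom(n_d - 1L, null$N, null$w[[g]], lower.tail = FALSE)
  p_overlap <- overlap_probability(
    reps$aa_stop - reps$aa_start + 1L,
    L = null$protein_length[[g]],
    mc_draws = null$mc_draws, seed = null$seed
  )
  list(orf_id = g, n_independent = n_d, p_count = p_count,
       p_overlap = p_overlap, evalue = null$G * p_count * p_overlap)
}

#' Assign a PBS category
#'
#' Precedence: `F` for genes on the experimentally-proven artifact registry;
#' `E` for highly connected prey (connectivity index >= `tau`); `D` for
#' singletons (`n_d == 1`, no independent corroboration regardless of
#' e-value); then thresholds on the e-value: `A` if `<= tA`, `B` if `<= tB`,
#' `C` if `<= tC`, else `D`. Category A is the most likely specific
#' interaction.
#'
#' @param orf_id Gene id.
#' @param n_d Independent-fragment count.
#' @param evalue The gene's e-value.
#' @param artifacts Character vector of known-artifact gene ids.
#' @param connectivity Named numeric vector: per-gene fraction of screens in
#'   a multi-screen registry that retained the gene.
#' @param thresholds Numeric `c(tA, tB, tC)`, strictly increasing.
#' @param tau Connectivity threshold for category E.
#' @return One of `"A".."F"`.
#' @export
assign_category <- function(orf_id, n_d, evalue,
                            artifacts = character(),
                            connectivity = numeric(),
                            thresholds = c(1e-10, 1e-5, 1e-2),
                            tau = 0.25) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    stop_usage("thresholds must be three increasing values tA < tB < tC")
  }
  if (orf_id %in% artifacts) return("F")
  conn <- if (orf_id %in% names(connectivity)) connectivity[[orf_id]] else 0
  if (conn >= tau) return("E")
  if (n_d == 1) return("D")
  if (evalue <= thresholds[1]) return("A")
  if (evalue <= thresholds[2]) return("B")
  if (evalue <= thresholds[3]) return("C")
  "D"
}

#' Connectivity index from a multi-screen registry
#'
#' Prey domains retained across many unrelated screens are likely sticky
#' rather than specific. The index is, per gene, the fraction of distinct
#' screens in the registry that retained it.
#'
#' @param registry Data frame with columns `screen_id` and `orf_id` (or
#'   `gene`).
#' @return Named numeric vector in `[0, 1]`.
#' @export
connectivity_index <- function(registry) {
  if (!"orf_id" %in% names(registry) && "gene" %in% names(registry)) {
    registry$orf_id <- registry$gene
  }
  if (!all(c("screen_id", "orf_id") %in% names(registry))) {
    stop_format("registry needs columns screen_id and orf_id")
  }
  n_screens <- length(unique(registry$screen_id))
  tab <- tapply(registry$screen_id, registry$orf_id,
                function(s) length(unique(s)))
  out <- as.numeric(tab) / n_screens
  names(out) <- names(tab)
  out
}

#' Score every clustered gene of a mapped screen
#'
#' @param intervals Fragment intervals ([map_screen()] output).
#' @param references A [reference_orfs()] set.
#' @param n_clones Total retained clones of the screen (all categories).
#' @inheritParams assign_category
#' @param mc_draws,seed Passed to [null_model()].
#' @return Data frame with one row per gene carrying the score ingredients
#'   and the category, sorted by e-value.
#' @export
score_screen <- function(intervals, references, n_clones,
                         artifacts = character(), connectivity = numeric(),
                         thresholds = c(1e-10, 1e-5, 1e-2), tau = 0.25,
                         mc_draws = 10000L, seed = NULL) {
  null <- null_model(references, n_clones, mc_draws = mc_draws, seed = seed)
  clusters <- cluster_fragments(intervals)
  clusters <- Filter(function(cl) cl$orf_id %in% references$id, clusters)
  if (!length(clusters)) {
    return(data.frame(gene = character(), n_independent = integer(),
                      p_count = numeric(), p_overlap = numeric(),
                      evalue = numeric(), category = character(),
                      stringsAsFactors = FALSE))
  }
  # one score per gene: its largest cluster (ties to the leftmost)
  by_gene <- split(clusters, vapply(clusters, `[[`, character(1), "orf_id"))
  rows <- lapply(by_gene, function(cls) {
    sizes <- vapply(cls, function(cl) nrow(cl$members), integer(1))
    sc <- score_gene(cls[[which.max(sizes)]], null)
    data.frame(gene = sc$orf_id, n_independent = sc$n_independent,
               p_count = sc$p_count, p_overlap = sc$p_overlap,
               evalue = sc$evalue,
               category = assign_category(sc$orf_id, sc$n_independent,
                                          sc$evalue, artifacts, connectivity,
                                          thresholds, tau),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$evalue, out$gene), , drop = FALSE]
}
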