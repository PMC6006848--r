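# Small exact quorum planted motif search solver, used to validate motif
# recovery on emitted sample sets, plus ranking and a quorum estimator.

# internal: minimum Hamming distance from motif m to any l-window of each
# sequence (Inf for sequences shorter than l). Vectorized over windows.
min_dists <- function(dataset, m) {
  mc <- seq_to_codes(m)
  l <- length(mc)
  vapply(dataset$seqs, function(s) {
    codes <- seq_to_codes(s)
    L <- length(codes)
    if (L < l) return(Inf)
    mm <- numeric(L - l + 1)
    for (j in seq_len(l)) mm <- mm + (codes[j:(L - l + j)] != mc[j])
    min(mm)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exact quorum planted motif search
#'
#' Finds every l-mer `y` that occurs in at least `ceiling(q t)` sequences
#' with up to `d` mismatches. The solver is exact: for each sequence it
#' enumerates the Hamming d-neighborhood codes of all its l-mers (every
#' motif is by definition a d-neighbor of each of its instances), takes the
#' per-sequence union, and accumulates a support table over the whole
#' `4^l` candidate space; candidates meeting the quorum are reported.
#'
#' Intended for sample-set scale (t up to a few hundred, `l <= 13`,
#' `d <= 3`); a cost estimate guards against larger instances unless
#' `force = TRUE`.
#'
#' @param dataset a [sam_dataset].
#' @param l,d motif length and mismatch allowance.
#' @param q quorum fraction in (0, 1].
#' @param force run even when the cost guard would refuse.
#' @return data frame of class `motif_results` with columns `motif`,
#'   `support` (sequences containing an occurrence within d),
#'   `total_min_dist` (sum of per-supporting-sequence minimum distances)
#'   and `rank`. Ordered by support descending, then total_min_dist
#'   ascending, then lexicographically.
#' @export
solve_qpms <- function(dataset, l, d, q, force = FALSE) {
  stopifnot(inherits(dataset, "sam_dataset"))
  if (!(d >= 0 && d < l)) stop("need 0 <= d < l")
  if (q <= 0 || q > 1) stop("need 0 < q <= 1")
  n_windows <- sum(pmax(0, nchar(dataset$seqs) - l + 1))
  ball <- sum(choose(l, 0:d) * 3^(0:d))
  est_ops <- n_windows * ball + 4^l
  if (!force && (l > 13 || d > 3 || est_ops > 5e8)) {
    stop("solve_qpms: instance too large (estimated ", format(est_ops),
         " operations for t=", dataset$t, ", l=", l, ", d=", d,
         "); use force = TRUE to override")
  }
  quorum <- ceiling(q * dataset$t)
  support <- integer(4^l)
  pats <- mismatch_patterns(l, d)
  for (s in dataset$seqs) {
    codes <- seq_to_codes(s)
    wc <- window_codes(codes, l)
    if (length(wc) == 0) next
    neigh <- vector("list", length(pats) + 1L)
    neigh[[1]] <- wc
    for (pi in seq_along(pats)) {
      p <- pats[[pi]]
      nc <- wc
      for (j in seq_along(p$pos)) {
        pw <- 4^(p$pos[j] - 1)
        old <- (wc %/% pw) %% 4
        nc <- nc + (((old + p$delta[j]) %% 4) - old) * pw
      }
      neigh[[pi + 1L]] <- nc
    }
    u <- unique(unlist(neigh, use.names = FALSE))
    support[u + 1] <- support[u + 1] + 1L
  }
  hits <- which(support >= quorum) - 1
  if (length(hits) == 0) {
    res <- data.frame(motif = character(0), support = integer(0),
                      total_min_dist = numeric(0), rank = integer(0))
    class(res) <- c("motif_results", "data.frame")
    return(res)
  }
  motifs <- vapply(hits, stn_inverse, character(1), width = l)
  tmd <- vapply(motifs, function(m) {
    md <- min_dists(dataset, m)
    sum(md[md <= d])
  }, numeric(1), USE.NAMES = FALSE)
  o <- order(-support[hits + 1], tmd, motifs)
  res <- data.frame(motif = motifs[o], support = support[hits + 1][o],
                    total_min_dist = tmd[o], rank = seq_along(o))
  class(res) <- c("motif_results", "data.frame")
  res
}

#' Rank of a motif among solver results
#'
#' @param results a `motif_results` data frame from [solve_qpms()].
#' @param m an l-mer.
#' @return the 1-based rank of `m`, or `NA_integer_` if `m` was not
#'   reported.
#' @export
rank_of <- function(results, m) {
  i <- match(m, results$motif)
  if (is.na(i)) NA_integer_ else as.integer(results$rank[i])
}

#' Estimate the quorum of a known motif in a dataset
#'
#' Scans every sequence for an occurrence of `m` within `d` mismatches;
#' `Q` is the number of sequences with at least one such occurrence and
#' `q_hat = Q / t`. Because background sequences contain chance
#' near-occurrences, `q_hat` upper-bounds the true proportion of
#' motif-bearing sequences.
#'
#' @param dataset a [sam_dataset].
#' @param m the motif l-mer.
#' @param d mismatch allowance.
#' @return list with `Q` (integer) and `q_hat` (`Q / t`).
#' @export
estimate_q <- function(dataset, m, d) {
  stopifnot(inherits(dataset, "sam_dataset"))
  md <- min_dists(dataset, m)
  Q <- sum(md <= d)
  list(Q = as.integer(Q), q_hat = Q / dataset$t)
}
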