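# Closed-form probabilities and counts used by the selection pipeline.

#' Probability that two random l-mers are within d mismatches
#'
#' `P_d = sum_{i=0}^{d} choose(l, i) * 3^i / 4^l` for the 4-letter DNA
#' alphabet: the chance that two independent uniform l-mers have Hamming
#' distance at most d.
#'
#' @param l motif length.
#' @param d maximum mismatch count, `0 <= d <= l`.
#' @return probability in `[0, 1]`.
#' @examples
#' p_d(9, 2) * 4^9  # 352 Hamming-ball strings
#' @export
p_d <- function(l, d) {
  if (d < 0 || d > l || l < 1) stop("p_d: need 0 <= d <= l, l >= 1")
  i <- 0:d
  sum(choose(l, i) * 3^i) / 4^l
}

#' Probability that a random pattern spans at least qt sequences
#'
#' For a random l-mer pattern, each n-length background sequence contains a
#' window within d mismatches with probability
#' `1 - (1 - P_d)^(n - l + 1)`; spanning at least `ceiling(q t)` of t
#' independent sequences is then a binomial tail. Small q makes the tail —
#' and hence pattern-tree pruning failure in suffix-tree qPMS solvers —
#' large, which is the motivation for sample selection.
#'
#' @param l,d motif length and mismatch allowance.
#' @param t number of sequences; `n` their length; `q` quorum in (0, 1].
#' @return probability in `[0, 1]`, nonincreasing in `q`.
#' @export
p_span <- function(l, d, t, n, q) {
  pd <- p_d(l, d)
  p_hit <- 1 - (1 - pd)^(n - l + 1)
  thr <- ceiling(q * t)
  if (thr <= 0) return(1)
  stats::pbinom(thr - 1, size = t, prob = p_hit, lower.tail = FALSE)
}

#' Number of reference-sequence combinations of an spd qPMS algorithm
#'
#' Sample-pattern-driven solvers enumerate all h-subsets of
#' `t - ceiling(qt) + h` reference sequences; this returns
#' `choose(t - ceiling(qt) + h, h)`.
#'
#' @param t sequence count; `q` quorum; `h` tuple size (>= 1).
#' @return the combination count.
#' @examples
#' n_com(20, 0.5, 2)  # choose(12, 2) = 66
#' @export
n_com <- function(t, q, h) {
  if (h < 1) stop("n_com: h must be >= 1")
  if (q <= 0 || q > 1) stop("n_com: q must be in (0, 1]")
  choose(t - ceiling(q * t) + h, h)
}

#' Expected mismatch-tolerant counts for background and motif windows
#'
#' Returns the two components of the initial selection threshold `f`:
#' `N_r`, the expected `count_k` of a random background w-mer, and `N_m`,
#' the expected number of motif-derived windows within k mismatches of a
#' window overlapping a motif instance.
#'
#' `N_r = t (n - w + 1) * sum_{i=0}^{k} choose(w, i) 3^i / 4^w`.
#'
#' `N_m` models the per-position disagreement between two windows covering
#' instances of the same motif: the `min(w, l)` instance-overlap positions
#' disagree with probability `beta = min(1, 2 d / l)` (two instances differ
#' from the motif in up to d positions each), and — when `w > l` — the
#' remaining `w - l` flank positions are background and disagree with
#' probability 3/4. `N_m = q t * P(total disagreements <= k)` under that
#' independent-position model. For `w <= l` this is the plain binomial
#' `q t * sum_{i=0}^{k} choose(w, i) beta^i (1 - beta)^(w - i)`.
#'
#' @param w,k window length and mismatch allowance.
#' @param l,d,q motif parameters.
#' @param t,n dataset dimensions.
#' @return named list with components `n_r` and `n_m`.
#' @export
expected_counts <- function(w, k, l, d, q, t, n) {
  if (k < 0 || k >= w) stop("expected_counts: need 0 <= k < w")
  n_r <- t * max(0, n - w + 1) * p_d(w, k)
  beta <- min(1, 2 * d / l)
  m <- min(w, l)       # positions covered by the instance
  fl <- w - m          # background flank positions (w > l only)
  # P(X + Y <= k), X ~ Binom(m, beta), Y ~ Binom(fl, 3/4)
  p_le <- 0
  for (i in 0:k) {
    for (j in 0:(k - i)) {
      if (i <= m && j <= fl) {
        p_le <- p_le + stats::dbinom(i, m, beta) * stats::dbinom(j, fl, 0.75)
      }
    }
  }
  list(n_r = n_r, n_m = q * t * p_le)
}
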