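# Stage 1: exact w-mer counting over a backward-search index, and
# mismatch-tolerant counts count_k(x) by Hamming-neighborhood aggregation.

# internal: stn codes of all w-windows of an integer code vector (A=0..T=3).
# The stn convention (first character least significant) makes this a plain
# weighted sum; codes are exact doubles for w <= 26.
window_codes <- function(codes, w) {
  L <- length(codes)
  if (L < w) return(numeric(0))
  out <- numeric(L - w + 1)
  for (i in seq_len(w)) out <- out + codes[i:(L - w + i)] * 4^(i - 1)
  out
}

# internal: suffix array by prefix doubling (radix order); txt is an integer
# vector, smaller value = lexicographically smaller, out-of-range rank 0.
suffix_array <- function(txt) {
  n <- length(txt)
  if (n == 1) return(1L)
  rk <- match(txt, sort(unique(txt)))
  k <- 1L
  repeat {
    rk2 <- c(rk[-seq_len(min(k, n))], rep(0L, min(k, n)))
    o <- order(rk, rk2, method = "radix")
    key1 <- rk[o]; key2 <- rk2[o]
    changed <- c(TRUE, key1[-1] != key1[-n] | key2[-1] != key2[-n])
    new <- cumsum(changed)
    rk[o] <- new
    if (new[n] == n) break
    k <- 2L * k
  }
  order(rk, method = "radix")
}

#' Backward-search index over a sequence set
#'
#' Builds a suffix array and Burrows-Wheeler transform of the concatenation
#' of all sequences, each followed by a sentinel symbol smaller than every
#' base, together with cumulative per-symbol occurrence counts. Given the
#' suffix-rank interval of strings prefixed by `phi'`, one backward
#' extension step yields the interval for `b . phi'`; the interval width is
#' the exact occurrence count. Sentinels guarantee that no counted
#' occurrence spans two sequences.
#'
#' @param dataset a [sam_dataset].
#' @return an object of class `sam_backward_index`.
#' @seealso [count_exact()], [build_count_table()]
#' @export
build_index <- function(dataset) {
  stopifnot(inherits(dataset, "sam_dataset"))
  pieces <- lapply(dataset$seqs, function(s) c(seq_to_codes(s) + 1L, 0L))
  txt <- unlist(pieces, use.names = FALSE)
  n <- length(txt)
  sa <- suffix_array(txt)
  bwt <- txt[ifelse(sa == 1L, n, sa - 1L)]
  # occ[i + 1, c]: occurrences of symbol c in bwt[1..i]
  occ <- vapply(1:4, function(c) cumsum(bwt == c), numeric(n))
  occ <- rbind(0, occ)
  # C[c]: number of text symbols strictly smaller than c (sentinel = 0)
  cnt <- tabulate(txt + 1L, nbins = 5L)
  C <- c(cnt[1], cnt[1] + cumsum(cnt[2:4]))
  structure(list(n = n, C = C, occ = occ, sa = sa,
                 n_seq = dataset$t,
                 total_bases = sum(nchar(dataset$seqs))),
            class = "sam_backward_index")
}

# internal: one backward-extension step; interval is c(lo, hi) over suffix
# ranks (1-based), symbol b in 1:4. Returns c(lo', hi') (empty if lo' > hi').
backward_step <- function(index, interval, b) {
  lo <- index$C[b] + index$occ[interval[1], b] + 1
  hi <- index$C[b] + index$occ[interval[2] + 1, b]
  c(lo, hi)
}

#' Exact occurrence count of a string via backward search
#'
#' Traverses the characters of `y` right to left, narrowing the suffix-rank
#' interval one symbol at a time; the final interval width is the number of
#' occurrences of `y` across all sequences.
#'
#' @param index a [build_index()] result.
#' @param y DNA string.
#' @return integer occurrence count (0 if absent).
#' @export
count_exact <- function(index, y) {
  stopifnot(inherits(index, "sam_backward_index"))
  iv <- c(1, index$n)
  cods <- seq_to_codes(y) + 1L
  for (b in rev(cods)) {
    iv <- backward_step(index, iv, b)
    if (iv[1] > iv[2]) return(0L)
  }
  as.integer(iv[2] - iv[1] + 1)
}

#' Dense table of exact w-mer counts
#'
#' Fills a table of size `4^w` whose entry at index `stn(y)` is the exact
#' occurrence count of the w-mer `y` in the dataset. The table is built by a
#' depth-first search of the complete quadtree of strings of length up to
#' `w` grown by prepending characters (so each node's string is a common
#' suffix of all its descendants), carrying the suffix-rank interval down so
#' every backward extension is a constant-time step and the backward search
#' over a shared suffix runs exactly once. Any node with an empty interval
#' (count 0) prunes its whole subtree.
#'
#' @param index a [build_index()] result.
#' @param w word length, `1 <= w <= 15` (the table has `4^w` entries).
#' @return object of class `count_table`: list with `w`, `values`
#'   (integer vector of length `4^w`) and `total` (sum of all entries).
#' @export
build_count_table <- function(index, w) {
  stopifnot(inherits(index, "sam_backward_index"))
  if (w < 1 || w > 15) stop("build_count_table: need 1 <= w <= 15")
  values <- integer(4^w)
  C <- index$C; occ <- index$occ
  rec <- function(lo, hi, depth, val) {
    if (depth == w) {
      values[val + 1] <<- as.integer(hi - lo + 1)
      return(invisible(NULL))
    }
    for (b in 1:4) {                      # A,C,G,T in ascending code order
      lo2 <- C[b] + occ[lo, b] + 1
      hi2 <- C[b] + occ[hi + 1, b]
      if (lo2 <= hi2) rec(lo2, hi2, depth + 1L, (b - 1) + 4 * val)
    }
  }
  rec(1, index$n, 0L, 0)
  structure(list(w = as.integer(w), values = values,
                 total = sum(as.numeric(values))),
            class = "count_table")
}

#' Dense w-mer count table by direct window tallying
#'
#' Produces a table bit-identical to [build_count_table()] by encoding every
#' window with a rolling stn code and tabulating. This is the fast path used
#' by the selection pipeline; the quadtree construction over the backward
#' index is the reference it is checked against.
#'
#' @param dataset a [sam_dataset].
#' @param w word length, `1 <= w <= 15`.
#' @return a `count_table`.
#' @export
scan_count_table <- function(dataset, w) {
  stopifnot(inherits(dataset, "sam_dataset"))
  if (w < 1 || w > 15) stop("scan_count_table: need 1 <= w <= 15")
  all_codes <- unlist(lapply(dataset$seqs, function(s) {
    window_codes(seq_to_codes(s), w)
  }), use.names = FALSE)
  values <- tabulate(as.integer(all_codes) + 1L, nbins = 4^w)
  structure(list(w = as.integer(w), values = values,
                 total = sum(as.numeric(values))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: w =", x$w, ",", sum(x$values > 0), "distinct w-mers,",
      "total windows =", x$total, "\n")
  invisible(x)
}

#' Mismatch-tolerant count of a single w-mer
#'
#' `count_k(x) = sum_{y in B_k(x)} count(y)`: the number of w-length
#' windows in the dataset within Hamming distance `k` of `x`, obtained by
#' `|B_k(x)|` table lookups.
#'
#' @param table a `count_table`.
#' @param x DNA string of length `table$w`.
#' @param k mismatch allowance, `0 <= k < nchar(x)`.
#' @return integer count.
#' @export
count_with_mismatches <- function(table, x, k) {
  stopifnot(inherits(table, "count_table"))
  if (nchar(x) != table$w) stop("count_with_mismatches: |x| must equal table w")
  if (k < 0 || k >= nchar(x)) stop("count_with_mismatches: need 0 <= k < |x|")
  sum(table$values[stn(neighbors(x, k)) + 1])
}

# internal: mutation patterns for exact-Hamming-distance code arithmetic.
# Returns a list of (positions, deltas) pairs covering all strings at
# Hamming distance 1..k; positions are 1-based digit indices.
mismatch_patterns <- function(w, k) {
  pats <- list()
  if (k < 1) return(pats)
  for (size in seq_len(k)) {
    for (ps in utils::combn(w, size, simplify = FALSE)) {
      subs <- as.matrix(expand.grid(rep(list(1:3), size)))
      for (r in seq_len(nrow(subs))) {
        pats[[length(pats) + 1L]] <- list(pos = ps, delta = subs[r, ])
      }
    }
  }
  pats
}

#' Mismatch-tolerant counts of every window in the dataset
#'
#' For each sequence and each 0-based window start, the `count_k` of the
#' window, computed by table lookups over the whole Hamming neighborhood.
#' The neighborhood enumeration is vectorized over windows: each mutation
#' pattern (position set plus substitutions) is applied to all window codes
#' at once by digit arithmetic on the stn encoding.
#'
#' @param dataset the dataset the table was built from.
#' @param table a `count_table` built from `dataset`.
#' @param k mismatch allowance.
#' @return list (one element per sequence) of data frames with columns
#'   `pos` (0-based window start) and `count`. Sequences shorter than `w`
#'   yield empty frames.
#' @export
count_all_windows <- function(dataset, table, k) {
  stopifnot(inherits(dataset, "sam_dataset"), inherits(table, "count_table"))
  w <- table$w
  if (k < 0 || k >= w) stop("count_all_windows: need 0 <= k < w")
  vals <- table$values
  pats <- mismatch_patterns(w, k)
  lapply(dataset$seqs, function(s) {
    wc <- window_codes(seq_to_codes(s), w)
    if (length(wc) == 0) {
      return(data.frame(pos = integer(0), count = integer(0)))
    }
    counts <- vals[wc + 1]
    for (p in pats) {
      nc <- wc
      for (j in seq_along(p$pos)) {
        pw <- 4^(p$pos[j] - 1)
        old <- (wc %/% pw) %% 4
        nc <- nc + (((old + p$delta[j]) %% 4) - old) * pw
      }
      counts <- counts + vals[nc + 1]
    }
    data.frame(pos = seq_along(wc) - 1L, count = as.integer(counts))
  })
}
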