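# Planted (l,d) motif dataset generator with a ground-truth sidecar.

#' Generate a planted (l,d) motif dataset
#'
#' Emulates the standard planted-motif simulation protocol: draw `t`
#' i.i.d.-uniform DNA sequences of length `n` and a uniform random l-mer
#' motif `m`; choose `ceiling(q t)` distinct sequences; implant into each a
#' single instance of `m` at a uniform position, overwriting the
#' background. An instance is built by choosing `d` distinct positions of
#' `m` uniformly and mutating each chosen position with probability `g` to
#' a uniformly chosen different base — so the per-instance mismatch count
#' is Binomial(d, g) and never exceeds `d`. Lower `g` means higher motif
#' conservation.
#'
#' Background sequences may still contain chance near-occurrences of `m`;
#' these are left in place, so the effective quorum of the dataset can
#' exceed `q`.
#'
#' @param t number of sequences; `n` sequence length.
#' @param l,d motif length and maximum mismatches (`0 <= d < l < n`).
#' @param q fraction of sequences receiving an implant, in (0, 1].
#' @param g per-selected-position mutation probability in `[0, 1]`.
#' @param seed optional RNG seed; the same seed reproduces the dataset and
#'   truth byte-for-byte.
#' @return list with `dataset` (a [sam_dataset]) and `truth`, a
#'   `planted_truth` list holding `motif` and an `implants` data frame
#'   (`seq_id`, `pos` 0-based, `instance`, `mismatches`).
#' @examples
#' sim <- generate_planted(t = 10, n = 50, l = 9, d = 2, q = 0.5, g = 0.5,
#'                         seed = 1)
#' sim$truth$motif
#' @export
generate_planted <- function(t, n, l, d, q, g, seed = NULL) {
  if (!(d >= 0 && d < l && l < n)) stop("need 0 <= d < l < n")
  if (q <= 0 || q > 1) stop("need 0 < q <= 1")
  if (g < 0 || g > 1) stop("need 0 <= g <= 1")
  with_seed(seed, {
    seq_mat <- matrix(sample.int(4L, t * n, replace = TRUE) - 1L,
                      nrow = t, ncol = n)
    motif_codes <- sample.int(4L, l, replace = TRUE) - 1L
    n_impl <- as.integer(ceiling(q * t))
    chosen <- sort(sample.int(t, n_impl))
    implants <- vector("list", n_impl)
    for (j in seq_len(n_impl)) {
      i <- chosen[j]
      inst <- motif_codes
      mut_pos <- if (d > 0) sample.int(l, d) else integer(0)
      for (p in mut_pos) {
        if (stats::runif(1) < g) {
          inst[p] <- (inst[p] + sample.int(3L, 1)) %% 4L
        }
      }
      pos0 <- sample.int(n - l + 1L, 1) - 1L
      seq_mat[i, (pos0 + 1):(pos0 + l)] <- inst
      implants[[j]] <- list(i = i, pos = pos0, inst = codes_to_seq(inst),
                            mm = sum(inst != motif_codes))
    }
    ids <- sprintf("seq_%04d", seq_len(t))
    seqs <- apply(seq_mat, 1, codes_to_seq)
    truth <- structure(
      list(motif = codes_to_seq(motif_codes),
           implants = data.frame(
             seq_id = ids[vapply(implants, `[[`, integer(1), "i")],
             pos = vapply(implants, `[[`, integer(1), "pos"),
             instance = vapply(implants, `[[`, character(1), "inst"),
             mismatches = vapply(implants, `[[`, integer(1), "mm"))),
      class = "planted_truth")
    list(dataset = sam_dataset(seqs, ids), truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth: motif", x$motif, "implanted in",
      nrow(x$implants), "sequences\n")
  invisible(x)
}

#' Measured proportion of motif-bearing sequences in a sample set
#'
#' The fraction of a sample set's sequences that actually received an
#' implant, judged against the simulator's ground truth. This is the
#' measured counterpart of the declared sample quorum `q'`.
#'
#' @param sample a `sample_set` (see [emit_sample_sets()]) or a character
#'   vector of sequence ids.
#' @param truth a `planted_truth`.
#' @return fraction in `[0, 1]`.
#' @export
measured_q_prime <- function(sample, truth) {
  ids <- if (is.character(sample)) sample else sample$sequence_ids
  if (length(ids) == 0) return(NA_real_)
  mean(ids %in% truth$implants$seq_id)
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `planted_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(motif = truth$motif, implants = truth$implants),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path path written by [write_truth()].
#' @return a `planted_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(motif = x$motif, implants = as.data.frame(x$implants)),
            class = "planted_truth")
}
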