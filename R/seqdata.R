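#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Run code with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL runs the code under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' DNA sequence dataset
#'
#' An ordered collection of named DNA sequences over the alphabet
#' \{A, C, G, T\}. This is the input container for the whole pipeline:
#' `t` is the number of sequences and `n` the nominal (maximum) sequence
#' length. Ragged datasets are allowed; per-sequence loops always use the
#' actual lengths.
#'
#' @param seqs character vector of DNA sequences (case-insensitive).
#' @param ids unique sequence identifiers; defaults to `names(seqs)` or
#'   `seq_1 ... seq_t`.
#' @return an object of class `sam_dataset` with fields `ids`, `seqs`,
#'   `t` (sequence count) and `n` (maximum length).
#' @examples
#' d <- sam_dataset(c(a = "ACGT", b = "GGGTTT"))
#' d$t
#' @export
sam_dataset <- function(seqs, ids = NULL) {
  if (length(seqs) < 1) stop("no sequences")
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("sequence '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T}")
  }
  structure(
    list(ids = ids, seqs = unname(seqs), t = length(seqs),
         n = max(nchar(seqs))),
    class = "sam_dataset"
  )
}

#' @export
print.sam_dataset <- function(x, ...) {
  cat("sam_dataset: t =", x$t, "sequences, n =", x$n, "(max length)\n")
  k <- min(3L, x$t)
  for (i in seq_len(k)) {
    s <- x$seqs[i]
    cat(" ", x$ids[i], ": ",
        if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s, "\n", sep = "")
  }
  if (x$t > k) cat("  ... and", x$t - k, "more\n")
  invisible(x)
}

#' Read a multi-FASTA file into a dataset
#'
#' Sequences are upper-cased on load. Characters outside \{A,C,G,T\} are
#' rejected by default; with `replace_n = TRUE` every ambiguous IUPAC code
#' (N and friends) is replaced by a uniformly random base, which is only
#' appropriate when a downstream method genuinely requires a 4-letter
#' alphabet.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param replace_n replace non-ACGT characters by random bases instead of
#'   erroring.
#' @param seed optional RNG seed used for the replacement draw.
#' @return a [sam_dataset].
#' @export
read_fasta <- function(path, replace_n = FALSE, seed = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(x) == 0) stop("no sequences in '", path, "'")
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (any(grepl("[^ACGTN]", seqs)) && !replace_n) {
    stop("non-ACGT characters in '", path,
         "'; use replace_n = TRUE to randomize ambiguous bases")
  }
  if (replace_n) {
    seqs <- with_seed(seed, {
      vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        amb <- !(ch %in% DNA_BASES)
        if (any(amb)) ch[amb] <- sample(DNA_BASES, sum(amb), replace = TRUE)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    })
  } else if (any(grepl("N", seqs, fixed = TRUE))) {
    stop("'N' characters present; use replace_n = TRUE to randomize them")
  }
  sam_dataset(seqs, ids)
}

#' Write a dataset to a multi-FASTA file
#'
#' Inverse of [read_fasta()]: reading the written file reproduces the
#' dataset (identical ids and sequences).
#'
#' @param dataset a [sam_dataset].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(dataset, path, width = 70L) {
  stopifnot(inherits(dataset, "sam_dataset"))
  x <- Biostrings::DNAStringSet(dataset$seqs)
  names(x) <- dataset$ids
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# internal: string -> integer codes A=0 C=1 G=2 T=3 (vector per character)
seq_to_codes <- function(s) {
  v <- utf8ToInt(s)
  out <- match(v, utf8ToInt("ACGT")) - 1L
  if (anyNA(out)) stop("character outside {A,C,G,T}")
  out
}

codes_to_seq <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

#' Integer encoding of a DNA string
#'
#' Reverses the string, maps A, C, G, T to the 2-bit codes 00, 01, 10, 11
#' and reads the concatenation as an integer. Because of the reversal the
#' first character is the least significant pair of bits, which is what
#' makes rolling window codes cheap. Bijective from length-L strings onto
#' `[0, 4^L)`.
#'
#' @param y character vector of DNA strings, each of length at most 26
#'   (the largest length for which the code is exactly representable in a
#'   double).
#' @return numeric vector of codes.
#' @examples
#' stn("AC")  # reverse -> "CA" -> bits 0100 -> 4
#' @export
stn <- function(y) {
  vapply(y, function(s) {
    n <- nchar(s)
    if (n > 26) stop("stn: string longer than 26 characters")
    sum(seq_to_codes(s) * 4^(seq_len(n) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

# internal inverse of stn for fixed width
stn_inverse <- function(code, width) {
  digits <- (code %/% 4^(seq_len(width) - 1)) %% 4
  codes_to_seq(digits)
}

#' Hamming distance between two equal-length DNA strings
#'
#' @param x,y DNA strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("hamming: length mismatch")
  sum(utf8ToInt(x) != utf8ToInt(y))
}

#' Hamming-ball neighborhood of a DNA string
#'
#' Returns `B_k(x)`, every string of the same length within Hamming
#' distance `k` of `x` (including `x` itself). The size is
#' `sum_{i=0}^{k} choose(|x|, i) * 3^i`.
#'
#' @param x DNA string.
#' @param k maximum number of mismatches, `0 <= k <= nchar(x)`.
#' @return character vector of neighbors (no duplicates).
#' @export
neighbors <- function(x, k) {
  if (k < 0) stop("neighbors: k must be >= 0")
  n <- nchar(x)
  if (k > n) stop("neighbors: k exceeds string length")
  base <- seq_to_codes(x)
  out <- list(codes_to_seq(base))
  if (k >= 1) {
    for (i in seq_len(k)) {
      pos_sets <- utils::combn(n, i, simplify = FALSE)
      for (ps in pos_sets) {
        # each selected position takes one of the 3 alternative bases
        subs <- expand.grid(rep(list(1:3), i))
        for (r in seq_len(nrow(subs))) {
          v <- base
          v[ps] <- (v[ps] + as.integer(subs[r, ])) %% 4L
          out[[length(out) + 1L]] <- codes_to_seq(v)
        }
      }
    }
  }
  unlist(out, use.names = FALSE)
}
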