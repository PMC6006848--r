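# Stage 2: select high-count w-mers, merge overlapping ones into
# high-frequency substrings (set A), enforce the substring cap by
# escalating the threshold f, then segment long substrings via attract
# tables into set A'.

#' High-frequency substring set
#'
#' A data frame of substrings with provenance: `seq_id`, 0-based half-open
#' `start`/`end` coordinates in the source sequence, and the substring
#' `text` itself. Members of both the merged set A and the segmented set
#' A' are represented this way; `text` always equals the source slice.
#'
#' @param seq_id,start,end,text columns as described.
#' @return data frame of class `hf_set`.
#' @export
hf_set <- function(seq_id = character(0), start = integer(0),
                   end = integer(0), text = character(0)) {
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end), text = as.character(text))
  stopifnot(all(df$end - df$start == nchar(df$text)))
  class(df) <- c("hf_set", "data.frame")
  df
}

# internal: accept an hf_set row / hf_set / plain character for text access
hf_texts <- function(x) {
  if (is.character(x)) x else x$text
}

# internal: l-window code matrix of a string (rows = windows, cols = digits)
lmer_windows <- function(text, l) {
  codes <- seq_to_codes(text)
  L <- length(codes)
  if (L < l) stop("substring shorter than l")
  m <- L - l + 1
  W <- matrix(0L, nrow = m, ncol = l)
  for (j in seq_len(l)) W[, j] <- codes[j:(m + j - 1)]
  W
}

#' Minimum inter-substring l-mer distance
#'
#' `dis(phi, phi')` is the minimum Hamming distance between any l-mer of
#' `phi` and any l-mer of `phi'`. It is symmetric and zero iff the two
#' substrings share an l-mer.
#'
#' @param phi,phi2 DNA strings (or single `hf_set` rows) of length >= l.
#' @param l window length.
#' @return integer minimum distance.
#' @export
dis <- function(phi, phi2, l) {
  W1 <- lmer_windows(hf_texts(phi), l)
  W2 <- lmer_windows(hf_texts(phi2), l)
  D <- matrix(0, nrow(W1), nrow(W2))
  for (j in seq_len(l)) D <- D + outer(W1[, j], W2[, j], "!=")
  as.integer(min(D))
}

# internal: all-pairs distance data over a set of substrings.
# W stacks the l-windows of every substring; M[u, c] is the minimum
# distance from window u to substring c; S[c, c'] = dis(c, c').
# Computed in window-column chunks so memory stays bounded.
build_dis_data <- function(texts, l, chunk = 4000L) {
  nS <- length(texts)
  Wl <- lapply(texts, lmer_windows, l = l)
  nwin <- vapply(Wl, nrow, integer(1))
  owner <- rep(seq_len(nS), nwin)
  W <- do.call(rbind, Wl)
  nw <- nrow(W)
  idx <- split(seq_len(nw), owner)
  M <- matrix(Inf, nw, nS)
  for (start in seq(1, nw, by = chunk)) {
    cols <- start:min(nw, start + chunk - 1L)
    D <- matrix(0, nw, length(cols))
    for (j in seq_len(l)) D <- D + outer(W[, j], W[cols, j], "!=")
    oc <- owner[cols]
    for (c in unique(oc)) {
      sel <- which(oc == c)
      cmin <- D[, sel[1]]
      for (s2 in sel[-1]) cmin <- pmin(cmin, D[, s2])
      M[, c] <- pmin(M[, c], cmin)
    }
  }
  S <- matrix(0, nS, nS)
  for (c in seq_len(nS)) {
    rows <- idx[[c]]
    cmin <- M[rows[1], ]
    for (r in rows[-1]) cmin <- pmin(cmin, M[r, ])
    S[c, ] <- cmin
  }
  list(owner = owner, idx = idx, M = M, S = S)
}

#' Pairwise dis matrix of a substring set
#'
#' @param x an `hf_set` or character vector of substrings.
#' @param l window length.
#' @return symmetric integer matrix of [dis()] values.
#' @export
dis_matrix <- function(x, l) {
  texts <- hf_texts(x)
  if (length(texts) == 1) return(matrix(0, 1, 1))
  build_dis_data(texts, l)$S
}

#' Extraction stage configuration
#'
#' @param f_init initial count threshold; `NULL` lets the pipeline derive
#'   it from [expected_counts()] (rounded, at least 1).
#' @param cap maximum number of substrings kept in A before the threshold
#'   is escalated (default 5000).
#' @param overlap_min minimum overlap (characters) for merging two
#'   selected w-mers; `NULL` means `ceiling(w / 2)`.
#' @param extend cut-out extension in characters on each side during
#'   segmentation (default 3).
#' @param step_frac fractional threshold escalation per pass (default 5%,
#'   applied as `f + max(1, ceiling(step_frac * f))`).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(f_init = NULL, cap = 5000L, overlap_min = NULL,
                              extend = 3L, step_frac = 0.05) {
  stopifnot(cap >= 1, extend >= 0, step_frac > 0)
  structure(list(f_init = f_init, cap = as.integer(cap),
                 overlap_min = overlap_min, extend = as.integer(extend),
                 step_frac = step_frac),
            class = "extraction_config")
}

#' Select high-count window positions
#'
#' Keeps, per sequence, the 0-based window starts whose `count_k` strictly
#' exceeds the threshold `f`.
#'
#' @param windows result of [count_all_windows()].
#' @param f nonnegative threshold.
#' @return list of ascending integer position vectors, one per sequence.
#' @export
select_high_frequency <- function(windows, f) {
  if (f < 0) stop("threshold f must be >= 0")
  lapply(windows, function(df) df$pos[df$count > f])
}

#' Merge overlapping selected w-mers into substrings
#'
#' Within one sequence, consecutive selected positions are chained whenever
#' their windows overlap by at least `overlap_min` characters
#' (`p' - p <= w - overlap_min`); a maximal chain becomes one substring
#' from the first window start to the last window end, so a substring can
#' combine more than two windows. Only substrings of length at least `l`
#' are kept. Merging never crosses sequences.
#'
#' @param selected per-sequence ascending position lists (from
#'   [select_high_frequency()]).
#' @param dataset the source [sam_dataset] (for provenance and text).
#' @param w window length; `overlap_min` minimum merge overlap;
#'   `l` minimum kept length.
#' @return an [hf_set] (the set A).
#' @export
merge_overlaps <- function(selected, dataset, w, overlap_min, l) {
  out <- list()
  for (i in seq_along(selected)) {
    pos <- selected[[i]]
    if (length(pos) == 0) next
    gap_ok <- diff(pos) <= (w - overlap_min)
    grp <- cumsum(c(TRUE, !gap_ok))
    for (g in split(pos, grp)) {
      s <- g[1]; e <- g[length(g)] + w
      if (e - s >= l) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = dataset$ids[i], start = s, end = e,
          text = substr(dataset$seqs[i], s + 1, e))
      }
    }
  }
  if (length(out) == 0) return(hf_set())
  df <- do.call(rbind, out)
  hf_set(df$seq_id, df$start, df$end, df$text)
}

#' Extract high-frequency substrings under a size cap
#'
#' Runs selection and merging starting at `f = f_init`; while more than
#' `cap` substrings result, the threshold is escalated by
#' `max(1, ceiling(step_frac * f))` and the pass repeats. Returns the
#' final set A, the final threshold, and the number of passes.
#'
#' @param windows result of [count_all_windows()].
#' @param dataset the source dataset.
#' @param w,l window and motif lengths.
#' @param config an [extraction_config()]; its `f_init` must be set.
#' @return list with `A` (an [hf_set]), `f` (final threshold) and
#'   `passes`. If the selection empties before the cap is met, `A` is
#'   empty and a warning is raised.
#' @export
extract_with_cap <- function(windows, dataset, w, l, config = extraction_config()) {
  f <- config$f_init
  if (is.null(f)) stop("extract_with_cap: config$f_init must be set")
  overlap_min <- if (is.null(config$overlap_min)) ceiling(w / 2) else config$overlap_min
  passes <- 0L
  repeat {
    passes <- passes + 1L
    sel <- select_high_frequency(windows, f)
    A <- merge_overlaps(sel, dataset, w, overlap_min, l)
    if (nrow(A) <= config$cap) {
      if (nrow(A) == 0) {
        warning("extract_with_cap: selection empty at f = ", f)
      }
      return(list(A = A, f = f, passes = passes))
    }
    if (sum(lengths(sel)) == 0) {
      warning("extract_with_cap: selection empty at f = ", f)
      return(list(A = hf_set(), f = f, passes = passes))
    }
    f <- f + max(1, ceiling(config$step_frac * f))
  }
}

#' Attract table of a high-frequency substring
#'
#' For a substring `phi`, the attract table has one entry per l-mer start
#' position of `phi`; entry `i` counts how many other substrings `phi'`
#' have position `i` among their nearest l-mer positions in `phi`, i.e.
#' `i` attains `min_x d_H(phi[i..i+l-1], x')` over the window pairs
#' defining `dis(phi, phi')`. All tied argmin positions are counted.
#' Maxima of the table mark likely motif-instance positions and guide
#' segmentation.
#'
#' @param phi a substring (string or single `hf_set` row).
#' @param others the remaining substrings (`hf_set` or character vector).
#' @param l window length.
#' @return object of class `attract_table`: list with `values` (integer
#'   vector of length `nchar(phi) - l + 1`) and `owner`.
#' @export
build_attract_table <- function(phi, others, l) {
  phi_text <- hf_texts(phi)
  other_texts <- hf_texts(others)
  npos <- nchar(phi_text) - l + 1
  values <- integer(npos)
  if (length(other_texts) > 0) {
    dd <- build_dis_data(c(phi_text, other_texts), l)
    rows <- dd$idx[[1]]
    # per other substring c' (columns 2..), positions matching S[1, c']
    B <- dd$M[rows, -1, drop = FALSE] == matrix(dd$S[1, -1], nrow = length(rows),
                                                ncol = length(other_texts),
                                                byrow = TRUE)
    values <- as.integer(rowSums(B))
  }
  structure(list(values = values, owner = phi_text), class = "attract_table")
}

# internal: recursive segmentation of a region [lo, hi) (0-based, relative
# to the substring) guided by the original attract values restricted to
# window positions fully inside the region. Returns a list of c(start, end)
# pieces clipped to the whole substring.
segment_region <- function(values, lo, hi, l, extend, len) {
  if (hi - lo < l) return(list())
  wpos <- lo:(hi - l)
  istar <- wpos[which.max(values[wpos + 1])]   # leftmost maximum
  piece <- c(max(0, istar - extend), min(len, istar + l + extend))
  c(list(piece),
    segment_region(values, lo, istar, l, extend, len),
    segment_region(values, istar + l, hi, l, extend, len))
}

#' Segment a substring at its attract-table maxima
#'
#' The l-mer at the maximum attract value (leftmost on ties) is cut out and
#' extended by up to `extend` characters on each side (clipped to the
#' substring); the left and right remainders — defined relative to the
#' unextended cut — are segmented recursively while their length is at
#' least `l`, reusing the original table restricted to the remainder's
#' window positions. Long substrings covering two adjacent motifs are thus
#' split into one piece per motif.
#'
#' @param phi substring (string or single `hf_set` row).
#' @param table its [build_attract_table()] result.
#' @param l motif length; `extend` per-side extension (default 3).
#' @return an [hf_set] of pieces (each of length in `[l, l + 2 extend]`),
#'   with source coordinates when `phi` carries provenance.
#' @export
segment <- function(phi, table, l, extend = 3L) {
  phi_text <- hf_texts(phi)
  len <- nchar(phi_text)
  stopifnot(length(table$values) == len - l + 1)
  pieces <- segment_region(table$values, 0L, len, l, extend, len)
  pieces <- pieces[order(vapply(pieces, `[`, numeric(1), 1))]
  rel <- do.call(rbind, pieces)
  if (is.character(phi)) {
    seq_id <- rep("", nrow(rel)); base <- 0L
  } else {
    seq_id <- rep(phi$seq_id, nrow(rel)); base <- phi$start
  }
  hf_set(seq_id, base + rel[, 1], base + rel[, 2],
         substring(phi_text, rel[, 1] + 1, rel[, 2]))
}

#' Build the segmented substring set A'
#'
#' Applies [build_attract_table()] and [segment()] to every member of A,
#' collecting all pieces of length at least `l` with provenance preserved.
#' With a single-member A the attract table is all zero and the leftmost
#' window is cut.
#'
#' All pairwise window distances are computed once for the whole set and
#' the per-substring tables are derived from that shared computation.
#'
#' @param A an [hf_set] (non-empty).
#' @param l motif length; `extend` per-side extension.
#' @return an [hf_set] (the set A').
#' @export
build_A_prime <- function(A, l, extend = 3L) {
  stopifnot(inherits(A, "hf_set"), nrow(A) >= 1)
  nS <- nrow(A)
  atts <- vector("list", nS)
  if (nS == 1) {
    atts[[1]] <- integer(nchar(A$text[1]) - l + 1)
  } else {
    dd <- build_dis_data(A$text, l)
    for (c in seq_len(nS)) {
      rows <- dd$idx[[c]]
      B <- dd$M[rows, -c, drop = FALSE] ==
        matrix(dd$S[c, -c], nrow = length(rows), ncol = nS - 1, byrow = TRUE)
      atts[[c]] <- as.integer(rowSums(B))
    }
  }
  pieces <- lapply(seq_len(nS), function(c) {
    segment(A[c, ], structure(list(values = atts[[c]], owner = A$text[c]),
                              class = "attract_table"), l, extend)
  })
  out <- do.call(rbind, pieces)
  hf_set(out$seq_id, out$start, out$end, out$text)
}

#' Write substring sets as BED-like TSV
#'
#' Serializes one or two substring sets (typically A and the segmented A')
#' for inspection: columns `seq_id`, `start`, `end` (0-based half-open),
#' `text`, `stage`.
#'
#' @param A an [hf_set]; `A_prime` optionally the segmented set.
#' @param path output path.
#' @export
write_hf_tsv <- function(A, path, A_prime = NULL) {
  df <- cbind(as.data.frame(A), stage = "A")
  if (!is.null(A_prime)) {
    df <- rbind(df, cbind(as.data.frame(A_prime), stage = "A'"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
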