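# Independent brute-force oracles and fixture builders shared by the suite.
# All oracles avoid the code paths they check: plain string slicing and
# double loops only.

random_dataset <- function(t, n, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(t), function(i) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  sam_dataset(seqs)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exact occurrence count of y by sliding a window over every sequence
naive_count <- function(dataset, y) {
  w <- nchar(y)
  sum(vapply(dataset$seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(0L)
    sum(vapply(seq_len(L - w + 1), function(i) {
      substr(s, i, i + w - 1) == y
    }, logical(1)))
  }, integer(1)))
}

# dense w-mer tally by substring extraction (independent of window_codes)
naive_table <- function(dataset, w) {
  vals <- integer(4^w)
  for (s in dataset$seqs) {
    L <- nchar(s)
    if (L < w) next
    for (i in seq_len(L - w + 1)) {
      idx <- stn(substr(s, i, i + w - 1)) + 1
      vals[idx] <- vals[idx] + 1L
    }
  }
  vals
}

# count_k(x) by the double loop over all windows testing hamming <= k
naive_count_k <- function(dataset, x, k) {
  w <- nchar(x)
  sum(vapply(dataset$seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(0L)
    sum(vapply(seq_len(L - w + 1), function(i) {
      hamming(substr(s, i, i + w - 1), x) <= k
    }, logical(1)))
  }, integer(1)))
}

# Eq-style dis by the double loop over all l-window pairs
naive_dis <- function(phi, phi2, l) {
  n1 <- nchar(phi) - l + 1
  n2 <- nchar(phi2) - l + 1
  best <- Inf
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      best <- min(best, hamming(substr(phi, i, i + l - 1),
                                substr(phi2, j, j + l - 1)))
    }
  }
  best
}

# attract table recomputed independently: for each other substring find all
# argmin window positions of phi and increment them
naive_attract <- function(phi, others, l) {
  npos <- nchar(phi) - l + 1
  vals <- integer(npos)
  for (o in others) {
    per_pos <- vapply(seq_len(npos), function(i) {
      naive_dis(substr(phi, i, i + l - 1), o, l)
    }, numeric(1))
    hits <- which(per_pos == min(per_pos))
    vals[hits] <- vals[hits] + 1L
  }
  vals
}

# mutate a string at `at` given 1-based positions (deterministic base step)
mutate_at <- function(x, at, step = 1L) {
  codes <- match(strsplit(x, "")[[1]], c("A", "C", "G", "T")) - 1L
  codes[at] <- (codes[at] + step) %% 4L
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

# cluster constructors over the internal representation
new_cluster_for_test <- function(texts, center = 1L) {
  members <- hf_set(paste0("m", seq_along(texts)), 0L, nchar(texts), texts)
  samselect:::new_cluster(members, center)
}

new_cluster_for_test_hf <- function(members, center = 1L) {
  samselect:::new_cluster(members, center)
}
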