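test_that("dis equals the brute-force window-pair minimum", {
  expect_equal(dis("AAAAA", "TTTTT", 5), 5)
  expect_equal(dis("ACGTACG", "ACGTACG", 4), 0)
  set.seed(41)
  for (i in 1:50) {
    a <- random_dna(sample(9:20, 1))
    b <- random_dna(sample(9:20, 1))
    expect_equal(dis(a, b, 9), naive_dis(a, b, 9))
    expect_equal(dis(a, b, 9), dis(b, a, 9))   # symmetry
  }
  expect_error(dis("ACGT", "ACGTACGTA", 9), "shorter")
})

test_that("dis_matrix agrees with pairwise dis", {
  set.seed(42)
  texts <- vapply(1:8, function(i) random_dna(sample(10:16, 1)), character(1))
  S <- dis_matrix(texts, 9)
  expect_true(isSymmetric(S))
  for (i in 1:8) for (j in 1:8) {
    expect_equal(S[i, j], naive_dis(texts[i], texts[j], 9))
  }
})

test_that("selection keeps strictly-above-threshold windows", {
  windows <- list(data.frame(pos = 0:3, count = c(5, 2, 7, 7)))
  expect_equal(select_high_frequency(windows, 7)[[1]], integer(0))
  expect_equal(select_high_frequency(windows, 0)[[1]], 0:3)
  expect_equal(select_high_frequency(windows, 4)[[1]], c(0L, 2L, 3L))
  expect_error(select_high_frequency(windows, -1), ">= 0")
})

test_that("overlap merging chains windows and keeps length >= l", {
  ds <- sam_dataset(random_dna(60))
  w <- 12; l <- 9

  # single window -> one substring of length w
  A <- merge_overlaps(list(10L), ds, w, 6, l)
  expect_equal(nrow(A), 1)
  expect_equal(c(A$start, A$end), c(10, 22))
  expect_equal(A$text, substr(ds$seqs[1], 11, 22))

  # positions 10 and 13 overlap by 9 >= 6: merged span [10, 25)
  A <- merge_overlaps(list(c(10L, 13L)), ds, w, 6, l)
  expect_equal(nrow(A), 1)
  expect_equal(c(A$start, A$end), c(10, 25))

  # positions 10 and 20 overlap by 2 < 6: two separate substrings
  A <- merge_overlaps(list(c(10L, 20L)), ds, w, 6, l)
  expect_equal(nrow(A), 2)
  expect_equal(A$start, c(10, 20))

  # chains combine more than two windows
  A <- merge_overlaps(list(c(5L, 10L, 15L)), ds, w, 6, l)
  expect_equal(nrow(A), 1)
  expect_equal(c(A$start, A$end), c(5, 27))

  # substrings are verbatim slices of their source
  for (r in seq_len(nrow(A))) {
    expect_equal(A$text[r], substr(ds$seqs[1], A$start[r] + 1, A$end[r]))
  }
})

test_that("threshold escalation enforces the substring cap", {
  # one 12-mer repeated 6 times, another repeated 3 times, in separate seqs
  set.seed(43)
  rep1 <- random_dna(12); rep2 <- random_dna(12)
  seqs <- c(vapply(1:6, function(i) paste0(random_dna(10), rep1, random_dna(10)),
                   character(1)),
            vapply(1:3, function(i) paste0(random_dna(10), rep2, random_dna(10)),
                   character(1)))
  ds <- sam_dataset(seqs)
  tb <- scan_count_table(ds, 12)
  wins <- count_all_windows(ds, tb, 0)

  cfg <- extraction_config(f_init = 1)
  res <- extract_with_cap(wins, ds, 12, 9, cfg)
  expect_lte(nrow(res$A), cfg$cap)
  expect_equal(res$f, 1)                        # cap already satisfied
  # every extracted substring covers one of the planted repeats (flank-char
  # collisions across sequences may extend a window, never invent one)
  expect_true(all(grepl(rep1, res$A$text, fixed = TRUE) |
                    grepl(rep2, res$A$text, fixed = TRUE)))
  expect_true(any(grepl(rep1, res$A$text, fixed = TRUE)))

  # cap = 6 forces escalation past the 3-fold repeat (count 3), keeping the
  # 6-fold repeat (count 6): one substring per carrying sequence
  cfg1 <- extraction_config(f_init = 1, cap = 6)
  res1 <- extract_with_cap(wins, ds, 12, 9, cfg1)
  expect_lte(nrow(res1$A), 6)
  expect_gte(res1$f, 3)
  expect_true(all(grepl(rep1, res1$A$text, fixed = TRUE)))

  # |A| is nonincreasing in f
  sizes <- vapply(0:6, function(f) {
    nrow(merge_overlaps(select_high_frequency(wins, f), ds, 12, 6, 9))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # empty selection warns and returns an empty set
  expect_warning(
    res_e <- extract_with_cap(wins, ds, 12, 9, extraction_config(f_init = 100)),
    "empty")
  expect_equal(nrow(res_e$A), 0)
})

test_that("attract tables match an independent recomputation", {
  # no others -> all-zero table
  t0 <- build_attract_table("ACGTACGTACGT", character(0), 9)
  expect_equal(t0$values, integer(4))

  # a unique exact copy marks its offset as a maximum
  set.seed(44)
  core <- random_dna(9)
  phi <- paste0(random_dna(2), core, random_dna(4))
  tab <- build_attract_table(phi, core, 9)
  expect_gte(tab$values[3], 1)
  expect_equal(which.max(tab$values), 3)

  # 10 random substrings: full table equality with the double-loop oracle
  texts <- vapply(1:10, function(i) random_dna(sample(11:18, 1)), character(1))
  for (c in 1:10) {
    tab <- build_attract_table(texts[c], texts[-c], 9)
    expect_equal(tab$values, naive_attract(texts[c], texts[-c], 9))
  }
})

test_that("segmentation respects length and coordinate contracts", {
  l <- 9; ext <- 3L
  # |phi| == l: single piece equal to phi
  phi <- hf_set("s", 5, 14, random_dna(9))
  tab <- build_attract_table(phi, character(0), l)
  pieces <- segment(phi[1, ], tab, l, ext)
  expect_equal(nrow(pieces), 1)
  expect_equal(pieces$text, phi$text)
  expect_equal(c(pieces$start, pieces$end), c(5, 14))

  # |phi| == l + 2 with max at second window: extension clips to phi
  txt <- random_dna(11)
  tab2 <- structure(list(values = c(0L, 5L, 1L), owner = txt),
                    class = "attract_table")
  p2 <- segment(txt, tab2, l, ext)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$text, txt)            # [max(0,1-3), min(11,1+9+3)) = whole

  # |phi| == 3l with two well-separated maxima: >= 2 pieces, all >= l,
  # all verbatim slices
  txt3 <- random_dna(27)
  vals <- integer(27 - l + 1)
  vals[c(1, 15)] <- c(9L, 8L)
  tab3 <- structure(list(values = vals, owner = txt3),
                    class = "attract_table")
  p3 <- segment(txt3, tab3, l, ext)
  expect_gte(nrow(p3), 2)
  expect_true(all(nchar(p3$text) >= l))
  expect_true(all(nchar(p3$text) <= l + 2 * ext))
  for (r in seq_len(nrow(p3))) {
    expect_equal(p3$text[r], substr(txt3, p3$start[r] + 1, p3$end[r]))
  }
  # the union of pieces covers both attract maxima
  covered <- unlist(lapply(seq_len(nrow(p3)), function(r) {
    (p3$start[r] + 1):p3$end[r]
  }))
  expect_true(all(c(1:9, 15:23) %in% covered))
})

test_that("build_A_prime preserves provenance and minimum length", {
  set.seed(45)
  ds_texts <- vapply(1:6, function(i) random_dna(sample(9:20, 1)), character(1))
  A <- hf_set(rep(paste0("s", 1:6)), rep(0L, 6), nchar(ds_texts), ds_texts)
  Ap <- build_A_prime(A, 9)
  expect_true(all(nchar(Ap$text) >= 9))
  expect_true(all(Ap$end - Ap$start == nchar(Ap$text)))
  # length-l members pass through unchanged
  keep <- A$text[nchar(A$text) == 9]
  expect_true(all(keep %in% Ap$text))
  # singleton A degenerates to the leftmost cut
  A1 <- hf_set("s1", 0L, 15L, random_dna(15))
  Ap1 <- build_A_prime(A1, 9)
  expect_equal(Ap1$start[1], 0)
  expect_true(all(nchar(Ap1$text) >= 9))
})

test_that("substring sets serialize to BED-like TSV", {
  A <- hf_set(c("s1", "s2"), c(0L, 3L), c(12L, 15L),
              c(strrep("A", 12), strrep("C", 12)))
  Ap <- hf_set("s1", 1L, 10L, strrep("A", 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hf_tsv(A, f, A_prime = Ap)
  tab <- utils::read.delim(f)
  expect_equal(names(tab), c("seq_id", "start", "end", "text", "stage"))
  expect_equal(nrow(tab), 3)
  expect_setequal(unique(tab$stage), c("A", "A'"))
})
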