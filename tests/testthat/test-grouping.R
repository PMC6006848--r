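# Fixture: `size` noisy copies of a base string, each with at most n_mut
# deterministic mutations, all of the same length (so dis = hamming-min
# over aligned windows).
noisy_group <- function(base, size, n_mut, offset = 0L) {
  vapply(seq_len(size), function(i) {
    if (n_mut == 0) return(base)
    at <- ((i + offset) %% nchar(base)) + 1L
    mutate_at(base, at, step = 1L + (i %% 3))
  }, character(1))
}

test_that("similarity follows the two-branch distance rule", {
  d <- 2
  # dis = 0 -> 0; identical strings
  expect_equal(similarity("ACGTACGTA", "ACGTACGTA", 9, d), 0)
  # construct 9-mers at known hamming distances
  base <- "ACGTACGTA"
  at4 <- mutate_at(base, 1:4)   # dis = 4 = 2d -> first branch
  expect_equal(similarity(base, at4, 9, d), -4)
  at5 <- mutate_at(base, 1:5)   # dis = 5 > 2d -> tenfold penalty
  expect_equal(similarity(base, at5, 9, d), -50)
  # always non-positive
  set.seed(51)
  for (i in 1:20) {
    s <- similarity(random_dna(10), random_dna(12), 9, d)
    expect_lte(s, 0)
  }
})

test_that("affinity propagation recovers a planted two-group partition", {
  set.seed(52)
  m1 <- random_dna(9)
  m2 <- mutate_at(m1, 1:9)                 # far from m1
  g1 <- noisy_group(m1, 12, 1)
  g2 <- noisy_group(m2, 10, 1)
  Ap <- hf_set(paste0("s", 1:22), 0L, 9L, c(g1, g2))
  cl <- cluster_ap(Ap, 9, 2, grouping_config(seed = 1))
  expect_equal(length(cl), 2)
  got <- lapply(cl, function(c) sort(c$members$seq_id))
  expect_setequal(got, list(sort(paste0("s", 1:12)),
                            sort(paste0("s", 13:22))))
  # centers are members; clusters partition A'
  for (c in cl) expect_true(c$members$text[c$center] %in% c$members$text)
  expect_setequal(unlist(lapply(cl, function(c) c$members$seq_id)), Ap$seq_id)
})

test_that("identical members collapse to a single cluster", {
  Ap <- hf_set(paste0("s", 1:6), 0L, 9L, rep("ACGTACGTA", 6))
  cl <- cluster_ap(Ap, 9, 2, grouping_config())
  expect_equal(length(cl), 1)
  expect_equal(cluster_size(cl[[1]]), 6)
})

test_that("cluster merging joins same-motif clusters and conserves members", {
  set.seed(53)
  m <- random_dna(9)
  c1 <- new_cluster_for_test(noisy_group(m, 15, 1))
  c2 <- new_cluster_for_test(noisy_group(m, 8, 1, offset = 3L))
  merged <- merge_clusters(list(c1, c2), 9, 2)
  expect_equal(length(merged), 1)
  expect_equal(cluster_size(merged[[1]]), 23)

  # unrelated clusters stay apart
  m2 <- mutate_at(m, 1:9)
  c3 <- new_cluster_for_test(noisy_group(m2, 8, 1))
  kept <- merge_clusters(list(c1, c3), 9, 2)
  expect_equal(length(kept), 2)
  expect_equal(sum(vapply(kept, cluster_size, integer(1))), 23)
})

test_that("trimming keeps the t' members closest to the center", {
  set.seed(54)
  base <- strrep("A", 9)
  # members at known hamming distances 0,1,2,...,8 from the center
  texts <- c(base, vapply(1:8, function(k) mutate_at(base, seq_len(k)),
                          character(1)))
  cl <- new_cluster_for_test(texts, center = 1L)
  tr <- trim_to_t_prime(cl, 4, 9)
  expect_equal(cluster_size(tr), 4)
  expect_equal(tr$members$text, texts[1:4])     # the 4 smallest distances
  expect_equal(tr$members$text[tr$center], base)  # center survives
  # |c| <= t' leaves membership unchanged
  tr2 <- trim_to_t_prime(cl, 20, 9)
  expect_setequal(tr2$members$text, texts)
})

test_that("Rule 1 removes the outlier and leaves a pairwise bounded set", {
  set.seed(55)
  m <- random_dna(9)
  good <- noisy_group(m, 10, 1)
  outlier <- mutate_at(m, 1:9)
  cl <- new_cluster_for_test(c(good, outlier), center = 1L)
  r1 <- apply_rule1(cl, 9, 2)
  expect_equal(cluster_size(r1), 10)
  expect_false(outlier %in% r1$members$text)
  D <- dis_matrix(r1$members$text, 9)
  expect_true(all(D <= 4))
  # already compliant cluster unchanged
  r1b <- apply_rule1(new_cluster_for_test(good), 9, 2)
  expect_equal(cluster_size(r1b), 10)
})

test_that("Rule 2 enforces the 3d/2 center bound exactly at the boundary", {
  d <- 4
  base <- strrep("A", 9)
  at6 <- mutate_at(base, 1:6)
  at7 <- mutate_at(base, 1:7)
  cl <- new_cluster_for_test(c(base, at6, at7), center = 1L)
  r2 <- apply_rule2(cl, 9, d)
  expect_true(at6 %in% r2$members$text)      # dis 6 <= 1.5 * 4
  expect_false(at7 %in% r2$members$text)     # dis 7 removed
  expect_equal(r2$members$text[r2$center], base)
  expect_true(all(r2$members$text %in% cl$members$text))
})

test_that("a_m calibration matches the analytic pair expectation", {
  # d = 0: identical instances, zero weight
  cal0 <- calibrate_am(10, 9, 0, n_samples = 50, seed = 1)
  expect_equal(cal0$a_m, 0)

  l <- 9; d <- 2; size <- 20
  cal <- calibrate_am(size, l, d, n_samples = 1000, seed = 56)
  # per-position change prob rho = (d/l) * 1/2; two instances differ at a
  # position with prob 2 rho (1-rho) + (2/3) rho^2
  rho <- (d / l) / 2
  p_diff <- 2 * rho * (1 - rho) + (2 / 3) * rho^2
  mu_expect <- choose(size, 2) * l * p_diff
  se <- cal$sigma / sqrt(1000)
  expect_lt(abs(cal$mu - mu_expect), 3 * se)

  # a_m grows with the sample size (pair count is quadratic)
  cal_small <- calibrate_am(10, l, d, n_samples = 400, seed = 57)
  cal_big <- calibrate_am(40, l, d, n_samples = 400, seed = 57)
  expect_gt(cal_big$a_m, cal_small$a_m)

  # memoised under a seed: identical on repeat call
  again <- calibrate_am(size, l, d, n_samples = 1000, seed = 56)
  expect_identical(again, cal)
})

test_that("Rule 3 accepts tight clusters and thins inflated ones", {
  cfg <- grouping_config(min_cluster = 5, removal_batch = 2, seed = 3,
                         calib_samples = 200)
  # identical strings: weight 0, accepted immediately
  cl0 <- new_cluster_for_test(rep("ACGTACGTA", 8))
  acc <- apply_rule3(cl0, 9, 2, cfg)
  expect_false(is.null(acc))
  expect_equal(attr(acc, "weight"), 0)

  # pairwise-bounded decoys at systematically large distances get thinned
  set.seed(58)
  base <- random_dna(9)
  decoys <- vapply(1:12, function(i) {
    mutate_at(base, ((i * 2 + 0:1) %% 9) + 1, step = 1L + (i %% 3))
  }, character(1))
  cld <- new_cluster_for_test(c(base, decoys), center = 1L)
  res <- apply_rule3(cld, 9, 1, cfg)   # d = 1 makes the threshold tight
  if (!is.null(res)) {
    expect_lt(cluster_size(res), cluster_size(cld))
    D <- dis_matrix(res$members$text, 9)
    n <- cluster_size(res)
    cal <- calibrate_am(n, 9, 1, cfg$calib_samples, seed = cfg$seed + n)
    expect_lte(sum(D[upper.tri(D)]), cal$a_m)
  }
})

test_that("sample sets deduplicate sequences and rank by size", {
  set.seed(59)
  m <- random_dna(9)
  ds <- random_dataset(12, 30, seed = 60)
  # big cluster: 5 distinct sequences, one sequence contributing twice
  big <- hf_set(c("seq_1", "seq_2", "seq_3", "seq_4", "seq_5", "seq_5"),
                0L, 9L, noisy_group(m, 6, 1))
  small <- hf_set(c("seq_6", "seq_7", "seq_8"), 0L, 9L, noisy_group(m, 3, 0))
  ids <- ds$ids
  names(ds$seqs) <- NULL
  clusters <- list(new_cluster_for_test_hf(small),
                   new_cluster_for_test_hf(big))
  sets <- emit_sample_sets(clusters, ds, grouping_config(q_prime = 0.9), l = 9)
  expect_equal(length(sets), 2)
  expect_equal(sets[[1]]$rank, 1)
  expect_equal(sets[[1]]$t_prime, 5)          # seq_5 counted once
  expect_equal(anyDuplicated(sets[[1]]$sequence_ids), 0)
  expect_equal(sets[[2]]$t_prime, 3)
  expect_equal(sets[[2]]$rank, 2)
  expect_equal(sets[[1]]$q_prime, 0.9)
})
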