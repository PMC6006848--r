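# Shared end-to-end fixture: five seeded low-conservation simulations
# (t = 500, n = 600, (l,d) = (9,2), q = 0.5, g = 0.8), each run through the
# full selection pipeline with t' = 50 and the exact solver at q' = 0.95.
# Computed once and reused by the motif-recovery, sample-quality and
# rules-audit checks.
.e2e_cache <- new.env(parent = emptyenv())

e2e_runs <- function() {
  if (!is.null(.e2e_cache$runs)) return(.e2e_cache$runs)
  .e2e_cache$runs <- lapply(1:5, function(seed) {
    sim <- generate_planted(t = 500, n = 600, l = 9, d = 2, q = 0.5,
                            g = 0.8, seed = seed)
    grp <- grouping_config(t_prime = 50, q_prime = 0.95, seed = seed)
    sets <- suppressWarnings(
      select_samples(sim$dataset, 9, 2, 0.5, grouping = grp))
    rank <- NA_integer_; qp <- NA_real_
    if (length(sets) > 0) {
      s1 <- sets[[1]]
      res <- solve_qpms(sample_dataset(s1, sim$dataset), 9, 2, 0.95)
      rank <- rank_of(res, sim$truth$motif)
      qp <- measured_q_prime(s1, sim$truth)
    }
    list(sets = sets, config = grp, rank = rank, q_measured = qp)
  })
  .e2e_cache$runs
}

# exhaustive qPMS oracle over the whole 4^l candidate space
exhaustive_qpms_oracle <- function(dataset, l, d, q) {
  cands <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), l)),
                 1, paste, collapse = "")
  quorum <- ceiling(q * dataset$t)
  supp <- vapply(cands, function(m) {
    sum(vapply(dataset$seqs, function(s) {
      L <- nchar(s)
      if (L < l) return(FALSE)
      any(vapply(seq_len(L - l + 1), function(i) {
        hamming(substr(s, i, i + l - 1), m) <= d
      }, logical(1)))
    }, logical(1)))
  }, numeric(1))
  sort(cands[supp >= quorum])
}
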