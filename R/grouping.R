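# Stage 3: cluster the segmented substrings by affinity propagation with a
# distance-derived similarity, merge clusters belonging to one motif, trim
# to t', enforce the motif-set rules with the calibrated weight threshold
# a_m, and emit ranked sample sequence sets.

#' Similarity between two high-frequency substrings
#'
#' `sim = -dis` when `dis <= 2d` (two instances of one motif can differ by
#' at most 2d), and `-10 * dis` otherwise, so pairs that cannot share a
#' motif are pushed far apart. Always non-positive.
#'
#' @param phi,phi2 substrings (strings or single `hf_set` rows).
#' @param l,d motif length and mismatch allowance.
#' @return the similarity value.
#' @export
similarity <- function(phi, phi2, l, d) {
  sim_from_dis(dis(phi, phi2, l), d)
}

# internal: vectorized Eq-style similarity from dis values
sim_from_dis <- function(dv, d) {
  ifelse(dv <= 2 * d, -dv, -10 * dv)
}

# internal: dis from one substring to each of a vector of substrings
dis_vec <- function(phi, texts, l) {
  if (length(texts) == 0) return(integer(0))
  build_dis_data(c(hf_texts(phi), texts), l)$S[1, -1]
}

#' Grouping stage configuration
#'
#' @param t_prime requested sample-set size (default 100).
#' @param q_prime declared proportion of motif-bearing sequences in an
#'   emitted set (default 0.95, the simulated-data profile; 0.9 suits
#'   noisier real data).
#' @param damping,max_iter,conv_iter affinity-propagation controls:
#'   message damping, iteration cap, and the number of consecutive
#'   iterations the exemplar set must stay unchanged to declare
#'   convergence.
#' @param calib_samples number of random motif-instance samples used to
#'   calibrate the weight threshold `a_m` (default 1000).
#' @param removal_batch members removed per iteration when a cluster fails
#'   the weight test (default 10).
#' @param min_cluster smallest cluster kept (default 20); smaller clusters
#'   are discarded rather than emitted as degenerate sample sets.
#' @param seed RNG seed for the calibration draws.
#' @return list of class `grouping_config`.
#' @export
grouping_config <- function(t_prime = 100L, q_prime = 0.95, damping = 0.9,
                            max_iter = 1000L, conv_iter = 100L,
                            calib_samples = 1000L, removal_batch = 10L,
                            min_cluster = 20L, seed = NULL) {
  stopifnot(q_prime > 0, q_prime <= 1, removal_batch >= 1,
            damping >= 0.5, damping < 1)
  structure(list(t_prime = as.integer(t_prime), q_prime = q_prime,
                 damping = damping, max_iter = as.integer(max_iter),
                 conv_iter = as.integer(conv_iter),
                 calib_samples = as.integer(calib_samples),
                 removal_batch = as.integer(removal_batch),
                 min_cluster = as.integer(min_cluster), seed = seed),
            class = "grouping_config")
}

# internal: cluster constructor; center is an index into members
new_cluster <- function(members, center, dsub = NULL, merged_from = list()) {
  stopifnot(nrow(members) >= 1, center >= 1, center <= nrow(members))
  structure(list(members = members, center = as.integer(center),
                 dsub = dsub, merged_from = merged_from),
            class = "sam_cluster")
}

#' @export
print.sam_cluster <- function(x, ...) {
  cat("sam_cluster:", nrow(x$members), "members, center",
      x$members$text[x$center], "\n")
  invisible(x)
}

#' Cluster size
#' @param cluster a `sam_cluster`.
#' @return number of members.
#' @export
cluster_size <- function(cluster) nrow(cluster$members)

# internal: pairwise dis matrix of a cluster, cached on the object
cluster_dis <- function(cluster, l) {
  if (!is.null(cluster$dsub)) return(cluster$dsub)
  dis_matrix(cluster$members$text, l)
}

# internal: cluster weight, Eq-style sum of dis over unordered pairs
cluster_weight <- function(D) {
  if (nrow(D) < 2) return(0)
  sum(D[upper.tri(D)])
}

# internal: Frey-Dueck affinity propagation on a similarity matrix.
# Returns the exemplar index for every item; deterministic under `seed`
# (a tiny jitter breaks message-passing ties that otherwise leave the
# exemplar scores pinned at exactly zero). Preference = median
# off-diagonal similarity. Fully tied inputs (all pairwise similarities
# equal, e.g. identical members) short-circuit to a single cluster.
ap_run <- function(S, damping = 0.9, max_iter = 1000L, conv_iter = 100L,
                   seed = 0L) {
  N <- nrow(S)
  if (N == 1) return(1L)
  off <- S[row(S) != col(S)]
  if (max(off) == min(off)) return(rep(1L, N))
  scale <- max(off) - min(off)
  S <- S + with_seed(if (is.null(seed)) 0L else seed,
                     matrix(stats::runif(N * N), N, N)) * 1e-9 * scale
  diag(S) <- stats::median(off)
  R <- A <- matrix(0, N, N)
  idx <- seq_len(N)
  ex_prev <- integer(0)
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    AS <- A + S
    I1 <- max.col(AS, ties.method = "first")
    Y1 <- AS[cbind(idx, I1)]
    AS[cbind(idx, I1)] <- -Inf
    Y2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - Y1
    Rnew[cbind(idx, I1)] <- S[cbind(idx, I1)] - Y2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, N, N, byrow = TRUE) - Rp
    Anew[Anew > 0] <- 0
    diag(Anew) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex) > 0 && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) {
    warning("affinity propagation identified no exemplars; ",
            "falling back to a single medoid cluster")
    ex <- which.max(colSums(S))
  } else if (!converged) {
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; using current exemplars")
  }
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  assign_to
}

#' Cluster segmented substrings by affinity propagation
#'
#' Builds the full pairwise [similarity()] matrix over A' and runs
#' affinity propagation, which chooses the number of clusters and their
#' exemplars automatically. Every member is assigned to exactly one
#' cluster; the exemplar becomes the cluster center.
#'
#' @param A_prime an [hf_set] with at least 2 members.
#' @param l,d motif parameters.
#' @param config a [grouping_config()].
#' @return list of `sam_cluster` objects.
#' @export
cluster_ap <- function(A_prime, l, d, config = grouping_config()) {
  stopifnot(inherits(A_prime, "hf_set"), nrow(A_prime) >= 2)
  dmat <- dis_matrix(A_prime, l)
  S <- sim_from_dis(dmat, d)
  assign_to <- ap_run(S, config$damping, config$max_iter, config$conv_iter,
                      seed = config$seed)
  lapply(sort(unique(assign_to)), function(e) {
    m <- which(assign_to == e)
    new_cluster(A_prime[m, , drop = FALSE],
                center = match(e, m),
                dsub = dmat[m, m, drop = FALSE])
  })
}

#' Merge clusters that correspond to one motif
#'
#' Greedy merging: clusters are ordered by size (largest first); for a
#' larger cluster with center `phi` and a smaller cluster `c'`, the number
#' of members of `c'` within `dis <= d` of `phi` is compared with the
#' random-case expectation `P_d |c'|` plus a 20% margin; exceeding it
#' merges `c'` into the larger cluster (whose center is kept). Passes
#' repeat until no merge occurs.
#'
#' @param clusters list of `sam_cluster`.
#' @param l,d motif parameters.
#' @return list of `sam_cluster` (never more than the input count; total
#'   membership conserved).
#' @export
merge_clusters <- function(clusters, l, d) {
  pd <- p_d(l, d)
  repeat {
    sizes <- vapply(clusters, cluster_size, integer(1))
    o <- order(-sizes)
    clusters <- clusters[o]
    merged_any <- FALSE
    i <- 1L
    while (i < length(clusters)) {
      big <- clusters[[i]]
      center_text <- big$members$text[big$center]
      j <- i + 1L
      while (j <= length(clusters)) {
        small <- clusters[[j]]
        nj <- cluster_size(small)
        dv <- dis_vec(center_text, small$members$text, l)
        if (sum(dv <= d) > pd * nj + 0.2 * nj) {
          big <- new_cluster(
            rbind(big$members, small$members), big$center, dsub = NULL,
            merged_from = c(big$merged_from,
                            list(small$members$text[small$center])))
          clusters[[i]] <- big
          clusters[[j]] <- NULL
          merged_any <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  clusters
}

#' Keep the t' members closest to the cluster center
#'
#' Members are sorted by `dis` to the center (ascending, original order on
#' ties; the center itself always first) and the first
#' `min(|c|, t_prime)` are kept.
#'
#' @param cluster a `sam_cluster`.
#' @param t_prime requested size.
#' @param l motif length.
#' @return the trimmed `sam_cluster`.
#' @export
trim_to_t_prime <- function(cluster, t_prime, l) {
  n <- cluster_size(cluster)
  D <- cluster_dis(cluster, l)
  key <- D[, cluster$center]
  key[cluster$center] <- -1           # center sorts first
  ord <- order(key)                   # stable: ties keep insertion order
  keep <- sort(ord[seq_len(min(n, t_prime))])
  new_cluster(cluster$members[keep, , drop = FALSE],
              center = match(cluster$center, keep),
              dsub = D[keep, keep, drop = FALSE],
              merged_from = cluster$merged_from)
}

#' Enforce pairwise boundedness (Rule 1)
#'
#' While any pair of members is at `dis > 2d`, the member involved in the
#' most violations is removed (ties: larger distance to the center, then
#' the later member). The center itself is never removed. On exit the
#' cluster is a pairwise bounded set.
#'
#' @param cluster a `sam_cluster`.
#' @param l,d motif parameters.
#' @return the filtered `sam_cluster`.
#' @export
apply_rule1 <- function(cluster, l, d) {
  D <- cluster_dis(cluster, l)
  keep <- seq_len(nrow(D))
  center <- cluster$center
  repeat {
    Dk <- D[keep, keep, drop = FALSE]
    nv <- rowSums(Dk > 2 * d)
    ci <- match(center, keep)
    nv[ci] <- -1                      # protect the center
    if (max(nv) <= 0) break
    cand <- which(nv == max(nv))
    if (length(cand) > 1) {
      cd <- Dk[cand, ci]
      cand <- cand[cd == max(cd)]
    }
    drop_i <- cand[length(cand)]      # later member on remaining ties
    keep <- keep[-drop_i]
  }
  new_cluster(cluster$members[keep, , drop = FALSE],
              center = match(center, keep),
              dsub = D[keep, keep, drop = FALSE],
              merged_from = cluster$merged_from)
}

#' Enforce the center-distance bound (Rule 2)
#'
#' Removes members whose `dis` to the cluster center exceeds `3d/2`
#' (equivalently, integer `dis > floor(3d/2)`). The center, at distance 0,
#' always survives.
#'
#' @param cluster a `sam_cluster`.
#' @param l,d motif parameters.
#' @return the filtered `sam_cluster`.
#' @export
apply_rule2 <- function(cluster, l, d) {
  D <- cluster_dis(cluster, l)
  keep <- which(D[, cluster$center] <= 1.5 * d)
  new_cluster(cluster$members[keep, , drop = FALSE],
              center = match(cluster$center, keep),
              dsub = D[keep, keep, drop = FALSE],
              merged_from = cluster$merged_from)
}

# memo cache for calibration results
.calib_cache <- new.env(parent = emptyenv())

#' Calibrate the motif-set weight threshold a_m
#'
#' Draws `n_samples` random samples, each holding `size` instances of a
#' fresh uniform random l-mer motif; an instance mutates each of `d`
#' distinct uniformly chosen positions with probability 1/2 (intermediate
#' conservation) to a uniformly different base. The sample weight is the
#' sum of Hamming distances over unordered instance pairs. `a_m` is the
#' mean plus one standard deviation of these weights: clusters whose
#' weight exceeds `a_m` are unlikely to be pure motif-instance sets.
#'
#' @param size number of instances per sample (the cluster size), >= 2.
#' @param l,d motif parameters.
#' @param n_samples number of calibration samples (default 1000).
#' @param seed optional RNG seed (results are memoised per
#'   size/l/d/n_samples/seed).
#' @return list with `a_m`, `mu` and `sigma`.
#' @export
calibrate_am <- function(size, l, d, n_samples = 1000L, seed = NULL) {
  stopifnot(size >= 2)
  key <- paste(size, l, d, n_samples,
               if (is.null(seed)) "NULL" else seed, sep = "_")
  if (!is.null(seed) && !is.null(.calib_cache[[key]])) {
    return(.calib_cache[[key]])
  }
  res <- with_seed(seed, {
    weights <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      motif <- sample.int(4L, l, replace = TRUE) - 1L
      inst <- matrix(motif, nrow = size, ncol = l, byrow = TRUE)
      if (d > 0) {
        for (i in seq_len(size)) {
          mp <- sample.int(l, d)
          fire <- stats::runif(d) < 0.5
          for (p in mp[fire]) {
            inst[i, p] <- (inst[i, p] + sample.int(3L, 1)) %% 4L
          }
        }
      }
      wsum <- 0
      for (j in seq_len(l)) {
        cnt <- tabulate(inst[, j] + 1L, nbins = 4L)
        wsum <- wsum + (size^2 - sum(cnt^2)) / 2
      }
      weights[s] <- wsum
    }
    mu <- mean(weights)
    sigma <- stats::sd(weights)
    list(a_m = mu + sigma, mu = mu, sigma = sigma)
  })
  if (!is.null(seed)) .calib_cache[[key]] <- res
  res
}

#' Accept, thin, or discard a cluster by its weight (Rule 3)
#'
#' Computes the cluster weight (sum of pairwise `dis`) and accepts the
#' cluster when it is at most the calibrated threshold `a_m` for the
#' current size. Otherwise the `removal_batch` members with the largest
#' total distance to the rest (never the center) are removed and the test
#' repeats with a recalibrated threshold. Clusters that shrink below
#' `min_cluster` before acceptance are discarded.
#'
#' @param cluster a `sam_cluster` that already satisfies Rules 1-2.
#' @param l,d motif parameters.
#' @param config a [grouping_config()].
#' @return the accepted `sam_cluster` (with attributes `weight` and `a_m`)
#'   or `NULL` if discarded.
#' @export
apply_rule3 <- function(cluster, l, d, config = grouping_config()) {
  repeat {
    n <- cluster_size(cluster)
    if (n < config$min_cluster) return(NULL)
    D <- cluster_dis(cluster, l)
    w <- cluster_weight(D)
    seed <- if (is.null(config$seed)) NULL else config$seed + n
    cal <- calibrate_am(n, l, d, config$calib_samples, seed = seed)
    if (w <= cal$a_m) {
      attr(cluster, "weight") <- w
      attr(cluster, "a_m") <- cal$a_m
      return(cluster)
    }
    tot <- rowSums(D)
    tot[cluster$center] <- -Inf
    drop_i <- order(tot, decreasing = TRUE)[seq_len(min(config$removal_batch,
                                                        n - 1L))]
    keep <- setdiff(seq_len(n), drop_i)
    cluster <- new_cluster(cluster$members[keep, , drop = FALSE],
                           center = match(cluster$center, keep),
                           dsub = D[keep, keep, drop = FALSE],
                           merged_from = cluster$merged_from)
  }
}

#' Emit ranked sample sequence sets from accepted clusters
#'
#' Per cluster, the source sequence ids of its members are collected
#' (members ordered by distance to the center, so a sequence contributing
#' several members is represented by the one closest to the center) and
#' deduplicated. Sets are ranked by size descending — a larger set is more
#' likely to carry a well-conserved motif — with ties broken by smaller
#' mean member-to-center distance.
#'
#' @param clusters list of accepted `sam_cluster` objects.
#' @param dataset the source [sam_dataset].
#' @param config a [grouping_config()] (supplies the declared `q_prime`).
#' @param l motif length.
#' @return list of `sample_set` objects: `sequence_ids`, `t_prime`,
#'   `q_prime`, `rank`, `source_cluster`.
#' @export
emit_sample_sets <- function(clusters, dataset, config = grouping_config(),
                             l = NULL) {
  if (length(clusters) == 0) {
    out <- list()
    attr(out, "status") <- "no clusters survived the motif-set rules"
    return(out)
  }
  sets <- lapply(clusters, function(cl) {
    D <- cluster_dis(cl, l)
    key <- D[, cl$center]
    key[cl$center] <- -1
    ord <- order(key)
    ids <- cl$members$seq_id[ord]
    stopifnot(all(ids %in% dataset$ids))
    seq_ids <- ids[!duplicated(ids)]
    structure(list(sequence_ids = seq_ids,
                   t_prime = length(seq_ids),
                   q_prime = config$q_prime,
                   rank = NA_integer_,
                   mean_center_dist = mean(D[, cl$center]),
                   source_cluster = cl),
              class = "sample_set")
  })
  o <- order(-vapply(sets, `[[`, integer(1), "t_prime"),
             vapply(sets, `[[`, numeric(1), "mean_center_dist"))
  sets <- sets[o]
  for (r in seq_along(sets)) sets[[r]]$rank <- r
  sets
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set rank", x$rank, ": t' =", x$t_prime,
      "sequences, declared q' =", x$q_prime, "\n")
  invisible(x)
}

#' Materialize a sample set as a dataset
#'
#' @param sample a `sample_set`.
#' @param dataset the original [sam_dataset].
#' @return a [sam_dataset] restricted to the sample's sequences (input
#'   order preserved by selection order of the sample).
#' @export
sample_dataset <- function(sample, dataset) {
  i <- match(sample$sequence_ids, dataset$ids)
  stopifnot(!anyNA(i))
  sam_dataset(dataset$seqs[i], dataset$ids[i])
}

#' Select sample sequence sets from a large dataset
#'
#' The whole three-stage pipeline: mismatch-tolerant word counting,
#' high-frequency substring extraction with the 5000-substring cap and
#' attract-table segmentation, then affinity-propagation grouping with
#' cluster merging, trimming to `t'` and the three motif-set rules.
#' Emits ranked sample sequence sets whose sequences are enriched in
#' instances of a single motif; running a qPMS solver on the first set
#' with quorum `q'` is the intended follow-up.
#'
#' @param dataset a [sam_dataset].
#' @param l,d,q motif length, mismatch allowance and (original-dataset)
#'   quorum; `q` enters the initial threshold and the merge test.
#' @param w,k word length and count mismatch allowance (defaults 12 and 1).
#' @param extraction an [extraction_config()].
#' @param grouping a [grouping_config()].
#' @param verbose print per-stage sizes.
#' @return list of `sample_set` objects (possibly empty) with an attached
#'   `stats` attribute: final threshold `f`, `n_A`, `n_A_prime`,
#'   `n_clusters`, `n_merged`, `n_accepted`.
#' @export
select_samples <- function(dataset, l, d, q, w = 12L, k = 1L,
                           extraction = extraction_config(),
                           grouping = grouping_config(),
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "sam_dataset"))
  say <- function(...) if (verbose) message(...)
  tab <- scan_count_table(dataset, w)
  windows <- count_all_windows(dataset, tab, k)
  if (is.null(extraction$f_init)) {
    ec <- expected_counts(w, k, l, d, q, dataset$t, dataset$n)
    extraction$f_init <- max(1, round(ec$n_r + ec$n_m))
  }
  say("initial threshold f = ", extraction$f_init)
  ex <- extract_with_cap(windows, dataset, w, l, extraction)
  say("|A| = ", nrow(ex$A), " at final f = ", ex$f,
      " (", ex$passes, " passes)")
  stats <- list(f = ex$f, n_A = nrow(ex$A), n_A_prime = 0L,
                n_clusters = 0L, n_merged = 0L, n_accepted = 0L)
  empty <- function(status) {
    out <- list()
    attr(out, "status") <- status
    attr(out, "stats") <- stats
    out
  }
  if (nrow(ex$A) == 0) return(empty("no high-frequency substrings"))
  A_prime <- build_A_prime(ex$A, l, extraction$extend)
  stats$n_A_prime <- nrow(A_prime)
  say("|A'| = ", nrow(A_prime))
  if (nrow(A_prime) < 2) return(empty("fewer than 2 segmented substrings"))
  clusters <- cluster_ap(A_prime, l, d, grouping)
  stats$n_clusters <- length(clusters)
  say(length(clusters), " clusters from affinity propagation")
  clusters <- merge_clusters(clusters, l, d)
  stats$n_merged <- length(clusters)
  say(length(clusters), " clusters after merging")
  accepted <- list()
  for (cl in clusters) {
    cl <- trim_to_t_prime(cl, grouping$t_prime, l)
    cl <- apply_rule1(cl, l, d)
    cl <- apply_rule2(cl, l, d)
    cl <- apply_rule3(cl, l, d, grouping)
    if (!is.null(cl)) accepted[[length(accepted) + 1L]] <- cl
  }
  stats$n_accepted <- length(accepted)
  say(length(accepted), " clusters accepted by Rules 1-3")
  sets <- emit_sample_sets(accepted, dataset, grouping, l)
  attr(sets, "stats") <- stats
  sets
}
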