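# Independent oracles and small fixture builders shared across tests.

# Brute-force enumeration of all maximal-density tag segments: a segment is
# maximal for some density d iff its break density (min over prefix/suffix
# splits) exceeds its merge density (max over flanking attachment runs).
# O(n^2); independent of the recursive implementation.
brute_paraclu <- function(positions, counts, min_tags = 5, min_density_fold = 2,
                          max_length = 200) {
  n <- length(positions)
  cs <- cumsum(as.numeric(counts))
  tsum <- function(i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) brk <- Inf else {
      ks <- i:(j - 1)
      pd <- sapply(ks, function(k) tsum(i, k) / (positions[k + 1] - positions[i]))
      sd_ <- sapply(ks, function(k) tsum(k + 1, j) / (positions[j] - positions[k]))
      brk <- min(c(pd, sd_))
    }
    merge_d <- 0
    if (i > 1) merge_d <- max(merge_d, sapply(1:(i - 1), function(l)
      tsum(l, i - 1) / (positions[i] - positions[l])))
    if (j < n) merge_d <- max(merge_d, sapply((j + 1):n, function(r)
      tsum(j + 1, r) / (positions[r] - positions[j])))
    if (brk > merge_d)
      rows[[length(rows) + 1]] <- data.frame(start = positions[i],
                                             end = positions[j] + 1L,
                                             tag_count = tsum(i, j),
                                             min_density = merge_d,
                                             max_density = brk)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[out$tag_count >= min_tags & (out$end - out$start) <= max_length, , drop = FALSE]
  out <- out[out$min_density == 0 |
               out$max_density / out$min_density >= min_density_fold, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

# naive per-tag aggregation loop, the oracle for aggregate_tags_to_features
naive_aggregate <- function(tag_streams, intervals, strand_rule) {
  out <- matrix(0L, nrow(intervals), length(tag_streams),
                dimnames = list(intervals$feature_id, names(tag_streams)))
  for (s in seq_along(tag_streams)) {
    ts <- tag_streams[[s]]
    for (r in seq_len(nrow(ts))) {
      for (f in seq_len(nrow(intervals))) {
        if (ts$chrom[r] != intervals$chrom[f]) next
        if (ts$pos[r] < intervals$start[f] || ts$pos[r] >= intervals$end[f]) next
        ok <- switch(strand_rule,
                     "same-strand" = ts$strand[r] == intervals$strand[f],
                     "plus-only" = ts$strand[r] == "+",
                     "minus-only" = ts$strand[r] == "-",
                     "both" = TRUE)
        if (ok) out[f, s] <- out[f, s] + ts$count[r]
      }
    }
  }
  out
}

# all-pairs interval overlap scan (half-open coordinates)
naive_overlaps <- function(query, subject) {
  hits <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] && subject$start[j] < query$end[i])
      hits[[length(hits) + 1]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, hits)
  data.frame(query = m[, 1], subject = m[, 2])
}

# small tag stream constructor
make_stream <- function(chrom, pos, strand, count, sample_id = "S1") {
  ts <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand, count = as.integer(count))
  data.table::setattr(ts, "sample_id", sample_id)
  data.table::setattr(ts, "library_size", sum(ts$count))
  ts
}

# exhaustive permutation distribution of the best in-window p for tiny n:
# returns the exact permutation p of the observed best association
exact_perm_p <- function(y, dosage) {
  n <- length(y)
  perms <- combinat_perms(n)
  best_p_of <- function(yy) {
    ps <- apply(dosage, 2, function(g) {
      if (sd(g) == 0) return(1)
      r <- cor(yy, g)
      df <- n - 2
      t <- abs(r) * sqrt(df / (1 - min(r^2, 1 - 1e-14)))
      2 * pt(t, df, lower.tail = FALSE)
    })
    min(ps)
  }
  obs <- best_p_of(y)
  cnt <- 0L
  for (k in seq_len(nrow(perms))) {
    if (best_p_of(y[perms[k, ]]) <= obs + 1e-15) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

# all permutations of 1..n (n <= 7)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    out[row, ] <- append(sub[k, ], n, after = pos - 1)
    row <- row + 1L
  }
  out
}

# a small simulated cohort shared by several tests
small_cohort <- function(seed = 7, n_samples = 80, n_genes = 50, n_enhancers = 15) {
  cfg <- sim_config(n_samples = n_samples, n_variants = 1200, n_genes = n_genes,
                    n_enhancers = n_enhancers, n_tads = 6, tad_span = 3e5,
                    depth_mean = 5e4, depth_sd = 1e4, seed = seed)
  gm <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, gm)
  tg <- simulate_cage_tags(gm, ann, cfg)
  list(cfg = cfg, gm = gm, ann = ann, tg = tg)
}
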