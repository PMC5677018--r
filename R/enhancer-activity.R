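# Transcribed-enhancer detection from CTSS data: density clustering of tag
# positions, bidirectional selection, directionality scoring, and activity
# quantification.

#' Density clustering of CTSS positions (Paraclu-style)
#'
#' Finds all segments of tag positions that are maximal-scoring for some
#' density parameter d under the score (total tags) - d * (spanned bases),
#' by recursive splitting: each segment records the density at which it
#' becomes maximal (`min_density`) and the density at which it breaks apart
#' (`max_density`, the minimal prefix/suffix density). Emitted clusters must
#' have at least `min_tags` tags, `max_density / min_density >=
#' min_density_fold` (single-position clusters have infinite maximum
#' density and pass), and length at most `max_length` nt.
#'
#' @param positions sorted integer tag positions (single chrom and strand)
#' @param counts tag counts per position (>= 1)
#' @param min_tags minimum tags per cluster (default 5)
#' @param min_density_fold minimum (max density)/(baseline density) (default 2)
#' @param max_length maximum cluster length in nt (default 200)
#' @return `data.table`: start, end (half-open), tag_count, min_density,
#'   max_density
#' @export
paraclu_cluster <- function(positions, counts, min_tags = 5,
                            min_density_fold = 2, max_length = 200) {
  if (length(positions) == 0L)
    return(data.table(start = integer(), end = integer(), tag_count = numeric(),
                      min_density = numeric(), max_density = numeric()))
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be sorted and unique")
  np <- length(positions)
  cs <- cumsum(as.numeric(counts))
  cs0 <- c(0, cs)
  tag_sum <- function(i, j) cs[j] - cs0[i]
  out <- vector("list", 2L * np)
  n_out <- 0L
  # explicit work stack (segments can nest ~n deep on pathological tracks);
  # every visited segment is a candidate, recorded with its break density
  # (the minimal prefix/suffix density, at which it splits apart)
  stack <- list(c(1, np))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr[1]; j <- fr[2]
    if (i > j) next
    if (i == j) {
      n_out <- n_out + 1L
      out[[n_out]] <- c(i, j, Inf)
      next
    }
    ks <- i:(j - 1)
    pd <- (cs[ks] - cs0[i]) / (positions[ks + 1] - positions[i])
    sd_ <- (cs[j] - cs[ks]) / (positions[j] - positions[ks])
    brk <- min(pd, sd_)
    kstar <- ks[which.min(pmin(pd, sd_))]
    n_out <- n_out + 1L
    out[[n_out]] <- c(i, j, brk)
    stack[[length(stack) + 1L]] <- c(i, kstar)
    stack[[length(stack) + 1L]] <- c(kstar + 1, j)
  }
  m <- do.call(rbind, out[seq_len(n_out)])
  # minimum density at which a candidate is maximal = the densest flanking
  # run that would attach to it; the candidate is a cluster iff it breaks
  # apart only above that density
  merge_d <- vapply(seq_len(nrow(m)), function(r) {
    i <- m[r, 1]; j <- m[r, 2]
    md <- 0
    if (i > 1) {
      ls <- 1:(i - 1)
      md <- max(md, (cs[i - 1] - cs0[ls]) / (positions[i] - positions[ls]))
    }
    if (j < np) {
      rs <- (j + 1):np
      md <- max(md, (cs[rs] - cs[j]) / (positions[rs] - positions[j]))
    }
    md
  }, numeric(1))
  keep <- m[, 3] > merge_d
  m <- m[keep, , drop = FALSE]; merge_d <- merge_d[keep]
  res <- data.table(start = positions[m[, 1]], end = positions[m[, 2]] + 1L,
                    tag_count = tag_sum(m[, 1], m[, 2]),
                    min_density = merge_d, max_density = m[, 3])
  res <- res[tag_count >= min_tags & (end - start) <= max_length]
  res <- res[min_density == 0 | max_density / min_density >= min_density_fold]
  setorder(res, start, end)
  res
}

#' Cluster pooled CTSS tags per chromosome and strand
#'
#' Pools tag streams across all samples, then runs [paraclu_cluster()] on
#' each (chrom, strand) track.
#'
#' @param tag_streams named list of per-sample tag streams
#' @param ... passed to [paraclu_cluster()]
#' @return `data.table` of clusters with chrom and strand columns
#' @export
cluster_tag_streams <- function(tag_streams, ...) {
  pooled <- rbindlist(lapply(tag_streams, function(ts) ts))
  if (nrow(pooled) == 0L)
    return(data.table(chrom = character(), strand = character(), start = integer(),
                      end = integer(), tag_count = numeric(), min_density = numeric(),
                      max_density = numeric()))
  pooled <- pooled[, .(count = sum(count)), by = .(chrom, pos, strand)]
  setorder(pooled, chrom, strand, pos)
  pooled[, {
    cl <- paraclu_cluster(pos, count, ...)
    if (nrow(cl)) cl else NULL
  }, by = .(chrom, strand)]
}

#' Select enhancers with bidirectional transcription
#'
#' An enhancer region is kept iff at least one plus-strand and at least one
#' minus-strand tag cluster each overlap the window [mid - window,
#' mid + window).
#'
#' @param enhancers interval table with a `midpoint` column
#' @param clusters cluster table from [cluster_tag_streams()]
#' @param window half-window around the midpoint (default 400 nt)
#' @return the enhancer table with a logical `bidirectional` column
#' @export
select_bidirectional <- function(enhancers, clusters, window = 400) {
  if (nrow(enhancers) == 0L) {
    enhancers$bidirectional <- logical(0)
    return(enhancers)
  }
  win <- data.table(chrom = enhancers$chrom,
                    start = enhancers$midpoint - as.integer(window),
                    end = enhancers$midpoint + as.integer(window),
                    strand = ".", feature_id = enhancers$feature_id)
  has_strand <- function(str) {
    cl <- clusters[strand == str]
    if (nrow(cl) == 0L) return(rep(FALSE, nrow(win)))
    cli <- data.table(chrom = cl$chrom, start = cl$start, end = cl$end,
                      strand = ".", feature_id = sprintf("c%d", seq_len(nrow(cl))))
    ov <- find_interval_overlaps(win, cli)
    seq_len(nrow(win)) %in% ov$query
  }
  out <- copy(enhancers)
  out[, bidirectional := has_strand("+") & has_strand("-")]
  out
}

#' Quantify enhancer activity and directionality
#'
#' For each enhancer, counts CAGE tags in the two flanking 200 nt windows
#' (R: minus strand, [mid - 200, mid); F: plus strand, [mid, mid + 200)),
#' normalizes window counts to TPM and then between samples by RLE (the
#' twice-normalized chain). The directionality score D = (F - R)/(F + R) is
#' cohort-level, computed from the across-sample sums of normalized window
#' expression; per-sample activity is F_s + R_s.
#'
#' @param tag_streams named list of per-sample tag streams
#' @param enhancers enhancer table (must carry `midpoint`); typically the
#'   bidirectional subset from [select_bidirectional()]
#' @param window flanking window width (default 200 nt)
#' @return list: `quants` (`data.table`: enhancer_id, midpoint, F, R, D,
#'   n_null), `activity` (enhancers x samples matrix of summed normalized
#'   window expression), `size_factors`
#' @export
directionality_and_quantify <- function(tag_streams, enhancers, window = 200) {
  stopifnot(nrow(enhancers) > 0)
  w <- as.integer(window)
  fwin <- data.table(chrom = enhancers$chrom, start = enhancers$midpoint,
                     end = enhancers$midpoint + w, strand = "+",
                     feature_id = paste0(enhancers$feature_id, "_F"))
  rwin <- data.table(chrom = enhancers$chrom, start = enhancers$midpoint - w,
                     end = enhancers$midpoint, strand = "-",
                     feature_id = paste0(enhancers$feature_id, "_R"))
  wins <- rbindlist(list(fwin, rwin))
  raw <- aggregate_tags_to_features(tag_streams, wins, "same-strand")
  lib <- vapply(tag_streams, function(ts) sum(ts$count), numeric(1))
  tpm <- tpm_normalize(raw, lib)
  sf <- tryCatch(rle_size_factors(tpm), error = function(e) {
    message("enhancer window RLE degenerate; size factors set to 1")
    setNames(rep(1, ncol(tpm)), colnames(tpm))
  })
  norm <- sweep(tpm, 2, sf, "/")
  nf <- norm[seq_len(nrow(enhancers)), , drop = FALSE]
  nr <- norm[nrow(enhancers) + seq_len(nrow(enhancers)), , drop = FALSE]
  Fsum <- rowSums(nf); Rsum <- rowSums(nr)
  D <- ifelse(Fsum + Rsum > 0, (Fsum - Rsum) / (Fsum + Rsum), NA_real_)
  activity <- nf + nr
  rownames(activity) <- enhancers$feature_id
  quants <- data.table(enhancer_id = enhancers$feature_id,
                       midpoint = enhancers$midpoint,
                       F = Fsum, R = Rsum, D = D,
                       n_null = rowSums(activity == 0))
  list(quants = quants, activity = activity, size_factors = sf)
}

#' Build the enhancer activity matrix
#'
#' Keeps enhancers with defined |D| < `d_max` and with zero-activity sample
#' count at most `max_null_fraction` of the cohort; enhancers with F + R = 0
#' (undefined D) are dropped with a message.
#'
#' @param quant result of [directionality_and_quantify()]
#' @param enhancers the enhancer interval table the quants were computed on
#' @param d_max maximum |D| (default 0.8, strict)
#' @param max_null_fraction maximum fraction of samples with zero activity
#'   (default 50/154, mirroring an absolute cutoff of 50 of 154 samples)
#' @return `expression_matrix`-like list: `values` (kept enhancers x
#'   samples), `features`, `quants` (kept rows), `size_factors`
#' @export
build_enhancer_matrix <- function(quant, enhancers, d_max = 0.8,
                                  max_null_fraction = 50 / 154) {
  q <- quant$quants
  n_samples <- ncol(quant$activity)
  undef <- is.na(q$D)
  if (any(undef))
    message(sum(undef), " enhancer(s) dropped: F + R = 0 (D undefined)")
  keep <- !undef & abs(q$D) < d_max & q$n_null <= max_null_fraction * n_samples
  if (!any(keep)) stop("no enhancer passes the directionality and null filters")
  feats <- enhancers[match(q$enhancer_id[keep], enhancers$feature_id)]
  structure(list(values = quant$activity[keep, , drop = FALSE],
                 size_factors = quant$size_factors,
                 features = feats, quants = q[keep]),
            class = "expression_matrix")
}
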