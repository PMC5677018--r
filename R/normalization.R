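# TPM / RLE normalization of CAGE feature counts and covariate derivation.

#' Tags-per-million normalization
#'
#' @param raw_counts features x samples count matrix
#' @param library_sizes per-sample mapped-tag totals (> 0), recycled from
#'   column sums when `NULL`
#' @return matrix of TPM values (count * 1e6 / library size)
#' @export
tpm_normalize <- function(raw_counts, library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- colSums(raw_counts)
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  if (length(library_sizes) != ncol(raw_counts))
    stop("library_sizes must have one entry per sample")
  sweep(raw_counts, 2, library_sizes, "/") * 1e6
}

#' Relative log expression (median-of-ratios) size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features nonzero in every sample) of value / geometric-mean-across-
#' samples, rescaled so the factors have geometric mean 1.
#'
#' @param m features x samples matrix of nonnegative values
#' @return numeric vector of size factors (geometric mean 1)
#' @export
rle_size_factors <- function(m) {
  all_nz <- rowSums(m <= 0) == 0L
  if (!any(all_nz)) stop("degenerate matrix: no feature is nonzero in every sample")
  logm <- log(m[all_nz, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Apply RLE normalization
#'
#' @param m features x samples matrix
#' @param size_factors optional precomputed factors
#' @return list with `values` (normalized matrix) and `size_factors`
#' @export
rle_normalize <- function(m, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- rle_size_factors(m)
  list(values = sweep(m, 2, size_factors, "/"), size_factors = size_factors)
}

#' Filter features by mean expression
#'
#' Keeps features whose mean over samples is at least `threshold`
#' (boundary value kept).
#'
#' @param m features x samples normalized matrix
#' @param threshold minimum mean expression (default 0.5 RLE-TPM)
#' @return filtered matrix, with attributes `n_kept` and `n_dropped`
#' @export
filter_by_mean <- function(m, threshold = 0.5) {
  keep <- rowMeans(m) >= threshold
  out <- m[keep, , drop = FALSE]
  setattr(out, "n_kept", sum(keep))
  setattr(out, "n_dropped", sum(!keep))
  out
}

#' Principal-component covariates
#'
#' Computes the top-k principal-component scores of the sample-by-feature
#' data. Expression features are centered and scaled to unit variance;
#' genotype dosages are centered only.
#'
#' @param m features x samples matrix (expression) or a `genotype_matrix`
#' @param k number of components (0 < k < n_samples)
#' @return samples x k matrix of PC scores
#' @export
pca_covariates <- function(m, k) {
  if (k <= 0) stop("k must be positive")
  if (inherits(m, "genotype_matrix")) {
    x <- m$dosage
    for (j in seq_len(ncol(x))) {
      xm <- mean(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- xm
    }
    scale_flag <- FALSE
  } else {
    x <- t(m)
    scale_flag <- TRUE
  }
  if (k >= nrow(x)) stop("k must be smaller than the number of samples")
  keep <- apply(x, 2, function(col) sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = scale_flag)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}

#' Rank-based inverse normal transform, per feature
#'
#' @param m features x samples matrix
#' @return matrix of the same shape; each row mapped to normal scores
#'   qnorm((rank - 0.5)/n), ties by average rank
#' @export
inverse_normal_transform <- function(m) {
  t(apply(m, 1, function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x))))
}

#' Build a normalized expression matrix from tag streams
#'
#' Aggregates tags into feature counts, applies TPM then RLE normalization,
#' and filters on mean expression: the standard promoter-expression chain.
#'
#' @param tag_streams named list of per-sample tag streams
#' @param intervals feature intervals (CAGE peaks)
#' @param strand_rule passed to [aggregate_tags_to_features()]
#' @param mean_threshold minimum mean RLE-TPM (default 0.5)
#' @return list of class `expression_matrix` with elements `values`
#'   (features x samples, RLE-TPM), `size_factors`, `features` (interval
#'   table restricted to kept features), `library_sizes`
#' @export
build_expression_matrix <- function(tag_streams, intervals,
                                    strand_rule = "same-strand",
                                    mean_threshold = 0.5) {
  raw <- aggregate_tags_to_features(tag_streams, intervals, strand_rule)
  lib <- vapply(tag_streams, function(ts) sum(ts$count), numeric(1))
  tpm <- tpm_normalize(raw, lib)
  nz <- rowSums(tpm <= 0) == 0L
  sf <- if (any(nz)) rle_size_factors(tpm) else setNames(rep(1, ncol(tpm)), colnames(tpm))
  norm <- sweep(tpm, 2, sf, "/")
  filt <- filter_by_mean(norm, mean_threshold)
  feats <- intervals[match(rownames(filt), intervals$feature_id)]
  structure(list(values = filt, size_factors = sf, features = feats,
                 library_sizes = lib, raw = raw[rownames(filt), , drop = FALSE]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (RLE-TPM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
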