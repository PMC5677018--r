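# Permutation-based cis-QTL mapping within TAD windows, with Storey q-value
# control genome-wide. Shared by the puQTL, eaQTL and gene-level passes.

#' Residualize a phenotype on covariates
#'
#' Ordinary least squares; residuals are orthogonal to every covariate
#' column. An intercept is always included.
#'
#' @param y numeric phenotype vector, or a samples x phenotypes matrix
#' @param covariates samples x k covariate matrix (may be NULL)
#' @return residuals with the same shape as `y`
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  C <- cbind(intercept = rep(1, nrow(y)), covariates)
  qr_c <- qr(C)
  if (qr_c$rank < ncol(C)) stop("covariate matrix is rank deficient")
  res <- qr.resid(qr_c, y)
  if (ncol(res) == 1L) drop(res) else res
}

# column-standardize (mean 0, sd 1); zero-variance columns flagged NA
std_cols <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2, mu)^2) / (nrow(m) - 1))
  out <- sweep(m, 2, mu)
  ok <- s > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, s[ok], "/")
  out[, !ok] <- NA_real_
  attr(out, "sd") <- s
  out
}

r_to_p <- function(r, df) {
  r2 <- pmin(r^2, 1 - 1e-14)
  tstat <- abs(r) * sqrt(df / (1 - r2))
  2 * pt(tstat, df = df, lower.tail = FALSE)
}

#' Nominal association scan of one phenotype across a variant window
#'
#' Simple linear regression of the (already residualized) phenotype on each
#' variant's dosage. P-values come from the t statistic of the correlation
#' with df = n - 2 - n_covariates, correcting the degrees of freedom for the
#' prior residualization. The lead variant has the smallest p, ties broken
#' by smallest genomic position.
#'
#' @param y residualized phenotype (length n)
#' @param dosage samples x variants dosage matrix (the window)
#' @param variant_meta `data.table` with variant_id and pos for the window
#'   columns
#' @param n_covariates number of covariates regressed out beforehand
#' @return `data.table` (variant_id, pos, beta, r, p) with monomorphic
#'   variants skipped; attribute `lead` = row index of the lead variant
#' @export
nominal_scan <- function(y, dosage, variant_meta, n_covariates = 0) {
  n <- length(y)
  df <- n - 2 - n_covariates
  gs <- std_cols(dosage)
  sds <- attr(gs, "sd")
  ok <- which(sds > 0)
  if (!length(ok)) {
    out <- data.table(variant_id = character(), pos = integer(),
                      beta = numeric(), r = numeric(), p = numeric())
    setattr(out, "lead", NA_integer_)
    return(out)
  }
  ys <- (y - mean(y))
  ysd <- sqrt(sum(ys^2) / (n - 1))
  r <- as.vector(crossprod(gs[, ok, drop = FALSE], ys / ysd)) / (n - 1)
  beta <- r * ysd / sds[ok]
  p <- r_to_p(r, df)
  out <- data.table(variant_id = variant_meta$variant_id[ok],
                    pos = variant_meta$pos[ok], beta = beta, r = r, p = p)
  lead <- order(out$p, out$pos)[1]
  setattr(out, "lead", lead)
  out
}

# per-phenotype RNG seed derived from the global seed so results do not
# depend on scheduling order
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

fit_beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  if (v <= 0) return(c(a = 1, b = 1))
  k <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * k, (1 - m) * k), 1e-3))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(optim(start, nll, method = "Nelder-Mead"), error = function(e) NULL)
  if (is.null(fit)) return(c(a = exp(start[1]), b = exp(start[2])))
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Permutation adjustment of the best in-window association
#'
#' Shuffles the covariate-residualized phenotype across samples `n_perm`
#' times, recording the best in-window p-value of each permutation.
#' `empirical` mode returns (1 + #\{perm best p <= observed\}) / (1 + n_perm);
#' `beta` mode fits a two-parameter Beta distribution to the permutation
#' best-p values by maximum likelihood and returns its CDF at the observed
#' best p.
#'
#' @param y residualized phenotype
#' @param dosage samples x variants window dosage matrix
#' @param n_perm number of permutations (default 1000)
#' @param mode `"beta"` or `"empirical"`; beta with fewer than 100
#'   permutations falls back to empirical with a warning
#' @param n_covariates degrees-of-freedom correction
#' @param seed RNG seed for the permutations
#' @param perm_indices optional n x n_perm matrix of explicit permutation
#'   indices (e.g. the full enumeration for small n); overrides random
#'   shuffling
#' @return list: adjusted_p, best_nominal_p, empirical_p, beta_shape (a, b or
#'   NULL), n_perm
#' @export
permutation_adjust <- function(y, dosage, n_perm = 1000,
                               mode = c("beta", "empirical"),
                               n_covariates = 0, seed = 1L,
                               perm_indices = NULL) {
  mode <- match.arg(mode)
  if (!is.null(perm_indices)) n_perm <- ncol(perm_indices)
  if (mode == "beta" && n_perm < 100) {
    warning("beta approximation unstable with n_perm < 100; using empirical")
    mode <- "empirical"
  }
  n <- length(y)
  df <- n - 2 - n_covariates
  gs <- std_cols(dosage)
  ok <- which(attr(gs, "sd") > 0)
  if (!length(ok)) stop("window contains only monomorphic variants")
  gs <- gs[, ok, drop = FALSE]
  ys <- (y - mean(y)) / sqrt(sum((y - mean(y))^2) / (n - 1))
  r_obs <- abs(as.vector(crossprod(gs, ys)) / (n - 1))
  best_r <- max(r_obs)
  best_p <- r_to_p(best_r, df)
  if (is.null(perm_indices)) {
    set.seed(seed)
    perm_indices <- replicate(n_perm, sample.int(n))
  }
  Yp <- matrix(ys[perm_indices], nrow = n)
  rp <- abs(crossprod(Yp, gs)) / (n - 1)      # n_perm x n_variants
  best_rp <- rp[cbind(seq_len(n_perm), max.col(rp, ties.method = "first"))]
  best_pp <- r_to_p(best_rp, df)
  emp <- (1 + sum(best_pp <= best_p)) / (1 + n_perm)
  if (mode == "empirical")
    return(list(adjusted_p = emp, best_nominal_p = best_p, empirical_p = emp,
                beta_shape = NULL, n_perm = n_perm))
  shape <- fit_beta_mle(best_pp)
  list(adjusted_p = pbeta(best_p, shape["a"], shape["b"]),
       best_nominal_p = best_p, empirical_p = emp,
       beta_shape = shape, n_perm = n_perm)
}

#' Storey pi0 estimate and q-values
#'
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the lambda grid,
#' smoothed with a cubic spline and evaluated at the largest lambda, clipped
#' to (0, 1]. q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j).
#'
#' @param p vector of p-values in [0, 1]
#' @param lambda_grid grid for the pi0 estimator
#' @return list: pi0, qvalues (same order as `p`), lambda_grid
#' @export
storey_qvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(p)
  pi0_l <- vapply(lambda_grid, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  pi0 <- if (length(lambda_grid) >= 4 && var(pi0_l) > 0) {
    sp <- smooth.spline(lambda_grid, pi0_l, df = 3)
    predict(sp, x = max(lambda_grid))$y
  } else pi0_l[length(pi0_l)]
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p)
  ranked <- p[o]
  q <- pi0 * m * ranked / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  qout <- numeric(m)
  qout[o] <- q
  list(pi0 = pi0, qvalues = qout, lambda_grid = lambda_grid)
}

#' Keep results significant at the chosen FDR
#'
#' @param results `data.table` with a `qvalue` column
#' @param fdr false discovery rate threshold (default 0.05; q < fdr kept)
#' @return the significant subset
#' @export
call_significant <- function(results, fdr = 0.05) {
  results[qvalue < fdr]
}

#' Assign phenotypes to cis windows
#'
#' Each phenotype anchor (stranded 5' end for CAGE peaks, midpoint for
#' enhancers) is looked up in the TAD set; the candidate variants are all
#' variants inside that TAD. Phenotypes outside every TAD fall back to a
#' +/- `orphan_flank` window around the anchor (logged via attribute).
#'
#' @param features interval `data.table` of phenotypes
#' @param tads interval `data.table` of TADs
#' @param variants variant table (chrom, pos)
#' @param anchor_type `"peak"` or `"midpoint"`
#' @param orphan_flank fallback half-window in bases (default 1 Mb)
#' @return list per phenotype of integer variant indices; attribute
#'   `n_orphans`
#' @export
assign_cis_windows <- function(features, tads, variants,
                               anchor_type = c("peak", "midpoint"),
                               orphan_flank = 1e6) {
  anchor_type <- match.arg(anchor_type)
  anchor <- feature_anchor(features, anchor_type)
  fa <- data.table(chrom = features$chrom, start = anchor, end = anchor + 1L,
                   strand = ".", feature_id = features$feature_id)
  ov <- find_interval_overlaps(fa, tads)
  tad_of <- rep(NA_integer_, nrow(features))
  tad_of[ov$query] <- ov$subject
  n_orphans <- sum(is.na(tad_of))
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    if (!is.na(tad_of[i])) {
      t <- tad_of[i]
      out[[i]] <- which(variants$chrom == tads$chrom[t] &
                          variants$pos >= tads$start[t] & variants$pos < tads$end[t])
    } else {
      out[[i]] <- which(variants$chrom == features$chrom[i] &
                          variants$pos >= anchor[i] - orphan_flank &
                          variants$pos < anchor[i] + orphan_flank)
    }
  }
  names(out) <- features$feature_id
  setattr(out, "n_orphans", n_orphans)
  out
}

#' Map cis QTLs for an expression matrix
#'
#' For each phenotype: residualize on covariates, scan all variants in the
#' phenotype's TAD window, adjust the best association by permutation, then
#' control the FDR genome-wide with Storey q-values.
#'
#' @param expr an `expression_matrix` (or list with `values` and `features`)
#' @param genotypes `genotype_matrix`
#' @param tads TAD interval table
#' @param covariates samples x k covariate matrix (e.g. from
#'   [qtl_covariates()]); NULL for none
#' @param n_perm permutations per phenotype (default 1000)
#' @param mode `"beta"` or `"empirical"` adjustment
#' @param transform per-feature phenotype transform before mapping:
#'   `"rank"` (inverse-normal, default), `"log"` (log of values + small
#'   offset), or `"none"`
#' @param anchor_type `"peak"` (stranded 5' end) or `"midpoint"`
#' @param fdr FDR threshold for the significance call
#' @param seed global seed; per-phenotype permutation seeds derive from it
#' @return `data.table` of class `qtl_result`: one row per phenotype with
#'   lead variant, slope, nominal/adjusted/empirical p, q-value, and window
#'   size; attribute `significant` holds the q < fdr subset
#' @export
map_cis_qtl <- function(expr, genotypes, tads, covariates = NULL,
                        n_perm = 1000, mode = c("beta", "empirical"),
                        transform = c("rank", "log", "none"),
                        anchor_type = c("peak", "midpoint"),
                        fdr = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  anchor_type <- match.arg(anchor_type)
  vals <- expr$values
  feats <- expr$features
  pheno <- switch(transform,
                  rank = inverse_normal_transform(vals),
                  log = log(vals + 1e-3),
                  none = vals)
  dos <- genotypes$dosage
  # mean-impute missing dosages once
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  stopifnot(ncol(pheno) == nrow(dos))
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  Yres <- residualize(t(pheno), covariates)   # samples x phenotypes
  windows <- assign_cis_windows(feats, tads, genotypes$variants, anchor_type)
  anchor <- feature_anchor(feats, anchor_type)
  rows <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    w <- windows[[i]]
    if (!length(w)) next
    sub <- dos[, w, drop = FALSE]
    sds <- apply(sub, 2, sd)
    if (all(sds == 0)) next
    y <- Yres[, i]
    scan <- nominal_scan(y, sub, genotypes$variants[w], n_covariates = n_cov)
    lead <- attr(scan, "lead")
    adj <- permutation_adjust(y, sub, n_perm = n_perm, mode = mode,
                              n_covariates = n_cov,
                              seed = derive_seed(seed, i))
    rows[[i]] <- data.table(
      phenotype_id = feats$feature_id[i], chrom = feats$chrom[i],
      start = feats$start[i], end = feats$end[i], strand = feats$strand[i],
      variant_id = scan$variant_id[lead],
      distance = scan$pos[lead] - anchor[i],
      beta = scan$beta[lead], nominal_p = scan$p[lead],
      adjusted_p = adj$adjusted_p, empirical_p = adj$empirical_p,
      beta_shape_a = if (is.null(adj$beta_shape)) NA_real_ else adj$beta_shape[["a"]],
      beta_shape_b = if (is.null(adj$beta_shape)) NA_real_ else adj$beta_shape[["b"]],
      n_variants = nrow(scan), n_perm = n_perm)
  }
  res <- rbindlist(rows)
  if (nrow(res) == 0L) stop("no phenotype could be tested")
  qv <- storey_qvalue(res$adjusted_p)
  res[, qvalue := qv$qvalues]
  setattr(res, "pi0", qv$pi0)
  setattr(res, "significant", call_significant(res, fdr))
  setattr(res, "class", c("qtl_result", class(res)))
  res
}

#' Standard covariate set for QTL mapping
#'
#' Genotype principal components plus expression principal components,
#' following common practice for CAGE-based QTL scans (3 genotype PCs with
#' 20 expression PCs for promoters, 12 for enhancers).
#'
#' @param expr `expression_matrix`
#' @param genotypes `genotype_matrix`
#' @param n_geno_pc genotype PCs (default 3)
#' @param n_expr_pc expression PCs (default 20)
#' @return samples x (n_geno_pc + n_expr_pc) covariate matrix
#' @export
qtl_covariates <- function(expr, genotypes, n_geno_pc = 3, n_expr_pc = 20) {
  n <- ncol(expr$values)
  n_expr_pc <- min(n_expr_pc, nrow(expr$values) - 1L, n - 2L)
  n_geno_pc <- min(n_geno_pc, n - 2L)
  g <- pca_covariates(genotypes, n_geno_pc)
  e <- pca_covariates(expr$values, n_expr_pc)
  colnames(g) <- paste0("gPC", seq_len(ncol(g)))
  colnames(e) <- paste0("ePC", seq_len(ncol(e)))
  cbind(g, e)
}
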