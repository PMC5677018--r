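# Cross-phenotype integration statistics: pi1 replication, LD, regulatory
# trait concordance (RTC), matched-permutation enrichment, causal inference
# testing on variant-enhancer-promoter triplets, and hierarchical TSS
# annotation.

#' Proportion of truly alternative tests (pi1)
#'
#' pi1 = 1 - pi0, with pi0 from the Storey estimator used by
#' [storey_qvalue()]. A bootstrap standard error over tests is included.
#'
#' @param pvalues p-values of the replication tests
#' @param lambda_grid grid for pi0
#' @param n_boot bootstrap resamples for the standard error (default 100)
#' @param seed RNG seed for the bootstrap
#' @return list: pi1, pi0, se, m, lambda_grid
#' @export
pi1 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                n_boot = 100, seed = 1L) {
  m <- length(pvalues)
  if (m < 100) warning("pi1 is unstable with fewer than 100 tests")
  pi0 <- storey_qvalue(pvalues, lambda_grid)$pi0
  se <- NA_real_
  if (n_boot > 0 && m >= 10) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      storey_qvalue(sample(pvalues, m, replace = TRUE), lambda_grid)$pi0
    }, numeric(1))
    se <- sd(1 - bs)
  }
  list(pi1 = 1 - pi0, pi0 = pi0, se = se, m = m, lambda_grid = lambda_grid)
}

#' LD statistics between two variants
#'
#' @param genotypes `genotype_matrix`
#' @param v1,v2 variant ids
#' @return list: r2 (squared Pearson correlation of dosages), rho (Spearman)
#' @export
ld_stats <- function(genotypes, v1, v2) {
  d1 <- genotypes$dosage[, v1]
  d2 <- genotypes$dosage[, v2]
  ok <- complete.cases(d1, d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (sd(d1) == 0 || sd(d2) == 0) stop("monomorphic variant: LD undefined")
  list(r2 = cor(d1, d2)^2, rho = cor(d1, d2, method = "spearman"))
}

#' Regulatory trait concordance (RTC)
#'
#' Tests whether a QTL variant and a GWAS variant tag the same functional
#' signal. For every variant s of the interval, the phenotype is
#' residualized on s and the QTL variant's association with the residual is
#' recorded; the rank counts how many of these pseudo-corrections destroy
#' the QTL association more than (or as much as) correcting on the GWAS
#' variant itself. RTC = (N - rank)/N: near 1 when removing the GWAS variant
#' is the most destructive correction (shared signal), uniform when the two
#' signals are independent.
#'
#' @param phenotype covariate-residualized phenotype vector
#' @param genotypes `genotype_matrix`
#' @param gwas_variant,qtl_variant variant ids, both inside the interval
#' @param interval_variants character vector of the N variant ids in the
#'   interval (defaults: all variants of the QTL variant's TAD)
#' @param high_confidence RTC threshold for the high-confidence flag
#'   (default 0.9)
#' @return list of class `rtc_result`: rtc, rank, n_variants, p_gwas
#'   (QTL association p after the GWAS correction), high_confidence
#' @export
rtc <- function(phenotype, genotypes, gwas_variant, qtl_variant,
                interval_variants, high_confidence = 0.9) {
  iv <- unique(c(interval_variants, gwas_variant, qtl_variant))
  iv <- iv[iv %in% colnames(genotypes$dosage)]
  N <- length(iv)
  if (N < 2) stop("RTC needs at least 2 variants in the interval")
  dos <- genotypes$dosage[, iv, drop = FALSE]
  for (j in seq_len(ncol(dos))) {
    if (anyNA(dos[, j])) dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
  }
  n <- length(phenotype)
  dq <- dos[, qtl_variant]
  p_after <- vapply(seq_len(N), function(j) {
    res_y <- residualize(phenotype, dos[, j])
    res_q <- residualize(dq, dos[, j])
    if (sd(res_q) < 1e-12) return(1)
    r <- cor(res_y, res_q)
    r_to_p(r, n - 3)
  }, numeric(1))
  p_gwas <- p_after[match(gwas_variant, iv)]
  # rank: corrections at least as destructive as the GWAS correction
  rank0 <- sum(p_after[iv != gwas_variant] > p_gwas)
  score <- (N - rank0) / N
  structure(list(rtc = score, rank = rank0, n_variants = N, p_gwas = p_gwas,
                 high_confidence = score > high_confidence),
            class = "rtc_result")
}

# MAF decile and log-spaced TSS-distance bins for matched null sampling
match_bins <- function(maf, tss_dist, n_maf_bins = 10, n_dist_bins = 10) {
  mb <- cut(maf, breaks = quantile(maf, probs = seq(0, 1, length.out = n_maf_bins + 1)),
            include.lowest = TRUE, labels = FALSE)
  d <- log10(pmax(abs(tss_dist), 1))
  db <- cut(d, breaks = seq(min(d), max(d) + 1e-9, length.out = n_dist_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  paste(mb, db, sep = ":")
}

#' GWAS-hit overlap enrichment with matched permutations
#'
#' A QTL variant overlaps when it matches a GWAS catalog variant or lies
#' within +/- `flank` of one with r2 > `r2_min`. The null redraws each QTL
#' variant from non-QTL variants in the same MAF decile and log-spaced
#' TSS-distance bin (bins widened when empty) and re-counts, `n_perm` times.
#'
#' @param qtl_variants character vector of QTL variant ids
#' @param gwas_catalog `data.table` (variant_id, chrom, pos)
#' @param genotypes `genotype_matrix`
#' @param tss_positions per-variant distance-to-nearest-TSS basis: a
#'   `data.table` of TSS positions (chrom, pos), used to compute distances
#' @param flank maximum distance to a GWAS variant (default 5e5)
#' @param r2_min minimum LD with the GWAS variant (default 0.5)
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return list of class `enrichment_result`: observed, perm_mean, odds_ratio,
#'   ci (2.5/97.5 permutation percentiles), p, n_perm
#' @export
gwas_overlap_enrichment <- function(qtl_variants, gwas_catalog, genotypes,
                                    tss_positions, flank = 5e5, r2_min = 0.5,
                                    n_perm = 1000, seed = 1L) {
  v <- genotypes$variants
  dos <- genotypes$dosage
  tss_dist <- vapply(seq_len(nrow(v)), function(i) {
    same <- tss_positions[chrom == v$chrom[i]]
    if (nrow(same) == 0L) return(Inf)
    min(abs(same$pos - v$pos[i]))
  }, numeric(1))
  bins <- match_bins(v$maf, tss_dist)
  is_qtl <- v$variant_id %in% qtl_variants
  overlaps_one <- function(ids) {
    vapply(ids, function(id) {
      i <- match(id, v$variant_id)
      if (v$variant_id[i] %in% gwas_catalog$variant_id) return(TRUE)
      near <- gwas_catalog[chrom == v$chrom[i] & abs(pos - v$pos[i]) <= flank]
      if (nrow(near) == 0L) return(FALSE)
      for (gid in near$variant_id) {
        if (!gid %in% colnames(dos)) next
        r2 <- suppressWarnings(cor(dos[, id], dos[, gid], use = "complete.obs")^2)
        if (!is.na(r2) && r2 > r2_min) return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  qtl_ids <- qtl_variants[qtl_variants %in% v$variant_id]
  obs_flags <- overlaps_one(qtl_ids)
  observed <- sum(obs_flags)
  nq <- length(qtl_ids)
  # pool of matched null candidates per bin
  pool <- split(v$variant_id[!is_qtl], bins[!is_qtl])
  maf_bin_of <- sub(":.*", "", bins)
  pool_maf <- split(v$variant_id[!is_qtl], maf_bin_of[!is_qtl])
  qtl_bins <- bins[match(qtl_ids, v$variant_id)]
  qtl_maf_bins <- maf_bin_of[match(qtl_ids, v$variant_id)]
  # precompute overlap flags for all pool variants on demand (cache)
  flag_cache <- new.env(parent = emptyenv())
  overlap_cached <- function(id) {
    val <- flag_cache[[id]]
    if (is.null(val)) {
      val <- overlaps_one(id)
      flag_cache[[id]] <- val
    }
    val
  }
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(b) {
    draws <- vapply(seq_len(nq), function(i) {
      cand <- pool[[qtl_bins[i]]]
      if (is.null(cand) || !length(cand)) cand <- pool_maf[[qtl_maf_bins[i]]]  # widen
      if (is.null(cand) || !length(cand)) cand <- v$variant_id[!is_qtl]
      cand[sample.int(length(cand), 1)]
    }, character(1))
    sum(vapply(draws, overlap_cached, logical(1)))
  }, numeric(1))
  perm_mean <- mean(perm_counts)
  odds <- function(k) (k + 0.5) / (nq - k + 0.5)
  or <- odds(observed) / odds(perm_mean)
  ci <- odds(observed) / odds(rev(quantile(perm_counts, c(0.025, 0.975))))
  p <- (1 + sum(perm_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, perm_mean = perm_mean, odds_ratio = or,
                 ci = sort(unname(ci)), p = p, n_perm = n_perm, n_qtl = nq),
            class = "enrichment_result")
}

#' Causal inference test for one triplet, one direction
#'
#' Tests whether M mediates the effect of L on T through four component
#' tests: (1) T ~ L; (2) M ~ L given T; (3) T ~ M given L; (4) an
#' equivalence test of the conditional independence of L and T given M. The
#' omnibus p is the maximum of the four. Component 4 is an equivalence test:
#' the mediator is permuted within strata of its fitted values on L (the
#' genotype classes, for a dosage), which preserves the mediator's
#' dependence on L while severing its link to T, so the F statistic of the
#' L block in T ~ M* + L follows the no-mediation alternative; p4 is the
#' fraction of permuted statistics at or below the observed F. Small p4
#' supports conditional independence (i.e. complete mediation).
#'
#' @param L dosage vector
#' @param M candidate mediator
#' @param T_ outcome
#' @param covariates optional covariate matrix
#' @param n_perm permutations for component 4 (default 500)
#' @param seed RNG seed
#' @return list: p1..p4, omnibus_p
#' @export
cit_direction <- function(L, M, T_, covariates = NULL, n_perm = 500, seed = 1L) {
  if (sd(L) == 0 || sd(M) == 0 || sd(T_) == 0) stop("zero-variance input")
  ok <- complete.cases(L, M, T_)
  L <- L[ok]; M <- M[ok]; T_ <- T_[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(L)
  # genotype dosages are modelled saturated (one indicator per genotype
  # class) so nonlinear allelic effects cannot masquerade as conditional
  # dependence; a continuous L enters linearly
  Lmat <- if (length(unique(L)) <= 3) {
    stats::model.matrix(~ factor(L))[, -1, drop = FALSE]
  } else cbind(L = L)
  ones <- rep(1, n)
  fstat_block <- function(y, X_other, X_block) {
    X_full <- cbind(ones, covariates, X_other, X_block)
    q_full <- qr(X_full)
    q_red <- qr(cbind(ones, covariates, X_other))
    rss_full <- sum(qr.resid(q_full, y)^2)
    rss_red <- sum(qr.resid(q_red, y)^2)
    df1 <- q_full$rank - q_red$rank
    df2 <- n - q_full$rank
    list(f = max(0, (rss_red - rss_full) / df1 / (rss_full / df2)),
         df1 = df1, df2 = df2)
  }
  p_of <- function(fs) pf(fs$f, fs$df1, fs$df2, lower.tail = FALSE)
  f1 <- fstat_block(T_, NULL, Lmat)
  p1 <- p_of(f1)
  p2 <- p_of(fstat_block(M, cbind(T_), Lmat))
  p3 <- p_of(fstat_block(T_, Lmat, cbind(M)))
  f_obs <- fstat_block(T_, cbind(M), Lmat)$f
  # component 4: permutation of the mediator within strata of its fitted
  # values on L (the genotype classes for a dosage). The permuted mediator
  # keeps its dependence on L but loses any link to T, so the L-block F in
  # T ~ M* + L follows the no-mediation alternative; a small fraction of
  # permuted F's at or below the observed F supports conditional
  # independence (complete mediation)
  fitL <- cbind(ones, covariates, Lmat)
  fitM <- drop(fitL %*% qr.coef(qr(fitL), M))
  strata <- if (length(unique(fitM)) <= 4) as.integer(factor(fitM)) else
    as.integer(cut(fitM, breaks = unique(quantile(fitM, probs = seq(0, 1, 0.25))),
                   include.lowest = TRUE, labels = FALSE))
  idx_by_stratum <- split(seq_len(n), strata)
  set.seed(seed)
  Mp <- matrix(M, n, n_perm)
  for (ix in idx_by_stratum) {
    if (length(ix) > 1)
      Mp[ix, ] <- vapply(seq_len(n_perm), function(b) M[ix][sample.int(length(ix))],
                         numeric(length(ix)))
  }
  # F of the L block in T ~ M* + L, vectorized over permutations: all
  # variables are first residualized on [1, covariates], then each
  # permutation needs only a small Gram solve
  B0 <- qr(cbind(ones, covariates))
  T0 <- qr.resid(B0, T_)
  L0 <- qr.resid(B0, Lmat)
  M0 <- qr.resid(B0, Mp)
  df1 <- qr(L0)$rank
  df2 <- n - B0$rank - 1L - df1
  tt <- sum(T0^2)
  LL <- crossprod(L0)
  LT <- crossprod(L0, T0)
  MM <- colSums(M0^2)
  MT <- as.vector(crossprod(M0, T0))
  ML <- crossprod(M0, L0)              # n_perm x k
  f_perm <- vapply(seq_len(n_perm), function(b) {
    G <- rbind(c(MM[b], ML[b, ]), cbind(ML[b, ], LL))
    cvec <- c(MT[b], LT)
    expl_full <- drop(crossprod(cvec, solve(G, cvec)))
    rss_full <- tt - expl_full
    rss_red <- tt - MT[b]^2 / MM[b]
    max(0, (rss_red - rss_full) / df1 / (rss_full / df2))
  }, numeric(1))
  p4 <- (1 + sum(f_perm <= f_obs)) / (1 + n_perm)
  ps <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, omnibus_p = max(ps))
}

#' Causal inference test, both directions
#'
#' Runs [cit_direction()] with M as the mediator of L -> T, and again with
#' the roles of M and T swapped; relabeling (M, T) to (T, M) therefore swaps
#' the two directional results exactly.
#'
#' @inheritParams cit_direction
#' @return list of class `cit_result` with elements `forward` (M mediates)
#'   and `reverse` (T mediates)
#' @export
cit_test <- function(L, M, T_, covariates = NULL, n_perm = 500, seed = 1L) {
  structure(list(forward = cit_direction(L, M, T_, covariates, n_perm, seed),
                 reverse = cit_direction(L, T_, M, covariates, n_perm, seed)),
            class = "cit_result")
}

#' Build eaQTL-enhancer-promoter triplets
#'
#' One triplet per (eaQTL variant, its enhancer, each paired promoter).
#' A triplet is flagged shared when the eaQTL variant is itself a puQTL
#' variant or is in LD (Spearman rho > `rho_min`) with one.
#'
#' @param eaqtls significant eaQTL table (phenotype_id = enhancer_id,
#'   variant_id)
#' @param pairs pairing table (enhancer_id, peak_id)
#' @param puqtls significant puQTL table (phenotype_id = peak_id, variant_id)
#' @param genotypes `genotype_matrix` for the LD computation
#' @param rho_min Spearman threshold (default 0.8)
#' @return `data.table`: variant_id, enhancer_id, promoter_id, shared,
#'   best_rho, puqtl_variant
#' @export
build_triplets <- function(eaqtls, pairs, puqtls, genotypes, rho_min = 0.8) {
  if (nrow(pairs) == 0L || nrow(eaqtls) == 0L)
    return(data.table(variant_id = character(), enhancer_id = character(),
                      promoter_id = character(), shared = logical(),
                      best_rho = numeric(), puqtl_variant = character()))
  pu_vars <- unique(puqtls$variant_id)
  rows <- list()
  for (i in seq_len(nrow(eaqtls))) {
    eid <- eaqtls$phenotype_id[i]
    vid <- eaqtls$variant_id[i]
    paired <- pairs[enhancer_id == eid, peak_id]
    if (!length(paired)) next
    best_rho <- 0; shared <- vid %in% pu_vars
    if (!shared && length(pu_vars)) {
      rhos <- vapply(pu_vars, function(pv) {
        if (!pv %in% colnames(genotypes$dosage)) return(0)
        abs(ld_stats(genotypes, vid, pv)$rho)
      }, numeric(1))
      best_rho <- max(rhos)
      shared <- best_rho > rho_min
    } else if (shared) best_rho <- 1
    rows[[length(rows) + 1L]] <- data.table(
      variant_id = vid, enhancer_id = eid, promoter_id = paired,
      shared = shared, best_rho = best_rho,
      puqtl_variant = if (vid %in% pu_vars) vid else NA_character_)
  }
  if (!length(rows)) return(data.table(variant_id = character(), enhancer_id = character(),
                                       promoter_id = character(), shared = logical(),
                                       best_rho = numeric(), puqtl_variant = character()))
  rbindlist(rows)
}

#' Run causal inference testing over triplets
#'
#' For each triplet, tests enhancer activity as the mediator of promoter
#' expression and vice versa; omnibus p-values are FDR-adjusted with
#' [storey_qvalue()] per direction.
#'
#' @param triplets output of [build_triplets()]
#' @param enh_expr,prom_expr `expression_matrix` objects for enhancers and
#'   promoters
#' @param genotypes `genotype_matrix`
#' @param covariates optional covariates
#' @param n_perm CIT permutations
#' @param fdr FDR level for the causal call
#' @param seed RNG seed
#' @return triplet table with component p-values, omnibus p and q per
#'   direction, and the causal call
#' @export
cit_triplets <- function(triplets, enh_expr, prom_expr, genotypes,
                         covariates = NULL, n_perm = 500, fdr = 0.05, seed = 1L) {
  if (nrow(triplets) == 0L) return(triplets)
  out <- copy(triplets)
  fw <- rv <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    vid <- out$variant_id[i]
    L <- genotypes$dosage[, vid]
    L[is.na(L)] <- mean(L, na.rm = TRUE)
    M <- log(enh_expr$values[out$enhancer_id[i], ] + 1e-3)
    T_ <- log(prom_expr$values[out$promoter_id[i], ] + 1e-3)
    ct <- cit_test(L, M, T_, covariates, n_perm, seed = derive_seed(seed, i))
    fw[[i]] <- ct$forward; rv[[i]] <- ct$reverse
  }
  out[, `:=`(p_fwd = vapply(fw, `[[`, numeric(1), "omnibus_p"),
             p_rev = vapply(rv, `[[`, numeric(1), "omnibus_p"))]
  out[, q_fwd := storey_qvalue(p_fwd)$qvalues]
  out[, q_rev := storey_qvalue(p_rev)$qvalues]
  out[, causal_call := fifelse(q_fwd < fdr & q_rev >= fdr, "enhancer_mediates",
                        fifelse(q_rev < fdr & q_fwd >= fdr, "promoter_mediates",
                         fifelse(q_fwd < fdr & q_rev < fdr, "ambiguous", "none")))]
  out
}

#' Hierarchical TSS annotation of CAGE peaks
#'
#' Four-step hierarchy: (1) peaks within 500 nt upstream of an annotated
#' TSS on the same strand, or inside a 5'-UTR first exon or first intron,
#' are "Annotated gene"; otherwise (2) the chromatin segment class decides:
#' enhancer state gives "eRNA/enhancer", promoter state goes to step (3),
#' anything else is "other"; (3) promoter-state peaks overlapping an
#' annotated gene body on the opposite strand are "Antisense promoter",
#' the rest are "Putative promoter" (with intragenic/intergenic recorded).
#'
#' @param peaks CAGE peak interval table
#' @param transcripts transcript annotation intervals with a `type` column
#'   (`utr5_exon`, `utr5_intron`, `gene_body`) and gene strand
#' @param segments chromatin segment intervals with a `state` column
#'   (`promoter`, `enhancer`, ...)
#' @param upstream_window nt upstream of the TSS (default 500)
#' @return `data.table`: feature_id, label, context
#' @export
annotate_tss <- function(peaks, transcripts, segments, upstream_window = 500) {
  n <- nrow(peaks)
  label <- rep("other", n)
  context <- rep(NA_character_, n)
  if (n == 0L) return(data.table(feature_id = character(), label = character(),
                                 context = character()))
  anchor <- feature_anchor(peaks, "peak")
  pk <- data.table(chrom = peaks$chrom, start = anchor, end = anchor + 1L,
                   strand = peaks$strand, feature_id = peaks$feature_id)
  bodies <- transcripts[type == "gene_body"]
  # step 1: within 500 nt upstream of a TSS (same strand), or in 5'UTR
  # first exon / first intron
  tss <- bodies[, .(chrom, strand,
                    tss = fifelse(strand == "+", start, end - 1L))]
  ann1 <- rep(FALSE, n)
  if (nrow(tss)) {
    up <- data.table(chrom = tss$chrom,
                     start = fifelse(tss$strand == "+", tss$tss - as.integer(upstream_window),
                                     tss$tss + 1L),
                     end = fifelse(tss$strand == "+", tss$tss + 1L,
                                   tss$tss + as.integer(upstream_window) + 1L),
                     strand = tss$strand,
                     feature_id = sprintf("up%d", seq_len(nrow(tss))))
    ov <- find_interval_overlaps(pk, up, ignore_strand = TRUE)
    ok <- ov[pk$strand[query] == up$strand[subject]]
    ann1[unique(ok$query)] <- TRUE
  }
  utr <- transcripts[type %in% c("utr5_exon", "utr5_intron")]
  if (nrow(utr)) {
    ov <- find_interval_overlaps(pk, utr, ignore_strand = TRUE)
    ok <- ov[pk$strand[query] == utr$strand[subject]]
    ann1[unique(ok$query)] <- TRUE
  }
  label[ann1] <- "Annotated gene"
  # step 2: chromatin state for the rest
  todo <- which(!ann1)
  if (length(todo) && nrow(segments)) {
    ovs <- find_interval_overlaps(pk[todo], segments)
    st_of <- vapply(seq_along(todo), function(i) {
      s <- segments$state[ovs[query == i, subject]]
      if ("promoter" %in% s) "promoter" else if ("enhancer" %in% s) "enhancer" else "none"
    }, character(1))
    label[todo[st_of == "enhancer"]] <- "eRNA/enhancer"
    # step 3: promoter-state peaks -> antisense vs putative
    prom_idx <- todo[st_of == "promoter"]
    if (length(prom_idx) && nrow(bodies)) {
      ovb <- find_interval_overlaps(pk[prom_idx], bodies)
      for (ii in seq_along(prom_idx)) {
        i <- prom_idx[ii]
        hit <- ovb[query == ii, subject]
        anti <- any(bodies$strand[hit] != pk$strand[i])
        label[i] <- if (anti) "Antisense promoter" else "Putative promoter"
        context[i] <- if (length(hit)) "intragenic" else "intergenic"
      }
    } else if (length(prom_idx)) {
      label[prom_idx] <- "Putative promoter"
      context[prom_idx] <- "intergenic"
    }
  }
  data.table(feature_id = peaks$feature_id, label = label, context = context)
}

#' Functional-annotation enrichment of QTLs against the phenotype landscape
#'
#' Observed = number of QTLs falling inside any annotation interval. Each
#' permutation reassigns every QTL's (distance, side) offset from its
#' phenotype anchor to a uniformly drawn landscape phenotype and re-counts.
#'
#' @param qtl_positions `data.table` (chrom, pos, anchor) of QTL variants
#'   and their phenotype anchor positions
#' @param annotations interval table of functional annotations
#' @param landscape `data.table` (chrom, anchor) of all tested phenotype
#'   anchors
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return `enrichment_result` (see [gwas_overlap_enrichment()])
#' @export
feature_enrichment <- function(qtl_positions, annotations, landscape,
                               n_perm = 1000, seed = 1L) {
  nq <- nrow(qtl_positions)
  count_inside <- function(chrom, pos) {
    pts <- data.table(chrom = chrom, start = as.integer(pos), end = as.integer(pos) + 1L,
                      strand = ".", feature_id = sprintf("q%d", seq_along(pos)))
    length(unique(find_interval_overlaps(pts, annotations)$query))
  }
  observed <- count_inside(qtl_positions$chrom, qtl_positions$pos)
  offset <- qtl_positions$pos - qtl_positions$anchor
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(b) {
    j <- sample.int(nrow(landscape), nq, replace = TRUE)
    count_inside(landscape$chrom[j], landscape$anchor[j] + offset)
  }, numeric(1))
  odds <- function(k) (k + 0.5) / (nq - k + 0.5)
  or <- odds(observed) / odds(mean(perm_counts))
  ci <- sort(unname(odds(observed) / odds(rev(quantile(perm_counts, c(0.025, 0.975))))))
  p <- (1 + sum(perm_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, perm_mean = mean(perm_counts),
                 odds_ratio = or, ci = ci, p = p, n_perm = n_perm, n_qtl = nq),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d observed vs %.1f expected; OR %.2f (CI %.2f-%.2f), p = %.3g\n",
              x$observed, x$n_qtl, x$perm_mean, x$odds_ratio, x$ci[1], x$ci[2], x$p))
  invisible(x)
}
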