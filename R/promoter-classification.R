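# Five-group classification of puQTL-associated genes from the signed
# effects of the gene's lead variant on each of its promoter units.

#' Collapse proximal CAGE peaks into promoter units
#'
#' Single-linkage clustering of a gene's peaks by anchor position:
#' consecutive peaks closer than `max_gap` merge into one promoter unit
#' (so a chain 0, 150, 300 forms a single unit). Each unit carries the beta
#' and p of its most significant member peak.
#'
#' @param peaks `data.table` with columns peak_id, position, beta, p for one
#'   gene
#' @param max_gap merge distance in nt (peaks merge when < max_gap apart)
#' @return `data.table` of units: unit_id, position, beta, p, peak_ids
#' @export
collapse_proximal_peaks <- function(peaks, max_gap = 200) {
  stopifnot(nrow(peaks) > 0)
  o <- order(peaks$position)
  pk <- peaks[o]
  unit <- cumsum(c(1L, as.integer(diff(pk$position) >= max_gap)))
  pk[, .unit := unit]
  out <- pk[, {
    best <- which.min(p)
    .(position = position[best], beta = beta[best], p = p[best],
      peak_ids = paste(peak_id, collapse = ","))
  }, by = .unit]
  setnames(out, ".unit", "unit_id")
  out
}

#' Classify one puQTL-associated gene into groups 1-5
#'
#' Rules: one promoter unit -> group 1. Otherwise restrict to units with
#' p < `p_threshold`: exactly one significant unit -> group 2; two or more
#' with mixed beta signs -> group 3; two or more with the same sign ->
#' effect-size ratio ER = max|beta| / min|beta| over significant units,
#' group 5 when ER > `er_threshold` (strict), group 4 otherwise. A gene
#' whose units all fail `p_threshold` despite genome-wide significance is
#' logged as inconsistent and assigned group 2 on its best unit.
#'
#' @param units promoter units from [collapse_proximal_peaks()]
#' @param p_threshold per-unit significance threshold (default 0.05)
#' @param er_threshold ER cutoff separating groups 4 and 5 (default 2,
#'   strict: ER = 2 exactly is group 4)
#' @return list: group, er (NA unless groups 4/5), n_units,
#'   significant_units (unit ids), inconsistent (logical)
#' @export
classify_gene <- function(units, p_threshold = 0.05, er_threshold = 2) {
  n_units <- nrow(units)
  if (n_units == 1L)
    return(list(group = 1L, er = NA_real_, n_units = 1L,
                significant_units = units$unit_id, inconsistent = FALSE))
  sig <- units[p < p_threshold]
  if (nrow(sig) == 0L) {
    best <- units[which.min(p)]
    return(list(group = 2L, er = NA_real_, n_units = n_units,
                significant_units = best$unit_id, inconsistent = TRUE))
  }
  if (nrow(sig) == 1L)
    return(list(group = 2L, er = NA_real_, n_units = n_units,
                significant_units = sig$unit_id, inconsistent = FALSE))
  if (length(unique(sign(sig$beta))) > 1L)
    return(list(group = 3L, er = NA_real_, n_units = n_units,
                significant_units = sig$unit_id, inconsistent = FALSE))
  er <- max(abs(sig$beta)) / min(abs(sig$beta))
  list(group = if (er > er_threshold) 5L else 4L, er = er, n_units = n_units,
       significant_units = sig$unit_id, inconsistent = FALSE)
}

#' Classify all puQTL-associated genes
#'
#' For each gene with at least one genome-wide significant puQTL peak, takes
#' the gene's lead variant (the variant of its most significant peak-level
#' association), re-tests every peak of the gene against that single
#' variant, collapses proximal peaks into promoter units, and applies the
#' group rules.
#'
#' @param qtl_results `qtl_result` table from [map_cis_qtl()] on CAGE peaks
#' @param expr the `expression_matrix` the QTLs were mapped on (features must
#'   carry a `gene_id` column)
#' @param genotypes `genotype_matrix`
#' @param covariates covariate matrix used in mapping (for consistent
#'   re-testing)
#' @param transform phenotype transform used in mapping
#' @param fdr genome-wide significance threshold on q-values
#' @param p_threshold,er_threshold,max_gap classification parameters
#' @return `data.table`: gene_id, lead_variant, group, er, n_units,
#'   n_peaks, significant_units
#' @export
classify_genes <- function(qtl_results, expr, genotypes, covariates = NULL,
                           transform = c("rank", "log", "none"),
                           fdr = 0.05, p_threshold = 0.05, er_threshold = 2,
                           max_gap = 200) {
  transform <- match.arg(transform)
  feats <- expr$features
  if (!"gene_id" %in% names(feats)) stop("expression features lack gene_id")
  sig <- qtl_results[qvalue < fdr]
  if (nrow(sig) == 0L)
    return(data.table(gene_id = character(), lead_variant = character(),
                      group = integer(), er = numeric(), n_units = integer(),
                      n_peaks = integer(), significant_units = character()))
  sig[, gene_id := feats$gene_id[match(phenotype_id, feats$feature_id)]]
  vals <- switch(transform,
                 rank = inverse_normal_transform(expr$values),
                 log = log(expr$values + 1e-3),
                 none = expr$values)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  dos <- genotypes$dosage
  rows <- list()
  for (g in unique(sig$gene_id)) {
    gq <- sig[gene_id == g][order(adjusted_p)]
    lead_var <- gq$variant_id[1]
    gpeaks <- feats[gene_id == g]
    d <- dos[, lead_var]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    eff <- rbindlist(lapply(gpeaks$feature_id, function(pid) {
      y <- residualize(vals[pid, ], covariates)
      sc <- nominal_scan(y, matrix(d, ncol = 1),
                         data.table(variant_id = lead_var, pos = 0L),
                         n_covariates = n_cov)
      data.table(peak_id = pid, beta = sc$beta[1], p = sc$p[1])
    }))
    eff[, position := feature_anchor(gpeaks, "peak")]
    units <- collapse_proximal_peaks(eff, max_gap = max_gap)
    cl <- classify_gene(units, p_threshold, er_threshold)
    rows[[length(rows) + 1L]] <- data.table(
      gene_id = g, lead_variant = lead_var, group = cl$group, er = cl$er,
      n_units = cl$n_units, n_peaks = nrow(gpeaks),
      significant_units = paste(cl$significant_units, collapse = ";"),
      inconsistent = cl$inconsistent)
  }
  rbindlist(rows)
}
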