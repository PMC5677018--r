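# End-to-end orchestration: simulate (or ingest) -> normalize -> puQTL ->
# classify -> enhancer -> eaQTL -> integrate, with a manifest and a
# human-readable run report.

#' Pipeline run configuration
#'
#' @param out_dir run directory (created)
#' @param sim a [sim_config()] describing the synthetic cohort (the pipeline
#'   currently ingests simulated inputs; on-disk inputs can be loaded with
#'   the formats readers and passed through the stage functions directly)
#' @param stages character vector of stages to run, a subset of
#'   `c("normalize", "puqtl", "classify", "enhancer", "eaqtl", "integrate")`
#' @param n_perm permutations for QTL mapping
#' @param mode permutation adjustment mode
#' @param fdr FDR threshold
#' @param n_geno_pc,n_prom_pc,n_enh_pc covariate PC counts
#' @param transform phenotype transform for mapping
#' @param mean_threshold promoter expression filter (RLE-TPM)
#' @param d_max,max_null_fraction enhancer filters
#' @param cit_perm CIT permutations
#' @param seed root seed (mandatory); all stage seeds derive from it
#' @return a `run_config` list
#' @export
run_config <- function(out_dir, sim = sim_config(), stages = c("normalize", "puqtl",
                       "classify", "enhancer", "eaqtl", "integrate"),
                       n_perm = 1000, mode = "beta", fdr = 0.05,
                       n_geno_pc = 3, n_prom_pc = 20, n_enh_pc = 12,
                       transform = "rank", mean_threshold = 0.5,
                       d_max = 0.8, max_null_fraction = 50 / 154,
                       cit_perm = 500, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(out_dir = out_dir, sim = sim, stages = stages, n_perm = n_perm,
                 mode = mode, fdr = fdr, n_geno_pc = n_geno_pc,
                 n_prom_pc = n_prom_pc, n_enh_pc = n_enh_pc,
                 transform = transform, mean_threshold = mean_threshold,
                 d_max = d_max, max_null_fraction = max_null_fraction,
                 cit_perm = cit_perm, seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(run, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  message(msg)
  cat(msg, "\n", file = file.path(run, "pipeline.log"), append = TRUE)
}

write_stage_tsv <- function(x, run, name) {
  p <- file.path(run, paste0(name, ".tsv"))
  fwrite(as.data.table(x), p, sep = "\t", quote = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort,
#' writing every stage output as TSV into the run directory together with an
#' md5 manifest. Reruns with the same configuration and seed reproduce
#' byte-identical TSVs.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest path
#' @export
run_pipeline <- function(config) {
  run <- config$out_dir
  dir.create(run, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(run, "pipeline.log"))
  res <- list(config = config)
  outputs <- character()
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)

  stage_log(run, "simulate", "n_samples=%d n_variants=%d n_genes=%d n_enhancers=%d",
            sim$n_samples, sim$n_variants, sim$n_genes, sim$n_enhancers)
  genotypes <- simulate_genotypes(sim)
  annotation <- simulate_annotation(sim, genotypes)
  tags <- simulate_cage_tags(genotypes, annotation, sim)
  res$genotypes <- genotypes; res$annotation <- annotation; res$tags <- tags
  stage_log(run, "simulate", "%d variants kept (%d filtered), %d peaks, %d enhancers",
            nrow(genotypes$variants), attr(genotypes, "n_filtered") %||% 0L,
            nrow(annotation$peaks), nrow(annotation$enhancers))
  outputs["truth"] <- write_stage_tsv(tags$truth, run, "truth")

  if ("normalize" %in% config$stages) {
    prom <- build_expression_matrix(tags$tag_streams, annotation$peaks,
                                    mean_threshold = config$mean_threshold)
    res$prom_expr <- prom
    stage_log(run, "normalize", "%d of %d peaks kept at mean >= %.2f RLE-TPM",
              nrow(prom$values), nrow(annotation$peaks), config$mean_threshold)
    outputs["prom_expr"] <- write_stage_tsv(
      data.table(feature_id = rownames(prom$values), round(prom$values, 6)),
      run, "promoter_expression")
  }

  if ("puqtl" %in% config$stages) {
    cov <- qtl_covariates(res$prom_expr, genotypes, config$n_geno_pc, config$n_prom_pc)
    puqtl <- map_cis_qtl(res$prom_expr, genotypes, annotation$tads, cov,
                         n_perm = config$n_perm, mode = config$mode,
                         transform = config$transform, anchor_type = "peak",
                         fdr = config$fdr, seed = derive_seed(config$seed, 2L))
    res$puqtl <- puqtl
    res$puqtl_cov <- cov
    sig <- attr(puqtl, "significant")
    stage_log(run, "puqtl", "%d phenotypes tested, %d puQTLs at %g%% FDR",
              nrow(puqtl), nrow(sig), 100 * config$fdr)
    outputs["puqtl"] <- write_stage_tsv(puqtl, run, "puqtl")
  }

  if ("classify" %in% config$stages) {
    cls <- classify_genes(res$puqtl, res$prom_expr, genotypes, res$puqtl_cov,
                          transform = config$transform, fdr = config$fdr)
    res$classification <- cls
    stage_log(run, "classify", "%d genes classified; groups: %s", nrow(cls),
              paste(sprintf("%d:%d", 1:5, tabulate(cls$group, 5)), collapse = " "))
    outputs["classification"] <- write_stage_tsv(cls, run, "classification")
  }

  if ("enhancer" %in% config$stages) {
    clusters <- cluster_tag_streams(tags$tag_streams)
    bid <- select_bidirectional(annotation$enhancers, clusters)
    kept <- bid[bidirectional == TRUE]
    stage_log(run, "enhancer", "%d clusters; %d of %d enhancers bidirectional",
              nrow(clusters), nrow(kept), nrow(bid))
    if (nrow(kept)) {
      quant <- directionality_and_quantify(tags$tag_streams, kept)
      enh_mat <- build_enhancer_matrix(quant, kept, d_max = config$d_max,
                                       max_null_fraction = config$max_null_fraction)
      res$enh_expr <- enh_mat
      stage_log(run, "enhancer", "%d enhancers pass |D| < %.2f and null filters",
                nrow(enh_mat$values), config$d_max)
      outputs["enhancers"] <- write_stage_tsv(enh_mat$quants, run, "enhancers")
    }
    res$clusters <- clusters
  }

  if ("eaqtl" %in% config$stages && !is.null(res$enh_expr)) {
    cov_e <- qtl_covariates(res$enh_expr, genotypes, config$n_geno_pc, config$n_enh_pc)
    eaqtl <- map_cis_qtl(res$enh_expr, genotypes, annotation$tads, cov_e,
                         n_perm = config$n_perm, mode = config$mode,
                         transform = config$transform, anchor_type = "midpoint",
                         fdr = config$fdr, seed = derive_seed(config$seed, 3L))
    res$eaqtl <- eaqtl
    res$eaqtl_cov <- cov_e
    stage_log(run, "eaqtl", "%d enhancers tested, %d eaQTLs at %g%% FDR",
              nrow(eaqtl), nrow(attr(eaqtl, "significant")), 100 * config$fdr)
    outputs["eaqtl"] <- write_stage_tsv(eaqtl, run, "eaqtl")
  }

  if ("integrate" %in% config$stages && !is.null(res$puqtl)) {
    # gene-level mRNA stand-in: total raw tags per gene, normalized the same way
    feats <- res$prom_expr$features
    gene_counts <- rowsum(res$prom_expr$raw, group = feats$gene_id)
    gene_tpm <- tpm_normalize(gene_counts, res$prom_expr$library_sizes)
    gsf <- tryCatch(rle_size_factors(gene_tpm), error = function(e)
      setNames(rep(1, ncol(gene_tpm)), colnames(gene_tpm)))
    gene_norm <- sweep(gene_tpm, 2, gsf, "/")
    gene_feats <- res$annotation$genes[match(rownames(gene_norm),
                                             res$annotation$genes$feature_id)]
    keepg <- !is.na(gene_feats$feature_id)
    gene_expr <- structure(list(values = gene_norm[keepg, , drop = FALSE],
                                size_factors = gsf,
                                features = gene_feats[keepg]),
                           class = "expression_matrix")
    res$gene_expr <- gene_expr
    # pi1 replication: nominal p of each significant puQTL variant against
    # its gene's mRNA total
    sig <- attr(res$puqtl, "significant")
    if (nrow(sig)) {
      cov <- res$puqtl_cov
      vals <- inverse_normal_transform(gene_expr$values)
      repl_p <- rep(NA_real_, nrow(sig))
      gid <- feats$gene_id[match(sig$phenotype_id, feats$feature_id)]
      for (i in seq_len(nrow(sig))) {
        if (is.na(gid[i]) || !gid[i] %in% rownames(vals)) next
        y <- residualize(vals[gid[i], ], cov)
        d <- genotypes$dosage[, sig$variant_id[i]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        if (sd(d) == 0) next
        repl_p[i] <- r_to_p(cor(y, d), length(y) - 2 - ncol(cov))
      }
      ok <- !is.na(repl_p)
      res$pi1 <- if (sum(ok) >= 10)
        pi1(repl_p[ok], seed = derive_seed(config$seed, 4L)) else NULL
      if (!is.null(res$pi1))
        stage_log(run, "integrate", "pi1 = %.3f (se %.3f) over %d puQTL-gene pairs",
                  res$pi1$pi1, res$pi1$se, res$pi1$m)
      outputs["replication"] <- write_stage_tsv(
        data.table(phenotype_id = sig$phenotype_id, variant_id = sig$variant_id,
                   gene_id = gid, replication_p = repl_p), run, "replication")
    }
    # triplets + causal inference
    if (!is.null(res$eaqtl) && !is.null(res$enh_expr)) {
      ea_sig <- attr(res$eaqtl, "significant")
      pu_sig <- sig[sig$phenotype_id %in% rownames(res$prom_expr$values)]
      if (nrow(ea_sig)) {
        trip <- build_triplets(ea_sig, annotation$pairs, pu_sig, genotypes)
        trip <- trip[promoter_id %in% rownames(res$prom_expr$values)]
        if (nrow(trip)) {
          trip <- cit_triplets(trip, res$enh_expr, res$prom_expr, genotypes,
                               covariates = NULL, n_perm = config$cit_perm,
                               fdr = config$fdr, seed = derive_seed(config$seed, 5L))
          stage_log(run, "integrate", "%d triplets (%d shared); causal calls: %s",
                    nrow(trip), sum(trip$shared),
                    paste(names(table(trip$causal_call)), table(trip$causal_call),
                          collapse = " ", sep = ":"))
        }
        res$triplets <- trip
        outputs["triplets"] <- write_stage_tsv(trip, run, "triplets")
      }
    }
    # GWAS overlap enrichment of puQTL variants
    gwas <- tags$gwas
    if (!is.null(gwas) && nrow(gwas) && nrow(sig)) {
      tssdt <- data.table(chrom = feats$chrom, pos = feature_anchor(feats, "peak"))
      res$gwas_enrichment <- gwas_overlap_enrichment(
        unique(sig$variant_id), gwas, genotypes, tssdt,
        n_perm = min(config$n_perm, 200), seed = derive_seed(config$seed, 6L))
      stage_log(run, "integrate", "GWAS overlap OR = %.2f (p = %.3g)",
                res$gwas_enrichment$odds_ratio, res$gwas_enrichment$p)
    }
    # chromatin-annotation enrichment against the promoter landscape
    if (nrow(sig)) {
      vpos <- genotypes$variants[match(sig$variant_id, variant_id)]
      anch <- feature_anchor(feats, "peak")[match(sig$phenotype_id, feats$feature_id)]
      qp <- data.table(chrom = vpos$chrom, pos = vpos$pos, anchor = anch)
      land <- data.table(chrom = feats$chrom, anchor = feature_anchor(feats, "peak"))
      res$feature_enrichment <- feature_enrichment(
        qp, annotation$segments, land, n_perm = min(config$n_perm, 200),
        seed = derive_seed(config$seed, 7L))
      stage_log(run, "integrate", "segment enrichment OR = %.2f (p = %.3g)",
                res$feature_enrichment$odds_ratio, res$feature_enrichment$p)
    }
    # TSS annotation of the tested peaks
    res$tss_annotation <- annotate_tss(feats, annotation$transcripts,
                                       annotation$segments)
    outputs["tss_annotation"] <- write_stage_tsv(res$tss_annotation, run,
                                                 "tss_annotation")
  }

  manifest <- data.table(file = basename(unname(outputs)),
                         md5 = unname(tools::md5sum(unname(outputs))))
  setorder(manifest, file)
  fwrite(manifest, file.path(run, "manifest.tsv"), sep = "\t", quote = FALSE)
  res$manifest <- file.path(run, "manifest.tsv")
  res$outputs <- outputs
  invisible(res)
}

#' Write a human-readable run report
#'
#' Summarizes counts per stage by recomputing them from the stage TSVs in
#' the run directory; missing stage outputs are marked absent.
#'
#' @param run_dir pipeline run directory (must contain manifest.tsv)
#' @return invisibly, a list of the reported numbers
#' @export
write_report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.tsv")))
    stop("no manifest in ", run_dir)
  report <- list()
  lines <- c("# Pipeline run report", "")
  grab <- function(name) {
    p <- file.path(run_dir, paste0(name, ".tsv"))
    if (file.exists(p)) fread(p, sep = "\t") else NULL
  }
  pu <- grab("puqtl")
  if (!is.null(pu)) {
    report$n_tested <- nrow(pu)
    report$n_puqtl <- sum(pu$qvalue < 0.05)
    lines <- c(lines, sprintf("Promoters tested: %d", report$n_tested),
               sprintf("puQTLs (5%% FDR): %d", report$n_puqtl))
  } else lines <- c(lines, "puQTL stage: absent")
  cls <- grab("classification")
  if (!is.null(cls)) {
    report$group_sizes <- tabulate(cls$group, 5)
    report$n_classified <- nrow(cls)
    lines <- c(lines, sprintf("Classified genes: %d", report$n_classified),
               sprintf("Group sizes (1-5): %s", paste(report$group_sizes, collapse = " / ")))
  } else lines <- c(lines, "classification stage: absent")
  enh <- grab("enhancers")
  if (!is.null(enh)) {
    report$n_enhancers_kept <- nrow(enh)
    lines <- c(lines, sprintf("Enhancers quantified: %d", report$n_enhancers_kept))
  } else lines <- c(lines, "enhancer stage: absent")
  ea <- grab("eaqtl")
  if (!is.null(ea)) {
    report$n_eaqtl <- sum(ea$qvalue < 0.05)
    lines <- c(lines, sprintf("eaQTLs (5%% FDR): %d", report$n_eaqtl))
  } else lines <- c(lines, "eaQTL stage: absent")
  tr <- grab("triplets")
  if (!is.null(tr)) {
    report$n_triplets <- nrow(tr)
    report$n_shared <- if (nrow(tr)) sum(tr$shared) else 0L
    report$n_causal <- if (nrow(tr) && "causal_call" %in% names(tr))
      sum(tr$causal_call == "enhancer_mediates") else 0L
    lines <- c(lines, sprintf("Triplets: %d (%d shared; %d enhancer-causal)",
                              report$n_triplets, report$n_shared, report$n_causal))
  } else lines <- c(lines, "triplet stage: absent")
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(report)
}
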