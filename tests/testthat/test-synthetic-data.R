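test_that("config invariants are enforced", {
  expect_error(sim_config(n_samples = 3), "n_samples")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_variants = 1), "n_variants")
  expect_error(simulate_annotation(sim_config(tad_span = 1e4, n_tads = 3)),
               "tad_span")
})

test_that("genotype simulation is deterministic and respects forced MAF", {
  cfg <- sim_config(n_samples = 50, n_variants = 300, n_genes = 5, n_enhancers = 2,
                    n_tads = 2, tad_span = 2e5, seed = 3)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))

  cfg50 <- sim_config(n_samples = 200, n_variants = 200, maf_range = c(0.5, 0.5),
                      n_genes = 5, n_enhancers = 2, n_tads = 2, tad_span = 2e5,
                      seed = 4)
  g <- simulate_genotypes(cfg50)
  # every variant's sample alt frequency near 0.5 (binomial tolerance)
  expect_true(all(abs(g$variants$alt_freq - 0.5) < 0.15))
  expect_gt(mean(abs(g$variants$alt_freq - 0.5) < 0.08), 0.9)
})

test_that("LD structure follows the block span", {
  base <- list(n_samples = 150, n_variants = 500, n_genes = 5, n_enhancers = 2,
               n_tads = 2, tad_span = 2e5, seed = 9)
  neighbor_r2 <- function(gm, same_block_only) {
    v <- gm$variants; d <- gm$dosage
    r2 <- vapply(2:ncol(d), function(j) {
      if (same_block_only && v$ld_block[j] != v$ld_block[j - 1]) return(NA_real_)
      if (!same_block_only && v$ld_block[j] == v$ld_block[j - 1]) return(NA_real_)
      suppressWarnings(cor(d[, j], d[, j - 1])^2)
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  big <- simulate_genotypes(do.call(sim_config, c(base, ld_block_span = 50000)))
  expect_gte(neighbor_r2(big, TRUE), 0.5)
  tiny <- simulate_genotypes(do.call(sim_config, c(base, ld_block_span = 1)))
  # every variant is its own block: neighbors are independent
  expect_lt(neighbor_r2(tiny, FALSE), 0.1)
})

test_that("annotation layout satisfies its invariants", {
  cfg <- sim_config(n_samples = 20, n_variants = 100, n_genes = 30, n_enhancers = 10,
                    n_tads = 4, tad_span = 3e5, seed = 5)
  ann <- simulate_annotation(cfg)
  # every feature inside exactly one TAD
  tad_of <- function(pos) findInterval(pos, ann$tads$start)
  peak_anchor <- feature_anchor(ann$peaks, "peak")
  expect_true(all(peak_anchor >= 0 & peak_anchor < max(ann$tads$end)))
  expect_true(all(tad_of(peak_anchor) >= 1))
  gene_tads <- tapply(tad_of(peak_anchor), ann$peaks$gene_id, function(x) length(unique(x)))
  expect_true(all(gene_tads == 1))
  # multi-promoter genes include both < 200 nt and >= 200 nt gaps
  gaps <- unlist(tapply(peak_anchor, ann$peaks$gene_id,
                        function(x) if (length(x) > 1) diff(sort(x)) else NULL))
  expect_true(any(gaps < 200) && any(gaps >= 200))
  # enhancer midpoints >= 1 kb from any promoter anchor
  dmin <- vapply(ann$enhancers$midpoint, function(m) min(abs(peak_anchor - m)),
                 numeric(1))
  expect_true(all(dmin >= 1000))
})

test_that("degenerate annotation configs work", {
  cfg1 <- sim_config(n_samples = 20, n_variants = 100, n_genes = 10, n_enhancers = 0,
                     promoters_per_gene = 1, n_tads = 2, tad_span = 3e5, seed = 6)
  ann1 <- simulate_annotation(cfg1)
  expect_true(all(table(ann1$peaks$gene_id) == 1))
  cfg0 <- sim_config(n_samples = 20, n_variants = 100, n_genes = 0, n_enhancers = 0,
                     n_tads = 3, tad_span = 3e5, seed = 6)
  ann0 <- simulate_annotation(cfg0)
  expect_equal(nrow(ann0$peaks), 0L)
  expect_equal(nrow(ann0$tads), 3L)
})

test_that("annotation intervals survive a BED round trip", {
  cfg <- sim_config(n_samples = 20, n_variants = 100, n_genes = 15, n_enhancers = 5,
                    n_tads = 3, tad_span = 3e5, seed = 8)
  ann <- simulate_annotation(cfg)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann$peaks, p, extra_cols = c("gene_id", "peak_rank"))
  back <- read_bed(p, extra_cols = c("gene_id", "peak_rank"))
  expect_equal(back$start, ann$peaks$start)
  expect_equal(back$end, ann$peaks$end)
  expect_equal(back$strand, ann$peaks$strand)
  expect_equal(back$gene_id, ann$peaks$gene_id)
})

test_that("tag streams conserve library size and respect placement rules", {
  co <- small_cohort(seed = 12, n_samples = 30, n_genes = 20, n_enhancers = 8)
  for (s in sample(names(co$tg$tag_streams), 3)) {
    ts <- co$tg$tag_streams[[s]]
    expect_equal(attr(ts, "library_size"), sum(ts$count))
    expect_true(all(ts$count >= 1))
    expect_equal(anyDuplicated(ts[, c("chrom", "pos", "strand")]), 0L)
  }
  # promoter tags lie on the gene strand within peaks; enhancer tags are
  # divergent around the midpoint
  ts <- co$tg$tag_streams[[1]]
  enh <- co$ann$enhancers
  for (e in seq_len(min(4, nrow(enh)))) {
    win <- ts[ts$chrom == enh$chrom[e] & abs(ts$pos - enh$midpoint[e]) <= 200, ]
    if (nrow(win) == 0) next
    expect_true(all(win$strand[win$pos >= enh$midpoint[e]] == "+"))
    expect_true(all(win$strand[win$pos < enh$midpoint[e]] == "-"))
  }
})

test_that("null effects give calibrated association p-values", {
  cfg <- sim_config(n_samples = 100, n_variants = 200, n_genes = 60, n_enhancers = 2,
                    n_tads = 3, tad_span = 3e5, depth_mean = 5e4, depth_sd = 1e4,
                    effect_table = data.table::data.table(
                      feature_id = character(), feature_type = character(),
                      gene_id = character(), variant_id = character(),
                      slope = numeric(), topology = character()),
                    seed = 21)
  gm <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  tg <- simulate_cage_tags(gm, ann, cfg)
  expr <- build_expression_matrix(tg$tag_streams, ann$peaks)
  pheno <- inverse_normal_transform(expr$values)
  set.seed(1)
  vs <- sample(ncol(gm$dosage), nrow(pheno), replace = TRUE)
  ps <- vapply(seq_len(nrow(pheno)), function(i) {
    sc <- nominal_scan(pheno[i, ] - mean(pheno[i, ]),
                       gm$dosage[, vs[i], drop = FALSE],
                       gm$variants[vs[i]])
    sc$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted positive slopes give expression monotone in dosage", {
  hits <- 0; tries <- 0
  for (seed in 1:6) {
    co <- small_cohort(seed = 100 + seed, n_samples = 60, n_genes = 30, n_enhancers = 4)
    truth <- co$tg$truth
    truth <- truth[truth$feature_type == "peak" & truth$true_slope > 0.5, ]
    if (nrow(truth) == 0) next
    expr <- build_expression_matrix(co$tg$tag_streams, co$ann$peaks)
    for (i in seq_len(nrow(truth))) {
      fid <- truth$feature_id[i]
      if (!fid %in% rownames(expr$values)) next
      d <- co$gm$dosage[, truth$variant_id[i]]
      y <- expr$values[fid, ]
      mg <- tapply(y, d, mean)
      tries <- tries + 1
      if (!is.unsorted(mg)) hits <- hits + 1
    }
  }
  expect_gt(tries, 20)
  expect_gt(hits / tries, 0.8)
})

test_that("counts approach expectation as dispersion vanishes at high depth", {
  cfg <- sim_config(n_samples = 10, n_variants = 50, n_genes = 10, n_enhancers = 2,
                    n_tads = 2, tad_span = 3e5, depth_mean = 5e6, depth_sd = 1,
                    dispersion = 1e-6, seed = 31,
                    effect_table = data.table::data.table(
                      feature_id = character(), feature_type = character(),
                      gene_id = character(), variant_id = character(),
                      slope = numeric(), topology = character()))
  gm <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  tg <- simulate_cage_tags(gm, ann, cfg)
  raw <- aggregate_tags_to_features(tg$tag_streams, ann$peaks, "same-strand")
  # with near-zero dispersion and equal depths, per-feature counts are
  # essentially constant across samples
  cv <- apply(raw, 1, function(x) sd(x) / mean(x))
  expect_lt(median(cv, na.rm = TRUE), 0.05)
})

test_that("truth-table group labels follow the classification rules", {
  co <- small_cohort(seed = 13)
  truth <- co$tg$truth
  tp <- truth[truth$feature_type == "peak" & truth$topology != "v_e_p", ]
  expect_true(all(tp$true_group_label %in% 1:5))
  # recompute one gene's label by hand from planted slopes
  gid <- sub("_p[0-9]+$", "", tp$feature_id[1])
  peaks <- co$ann$peaks[co$ann$peaks$gene_id == gid, ]
  expect_true(all(tp[sub("_p[0-9]+$", "", tp$feature_id) == gid,
                    "true_group_label"] == tp$true_group_label[1]))
})
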