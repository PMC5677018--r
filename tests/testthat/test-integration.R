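test_that("pi1 behaves at the limits and under mixtures", {
  set.seed(41)
  expect_lt(pi1(runif(5000), n_boot = 0)$pi1, 0.05)
  strong <- rbeta(4000, 0.02, 1)
  mixed <- c(runif(1000), strong)
  r <- pi1(mixed, n_boot = 20)
  expect_lt(abs(r$pi1 - 0.8), 0.05)
  expect_true(is.finite(r$se))
  # all tiny p: pi1 -> 1
  expect_gt(pi1(rep(1e-6, 500), n_boot = 0)$pi1, 0.95)
  expect_warning(pi1(runif(50), n_boot = 0), "unstable")
})

test_that("LD statistics are exact on hand-computed dosages", {
  d1 <- c(0, 1, 2, 0, 1, 2)
  d2 <- c(0, 1, 2, 1, 1, 2)
  gm <- genotype_matrix(cbind(d1, d2, d1 * 0 + c(2, 2, 2, 2, 2, 2)),
                        data.frame(variant_id = c("a", "b", "mono"), chrom = "chr1",
                                   pos = c(1L, 2L, 3L), ref = "A", alt = "G"),
                        sprintf("S%d", 1:6))
  self <- ld_stats(gm, "a", "a")
  expect_equal(self$r2, 1)
  expect_equal(self$rho, 1)
  got <- ld_stats(gm, "a", "b")
  expect_equal(got$r2, cor(d1, d2)^2, tolerance = 1e-12)
  expect_equal(got$rho, cor(d1, d2, method = "spearman"), tolerance = 1e-12)
  expect_error(ld_stats(gm, "a", "mono"), "monomorphic")
})

test_that("independent variants have mean r2 near 1/n", {
  set.seed(42)
  n <- 100
  d <- matrix(rbinom(n * 200, 2, 0.4), n)
  gm <- genotype_matrix(d, data.frame(variant_id = sprintf("v%d", 1:200),
                                      chrom = "chr1", pos = 1:200, ref = "A", alt = "G"),
                        sprintf("S%d", 1:n))
  r2s <- vapply(1:100, function(i) ld_stats(gm, sprintf("v%d", 2 * i - 1),
                                            sprintf("v%d", 2 * i))$r2, numeric(1))
  expect_lt(abs(mean(r2s) - 1 / n), 0.01)
})

test_that("RTC formula and flags are as defined", {
  set.seed(43)
  cfg <- sim_config(n_samples = 120, n_variants = 40, ld_block_span = 3e4,
                    n_genes = 2, n_enhancers = 2, n_tads = 2, tad_span = 3e4, seed = 2)
  gm <- simulate_genotypes(cfg)
  iv <- gm$variants$variant_id[1:10]
  causal <- iv[3]
  y <- gm$dosage[, causal] * 0.9 + rnorm(120)
  r <- rtc(scale(y)[, 1], gm, gwas_variant = causal, qtl_variant = causal,
           interval_variants = iv)
  expect_equal(r$n_variants, 10L)
  expect_true(r$rtc >= 0 && r$rtc <= 1)
  # correcting on the causal variant itself is the most destructive
  # correction: rank 0, RTC = (N - 0)/N = 1
  expect_equal(r$rank, 0L)
  expect_equal(r$rtc, 1)
  expect_true(r$high_confidence)
  expect_error(rtc(y, gm, causal, causal, causal), "at least 2")
})

test_that("RTC separates shared from independent signals", {
  shared <- indep <- c()
  for (s in 1:25) {
    cfg <- sim_config(n_samples = 150, n_variants = 60, ld_block_span = 3e4,
                      n_genes = 2, n_enhancers = 2, n_tads = 2, tad_span = 3e4,
                      seed = 400 + s)
    gm <- simulate_genotypes(cfg)
    v <- gm$variants
    blocks <- unique(v$ld_block)
    iv_all <- v$variant_id
    set.seed(s)
    b1 <- v$variant_id[v$ld_block == blocks[1]]
    if (length(b1) < 4 || length(blocks) < 2) next
    causal <- b1[2]
    y <- gm$dosage[, causal] * 0.8 + rnorm(150)
    # shared: GWAS variant is an LD neighbor of the causal variant
    shared <- c(shared, rtc(scale(y)[, 1], gm, b1[3], causal, iv_all)$rtc)
    # independent: GWAS variant from a different LD block
    b2 <- v$variant_id[v$ld_block == blocks[2]]
    indep <- c(indep, rtc(scale(y)[, 1], gm, b2[2], causal, iv_all)$rtc)
  }
  expect_gt(length(shared), 15)
  expect_gte(median(shared) - median(indep), 0.3)
})

test_that("matched GWAS enrichment flags planted overlap and stays null-calibrated", {
  co <- small_cohort(seed = 45)
  truth <- co$tg$truth
  qtl_vars <- unique(truth$variant_id[!is.na(truth$variant_id)])
  tss <- data.table::data.table(chrom = co$ann$peaks$chrom,
                                pos = feature_anchor(co$ann$peaks, "peak"))
  # catalog = the QTL set itself: every variant overlaps, OR >> 1
  gw <- data.table::data.table(variant_id = qtl_vars,
                               chrom = "chr1",
                               pos = co$gm$variants$pos[match(qtl_vars,
                                 co$gm$variants$variant_id)],
                               trait = "t")
  r <- gwas_overlap_enrichment(qtl_vars, gw, co$gm, tss, n_perm = 100, seed = 1)
  expect_equal(r$observed, length(qtl_vars))
  expect_gt(r$odds_ratio, 1)
  expect_equal(r$p, 1 / 101)
  expect_gte(r$p, 1 / (r$n_perm + 1))
  # observed count equals a brute-force recomputation
  v <- co$gm$variants
  brute <- sum(vapply(qtl_vars, function(id) {
    i <- match(id, v$variant_id)
    if (id %in% gw$variant_id) return(TRUE)
    any(vapply(gw$variant_id, function(g) {
      abs(gw$pos[match(g, gw$variant_id)] - v$pos[i]) <= 5e5 &&
        suppressWarnings(cor(co$gm$dosage[, id], co$gm$dosage[, g]))^2 > 0.5
    }, logical(1)))
  }, logical(1)))
  expect_equal(r$observed, brute)
})

test_that("a null QTL set drawn from the matched sampler gives OR near 1", {
  co <- small_cohort(seed = 46)
  v <- co$gm$variants
  set.seed(3)
  gw_ids <- sample(v$variant_id, 25)
  gw <- data.table::data.table(variant_id = gw_ids, chrom = "chr1",
                               pos = v$pos[match(gw_ids, v$variant_id)], trait = "t")
  tss <- data.table::data.table(chrom = co$ann$peaks$chrom,
                                pos = feature_anchor(co$ann$peaks, "peak"))
  # the "QTL" set is drawn from the same frame the null sampler uses: the
  # enrichment must be null-calibrated
  obs <- pm <- ps <- c()
  for (r in 1:8) {
    set.seed(50 + r)
    qtl <- sample(v$variant_id, 40)
    e <- gwas_overlap_enrichment(qtl, gw, co$gm, tss, n_perm = 80, seed = r)
    obs <- c(obs, e$observed); pm <- c(pm, e$perm_mean); ps <- c(ps, e$p)
  }
  expect_gt(sum(obs) / sum(pm), 0.7)
  expect_lt(sum(obs) / sum(pm), 1.4)
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("CIT relabeling symmetry is exact and null component is calibrated", {
  tr <- simulate_mediation_triplet(n = 120, topology = "v_m_t", seed = 5)
  a <- cit_test(tr$L, tr$M, tr$T, n_perm = 100, seed = 9)
  b <- cit_test(tr$L, tr$T, tr$M, n_perm = 100, seed = 9)
  expect_identical(a$forward, b$reverse)
  expect_identical(a$reverse, b$forward)
  expect_error(cit_direction(rep(1, 50), rnorm(50), rnorm(50)), "zero-variance")
  # pure-noise outcome: component test 1 p is uniform
  set.seed(10)
  p1s <- vapply(1:60, function(s) {
    tr <- simulate_mediation_triplet(n = 80, topology = "null", seed = 600 + s)
    cit_direction(tr$L, tr$M, tr$T, n_perm = 50, seed = s)$p1
  }, numeric(1))
  expect_gt(stats::ks.test(p1s, "punif")$p.value, 0.01)
  # permutation floor respected
  expect_gte(a$forward$p4, 1 / 101)
})

test_that("CIT detects the causal direction on mediation chains", {
  fwd <- rev <- ind_f <- ind_r <- c()
  for (s in 1:25) {
    tr <- simulate_mediation_triplet(n = 150, topology = "v_m_t", seed = 700 + s)
    ct <- cit_test(tr$L, tr$M, tr$T, n_perm = 200, seed = s)
    fwd <- c(fwd, ct$forward$omnibus_p)
    rev <- c(rev, ct$reverse$omnibus_p)
    ti <- simulate_mediation_triplet(n = 150, topology = "independent", seed = 800 + s)
    ci <- cit_test(ti$L, ti$M, ti$T, n_perm = 200, seed = s)
    ind_f <- c(ind_f, ci$forward$omnibus_p)
    ind_r <- c(ind_r, ci$reverse$omnibus_p)
  }
  expect_gte(mean(fwd < 0.05), 0.8)
  expect_gte(mean(rev >= 0.05), 0.8)
  expect_gte(mean(ind_f >= 0.05), 0.9)
  expect_gte(mean(ind_r >= 0.05), 0.9)
})

test_that("triplet construction follows the pairing combinatorics", {
  ea <- data.table::data.table(phenotype_id = "enh1", variant_id = "v1")
  pairs <- data.table::data.table(enhancer_id = c("enh1", "enh1"),
                                  peak_id = c("p1", "p2"))
  pu <- data.table::data.table(phenotype_id = "p1", variant_id = "v1")
  d <- matrix(rbinom(300, 2, 0.4), 100, 3)
  gm <- genotype_matrix(d, data.frame(variant_id = c("v1", "v2", "v3"),
                                      chrom = "chr1", pos = 1:3, ref = "A", alt = "G"),
                        sprintf("S%d", 1:100))
  # one eaQTL enhancer paired with two promoters: two triplets
  tr <- build_triplets(ea, pairs, pu, gm)
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$promoter_id, c("p1", "p2"))
  expect_true(all(tr$shared))   # same variant is a puQTL
  # empty pairing: empty output
  empty <- build_triplets(ea, pairs[0], pu, gm)
  expect_equal(nrow(empty), 0L)
  # shared flag via LD equals a brute-force recomputation
  pu2 <- data.table::data.table(phenotype_id = "p9", variant_id = "v2")
  tr2 <- build_triplets(ea, pairs, pu2, gm)
  rho <- abs(cor(d[, 1], d[, 2], method = "spearman"))
  expect_equal(unique(tr2$shared), rho > 0.8)
  expect_equal(unique(tr2$best_rho), rho, tolerance = 1e-12)
})

test_that("TSS annotation follows the four-step hierarchy", {
  transcripts <- data.table::data.table(
    chrom = "chr1",
    start = c(10000L, 10200L, 10000L),
    end = c(10200L, 10800L, 15000L),
    strand = "+",
    feature_id = c("g1_utr5ex", "g1_utr5in", "g1_body"),
    score = 0, gene_id = "g1", type = c("utr5_exon", "utr5_intron", "gene_body"))
  segments <- data.table::data.table(
    chrom = "chr1", start = c(9000L, 30000L, 12000L), end = c(11000L, 31000L, 13000L),
    strand = ".", feature_id = c("s1", "s2", "s3"), score = 0,
    state = c("promoter", "enhancer", "promoter"))
  pk <- function(start, strand, id) genomic_intervals("chr1", start, start + 30L,
                                                      strand, id)
  peaks <- rbind(
    pk(9700L, "+", "upstream300"),      # 300 nt upstream of TSS, same strand
    pk(10300L, "+", "in_utr_intron"),   # inside 5'UTR first intron
    pk(30100L, "+", "in_enh_segment"),  # enhancer chromatin state
    pk(12100L, "-", "antisense"),       # promoter state, opposite strand in body
    pk(9700L, "-", "upstream_wrong_strand"),
    pk(40000L, "+", "nothing"))
  got <- annotate_tss(peaks, transcripts, segments)
  expect_equal(got$label[got$feature_id == "upstream300"], "Annotated gene")
  expect_equal(got$label[got$feature_id == "in_utr_intron"], "Annotated gene")
  expect_equal(got$label[got$feature_id == "in_enh_segment"], "eRNA/enhancer")
  expect_equal(got$label[got$feature_id == "antisense"], "Antisense promoter")
  # upstream on the wrong strand is not an annotated gene, falls to segment
  # step: promoter state, no gene-body overlap -> putative promoter
  expect_equal(got$label[got$feature_id == "upstream_wrong_strand"], "Putative promoter")
  expect_equal(got$label[got$feature_id == "nothing"], "other")
})

test_that("TSS annotation of simulated gene peaks matches hand labels", {
  co <- small_cohort(seed = 47, n_samples = 20, n_genes = 12, n_enhancers = 6)
  peaks <- co$ann$peaks[1:min(20, nrow(co$ann$peaks))]
  got <- annotate_tss(peaks, co$ann$transcripts, co$ann$segments)
  # hand rule for this layout: gene peaks within the 5'UTR first exon +
  # first intron span (800 nt downstream of the gene TSS) are annotated
  # genes; the more distal promoters of multi-promoter genes fall out of
  # the transcript structures and, sitting in promoter chromatin on their
  # own gene's strand, become putative promoters
  genes <- co$ann$genes
  tss <- feature_anchor(genes, "peak")[match(peaks$gene_id, genes$feature_id)]
  d <- ifelse(peaks$strand == "+", feature_anchor(peaks, "peak") - tss,
              tss - feature_anchor(peaks, "peak"))
  want <- ifelse(d >= -500 & d < 800, "Annotated gene", "Putative promoter")
  expect_equal(got$label, want)
})

test_that("feature enrichment is calibrated and counts exactly", {
  set.seed(48)
  land <- data.table::data.table(chrom = "chr1",
                                 anchor = sort(sample.int(1e6, 400)))
  ann <- genomic_intervals("chr1", land$anchor[1:100] - 50L, land$anchor[1:100] + 50L,
                           feature_id = sprintf("a%d", 1:100))
  # QTLs planted right inside annotations of a sparse landscape: OR >> 1
  qp <- data.table::data.table(chrom = "chr1", pos = land$anchor[1:40],
                               anchor = land$anchor[1:40])
  r <- feature_enrichment(qp, ann, land, n_perm = 200, seed = 2)
  expect_equal(r$observed, 40)
  expect_gt(r$odds_ratio, 1)
  expect_equal(r$p, 1 / 201)
  # observed equals naive recomputation
  naive <- sum(vapply(seq_len(nrow(qp)), function(i)
    any(qp$pos[i] >= ann$start & qp$pos[i] < ann$end), logical(1)))
  expect_equal(r$observed, naive)
  # annotations covering everything: OR = 1 by construction
  whole <- genomic_intervals("chr1", 0L, 2e6L, feature_id = "all")
  r2 <- feature_enrichment(qp, whole, land, n_perm = 50, seed = 3)
  expect_equal(r2$odds_ratio, 1)
})
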