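# Synthetic cohort generator: LD-structured genotypes, TAD-partitioned
# annotations, and negative-binomial CAGE tag counts with planted promoter
# and enhancer effects. Ground truth is returned alongside so every
# downstream stage can be scored.

#' Simulation configuration
#'
#' Defines a synthetic cohort emulating a CAGE QTL study: unrelated diploid
#' samples, one chromosome tiled by TADs, multi-promoter genes, enhancers
#' transcribed divergently, and planted allelic effects on the log expression
#' scale.
#'
#' @param n_samples number of diploid samples (>= 4)
#' @param n_variants number of biallelic variants (>= 2)
#' @param ld_block_span span (bases) of an LD block; variants within a block
#'   are correlated, blocks are independent
#' @param maf_range range of block base allele frequencies, within (0, 0.5]
#' @param n_genes number of genes
#' @param promoters_per_gene probability weights for 1..7 promoters per gene
#' @param n_enhancers number of enhancer regions
#' @param tad_span TAD width in bases
#' @param n_tads number of TADs tiling the chromosome
#' @param depth_mean,depth_sd mean and SD of per-sample library size (tags)
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2)
#' @param ld_decay per-variant state-switch rate of the within-block copying
#'   chain (smaller = stronger LD)
#' @param mutation_rate per-allele flip probability after template copying
#' @param effect_table optional pre-built planted-effect table (see
#'   [plant_effects()]); built automatically when `NULL`
#' @param effects parameters handed to [plant_effects()] when `effect_table`
#'   is `NULL`
#' @param frac_active_enhancers fraction of enhancers transcribed
#' @param frac_unidirectional fraction of enhancer regions given one-strand
#'   (promoter-like) transcription instead of a divergent pattern
#' @param seed integer seed; all generator randomness derives from it
#' @return a `sim_config` list
#' @export
sim_config <- function(n_samples = 154, n_variants = 20000, ld_block_span = 20000,
                       maf_range = c(0.05, 0.5), n_genes = 700,
                       promoters_per_gene = c(0.45, 0.25, 0.12, 0.08, 0.05, 0.03, 0.02),
                       n_enhancers = 100, tad_span = 1e6,
                       n_tads = max(2L, ceiling(n_genes / 10)),
                       depth_mean = 2e5, depth_sd = 6e4, dispersion = 0.1,
                       ld_decay = 0.1, mutation_rate = 0.01,
                       effect_table = NULL,
                       effects = list(frac_genes = 0.3, frac_enhancers = 0.4,
                                      slope_range = c(0.5, 1.5),
                                      med_gamma = 1.0, med_noise_sd = 1.0),
                       frac_active_enhancers = 0.7, frac_unidirectional = 0.15,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
              ld_block_span = as.integer(ld_block_span), maf_range = maf_range,
              n_genes = as.integer(n_genes), promoters_per_gene = promoters_per_gene,
              n_enhancers = as.integer(n_enhancers), tad_span = as.integer(tad_span),
              n_tads = as.integer(n_tads), depth_mean = depth_mean, depth_sd = depth_sd,
              dispersion = dispersion, ld_decay = ld_decay, mutation_rate = mutation_rate,
              effect_table = effect_table, effects = effects,
              frac_active_enhancers = frac_active_enhancers,
              frac_unidirectional = frac_unidirectional, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 4) stop("n_samples must be >= 4")
  if (cfg$n_variants < 2) stop("n_variants must be >= 2 (need at least 2 per block)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$ld_block_span <= 0 || cfg$tad_span <= 0) stop("all spans must be > 0")
  if (length(cfg$promoters_per_gene) > 7 || any(cfg$promoters_per_gene < 0))
    stop("promoters_per_gene must be nonnegative weights over 1..7")
  invisible(cfg)
}

#' Simulate LD-structured diploid genotypes
#'
#' Haplotypes are generated by block copy-with-mutation: each LD block has a
#' template haplotype; every sampled haplotype follows either the template or
#' its complement according to a two-state Markov chain along the block
#' (stationary minor-branch frequency drawn from `maf_range`, switch rate
#' `ld_decay`), then alleles are flipped with probability `mutation_rate`.
#' Haplotype pairs are summed into unphased dosages. Variants with a
#' cohort-wide alternative allele count below `min_alt_count` are removed
#' (count recorded in the `n_filtered` attribute).
#'
#' @param config a [sim_config()]
#' @param min_alt_count minimum alternative allele count for a variant to be
#'   emitted
#' @return a `genotype_matrix`
#' @export
simulate_genotypes <- function(config, min_alt_count = 10) {
  validate_sim_config(config)
  set.seed(config$seed)
  genome_len <- config$n_tads * config$tad_span
  pos <- sort(sample.int(genome_len, config$n_variants))
  block <- pos %/% config$ld_block_span
  n_hap <- 2L * config$n_samples
  alleles <- matrix(0L, nrow = n_hap, ncol = length(pos))
  eps <- config$mutation_rate
  cc <- config$ld_decay
  for (b in unique(block)) {
    idx <- which(block == b)
    q <- runif(1, config$maf_range[1], config$maf_range[2])
    template <- rbinom(length(idx), 1, 0.5)
    state <- rbinom(n_hap, 1, q)  # 1 = complement branch
    for (k in seq_along(idx)) {
      if (k > 1) {
        sw_up <- rbinom(n_hap, 1, cc * q)        # template -> complement
        sw_dn <- rbinom(n_hap, 1, cc * (1 - q))  # complement -> template
        state <- ifelse(state == 0L, sw_up, 1L - sw_dn)
      }
      a <- ifelse(state == 1L, 1L - template[k], template[k])
      flip <- rbinom(n_hap, 1, eps)
      alleles[, idx[k]] <- as.integer(xor(a, flip))
    }
  }
  dosage <- alleles[seq(1, n_hap, by = 2), , drop = FALSE] +
    alleles[seq(2, n_hap, by = 2), , drop = FALSE]
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  variants <- data.table(variant_id = sprintf("var_%05d", seq_along(pos)),
                         chrom = "chr1", pos = as.integer(pos - 1L),
                         ref = "A", alt = "G", ld_block = block)
  keep <- colSums(dosage) >= min_alt_count
  gm <- genotype_matrix(dosage[, keep, drop = FALSE], variants[keep], sample_ids)
  setattr(gm, "n_filtered", sum(!keep))
  gm
}

#' Simulate the annotation layout
#'
#' Places TADs, genes with CAGE peaks (inter-peak gaps drawn to include both
#' < 200 nt and >= 200 nt cases), enhancer midpoints at least 1 kb from any
#' promoter, transcript TSS/5'-UTR intervals, chromatin segments, an
#' enhancer-promoter pairing table, and a GWAS catalog (populated from
#' planted effects later, plus random background variants).
#'
#' @param config a [sim_config()]
#' @param genotypes optional `genotype_matrix` used to seed the GWAS catalog
#'   with real variant positions
#' @return a list of class `annotation_set` with elements `tads`, `peaks`,
#'   `genes`, `enhancers`, `transcripts`, `segments`, `pairs`, `gwas`
#' @export
simulate_annotation <- function(config, genotypes = NULL) {
  validate_sim_config(config)
  gene_span_max <- 12000L
  if (config$tad_span < gene_span_max + 4000L) stop("tad_span smaller than gene span")
  set.seed(config$seed + 1L)
  tads <- genomic_intervals(chrom = "chr1",
                            start = (seq_len(config$n_tads) - 1L) * config$tad_span,
                            end = seq_len(config$n_tads) * config$tad_span,
                            strand = ".",
                            feature_id = sprintf("tad_%03d", seq_len(config$n_tads)))
  peaks <- NULL; genes <- NULL
  if (config$n_genes > 0) {
    k_prom <- sample(seq_along(config$promoters_per_gene), config$n_genes,
                     replace = TRUE, prob = config$promoters_per_gene)
    gene_tad <- rep(seq_len(config$n_tads), length.out = config$n_genes)
    gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gene_tss <- tads$start[gene_tad] +
      as.integer(runif(config$n_genes, 2000, config$tad_span - gene_span_max - 2000))
    peak_list <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      k <- k_prom[g]
      # mix of tight (< 200 nt) and distal (>= 200 nt) inter-peak gaps
      gaps <- if (k > 1) ifelse(runif(k - 1) < 0.4,
                                as.integer(runif(k - 1, 40, 180)),
                                as.integer(runif(k - 1, 300, 2500))) else integer(0)
      anchors <- gene_tss[g] + cumsum(c(0L, gaps))
      width <- as.integer(runif(k, 20, 60))
      st <- if (gene_strand[g] == "+") anchors else anchors - width + 1L
      peak_list[[g]] <- data.table(
        chrom = "chr1", start = st, end = st + width,
        strand = gene_strand[g],
        feature_id = sprintf("gene_%04d_p%d", g, seq_len(k)),
        score = 0, gene_id = sprintf("gene_%04d", g), peak_rank = seq_len(k))
    }
    peaks <- rbindlist(peak_list)
    genes <- peaks[, .(chrom = chrom[1], start = min(start), end = max(end) + 500L,
                       strand = strand[1]), by = gene_id]
    setnames(genes, "gene_id", "feature_id")
    genes[, score := 0]
    setcolorder(genes, c("chrom", "start", "end", "strand", "feature_id", "score"))
  } else {
    peaks <- data.table(chrom = character(), start = integer(), end = integer(),
                        strand = character(), feature_id = character(), score = numeric(),
                        gene_id = character(), peak_rank = integer())
    genes <- data.table(chrom = character(), start = integer(), end = integer(),
                        strand = character(), feature_id = character(), score = numeric())
  }
  # enhancer midpoints >= 1 kb from any promoter peak
  enh <- NULL
  if (config$n_enhancers > 0) {
    enh_tad <- rep(seq_len(config$n_tads), length.out = config$n_enhancers)
    mids <- integer(config$n_enhancers)
    for (e in seq_len(config$n_enhancers)) {
      for (try in 1:100) {
        m <- tads$start[enh_tad[e]] + as.integer(runif(1, 1000, config$tad_span - 1000))
        near <- peaks[chrom == "chr1" & abs(((start + end) %/% 2) - m) < 1400]
        if (nrow(near) == 0L) break
      }
      mids[e] <- m
    }
    enh <- genomic_intervals(chrom = "chr1", start = mids - 200L, end = mids + 200L,
                             strand = ".", feature_id = sprintf("enh_%03d", seq_len(config$n_enhancers)),
                             score = 0, midpoint = mids)
  } else {
    enh <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), feature_id = character(), score = numeric(),
                      midpoint = integer())
  }
  # transcript structures for TSS annotation: TSS, 5'UTR first exon, first intron
  transcripts <- NULL
  if (nrow(genes) > 0) {
    tss <- feature_anchor(genes, "peak")
    fwd <- genes$strand == "+"
    utr_ex <- data.table(chrom = genes$chrom,
                         start = ifelse(fwd, tss, tss - 199L),
                         end = ifelse(fwd, tss + 200L, tss + 1L),
                         strand = genes$strand,
                         feature_id = paste0(genes$feature_id, "_utr5ex"),
                         score = 0, gene_id = genes$feature_id, type = "utr5_exon")
    utr_in <- data.table(chrom = genes$chrom,
                         start = ifelse(fwd, tss + 200L, tss - 799L),
                         end = ifelse(fwd, tss + 800L, tss - 199L),
                         strand = genes$strand,
                         feature_id = paste0(genes$feature_id, "_utr5in"),
                         score = 0, gene_id = genes$feature_id, type = "utr5_intron")
    body <- data.table(chrom = genes$chrom, start = genes$start, end = genes$end,
                       strand = genes$strand,
                       feature_id = paste0(genes$feature_id, "_body"),
                       score = 0, gene_id = genes$feature_id, type = "gene_body")
    transcripts <- rbindlist(list(utr_ex, utr_in, body))
  } else {
    transcripts <- data.table(chrom = character(), start = integer(), end = integer(),
                              strand = character(), feature_id = character(),
                              score = numeric(), gene_id = character(), type = character())
  }
  # chromatin segments: promoter state around peaks, enhancer state around midpoints
  seg_list <- list()
  if (nrow(peaks) > 0)
    seg_list$prom <- data.table(chrom = peaks$chrom, start = pmax(0L, peaks$start - 400L),
                                end = peaks$end + 400L, strand = ".",
                                feature_id = paste0("seg_prom_", seq_len(nrow(peaks))),
                                score = 0, state = "promoter")
  if (nrow(enh) > 0)
    seg_list$enh <- data.table(chrom = enh$chrom, start = enh$start - 200L,
                               end = enh$end + 200L, strand = ".",
                               feature_id = paste0("seg_enh_", seq_len(nrow(enh))),
                               score = 0, state = "enhancer")
  segments <- if (length(seg_list)) rbindlist(seg_list) else
    data.table(chrom = character(), start = integer(), end = integer(), strand = character(),
               feature_id = character(), score = numeric(), state = character())
  # enhancer-promoter pairing: each enhancer paired with 1-2 peaks of a gene
  # in the same TAD (when one exists)
  pairs <- data.table(enhancer_id = character(), peak_id = character())
  if (nrow(enh) > 0 && nrow(peaks) > 0) {
    enh_tadi <- enh$midpoint %/% config$tad_span
    peak_tadi <- feature_anchor(peaks, "peak") %/% config$tad_span
    pl <- list()
    for (e in seq_len(nrow(enh))) {
      cand <- which(peak_tadi == enh_tadi[e])
      if (!length(cand)) next
      take <- sample(cand, min(2L, length(cand)))
      pl[[length(pl) + 1L]] <- data.table(enhancer_id = enh$feature_id[e],
                                          peak_id = peaks$feature_id[take])
    }
    if (length(pl)) pairs <- rbindlist(pl)
  }
  ann <- list(tads = tads, peaks = peaks, genes = genes, enhancers = enh,
              transcripts = transcripts, segments = segments, pairs = pairs,
              gwas = data.table(variant_id = character(), chrom = character(),
                                pos = integer(), trait = character()))
  class(ann) <- "annotation_set"
  if (!is.null(genotypes)) ann$gwas <- simulate_gwas_catalog(config, genotypes)
  ann
}

# background GWAS catalog: random variants; planted-QTL-linked entries are
# added by simulate_cage_tags once effects are chosen
simulate_gwas_catalog <- function(config, genotypes, n_background = 50) {
  set.seed(config$seed + 5L)
  v <- genotypes$variants
  take <- sample(nrow(v), min(n_background, nrow(v)))
  data.table(variant_id = v$variant_id[take], chrom = v$chrom[take],
             pos = v$pos[take], trait = sprintf("trait_%02d", sample(20, length(take), TRUE)))
}

#' Plant allelic effects on promoters and enhancers
#'
#' Chooses target genes and enhancers, assigns each a cis variant from the
#' same TAD, and draws signed log-scale slopes. Multi-promoter genes are
#' planted with the full range of promoter-usage patterns: single-peak
#' effects, opposite-sign effects, and same-sign effects of similar or
#' clearly different magnitude. A subset of paired enhancers is planted with
#' mediation topologies.
#'
#' @param genotypes `genotype_matrix`
#' @param annotation `annotation_set`
#' @param config [sim_config()]
#' @return `data.table` with columns feature_id, feature_type, gene_id,
#'   variant_id, slope, topology
#' @export
plant_effects <- function(genotypes, annotation, config) {
  set.seed(config$seed + 2L)
  ef <- config$effects
  v <- genotypes$variants
  vt <- v$pos %/% config$tad_span
  pick_variant <- function(tad_i) {
    cand <- which(vt == tad_i)
    if (!length(cand)) return(NA_character_)
    v$variant_id[cand[sample.int(length(cand), 1)]]
  }
  rows <- list()
  peaks <- annotation$peaks
  if (nrow(peaks) > 0 && ef$frac_genes > 0) {
    gene_ids <- unique(peaks$gene_id)
    target <- sample(gene_ids, max(1L, round(ef$frac_genes * length(gene_ids))))
    for (g in target) {
      gp <- peaks[gene_id == g]
      tad_i <- feature_anchor(gp, "peak")[1] %/% config$tad_span
      vid <- pick_variant(tad_i)
      if (is.na(vid)) next
      s <- runif(1, ef$slope_range[1], ef$slope_range[2]) * sample(c(-1, 1), 1)
      k <- nrow(gp)
      if (k == 1L) {
        sl <- s
      } else {
        pattern <- sample(c("single", "opposite", "same_similar", "same_diff"), 1)
        sl <- rep(0, k)
        sl[1] <- s
        if (pattern == "opposite") sl[2] <- -s * runif(1, 0.6, 1.4)
        if (pattern == "same_similar") sl[2] <- s * runif(1, 0.55, 0.95)
        if (pattern == "same_diff") sl[2] <- s / runif(1, 2.3, 4)
        if (k > 2 && pattern != "single") sl[3:k] <- 0
      }
      rows[[length(rows) + 1L]] <- data.table(
        feature_id = gp$feature_id, feature_type = "peak", gene_id = g,
        variant_id = vid, slope = sl[seq_len(k)], topology = "none")
    }
  }
  enh <- annotation$enhancers
  if (nrow(enh) > 0 && ef$frac_enhancers > 0) {
    target_e <- sample(enh$feature_id, max(1L, round(ef$frac_enhancers * nrow(enh))))
    pairs <- annotation$pairs
    for (eid in target_e) {
      tad_i <- enh$midpoint[enh$feature_id == eid] %/% config$tad_span
      vid <- pick_variant(tad_i)
      if (is.na(vid)) next
      s <- runif(1, ef$slope_range[1], ef$slope_range[2]) * sample(c(-1, 1), 1)
      paired <- pairs[enhancer_id == eid, peak_id]
      topo <- if (length(paired)) sample(c("v_e_p", "independent", "none"), 1,
                                         prob = c(0.5, 0.25, 0.25)) else "none"
      rows[[length(rows) + 1L]] <- data.table(
        feature_id = eid, feature_type = "enhancer", gene_id = NA_character_,
        variant_id = vid, slope = s, topology = topo)
      if (topo == "independent" && length(paired)) {
        # same variant affects the paired promoter directly, no mediation
        rows[[length(rows) + 1L]] <- data.table(
          feature_id = paired[1], feature_type = "peak",
          gene_id = peaks[feature_id == paired[1], gene_id],
          variant_id = vid, slope = s * runif(1, 0.6, 1.0), topology = "independent")
      }
    }
  }
  if (!length(rows))
    return(data.table(feature_id = character(), feature_type = character(),
                      gene_id = character(), variant_id = character(),
                      slope = numeric(), topology = character()))
  rbindlist(rows)
}

# group label implied by planted slopes, using the classification rules
planted_group <- function(slopes, positions, max_gap = 200, er_threshold = 2) {
  o <- order(positions)
  slopes <- slopes[o]; positions <- positions[o]
  unit <- cumsum(c(1L, as.integer(diff(positions) >= max_gap)))
  usl <- vapply(split(slopes, unit), function(s) s[which.max(abs(s))], numeric(1))
  if (length(usl) == 1L) return(1L)
  sig <- usl[usl != 0]
  if (length(sig) <= 1L) return(2L)
  if (length(unique(sign(sig))) > 1L) return(3L)
  er <- max(abs(sig)) / min(abs(sig))
  if (er > er_threshold) 5L else 4L
}

#' Simulate CAGE tag streams with planted effects
#'
#' Generates per-sample CTSS tag streams. Promoter tags are placed on the
#' gene strand at positions inside each CAGE peak; enhancer tags are placed
#' divergently (minus strand left of the midpoint, plus strand right) so that
#' planted active enhancers satisfy the bidirectional criterion. Expected
#' log tag count = baseline + slope x dosage (+ mediation term), with
#' negative-binomial noise and per-sample library size variation.
#'
#' @param genotypes `genotype_matrix`
#' @param annotation `annotation_set`
#' @param config [sim_config()]
#' @return list with `tag_streams` (named list of per-sample tag streams),
#'   `truth` (truth table: feature_id, variant_id, true_slope,
#'   true_group_label, topology, is_bidirectional), `depths` (expected
#'   per-sample depth factors), and `mediators` (latent mediator values for
#'   mediated targets)
#' @export
simulate_cage_tags <- function(genotypes, annotation, config) {
  set.seed(config$seed + 3L)
  eff <- config$effect_table
  if (is.null(eff)) eff <- plant_effects(genotypes, annotation, config)
  if (nrow(eff) > 0) {
    missing <- setdiff(eff$feature_id,
                       c(annotation$peaks$feature_id, annotation$enhancers$feature_id))
    if (length(missing)) stop("effect targets not in annotation: ",
                              paste(head(missing, 3), collapse = ", "))
  }
  n <- config$n_samples
  sample_ids <- genotypes$sample_ids
  depth <- rlnorm(n, meanlog = log(config$depth_mean) - 0.5 * log(1 + (config$depth_sd / config$depth_mean)^2),
                  sdlog = sqrt(log(1 + (config$depth_sd / config$depth_mean)^2)))
  rel_depth <- depth / mean(depth)
  size <- 1 / config$dispersion
  peaks <- annotation$peaks
  enh <- annotation$enhancers
  n_feat_tot <- max(1L, nrow(peaks) + 2L * nrow(enh))

  # baseline per-feature relative abundance (log-normal across features)
  peak_base <- if (nrow(peaks)) exp(rnorm(nrow(peaks), 0, 1)) else numeric(0)
  # counts budget: promoters take ~85% of the library
  peak_mu0 <- if (nrow(peaks)) peak_base / sum(peak_base) * 0.85 * config$depth_mean else numeric(0)

  active_e <- if (nrow(enh)) runif(nrow(enh)) < config$frac_active_enhancers else logical(0)
  unidir_e <- if (nrow(enh)) runif(nrow(enh)) < config$frac_unidirectional else logical(0)
  enh_base <- if (nrow(enh)) exp(rnorm(nrow(enh), 0, 0.6)) else numeric(0)
  # per active enhancer side, mean tags/sample ~ 10-40
  enh_mu0 <- ifelse(active_e, enh_base * 20, 0.05)

  eff_peak <- eff[feature_type == "peak"]
  eff_enh <- eff[feature_type == "enhancer"]
  slope_of_peak <- setNames(rep(0, nrow(peaks)), peaks$feature_id)
  var_of_peak <- setNames(rep(NA_character_, nrow(peaks)), peaks$feature_id)
  if (nrow(eff_peak)) {
    slope_of_peak[eff_peak$feature_id] <- eff_peak$slope
    var_of_peak[eff_peak$feature_id] <- eff_peak$variant_id
  }

  dos <- genotypes$dosage

  # --- enhancer expected counts (per side), mediation latents -------------
  med_vals <- list()
  enh_muF <- enh_muR <- NULL
  if (nrow(enh)) {
    enh_muF <- matrix(rep(enh_mu0, each = n), nrow = n)  # samples x enhancers
    for (i in seq_len(nrow(eff_enh))) {
      j <- match(eff_enh$feature_id[i], enh$feature_id)
      vid <- eff_enh$variant_id[i]
      if (!vid %in% colnames(dos)) next
      d <- dos[, vid]; d[is.na(d)] <- mean(d, na.rm = TRUE)
      enh_muF[, j] <- enh_muF[, j] * exp(eff_enh$slope[i] * (d - mean(d)))
    }
    enh_muR <- enh_muF
    # unidirectional (promoter-like) regions: all signal on the plus side
    if (any(unidir_e)) {
      enh_muF[, unidir_e] <- enh_muF[, unidir_e] * 2
      enh_muR[, unidir_e] <- 0.02
    }
  }
  # sample enhancer side counts now so measured activity can mediate promoters
  cntF <- cntR <- NULL
  if (nrow(enh)) {
    cntF <- matrix(rnbinom(n * nrow(enh), mu = t(t(enh_muF) ) * rel_depth, size = size),
                   nrow = n)
    cntR <- matrix(rnbinom(n * nrow(enh), mu = t(t(enh_muR) ) * rel_depth, size = size),
                   nrow = n)
  }

  # --- promoter expected counts -------------------------------------------
  peak_mu <- NULL
  if (nrow(peaks)) {
    peak_mu <- matrix(rep(peak_mu0, each = n), nrow = n)  # samples x peaks
    for (i in seq_len(nrow(eff_peak))) {
      j <- match(eff_peak$feature_id[i], peaks$feature_id)
      vid <- eff_peak$variant_id[i]
      if (!vid %in% colnames(dos)) next
      d <- dos[, vid]; d[is.na(d)] <- mean(d, na.rm = TRUE)
      peak_mu[, j] <- peak_mu[, j] * exp(eff_peak$slope[i] * (d - mean(d)))
    }
    # mediated promoters: expected count follows measured enhancer activity
    med_rows <- eff_enh[topology == "v_e_p"]
    gamma <- config$effects$med_gamma %||% 1.0
    mns <- config$effects$med_noise_sd %||% 1.0
    if (nrow(med_rows) && nrow(enh)) {
      for (i in seq_len(nrow(med_rows))) {
        eid <- med_rows$feature_id[i]
        j_e <- match(eid, enh$feature_id)
        paired <- annotation$pairs[enhancer_id == eid, peak_id]
        if (!length(paired)) next
        A <- log((cntF[, j_e] + cntR[, j_e] + 1) / rel_depth)
        Az <- (A - mean(A)) / max(sd(A), 1e-8)
        med_vals[[eid]] <- Az
        for (pk in paired) {
          j_p <- match(pk, peaks$feature_id)
          noise <- rnorm(n, 0, mns)
          peak_mu[, j_p] <- peak_mu[, j_p] * exp(gamma * Az + noise - (gamma^2 + mns^2) / 2)
        }
      }
    }
  }

  # --- materialize tag streams --------------------------------------------
  streams <- vector("list", n)
  peak_cnt <- NULL
  if (nrow(peaks)) {
    peak_cnt <- matrix(rnbinom(n * nrow(peaks), mu = peak_mu * rel_depth, size = size),
                       nrow = n)
  }
  # fixed within-feature positional split (3 CTSS positions per peak, 2 per
  # enhancer side), chosen once so positions are stable across samples
  peak_off <- if (nrow(peaks)) cbind(0L, pmax(1L, as.integer((peaks$end - peaks$start) * 0.4)),
                                     pmax(2L, as.integer((peaks$end - peaks$start) * 0.8))) else NULL
  wsplit <- c(0.6, 0.3, 0.1)
  for (s in seq_len(n)) {
    parts <- list()
    if (nrow(peaks)) {
      cnt <- peak_cnt[s, ]
      nz <- which(cnt > 0)
      if (length(nz)) {
        c1 <- as.integer(round(cnt[nz] * wsplit[1]))
        c2 <- as.integer(round(cnt[nz] * wsplit[2]))
        c3 <- cnt[nz] - c1 - c2
        anch <- ifelse(peaks$strand[nz] == "+", peaks$start[nz], peaks$end[nz] - 1L)
        dirn <- ifelse(peaks$strand[nz] == "+", 1L, -1L)
        pp <- data.table(
          chrom = rep(peaks$chrom[nz], 3L),
          pos = c(anch + dirn * peak_off[nz, 1], anch + dirn * peak_off[nz, 2],
                  anch + dirn * peak_off[nz, 3]),
          strand = rep(peaks$strand[nz], 3L),
          count = c(c1, c2, c3))
        parts$peaks <- pp[count > 0]
      }
    }
    if (nrow(enh)) {
      fz <- which(cntF[s, ] > 0)
      if (length(fz)) {
        cf1 <- as.integer(round(cntF[s, fz] * 0.7)); cf2 <- cntF[s, fz] - cf1
        parts$enhF <- data.table(
          chrom = rep(enh$chrom[fz], 2L),
          pos = c(enh$midpoint[fz] + 60L, enh$midpoint[fz] + 120L),
          strand = "+", count = c(cf1, cf2))[count > 0]
      }
      rz <- which(cntR[s, ] > 0)
      if (length(rz)) {
        cr1 <- as.integer(round(cntR[s, rz] * 0.7)); cr2 <- cntR[s, rz] - cr1
        parts$enhR <- data.table(
          chrom = rep(enh$chrom[rz], 2L),
          pos = c(enh$midpoint[rz] - 60L, enh$midpoint[rz] - 120L),
          strand = "-", count = c(cr1, cr2))[count > 0]
      }
    }
    ts <- if (length(parts)) rbindlist(parts) else
      data.table(chrom = character(), pos = integer(), strand = character(), count = integer())
    ts <- ts[, .(count = sum(count)), by = .(chrom, pos, strand)]
    setorder(ts, chrom, pos, strand)
    setattr(ts, "sample_id", sample_ids[s])
    setattr(ts, "library_size", sum(ts$count))
    streams[[s]] <- ts
  }
  names(streams) <- sample_ids

  # --- truth table ---------------------------------------------------------
  truth_rows <- list()
  if (nrow(eff_peak)) {
    by_gene <- split(eff_peak, eff_peak$gene_id)
    for (g in names(by_gene)) {
      bg <- by_gene[[g]]
      gp <- peaks[gene_id == g]
      sl <- setNames(rep(0, nrow(gp)), gp$feature_id)
      sl[bg$feature_id] <- bg$slope
      grp <- planted_group(sl, feature_anchor(gp, "peak"))
      truth_rows[[length(truth_rows) + 1L]] <- data.table(
        feature_id = bg$feature_id, feature_type = "peak",
        variant_id = bg$variant_id, true_slope = bg$slope,
        true_group_label = grp, topology = bg$topology,
        is_bidirectional = NA)
    }
  }
  if (nrow(eff_enh)) {
    je <- match(eff_enh$feature_id, enh$feature_id)
    truth_rows[[length(truth_rows) + 1L]] <- data.table(
      feature_id = eff_enh$feature_id, feature_type = "enhancer",
      variant_id = eff_enh$variant_id, true_slope = eff_enh$slope,
      true_group_label = NA_integer_, topology = eff_enh$topology,
      is_bidirectional = !unidir_e[je] & active_e[je])
    # promoters downstream of a mediated enhancer inherit an indirect
    # genetic signal; recorded with slope 0 and the mediation topology
    med <- eff_enh[topology == "v_e_p"]
    for (i in seq_len(nrow(med))) {
      paired <- annotation$pairs[enhancer_id == med$feature_id[i], peak_id]
      if (!length(paired)) next
      truth_rows[[length(truth_rows) + 1L]] <- data.table(
        feature_id = paired, feature_type = "peak",
        variant_id = med$variant_id[i], true_slope = 0,
        true_group_label = NA_integer_, topology = "v_e_p",
        is_bidirectional = NA)
    }
  }
  if (nrow(enh)) {
    planted <- if (nrow(eff_enh)) eff_enh$feature_id else character(0)
    rest <- setdiff(enh$feature_id, planted)
    jr <- match(rest, enh$feature_id)
    if (length(rest))
      truth_rows[[length(truth_rows) + 1L]] <- data.table(
        feature_id = rest, feature_type = "enhancer", variant_id = NA_character_,
        true_slope = 0, true_group_label = NA_integer_, topology = "none",
        is_bidirectional = !unidir_e[jr] & active_e[jr])
  }
  truth <- if (length(truth_rows)) rbindlist(truth_rows) else
    data.table(feature_id = character(), feature_type = character(),
               variant_id = character(), true_slope = numeric(),
               true_group_label = integer(), topology = character(),
               is_bidirectional = logical())

  # augment the GWAS catalog with variants in LD with planted QTLs
  if (nrow(truth[!is.na(variant_id)]) && nrow(annotation$gwas)) {
    v <- genotypes$variants
    qv <- unique(truth[!is.na(variant_id), variant_id])
    qv <- qv[qv %in% v$variant_id]
    ld_partner <- vapply(qv, function(id) {
      b <- v$ld_block[v$variant_id == id]
      cand <- v$variant_id[v$ld_block == b & v$variant_id != id]
      if (length(cand)) cand[1] else id
    }, character(1))
    extra <- data.table(variant_id = unname(ld_partner),
                        chrom = v$chrom[match(ld_partner, v$variant_id)],
                        pos = v$pos[match(ld_partner, v$variant_id)],
                        trait = "planted_trait")
    annotation$gwas <- unique(rbindlist(list(annotation$gwas, extra)), by = "variant_id")
  }

  list(tag_streams = streams, truth = truth, depths = rel_depth,
       mediators = med_vals, gwas = annotation$gwas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single mediation triplet (dosage, mediator, outcome)
#'
#' Generates one variant-enhancer-promoter triplet under a chosen causal
#' topology, with the same negative-binomial count machinery as the full
#' generator. The mediator and outcome are returned as log normalized
#' expression values.
#'
#' @param n samples
#' @param maf allele frequency of the variant
#' @param beta per-allele log-scale slope on the first affected feature
#' @param gamma effect (per SD of measured mediator) on the downstream feature
#' @param topology `"v_m_t"` (variant -> mediator -> outcome),
#'   `"v_t_m"` (reverse chain), `"independent"` (variant affects both,
#'   no mediation), or `"null"` (no outcome effect)
#' @param dispersion NB overdispersion
#' @param noise_m,noise_t extra log-normal biological noise SD on mediator
#'   and outcome
#' @param depth_mean mean per-feature baseline count
#' @param seed integer seed
#' @return list with numeric vectors `L` (dosage), `M`, `T`
#' @export
simulate_mediation_triplet <- function(n = 150, maf = 0.3, beta = 1.0, gamma = 1.0,
                                       topology = c("v_m_t", "v_t_m", "independent", "null"),
                                       dispersion = 0.1, noise_m = 0.5, noise_t = 1.0,
                                       depth_mean = 200, seed = 1L) {
  topology <- match.arg(topology)
  set.seed(seed)
  size <- 1 / dispersion
  L <- rbinom(n, 2, maf)
  mk <- function(logmu) log1p(rnbinom(n, mu = exp(logmu + log(depth_mean)), size = size))
  b0 <- 0
  if (topology == "v_m_t") {
    M <- mk(b0 + beta * (L - mean(L)) + rnorm(n, 0, noise_m))
    Mz <- (M - mean(M)) / max(sd(M), 1e-8)
    Tv <- mk(b0 + gamma * Mz + rnorm(n, 0, noise_t))
  } else if (topology == "v_t_m") {
    Tv <- mk(b0 + beta * (L - mean(L)) + rnorm(n, 0, noise_m))
    Tz <- (Tv - mean(Tv)) / max(sd(Tv), 1e-8)
    M <- mk(b0 + gamma * Tz + rnorm(n, 0, noise_t))
  } else if (topology == "independent") {
    M <- mk(b0 + beta * (L - mean(L)) + rnorm(n, 0, noise_m))
    Tv <- mk(b0 + beta * (L - mean(L)) + rnorm(n, 0, noise_t))
  } else {
    M <- mk(b0 + beta * (L - mean(L)) + rnorm(n, 0, noise_m))
    Tv <- mk(b0 + rnorm(n, 0, noise_t))
  }
  list(L = L, M = M, T = Tv)
}

#' Write all simulated inputs to disk
#'
#' Emits the on-disk form of a synthetic cohort: a minimal VCF, per-sample
#' CTSS BED6 files, BED annotation files, and a TSV truth table.
#'
#' @param genotypes `genotype_matrix`
#' @param annotation `annotation_set`
#' @param tags result of [simulate_cage_tags()]
#' @param dir output directory (created)
#' @return invisibly, the named vector of written paths
#' @export
write_simulation <- function(genotypes, annotation, tags, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ctss"), showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.vcf"))
  write_genotypes_vcf(genotypes, paths[["genotypes"]])
  for (nm in c("tads", "peaks", "genes", "enhancers", "transcripts", "segments")) {
    p <- file.path(dir, paste0(nm, ".bed"))
    extra <- setdiff(names(annotation[[nm]]),
                     c("chrom", "start", "end", "strand", "feature_id", "score"))
    write_bed(annotation[[nm]], p, extra_cols = extra)
    paths[nm] <- p
  }
  fwrite(annotation$pairs, file.path(dir, "pairs.tsv"), sep = "\t")
  fwrite(tags$gwas %||% annotation$gwas, file.path(dir, "gwas.tsv"), sep = "\t")
  fwrite(tags$truth, file.path(dir, "truth.tsv"), sep = "\t")
  for (s in names(tags$tag_streams))
    write_ctss(tags$tag_streams[[s]], file.path(dir, "ctss", paste0(s, ".ctss.bed")))
  paths["pairs"] <- file.path(dir, "pairs.tsv")
  paths["gwas"] <- file.path(dir, "gwas.tsv")
  paths["truth"] <- file.path(dir, "truth.tsv")
  invisible(paths)
}
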