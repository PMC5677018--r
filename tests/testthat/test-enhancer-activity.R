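test_that("density clustering handles degenerate inputs per the filter rules", {
  # single position with 5 tags: one cluster, length 1, ratio treated as Inf
  one <- paraclu_cluster(100L, 5L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start, 1L)
  expect_equal(one$max_density, Inf)
  # 4 tags at one position: below the minimum tag count
  expect_equal(nrow(paraclu_cluster(100L, 4L)), 0L)
  expect_error(paraclu_cluster(c(5L, 2L), c(3L, 3L)), "sorted")
  expect_equal(nrow(paraclu_cluster(integer(0), integer(0))), 0L)
})

test_that("clusters conserve member tag counts", {
  set.seed(31)
  pos <- sort(sample.int(1000, 50))
  cnt <- sample.int(15, 50, replace = TRUE)
  cl <- paraclu_cluster(pos, cnt, min_tags = 1, max_length = 1000)
  for (r in seq_len(nrow(cl))) {
    members <- pos >= cl$start[r] & pos < cl$end[r]
    expect_equal(cl$tag_count[r], sum(cnt[members]))
  }
})

test_that("clustering equals brute-force maximal-density enumeration", {
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    if (rep %% 3 == 0) {
      pos <- sort(sample.int(60, n)); cnt <- rep(sample(1:4, 1), n)
    } else {
      pos <- sort(sample.int(400, n)); cnt <- sample.int(20, n, replace = TRUE)
    }
    got <- as.data.frame(paraclu_cluster(pos, cnt))
    want <- brute_paraclu(pos, cnt)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
      next
    }
    rownames(got) <- rownames(want) <- NULL
    expect_equal(nrow(got), nrow(want), info = paste("rep", rep))
    expect_equal(got$start, want$start, info = paste("rep", rep))
    expect_equal(got$end, want$end)
    expect_equal(got$tag_count, want$tag_count)
    expect_equal(got$min_density, want$min_density, tolerance = 1e-9)
    expect_equal(got$max_density, want$max_density, tolerance = 1e-9)
  }
})

test_that("bidirectional selection requires clusters on both strands", {
  enh <- genomic_intervals("chr1", 800L, 1200L, ".", "e1", score = 0,
                           midpoint = 1000L)
  mk_cl <- function(strand, start, end) data.table::data.table(
    chrom = "chr1", strand = strand, start = start, end = end,
    tag_count = 10, min_density = 0, max_density = Inf)
  # plus-only: rejected
  expect_false(select_bidirectional(enh, mk_cl("+", 1050L, 1080L))$bidirectional)
  # clusters at mid-100 (minus) and mid+50 (plus): kept
  both <- rbind(mk_cl("+", 1050L, 1080L), mk_cl("-", 900L, 920L))
  expect_true(select_bidirectional(enh, both)$bidirectional)
  # clusters outside the 400 nt window: rejected
  far <- rbind(mk_cl("+", 1500L, 1520L), mk_cl("-", 400L, 420L))
  expect_false(select_bidirectional(enh, far)$bidirectional)
})

test_that("bidirectional flags equal a naive overlap recomputation", {
  set.seed(33)
  mids <- sort(sample(seq(2000L, 50000L, by = 100L), 30))
  enh <- genomic_intervals("chr1", mids - 200L, mids + 200L, ".",
                           sprintf("e%d", seq_along(mids)), score = 0, midpoint = mids)
  cl <- data.table::data.table(
    chrom = "chr1", strand = sample(c("+", "-"), 80, TRUE),
    start = st <- sample.int(52000L, 80), end = st + sample.int(150, 80),
    tag_count = 10, min_density = 0, max_density = Inf)
  got <- select_bidirectional(enh, cl)$bidirectional
  want <- vapply(seq_along(mids), function(i) {
    lo <- mids[i] - 400L; hi <- mids[i] + 400L
    ok <- function(str) any(cl$strand == str & cl$start < hi & cl$end > lo)
    ok("+") && ok("-")
  }, logical(1))
  expect_equal(got, want)
})

test_that("directionality identities hold exactly", {
  # two samples; enhancer at mid 1000 with known window counts
  enh <- genomic_intervals("chr1", 800L, 1200L, ".", "e1", score = 0,
                           midpoint = 1000L)
  s1 <- make_stream("chr1", c(1050, 950), c("+", "-"), c(3, 1), "S1")
  s2 <- make_stream("chr1", c(1050, 950), c("+", "-"), c(3, 1), "S2")
  q <- directionality_and_quantify(list(S1 = s1, S2 = s2), enh)
  # F = 3x, R = 1x after normalization: D = (F-R)/(F+R) = 0.5
  expect_equal(q$quants$D, 0.5, tolerance = 1e-12)
  # F = R gives D = 0
  s3 <- make_stream("chr1", c(1050, 950), c("+", "-"), c(2, 2), "S1")
  q0 <- directionality_and_quantify(list(S1 = s3, S2 = s3), enh)
  expect_equal(q0$quants$D, 0, tolerance = 1e-12)
  # R = 0 gives D = 1
  s4 <- make_stream("chr1", 1050, "+", 4, "S1")
  q1 <- directionality_and_quantify(list(S1 = s4, S2 = s4), enh)
  expect_equal(q1$quants$D, 1)
  # strand swap (mirror the tags about the midpoint) negates D
  s5 <- make_stream("chr1", c(950, 1050), c("-", "+"), c(3, 1), "S1")
  qm <- directionality_and_quantify(list(S1 = s5, S2 = s5), enh)
  expect_equal(qm$quants$D, -q$quants$D, tolerance = 1e-12)
})

test_that("cohort D equals a hand recomputation from raw tags", {
  set.seed(34)
  enh <- genomic_intervals("chr1", c(800L, 4800L), c(1200L, 5200L), ".",
                           c("e1", "e2"), score = 0, midpoint = c(1000L, 5000L))
  streams <- lapply(1:4, function(s) {
    pos <- c(1000 + sample(0:199, 5), 1000 - sample(1:200, 5),
             5000 + sample(0:199, 5), 5000 - sample(1:200, 5))
    str <- rep(c("+", "-", "+", "-"), each = 5)
    dt <- data.table::data.table(chrom = "chr1", pos = as.integer(pos), strand = str,
                                 count = sample.int(6, 20, TRUE))
    dt <- dt[, .(count = sum(count)), by = .(chrom, pos, strand)]
    data.table::setattr(dt, "library_size", sum(dt$count))
    dt
  })
  names(streams) <- sprintf("S%d", 1:4)
  q <- directionality_and_quantify(streams, enh)
  # hand pipeline: window counts -> TPM -> RLE -> sums
  cnt <- function(e, mid) {
    fs <- sapply(streams, function(ts) sum(ts$count[ts$strand == "+" &
      ts$pos >= mid & ts$pos < mid + 200]))
    rs <- sapply(streams, function(ts) sum(ts$count[ts$strand == "-" &
      ts$pos >= mid - 200 & ts$pos < mid]))
    rbind(fs, rs)
  }
  raw <- rbind(cnt(1, 1000)[1, ], cnt(2, 5000)[1, ], cnt(1, 1000)[2, ], cnt(2, 5000)[2, ])
  lib <- sapply(streams, function(ts) sum(ts$count))
  tpm <- sweep(raw, 2, lib, "/") * 1e6
  sf <- rle_size_factors(tpm)
  nrm <- sweep(tpm, 2, sf, "/")
  D_hand <- (rowSums(nrm)[1:2] - rowSums(nrm)[3:4]) /
    (rowSums(nrm)[1:2] + rowSums(nrm)[3:4])
  expect_equal(q$quants$D, unname(D_hand), tolerance = 1e-10)
})

test_that("enhancer matrix filters on |D| and null-sample count", {
  act <- matrix(1, 4, 154, dimnames = list(sprintf("e%d", 1:4), sprintf("S%d", 1:154)))
  act[3, 1:51] <- 0   # null in 51 of 154 samples: dropped
  act[4, 1:50] <- 0   # null in 50 of 154: kept
  q <- list(quants = data.table::data.table(
    enhancer_id = sprintf("e%d", 1:4), midpoint = 1:4 * 1000L,
    F = c(0.925, 0.895, 1, 1), R = c(0.075, 0.105, 1, 1),
    D = c(0.85, 0.79, 0, 0), n_null = rowSums(act == 0)),
    activity = act, size_factors = setNames(rep(1, 154), colnames(act)))
  enh <- genomic_intervals("chr1", 1:4 * 1000L - 200L, 1:4 * 1000L + 200L, ".",
                           sprintf("e%d", 1:4), score = 0, midpoint = 1:4 * 1000L)
  em <- build_enhancer_matrix(q, enh)
  expect_setequal(rownames(em$values), c("e2", "e4"))
  # brute-force filter recomputation
  want <- q$quants$enhancer_id[abs(q$quants$D) < 0.8 &
                                 q$quants$n_null <= 50 / 154 * 154]
  expect_setequal(rownames(em$values), want)
})

test_that("planted bidirectional enhancers survive and unidirectional fail", {
  pass_bid <- c(); rej_uni <- c()
  for (seed in 1:5) {
    co <- small_cohort(seed = 200 + seed, n_samples = 60, n_genes = 15,
                       n_enhancers = 20)
    clus <- cluster_tag_streams(co$tg$tag_streams)
    bid <- select_bidirectional(co$ann$enhancers, clus)
    qn <- directionality_and_quantify(co$tg$tag_streams,
                                      bid[bid$bidirectional == TRUE])
    em <- tryCatch(build_enhancer_matrix(qn, bid[bid$bidirectional == TRUE]),
                   error = function(e) NULL)
    kept <- if (is.null(em)) character(0) else rownames(em$values)
    truth <- co$tg$truth[co$tg$truth$feature_type == "enhancer", ]
    tb <- truth$feature_id[truth$is_bidirectional]
    tu <- truth$feature_id[!truth$is_bidirectional & truth$true_slope != 0]
    pass_bid <- c(pass_bid, tb %in% kept)
    rej_uni <- c(rej_uni, !(tu %in% kept))
  }
  expect_gt(length(pass_bid), 30)
  expect_gte(mean(pass_bid), 0.95)
  expect_gte(mean(rej_uni), 0.95)
})
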