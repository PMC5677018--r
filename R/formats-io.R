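#' @import data.table
#' @importFrom stats median cor qnorm pnorm pbeta pf pt qbeta rbinom rnbinom
#'   rnorm runif rlnorm complete.cases lm coef resid prcomp smooth.spline
#'   predict sd var quantile rpois optim setNames ks.test ecdf
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# VCF positions are converted from 1-based on read and back on write.

#' Construct a table of genomic intervals
#'
#' Intervals are plain `data.table`s with columns `chrom`, `start`, `end`,
#' `strand`, `feature_id` plus arbitrary attribute columns. Coordinates are
#' 0-based half-open.
#'
#' @param chrom character chromosome names
#' @param start,end integer 0-based half-open bounds, `start < end`
#' @param strand one of `"+"`, `"-"`, `"."`
#' @param feature_id unique feature identifiers
#' @param ... further attribute columns recycled to length
#' @return a `data.table` of intervals
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", feature_id = NULL, ...) {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(feature_id)) feature_id <- sprintf("feat_%d", seq_len(n))
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   feature_id = as.character(feature_id), ...)
  validate_intervals(dt)
  dt
}

validate_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  bad <- which(!(dt$start < dt$end))
  if (length(bad))
    stop("invalid interval(s): start >= end at row(s) ", paste(head(bad, 5), collapse = ", "))
  if (any(!nzchar(dt$chrom))) stop("empty chrom name")
  invisible(dt)
}

# Intervals -> GRanges (internal; GRanges is 1-based closed)
as_granges <- function(dt, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(dt)) dt$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1L, end = dt$end),
                         strand = strand)
}

#' Read a BED file as genomic intervals
#'
#' Accepts BED4/BED6/BED6+ (chrom, start, end, name[, score, strand, ...]).
#' Input order is preserved; records with `start >= end` are rejected with
#' file and line context.
#'
#' @param path BED file path
#' @param kind optional label stored in the `kind` attribute
#' @param extra_cols names for columns beyond the sixth, if present
#' @return `data.table` of intervals (see [genomic_intervals()])
#' @export
read_bed <- function(path, kind = NULL, extra_cols = NULL) {
  dt <- tryCatch(suppressWarnings(fread(path, header = FALSE, sep = "\t")),
                 error = function(e) data.table())
  if (nrow(dt) == 0L) {
    out <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), feature_id = character(), score = numeric())
    setattr(out, "kind", kind)
    return(out)
  }
  if (ncol(dt) < 4L) stop("BED file ", path, " has fewer than 4 columns")
  out <- data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), feature_id = as.character(dt[[4]]))
  out[, score := if (ncol(dt) >= 5L) suppressWarnings(as.numeric(dt[[5]])) else 0]
  out[, strand := if (ncol(dt) >= 6L) as.character(dt[[6]]) else "."]
  if (!is.null(extra_cols) && ncol(dt) >= 7L) {
    for (i in seq_along(extra_cols)) {
      if (6L + i <= ncol(dt)) out[[extra_cols[i]]] <- dt[[6L + i]]
    }
  }
  bad <- which(!(out$start < out$end))
  if (length(bad))
    stop("BED record with start >= end in ", path, " at line(s) ",
         paste(head(bad, 5), collapse = ", "))
  setcolorder(out, c("chrom", "start", "end", "strand", "feature_id", "score"))
  setattr(out, "kind", kind)
  out
}

#' Write genomic intervals as BED6(+)
#'
#' @param intervals interval `data.table`
#' @param path output path
#' @param extra_cols attribute columns appended after the sixth column
#' @export
write_bed <- function(intervals, path, extra_cols = NULL) {
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  out <- data.table(intervals$chrom, intervals$start, intervals$end,
                    intervals$feature_id, score, strand)
  for (cc in extra_cols) out[[cc]] <- intervals[[cc]]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-sample CTSS file (BED6: chrom, pos, pos+1, label, count, strand)
#'
#' @param path CTSS BED6 path
#' @param sample_id sample identifier stored as an attribute
#' @return `data.table` with columns chrom, pos, strand, count; attributes
#'   `sample_id` and `library_size`
#' @export
read_ctss <- function(path, sample_id = NULL) {
  bed <- read_bed(path)
  ts <- data.table(chrom = bed$chrom, pos = bed$start,
                   strand = bed$strand, count = as.integer(bed$score))
  validate_tag_stream(ts)
  setattr(ts, "sample_id", sample_id)
  setattr(ts, "library_size", sum(ts$count))
  ts
}

validate_tag_stream <- function(ts) {
  if (nrow(ts) == 0L) return(invisible(ts))
  if (any(ts$count < 1L)) stop("CTSS counts must be >= 1")
  if (anyDuplicated(ts[, .(chrom, pos, strand)]))
    stop("duplicate CTSS positions within (chrom, strand)")
  invisible(ts)
}

#' Write a tag stream as CTSS BED6
#' @param tags tag stream `data.table` (chrom, pos, strand, count)
#' @param path output path
#' @export
write_ctss <- function(tags, path) {
  label <- sprintf("%s:%d:%s", tags$chrom, tags$pos, tags$strand)
  out <- data.table(tags$chrom, tags$pos, tags$pos + 1L, label, tags$count, tags$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a genotype matrix object
#'
#' @param dosage samples x variants matrix with entries in \{0, 1, 2\} (NA allowed)
#' @param variants `data.frame` with columns variant_id, chrom, pos (0-based),
#'   ref, alt
#' @param sample_ids character vector, one per dosage row
#' @return object of class `genotype_matrix` with per-variant MAF and
#'   alternative-allele counts computed from the dosages
#' @export
genotype_matrix <- function(dosage, variants, sample_ids) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(sample_ids), ncol(dosage) == nrow(variants))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$variant_id
  variants <- as.data.table(variants)
  variants[, alt_count := colSums(dosage, na.rm = TRUE)]
  af <- colMeans(dosage, na.rm = TRUE) / 2
  variants[, alt_freq := af]
  variants[, maf := pmin(af, 1 - af)]
  structure(list(sample_ids = sample_ids, variants = variants, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$sample_ids), nrow(x$variants)))
  dropped <- attr(x, "n_filtered")
  if (!is.null(dropped)) cat(sprintf("  (%d variants removed by alt-count filter)\n", dropped))
  invisible(x)
}

#' Read genotypes from VCF or dosage TSV
#'
#' Variants with fewer than `min_alt_count` alternative alleles across the
#' cohort are removed (the count removed is recorded in the `n_filtered`
#' attribute). VCF positions are converted to 0-based.
#'
#' @param path a VCF (`.vcf`) with GT fields, or a dosage TSV whose first five
#'   columns are variant_id, chrom, pos, ref, alt followed by one column per
#'   sample
#' @param min_alt_count minimum cohort-wide alternative allele count
#' @param expected_samples optional sample ids that must match the file header
#' @return a `genotype_matrix`
#' @export
read_genotypes <- function(path, min_alt_count = 10, expected_samples = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), gt_to_dosage)
    fix <- as.data.table(vcfR::getFIX(v))
    variants <- data.table(variant_id = fix$ID, chrom = fix$CHROM,
                           pos = as.integer(fix$POS) - 1L,
                           ref = fix$REF, alt = fix$ALT)
    dosage <- t(dos)
    sample_ids <- rownames(dosage)
  } else {
    dt <- fread(path, header = TRUE, sep = "\t")
    variants <- data.table(variant_id = as.character(dt[[1]]), chrom = as.character(dt[[2]]),
                           pos = as.integer(dt[[3]]), ref = as.character(dt[[4]]),
                           alt = as.character(dt[[5]]))
    dosage <- t(as.matrix(dt[, -(1:5)]))
    sample_ids <- colnames(dt)[-(1:5)]
  }
  if (!is.null(expected_samples) && !identical(sort(sample_ids), sort(expected_samples)))
    stop("sample identity error: genotype samples do not match expression samples")
  alt_counts <- colSums(dosage, na.rm = TRUE)
  keep <- alt_counts >= min_alt_count
  gm <- genotype_matrix(dosage[, keep, drop = FALSE], variants[keep], sample_ids)
  setattr(gm, "n_filtered", sum(!keep))
  if (any(!keep))
    message(sum(!keep), " variant(s) removed: alternative allele count < ", min_alt_count)
  gm
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
}

#' Write a genotype matrix as a minimal VCF (CHROM POS ID REF ALT GT)
#' @param gm `genotype_matrix`
#' @param path output path
#' @export
write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  v <- gm$variants
  d <- gm$dosage
  lines <- vapply(seq_len(nrow(v)), function(j) {
    g <- d[, j]
    gs <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    paste(c(v$chrom[j], v$pos[j] + 1L, v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Write / read a numeric matrix as TSV with a feature-id column
#'
#' The header row holds sample ids; the first column holds feature ids.
#' Column order is deterministic (as stored).
#'
#' @param m numeric matrix with row and column names
#' @param path file path
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table(feature_id = rownames(m))
  for (s in colnames(m)) dt[[s]] <- m[, s]
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Aggregate CTSS tags into feature-level counts
#'
#' For every interval and sample, sums the tag counts of CTSS positions
#' falling inside the interval, subject to a strand rule. Tags outside all
#' intervals are ignored.
#'
#' @param tag_streams named list of tag streams (one per sample)
#' @param intervals interval `data.table` with unique `feature_id`
#' @param strand_rule `"same-strand"` (tag strand must equal interval strand),
#'   `"plus-only"`, `"minus-only"`, or `"both"`
#' @return integer matrix features x samples
#' @export
aggregate_tags_to_features <- function(tag_streams, intervals,
                                       strand_rule = c("same-strand", "plus-only",
                                                       "minus-only", "both")) {
  strand_rule <- match.arg(strand_rule)
  if (anyDuplicated(intervals$feature_id)) stop("duplicate feature_id in intervals")
  samples <- names(tag_streams)
  if (is.null(samples)) samples <- sprintf("S%d", seq_along(tag_streams))
  out <- matrix(0L, nrow = nrow(intervals), ncol = length(tag_streams),
                dimnames = list(intervals$feature_id, samples))
  if (nrow(intervals) == 0L) return(out)
  gr_f <- as_granges(intervals, use_strand = FALSE)
  for (k in seq_along(tag_streams)) {
    ts <- tag_streams[[k]]
    if (nrow(ts) == 0L) next
    keep <- switch(strand_rule,
                   "plus-only" = ts$strand == "+",
                   "minus-only" = ts$strand == "-",
                   rep(TRUE, nrow(ts)))
    ts <- ts[keep]
    if (nrow(ts) == 0L) next
    gr_t <- GenomicRanges::GRanges(ts$chrom, IRanges::IRanges(ts$pos + 1L, ts$pos + 1L))
    hits <- GenomicRanges::findOverlaps(gr_t, gr_f, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (strand_rule == "same-strand") {
      ok <- ts$strand[qh] == intervals$strand[sh]
      qh <- qh[ok]; sh <- sh[ok]
    }
    if (length(qh) == 0L) next
    agg <- rowsum(ts$count[qh], group = sh)
    out[as.integer(rownames(agg)), k] <- out[as.integer(rownames(agg)), k] + as.integer(agg)
  }
  out
}

#' Overlap query between two interval sets
#'
#' @param query,subject interval `data.table`s
#' @param ignore_strand ignore strand when testing overlap (default TRUE)
#' @return `data.table` with columns `query` and `subject` (row indices)
#' @export
find_interval_overlaps <- function(query, subject, ignore_strand = TRUE) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.table(query = integer(), subject = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges(query, !ignore_strand),
                                      as_granges(subject, !ignore_strand),
                                      ignore.strand = ignore_strand)
  data.table(query = S4Vectors::queryHits(hits), subject = S4Vectors::subjectHits(hits))
}

#' Anchor position of a feature for distance and TAD lookup
#'
#' CAGE peaks anchor at their stranded 5' end; enhancers at their midpoint.
#'
#' @param intervals interval `data.table`
#' @param type `"peak"` (5' end on the feature strand) or `"midpoint"`
#' @return integer vector of anchor positions
#' @export
feature_anchor <- function(intervals, type = c("peak", "midpoint")) {
  type <- match.arg(type)
  if (type == "midpoint") return(as.integer((intervals$start + intervals$end) %/% 2))
  ifelse(intervals$strand == "-", intervals$end - 1L, intervals$start)
}
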