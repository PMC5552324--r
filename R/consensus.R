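# k-of-n ensemble consensus over per-caller callsets, depth / on-target
# filtering, and truth-set benchmarking.

#' Merge per-caller callsets into a k-of-n consensus
#'
#' A variant is retained for a sample iff at least `k` callers report a
#' non-reference genotype (het / hom_alt / hemi) for that sample — the
#' "independently called by at least two tools" rule generalized to any k.
#' The consensus genotype is the majority vote among supporting callers,
#' ties resolved toward `het` (the weaker claim); `min_depth` records the
#' minimum read depth among supporters, which the depth filter tests.
#'
#' @param callsets List of caller-observation tables (one per caller, as
#'   produced by [read_caller_vcf()]); list names override the `caller`
#'   column as the configured caller set.
#' @param k Concordance threshold, `1 <= k <= length(callsets)`.
#' @return Object of class `consensus_callset`: a `data.table` with one row
#'   per retained (sample, variant) pair and columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `id`, `genotype`, `n_supporting`, `callers`,
#'   `min_depth`; attributes `k`, `n_callers`, `caller_set`.
#' @export
merge_callsets <- function(callsets, k = 2L) {
  k <- as.integer(k)
  n <- length(callsets)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) {
    stop("k (", k, ") exceeds the number of callers (", n, ")",
         call. = FALSE)
  }
  labels <- names(callsets)
  if (is.null(labels)) {
    labels <- vapply(callsets, function(cs) cs$caller[1], "")
  }
  obs <- rbindlist(Map(function(cs, lab) {
    cs <- as.data.table(cs)
    cs[, caller := lab]
    cs
  }, callsets, labels), use.names = TRUE)
  if (!all(obs$genotype %in% .GENOTYPES)) {
    stop("unknown genotype class in observations", call. = FALSE)
  }
  calls <- obs[genotype %in% .NONREF_GENOTYPES]
  if (nrow(calls) == 0L) {
    cons <- data.table(sample = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), id = character(0),
                       genotype = character(0), n_supporting = integer(0),
                       callers = character(0), min_depth = integer(0))
  } else {
    # one vote per caller per (sample, variant)
    calls <- unique(calls, by = c("caller", "sample", "chrom", "pos",
                                  "ref", "alt"))
    cons <- calls[, {
      gt_tab <- table(genotype)
      top <- names(gt_tab)[gt_tab == max(gt_tab)]
      gt <- if (length(top) == 1L) top else "het"
      list(id = if (all(is.na(id))) NA_character_ else stats::na.omit(id)[1],
           genotype = gt,
           n_supporting = .N,
           callers = paste(sort(caller), collapse = ","),
           min_depth = min(depth))
    }, by = .(sample, chrom, pos, ref, alt)]
    cons <- cons[n_supporting >= k]
    setorder(cons, sample, chrom, pos, ref, alt)
  }
  setattr(cons, "class", c("consensus_callset", "data.table", "data.frame"))
  setattr(cons, "k", k)
  setattr(cons, "n_callers", n)
  setattr(cons, "caller_set", labels)
  cons[]
}

reclass_consensus <- function(cons, template) {
  setattr(cons, "class", c("consensus_callset", "data.table", "data.frame"))
  setattr(cons, "k", attr(template, "k"))
  setattr(cons, "n_callers", attr(template, "n_callers"))
  setattr(cons, "caller_set", attr(template, "caller_set"))
  cons[]
}

#' @export
print.consensus_callset <- function(x, ...) {
  cat("Consensus callset (k=", attr(x, "k"), " of n=", attr(x, "n_callers"),
      "): ", nrow(x), " sample-variant calls, ",
      nrow(unique(x[, c("chrom", "pos", "ref", "alt")])),
      " distinct variants\n", sep = "")
  invisible(x)
}

#' Filter consensus calls by minimum supporting read depth
#'
#' Retains a call iff the minimum depth among its supporting callers'
#' observations reaches `min_depth` (inclusive) — the strictest reading of a
#' "read depth of 20 or more" rule under multi-caller support.
#'
#' @param cs A `consensus_callset`.
#' @param min_depth Inclusive threshold (default 20).
#' @return Filtered `consensus_callset`.
#' @export
apply_depth_filter <- function(cs, min_depth = 20L) {
  thr <- as.integer(min_depth)
  d <- as.data.table(cs)
  reclass_consensus(d[d$min_depth >= thr], cs)
}

#' Restrict consensus calls to target regions
#'
#' Keeps calls whose 1-based position falls inside a target interval
#' (BED half-open convention converted on load).
#'
#' @param cs A `consensus_callset`.
#' @param targets `GRanges` from [read_targets()].
#' @return Filtered `consensus_callset`.
#' @export
restrict_to_targets <- function(cs, targets) {
  d <- as.data.table(cs)
  if (nrow(d) == 0L || length(targets) == 0L) {
    return(reclass_consensus(d[0L], cs))
  }
  q <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, width = 1L))
  hit <- IRanges::overlapsAny(q, targets)
  reclass_consensus(d[hit], cs)
}

#' Site-level variant table of a callset
#'
#' @param cs A `consensus_callset` or observation table.
#' @return Deduplicated `gvariants` table.
#' @export
consensus_variants <- function(cs) {
  d <- as.data.table(cs)
  if (nrow(d) == 0L) {
    return(gvariants(character(0), integer(0), character(0), character(0)))
  }
  u <- unique(d[, .(chrom, pos, ref, alt,
                    id = if ("id" %in% names(d)) id else NA_character_,
                    hgvs = NA_character_)],
              by = c("chrom", "pos", "ref", "alt"))
  setattr(u, "class", c("gvariants", "data.table", "data.frame"))
  u[]
}

#' Benchmark a callset against a truth set
#'
#' Allele-level confusion counts: TP are called variants present in the
#' truth set, FP are called variants absent from it, FN are truth variants
#' not called. Sensitivity = TP/(TP+FN); precision = TP/(TP+FP), reported as
#' `NA` (undefined, not zero) for an empty callset.
#'
#' @param cs Callset: a `consensus_callset`, observation table, or variant
#'   table. Reduced to unique `(chrom, pos, ref, alt)` tuples.
#' @param truth Truth-set variant table (normalized).
#' @return List of class `benchmark_result`: `TP`, `FP`, `FN`,
#'   `sensitivity`, `precision`.
#' @export
benchmark_callset <- function(cs, truth) {
  called <- unique(variant_key(consensus_variants(cs)))
  truth_keys <- unique(variant_key(as.data.table(truth)))
  tp <- sum(called %in% truth_keys)
  fp <- length(called) - tp
  fn <- length(truth_keys) - tp
  structure(list(
    TP = tp, FP = fp, FN = fn,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  sensitivity=%s precision=%s\n",
              x$TP, x$FP, x$FN,
              format(x$sensitivity, digits = 4),
              format(x$precision, digits = 4)))
  invisible(x)
}

#' Per-caller and consensus benchmark report
#'
#' @param callsets List of caller observation tables.
#' @param truth Truth-set variant table.
#' @param k Consensus threshold.
#' @return `data.table` with one row per caller plus a `consensus` row:
#'   columns `callset`, `TP`, `FP`, `FN`, `sensitivity`, `precision`.
#' @export
benchmark_report <- function(callsets, truth, k = 2L) {
  labels <- names(callsets)
  if (is.null(labels)) {
    labels <- vapply(callsets, function(cs) cs$caller[1], "")
  }
  rows <- lapply(seq_along(callsets), function(i) {
    b <- benchmark_callset(
      as.data.table(callsets[[i]])[genotype %in% .NONREF_GENOTYPES], truth)
    data.table(callset = labels[i], TP = b$TP, FP = b$FP, FN = b$FN,
               sensitivity = b$sensitivity, precision = b$precision)
  })
  bc <- benchmark_callset(merge_callsets(callsets, k = k), truth)
  rbindlist(c(rows, list(data.table(
    callset = sprintf("consensus_k%d", k), TP = bc$TP, FP = bc$FP,
    FN = bc$FN, sensitivity = bc$sensitivity, precision = bc$precision))))
}

#' Write a consensus callset as a VCF with supporter annotations
#'
#' INFO carries `SUP` (supporter count, maximum over samples) and `CALLERS`;
#' per-sample fields are GT:DP (DP = minimum supporting depth).
#'
#' @param cs A `consensus_callset`.
#' @param path Output file.
#' @param samples Sample column order.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(cs, path, samples = NULL) {
  d <- copy(as.data.table(cs))
  if (is.null(samples)) samples <- sort(unique(d$sample))
  info_lines <- c(
    '##INFO=<ID=SUP,Number=1,Type=Integer,Description="Supporting callers (max over samples)">',
    '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Supporting caller labels">')
  if (nrow(d) == 0L) {
    writeLines(vcf_header(samples, info_lines), path)
    return(invisible(path))
  }
  sites <- d[, .(sup = max(n_supporting),
                 callers = paste(sort(unique(unlist(strsplit(callers, ",")))),
                                 collapse = ","),
                 id = if (all(is.na(id))) "." else stats::na.omit(id)[1]),
             by = .(chrom, pos, ref, alt)]
  d[, cell := paste0(gt_string(genotype), ":", min_depth)]
  wide <- dcast(d, chrom + pos + ref + alt ~ sample, value.var = "cell",
                fill = "0/0:0", fun.aggregate = function(x) x[1])
  for (sm in setdiff(samples, names(wide))) {
    set(wide, j = sm, value = "0/0:0")
  }
  wide <- merge(wide, sites, by = c("chrom", "pos", "ref", "alt"))
  setorder(wide, chrom, pos, ref, alt)
  cells <- do.call(paste, c(wide[, samples, with = FALSE], sep = "\t"))
  recs <- paste(wide$chrom, wide$pos, wide$id, wide$ref, wide$alt, ".",
                "PASS", sprintf("SUP=%d;CALLERS=%s", wide$sup, wide$callers),
                "GT:DP", cells, sep = "\t")
  writeLines(c(vcf_header(samples, info_lines), recs), path)
  invisible(path)
}
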