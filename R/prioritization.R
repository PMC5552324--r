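# Four-tool threshold intersection: tool-set labels and candidate tiers.

.TOOL_ORDER <- c("CADD", "GWAVA", "GENOMISER", "SPIDEX")

#' Threshold configuration for noncoding-variant prioritization
#'
#' Comparison directions are tool-specific and deliberate:
#' * CADD PHRED: pass if strictly greater than `cadd_min` (default 15);
#' * GWAVA region score: pass if greater *or equal* to `gwava_min`
#'   (default 0.5) — scores of exactly 0.5 count as functional;
#' * Genomiser variant score: pass if strictly greater than `genomiser_min`
#'   (default 0.6, the low end of the tool's published 0.6-0.9 range);
#' * SPIDEX: pass if `|dPSI|` strictly greater than `spidex_abs_min`
#'   (default 5) — splicing disruption is directionless.
#'
#' A missing (NA) score never passes.
#'
#' @param cadd_min,gwava_min,genomiser_min,spidex_abs_min Numeric cutoffs.
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(cadd_min = 15, gwava_min = 0.5,
                             genomiser_min = 0.6, spidex_abs_min = 5) {
  cfg <- list(cadd_min = cadd_min, gwava_min = gwava_min,
              genomiser_min = genomiser_min, spidex_abs_min = spidex_abs_min)
  if (!all(vapply(cfg, function(x) is.numeric(x) && is.finite(x), TRUE))) {
    stop("all thresholds must be finite numbers", call. = FALSE)
  }
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(
    "Thresholds: CADD > %s | GWAVA >= %s | Genomiser > %s | |dPSI| > %s\n",
    x$cadd_min, x$gwava_min, x$genomiser_min, x$spidex_abs_min))
  invisible(x)
}

#' Compute tool-set labels and candidate tiers
#'
#' A tool enters a variant's tool set iff its score is present and passes
#' its configured comparison. Tiers: 1 when CADD, GWAVA and Genomiser all
#' pass (the triple-intersection candidates), 2 for any other two-or-more
#' tool set, 3 for a single tool, 0 for none.
#'
#' @param annotated Variant table with score columns (see
#'   [annotate_scores()]).
#' @param cfg A [threshold_config()].
#' @return `data.table` with `pass_cadd`, `pass_gwava`, `pass_genomiser`,
#'   `pass_spidex`, `toolset` (comma-joined in CADD, GWAVA, GENOMISER,
#'   SPIDEX order; `""` for none) and `tier` columns appended.
#' @export
partition_by_tools <- function(annotated, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  v <- copy(as.data.table(annotated))
  pass <- function(x, f) !is.na(x) & f(x)
  v[, pass_cadd := pass(cadd_phred, function(x) x > cfg$cadd_min)]
  v[, pass_gwava := pass(gwava_region, function(x) x >= cfg$gwava_min)]
  v[, pass_genomiser := pass(genomiser, function(x) x > cfg$genomiser_min)]
  v[, pass_spidex := pass(spidex_dpsi,
                          function(x) abs(x) > cfg$spidex_abs_min)]
  pm <- as.matrix(v[, .(CADD = pass_cadd, GWAVA = pass_gwava,
                        GENOMISER = pass_genomiser, SPIDEX = pass_spidex)])
  v[, toolset := apply(pm, 1L, function(r) {
    paste(.TOOL_ORDER[r], collapse = ",")
  })]
  v[, tier := fifelse(pass_cadd & pass_gwava & pass_genomiser, 1L,
                      fifelse(rowSums(pm) >= 2L, 2L,
                              fifelse(rowSums(pm) == 1L, 3L, 0L)))]
  v[]
}

#' Group prioritized variants by exact tool set
#'
#' The Venn-diagram partition: variants grouped by their exact tool-set
#' label; variants passing no tool are left out, so group sizes sum to the
#' number of variants with a non-empty tool set.
#'
#' @param prioritized Output of [partition_by_tools()].
#' @return List with `groups` (named list of `data.table`s) and `counts`
#'   (named integer vector, sorted by decreasing set size then tool order).
#' @export
venn_partition <- function(prioritized) {
  p <- as.data.table(prioritized)
  p <- p[toolset != ""]
  if (nrow(p) == 0L) {
    return(list(groups = setNames(list(), character(0)),
                counts = setNames(integer(0), character(0))))
  }
  groups <- split(p, by = "toolset")
  ntools <- vapply(strsplit(names(groups), ","), length, 1L)
  first_tool <- match(vapply(strsplit(names(groups), ","), `[[`, "", 1L),
                      .TOOL_ORDER)
  ord <- order(-ntools, first_tool)
  groups <- groups[ord]
  counts <- vapply(groups, nrow, 1L)
  list(groups = groups, counts = counts)
}
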