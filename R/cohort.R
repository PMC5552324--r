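# Cohort allele frequencies, fold enrichment against reference populations,
# compound-heterozygote detection, and pedigree segregation summaries.

.CARRIER_STATES <- c("carrier_het", "carrier_hom", "noncarrier", "untyped")

alt_allele_count <- function(genotype) {
  c(hom_ref = 0L, het = 1L, hom_alt = 2L, hemi = 1L, missing = NA_integer_)[
    genotype]
}

ploidy_of <- function(sex, chrom) {
  ifelse(is_x_chrom(chrom) & sex == "male", 1L, 2L)
}

#' Cohort allele frequency of a variant
#'
#' AF = alt allele count / total called alleles, with het = 1, hom_alt = 2
#' and hemi = 1 alt allele; diploid samples contribute 2 alleles, hemizygous
#' males 1 for X-linked variants; `missing` genotypes drop out of both
#' numerator and denominator.
#'
#' @param g A `cohort_genotypes` object.
#' @param key Variant key(s) `chrom:pos:ref:alt`; default all variants.
#' @return `data.table` with `key`, `alt_alleles`, `called_alleles`,
#'   `carriers` (samples with >= 1 alt allele) and `af`.
#' @export
cohort_allele_frequency <- function(g, key = NULL) {
  stopifnot(inherits(g, "cohort_genotypes"))
  if (is.null(key)) key <- g$variants$key
  missing_keys <- setdiff(key, colnames(g$geno))
  if (length(missing_keys)) {
    stop("no genotypes for variant(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  chrom <- g$variants$chrom[match(key, g$variants$key)]
  rows <- lapply(seq_along(key), function(i) {
    gt <- g$geno[, key[i]]
    cnt <- alt_allele_count(gt)
    pl <- ploidy_of(g$samples$sex, chrom[i])
    called <- sum(pl[gt != "missing"])
    if (called == 0L) {
      stop("allele frequency undefined for ", key[i],
           " (zero called alleles)", call. = FALSE)
    }
    r <- data.table(alt_alleles = sum(cnt, na.rm = TRUE),
                    called_alleles = called,
                    carriers = sum(cnt > 0L, na.rm = TRUE),
                    af = sum(cnt, na.rm = TRUE) / called)
    r[, key := key[i]]
    setcolorder(r, "key")
    r
  })
  rbindlist(rows)
}

#' Fold enrichment of a cohort allele frequency over a reference MAF
#'
#' @param proband_af Cohort allele frequency in `[0, 1]`.
#' @param reference_maf Reference-population MAF in `[0, 1]`.
#' @return List: `fold` (`Inf` flagged when the reference MAF is 0 but the
#'   cohort carries the allele; 1 with `degenerate = TRUE` when both are 0)
#'   plus `infinite` and `degenerate` flags.
#' @export
fold_enrichment <- function(proband_af, reference_maf) {
  if (is.na(proband_af) || is.na(reference_maf)) {
    return(list(fold = NA_real_, infinite = FALSE, degenerate = FALSE))
  }
  if (proband_af < 0 || reference_maf < 0) {
    stop("allele frequencies must be non-negative", call. = FALSE)
  }
  if (reference_maf == 0 && proband_af > 0) {
    list(fold = Inf, infinite = TRUE, degenerate = FALSE)
  } else if (reference_maf == 0 && proband_af == 0) {
    list(fold = 1, infinite = FALSE, degenerate = TRUE)
  } else {
    list(fold = proband_af / reference_maf, infinite = FALSE,
         degenerate = FALSE)
  }
}

#' Per-variant enrichment report for a cohort
#'
#' Computes cohort allele frequencies, fold enrichment against the 1000
#' Genomes EUR and gnomAD MAFs, and an `enriched` flag: fold >= `fold_min`
#' (default 3) relative to the configured reference population (infinite
#' folds count as enriched; an NA reference MAF gives an NA flag).
#'
#' @param g A `cohort_genotypes` object.
#' @param scores Score table carrying `maf_1000g` / `maf_gnomad` for the
#'   cohort variants (matched by key, with dbSNP-id fallback).
#' @param fold_min Enrichment threshold (default 3).
#' @param reference `"maf_1000g"` (default) or `"maf_gnomad"`.
#' @return `data.table`: key, af, both MAFs, both folds, `enriched`.
#' @export
enrichment_table <- function(g, scores, fold_min = 3,
                             reference = c("maf_1000g", "maf_gnomad")) {
  reference <- match.arg(reference)
  af <- cohort_allele_frequency(g)
  ann <- annotate_scores(g$variants, scores)
  ann[, key := variant_key(ann)]
  out <- merge(af, ann[, .(key, maf_1000g, maf_gnomad)], by = "key",
               sort = FALSE)
  fold1 <- mapply(function(a, m) fold_enrichment(a, m)$fold,
                  out$af, out$maf_1000g)
  fold2 <- mapply(function(a, m) fold_enrichment(a, m)$fold,
                  out$af, out$maf_gnomad)
  out[, `:=`(fold_1000g = as.numeric(fold1), fold_gnomad = as.numeric(fold2))]
  ref_fold <- if (reference == "maf_1000g") out$fold_1000g else
    out$fold_gnomad
  out[, enriched := ref_fold >= fold_min]
  out[]
}

#' Detect compound-heterozygous candidate pairs per sample
#'
#' For each cohort sample, reports every unordered pair of distinct carried
#' variants in which one side is a pathogenic / likely-pathogenic variant
#' from the exonic / splice-site screen (selected by clinical class, so
#' near-splice intronic mutations such as c.1227-13G>A qualify) and the
#' other a tier-1 intronic candidate. "Carried" means a het, hom_alt or
#' hemi genotype.
#'
#' @param g A `cohort_genotypes` object.
#' @param candidates `data.table` with columns `key`, `gene`, `region`
#'   (reporting only), `clinical_class`, `tier`.
#' @return `data.table` with `sample`, `exonic_key`, `exonic_gene`,
#'   `intronic_key`, `intronic_gene`.
#' @export
find_compound_het <- function(g, candidates) {
  stopifnot(inherits(g, "cohort_genotypes"))
  cand <- as.data.table(candidates)
  cand <- cand[key %in% colnames(g$geno)]
  exonic <- cand[clinical_class %in% c("pathogenic", "likely_pathogenic")]
  intronic <- cand[!is.na(tier) & tier == 1L]
  empty <- data.table(sample = character(0), exonic_key = character(0),
                      exonic_gene = character(0),
                      intronic_key = character(0),
                      intronic_gene = character(0))
  if (nrow(exonic) == 0L || nrow(intronic) == 0L) return(empty)
  carried <- g$geno %in% .NONREF_GENOTYPES
  dim(carried) <- dim(g$geno); dimnames(carried) <- dimnames(g$geno)
  rows <- lapply(rownames(carried), function(sm) {
    ex <- exonic[carried[sm, exonic$key]]
    intr <- intronic[carried[sm, intronic$key]]
    if (nrow(ex) == 0L || nrow(intr) == 0L) return(NULL)
    pairs <- CJ(e = seq_len(nrow(ex)), i = seq_len(nrow(intr)))
    data.table(sample = sm,
               exonic_key = ex$key[pairs$e], exonic_gene = ex$gene[pairs$e],
               intronic_key = intr$key[pairs$i],
               intronic_gene = intr$gene[pairs$i])[exonic_key != intronic_key]
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) empty else out[]
}

#' Carrier-class versus phenotype segregation summary for one family
#'
#' With two tracked variants, members are binned into carrier classes
#' `both` / `first_only` / `second_only` / `neither`; with one variant,
#' `carrier` / `noncarrier`. Members untyped for any tracked variant are
#' excluded from counts and reported. Model-consistency flags (computed on
#' members with known phenotype only):
#' * `monogenic_consistent`: every carrier of the first tracked variant is
#'   affected and every non-carrier of it is unaffected;
#' * `digenic_consistent` (two variants): every dual carrier is affected
#'   and every single carrier or non-carrier is unaffected.
#'
#' Flags are `NA` (indeterminate) when no informative member has a known
#' phenotype, and `digenic_consistent` is `NA` with a single variant.
#'
#' @param ped A `pedigree` from [read_pedigree()].
#' @param variants Character vector of 1 or 2 tracked-variant column names
#'   (default: all tracked columns of the pedigree).
#' @return List of class `segregation_summary`: `counts` (data.table of
#'   carrier_class x phenotype), `monogenic_consistent`,
#'   `digenic_consistent`, `untyped` (excluded member ids).
#' @export
segregation_summary <- function(ped, variants = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ped$carriers)) {
    stop("pedigree has no tracked-variant carrier columns", call. = FALSE)
  }
  if (is.null(variants)) variants <- colnames(ped$carriers)
  if (!length(variants) %in% 1:2) {
    stop("segregation_summary() tracks 1 or 2 variants", call. = FALSE)
  }
  missing_v <- setdiff(variants, colnames(ped$carriers))
  if (length(missing_v)) {
    stop("variant(s) not tracked in pedigree: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  st <- ped$carriers[, variants, drop = FALSE]
  untyped <- rownames(st)[apply(st == "untyped", 1L, any)]
  keep <- setdiff(rownames(st), untyped)
  carrier <- st[keep, , drop = FALSE] %in% c("carrier_het", "carrier_hom")
  dim(carrier) <- c(length(keep), length(variants))
  rownames(carrier) <- keep
  if (length(variants) == 2L) {
    cls <- fifelse(carrier[, 1L] & carrier[, 2L], "both",
                   fifelse(carrier[, 1L], "first_only",
                           fifelse(carrier[, 2L], "second_only", "neither")))
    class_levels <- c("both", "first_only", "second_only", "neither")
  } else {
    cls <- fifelse(carrier[, 1L], "carrier", "noncarrier")
    class_levels <- c("carrier", "noncarrier")
  }
  ph <- ped$members$phenotype[match(keep, ped$members$individual)]
  counts <- CJ(carrier_class = class_levels,
               phenotype = c("affected", "unaffected", "unknown"))
  tab <- data.table(carrier_class = cls, phenotype = ph)[
    , .(n = .N), by = .(carrier_class, phenotype)]
  counts <- merge(counts, tab, by = c("carrier_class", "phenotype"),
                  all.x = TRUE)
  counts[is.na(n), n := 0L]
  counts[, carrier_class := factor(carrier_class, levels = class_levels)]
  setorder(counts, carrier_class, phenotype)
  known <- ph != "unknown"
  flag <- function(pred_affected) {
    # consistent iff predicted-affected members are affected and
    # predicted-unaffected members are unaffected, among known phenotypes
    if (!any(known)) return(NA)
    all((ph[known] == "affected") == pred_affected[known])
  }
  mono <- flag(carrier[, 1L])
  dig <- if (length(variants) == 2L) {
    flag(carrier[, 1L] & carrier[, 2L])
  } else NA
  structure(list(family = ped$family, variants = variants, counts = counts,
                 monogenic_consistent = mono, digenic_consistent = dig,
                 untyped = untyped),
            class = "segregation_summary")
}

#' @export
print.segregation_summary <- function(x, ...) {
  cat("Segregation summary, family", x$family, "\n")
  cat("  tracked:", paste(x$variants, collapse = " + "), "\n")
  wide <- dcast(x$counts, carrier_class ~ phenotype, value.var = "n")
  print(as.data.frame(wide), row.names = FALSE)
  cat("  monogenic-consistent:", x$monogenic_consistent,
      "| digenic-consistent:", x$digenic_consistent, "\n")
  if (length(x$untyped)) {
    cat("  excluded (untyped):", paste(x$untyped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a segregation summary as a TSV report
#'
#' @param seg A `segregation_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segregation_tsv <- function(seg, path) {
  wide <- dcast(seg$counts, carrier_class ~ phenotype, value.var = "n")
  wide[, `:=`(family = seg$family,
              tracked = paste(seg$variants, collapse = "+"),
              monogenic_consistent = seg$monogenic_consistent,
              digenic_consistent = seg$digenic_consistent)]
  fwrite(wide, path, sep = "\t")
  invisible(path)
}
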