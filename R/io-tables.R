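# Readers/writers for BED targets & TF peaks, BED12/GFF3 gene models,
# annotation score TSVs, PED-style pedigrees and cohort genotype matrices.
# Coordinate conventions: BED/gene models 0-based half-open, VCF 1-based.

#' Read target regions from BED
#'
#' Intervals are sorted and overlaps merged, so containment queries see a
#' disjoint set.
#'
#' @param path BED file (columns chrom, start, end; extra columns ignored).
#' @param chrom_style Passed to [normalize_chrom()].
#' @return A reduced [GenomicRanges::GRanges] (0-based half-open input,
#'   stored 1-based closed as GRanges convention).
#' @export
read_targets <- function(path, chrom_style = "as-is") {
  sz <- file.size(path)
  if (is.na(sz)) stop("missing BED file: ", path, call. = FALSE)
  if (sz == 0) return(GenomicRanges::GRanges())
  d <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(d) == 0L) return(GenomicRanges::GRanges())
  if (ncol(d) < 3L) stop("BED file needs >= 3 columns: ", path, call. = FALSE)
  setnames(d, 1:3, c("chrom", "start", "end"))
  if (any(d$start >= d$end)) {
    stop("BED interval with start >= end in ", path, call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    normalize_chrom(d$chrom, chrom_style),
    IRanges::IRanges(start = d$start + 1L, end = d$end))
  GenomicRanges::reduce(sort(gr))
}

#' Read transcription-factor ChIP-seq peaks from BED
#'
#' @param path BED file whose 4th column names the factor.
#' @inheritParams read_targets
#' @return A `GRanges` with metadata column `tf`.
#' @export
read_tf_peaks <- function(path, chrom_style = "as-is") {
  d <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(d) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$tf <- character(0)
    return(gr)
  }
  if (ncol(d) < 4L) {
    stop("TF peak BED needs a 4th (name) column: ", path, call. = FALSE)
  }
  setnames(d, 1:4, c("chrom", "start", "end", "tf"))
  gr <- GenomicRanges::GRanges(
    normalize_chrom(d$chrom, chrom_style),
    IRanges::IRanges(start = d$start + 1L, end = d$end))
  S4Vectors::mcols(gr)$tf <- as.character(d$tf)
  sort(gr)
}

#' Gene models as an exon table
#'
#' @param gene,chrom,strand Per-exon gene symbol, chromosome and strand.
#' @param start,end 0-based half-open exon coordinates.
#' @return `data.table` of class `gene_models` with one row per exon,
#'   sorted, with per-gene exons validated non-overlapping.
#' @export
gene_models <- function(gene, chrom, strand, start, end) {
  m <- data.table(gene = as.character(gene), chrom = as.character(chrom),
                  strand = as.character(strand),
                  start = as.integer(start), end = as.integer(end))
  validate_gene_models(m)
  setattr(m, "class", c("gene_models", class(m)))
  m[]
}

validate_gene_models <- function(m) {
  if (nrow(m) == 0L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(m$start >= m$end)) {
    stop("exon with start >= end", call. = FALSE)
  }
  if (!all(m$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  setorder(m, gene, start)
  overlaps <- m[, if (.N > 1L) any(start[-1L] < end[-.N]) else FALSE,
                by = gene]$V1
  if (any(overlaps)) stop("overlapping exons within a gene", call. = FALSE)
  invisible(m)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12: one line per gene; exons reconstructed from blockStarts/blockSizes.
#' GFF3: `exon` features grouped by the `gene=` (or `Parent=`) attribute.
#'
#' @param path Input file.
#' @param format `"bed12"` or `"gff3"` (guessed from the extension by
#'   default).
#' @inheritParams read_targets
#' @return A `gene_models` exon table (0-based half-open coordinates).
#' @export
read_gene_models <- function(path, format = NULL, chrom_style = "as-is") {
  if (is.null(format)) {
    format <- if (grepl("gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
    else "bed12"
  }
  format <- match.arg(format, c("bed12", "gff3"))
  if (format == "bed12") {
    d <- fread(path, header = FALSE, sep = "\t")
    if (ncol(d) < 12L) stop("not BED12: ", path, call. = FALSE)
    m <- rbindlist(lapply(seq_len(nrow(d)), function(i) {
      sizes <- as.integer(strsplit(sub(",$", "", d[[11]][i]), ",")[[1]])
      offs <- as.integer(strsplit(sub(",$", "", d[[12]][i]), ",")[[1]])
      if (length(sizes) != d[[10]][i] || length(offs) != d[[10]][i]) {
        stop("BED12 block count mismatch at line ", i, " of ", path,
             call. = FALSE)
      }
      data.table(gene = d[[4]][i], chrom = d[[1]][i], strand = d[[6]][i],
                 start = d[[2]][i] + offs, end = d[[2]][i] + offs + sizes)
    }))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    d <- fread(text = lines, header = FALSE, sep = "\t",
               col.names = c("chrom", "source", "type", "start", "end",
                             "score", "strand", "phase", "attr"))
    d <- d[type == "exon"]
    if (nrow(d) == 0L) stop("no exon features in ", path, call. = FALSE)
    gene <- sub(".*(?:^|;)gene=([^;]+).*", "\\1", d$attr)
    no_gene <- !grepl("(^|;)gene=", d$attr)
    gene[no_gene] <- sub(".*(?:^|;)Parent=([^;]+).*", "\\1", d$attr[no_gene])
    # GFF3 is 1-based closed; convert to 0-based half-open
    m <- data.table(gene = gene, chrom = d$chrom, strand = d$strand,
                    start = d$start - 1L, end = d$end)
  }
  m[, chrom := normalize_chrom(chrom, chrom_style)]
  validate_gene_models(m)
  setattr(m, "class", c("gene_models", "data.table", "data.frame"))
  m[]
}

#' Write gene models as BED12
#'
#' @param models A `gene_models` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  g <- as.data.table(models)[, {
    s <- min(start); e <- max(end)
    list(chrom = chrom[1], start = s, end = e, strand = strand[1],
         n = .N, sizes = paste(end - start, collapse = ","),
         offs = paste(start - s, collapse = ","))
  }, by = gene]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   g$chrom, g$start, g$end, g$gene, g$strand,
                   g$start, g$end, g$n, g$sizes, g$offs)
  writeLines(lines, path)
  invisible(path)
}

.CLINICAL_CLASSES <- c("pathogenic", "likely_pathogenic", "VUS",
                       "likely_benign", "benign", "conflicting",
                       "unclassified")

.SCORE_NUM_COLS <- c("cadd_phred", "gwava_region", "genomiser", "spidex_dpsi",
                     "maf_1000g", "maf_gnomad")

#' Read a precomputed annotation score table
#'
#' TSV with header; recognised columns: `chrom`, `pos`, `ref`, `alt`, `id`,
#' `hgvs`, `gene`, `cadd_phred`, `gwava_region`, `genomiser`, `spidex_dpsi`,
#' `maf_1000g`, `maf_gnomad`, `clinical_class` (missing columns are added as
#' all-NA). `"."` and `"NA"` entries load as NA — explicitly distinct from a
#' printed `0`, which loads as numeric zero.
#'
#' @param path TSV file(s); several tables (e.g. an intronic score table
#'   plus a clinically classified exonic table) are stacked with missing
#'   columns filled as NA.
#' @inheritParams read_targets
#' @return `data.table` with typed score columns.
#' @export
read_score_table <- function(path, chrom_style = "as-is") {
  if (length(path) > 1L) {
    return(rbindlist(lapply(path, read_score_table,
                            chrom_style = chrom_style), fill = TRUE))
  }
  d <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
             na.strings = c(".", "NA", ""))
  for (col in .SCORE_NUM_COLS) {
    if (col %in% names(d)) {
      bad <- !is.na(d[[col]]) &
        is.na(suppressWarnings(as.numeric(d[[col]])))
      if (any(bad)) {
        stop("non-numeric value in column '", col, "' of ", path,
             call. = FALSE)
      }
      set(d, j = col, value = as.numeric(d[[col]]))
    } else set(d, j = col, value = NA_real_)
  }
  rng_chk <- function(col, lo, hi) {
    x <- d[[col]]
    if (any(!is.na(x) & (x < lo | x > hi))) {
      stop("column '", col, "' out of [", lo, ",", hi, "] in ", path,
           call. = FALSE)
    }
  }
  rng_chk("gwava_region", 0, 1); rng_chk("genomiser", 0, 1)
  rng_chk("maf_1000g", 0, 1); rng_chk("maf_gnomad", 0, 1)
  if ("pos" %in% names(d)) set(d, j = "pos", value = as.integer(d$pos))
  else set(d, j = "pos", value = NA_integer_)
  for (col in c("chrom", "ref", "alt", "id", "hgvs", "gene")) {
    if (!col %in% names(d)) set(d, j = col, value = NA_character_)
  }
  if (!"clinical_class" %in% names(d)) {
    set(d, j = "clinical_class", value = "unclassified")
  }
  d[is.na(clinical_class), clinical_class := "unclassified"]
  bad_cls <- setdiff(unique(d$clinical_class), .CLINICAL_CLASSES)
  if (length(bad_cls)) {
    stop("unknown clinical_class value(s): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  d[, chrom := normalize_chrom(chrom, chrom_style)]
  d[]
}

#' Read a PED-style pedigree with per-variant carrier status
#'
#' TSV with header `family`, `individual`, `father`, `mother`, `sex`,
#' `phenotype`, then one column per tracked variant holding
#' `carrier_het` / `carrier_hom` / `noncarrier` / `untyped`. `0` or empty
#' parent fields mean "founder".
#'
#' @param path TSV file.
#' @return Object of class `pedigree`: list with `family`, `members`
#'   (data.table) and `carriers` (member x variant character matrix).
#' @export
read_pedigree <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz == 0) {
    stop("empty or missing pedigree file: ", path, call. = FALSE)
  }
  d <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  req <- c("family", "individual", "father", "mother", "sex", "phenotype")
  if (!all(req %in% names(d)) || nrow(d) == 0L) {
    stop("pedigree file must have columns ", paste(req, collapse = ", "),
         " and at least one member: ", path, call. = FALSE)
  }
  if (length(unique(d$family)) != 1L) {
    stop("pedigree file must describe a single family: ", path, call. = FALSE)
  }
  d[father %in% c("0", ""), father := NA_character_]
  d[mother %in% c("0", ""), mother := NA_character_]
  bad_ph <- setdiff(unique(d$phenotype),
                    c("affected", "unaffected", "unknown"))
  if (length(bad_ph)) {
    stop("phenotype must be affected/unaffected/unknown; found: ",
         paste(bad_ph, collapse = ", "), call. = FALSE)
  }
  dangling <- setdiff(stats::na.omit(c(d$father, d$mother)), d$individual)
  if (length(dangling)) {
    stop("parent id(s) not in family: ", paste(dangling, collapse = ", "),
         call. = FALSE)
  }
  var_cols <- setdiff(names(d), req)
  carriers <- NULL
  if (length(var_cols)) {
    carriers <- as.matrix(d[, var_cols, with = FALSE])
    rownames(carriers) <- d$individual
    bad <- setdiff(unique(as.vector(carriers)),
                   c("carrier_het", "carrier_hom", "noncarrier", "untyped"))
    if (length(bad)) {
      stop("carrier status must be carrier_het/carrier_hom/noncarrier/",
           "untyped; found: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(family = d$family[1],
                 members = d[, req, with = FALSE],
                 carriers = carriers),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  aff <- sum(x$members$phenotype == "affected")
  cat("Pedigree: family", x$family, "-", nrow(x$members), "members,",
      aff, "affected,", if (is.null(x$carriers)) 0 else ncol(x$carriers),
      "tracked variant(s)\n")
  invisible(x)
}

#' Read cohort genotypes from a sample x variant TSV
#'
#' First two columns `sample` and `sex` (`male`/`female`); every further
#' column is one variant keyed `chrom:pos:ref:alt`, holding genotype classes
#' `hom_ref`/`het`/`hom_alt`/`hemi`/`missing`. X-linked variants follow the
#' hemizygous-male ploidy rule; `hemi` on an autosome or in a female is
#' rejected.
#'
#' @param path TSV file.
#' @return Object of class `cohort_genotypes`: list with `samples`
#'   (data.table: sample, sex), `geno` (character matrix sample x variant)
#'   and `variants` (data.table keyed by `key`).
#' @export
read_cohort_genotypes <- function(path) {
  d <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("sample", "sex") %in% names(d))) {
    stop("cohort TSV needs 'sample' and 'sex' columns: ", path, call. = FALSE)
  }
  keys <- setdiff(names(d), c("sample", "sex"))
  geno <- as.matrix(d[, keys, with = FALSE])
  rownames(geno) <- d$sample
  parts <- tstrsplit(keys, ":", fixed = TRUE)
  if (length(parts) != 4L) {
    stop("variant columns must be keyed chrom:pos:ref:alt", call. = FALSE)
  }
  variants <- data.table(chrom = parts[[1]], pos = as.integer(parts[[2]]),
                         ref = parts[[3]], alt = parts[[4]])
  variants[, key := keys]
  setcolorder(variants, "key")
  cohort_genotypes(d[, .(sample, sex)], geno, variants)
}

#' Assemble a cohort-genotype object
#'
#' @param samples data.table/data.frame with `sample` and `sex`.
#' @param geno Character matrix (sample x variant key).
#' @param variants data.table with `key`, `chrom`, `pos`, `ref`, `alt`.
#' @return Object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(samples, geno, variants) {
  samples <- as.data.table(samples)
  if (!all(samples$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  bad_g <- setdiff(unique(as.vector(geno)), .GENOTYPES)
  if (length(bad_g)) {
    stop("unknown genotype class(es): ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(geno)) stop("genotype matrix must be complete", call. = FALSE)
  variants <- as.data.table(variants)
  hemi_ok <- outer(samples$sex == "male", is_x_chrom(variants$chrom), `&`)
  if (any(geno == "hemi" & !hemi_ok)) {
    stop("hemizygous genotype outside male X", call. = FALSE)
  }
  if (any(geno == "hom_alt" & hemi_ok) || any(geno == "het" & hemi_ok)) {
    stop("diploid genotype for male X variant; use 'hemi'/'hom_ref'",
         call. = FALSE)
  }
  structure(list(samples = samples, geno = geno, variants = variants),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("Cohort genotypes:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Write cohort genotypes back to TSV
#'
#' @param g A `cohort_genotypes` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_genotypes <- function(g, path) {
  d <- data.table(sample = g$samples$sample, sex = g$samples$sex)
  d <- cbind(d, as.data.table(g$geno))
  fwrite(d, path, sep = "\t")
  invisible(path)
}
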