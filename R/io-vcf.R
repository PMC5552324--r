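# VCF 4.2 reading/writing for the fixed dialect the pipeline exchanges:
# per-sample GT (+ optional DP), multiallelic records split on load.
# Kept deliberately lean: each consensus-simulation replicate parses five
# small files, where heavyweight general-purpose readers dominate runtime.

parse_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) {
    stop("not a VCF file (missing #CHROM header line): ", path, call. = FALSE)
  }
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  samples <- if (length(header) > 9L) header[10:length(header)] else character(0)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  body_idx <- body_idx[body_idx > hdr_idx]
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- 8L + if (length(samples)) 1L + length(samples) else 0L
  bad <- which(nf < want)
  if (length(bad)) {
    stop("malformed VCF record at line ", body_idx[bad[1]], " of ", path,
         " (expected >= ", want, " fields, found ", nf[bad[1]], ")",
         call. = FALSE)
  }
  pos_chr <- vapply(fields, `[[`, "", 2L)
  if (length(pos_chr) && any(grepl("[^0-9]", pos_chr))) {
    bad <- which(grepl("[^0-9]", pos_chr))[1]
    stop("malformed VCF record at line ", body_idx[bad], " of ", path,
         " (non-numeric POS)", call. = FALSE)
  }
  list(samples = samples, fields = fields, line_no = body_idx)
}

gt_to_class <- function(gt, allele_idx) {
  # gt like "0/1", "1|1", "1", "./.", "."; allele_idx is the 1-based ALT index
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (all(a == ".")) return("missing")
    if (any(a == ".")) a <- a[a != "."]
    hits <- sum(a == as.character(allele_idx[i]))
    if (length(a) == 1L) {
      if (hits == 1L) "hemi" else "hom_ref"
    } else if (hits == 0L) "hom_ref"
    else if (hits == length(a)) "hom_alt"
    else "het"
  }, "")
}

#' Read one caller's VCF into caller observations
#'
#' Produces one observation per alt allele per sample: multiallelic records
#' are split, genotype class and read depth (FORMAT/DP) are extracted, and
#' all variants are normalized on load (left-aligned when a `reference` is
#' supplied, trimmed otherwise). A missing DP field is treated as depth 0,
#' so such calls can never pass the depth filter.
#'
#' @param path VCF 4.x file.
#' @param caller Caller label recorded on every observation.
#' @param reference Optional named vector of chromosome sequences used to
#'   left-align indels.
#' @param chrom_style Passed to [normalize_chrom()].
#' @return `data.table` with columns `caller`, `sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `id`, `genotype`, `depth`.
#' @export
read_caller_vcf <- function(path, caller, reference = NULL,
                            chrom_style = "as-is") {
  p <- parse_vcf(path)
  if (length(p$samples) == 0L) {
    stop("caller VCF has no sample columns: ", path, call. = FALSE)
  }
  if (length(p$fields) == 0L) {
    return(data.table(caller = character(0), sample = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      id = character(0), genotype = character(0),
                      depth = integer(0)))
  }
  recs <- rbindlist(lapply(seq_along(p$fields), function(i) {
    f <- p$fields[[i]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    dp_i <- match("DP", fmt)
    if (is.na(gt_i)) {
      stop("malformed VCF record at line ", p$line_no[i], " of ", path,
           " (no GT in FORMAT)", call. = FALSE)
    }
    sm <- strsplit(f[10:(9L + length(p$samples))], ":", fixed = TRUE)
    gts <- vapply(sm, function(x) if (length(x) >= gt_i) x[gt_i] else ".", "")
    dps <- if (is.na(dp_i)) rep(NA_character_, length(sm)) else
      vapply(sm, function(x) if (length(x) >= dp_i) x[dp_i] else ".", "")
    dps <- suppressWarnings(as.integer(dps))
    dps[is.na(dps)] <- 0L  # missing DP -> fails any depth >= 1 filter
    CJ(ai = seq_along(alts), si = seq_along(p$samples))[, .(
      sample = p$samples[si],
      chrom = f[1], pos = as.integer(f[2]),
      ref = toupper(f[4]), alt = toupper(alts[ai]),
      id = if (f[3] %in% c(".", "")) NA_character_ else f[3],
      genotype = gt_to_class(gts[si], ai),
      depth = dps[si])]
  }))
  recs[, chrom := normalize_chrom(chrom, chrom_style)]
  caller_label <- caller
  recs[, caller := caller_label]
  setcolorder(recs, c("caller", "sample", "chrom", "pos", "ref", "alt",
                      "id", "genotype", "depth"))
  norm <- normalize_variants(
    recs[, .(chrom, pos, ref, alt, id, hgvs = NA_character_)], reference)
  recs[, `:=`(pos = norm$pos, ref = norm$ref, alt = norm$alt)]
  recs[]
}

#' Read a truth-set VCF as a site-level variant table
#'
#' @inheritParams read_caller_vcf
#' @return A normalized, deduplicated `gvariants` table.
#' @export
read_truth_vcf <- function(path, reference = NULL, chrom_style = "as-is") {
  p <- parse_vcf(path)
  if (length(p$fields) == 0L) {
    return(gvariants(character(0), integer(0), character(0), character(0)))
  }
  recs <- rbindlist(lapply(p$fields, function(f) {
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    data.table(chrom = f[1], pos = as.integer(f[2]), ref = toupper(f[4]),
               alt = toupper(alts),
               id = if (f[3] %in% c(".", "")) NA_character_ else f[3],
               hgvs = NA_character_)
  }))
  recs[, chrom := normalize_chrom(chrom, chrom_style)]
  recs <- normalize_variants(recs, reference)
  recs <- unique(recs, by = c("chrom", "pos", "ref", "alt"))
  validate_gvariants(recs)
  setattr(recs, "class", c("gvariants", "data.table", "data.frame"))
  recs[]
}

vcf_header <- function(samples, info_lines = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=deepintron",
    info_lines,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
}

.GT_STRING <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                hemi = "1", missing = "./.")

gt_string <- function(genotype) {
  out <- .GT_STRING[genotype]
  if (anyNA(out)) {
    stop("unknown genotype class: ",
         paste(unique(genotype[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Write caller observations as a multi-sample VCF
#'
#' Inverse of [read_caller_vcf()] for the package's dialect (GT:DP). Sites
#' absent for a sample are written as hom_ref with the site's median depth.
#'
#' @param obs Observation table (one caller).
#' @param path Output file.
#' @param samples Sample column order; defaults to the samples present.
#' @return `path`, invisibly.
#' @export
write_observations_vcf <- function(obs, path, samples = NULL) {
  obs <- as.data.table(obs)
  if (is.null(samples)) samples <- sort(unique(obs$sample))
  if (nrow(obs) == 0L) {
    writeLines(vcf_header(samples), path)
    return(invisible(path))
  }
  d <- copy(obs)
  d[, cell := paste0(gt_string(genotype), ":", depth)]
  wide <- dcast(d, chrom + pos + ref + alt + id ~ sample,
                value.var = "cell", fill = "0/0:0",
                fun.aggregate = function(x) x[1])
  for (sm in setdiff(samples, names(wide))) {
    set(wide, j = sm, value = "0/0:0")
  }
  setorder(wide, chrom, pos, ref, alt)
  cells <- do.call(paste, c(wide[, samples, with = FALSE], sep = "\t"))
  recs <- paste(wide$chrom, wide$pos, fifelse(is.na(wide$id), ".", wide$id),
                wide$ref, wide$alt, ".", "PASS", ".", "GT:DP", cells,
                sep = "\t")
  writeLines(c(vcf_header(samples), recs), path)
  invisible(path)
}

#' Write a site-level variant table as a VCF without sample columns
#'
#' @param v Variant table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(v, path) {
  v <- as.data.table(v)
  setorder(v, chrom, pos, ref, alt)
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                  v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id),
                  v$ref, v$alt)
  writeLines(c(vcf_header(character(0)), recs), path)
  invisible(path)
}
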