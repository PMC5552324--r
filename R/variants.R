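#' @import data.table
#' @importFrom stats rbinom rnbinom rnorm runif rpois setNames
#' @importFrom utils head tail
NULL

.VALID_BASES <- c("A", "C", "G", "T")
.GENOTYPES <- c("hom_ref", "het", "hom_alt", "hemi", "missing")
.NONREF_GENOTYPES <- c("het", "hom_alt", "hemi")

#' Construct a table of genomic variants
#'
#' The variant table is the package's core currency: a `data.table` with one
#' row per allele and columns `chrom`, `pos` (1-based position of the first
#' reference base), `ref`, `alt`, `id` (dbSNP identifier or `NA`) and `hgvs`
#' (HGVS-c string or `NA`). All cross-caller and cross-table joins key on the
#' normalized `(chrom, pos, ref, alt)` tuple.
#'
#' @param chrom Chromosome names, as spelled in the source file.
#' @param pos 1-based positions (integer-valued).
#' @param ref,alt Reference / alternate allele strings (A/C/G/T only, at
#'   least one base each, `ref != alt` row-wise).
#' @param id Optional dbSNP identifiers (`NA` where absent).
#' @param hgvs Optional HGVS-c strings (`NA` where absent).
#' @return A `data.table` of class `gvariants`.
#' @export
#' @examples
#' gvariants("chr10", 1201267, "T", "C", id = "rs113195070",
#'           hgvs = "c.499+367T>C")
gvariants <- function(chrom, pos, ref, alt, id = NA_character_,
                      hgvs = NA_character_) {
  v <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  id = as.character(id), hgvs = as.character(hgvs))
  validate_gvariants(v)
  setattr(v, "class", c("gvariants", class(v)))
  v[]
}

validate_gvariants <- function(v) {
  if (nrow(v) == 0L) return(invisible(v))
  if (anyNA(v$pos) || any(v$pos < 1L)) {
    stop("variant positions must be positive integers", call. = FALSE)
  }
  ok_allele <- function(a) nzchar(a) & !grepl("[^ACGT]", a)
  bad <- !ok_allele(v$ref) | !ok_allele(v$alt)
  if (any(bad)) {
    stop("alleles must be non-empty A/C/G/T strings; offending row(s): ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  same <- v$ref == v$alt
  if (any(same)) {
    stop("ref and alt identical at row(s): ",
         paste(head(which(same), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(v)
}

#' Variant identity key
#'
#' @param v A variant table (or any data.frame with `chrom`, `pos`, `ref`,
#'   `alt` columns).
#' @return Character vector `"chrom:pos:ref:alt"`, one per row.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Normalize one variant to its canonical left-aligned, trimmed form
#'
#' Implements the standard left-align + trim canonicalization so that
#' indels reported by different callers in different but equivalent spellings
#' match exactly. SNVs are already canonical and are returned unchanged.
#' The transformation is a fixed point: applying it twice equals applying it
#' once.
#'
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings.
#' @param context Local reference sequence covering the variant site and
#'   enough flanking sequence to the left for alignment, or `NULL` for
#'   trim-only normalization (no repositioning).
#' @param context_start 1-based genomic position of the first `context` base.
#' @return `list(pos =, ref =, alt =)` in canonical form.
#' @export
normalize_allele <- function(pos, ref, alt, context = NULL,
                             context_start = 1L) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is.null(context)) {
    context <- toupper(context)
    off <- pos - as.integer(context_start) + 1L
    if (off < 1L || off + nchar(ref) - 1L > nchar(context)) {
      stop("reference context does not cover the variant", call. = FALSE)
    }
    if (substr(context, off, off + nchar(ref) - 1L) != ref) {
      stop("reference inconsistency: ref allele '", ref,
           "' does not match context at position ", pos, call. = FALSE)
    }
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    changed <- FALSE
    # shared trailing base: truncate, or left-extend from context when a
    # bare truncation would empty an allele
    while (nchar(ref) >= 1L && nchar(alt) >= 1L && last(ref) == last(alt)) {
      if (nchar(ref) > 1L && nchar(alt) > 1L) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
        changed <- TRUE
      } else if (!is.null(context) && pos > as.integer(context_start)) {
        prev <- substr(context, pos - as.integer(context_start),
                       pos - as.integer(context_start))
        ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
        changed <- TRUE
      } else break
    }
    # shared leading base: trim while both alleles keep >= 1 base
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize a variant table
#'
#' Applies [normalize_allele()] row-wise. A reference is only needed to
#' left-align indels; with `reference = NULL` alleles are trimmed in place.
#'
#' @param v A variant table.
#' @param reference Named character vector (or list) of chromosome sequences,
#'   or `NULL`.
#' @return The table with `pos`, `ref`, `alt` canonicalized.
#' @export
normalize_variants <- function(v, reference = NULL) {
  if (nrow(v) == 0L) return(v)
  needs <- nchar(v$ref) > 1L | nchar(v$alt) > 1L
  if (!any(needs)) return(v)
  v <- copy(v)
  for (i in which(needs)) {
    ctx <- NULL; ctx_start <- 1L
    if (!is.null(reference) && !is.null(reference[[v$chrom[i]]])) {
      seqchr <- reference[[v$chrom[i]]]
      ctx_start <- max(1L, v$pos[i] - 500L)
      ctx_end <- min(nchar(seqchr), v$pos[i] + nchar(v$ref[i]) + 10L)
      ctx <- substr(seqchr, ctx_start, ctx_end)
    }
    n <- normalize_allele(v$pos[i], v$ref[i], v$alt[i], ctx, ctx_start)
    set(v, i, "pos", n$pos); set(v, i, "ref", n$ref); set(v, i, "alt", n$alt)
  }
  v
}

#' Is a variant in trimmed (normalization-compatible) form?
#'
#' Checks the representation invariants that do not require a reference:
#' no shared trailing base, and a shared leading base only when one allele
#' would otherwise be empty.
#'
#' @param v A variant table.
#' @return Logical vector.
#' @export
is_trimmed <- function(v) {
  if (nrow(v) == 0L) return(logical(0))
  last <- function(x) substr(x, nchar(x), nchar(x))
  trail <- last(v$ref) == last(v$alt) & (nchar(v$ref) > 1L | nchar(v$alt) > 1L)
  lead <- substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L) &
    nchar(v$ref) > 1L & nchar(v$alt) > 1L
  !(trail | lead)
}

#' Allele-exact variant identity
#'
#' Two variants are the same call iff their normalized
#' `(chrom, pos, ref, alt)` tuples are identical. Both inputs must be in
#' trimmed form (see [is_trimmed()]); comparing unnormalized spellings is a
#' contract violation because equivalent indel spellings would spuriously
#' differ.
#'
#' @param a,b Single-row variant tables (or lists with the four fields).
#' @return `TRUE` or `FALSE`.
#' @export
same_variant <- function(a, b) {
  pick <- function(x) {
    as.data.table(as.list(x)[c("chrom", "pos", "ref", "alt")])
  }
  a <- pick(a)
  b <- pick(b)
  if (!all(is_trimmed(a)) || !all(is_trimmed(b))) {
    stop("same_variant() requires normalized (trimmed) variants",
         call. = FALSE)
  }
  a$chrom == b$chrom && a$pos == b$pos && a$ref == b$ref && a$alt == b$alt
}

#' Reconcile chromosome-name dialects
#'
#' Mixed-source joins ("chr10" vs "10") are reconciled by a configurable
#' style applied at load time.
#'
#' @param x Chromosome names.
#' @param style `"as-is"` (leave untouched), `"strip"` (remove a leading
#'   "chr"), or `"add"` (ensure a leading "chr").
#' @return Character vector.
#' @export
normalize_chrom <- function(x, style = c("as-is", "strip", "add")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "strip") sub("^chr", "", x)
  else if (style == "add") ifelse(grepl("^chr", x), x, paste0("chr", x))
  else x
}

is_x_chrom <- function(chrom) {
  normalize_chrom(chrom, "strip") == "X"
}
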