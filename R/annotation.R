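# Score joining, genomic-region / splice-distance classification, and
# TF-binding-site overlap.

.REGION_CLASSES <- c("exonic", "canonical_splice_site", "proximal_intronic",
                     "deep_intronic", "intergenic")

#' Join precomputed scores onto variants
#'
#' Left join: every input variant appears exactly once in the output;
#' unmatched variants carry all-NA scores. Matching prefers the normalized
#' `(chrom, pos, ref, alt)` tuple and falls back to the dbSNP id for score
#' rows that match no tuple. Two score rows with the same key but different
#' values are an ambiguity error.
#'
#' @param variants Variant table.
#' @param scores Score table from [read_score_table()].
#' @return `data.table`: the variants with score columns appended.
#' @export
annotate_scores <- function(variants, scores) {
  v <- as.data.table(variants)
  s <- as.data.table(scores)
  score_cols <- c(.SCORE_NUM_COLS, "clinical_class")
  if (nrow(v) == 0L) {
    out <- copy(v)
    for (col in score_cols) {
      set(out, j = col, value = if (col == "clinical_class") character(0)
          else numeric(0))
    }
    return(out[])
  }
  s <- unique(s)  # identical duplicate rows are harmless; conflicts are not
  s[, .skey := fifelse(is.na(chrom) | is.na(pos) | is.na(ref) | is.na(alt),
                       NA_character_, paste(chrom, pos, ref, alt, sep = ":"))]
  dup_key <- s[!is.na(.skey)][duplicated(.skey), .skey]
  dup_id <- s[!is.na(id)][duplicated(id), id]
  dups <- unique(c(dup_key, dup_id))
  if (length(dups)) {
    stop("ambiguous score table: multiple conflicting rows for key(s): ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  out <- copy(v)
  out[, .vkey := variant_key(out)]
  m <- match(out$.vkey, s$.skey)
  vid <- if ("id" %in% names(out)) out$id else rep(NA_character_, nrow(out))
  fallback <- is.na(m) & !is.na(vid)
  m[fallback] <- match(vid[fallback], s$id)
  for (col in score_cols) {
    filler <- if (col == "clinical_class") NA_character_ else NA_real_
    set(out, j = col,
        value = ifelse(is.na(m), filler, s[[col]][m]))
  }
  if ("gene" %in% names(s) && !"gene" %in% names(out)) {
    set(out, j = "gene", value = ifelse(is.na(m), NA_character_,
                                        s$gene[m]))
  }
  out[is.na(clinical_class), clinical_class := "unclassified"]
  out[, .vkey := NULL]
  out[]
}

#' Classify variants by genomic region and splice-site distance
#'
#' Positions inside an exon of a covering gene are `exonic`. Intronic
#' positions are classified by the distance (in nucleotides, unsigned) to
#' the nearest exon-intron boundary of that gene: 1-2 nt =
#' `canonical_splice_site` (the near-invariant GT/AG dinucleotides),
#' 3-99 nt = `proximal_intronic`, and >= 100 nt = `deep_intronic` (the
#' standard "at least 100 bp from the nearest canonical splice site"
#' definition). Positions outside every gene span are `intergenic` with no
#' distance. When gene spans overlap, the gene giving the smallest distance
#' wins (exonic beats intronic).
#'
#' @param variants Variant table.
#' @param models A `gene_models` exon table.
#' @return `data.table`: the variants with `region`, `splice_distance`,
#'   `gene` appended.
#' @export
classify_region <- function(variants, models) {
  v <- copy(as.data.table(variants))
  m <- as.data.table(models)
  spans <- m[, .(span_start = min(start) + 1L, span_end = max(end),
                 chrom = chrom[1]), by = gene]
  region <- rep("intergenic", nrow(v))
  dist <- rep(NA_integer_, nrow(v))
  gene_out <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    cover <- spans[chrom == v$chrom[i] & span_start <= p & span_end >= p]
    if (nrow(cover) == 0L) next
    best_d <- NA_integer_; best_g <- NA_character_; best_exonic <- FALSE
    for (g in cover$gene) {
      ex <- m[gene == g]
      inside <- any(ex$start + 1L <= p & ex$end >= p)
      # boundary coords: first and last base of each exon (1-based)
      d <- min(abs(p - (ex$start + 1L)), abs(p - ex$end))
      if (inside) {
        if (!best_exonic || d < best_d) {
          best_exonic <- TRUE; best_d <- d; best_g <- g
        }
      } else if (!best_exonic && (is.na(best_d) || d < best_d)) {
        best_d <- d; best_g <- g
      }
    }
    gene_out[i] <- best_g
    dist[i] <- best_d
    region[i] <- if (best_exonic) "exonic"
    else if (best_d <= 2L) "canonical_splice_site"
    else if (best_d <= 99L) "proximal_intronic"
    else "deep_intronic"
  }
  if ("gene" %in% names(v)) {
    v[, gene := fifelse(is.na(gene_out), gene, gene_out)]
  } else v[, gene := gene_out]
  v[, `:=`(region = region, splice_distance = dist)]
  v[]
}

#' Transcription-factor binding-site overlap
#'
#' Names every TF whose ChIP-seq peak interval contains a variant's
#' position (half-open BED convention: a position equal to an interval's
#' `end` is outside).
#'
#' @param variants Variant table.
#' @param peaks `GRanges` with `tf` metadata, from [read_tf_peaks()].
#' @return `data.table`: the variants with a `tfbs` column
#'   (comma-separated sorted TF names, `""` when none) and a `tf_hits`
#'   list-column of character vectors.
#' @export
tfbs_overlap <- function(variants, peaks) {
  v <- copy(as.data.table(variants))
  if (nrow(v) == 0L) {
    v[, `:=`(tfbs = character(0), tf_hits = list())]
    return(v[])
  }
  hits_list <- vector("list", nrow(v))
  if (length(peaks) > 0L) {
    q <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, width = 1L))
    ov <- GenomicRanges::findOverlaps(q, peaks)
    tf <- S4Vectors::mcols(peaks)$tf
    for (i in seq_len(nrow(v))) hits_list[[i]] <- character(0)
    if (length(ov) > 0L) {
      sp <- split(tf[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
      for (qn in names(sp)) {
        hits_list[[as.integer(qn)]] <- sort(unique(sp[[qn]]))
      }
    }
  } else {
    for (i in seq_len(nrow(v))) hits_list[[i]] <- character(0)
  }
  v[, tfbs := vapply(hits_list, paste, "", collapse = ",")]
  v[, tf_hits := hits_list]
  v[]
}
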