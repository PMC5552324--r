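# Independent brute-force oracles used to validate the implementation on
# random instances. Deliberately naive: enumeration and O(n^2) scans.

library(data.table)

ext_file <- function(...) {
  system.file("extdata", ..., package = "deepintron", mustWork = TRUE)
}

random_seq <- function(n, runs = TRUE) {
  if (!runs) return(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = ""))
  out <- character(0)
  while (sum(nchar(out)) < n) {
    out <- c(out, strrep(sample(c("A", "C", "G", "T"), 1),
                         sample(1:5, 1, prob = c(.4, .25, .2, .1, .05))))
  }
  substr(paste(out, collapse = ""), 1, n)
}

apply_variant_to_seq <- function(seqc, pos, ref, alt) {
  stopifnot(substr(seqc, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seqc, 1L, pos - 1L), alt,
         substr(seqc, pos + nchar(ref), nchar(seqc)))
}

# Exhaustive-equivalence oracle: enumerate every (pos, ref, alt) spelling
# inside the context that reproduces the same alternate haplotype, keep the
# trimmed ones, and return the minimal-position (then minimal-length) one.
# When a repeat run reaches the context edge no trimmed spelling exists
# (left-alignment is context-limited); fall back to the minimal-position,
# minimal-length spelling among all equivalents, which is where a
# context-bounded normalizer must stop.
oracle_normalize <- function(seqc, pos, ref, alt) {
  H <- apply_variant_to_seq(seqc, pos, ref, alt)
  nS <- nchar(seqc); nH <- nchar(H)
  best <- NULL; best_any <- NULL
  for (p in seq_len(nS)) {
    for (lr in 0:10) {
      la <- lr + nH - nS
      if (la < 1L || lr < 1L) next
      if (p + lr - 1L > nS || p + la - 1L > nH) next
      r <- substr(seqc, p, p + lr - 1L)
      a <- substr(H, p, p + la - 1L)
      if (r == a) next
      if (!identical(paste0(substr(seqc, 1L, p - 1L), a,
                            substr(seqc, p + lr, nS)), H)) next
      cand <- list(pos = p, ref = r, alt = a)
      better <- function(old) {
        is.null(old) || p < old$pos ||
          (p == old$pos && nchar(r) < nchar(old$ref))
      }
      if (better(best_any)) best_any <- cand
      if (is_trimmed(data.frame(chrom = "c", pos = p, ref = r, alt = a)) &&
          better(best)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) best_any else best
}

# every equivalent trimmed spelling (for equivalence-class tests)
oracle_equivalents <- function(seqc, pos, ref, alt) {
  H <- apply_variant_to_seq(seqc, pos, ref, alt)
  nS <- nchar(seqc); nH <- nchar(H)
  out <- list()
  for (p in seq_len(nS)) {
    for (lr in 0:10) {
      la <- lr + nH - nS
      if (la < 1L || lr < 1L) next
      if (p + lr - 1L > nS || p + la - 1L > nH) next
      r <- substr(seqc, p, p + lr - 1L)
      a <- substr(H, p, p + la - 1L)
      if (r == a) next
      if (!identical(paste0(substr(seqc, 1L, p - 1L), a,
                            substr(seqc, p + lr, nS)), H)) next
      out[[length(out) + 1L]] <- list(pos = p, ref = r, alt = a)
    }
  }
  out
}

oracle_consensus <- function(obs, k) {
  nonref <- obs[genotype %in% c("het", "hom_alt", "hemi")]
  votes <- unique(nonref[, .(caller, sample, chrom, pos, ref, alt)])
  cnt <- votes[, .N, by = .(sample, chrom, pos, ref, alt)]
  out <- cnt[N >= k][, N := NULL]
  setorder(out, sample, chrom, pos, ref, alt)
  out[]
}

oracle_in_targets <- function(pos_tbl, bed) {
  # bed: data.table chrom,start(0-based),end; point-in-interval scan
  vapply(seq_len(nrow(pos_tbl)), function(i) {
    any(bed$chrom == pos_tbl$chrom[i] &
          bed$start < pos_tbl$pos[i] & pos_tbl$pos[i] <= bed$end)
  }, TRUE)
}

oracle_compound_het <- function(geno, exonic_keys, tier1_keys) {
  # geno: sample x key character matrix
  carried <- geno %in% c("het", "hom_alt", "hemi")
  dim(carried) <- dim(geno); dimnames(carried) <- dimnames(geno)
  rows <- list()
  for (sm in rownames(geno)) {
    for (e in exonic_keys) {
      for (i in tier1_keys) {
        if (e != i && carried[sm, e] && carried[sm, i]) {
          rows[[length(rows) + 1L]] <- data.table(sample = sm,
                                                  exonic_key = e,
                                                  intronic_key = i)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.table(sample = character(0), exonic_key = character(0),
                      intronic_key = character(0)))
  }
  out <- rbindlist(rows)
  setorder(out, sample, exonic_key, intronic_key)
  out[]
}

random_observations <- function(n, callers, samples, chroms = "chr1",
                                max_pos = 50L) {
  data.table(
    caller = sample(callers, n, TRUE),
    sample = sample(samples, n, TRUE),
    chrom = sample(chroms, n, TRUE),
    pos = sample.int(max_pos, n, TRUE),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = "N_FIX", id = NA_character_,
    genotype = sample(c("het", "hom_alt", "hom_ref", "missing"), n, TRUE,
                      prob = c(.5, .2, .2, .1)),
    depth = sample.int(60L, n, TRUE) - 1L
  )[, alt := vapply(ref, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")][]
}

make_vcf_file <- function(records, samples = "S1",
                          format_line = TRUE, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (length(samples)) c("FORMAT", samples)),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
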