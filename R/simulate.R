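# Seeded generators for every input the pipeline consumes: toy genome and
# gene models, truth variants with per-caller callsets (independent error
# rates, indel-representation jitter), score tables with pathogenic-like /
# benign-like separation, cohort genotypes at planted allele frequencies,
# and a two-variant family pedigree under a digenic or monogenic penetrance
# rule.

#' Simulation configuration
#'
#' Defaults state the emulated world: a 16-proband cohort sequenced at high
#' depth (read depth ~ NegBin with mean 180, matching 130-200+ panel
#' averages), four independent callers with per-caller sensitivities in the
#' mid-0.9s, occasional unnormalized indel spellings, and one planted
#' pathogenic-like deep-intronic variant at cohort allele frequency 0.19
#' against a reference MAF of 0.06 (about 3-fold enrichment). Pathogenic-like
#' variants clear each score threshold with probability 0.995 (tight
#' separation); benign-like variants pass with probability 0.02.
#'
#' @param seed Master seed; every generator stream derives from it, and a
#'   fixed seed makes all outputs byte-identical.
#' @param n_callers Number of callers (default 4).
#' @param caller_sensitivity Per-caller detection probability for a true
#'   variant in a carrier sample; recycled to `n_callers`.
#' @param fp_per_kb Per-caller false-positive rate per targeted kilobase.
#' @param indel_jitter_prob Probability a caller reports a true indel in an
#'   alternative equivalent spelling.
#' @param caller_labels Caller names.
#' @param n_truth_variants Number of truth variants planted in targets.
#' @param indel_frac Fraction of truth variants that are indels.
#' @param n_samples Cohort size (default 16, half male).
#' @param n_genes,n_exons,exon_len,intron_len Toy gene geometry.
#' @param depth_mean,depth_size Negative-binomial read-depth parameters.
#' @param background_af Allele-frequency range for background variants.
#' @param planted_af Cohort allele frequency of the planted candidate; its
#'   alt-allele count is placed exactly (round(2n x AF)) so the planted
#'   enrichment is a property of the stated world, not of sampling noise.
#' @param planted_maf Reference-population MAF of the planted candidate.
#' @param pathogenic_frac Fraction of background variants flagged
#'   pathogenic-like for score simulation.
#' @param pathogenic_pass,benign_pass Per-tool probability that a
#'   pathogenic-like / benign-like variant clears a threshold.
#' @param spidex_null_rate Probability a variant has no SPIDEX score (most
#'   deep-intronic sites are unscored).
#' @param penetrance `"digenic"` (affected iff both tracked variants
#'   carried) or `"monogenic"` (affected iff the first is carried).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_callers = 4L,
                       caller_sensitivity = c(0.97, 0.95, 0.96, 0.94),
                       fp_per_kb = 0.2,
                       indel_jitter_prob = 0.15,
                       caller_labels = c("GATK_UG", "SAMTOOLS",
                                         "GATK_HC", "FREEBAYES"),
                       n_truth_variants = 60L,
                       indel_frac = 0.2,
                       n_samples = 16L,
                       n_genes = 3L, n_exons = 4L,
                       exon_len = 150L, intron_len = 2000L,
                       depth_mean = 180, depth_size = 10,
                       background_af = c(0.02, 0.30),
                       planted_af = 0.19,
                       planted_maf = 0.06,
                       pathogenic_frac = 0.10,
                       pathogenic_pass = 0.995,
                       benign_pass = 0.02,
                       spidex_null_rate = 0.8,
                       penetrance = c("digenic", "monogenic")) {
  cfg <- list(seed = as.integer(seed), n_callers = as.integer(n_callers),
              caller_sensitivity = rep_len(caller_sensitivity, n_callers),
              fp_per_kb = fp_per_kb,
              indel_jitter_prob = indel_jitter_prob,
              caller_labels = rep_len(caller_labels, n_callers),
              n_truth_variants = as.integer(n_truth_variants),
              indel_frac = indel_frac,
              n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes), n_exons = as.integer(n_exons),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              depth_mean = depth_mean, depth_size = depth_size,
              background_af = background_af,
              planted_af = planted_af, planted_maf = planted_maf,
              pathogenic_frac = pathogenic_frac,
              pathogenic_pass = pathogenic_pass, benign_pass = benign_pass,
              spidex_null_rate = spidex_null_rate,
              penetrance = match.arg(penetrance))
  probs <- c(cfg$caller_sensitivity, cfg$indel_jitter_prob,
             cfg$indel_frac, cfg$pathogenic_frac, cfg$pathogenic_pass,
             cfg$benign_pass, cfg$spidex_null_rate, cfg$planted_af,
             cfg$planted_maf)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# per-generator RNG streams derived from the master seed, so each fixture
# is individually reproducible
with_stream <- function(cfg, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed %% 1000000L) * 1000L + stream)
  expr
}

#' Simulate the toy genome and gene models
#'
#' Random A/C/G/T sequence with exaggerated homopolymer runs (so indel
#' jitter has room to mis-spell), carrying `n_genes` equally spaced genes.
#'
#' @param cfg A [sim_config()].
#' @return List: `reference` (named list of chromosome sequences), `models`
#'   (a `gene_models` table), `targets` (`GRanges` gene spans +- 100 bp).
#' @export
sim_genome <- function(cfg) {
  with_stream(cfg, 1L, {
    gene_span <- cfg$n_exons * cfg$exon_len +
      (cfg$n_exons - 1L) * cfg$intron_len
    gap <- 1000L
    chrom_len <- cfg$n_genes * (gene_span + gap) + gap
    # runs of length 1-6 inflate homopolymer content
    n_runs <- ceiling(chrom_len / 2.5)
    runs <- sample(1:6, n_runs, replace = TRUE,
                   prob = c(0.45, 0.25, 0.15, 0.08, 0.05, 0.02))
    bases <- sample(.VALID_BASES, n_runs, replace = TRUE)
    seqc <- paste(rep.int(bases, runs), collapse = "")
    seqc <- substr(seqc, 1L, chrom_len)
    models <- rbindlist(lapply(seq_len(cfg$n_genes), function(gi) {
      g0 <- gap + (gi - 1L) * (gene_span + gap)
      starts <- g0 + (seq_len(cfg$n_exons) - 1L) *
        (cfg$exon_len + cfg$intron_len)
      data.table(gene = sprintf("TOYG%d", gi), chrom = "chr1",
                 strand = if (gi %% 2L) "+" else "-",
                 start = starts, end = starts + cfg$exon_len)
    }))
    setattr(models, "class", c("gene_models", "data.table", "data.frame"))
    spans <- models[, .(start = max(0L, min(start) - 100L),
                        end = max(end) + 100L), by = .(gene, chrom)]
    targets <- GenomicRanges::reduce(GenomicRanges::GRanges(
      spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end)))
    list(reference = list(chr1 = seqc), models = models, targets = targets)
  })
}

random_alt <- function(ref_base) {
  vapply(ref_base, function(b) sample(setdiff(.VALID_BASES, b), 1L), "")
}

#' Simulate truth variants and cohort genotypes
#'
#' Truth variants are placed uniformly in target regions (SNVs and 1-3 bp
#' indels, normalized by construction). Each gets a cohort allele frequency:
#' background variants draw from `background_af` with binomially sampled
#' genotypes; the planted candidate (always the first variant, an SNV deep
#' inside an intron) has its alt-allele count placed exactly.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [sim_genome()] (regenerated when NULL).
#' @return List: `variants` (truth `gvariants` + `pathogenic`, `af`,
#'   `maf_1000g` columns), `genotypes` (a `cohort_genotypes`), `genome`.
#' @export
sim_truth <- function(cfg, genome = NULL) {
  if (is.null(genome)) genome <- sim_genome(cfg)
  seqc <- genome$reference$chr1
  with_stream(cfg, 2L, {
    tg <- as.data.table(genome$targets)
    tg_pos <- unlist(lapply(seq_len(nrow(tg)), function(i) {
      tg$start[i]:tg$end[i]
    }))
    n <- cfg$n_truth_variants
    pos <- sort(sample(tg_pos, n))
    pos <- pos[pos > 5L & pos < nchar(seqc) - 10L]
    pos <- unique(pos)
    n <- length(pos)
    is_indel <- runif(n) < cfg$indel_frac
    is_indel[1L] <- FALSE  # planted candidate stays an SNV
    ref <- substr(rep(seqc, n), pos, pos)
    alt <- random_alt(ref)
    for (i in which(is_indel)) {
      len <- sample(1:3, 1L)
      if (runif(1) < 0.5) {  # deletion
        ref[i] <- substr(seqc, pos[i], pos[i] + len)
        alt[i] <- substr(seqc, pos[i], pos[i])
      } else {               # insertion
        ref[i] <- substr(seqc, pos[i], pos[i])
        alt[i] <- paste0(ref[i], paste(sample(.VALID_BASES, len,
                                              replace = TRUE),
                                       collapse = ""))
      }
    }
    v <- gvariants("chr1", pos, ref, alt)
    v <- normalize_variants(v, genome$reference)
    v <- unique(v, by = c("chrom", "pos", "ref", "alt"))
    n <- nrow(v)
    v[, pathogenic := runif(n) < cfg$pathogenic_frac]
    v[1L, pathogenic := TRUE]
    v[, af := runif(n, cfg$background_af[1], cfg$background_af[2])]
    v[, maf_1000g := pmin(0.95, af * runif(n, 0.5, 2))]
    v[1L, `:=`(af = cfg$planted_af, maf_1000g = cfg$planted_maf)]
    samples <- data.table(
      sample = sprintf("S%02d", seq_len(cfg$n_samples)),
      sex = rep(c("male", "female"), length.out = cfg$n_samples))
    geno <- matrix("hom_ref", nrow = cfg$n_samples, ncol = n,
                   dimnames = list(samples$sample, variant_key(v)))
    for (j in seq_len(n)) {
      if (j == 1L) {
        # exact placement: round(2n x AF) alt alleles as het carriers
        n_alt <- round(2L * cfg$n_samples * cfg$planted_af)
        carriers <- sample(cfg$n_samples, min(n_alt, cfg$n_samples))
        geno[carriers, j] <- "het"
        extra <- n_alt - length(carriers)
        if (extra > 0L) geno[carriers[seq_len(extra)], j] <- "hom_alt"
      } else {
        alleles <- rbinom(cfg$n_samples, 2L, v$af[j])
        geno[alleles == 1L, j] <- "het"
        geno[alleles == 2L, j] <- "hom_alt"
      }
    }
    # a truth variant must exist in the cohort: drop zero-carrier draws
    carried <- colSums(geno != "hom_ref") > 0L
    v <- v[carried]
    geno <- geno[, carried, drop = FALSE]
    variants <- copy(as.data.table(v))
    variants[, key := variant_key(v)]
    setcolorder(variants, "key")
    list(variants = v,
         genotypes = cohort_genotypes(samples, geno,
                                      variants[, .(key, chrom, pos, ref,
                                                   alt)]),
         genome = genome)
  })
}

# one right-shift/pad step producing an equivalent unnormalized spelling;
# verified equivalent by construction (haplotype identity), used to emulate
# caller-specific indel representation
jitter_spelling <- function(pos, ref, alt, seqc) {
  if (nchar(ref) == nchar(alt)) return(list(pos = pos, ref = ref, alt = alt))
  nxt <- substr(seqc, pos + nchar(ref), pos + nchar(ref))
  if (!nzchar(nxt)) return(list(pos = pos, ref = ref, alt = alt))
  longer <- if (nchar(ref) > nchar(alt)) ref else alt
  if (substr(longer, 2L, 2L) == nxt) {
    # the run continues: shift the representation right by one base
    new_ref <- paste0(substr(seqc, pos + 1L, pos + nchar(ref) - 1L), nxt)
    if (nchar(ref) > nchar(alt)) {
      return(list(pos = pos + 1L, ref = new_ref,
                  alt = substr(new_ref, 1L, nchar(alt))))
    }
    new_alt <- paste0(substr(alt, 2L, nchar(alt)), nxt)
    return(list(pos = pos + 1L, ref = substr(seqc, pos + 1L, pos + 1L),
                alt = paste0(substr(seqc, pos + 1L, pos + 1L),
                             substr(new_alt, 2L, nchar(new_alt)))))
  }
  # no run: pad both alleles with the shared following reference base
  list(pos = pos, ref = paste0(ref, nxt), alt = paste0(alt, nxt))
}

#' Simulate per-caller callsets from a truth set
#'
#' Every (carrier sample, truth variant) pair is detected by caller `c`
#' with probability `caller_sensitivity[c]`, independently across callers
#' and samples. False positives arrive per caller as a Poisson draw at
#' `fp_per_kb` over the target footprint, each assigned het to one random
#' sample. With probability `indel_jitter_prob` a caller reports a true
#' indel in an equivalent unnormalized spelling. Depth is NegBin
#' (`depth_mean`, `depth_size`).
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [sim_truth()] (regenerated when NULL).
#' @return List: `callsets` (named list of observation tables, one per
#'   caller, spellings as emitted, NOT normalized), `truth`.
#' @export
sim_callers <- function(cfg, truth = NULL) {
  if (is.null(truth)) truth <- sim_truth(cfg)
  seqc <- truth$genome$reference$chr1
  v <- truth$variants
  geno <- truth$genotypes$geno
  with_stream(cfg, 3L, {
    target_kb <- sum(IRanges::width(truth$genome$targets)) / 1000
    callsets <- lapply(seq_len(cfg$n_callers), function(ci) {
      s_c <- cfg$caller_sensitivity[ci]
      rows <- list()
      for (j in seq_len(nrow(v))) {
        carriers <- which(geno[, j] != "hom_ref")
        if (length(carriers) == 0L) next
        hit <- carriers[runif(length(carriers)) < s_c]
        if (length(hit) == 0L) next
        sp <- list(pos = v$pos[j], ref = v$ref[j], alt = v$alt[j])
        if (nchar(sp$ref) != nchar(sp$alt) &&
            runif(1) < cfg$indel_jitter_prob) {
          sp <- jitter_spelling(sp$pos, sp$ref, sp$alt, seqc)
        }
        rows[[length(rows) + 1L]] <- data.table(
          caller = cfg$caller_labels[ci],
          sample = rownames(geno)[hit],
          chrom = v$chrom[j], pos = sp$pos, ref = sp$ref, alt = sp$alt,
          id = NA_character_, genotype = geno[hit, j],
          depth = rnbinom(length(hit), size = cfg$depth_size,
                          mu = cfg$depth_mean))
      }
      n_fp <- rpois(1L, cfg$fp_per_kb * target_kb)
      if (n_fp > 0L) {
        tg <- as.data.table(truth$genome$targets)
        fp_pos <- sample(unlist(lapply(seq_len(nrow(tg)), function(i) {
          tg$start[i]:tg$end[i]
        })), n_fp)
        fp_ref <- substr(rep(seqc, n_fp), fp_pos, fp_pos)
        rows[[length(rows) + 1L]] <- data.table(
          caller = cfg$caller_labels[ci],
          sample = sample(rownames(geno), n_fp, replace = TRUE),
          chrom = "chr1", pos = fp_pos, ref = fp_ref,
          alt = random_alt(fp_ref), id = NA_character_,
          genotype = "het",
          depth = rnbinom(n_fp, size = cfg$depth_size, mu = cfg$depth_mean))
      }
      out <- rbindlist(rows)
      # a caller emits one record per site; de-duplicate FP collisions
      unique(out, by = c("sample", "chrom", "pos", "ref", "alt"))
    })
    names(callsets) <- cfg$caller_labels
    list(callsets = callsets, truth = truth)
  })
}

#' Simulate a precomputed score table
#'
#' Pathogenic-like variants clear each of the CADD / GWAVA / Genomiser
#' thresholds independently with probability `pathogenic_pass` (scores
#' drawn above the cutoff) and fall below otherwise; benign-like variants
#' use `benign_pass`. SPIDEX is NA at `spidex_null_rate` and small
#' otherwise. Reference MAFs come from the truth table.
#'
#' @param cfg A [sim_config()].
#' @param variants Truth variant table with `pathogenic` and `maf_1000g`
#'   columns (from [sim_truth()]).
#' @param thresholds A [threshold_config()].
#' @return Score `data.table` as produced by [read_score_table()].
#' @export
sim_scores <- function(cfg, variants,
                       thresholds = threshold_config()) {
  v <- as.data.table(variants)
  n <- nrow(v)
  with_stream(cfg, 4L, {
    pass_p <- fifelse(v$pathogenic, cfg$pathogenic_pass, cfg$benign_pass)
    draw <- function(pass, above, below) fifelse(pass, above, below)
    pass_cadd <- runif(n) < pass_p
    pass_gwava <- runif(n) < pass_p
    pass_geno <- runif(n) < pass_p
    out <- data.table(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      id = NA_character_, hgvs = NA_character_,
      gene = if ("gene" %in% names(v)) v$gene else NA_character_,
      cadd_phred = draw(pass_cadd,
                        thresholds$cadd_min + abs(rnorm(n, 5, 2.5)),
                        runif(n, 0, thresholds$cadd_min)),
      gwava_region = draw(pass_gwava,
                          pmin(1, thresholds$gwava_min +
                                 abs(rnorm(n, 0.15, 0.08))),
                          runif(n, 0, thresholds$gwava_min - 1e-6)),
      genomiser = draw(pass_geno,
                       pmin(1, thresholds$genomiser_min + 1e-6 +
                              abs(rnorm(n, 0.2, 0.1))),
                       runif(n, 0, thresholds$genomiser_min)),
      spidex_dpsi = fifelse(runif(n) < cfg$spidex_null_rate, NA_real_,
                            rnorm(n, 0, 2)),
      maf_1000g = v$maf_1000g,
      maf_gnomad = pmin(0.95, v$maf_1000g * runif(n, 0.8, 1.25)),
      clinical_class = "unclassified")
    out
  })
}

#' Simulate a family pedigree under a penetrance rule
#'
#' Builds a nuclear family (two founders, `n_children` children) tracking
#' one or two variants. The transmitting founder is compound het for both
#' tracked variants (digenic) or het for the first (monogenic); children
#' inherit each founder allele with probability 1/2. Phenotypes follow the
#' penetrance rule with full penetrance: digenic = affected iff both
#' variants carried; monogenic = affected iff the first is carried.
#'
#' @param cfg A [sim_config()].
#' @param variant_keys Character vector (length 2 for digenic) of tracked
#'   variant keys.
#' @param n_children Number of children (default 4).
#' @return A `pedigree` object.
#' @export
sim_pedigree <- function(cfg, variant_keys = c("varA", "varB"),
                         n_children = 4L) {
  digenic <- cfg$penetrance == "digenic"
  if (digenic && length(variant_keys) != 2L) {
    stop("digenic penetrance needs two tracked variants", call. = FALSE)
  }
  with_stream(cfg, 5L, {
    nv <- length(variant_keys)
    ids <- c("I-1", "I-2", sprintf("II-%d", seq_len(n_children)))
    founders_carrier <- rbind(rep(FALSE, nv),  # I-1 marries in
                              rep(TRUE, nv))   # I-2 transmits
    child_carrier <- matrix(runif(n_children * nv) < 0.5, n_children, nv)
    carrier <- rbind(founders_carrier, child_carrier)
    affected <- if (digenic) carrier[, 1L] & carrier[, 2L] else carrier[, 1L]
    members <- data.table(
      family = "SIMFAM1", individual = ids,
      father = c(NA, NA, rep("I-2", n_children)),
      mother = c(NA, NA, rep("I-1", n_children)),
      sex = c("female", "male",
              rep(c("male", "female"), length.out = n_children)),
      phenotype = fifelse(affected, "affected", "unaffected"))
    carriers <- matrix(fifelse(carrier, "carrier_het", "noncarrier"),
                       nrow(members), nv,
                       dimnames = list(ids, variant_keys))
    structure(list(family = "SIMFAM1", members = members,
                   carriers = carriers), class = "pedigree")
  })
}

#' Write a pedigree to the package's PED-style TSV dialect
#'
#' @param ped A `pedigree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  d <- copy(ped$members)
  d[is.na(father), father := "0"]
  d[is.na(mother), mother := "0"]
  if (!is.null(ped$carriers)) {
    d <- cbind(d, as.data.table(ped$carriers))
  }
  fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Generate and write every synthetic input to a directory
#'
#' Emits the same dialects the package readers consume: per-caller VCFs, a
#' truth VCF, the reference FASTA, targets BED, gene models BED12, score
#' TSV, cohort genotype TSV and a pedigree TSV. A fixed seed makes the
#' directory byte-identical across runs.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @return Named list of file paths, invisibly; plus the in-memory objects
#'   as attribute `"objects"`.
#' @export
simulate_inputs <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- sim_callers(cfg)
  truth <- sim$truth
  scores <- sim_scores(cfg, truth$variants)
  keys <- variant_key(truth$variants)
  ped_keys <- if (length(keys) >= 2L) keys[1:2] else keys
  ped <- sim_pedigree(cfg, variant_keys = ped_keys)
  paths <- list(
    genome_fa = file.path(out_dir, "genome.fa"),
    targets_bed = file.path(out_dir, "targets.bed"),
    gene_models_bed12 = file.path(out_dir, "gene_models.bed12"),
    truth_vcf = file.path(out_dir, "truth.vcf"),
    scores_tsv = file.path(out_dir, "scores.tsv"),
    cohort_tsv = file.path(out_dir, "cohort_genotypes.tsv"),
    pedigree_tsv = file.path(out_dir, "pedigree.tsv"))
  writeLines(c(">chr1", truth$genome$reference$chr1), paths$genome_fa)
  tg <- as.data.table(truth$genome$targets)
  writeLines(sprintf("%s\t%d\t%d", tg$seqnames, tg$start - 1L, tg$end),
             paths$targets_bed)
  write_gene_models_bed12(truth$genome$models, paths$gene_models_bed12)
  write_sites_vcf(truth$variants, paths$truth_vcf)
  fwrite(sim_scores_for_write(scores), paths$scores_tsv, sep = "\t")
  write_cohort_genotypes(truth$genotypes, paths$cohort_tsv)
  write_pedigree(ped, paths$pedigree_tsv)
  for (lab in names(sim$callsets)) {
    p <- file.path(out_dir, sprintf("caller_%s.vcf", lab))
    write_observations_vcf(sim$callsets[[lab]], p,
                           samples = truth$genotypes$samples$sample)
    paths[[sprintf("caller_%s", lab)]] <- p
  }
  attr(paths, "objects") <- list(sim = sim, truth = truth, scores = scores,
                                 pedigree = ped)
  invisible(paths)
}

sim_scores_for_write <- function(scores) {
  out <- copy(scores)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      set(out, j = col, value = as.character(out[[col]]))
    }
  }
  out[is.na(out)] <- "."
  out
}

#' Read a FASTA file into a named list of sequences
#'
#' Minimal single-purpose loader for the simulator's small toy genomes.
#'
#' @param path FASTA file.
#' @return Named list of uppercase sequence strings.
#' @export
read_reference_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("not a FASTA file: ", path, call. = FALSE)
  names_ <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- lapply(seq_along(hdr), function(i) {
    toupper(paste(lines[starts[i]:ends[i]], collapse = ""))
  })
  setNames(out, names_)
}
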