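# Stage orchestration behind one entry point: consensus -> depth filter ->
# on-target restriction -> annotation -> threshold prioritization -> cohort
# enrichment -> segregation, with a JSON run manifest recording the funnel.

default_pipeline_config <- function() {
  list(
    callers = NULL,        # named list caller label -> VCF path
    truth_vcf = NULL,
    reference_fa = NULL,
    targets_bed = NULL,
    gene_models = NULL,
    scores_tsv = NULL,
    peaks_bed = NULL,
    cohort_tsv = NULL,
    pedigrees = NULL,      # list of pedigree TSV paths
    chrom_style = "as-is",
    k = 2L,
    min_depth = 20L,
    thresholds = list(),   # overrides for threshold_config()
    fold_min = 3,
    reference_pop = "maf_1000g",
    seed = NULL,
    simulate = FALSE,      # TRUE: generate inputs first via sim_config()
    sim = list(),          # overrides for sim_config()
    out = "deepintron_out")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(base, cfg)
}

check_inputs_exist <- function(cfg) {
  paths <- c(unlist(cfg$callers), cfg$truth_vcf, cfg$reference_fa,
             cfg$targets_bed, cfg$gene_models, unlist(cfg$scores_tsv),
             cfg$peaks_bed, cfg$cohort_tsv, unlist(cfg$pedigrees))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Run the full discovery pipeline
#'
#' Stages run in funnel order; every intermediate is persisted under
#' `cfg$out` and the run manifest records per-stage variant counts (each
#' filtering stage non-increasing), input digests and the config snapshot.
#' Stages whose inputs are absent from the config are skipped: a run may
#' start from caller VCFs, or directly from a score table + cohort
#' genotypes.
#'
#' @param cfg Config list ([read_pipeline_config()]) or path to a YAML
#'   config.
#' @param log Log level: `"info"` prints per-stage counts, `"quiet"`
#'   nothing, `"debug"` per-variant decisions.
#' @return Named list of output paths plus the in-memory results
#'   (invisibly).
#' @export
run_pipeline <- function(cfg, log = c("info", "quiet", "debug")) {
  log <- match.arg(log)
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- utils::modifyList(default_pipeline_config(), cfg)
  say <- function(...) if (log != "quiet") message(sprintf(...))
  if (isTRUE(cfg$simulate)) {
    sim_args <- cfg$sim
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim_dir <- file.path(cfg$out, "inputs")
    say("stage 0: simulating inputs into %s", sim_dir)
    paths <- simulate_inputs(scfg, sim_dir)
    cfg$callers <- as.list(setNames(
      unlist(paths[grep("^caller_", names(paths))]),
      sub("^caller_", "", grep("^caller_", names(paths), value = TRUE))))
    cfg$truth_vcf <- paths$truth_vcf
    cfg$reference_fa <- paths$genome_fa
    cfg$targets_bed <- paths$targets_bed
    cfg$gene_models <- paths$gene_models_bed12
    cfg$scores_tsv <- paths$scores_tsv
    cfg$cohort_tsv <- paths$cohort_tsv
    cfg$pedigrees <- list(paths$pedigree_tsv)
  }
  check_inputs_exist(cfg)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = sprintf("deepintron %s",
                   as.character(utils::packageVersion("deepintron"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[!vapply(cfg, is.null, TRUE)],
    inputs = list(), stages = list())
  for (p in c(unlist(cfg$callers), cfg$truth_vcf, cfg$targets_bed,
              cfg$gene_models, unlist(cfg$scores_tsv), cfg$peaks_bed,
              cfg$cohort_tsv, unlist(cfg$pedigrees))) {
    manifest$inputs[[p]] <- unname(tools::md5sum(p))
  }
  record <- function(stage, n_in, n_out) {
    manifest$stages[[stage]] <<- list(n_in = n_in, n_out = n_out)
    say("stage %-12s: %d -> %d", stage, n_in, n_out)
  }
  out_paths <- list(manifest = file.path(cfg$out, "manifest.json"))
  reference <- if (!is.null(cfg$reference_fa)) {
    read_reference_fasta(cfg$reference_fa)
  } else NULL
  results <- list()

  cons <- NULL
  if (!is.null(cfg$callers)) {
    callsets <- lapply(names(cfg$callers), function(lab) {
      read_caller_vcf(cfg$callers[[lab]], lab, reference = reference,
                      chrom_style = cfg$chrom_style)
    })
    names(callsets) <- names(cfg$callers)
    n_in <- sum(vapply(callsets, nrow, 1L))
    cons <- merge_callsets(callsets, k = cfg$k)
    record("consensus", n_in, nrow(cons))
    cons <- apply_depth_filter(cons, cfg$min_depth)
    record("depth", manifest$stages$consensus$n_out, nrow(cons))
    if (!is.null(cfg$targets_bed)) {
      targets <- read_targets(cfg$targets_bed, cfg$chrom_style)
      cons <- restrict_to_targets(cons, targets)
      record("on_target", manifest$stages$depth$n_out, nrow(cons))
    }
    out_paths$consensus_vcf <- file.path(cfg$out, "consensus.vcf")
    write_consensus_vcf(cons, out_paths$consensus_vcf)
    results$consensus <- cons
    if (!is.null(cfg$truth_vcf)) {
      truth <- read_truth_vcf(cfg$truth_vcf, reference = reference,
                              chrom_style = cfg$chrom_style)
      rep_ <- benchmark_report(callsets, truth, k = cfg$k)
      out_paths$benchmark_tsv <- file.path(cfg$out, "benchmark.tsv")
      fwrite(rep_, out_paths$benchmark_tsv, sep = "\t")
      results$benchmark <- rep_
      say("benchmark: consensus sensitivity %.4f, precision %.4f",
          rep_[.N, sensitivity], rep_[.N, precision])
    }
  }

  variants <- if (!is.null(cons)) consensus_variants(cons)
  else if (!is.null(cfg$scores_tsv)) {
    s <- read_score_table(unlist(cfg$scores_tsv), cfg$chrom_style)
    s[!is.na(chrom) & !is.na(pos) & !is.na(ref) & !is.na(alt),
      .(chrom, pos, ref, alt, id, hgvs)]
  } else NULL

  prioritized <- NULL
  if (!is.null(variants) && !is.null(cfg$scores_tsv)) {
    scores <- read_score_table(unlist(cfg$scores_tsv), cfg$chrom_style)
    ann <- annotate_scores(variants, scores)
    if (!is.null(cfg$gene_models)) {
      models <- read_gene_models(cfg$gene_models,
                                 chrom_style = cfg$chrom_style)
      ann <- classify_region(ann, models)
    }
    if (!is.null(cfg$peaks_bed)) {
      peaks <- read_tf_peaks(cfg$peaks_bed, cfg$chrom_style)
      ann <- tfbs_overlap(ann, peaks)
      ann[, tf_hits := NULL]
    }
    record("annotate", nrow(variants), nrow(ann))
    out_paths$annotated_tsv <- file.path(cfg$out, "annotated.tsv")
    fwrite(ann, out_paths$annotated_tsv, sep = "\t")
    thr <- do.call(threshold_config, cfg$thresholds)
    prioritized <- partition_by_tools(ann, thr)
    if (log == "debug") {
      for (i in seq_len(nrow(prioritized))) {
        say("  %s -> {%s} tier %d", variant_key(prioritized[i]),
            prioritized$toolset[i], prioritized$tier[i])
      }
    }
    record("prioritize", nrow(ann), sum(prioritized$toolset != ""))
    # tier-1 block first; unprioritized (tier 0) rows last
    prioritized[, .ord := fifelse(tier == 0L, 4L, tier)]
    setorder(prioritized, .ord, chrom, pos)
    prioritized[, .ord := NULL]
    out_paths$prioritized_tsv <- file.path(cfg$out, "prioritized.tsv")
    fwrite(prioritized, out_paths$prioritized_tsv, sep = "\t")
    vp <- venn_partition(prioritized)
    out_paths$venn_tsv <- file.path(cfg$out, "venn_counts.tsv")
    fwrite(data.table(toolset = names(vp$counts), n = vp$counts),
           out_paths$venn_tsv, sep = "\t")
    results$prioritized <- prioritized
    results$venn <- vp
  }

  if (!is.null(cfg$cohort_tsv) && !is.null(cfg$scores_tsv)) {
    g <- read_cohort_genotypes(cfg$cohort_tsv)
    scores <- read_score_table(unlist(cfg$scores_tsv), cfg$chrom_style)
    enr <- enrichment_table(g, scores, fold_min = cfg$fold_min,
                            reference = cfg$reference_pop)
    record("enrichment", nrow(g$variants), sum(enr$enriched, na.rm = TRUE))
    out_paths$enrichment_tsv <- file.path(cfg$out, "enrichment.tsv")
    fwrite(enr, out_paths$enrichment_tsv, sep = "\t")
    results$enrichment <- enr
    if (!is.null(prioritized)) {
      cand <- copy(prioritized)
      cand[, key := variant_key(cand)]
      if (!"region" %in% names(cand)) cand[, region := NA_character_]
      if (!"gene" %in% names(cand)) cand[, gene := NA_character_]
      ch <- find_compound_het(
        g, cand[, .(key, gene, region, clinical_class, tier)])
      out_paths$compound_het_tsv <- file.path(cfg$out, "compound_het.tsv")
      fwrite(ch, out_paths$compound_het_tsv, sep = "\t")
      results$compound_het <- ch
    }
  }

  if (!is.null(cfg$pedigrees)) {
    results$segregation <- list()
    for (p in unlist(cfg$pedigrees)) {
      ped <- read_pedigree(p)
      seg <- segregation_summary(ped)
      key <- sprintf("segregation_%s_tsv", ped$family)
      out_paths[[key]] <- file.path(
        cfg$out, sprintf("segregation_family_%s.tsv", ped$family))
      write_segregation_tsv(seg, out_paths[[key]])
      results$segregation[[ped$family]] <- seg
      say("family %s: monogenic=%s digenic=%s", ped$family,
          seg$monogenic_consistent, seg$digenic_consistent)
    }
  }

  stages <- manifest$stages
  filt <- c("consensus", "depth", "on_target")
  for (st in intersect(filt, names(stages))) {
    if (stages[[st]]$n_out > stages[[st]]$n_in) {
      stop("manifest invariant violated: stage ", st, " grew", call. = FALSE)
    }
  }
  jsonlite::write_json(manifest, out_paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  out <- list(paths = out_paths, results = results, manifest = manifest)
  invisible(out)
}
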