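cohort_fixture <- function() {
  read_cohort_genotypes(ext_file("cohort_genotypes_synthetic.tsv"))
}

all_scores <- function() {
  read_score_table(c(ext_file("intronic_scores.tsv"),
                     ext_file("exonic_variants.tsv")))
}

test_that("allele frequencies follow the allele-counting rules", {
  g <- cohort_fixture()
  af <- cohort_allele_frequency(g)
  # 6 het among 16 diploid probands
  expect_equal(af[key == "chr10:1201267:T:C", af], 6 / 32)
  expect_equal(af[key == "chr10:1201267:T:C", carriers], 6L)
  # 1 het among 16
  expect_equal(af[key == "chr7:1300584:T:G", af], 1 / 32)
  # hom counts two alleles: 11 hom + 5 het = 27/32
  expect_equal(af[key == "chr10:1801964:G:C", af], 27 / 32)
  # X-linked: 1 male hemi + 2 female het over 8 + 16 alleles
  expect_equal(af[key == "chrX:1097377:C:T", af], 3 / 24)
  expect_equal(af[key == "chrX:1097377:C:T", called_alleles], 24L)
})

test_that("X-linked AF uses hemizygous males: 1 hemi among 8M+8F is 1/24", {
  samples <- data.table(sample = sprintf("S%02d", 1:16),
                        sex = rep(c("male", "female"), each = 8))
  geno <- matrix("hom_ref", 16, 1,
                 dimnames = list(samples$sample, "chrX:100:A:G"))
  geno["S01", 1] <- "hemi"
  g <- cohort_genotypes(samples, geno,
                        data.table(chrom = "chrX", pos = 100L, ref = "A",
                                   alt = "G")[, key := "chrX:100:A:G"])
  expect_equal(cohort_allele_frequency(g)$af, 1 / 24)
})

test_that("AF edge cases: no carriers, missing genotypes, all missing", {
  samples <- data.table(sample = c("A", "B"), sex = c("male", "female"))
  vt <- data.table(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  vt[, key := "chr1:1:A:G"]
  mk <- function(gts) {
    cohort_genotypes(samples,
                     matrix(gts, 2, 1,
                            dimnames = list(samples$sample, vt$key)), vt)
  }
  expect_equal(cohort_allele_frequency(mk(c("hom_ref", "hom_ref")))$af, 0)
  # missing drops out of the denominator
  expect_equal(cohort_allele_frequency(mk(c("het", "missing")))$af, 1 / 2)
  expect_error(cohort_allele_frequency(mk(c("missing", "missing"))),
               "undefined")
  expect_error(cohort_genotypes(samples,
                                matrix(c("hemi", "hom_ref"), 2, 1,
                                       dimnames = list(samples$sample,
                                                       vt$key)), vt),
               "hemizygous")
})

test_that("fold enrichment handles ratios, zeros and domain errors", {
  expect_equal(fold_enrichment(0.1875, 0.06)$fold, 3.125)
  expect_equal(fold_enrichment(0.05, 0.05)$fold, 1)
  inf <- fold_enrichment(0.03, 0)
  expect_true(is.infinite(inf$fold) && inf$infinite)
  deg <- fold_enrichment(0, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$fold, 1)
  expect_error(fold_enrichment(-0.1, 0.5), "non-negative")
  expect_true(is.na(fold_enrichment(0.1, NA)$fold))
})

test_that("enrichment flags exactly the >= 3-fold variants", {
  enr <- enrichment_table(cohort_fixture(), all_scores())
  expect_equal(enr[key == "chr10:1201267:T:C", fold_1000g], 3.125)
  expect_true(enr[key == "chr10:1201267:T:C", enriched])
  expect_false(enr[key == "chr10:3002127:G:A", enriched])
  tier1 <- c("chr10:1097891:A:C", "chr10:1201267:T:C", "chr15:1000772:T:C",
             "chr2:1501872:T:C", "chr2:1100163:C:T", "chr7:1300584:T:G")
  expect_equal(sum(enr[key %in% tier1, enriched]), 2L)
})

test_that("compound-het detection finds the two documented probands", {
  g <- cohort_fixture()
  scores <- all_scores()
  ann <- annotate_scores(g$variants, scores)
  models <- read_gene_models(ext_file("gene_models_synthetic.bed12"))
  ann <- classify_region(ann, models)
  pri <- partition_by_tools(ann)
  pri[, key := variant_key(pri)]
  ch <- find_compound_het(g, pri[, .(key, gene, region, clinical_class,
                                     tier)])
  expect_equal(sort(ch$sample), c("P06", "P15"))
  expect_equal(unique(ch$exonic_gene), "MYBPC3")
  expect_equal(unique(ch$intronic_gene), "VCL")
  expect_equal(unique(ch$intronic_key), "chr10:1201267:T:C")
})

test_that("a sample carrying a single candidate yields no pair", {
  samples <- data.table(sample = "S1", sex = "male")
  keys <- c("chr1:1:A:G", "chr1:2:C:T")
  geno <- matrix(c("het", "hom_ref"), 1, 2,
                 dimnames = list("S1", keys))
  vt <- data.table(chrom = "chr1", pos = 1:2, ref = c("A", "C"),
                   alt = c("G", "T"))
  vt[, key := keys]
  g <- cohort_genotypes(samples, geno, vt)
  cand <- data.table(gene = c("G1", "G2"),
                     region = c("exonic", "deep_intronic"),
                     clinical_class = c("pathogenic", "unclassified"),
                     tier = c(NA_integer_, 1L))
  cand[, key := keys]
  expect_equal(nrow(find_compound_het(g, cand)), 0L)
})

test_that("compound-het detection equals brute-force pair enumeration", {
  set.seed(77)
  for (rep in 1:50) {
    n_s <- sample(3:8, 1); n_v <- sample(4:10, 1)
    samples <- data.table(sample = sprintf("S%d", 1:n_s),
                          sex = sample(c("male", "female"), n_s, TRUE))
    keys <- sprintf("chr1:%d:A:G", seq_len(n_v))
    geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                          n_s * n_v, TRUE, prob = c(.4, .35, .15, .1)),
                   n_s, n_v, dimnames = list(samples$sample, keys))
    vt <- data.table(chrom = "chr1", pos = seq_len(n_v), ref = "A",
                     alt = "G")
    vt[, key := keys]
    g <- cohort_genotypes(samples, geno, vt)
    is_ex <- seq_len(n_v) <= n_v / 2
    cand <- data.table(
      gene = sprintf("G%d", seq_len(n_v)),
      region = ifelse(is_ex, "exonic", "deep_intronic"),
      clinical_class = sample(c("pathogenic", "likely_pathogenic", "VUS"),
                              n_v, TRUE),
      tier = sample(c(0:3, NA), n_v, TRUE))
    cand[, key := keys]
    got <- find_compound_het(g, cand)
    setorder(got, sample, exonic_key, intronic_key)
    want <- oracle_compound_het(
      geno,
      cand[clinical_class %in% c("pathogenic", "likely_pathogenic"), key],
      cand[!is.na(tier) & tier == 1L, key])
    expect_equal(got[, .(sample, exonic_key, intronic_key)], want,
                 ignore_attr = TRUE)
  }
})

test_that("family 6 segregates digenically, not monogenically", {
  seg <- segregation_summary(read_pedigree(ext_file("family6.ped.tsv")))
  expect_true(seg$digenic_consistent)
  expect_false(seg$monogenic_consistent)
  cnt <- dcast(seg$counts, carrier_class ~ phenotype, value.var = "n")
  expect_equal(cnt[carrier_class == "both", affected], 2L)
  expect_equal(cnt[carrier_class == "both", unaffected], 0L)
  expect_equal(cnt[carrier_class == "first_only", affected], 0L)
  expect_equal(cnt[carrier_class == "first_only", unaffected], 2L)
  expect_equal(cnt[carrier_class == "neither", unaffected], 2L)
})

test_that("family 15 segregates monogenically", {
  seg <- segregation_summary(read_pedigree(ext_file("family15.ped.tsv")))
  expect_true(seg$monogenic_consistent)
  expect_true(is.na(seg$digenic_consistent))  # single tracked variant
  cnt <- dcast(seg$counts, carrier_class ~ phenotype, value.var = "n")
  expect_equal(cnt[carrier_class == "carrier", affected], 3L)
})

test_that("all-unknown phenotypes give indeterminate flags; untyped excluded", {
  tmp <- tempfile()
  writeLines(c(paste("family", "individual", "father", "mother", "sex",
                     "phenotype", "v1", sep = "\t"),
               "f\tA\t0\t0\tmale\tunknown\tcarrier_het",
               "f\tB\t0\t0\tfemale\tunknown\tnoncarrier",
               "f\tC\t0\t0\tfemale\taffected\tuntyped"), tmp)
  seg <- segregation_summary(read_pedigree(tmp))
  expect_true(is.na(seg$monogenic_consistent))
  expect_equal(seg$untyped, "C")
  expect_equal(sum(seg$counts$n), 2L)
})
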