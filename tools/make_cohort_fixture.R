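# Regenerates inst/extdata/cohort_genotypes_synthetic.tsv.
# Genotype configuration: the minimal composition consistent with each
# published proband allele frequency (n/32 for autosomes) and the stated
# carrier counts; X-linked variants follow the hemizygous-male ploidy rule.
suppressMessages(library(data.table))

samples <- sprintf("P%02d", 1:16)
male <- c("P01", "P02", "P05", "P06", "P07", "P08", "P13", "P16")
sex <- ifelse(samples %in% male, "male", "female")

het <- list(
  "chr10:1097891:A:C" = "P03",
  "chr10:1201267:T:C" = c("P01", "P04", "P06", "P09", "P12", "P15"),
  "chr15:1000772:T:C" = "P05",
  "chr2:1501872:T:C" = "P07",
  "chr2:1100163:C:T" = "P02",
  "chr7:1300584:T:G" = "P10",
  "chr10:1001465:C:T" = c("P02", "P05", "P08", "P11", "P14"),
  "chr10:1092729:C:T" = "P13",
  "chr10:1104899:C:A" = c("P03", "P16"),
  "chr10:3002127:G:A" = sprintf("P%02d", 1:8),
  "chr10:3102514:C:T" = "P09",
  "chr10:3102593:C:T" = "P11",
  "chr12:1000904:C:T" = "P12",
  "chr7:1155754:T:G" = c("P01", "P03", "P06", "P09", "P14", "P16"),
  "chr7:1070059:C:T" = c("P04", "P13"),
  "chrX:1097415:A:G" = "P09",
  "chrX:1097377:C:T" = c("P10", "P11"),
  "chr2:1701401:G:A" = c("P01", "P02", "P04", "P07", "P10", "P13", "P16"),
  "chrX:1200461:A:G" = "P14",
  "chr10:1801964:G:C" = sprintf("P%02d", 12:16),
  "chr10:5000539:G:T" = "P06",
  "chr2:1000617:T:C" = "P08",
  "chr2:1200315:G:T" = c("P05", "P15"),
  "chr2:1301311:A:G" = c("P03", "P06", "P09", "P12", "P15"),
  "chr2:1401531:C:G" = c("P07", "P14"),
  "chr2:1202615:A:C" = "P16",
  # exonic / splice-site screen
  "chr1:1100350:G:C" = "P01",
  "chr11:1300882:G:A" = "P02",
  "chr2:1802450:C:G" = "P05",
  "chr11:1401188:G:A" = "P06",
  "chr15:3000062:G:T" = "P07",
  "chr11:1601850:C:T" = "P08",
  "chr15:3200641:A:G" = "P12",
  "chr14:1100392:G:A" = c("P14", "P16"),
  "chrX:3000187:T:A" = "P14",
  "chr11:1401250:G:A" = "P15")
hom <- list(
  "chr7:1155754:T:G" = "P08",
  "chr10:1801964:G:C" = sprintf("P%02d", 1:11))
hemi <- list(
  "chrX:1097377:C:T" = "P01")

keys <- names(het)
geno <- matrix("hom_ref", length(samples), length(keys),
               dimnames = list(samples, keys))
for (k in keys) geno[het[[k]], k] <- "het"
for (k in names(hom)) geno[hom[[k]], k] <- "hom_alt"
for (k in names(hemi)) geno[hemi[[k]], k] <- "hemi"

d <- data.table(sample = samples, sex = sex)
d <- cbind(d, as.data.table(geno))
fwrite(d, "inst/extdata/cohort_genotypes_synthetic.tsv", sep = "\t")
cat("wrote", nrow(d), "samples x", length(keys), "variants\n")
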