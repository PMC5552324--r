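test_that("gvariants enforces allele invariants", {
  v <- gvariants("chr1", 100, "A", "G", id = "rs1")
  expect_s3_class(v, "gvariants")
  expect_error(gvariants("chr1", 100, "A", "A"), "identical")
  expect_error(gvariants("chr1", 100, "N", "G"), "A/C/G/T")
  expect_error(gvariants("chr1", 100, "", "G"), "A/C/G/T")
})

test_that("SNVs are already canonical under normalization", {
  n <- normalize_allele(100, "A", "G")
  expect_equal(n, list(pos = 100L, ref = "A", alt = "G"))
})

test_that("a mid-run deletion left-aligns to the run start (oracle)", {
  # context GTTTTC starting at position 11; delete one T spelled mid-run
  ctx <- "GTTTTC"
  v <- normalize_allele(13, "TT", "T", context = ctx, context_start = 11)
  o <- oracle_normalize(ctx, 3, "TT", "T")
  expect_equal(v$pos - 10L, o$pos)
  expect_equal(v$ref, o$ref)
  expect_equal(v$alt, o$alt)
  expect_equal(v$pos, 11L)  # anchored at the G before the T-run? no: run start
})

test_that("normalization matches the exhaustive-equivalence oracle on random indels", {
  set.seed(41)
  n_cases <- 150
  for (i in seq_len(n_cases)) {
    ctx <- random_seq(60)
    pos <- sample(5:50, 1)
    if (runif(1) < 0.5) {  # deletion
      len <- sample(1:3, 1)
      ref <- substr(ctx, pos, pos + len)
      alt <- substr(ctx, pos, pos)
    } else {               # insertion
      ref <- substr(ctx, pos, pos)
      alt <- paste0(ref, random_seq(sample(1:3, 1), runs = FALSE))
    }
    if (ref == alt) next
    got <- normalize_allele(pos, ref, alt, context = ctx, context_start = 1)
    want <- oracle_normalize(ctx, pos, ref, alt)
    expect_equal(got[c("pos", "ref", "alt")], want,
                 info = sprintf("case %d: %d %s>%s in %s", i, pos, ref, alt,
                                ctx))
    # every equivalent trimmed spelling normalizes to the same tuple
    for (eq in oracle_equivalents(ctx, pos, ref, alt)) {
      renorm <- normalize_allele(eq$pos, eq$ref, eq$alt, context = ctx,
                                 context_start = 1)
      expect_equal(renorm[c("pos", "ref", "alt")], want)
    }
  }
})

test_that("normalization is idempotent on random indels", {
  set.seed(42)
  for (i in 1:1000) {
    ctx <- random_seq(50)
    pos <- sample(5:40, 1)
    if (runif(1) < 0.5) {
      ref <- substr(ctx, pos, pos + sample(1:3, 1))
      alt <- substr(ctx, pos, pos)
    } else {
      ref <- substr(ctx, pos, pos)
      alt <- paste0(ref, random_seq(sample(1:3, 1), runs = FALSE))
    }
    if (ref == alt) next
    once <- normalize_allele(pos, ref, alt, ctx, 1)
    twice <- normalize_allele(once$pos, once$ref, once$alt, ctx, 1)
    expect_identical(once, twice)
  }
})

test_that("normalization rejects a ref/context mismatch", {
  expect_error(normalize_allele(3, "AA", "A", context = "GGGGG",
                                context_start = 1),
               "reference inconsistency")
})

test_that("same_variant is allele-exact and demands trimmed input", {
  a <- gvariants("chr1", 100, "A", "G")
  expect_true(same_variant(a, gvariants("chr1", 100, "A", "G")))
  expect_false(same_variant(a, gvariants("chr1", 100, "A", "T")))
  expect_false(same_variant(a, gvariants("chr2", 100, "A", "G")))
  untrimmed <- data.table(chrom = "chr1", pos = 100L, ref = "AT", alt = "GT")
  expect_error(same_variant(untrimmed, a), "normalized")
  # two spellings of one homopolymer deletion agree after normalization
  ctx <- "GAAAAC"  # delete one A
  s1 <- normalize_allele(2, "AA", "A", ctx, 1)
  s2 <- normalize_allele(4, "AA", "A", ctx, 1)
  expect_true(same_variant(
    gvariants("chr1", s1$pos, s1$ref, s1$alt),
    gvariants("chr1", s2$pos, s2$ref, s2$alt)))
})

test_that("read_caller_vcf extracts genotype and depth", {
  p <- make_vcf_file("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:35",
                     samples = "S1")
  obs <- read_caller_vcf(p, "toolA")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$genotype, "het")
  expect_equal(obs$depth, 35L)
  expect_equal(obs$caller, "toolA")
})

test_that("multiallelic records split into one observation per alt allele", {
  p <- make_vcf_file("chr1\t200\trs9\tCT\tC,CTT\t50\tPASS\t.\tGT:DP\t1/2:28",
                     samples = "S1")
  obs <- read_caller_vcf(p, "toolA")
  expect_equal(nrow(obs), 2L)
  expect_equal(unique(obs$chrom), "chr1")
  expect_setequal(obs$genotype, "het")  # one copy of each alt
  # allele count conservation over random multiallelic files
  set.seed(7)
  for (rep in 1:20) {
    n_rec <- sample(1:6, 1)
    recs <- vapply(seq_len(n_rec), function(i) {
      n_alt <- sample(1:3, 1)
      alts <- paste(sample(c("A", "C", "G", "T"), n_alt), collapse = ",")
      sprintf("chr1\t%d\t.\tN\t%s\t.\tPASS\t.\tGT:DP\t0/1:30",
              i * 10, alts)
    }, "")
    # N is invalid; substitute a fixed ref not colliding with alts
    recs <- gsub("\tN\t", "\tT\t", recs)
    alts_per <- vapply(strsplit(vapply(strsplit(recs, "\t"), `[[`, "", 5),
                                ","), length, 1L)
    obs <- suppressWarnings(
      read_caller_vcf(make_vcf_file(recs, "S1"), "x"))
    expect_equal(nrow(obs), sum(alts_per))
  }
})

test_that("missing DP loads as depth 0 and malformed records name lines", {
  p <- make_vcf_file("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
                     samples = "S1")
  expect_equal(read_caller_vcf(p, "x")$depth, 0L)
  bad <- make_vcf_file(c("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:10",
                         "chr1\tBAD\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:10"),
                       samples = "S1")
  expect_error(read_caller_vcf(bad, "x"), "line 6")
  short <- make_vcf_file("chr1\t100\t.\tA", samples = "S1")
  expect_error(read_caller_vcf(short, "x"), "malformed VCF record at line 5")
})

test_that("VCF round-trip write-then-read reproduces observations", {
  set.seed(11)
  obs <- random_observations(40, "toolA", c("S1", "S2", "S3"))
  obs <- obs[genotype %in% c("het", "hom_alt")]
  obs <- unique(obs, by = c("sample", "chrom", "pos", "ref", "alt"))
  p <- tempfile(fileext = ".vcf")
  write_observations_vcf(obs, p, samples = c("S1", "S2", "S3"))
  back <- read_caller_vcf(p, "toolA")
  back <- back[genotype != "hom_ref"]
  cols <- c("sample", "chrom", "pos", "ref", "alt", "genotype", "depth")
  setorderv(obs, cols); setorderv(back, cols)
  expect_equal(as.data.frame(back[, ..cols]), as.data.frame(obs[, ..cols]))
})

test_that("lean VCF reader agrees with VariantAnnotation on a mixed fixture", {
  skip_if_not_installed("VariantAnnotation")
  recs <- c("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:35\t0/0:40",
            "chr1\t200\trs1\tCT\tC,CTT\t50\tPASS\t.\tGT:DP\t1/2:28\t0/1:22",
            "chr1\t300\t.\tG\tT\t50\tPASS\t.\tGT:DP\t./.:.\t1/1:60")
  p <- make_vcf_file(recs, samples = c("S1", "S2"))
  got <- read_caller_vcf(p, "x")
  vcf <- VariantAnnotation::readVcf(p, genome = "toy")
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  # spot-check against the oracle's parse
  expect_equal(unname(gt["chr1:100_A/G", "S1"]), "0/1")
  expect_equal(got[pos == 100 & sample == "S1", genotype], "het")
  expect_equal(got[pos == 100 & sample == "S1", depth],
               unname(dp["chr1:100_A/G", "S1"]))
  expect_equal(got[pos == 300 & sample == "S1", genotype], "missing")
  expect_equal(got[pos == 300 & sample == "S2", genotype], "hom_alt")
  # multiallelic: S1 1/2 carries one copy of each alt
  expect_equal(got[pos == 200 & sample == "S1", genotype], c("het", "het"))
})

test_that("pedigree fixtures load with expected structure", {
  p6 <- read_pedigree(ext_file("family6.ped.tsv"))
  expect_equal(nrow(p6$members), 6L)
  expect_equal(sum(p6$members$phenotype == "affected"), 2L)
  expect_equal(ncol(p6$carriers), 2L)
  p15 <- read_pedigree(ext_file("family15.ped.tsv"))
  expect_equal(nrow(p15$members), 3L)
  expect_equal(sum(p15$members$phenotype == "affected"), 3L)
  expect_true(all(p15$carriers[, 1] == "carrier_het"))
})

test_that("pedigree reader rejects structural errors", {
  empty <- tempfile(); file.create(empty)
  expect_error(read_pedigree(empty), "empty")
  bad <- tempfile()
  writeLines(c("family\tindividual\tfather\tmother\tsex\tphenotype",
               "1\tII-1\tI-9\t0\tmale\taffected"), bad)
  expect_error(read_pedigree(bad), "I-9")
})

test_that("BED half-open and VCF 1-based conversions round-trip", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", bed)
  gr <- read_targets(bed)
  expect_equal(GenomicRanges::start(gr), 100L)  # first covered 1-based base
  expect_equal(GenomicRanges::end(gr), 200L)    # last covered 1-based base
  # gene models: BED12 <-> exon table round-trip
  m <- read_gene_models(ext_file("gene_models_synthetic.bed12"))
  out <- tempfile(fileext = ".bed12")
  write_gene_models_bed12(m, out)
  m2 <- read_gene_models(out)
  setkey(m, gene, start); setkey(m2, gene, start)
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("BED12 gene-model parsing agrees with rtracklayer", {
  skip_if_not_installed("rtracklayer")
  m <- read_gene_models(ext_file("gene_models_synthetic.bed12"))
  gr <- rtracklayer::import(ext_file("gene_models_synthetic.bed12"),
                            format = "bed")
  bl <- rtracklayer::blocks(gr)
  vcl <- as.data.frame(bl[[which(gr$name == "VCL")]])
  got <- m[gene == "VCL"]
  expect_equal(got$start + 1L, vcl$start)  # GRanges 1-based closed
  expect_equal(got$end, vcl$end)
})

test_that("GFF3 gene models load equivalently to BED12", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr9\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1;gene=DEMO",
               "chr9\tsrc\texon\t1001\t1100\t.\t+\t.\tParent=g1;gene=DEMO",
               "chr9\tsrc\texon\t1501\t1600\t.\t+\t.\tParent=g1;gene=DEMO"),
             gff)
  m <- read_gene_models(gff)
  expect_equal(m$start, c(1000L, 1500L))  # 0-based half-open
  expect_equal(m$end, c(1100L, 1600L))
  expect_equal(unique(m$gene), "DEMO")
})

test_that("chromosome-name dialects reconcile", {
  expect_equal(normalize_chrom(c("chr1", "2", "chrX"), "strip"),
               c("1", "2", "X"))
  expect_equal(normalize_chrom(c("chr1", "2"), "add"), c("chr1", "chr2"))
  p <- make_vcf_file("10\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:30", "S1")
  expect_equal(read_caller_vcf(p, "x", chrom_style = "add")$chrom, "chr10")
})
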