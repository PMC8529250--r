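toy_callset <- function() {
  variants <- data.frame(
    key = c("chr1:100_A/G", "chr1:200_C/T", "chrX:50_G/A"),
    chrom = c("chr1", "chr1", "chrX"),
    pos = c(100L, 200L, 50L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    filter_build_a = c("PASS", "PASS", "PASS"),
    filter_build_b = c("PASS", "LowQual", "PASS"),
    stringsAsFactors = FALSE)
  dosage <- matrix(c(0L, 1L, 2L, 1L,
                     0L, 0L, 1L, NA,
                     1L, 0L, 2L, 1L), nrow = 3, byrow = TRUE)
  gq <- matrix(99L, 3, 4)
  ploidy <- matrix(2L, 3, 4)
  samples <- c("S1", "S2", "S3", "S4")
  colnames(dosage) <- colnames(gq) <- colnames(ploidy) <- samples
  new_callset(variants, dosage, gq, ploidy, samples)
}

toy_samples <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                          sex = c("male", "female", "female", "male"),
                          age = c(40, 50, 60, 70), stringsAsFactors = FALSE)

test_that("variant_key serializes and parses the chrom:pos_ref/alt form", {
  expect_equal(variant_key("chr2", 21232683, "G", "A"), "chr2:21232683_G/A")
  parsed <- parse_variant_key("chr2:21232683_G/A")
  expect_equal(parsed$chrom, "chr2")
  expect_equal(parsed$pos, 21232683L)
  expect_equal(parsed$ref, "G")
  expect_equal(parsed$alt, "A")
  # round trip on indel alleles
  k <- variant_key("chr6", 129204285, "TC", "T")
  p <- parse_variant_key(k)
  expect_equal(variant_key(p$chrom, p$pos, p$ref, p$alt), k)
  expect_error(parse_variant_key("not-a-key"))
})

test_that("consensus filter requires PASS in both builds and GQ 99 on carriers", {
  cs <- toy_callset()
  cs$gq[3, 1] <- 80L  # a carrier genotype below the GQ floor on site 3
  res <- apply_consensus_filter(cs, gq_required = 99)
  expect_equal(n_variants(res$callset), 1L)
  expect_equal(res$callset$variants$key, "chr1:100_A/G")
  expect_setequal(res$rejections$key, c("chr1:200_C/T", "chrX:50_G/A"))
  expect_equal(res$rejections$reason[res$rejections$key == "chr1:200_C/T"],
               "build_b")
  expect_equal(res$rejections$reason[res$rejections$key == "chrX:50_G/A"],
               "GQ")
  # low GQ on a homozygous-reference genotype does not reject the site
  cs2 <- toy_callset()
  cs2$gq[1, 1] <- 10L  # S1 dosage is 0 at site 1
  res2 <- apply_consensus_filter(cs2, gq_required = 99)
  expect_true("chr1:100_A/G" %in% res2$callset$variants$key)
})

test_that("site counts honor missingness and the sex-aware chrX policy", {
  cs <- toy_callset()
  cnt <- compute_site_counts(cs, toy_samples, chrx_policy = "sex_aware")
  # autosomal site 1: all called, AN = 8
  expect_equal(cnt$an[1], 8L)
  expect_equal(cnt$ac[1], 4L)
  # site 2: one missing genotype reduces AN by 2
  expect_equal(cnt$an[2], 6L)
  expect_equal(cnt$ac[2], 1L)
  # chrX: males contribute one allele, hemizygous dosage capped at 1
  # S1 male (1 -> 1 of 1), S2 female (0 of 2), S3 female (2 of 2), S4 male (1 of 1)
  expect_equal(cnt$an[3], 1L + 2L + 2L + 1L)
  expect_equal(cnt$ac[3], 1L + 0L + 2L + 1L)
  # diploid policy counts everyone as two alleles
  cnt_d <- compute_site_counts(cs, toy_samples, chrx_policy = "diploid")
  expect_equal(cnt_d$an[3], 8L)
  expect_equal(cnt$af, cnt$ac / cnt$an)
})

test_that("VCF round trip preserves keys, dosages, GQ, and filter statuses", {
  sim <- small_sim()
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_callset(sim$callset, file.path(dir, "c.vcf"), file.path(dir, "f.tsv"))
  back <- read_callset(file.path(dir, "c.vcf"), file.path(dir, "f.tsv"))
  expect_equal(back$variants$key, sim$callset$variants$key)
  expect_equal(unname(back$dosage), unname(sim$callset$dosage))
  expect_equal(unname(back$gq), unname(sim$callset$gq))
  expect_equal(back$variants$filter_build_a, sim$callset$variants$filter_build_a)
  expect_equal(back$variants$filter_build_b, sim$callset$variants$filter_build_b)
  expect_equal(back$samples, sim$callset$samples)
})

test_that("multi-allelic records decompose into one key per alternate allele", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG,T\t.\t.\t.\tGT:GQ\t0/1:99\t1/2:99"), vcf)
  flt <- file.path(dir, "f.tsv")
  writeLines(c("variant_key\tfilter_build_a\tfilter_build_b",
               "chr1:100_A/G\tPASS\tPASS",
               "chr1:100_A/T\tPASS\tPASS"), flt)
  cs <- read_callset(vcf, flt)
  expect_setequal(cs$variants$key, c("chr1:100_A/G", "chr1:100_A/T"))
  dg <- cs$dosage[match("chr1:100_A/G", cs$variants$key), ]
  dt <- cs$dosage[match("chr1:100_A/T", cs$variants$key), ]
  # S2 is 1/2: one G allele and one T allele; other alts count as ref
  expect_equal(unname(dg), c(1L, 1L))
  expect_equal(unname(dt), c(0L, 1L))
})

test_that("missing sidecar filter rows are a hard error naming the variant", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  sim <- small_sim()
  write_callset(sim$callset, file.path(dir, "c.vcf"), file.path(dir, "f.tsv"))
  flt <- read.delim(file.path(dir, "f.tsv"), stringsAsFactors = FALSE)
  dropped <- flt$variant_key[1]
  write.table(flt[-1, ], file.path(dir, "f.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_callset(file.path(dir, "c.vcf"), file.path(dir, "f.tsv")),
               dropped, fixed = TRUE)
})

test_that("annotation reader validates enums and normalizes ClinVar strings", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  path <- file.path(dir, "ann.tsv")
  hdr <- paste(c("variant_key", "gene", "consequence", "truncation_confidence",
                 "sift", "polyphen", "rsid", "in_second_cohort",
                 "clinvar_class", "max_af", "ref_nfe_ac", "ref_nfe_an"),
               collapse = "\t")
  row1 <- "chr1:1_A/G\tG1\tmissense\tnot_applicable\tdeleterious\tprobably_damaging\trs1\tTRUE\tPathogenic/Likely_pathogenic\t0.001\t5\t100000"
  writeLines(c(hdr, row1), path)
  ann <- read_annotations(path)
  expect_equal(ann$clinvar_class, "likely_pathogenic")
  # unknown enum value is a hard error with the line number
  writeLines(c(hdr, sub("missense", "weird_csq", row1)), path)
  expect_error(read_annotations(path), "weird_csq")
  # ac > an is rejected
  writeLines(c(hdr, sub("5\t100000", "9\t8", row1)), path)
  expect_error(read_annotations(path), "ac > an")
})
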