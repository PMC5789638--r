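test_that("VCF genotypes map to the four-state code and round-trip exactly", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1\t12345\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
           "chr2\t500\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1|0",
           "1\t99999\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t./0")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f, "array", verbose = FALSE)
  expect_equal(dim(gm), c(3L, 3L))
  # sorted by chrom then pos; "chr" prefix stripped
  expect_equal(gm$sites$chrom, c(1L, 1L, 2L))
  expect_equal(gm$sites$pos, c(12345L, 99999L, 500L))
  expect_equal(gm$geno[1, ], c(s1 = 1L, s2 = 0L, s3 = 2L))
  # phased treated as unphased; half-missing is missing
  expect_equal(gm$geno[3, ], c(s1 = NA_integer_, s2 = 1L, s3 = 1L))
  expect_equal(gm$geno[2, ], c(s1 = 2L, s2 = 0L, s3 = NA_integer_))
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f2)
  gm2 <- read_vcf(f2, "array", verbose = FALSE)
  expect_identical(gm2$geno, gm$geno)
  expect_identical(gm2$sites[c("chrom", "pos", "ref", "alt")],
                   gm$sites[c("chrom", "pos", "ref", "alt")])
})

test_that("non-autosomal, multi-allelic and non-SNP records are skipped with a count", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1"), collapse = "\t"),
           "1\t100\ta\tA\tG\t.\t.\t.\tGT\t0/1",
           "X\t200\tb\tA\tG\t.\t.\t.\tGT\t0/1",
           "1\t300\tc\tA\tG,T\t.\t.\t.\tGT\t0/1",
           "1\t400\td\tAT\tA\t.\t.\t.\tGT\t0/1",
           "23\t500\te\tA\tG\t.\t.\t.\tGT\t0/1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(gm <- read_vcf(f, "wgs"), "skipped 2 .* 2 ")
  expect_equal(nrow(gm$sites), 1L)
  expect_equal(gm$sites$pos, 100L)
})

test_that("PED/MAP allele pairs map to the four-state code", {
  map <- c("1\trs1\t0\t1000", "1\trs2\t0\t2000", "1\trs3\t0\t3000")
  # ind1: A/A (hom major), A/G het, 0/0 missing
  # ind2: A/A, G/A het (order-free), C/C (C is the only observed allele at
  # rs3, so it becomes the reference under the major-allele rule)
  ped <- c("f1\tind1\t0\t0\t1\t0\tA A\tA G\t0 0",
           "f2\tind2\t0\t0\t2\t0\tA A\tG A\tC C")
  fm <- withr::local_tempfile(fileext = ".map")
  fp <- withr::local_tempfile(fileext = ".ped")
  writeLines(map, fm); writeLines(ped, fp)
  gm <- read_ped_map(fp, fm, "array")
  expect_equal(gm$individuals, c("ind1", "ind2"))
  expect_equal(unname(gm$geno[1, ]), c(0L, 0L))     # A is (only) major allele
  expect_equal(unname(gm$geno[2, ]), c(1L, 1L))     # het regardless of order
  expect_equal(unname(gm$geno[3, ]), c(NA_integer_, 0L))  # "0 0" missing
  expect_equal(gm$sites$id, c("rs1", "rs2", "rs3"))
  # explicit reference alleles override the major-allele rule
  gm2 <- read_ped_map(fp, fm, "array", ref_alleles = c("A", "A", "A"))
  expect_equal(unname(gm2$geno[3, ]), c(NA_integer_, 2L))
})

test_that("PED column-count mismatch is fatal with both counts reported", {
  fm <- withr::local_tempfile(fileext = ".map")
  fp <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1\trs1\t0\t1000", "1\trs2\t0\t2000"), fm)
  writeLines("f1\tind1\t0\t0\t1\t0\tA A", fp)
  expect_error(read_ped_map(fp, fm), "8 columns|implies 10")
})

test_that("hom table writes PLINK-style rows and round-trips a callset", {
  segs <- data.frame(iid = c("a", "a", "b"), chrom = c(1L, 2L, 1L),
                     start = c(1000001L, 5000L, 200L),
                     end = c(2000000L, 900000L, 600199L),
                     nsnp = c(500L, 120L, 60L), nhet = c(1L, 0L, 2L))
  cs <- roh_callset(segs, roh_params(), channel = "wgs",
                    individuals = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".hom")
  write_hom_table(cs, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("IID", "CHR", "POS1", "POS2", "KB", "NSNP", "NHET"))
  expect_equal(tab$KB[tab$POS1 == 1000001], 1000.000)
  cs2 <- read_hom_table(f, roh_params(), channel = "wgs",
                        individuals = cs$individuals)
  expect_equal(cs2$segments, cs$segments)
  # empty callset -> header-only file
  cs0 <- roh_callset(segs[0, ], roh_params(), individuals = "a")
  f0 <- withr::local_tempfile(fileext = ".hom")
  write_hom_table(cs0, f0)
  expect_equal(length(readLines(f0)), 1L)
  expect_equal(nrow(read_hom_table(f0, individuals = "a")$segments), 0L)
})

test_that("the container enforces its invariants", {
  expect_error(make_gm(c(0L, 3L)), "codes")
  sites <- data.frame(chrom = c(1L, 1L), pos = c(100L, 100L),
                      id = c("a", "b"), ref = "A", alt = "G")
  expect_error(genotype_matrix(matrix(0L, 2, 1), sites, "i1", "array"),
               "duplicate")
  sites$pos <- c(100L, 50L)   # unsorted input is sorted on construction
  gm <- genotype_matrix(matrix(c(0L, 1L), 2, 1), sites, "i1", "array")
  expect_equal(gm$sites$pos, c(50L, 100L))
  expect_equal(gm$geno[, 1], c(1L, 0L), ignore_attr = TRUE)
  expect_error(genotype_matrix(matrix(0L, 1, 1),
                               data.frame(chrom = 1L, pos = 10L, id = "x",
                                          ref = "A", alt = "A"),
                               "i1", "array"), "differ")
  segs <- data.frame(iid = "a", chrom = 1L, start = c(100L, 500L),
                     end = c(600L, 900L), nsnp = c(10L, 10L), nhet = c(0L, 0L))
  expect_error(roh_callset(segs), "overlapping")
})
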