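write_lines <- function(lines, file) writeLines(lines, file)

test_that("population table reads, validates and parses neighbor sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("population_id\tlatitude\tlongitude\tgroup\tneighbor_set",
                "A\t50.5\t40.2\tfocal\tB,C",
                "B\t51.0\t41.0\tneighbor\t",
                "C\t49.9\t39.5\tneighbor\t"), f)
  pt <- read_population_table(f)
  expect_s3_class(pt, "pop_table")
  expect_equal(nrow(pt), 3)
  expect_equal(pt$neighbor_set[[1]], c("B", "C"))
  expect_equal(pt$neighbor_set[[2]], character(0))
})

test_that("population table errors name the offending row or id", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("population_id\tlatitude\tlongitude",
                "A\t50\t40", "B\t91\t41"), f)
  expect_error(read_population_table(f), "row 2")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("population_id\tlatitude\tlongitude\tneighbor_set",
                "A\t50\t40\tZZ", "B\t51\t41\t"), f2)
  expect_error(read_population_table(f2), "ZZ")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("population_id\tlatitude\tlongitude",
                "A\t50\t40", "A\t51\t41"), f3)
  expect_error(read_population_table(f3), "duplicate")

  expect_error(pop_table("A", 50, 40, neighbor_set = list("A")),
               "itself")
})

test_that("IBD segments read with canonical pair order and computed lengths", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_a\tsample_b\tchromosome\tstart_cM\tend_cM",
                "s2\ts1\t1\t10\t12.5",
                "s1\ts3\t2\t5\t6.1",
                "s3\ts2\t1\t50\t51.2"), f)
  pt <- pop_table(c("A", "B"), c(50, 51), c(40, 41))
  smap <- c(s1 = "A", s2 = "A", s3 = "B")
  seg <- read_ibd_segments(f, pt, smap)
  expect_equal(nrow(seg), 3)
  expect_true(all(seg$sample_a < seg$sample_b))
  expect_equal(seg$length_cM, seg$end_cM - seg$start_cM, tolerance = 1e-9)
  # row 1 was given reversed: population labels must follow the swap
  r1 <- seg[seg$sample_a == "s1" & seg$sample_b == "s2", ]
  expect_equal(r1$population_a, "A")

  # degenerate segment
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_a\tsample_b\tchromosome\tstart_cM\tend_cM",
                "s1\ts2\t1\t10\t10"), f2)
  expect_error(read_ibd_segments(f2, pt, smap), "row 1")
  # unknown sample
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_a\tsample_b\tchromosome\tstart_cM\tend_cM",
                "s1\tzz\t1\t10\t11"), f3)
  expect_error(read_ibd_segments(f3, pt, smap), "zz")
})

test_that("write_table round-trips values and renders zero p-values", {
  df <- data.frame(id = c("x", "y"), p_value = c(0, 0.123456789012345),
                   val = c(1.5, -2.25e-7), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$p_value, df$p_value, tolerance = 1e-10)
  expect_equal(back$val, df$val, tolerance = 1e-10)
  lines <- readLines(f)
  expect_match(lines[2], "\t0\t")  # p = 0 rendered, not blank

  # empty result set: header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(df[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})

test_that("segment write/read is idempotent on canonical tables", {
  sim <- make_injected_network(delta = 0, n_per_pop = 3L, seed = 4,
                               pops = make_scan_world(2, 2, seed = 2))
  seg <- sim$segments[seq_len(min(50, nrow(sim$segments))), ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(seg[, c("sample_a", "sample_b", "chromosome",
                      "start_cM", "end_cM")], f)
  back <- read_ibd_segments(f, sim$pops, sim$sample_map)
  expect_equal(back$sample_a, seg$sample_a)
  expect_equal(back$length_cM, seg$length_cM, tolerance = 1e-9)
})

test_that("genetic map interpolation is linear between anchors", {
  f <- withr::local_tempfile(fileext = ".map")
  write_lines(c("1\trs1\t0.0\t1000", "1\trs2\t2.0\t3000",
                "2\trs3\t0.0\t500", "2\trs4\t1.0\t1500"), f)
  gm <- read_genetic_map(f)
  expect_s3_class(gm, "genetic_map")
  expect_equal(interpolate_cM(gm, "1", 2000), 1.0)
  expect_equal(interpolate_cM(gm, c("1", "2"), c(1000, 1000)), c(0, 0.5))
  expect_error(interpolate_cM(gm, "3", 100), "chromosome 3")
})

test_that("matrix genotypes validate dosages and attach map positions", {
  mat_f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_id\tsnpA\tsnpB",
                "i1\t0\t2", "i2\t1\t-1", "i3\t2\t0"), mat_f)
  snps <- data.frame(id = c("snpA", "snpB"), chromosome = "1",
                     pos_bp = c(1000, 3000), stringsAsFactors = FALSE)
  map_f <- withr::local_tempfile(fileext = ".map")
  write_lines(c("1\trs1\t0.0\t1000", "1\trs2\t2.0\t3000"), map_f)
  g <- read_genotypes(mat_f, "matrix",
                      sample_map = c(i1 = "P1", i2 = "P1", i3 = "P2"),
                      map = read_genetic_map(map_f), snp_table = snps)
  expect_equal(dim(g), c(3L, 2L))
  expect_true(is.na(g$dosage["i2", "snpB"]))
  expect_equal(g$snps$pos_cM, c(0, 2))

  bad_f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("sample_id\tsnpA", "i1\t3"), bad_f)
  expect_error(read_genotypes(bad_f, "matrix",
                              sample_map = c(i1 = "P1"), snp_table = snps),
               "row 1, column 1")
})

test_that("VCF genotypes load biallelic SNPs and skip multi-allelic records", {
  vcf_f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "i1", "i2", sep = "\t"))
  rows <- c(paste("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
                  "0/1", "1/1", sep = "\t"),
            paste("1", "200", "rs2", "C", "T,G", ".", ".", ".", "GT",
                  "0/1", "0/2", sep = "\t"),
            paste("1", "300", "rs3", "G", "A", ".", ".", ".", "GT",
                  "./.", "0/0", sep = "\t"))
  writeLines(c(hdr, rows), vcf_f)
  expect_message(
    g <- read_genotypes(vcf_f, "vcf",
                        sample_map = c(i1 = "P1", i2 = "P1")),
    "skipped")
  expect_equal(dim(g), c(2L, 2L))          # rs2 dropped
  expect_equal(unname(g$dosage["i1", "rs1"]), 1)
  expect_equal(unname(g$dosage["i2", "rs1"]), 2)
  expect_true(is.na(g$dosage["i1", "rs3"]))
})
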