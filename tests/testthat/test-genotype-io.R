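write_ped_fixture <- function(ped_lines, map_lines) {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

test_that("PED/MAP reading codes dosage as copies of the second-observed allele", {
  fx <- write_ped_fixture(
    c("f1 sample1 0 0 1 -9 A A G G",
      "f2 sample2 0 0 2 -9 A C G G"),
    c("1\tm1\t0\t100", "1\tm2\t0\t200"))
  g <- read_ped_map(fx$ped, fx$map)
  expect_equal(unname(g$dosage), matrix(c(0L, 1L, 0L, 0L), 2, 2))
  expect_equal(g$markers$allele_a, c("A", "G"))
  ## marker 2 is monomorphic in the file: allele_b unknown
  expect_equal(g$markers$allele_b, c("C", NA))
  expect_equal(g$samples$sex, c("male", "female"))
  ## within-pair allele order is irrelevant
  fx2 <- write_ped_fixture(
    c("f1 sample1 0 0 1 -9 A A G G",
      "f2 sample2 0 0 2 -9 C A G G"),
    c("1\tm1\t0\t100", "1\tm2\t0\t200"))
  expect_equal(read_ped_map(fx2$ped, fx2$map)$dosage, g$dosage)
})

test_that("a 0 0 allele pair reads as a missing call, others unchanged", {
  fx <- write_ped_fixture(
    c("f1 s1 0 0 1 -9 A A 0 0",
      "f2 s2 0 0 1 -9 A C G T"),
    c("1\tm1\t0\t100", "1\tm2\t0\t200"))
  g <- read_ped_map(fx$ped, fx$map)
  expect_true(is.na(g$dosage["s1", "m2"]))
  expect_equal(sum(is.na(g$dosage)), 1L)
  expect_equal(unname(g$dosage[, "m1"]), c(0L, 1L))
})

test_that("format errors name the problem", {
  fx <- write_ped_fixture(
    c("f1 s1 0 0 1 -9 A A G G T T"),
    c("1\tm1\t0\t100", "1\tm2\t0\t200"))
  expect_error(read_ped_map(fx$ped, fx$map), "6 marker columns.*2 markers")
  fx <- write_ped_fixture(
    c("f1 s1 0 0 1 -9 A A", "f2 s2 0 0 1 -9 A C", "f3 s3 0 0 1 -9 A T"),
    c("1\tm1\t0\t100"))
  expect_error(read_ped_map(fx$ped, fx$map), "third allele.*m1")
  fx <- write_ped_fixture(
    c("f1 s1 0 0 1 -9 A A", "f2 s1 0 0 1 -9 A A"),
    c("1\tm1\t0\t100"))
  expect_error(read_ped_map(fx$ped, fx$map), "duplicate sample")
})

test_that("PED/MAP round trip is the identity on random matrices", {
  for (seed in 1:20) {
    g <- random_genotype_matrix(seed, n = sample(2:8, 1),
                                m = sample(5:40, 1),
                                missing_rate = runif(1, 0, 0.2))
    ped <- tempfile(); map <- tempfile()
    write_ped_map(g, ped, map)
    g2 <- read_ped_map(ped, map)
    expect_identical(g2$dosage, g$dosage)
    expect_identical(g2$markers, g$markers)
    expect_identical(g2$samples, g$samples)
  }
})

test_that("one missing cell writes exactly one 0 0 pair; empty cohort writes a valid PED/MAP", {
  g <- random_genotype_matrix(5, n = 4, m = 10, missing_rate = 0)
  g$dosage[2, 3] <- NA_integer_
  g <- genotype_matrix(g$dosage, g$samples[, c("id", "sex")], g$markers)
  ped <- tempfile(); map <- tempfile()
  write_ped_map(g, ped, map)
  for (i in 1:4) {
    f <- strsplit(readLines(ped)[i], " ")[[1]]
    ## two "0" allele fields (one missing genotype) on row 2, none elsewhere
    expect_equal(sum(f[-(1:6)] == "0"), if (i == 2) 2L else 0L)
  }
  g0 <- subset_genotypes(g, samples = integer(0))
  write_ped_map(g0, ped, map)
  expect_equal(length(readLines(ped)), 0L)
  expect_equal(nrow(utils::read.table(map)), 10L)
  g2 <- read_ped_map(ped, map)
  expect_equal(n_samples(g2), 0L)
  expect_equal(n_markers(g2), 10L)
})

test_that("markers are sorted by chromosome then position with id tie-break", {
  g <- genotype_matrix(
    matrix(c(0L, 1L, 0L, 1L, 2L, 0L), 1),
    data.frame(id = "s1", sex = "male"),
    data.frame(id = c("b", "a", "c", "d", "e", "f"),
               chromosome = c("2", "2", "1", "X", "0", "10"),
               position_bp = c(5, 5, 9, 1, 1, 1),
               allele_a = "A", allele_b = "B"))
  expect_equal(g$markers$id, c("c", "a", "b", "f", "d", "e"))
  expect_equal(g$markers$chromosome, c("1", "2", "2", "10", "X", "0"))
})

write_vcf_fixture <- function(records,
                              samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

test_that("VCF genotypes map 0/0, 0/1, 1/1 and ./. onto dosages", {
  v <- write_vcf_fixture(
    "1\t1000\trs1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  g <- read_vcf(v)
  expect_equal(unname(g$dosage[, 1]), c(0L, 1L, 2L))
  v <- write_vcf_fixture(
    "1\t1000\trs1\tA\tC\t.\tPASS\t.\tGT:DP\t0|0:3\t1/0:2\t./.:0")
  g <- read_vcf(v)
  expect_equal(unname(g$dosage[, 1]), c(0L, 1L, NA))
})

test_that("VCF indel flag and error cases", {
  v <- write_vcf_fixture(
    "1\t1000\trs1\tA\tAT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  expect_true(read_vcf(v)$markers$is_indel[1])
  v <- write_vcf_fixture(
    "1\t2000\trs2\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  expect_error(read_vcf(v), "multiallelic record at 1:2000")
  v <- write_vcf_fixture(
    "1\t3000\trs3\tA\tC\t.\tPASS\t.\tDP\t3\t2\t1")
  expect_error(read_vcf(v), "no GT field")
})
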