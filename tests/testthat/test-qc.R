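gm_from_dosage <- function(d, sex = NULL, chrom = "1") {
  n <- nrow(d); m <- ncol(d)
  if (is.null(sex)) sex <- rep("female", n)
  genotype_matrix(
    d,
    data.frame(id = sprintf("s%02d", 1:n), sex = sex),
    data.frame(id = sprintf("m%03d", 1:m),
               chromosome = rep(chrom, length.out = m),
               position_bp = seq_len(m) * 1000L,
               allele_a = "A", allele_b = "B"),
    normalize = FALSE)
}

test_that("DST matches hand-computed identity-by-state sharing", {
  g <- gm_from_dosage(rbind(c(0L, 2L), c(0L, 2L)))
  expect_equal(pairwise_dst(g)[1, 2], 1.0)
  g <- gm_from_dosage(rbind(c(0L, 2L), c(2L, 0L)))
  expect_equal(pairwise_dst(g)[1, 2], 0.0)
  g <- gm_from_dosage(rbind(c(0L, 2L), c(0L, 1L)))
  expect_equal(pairwise_dst(g)[1, 2], 0.75)  # one IBS2 + one IBS1
  expect_error(pairwise_dst(subset_genotypes(g, samples = 1L)),
               "at least 2 samples")
})

test_that("DST equals the double-loop oracle under missingness", {
  for (seed in 1:5) {
    g <- random_genotype_matrix(seed, n = 12, m = 80, missing_rate = 0.15)
    expect_equal(pairwise_dst(g), naive_dst(g), tolerance = 1e-12)
  }
})

test_that("duplicate detection keeps the higher-call-rate member and resolves groups", {
  set.seed(99)
  base <- rbinom(1000, 2L, 0.4)
  d <- rbind(base, base, rbinom(1000, 2L, 0.4))
  d[2, sample(1000, 50)] <- NA  # duplicate with 5% missing
  storage.mode(d) <- "integer"
  g <- gm_from_dosage(d)
  dup <- find_duplicates(g)
  expect_equal(dup$pairs$id1, "s01")
  expect_equal(dup$pairs$id2, "s02")
  expect_equal(dup$pairs$retained, "s01")
  expect_equal(dup$remove, "s02")

  ## triple of mutual duplicates: one kept (lexicographic tie-break)
  d3 <- rbind(base, base, base)
  storage.mode(d3) <- "integer"
  dup3 <- find_duplicates(gm_from_dosage(d3))
  expect_equal(nrow(dup3$pairs), 3L)
  expect_equal(dup3$remove, c("s02", "s03"))

  ## similarity below the threshold is not flagged
  d2 <- rbind(base, base)
  d2[2, 1:80] <- (base[1:80] + 1L) %% 3L  # perturb 8% of the markers
  storage.mode(d2) <- "integer"
  g2 <- gm_from_dosage(d2)
  expect_lt(pairwise_dst(g2)[1, 2], 0.99)
  expect_equal(nrow(find_duplicates(g2)$pairs), 0L)
})

test_that("HWE exact test reproduces enumerated p-values", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1.0, tolerance = 1e-12)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)  # monomorphic
  expect_error(hwe_exact_test(-1, 0, 1), "non-negative")
})

test_that("HWE exact test agrees with the multinomial oracle on a sweep", {
  for (n in c(5L, 13L, 20L)) {
    for (na in 0:n) for (nh in 0:(n - na)) {
      nb <- n - na - nh
      expect_equal(hwe_exact_test(na, nh, nb), hwe_oracle(na, nh, nb),
                   tolerance = 1e-12)
    }
  }
})

test_that("apply_qc removes each violation class and reports marginal counts", {
  set.seed(21)
  n <- 60
  m <- 100
  p <- runif(m, 0.2, 0.5)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  chrom <- rep("1", m)
  ## disjoint violation classes by construction
  rare <- 1:5          # monomorphic -> MAF 0
  hwe_bad <- 6:8       # all-homozygote split, no hets
  lowcall <- 9:12      # 20% missing
  on_x <- 13:14
  indel <- 15
  d[, rare] <- 0L
  for (j in hwe_bad) d[, j] <- rep(c(0L, 2L), length.out = n)
  for (j in lowcall) d[sample(n, 12), j] <- NA
  chrom[on_x] <- "X"
  g <- genotype_matrix(
    d,
    data.frame(id = sprintf("s%02d", 1:n), sex = "female"),
    data.frame(id = sprintf("m%03d", 1:m), chromosome = chrom,
               position_bp = seq_len(m) * 1000L,
               allele_a = ifelse(seq_len(m) == indel, "I", "A"),
               allele_b = ifelse(seq_len(m) == indel, "D", "B")),
    normalize = FALSE)
  res <- apply_qc(g)
  expect_equal(unname(res$report$excluded["maf"]), 5L)
  expect_equal(unname(res$report$excluded["hwe"]), 3L)
  expect_equal(unname(res$report$excluded["marker_callrate"]), 4L)
  expect_equal(unname(res$report$excluded["chrX"]), 2L)
  expect_equal(unname(res$report$excluded["chrY"]), 0L)
  expect_equal(unname(res$report$excluded["chr0"]), 0L)
  expect_equal(unname(res$report$excluded["indel"]), 1L)
  expect_equal(res$report$n_markers_kept, 85L)

  ## idempotence: a second pass removes nothing
  res2 <- apply_qc(res$genotypes)
  expect_equal(res2$report$n_markers_kept, 85L)
  expect_true(all(res2$report$excluded == 0L))
  expect_identical(res2$genotypes$dosage, res$genotypes$dosage)
})

test_that("MAF exactly at the floor is retained (strict less-than rule)", {
  ## 50 samples, one heterozygote -> MAF = 1/100 = 0.01
  d <- matrix(0L, 50, 3)
  d[1, 1] <- 1L
  d[, 2] <- rep(c(0L, 1L, 1L, 2L), length.out = 50)  # near-HWE marker
  d[, 3] <- rep(c(0L, 1L, 2L, 1L, 0L), 10)
  g <- gm_from_dosage(d)
  res <- apply_qc(g)
  expect_equal(unname(res$report$excluded["maf"]), 0L)
  expect_true("m001" %in% res$genotypes$markers$id)
})

test_that("a chromosome X marker is removed regardless of other statistics", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L), 10), 40, 2)
  g <- gm_from_dosage(d, chrom = c("X", "1"))
  res <- apply_qc(g)
  expect_equal(res$genotypes$markers$chromosome, "1")
  expect_equal(unname(res$report$excluded["chrX"]), 1L)
})

test_that("removing every marker yields an empty matrix with a warning", {
  d <- matrix(0L, 10, 4)  # all monomorphic
  g <- gm_from_dosage(d)
  expect_warning(res <- apply_qc(g), "every marker")
  expect_equal(n_markers(res$genotypes), 0L)
  expect_equal(res$report$n_markers_kept, 0L)
})
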