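test_that("IBS distance complements DST and handles the boundary cases", {
  d <- rbind(c(0L, 2L), c(0L, 1L))
  g <- genotype_matrix(d, data.frame(id = c("a", "b"), sex = "female"),
                       data.frame(id = c("m1", "m2"), chromosome = "1",
                                  position_bp = c(1L, 2L),
                                  allele_a = "A", allele_b = "B"),
                       normalize = FALSE)
  expect_equal(ibs_distance(g)["a", "b"], 0.25)
  expect_equal(diag(ibs_distance(g)), c(a = 0, b = 0))
  d2 <- rbind(c(0L, 2L), c(0L, 2L))
  g2 <- genotype_matrix(d2, g$samples[, c("id", "sex")], g$markers,
                        normalize = FALSE)
  expect_equal(ibs_distance(g2)["a", "b"], 0)
  d3 <- rbind(c(0L, 0L), c(2L, 2L))
  g3 <- genotype_matrix(d3, g$samples[, c("id", "sex")], g$markers,
                        normalize = FALSE)
  expect_equal(ibs_distance(g3)["a", "b"], 1)
})

test_that("IBS and G agree with naive double-loop oracles", {
  for (seed in 1:3) {
    g <- random_genotype_matrix(seed, n = 20, m = 500, missing_rate = 0.05)
    expect_equal(ibs_distance(g), 1 - naive_dst(g), tolerance = 1e-12)
    expect_equal(unname(diag(ibs_distance(g))), rep(0, 20))
    expect_equal(grm_vanraden(g)$G, naive_grm(g), tolerance = 1e-12)
  }
})

test_that("single-marker VanRaden G matches the closed-form example", {
  d <- matrix(c(0L, 2L), 2, 1)
  g <- genotype_matrix(d, data.frame(id = c("a", "b"), sex = "female"),
                       data.frame(id = "m1", chromosome = "1",
                                  position_bp = 1L,
                                  allele_a = "A", allele_b = "B"),
                       normalize = FALSE)
  G <- grm_vanraden(g, freqs = 0.5)$G
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2, 2))
})

test_that("G is centred with in-sample frequencies and scales to ~1 diagonal under HWE", {
  set.seed(31)
  n <- 200; m <- 2000
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  g <- genotype_matrix(
    d, data.frame(id = sprintf("s%03d", 1:n), sex = "female"),
    data.frame(id = sprintf("m%04d", 1:m), chromosome = "1",
               position_bp = 1:m, allele_a = "A", allele_b = "B"),
    normalize = FALSE)
  grm <- grm_vanraden(g)
  expect_equal(max(abs(colSums(grm$G))), 0, tolerance = 1e-8)
  expect_gt(mean(diag(grm$G)), 0.95)
  expect_lt(mean(diag(grm$G)), 1.05)
  ## a sample sitting exactly at 2p everywhere has a zero row
  expect_error(grm_vanraden(subset_genotypes(g, markers = integer(0))),
               "monomorphic|one frequency")
})

test_that("coding flips leave IBS unchanged and G unchanged under consistent flips", {
  g <- random_genotype_matrix(7, n = 10, m = 60, missing_rate = 0)
  flip <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  d2 <- g$dosage
  d2[, flip] <- 2L - d2[, flip]
  g2 <- genotype_matrix(d2, g$samples[, c("id", "sex")], g$markers,
                        normalize = FALSE)
  expect_equal(ibs_distance(g), ibs_distance(g2), tolerance = 1e-12)
  p <- colSums(g$dosage) / (2 * nrow(g$dosage))
  p2 <- ifelse(flip, 1 - p, p)
  expect_equal(grm_vanraden(g, freqs = p)$G, grm_vanraden(g2, freqs = p2)$G,
               tolerance = 1e-12)
})

test_that("simulated parent-offspring and half-sib pairs land at the expected G", {
  po <- c(); hs <- c()
  for (s in 1:5) {
    cfg <- halfsib_config(900 + s, n_fam = 3, n_off = 5, n_other = 2,
                          n_chromosomes = 4, markers_per_chromosome = 800)
    sim <- simulate_cohort(cfg)
    ## relationships on the founder-population scale need base-population
    ## frequencies, which the simulation truth provides
    G <- grm_vanraden(sim$genotypes,
                      freqs = sim$truth$markers$founder_freq)$G
    for (f in 1:3) {
      kids <- grep(paste0("^C", f, "_"), rownames(G), value = TRUE)
      po <- c(po, G[paste0("B", f), kids])
      if (length(kids) > 1) {
        Gk <- G[kids, kids]
        hs <- c(hs, Gk[upper.tri(Gk)])
      }
    }
  }
  expect_equal(mean(po), 0.5, tolerance = 0.1)   # ~0.5 +- 0.05 absolute
  expect_lt(abs(mean(po) - 0.5), 0.05)
  expect_lt(abs(mean(hs) - 0.25), 0.05)
})

test_that("PCA reproduces G spectrally and separates duplicate clusters", {
  set.seed(41)
  base1 <- rbinom(300, 2L, 0.3)
  base2 <- rbinom(300, 2L, 0.7)
  d <- rbind(base1, base1, base1, base2, base2, base2)
  storage.mode(d) <- "integer"
  g <- genotype_matrix(
    d, data.frame(id = sprintf("s%d", 1:6), sex = "female"),
    data.frame(id = sprintf("m%03d", 1:300), chromosome = "1",
               position_bp = 1:300, allele_a = "A", allele_b = "B"),
    normalize = FALSE)
  grm <- grm_vanraden(g)
  pca <- grm_pca(grm)
  expect_equal(sum(pca$eigenvalues), sum(diag(grm$G)), tolerance = 1e-8)
  ## within-cluster coordinates identical, PC1 separates the clusters
  expect_lt(max(abs(pca$coordinates[1, ] - pca$coordinates[2, ])), 1e-6)
  expect_gt(abs(pca$coordinates[1, 1] - pca$coordinates[4, 1]), 0.1)
  ## full-rank reconstruction
  Ghat <- tcrossprod(pca$coordinates)
  expect_equal(unname(Ghat), unname(grm$G), tolerance = 1e-8)
  expect_error(grm_pca(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
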