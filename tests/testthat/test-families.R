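test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-12)
  ## pendant branch lengths a=1, b=2, c=3
  tip_len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d_bad <- d; d_bad[1, 2] <- 9
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ exactly recovers random additive trees", {
  for (seed in 1:25) {
    set.seed(seed)
    true <- ape::unroot(ape::rtree(8, br = function(n) runif(n, 0.1, 2)))
    d <- ape::cophenetic.phylo(true)
    got <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(got, true, method = "PH85")), 0)
    cp <- ape::cophenetic.phylo(got)
    expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-9)
  }
})

test_that("two identical leaves join first with zero pendant branches", {
  set.seed(77)
  true <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.5, 2)))
  d <- ape::cophenetic.phylo(true)
  ids <- c(rownames(d), "t1b")
  d2 <- rbind(cbind(d, d[, "t1"]), c(d["t1", ], 0))
  dimnames(d2) <- list(ids, ids)
  tr <- nj_tree(d2)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["t1", "t1b"], 0, tolerance = 1e-12)
})

test_that("Newick serialisation round-trips and quotes reserved labels", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A B", "B", "C:x"), c("A B", "B", "C:x")))
  tr <- nj_tree(d)
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  expect_match(nwk, "'A B'", fixed = TRUE)
  expect_match(nwk, "'C:x'", fixed = TRUE)
  back <- ape::read.tree(text = nwk)
  ## ape keeps the quotes of quoted labels; strip them before comparing
  q <- grepl("^'.*'$", back$tip.label)
  back$tip.label[q] <- gsub("''", "'",
                            sub("^'(.*)'$", "\\1", back$tip.label[q]))
  expect_setequal(back$tip.label, tr$tip.label)
  cp1 <- ape::cophenetic.phylo(tr)
  cp2 <- ape::cophenetic.phylo(back)
  expect_equal(cp2[rownames(cp1), colnames(cp1)], cp1, tolerance = 1e-9)
})

test_that("family construction follows the kinship rule on a constructed G", {
  ids <- c("A", "B", "C", "x", "y")
  G <- matrix(-0.01, 5, 5, dimnames = list(ids, ids))
  diag(G) <- 1
  G["A", "B"] <- G["B", "A"] <- 0.3
  G["A", "x"] <- G["x", "A"] <- 0.26
  G["y", "A"] <- G["A", "y"] <- 0.02
  sex <- setNames(c("male", "male", "male", "female", "female"), ids)
  fam <- build_families(G, sex, threshold = 0.1)
  expect_equal(length(fam$families), 2L)
  expect_setequal(fam$families[[1]]$bulls, c("A", "B"))
  expect_equal(fam$families[[1]]$cows, "x")
  expect_equal(fam$families[[2]]$bulls, "C")
  expect_equal(fam$other, "y")

  ## three bulls mutually >= threshold form one family
  G3 <- matrix(0.3, 3, 3, dimnames = list(ids[1:3], ids[1:3]))
  diag(G3) <- 1
  fam3 <- build_families(G3, sex[1:3], threshold = 0.1)
  expect_equal(length(fam3$families), 1L)
  expect_setequal(fam3$families[[1]]$bulls, c("A", "B", "C"))

  ## cows below threshold everywhere go to "other"
  expect_true("y" %in% fam$assignments$id[fam$assignments$family == "other"])
  expect_error(build_families(G, setNames(rep("female", 5), ids)),
               "no bulls")
  expect_error(build_families(G, sex[1:4]), "sex label")
})

test_that("raising the threshold only refines families, never merges them", {
  set.seed(55)
  n <- 8
  ids <- paste0("b", 1:n)
  M <- matrix(runif(n * n, -0.05, 0.4), n, n)
  G <- (M + t(M)) / 2
  diag(G) <- 1
  dimnames(G) <- list(ids, ids)
  sex <- setNames(rep("male", n), ids)
  prev <- build_families(G, sex, threshold = 0.05)$assignments$family
  for (thr in c(0.1, 0.2, 0.3)) {
    cur <- build_families(G, sex, threshold = thr)$assignments$family
    ## every family at the higher threshold is contained in one family
    ## at the lower threshold
    for (f in unique(cur)) {
      expect_equal(length(unique(prev[cur == f])), 1L)
    }
    prev <- cur
  }
})

test_that("families recovered from simulated half-sib structure match truth", {
  cfg <- halfsib_config(321, n_fam = 3, n_off = 8, n_other = 4,
                        n_chromosomes = 5, markers_per_chromosome = 1000)
  sim <- simulate_cohort(cfg)
  fam <- build_families(grm_vanraden(sim$genotypes), sim$genotypes$samples)
  acc <- family_accuracy(fam, sim$truth$samples, paste0("B", 1:3))
  expect_gte(acc, 0.95)
})
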