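## Independent brute-force oracles used to validate the package's
## implementations, plus small fixture generators. Everything here is
## deliberately naive: full enumeration and double loops, no shared code
## with the package internals.

## ---- Hardy-Weinberg: full multinomial enumeration ----
## Enumerate every genotype-count triple (a, h, b) with a + h + b = N,
## compute its HWE multinomial probability at the observed allele
## frequency, condition on the observed allele count, and sum the
## probabilities of outcomes no more likely than the observed one.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  tri <- expand.grid(a = 0:n, h = 0:n)
  tri <- tri[tri$a + tri$h <= n, ]
  tri$b <- n - tri$a - tri$h
  n_allele_a <- 2 * n_aa + n_ab
  if (n_allele_a == 0 || n_allele_a == 2 * n) return(1)
  p <- n_allele_a / (2 * n)
  coef <- factorial(n) / (factorial(tri$a) * factorial(tri$h) *
                          factorial(tri$b))
  prob <- coef * p^(2 * tri$a + tri$h) * (1 - p)^(tri$h + 2 * tri$b) *
          2^tri$h
  same_class <- (2 * tri$a + tri$h) == n_allele_a
  prob <- prob[same_class] / sum(prob[same_class])
  h <- tri$h[same_class]
  obs <- prob[h == n_ab]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

## ---- ROH: naive rule-by-rule scanner ----
## Direct translation of the scanning rules with explicit loops.
roh_oracle <- function(d, pos, p) {
  m <- length(d)
  w <- p$window_snp
  if (m < w) return(data.frame(start_bp = integer(), end_bp = integer(),
                               n_snps = integer(), length_bp = integer()))
  nwin <- m - w + 1
  winhom <- logical(nwin)
  for (k in seq_len(nwin)) {
    win <- d[k:(k + w - 1)]
    winhom[k] <- sum(win == 1L, na.rm = TRUE) <= p$window_het_max &&
                 sum(is.na(win)) <= p$window_missing_max
  }
  in_run <- logical(m)
  for (i in seq_len(m)) {
    ks <- max(1, i - w + 1):min(i, nwin)
    in_run[i] <- mean(winhom[ks]) > p$window_hit_fraction
  }
  hom <- !is.na(d) & d != 1L
  trim <- function(a, b) {
    while (a <= b && !hom[a]) a <- a + 1
    while (b >= a && !hom[b]) b <- b - 1
    if (a > b) NULL else c(a, b)
  }
  segs <- list()
  i <- 1
  while (i <= m) {
    if (!in_run[i]) { i <- i + 1; next }
    j <- i
    while (j < m && in_run[j + 1]) j <- j + 1
    t0 <- trim(i, j)
    if (!is.null(t0)) {
      ## split at gaps, walking marker by marker
      pieces <- list()
      a <- t0[1]
      for (q in t0[1]:t0[2]) {
        if (q > a && pos[q] - pos[q - 1] > p$max_gap_kb * 1000) {
          pieces[[length(pieces) + 1]] <- c(a, q - 1)
          a <- q
        }
      }
      pieces[[length(pieces) + 1]] <- c(a, t0[2])
      for (pc in pieces) {
        t1 <- trim(pc[1], pc[2])
        if (is.null(t1)) next
        n_snps <- t1[2] - t1[1] + 1
        len <- pos[t1[2]] - pos[t1[1]]
        if (n_snps >= p$min_snp && len >= p$min_length_kb * 1000 &&
            (len / 1000) / n_snps <= p$min_density_kb_per_snp)
          segs[[length(segs) + 1]] <- data.frame(
            start_bp = pos[t1[1]], end_bp = pos[t1[2]],
            n_snps = n_snps, length_bp = len)
      }
    }
    i <- j + 1
  }
  if (!length(segs)) return(data.frame(start_bp = integer(),
                                       end_bp = integer(),
                                       n_snps = integer(),
                                       length_bp = integer()))
  do.call(rbind, segs)
}

## one-sample genotype matrix on a single chromosome, for ROH tests
roh_gm <- function(d, pos, chrom = "1") {
  d <- matrix(as.integer(d), nrow = 1)
  genotype_matrix(
    d,
    data.frame(id = "s1", sex = "female"),
    data.frame(id = sprintf("m%04d", seq_along(pos)), chromosome = chrom,
               position_bp = as.integer(pos),
               allele_a = "A", allele_b = "B"),
    normalize = FALSE)
}

## random single-chromosome instance exercising the ROH scanner: HWE
## background with implanted homozygous stretches and missing calls
random_roh_instance <- function(seed, m = 500) {
  set.seed(seed)
  pos <- sort(sample.int(15e6, m))  # ~30 kb mean spacing
  p <- runif(m, 0.1, 0.5)
  d <- rbinom(m, 1L, p) + rbinom(m, 1L, p)
  n_tracts <- sample(0:3, 1)
  for (t in seq_len(n_tracts)) {
    a <- sample.int(m - 100, 1)
    b <- min(m, a + sample(60:300, 1))
    hom <- rbinom(b - a + 1, 1L, 0.5) * 2L
    ## sprinkle occasional hets/missing inside the tract
    noise <- runif(b - a + 1)
    hom[noise < 0.01] <- 1L
    d[a:b] <- hom
  }
  d[runif(m) < 0.02] <- NA
  list(d = as.integer(d), pos = pos)
}

## ---- pairwise similarity / relationship: double loops ----
naive_dst <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(d[i, ]) & !is.na(d[j, ])
    if (!any(ok)) next
    ibs2 <- sum(d[i, ok] == d[j, ok])
    ibs1 <- sum(abs(d[i, ok] - d[j, ok]) == 1)
    out[i, j] <- (ibs2 + 0.5 * ibs1) / sum(ok)
  }
  diag(out) <- 1
  dimnames(out) <- list(g$samples$id, g$samples$id)
  out
}

naive_grm <- function(g) {
  d <- g$dosage
  p <- sapply(seq_len(ncol(d)), function(j) {
    x <- d[, j][!is.na(d[, j])]
    if (!length(x)) return(NA_real_)
    sum(x) / (2 * length(x))
  })
  use <- which(!is.na(p) & p > 0 & p < 1)
  n <- nrow(d)
  G <- matrix(0, n, n)
  denom <- 2 * sum(p[use] * (1 - p[use]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in use) {
      zi <- if (is.na(d[i, k])) 0 else d[i, k] - 2 * p[k]
      zj <- if (is.na(d[j, k])) 0 else d[j, k] - 2 * p[k]
      s <- s + zi * zj
    }
    G[i, j] <- s / denom
  }
  dimnames(G) <- list(g$samples$id, g$samples$id)
  G
}

## ---- generic fixtures ----
random_genotype_matrix <- function(seed, n = 10, m = 50,
                                   missing_rate = 0.05,
                                   chroms = c("1", "2")) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.95)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  d[runif(n * m) < missing_rate] <- NA
  genotype_matrix(
    d,
    data.frame(id = sprintf("s%02d", 1:n),
               sex = rep(c("male", "female"), length.out = n)),
    data.frame(id = sprintf("m%03d", 1:m),
               chromosome = sample(chroms, m, replace = TRUE),
               position_bp = sample.int(5e7, m),
               allele_a = "A", allele_b = "B"))
}

## paternal half-sib pedigree: n_fam sires with n_off cow offspring each,
## plus n_other unrelated cows; dams unchipped
halfsib_config <- function(seed, n_fam = 3, n_off = 10, n_other = 5,
                           n_chromosomes = 5, markers_per_chromosome = 1000) {
  rows <- list()
  truth <- character()
  for (f in seq_len(n_fam)) {
    sire <- paste0("B", f)
    truth[sire] <- paste0("fam", f)
    for (k in seq_len(n_off)) {
      id <- paste0("C", f, "_", k)
      rows[[length(rows) + 1]] <- data.frame(
        child = id, sire = sire, dam = paste0("D", f, "_", k),
        child_sex = "female", stringsAsFactors = FALSE)
      truth[id] <- paste0("fam", f)
    }
  }
  ped <- do.call(rbind, rows)
  other <- paste0("CO", seq_len(n_other))
  truth[other] <- "other"
  attr(ped, "founders") <- data.frame(id = other, sex = "female",
                                      stringsAsFactors = FALSE)
  gids <- c(paste0("B", seq_len(n_fam)), ped$child, other)
  sim_config(seed = seed, n_chromosomes = n_chromosomes,
             markers_per_chromosome = markers_per_chromosome,
             pedigree = ped, family_truth = truth, genotyped_ids = gids)
}

## full-sib-mating pedigree: founder pair -> two full sibs -> n_off
## offspring with pedigree F = 0.25
fullsib_mating_pedigree <- function(n_quartet = 25, n_off = 4) {
  rows <- list()
  for (q in seq_len(n_quartet)) {
    s1 <- paste0("S", q); s2 <- paste0("D", q)
    rows[[length(rows) + 1]] <- data.frame(
      child = s1, sire = paste0("P", q, "s"), dam = paste0("P", q, "d"),
      child_sex = "male", stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      child = s2, sire = paste0("P", q, "s"), dam = paste0("P", q, "d"),
      child_sex = "female", stringsAsFactors = FALSE)
    for (k in seq_len(n_off))
      rows[[length(rows) + 1]] <- data.frame(
        child = paste0("O", q, "_", k), sire = s1, dam = s2,
        child_sex = "female", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## score family recovery against simulation truth, mapping each true
## family label to the discovered label of its sire
family_accuracy <- function(fam, truth, sires) {
  a <- fam$assignments
  sire_fam <- setNames(a$family[match(sires, a$id)],
                       truth$family[match(sires, truth$id)])
  expected <- ifelse(truth$family == "other", "other",
                     sire_fam[truth$family])
  mean(a$family[match(truth$id, a$id)] == expected)
}
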