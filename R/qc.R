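#' Quality-control thresholds
#'
#' Bundles the thresholds of the marker/sample QC stage. Defaults follow
#' standard SNP-array practice for livestock conservation panels: duplicates
#' at DST >= 0.99, markers dropped when MAF < 0.01, Hardy-Weinberg exact
#' p < 1e-6 or call rate < 0.90, samples dropped below 90% call rate;
#' sex-chromosome (X, Y), unplaced ("0") and insertion/deletion markers are
#' removed.
#'
#' @param dst_duplicate DST similarity at or above which two samples are
#'   treated as the same animal.
#' @param maf_min Minimum minor allele frequency (strict `<` removes).
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value.
#' @param marker_callrate_min Minimum per-marker call rate.
#' @param sample_callrate_min Minimum per-sample call rate.
#' @param autosomes Chromosome labels treated as autosomal.
#' @param drop_indels Drop insertion/deletion markers?
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(dst_duplicate = 0.99,
                          maf_min = 0.01,
                          hwe_p_min = 1e-6,
                          marker_callrate_min = 0.90,
                          sample_callrate_min = 0.90,
                          autosomes = cattle_autosomes(),
                          drop_indels = TRUE) {
  frac <- c(dst_duplicate, maf_min, hwe_p_min,
            marker_callrate_min, sample_callrate_min)
  if (any(frac < 0 | frac > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(dst_duplicate = dst_duplicate, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 marker_callrate_min = marker_callrate_min,
                 sample_callrate_min = sample_callrate_min,
                 autosomes = autosomes, drop_indels = drop_indels),
            class = "qc_thresholds")
}

#' Pairwise identity-by-state similarity (DST)
#'
#' For each sample pair, over markers where both calls are present:
#' `DST = (N_IBS2 + 0.5 N_IBS1) / N_valid`, where IBS2 counts markers with
#' identical dosage and IBS1 markers whose dosages differ by one. This equals
#' `1 - sum|d_i - d_j| / (2 N_valid)` and is computed by matrix products.
#' Pairs sharing no valid marker get `NA`.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @return A symmetric matrix with unit diagonal and sample ids as dimnames.
#' @export
pairwise_dst <- function(g) {
  if (n_samples(g) < 2L) stop("pairwise DST needs at least 2 samples")
  d <- g$dosage
  V <- (!is.na(d)) * 1
  X <- d; X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  ## sum over shared markers of |d_i - d_j|, via indicator decomposition:
  ## |a-b| = a + b - 2*min(a,b); with dosages in {0,1,2},
  ## min(a,b) = 1*(both>=1) + 1*(both==2)
  G1 <- (d >= 1L) * 1; G1[is.na(d)] <- 0
  G2 <- (d == 2L) * 1; G2[is.na(d)] <- 0
  Svalid <- V %*% t(V)
  Sx <- X %*% t(V)
  Sabs <- Sx + t(Sx) - 2 * (G1 %*% t(G1) + G2 %*% t(G2))
  dst <- 1 - Sabs / (2 * Svalid)
  dst[Svalid == 0] <- NA_real_
  diag(dst) <- 1
  dimnames(dst) <- list(g$samples$id, g$samples$id)
  dst
}

#' Detect duplicate samples
#'
#' Flags all unordered sample pairs with DST at or above the duplicate
#' threshold. Within each connected group of mutual duplicates, the sample
#' with the highest call rate is retained (ties broken by lexicographically
#' smaller id); all others are marked for removal.
#'
#' @param g A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @return A list with `pairs` (data frame: id1, id2, dst, retained) and
#'   `remove` (character vector of sample ids to drop).
#' @export
find_duplicates <- function(g, thr = qc_thresholds()) {
  dst <- pairwise_dst(g)
  ids <- g$samples$id
  n <- length(ids)
  hit <- which(upper.tri(dst) & !is.na(dst) & dst >= thr$dst_duplicate,
               arr.ind = TRUE)
  if (!nrow(hit)) {
    return(list(pairs = data.frame(id1 = character(), id2 = character(),
                                   dst = numeric(), retained = character(),
                                   stringsAsFactors = FALSE),
                remove = character()))
  }
  comp <- connected_components(n, hit)
  keep <- character(n)
  for (cc in unique(comp[hit])) {
    members <- which(comp == cc)
    cr <- g$samples$call_rate[members]
    best <- members[order(-cr, ids[members])][1L]
    keep[members] <- ids[best]
  }
  pairs <- data.frame(id1 = ids[hit[, 1L]], id2 = ids[hit[, 2L]],
                      dst = dst[hit], retained = keep[hit[, 1L]],
                      stringsAsFactors = FALSE)
  ord <- order(pairs$id1, pairs$id2)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  flagged <- unique(c(hit[, 1L], hit[, 2L]))
  remove <- ids[flagged][ids[flagged] != keep[flagged]]
  list(pairs = pairs, remove = sort(remove))
}

## connected components over n nodes given an edge matrix (2 columns),
## by breadth-first search
connected_components <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test of Hardy-Weinberg genotype proportions.
#' Conditional on the observed allele counts, the number of heterozygotes h
#' has probability proportional to `N! / (n_a! h! n_b!) * 2^h` over feasible
#' h of the correct parity; the p-value sums the probabilities of all
#' outcomes no more likely than the observed one (no mid-p correction).
#' Monomorphic markers return 1.
#'
#' @param n_hom_a Count of homozygotes for the first allele.
#' @param n_het Count of heterozygotes.
#' @param n_hom_b Count of homozygotes for the second allele.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  if (n_hom_a < 0 || n_het < 0 || n_hom_b < 0)
    stop("genotype counts must be non-negative")
  n <- n_hom_a + n_het + n_hom_b
  if (n == 0) stop("at least one genotyped individual is required")
  rare <- 2L * min(n_hom_a, n_hom_b) + n_het
  if (rare == 0L) return(1)
  h <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  ## log unnormalised probabilities of each feasible heterozygote count
  na <- (rare - h) / 2
  nb <- n - na - h
  logp <- h * log(2) - lfactorial(na) - lfactorial(h) - lfactorial(nb)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, h)]
  ## tolerance guards against ties split by floating-point rounding
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Apply marker and sample quality control
#'
#' Reproduces a standard chip-QC stage in a fixed order: (1) remove
#' duplicate samples (keeping the higher-call-rate member), (2) remove
#' samples below the sample call-rate floor, (3) on the surviving samples
#' compute per-marker statistics and drop markers that are non-autosomal,
#' insertion/deletions, below the MAF floor, out of Hardy-Weinberg
#' equilibrium, or below the marker call-rate floor. The report gives
#' MARGINAL per-rule counts (each rule evaluated independently on the
#' post-sample-QC marker set — rules may overlap, so the counts need not sum
#' to the number removed) plus the joint survivor count, mirroring the
#' layout of published chip-QC tables.
#'
#' @param g A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`).
#' @export
apply_qc <- function(g, thr = qc_thresholds()) {
  n_markers_total <- n_markers(g)
  n_samples_total <- n_samples(g)

  dup <- if (n_samples(g) >= 2L) find_duplicates(g, thr)
         else list(pairs = data.frame(), remove = character())
  keep_samples <- setdiff(g$samples$id, dup$remove)
  g1 <- subset_genotypes(g, samples = keep_samples)

  low_cr <- g1$samples$id[g1$samples$call_rate < thr$sample_callrate_min]
  if (length(low_cr))
    g1 <- subset_genotypes(g1, samples = setdiff(g1$samples$id, low_cr))

  st <- marker_qc_stats(g1, thr)
  fail_maf <- st$maf < thr$maf_min
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < thr$hwe_p_min
  fail_cr <- st$callrate < thr$marker_callrate_min
  on_x <- g1$markers$chromosome == "X"
  on_y <- g1$markers$chromosome == "Y"
  on_0 <- g1$markers$chromosome == "0"
  non_auto <- !(g1$markers$chromosome %in% thr$autosomes)
  indel <- g1$markers$is_indel

  keep <- !fail_maf & !fail_hwe & !fail_cr & !non_auto &
          !(thr$drop_indels & indel)
  g2 <- if (any(keep)) subset_genotypes(g1, markers = which(keep))
        else empty_marker_matrix(g1)
  if (!any(keep))
    warning("quality control removed every marker")

  report <- structure(list(
    n_markers_total = n_markers_total,
    n_samples_total = n_samples_total,
    excluded = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                 marker_callrate = sum(fail_cr),
                 chrX = sum(on_x), chrY = sum(on_y), chr0 = sum(on_0),
                 indel = if (thr$drop_indels) sum(indel) else 0L),
    n_markers_kept = sum(keep),
    duplicate_pairs = dup$pairs,
    samples_removed_duplicate = sort(dup$remove),
    samples_removed_callrate = sort(low_cr),
    n_samples_kept = n_samples(g2),
    thresholds = thr), class = "qc_report")
  list(genotypes = g2, report = report)
}

## per-marker MAF, callrate and HWE p-value (HWE on autosomal non-indel
## markers only, complete genotypes)
marker_qc_stats <- function(g, thr) {
  d <- g$dosage
  n_valid <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_valid, 1L))
  maf <- pmin(p, 1 - p)
  maf[n_valid == 0L] <- 0
  callrate <- n_valid / nrow(d)
  hwe_p <- rep(NA_real_, ncol(d))
  testable <- which(g$markers$chromosome %in% thr$autosomes &
                    !g$markers$is_indel & n_valid > 0L)
  for (j in testable) {
    dj <- d[, j]
    hwe_p[j] <- hwe_exact_test(sum(dj == 0L, na.rm = TRUE),
                               sum(dj == 1L, na.rm = TRUE),
                               sum(dj == 2L, na.rm = TRUE))
  }
  data.frame(maf = maf, callrate = callrate, hwe_p = hwe_p)
}

empty_marker_matrix <- function(g) {
  genotype_matrix(matrix(NA_integer_, n_samples(g), 0L),
                  g$samples[, c("id", "sex")],
                  g$markers[0L, , drop = FALSE])
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control summary\n")
  cat(sprintf("  %-45s %s\n", "Total number of SNPs", x$n_markers_total))
  lab <- c(maf = "SNP with MAF below floor",
           hwe = "SNP out of Hardy-Weinberg equilibrium",
           marker_callrate = "SNP with callrate below floor",
           chrX = "SNPs on chromosome X",
           chrY = "SNPs on chromosome Y",
           chr0 = "SNPs on chromosome 0 (unplaced)",
           indel = "insertion/deletion")
  for (k in names(lab))
    cat(sprintf("  %-45s %s\n", lab[[k]], x$excluded[[k]]))
  cat(sprintf("  %-45s %s\n", "SNPs used after quality control",
              x$n_markers_kept))
  cat(sprintf("  Duplicate pairs found: %d; samples removed: %d duplicate, %d low call rate; %d samples kept\n",
              nrow(x$duplicate_pairs), length(x$samples_removed_duplicate),
              length(x$samples_removed_callrate), x$n_samples_kept))
  invisible(x)
}
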