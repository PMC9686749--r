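#' Per-marker diversity statistics
#'
#' For each marker, over non-missing genotypes: allele-b frequency
#' `p = dosage sum / (2 n_valid)`, minor allele frequency `min(p, 1-p)`,
#' observed heterozygosity `Ho = n_het / n_valid`, expected heterozygosity
#' `He = 2 p (1-p)`, Botstein's polymorphism information content in its
#' biallelic form `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, and the effective
#' number of alleles `Ae = 1 / (p^2 + q^2)` (reciprocal expected
#' homozygosity). A marker is polymorphic when its MAF is at or above
#' `maf_min`. Markers with no valid genotype get `NA` statistics.
#'
#' @param g A [genotype_matrix()] with at least one sample.
#' @param maf_min Polymorphism floor (same threshold as marker QC).
#' @return Data frame with one row per marker: `id`, `chromosome`, `p`,
#'   `maf`, `callrate`, `ho`, `he`, `pic`, `ae`, `polymorphic`.
#' @export
marker_stats <- function(g, maf_min = 0.01) {
  if (n_samples(g) < 1L) stop("marker statistics need at least one sample")
  d <- g$dosage
  n_valid <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_valid)   # NaN when n_valid == 0
  q <- 1 - p
  maf <- pmin(p, q)
  ho <- colSums(d == 1L, na.rm = TRUE) / n_valid
  he <- 2 * p * q
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  ae <- 1 / (p^2 + q^2)
  undef <- n_valid == 0L
  out <- data.frame(id = g$markers$id, chromosome = g$markers$chromosome,
                    n_valid = n_valid, p = p, maf = maf,
                    callrate = n_valid / nrow(d),
                    ho = ho, he = he, pic = pic, ae = ae,
                    polymorphic = maf >= maf_min,
                    stringsAsFactors = FALSE)
  out[undef, c("p", "maf", "ho", "he", "pic", "ae")] <- NA_real_
  out$polymorphic[undef] <- NA
  rownames(out) <- NULL
  out
}

#' Cohort-level diversity summary
#'
#' Averages per-marker statistics over markers with defined values and
#' reports the proportion of polymorphic markers (PN) plus MAF and PIC
#' histograms for the polymorphic set. PN is meant to be computed on the
#' pre-marker-QC set (after sample QC); on a fully QC-filtered matrix every
#' survivor is polymorphic by construction.
#'
#' @param stats A data frame from [marker_stats()].
#' @return A list of class `cohort_diversity`: `n_markers`, `pn`,
#'   `mean_maf`, `mean_ho`, `mean_he`, `mean_pic`, `mean_ae`,
#'   `maf_histogram` (bins of width 0.1 over [0, 0.5]), `pic_histogram`
#'   (bins of width 0.075 over [0, 0.375]).
#' @export
cohort_diversity <- function(stats) {
  def <- stats[!is.na(stats$maf), , drop = FALSE]
  if (!nrow(def)) stop("no marker has defined statistics")
  poly <- def[def$polymorphic, , drop = FALSE]
  maf_breaks <- seq(0, 0.5, by = 0.1)
  pic_breaks <- seq(0, 0.375, by = 0.075)
  maf_h <- table(cut(poly$maf, maf_breaks, include.lowest = TRUE,
                     right = FALSE))
  ## top MAF bin is closed: [0.4, 0.5]
  pic_h <- table(cut(poly$pic, pic_breaks, include.lowest = TRUE,
                     right = FALSE))
  structure(list(
    n_markers = nrow(def),
    pn = nrow(poly) / nrow(def),
    mean_maf = mean(def$maf),
    mean_ho = mean(def$ho),
    mean_he = mean(def$he),
    mean_pic = mean(def$pic),
    mean_ae = mean(def$ae),
    maf_histogram = as.data.frame(maf_h, responseName = "count",
                                  stringsAsFactors = FALSE),
    pic_histogram = as.data.frame(pic_h, responseName = "count",
                                  stringsAsFactors = FALSE)),
    class = "cohort_diversity")
}

#' @export
print.cohort_diversity <- function(x, ...) {
  cat("Population genetic diversity\n")
  cat(sprintf("  %-42s %s\n", "Markers considered", x$n_markers))
  pn <- if (!is.null(x$pn_pre_marker_qc)) x$pn_pre_marker_qc else x$pn
  cat(sprintf("  %-42s %.3f\n", "Proportion of Polymorphic Markers (PN)", pn))
  cat(sprintf("  %-42s %.3f\n", "Expected Heterozygosity (HE)", x$mean_he))
  cat(sprintf("  %-42s %.3f\n", "Heterozygosity Observed (HO)", x$mean_ho))
  cat(sprintf("  %-42s %.3f\n", "Polymorphism Information Content (PIC)",
              x$mean_pic))
  cat(sprintf("  %-42s %.3f\n", "Effective Numbers of Alleles", x$mean_ae))
  cat(sprintf("  %-42s %.3f\n", "Minor Allele Frequency (MAF)", x$mean_maf))
  invisible(x)
}

#' Per-individual observed heterozygosity
#'
#' Fraction of an individual's non-missing genotypes that are heterozygous;
#' complements the across-marker Ho mean.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with `id` and `ho_individual`.
#' @export
individual_heterozygosity <- function(g) {
  d <- g$dosage
  data.frame(id = g$samples$id,
             ho_individual = rowSums(d == 1L, na.rm = TRUE) /
               rowSums(!is.na(d)),
             stringsAsFactors = FALSE)
}

#' Composite linkage-disequilibrium r-squared for one marker pair
#'
#' Squared Pearson correlation of the dosage vectors over samples with calls
#' at both markers (genotype-correlation / composite LD; no phasing).
#'
#' @param g A [genotype_matrix()].
#' @param i,j Marker indices or ids.
#' @return r-squared in [0, 1], or `NA` if either marker has zero variance
#'   on the shared samples.
#' @export
ld_r2 <- function(g, i, j) {
  i <- resolve_index(i, g$markers$id)
  j <- resolve_index(j, g$markers$id)
  x <- g$dosage[, i]
  y <- g$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD-based effective population size (Sved's relation)
#'
#' Pairs autosomal polymorphic markers within chromosomes, converts their
#' physical separation to genetic distance `c` (Morgans) with a constant
#' map rate, bins the pairs by distance, and inverts Sved's expectation
#' `E[r2] = 1 / (1 + 4 Ne c)` per bin after subtracting the sample-size
#' term `1/(2n)` from the mean r-squared:
#' `Ne = (1/mean_r2_adj - 1) / (4 c_mid)` with `c_mid` the bin midpoint.
#'
#' @param g A [genotype_matrix()].
#' @param bins_cM Numeric vector of bin breakpoints in centiMorgans
#'   (default: 10 log-spaced bins over 0.5 to 10 cM).
#' @param map_rate_cM_per_Mb Constant map rate (default 1 cM/Mb).
#' @param maf_min Markers below this MAF are excluded from pairing.
#' @param autosomes Chromosome labels used.
#' @return Data frame with one row per bin: `c_morgans` (midpoint),
#'   `n_pairs`, `mean_r2`, `mean_r2_adj`, `ne` (`NA` where the adjusted
#'   mean is non-positive or the bin is empty).
#' @export
estimate_ne <- function(g, bins_cM = default_ne_bins(),
                        map_rate_cM_per_Mb = 1, maf_min = 0.05,
                        autosomes = cattle_autosomes()) {
  stopifnot(length(bins_cM) >= 2L, !is.unsorted(bins_cM))
  st <- marker_stats(g, maf_min = maf_min)
  use <- which(g$markers$chromosome %in% autosomes &
               !is.na(st$maf) & st$maf >= maf_min)
  bins_M <- bins_cM / 100
  nb <- length(bins_M) - 1L
  sum_r2 <- numeric(nb)
  n_pair <- numeric(nb)
  n <- n_samples(g)
  for (chr in unique(g$markers$chromosome[use])) {
    idx <- use[g$markers$chromosome[use] == chr]
    if (length(idx) < 2L) next
    d <- g$dosage[, idx, drop = FALSE]
    storage.mode(d) <- "double"
    r2 <- suppressWarnings(
      stats::cor(d, use = "pairwise.complete.obs"))^2
    pos <- g$markers$position_bp[idx]
    sep <- abs(outer(pos, pos, "-")) * map_rate_cM_per_Mb / 1e8  # Morgans
    ut <- upper.tri(r2)
    ok <- ut & !is.na(r2)
    bin <- findInterval(sep[ok], bins_M, rightmost.closed = TRUE)
    val <- r2[ok]
    inb <- bin >= 1L & bin <= nb
    if (any(inb)) {
      sums <- tapply(val[inb], bin[inb], sum)
      cnts <- tapply(val[inb], bin[inb], length)
      k <- as.integer(names(sums))
      sum_r2[k] <- sum_r2[k] + sums
      n_pair[k] <- n_pair[k] + cnts
    }
  }
  if (all(n_pair == 0))
    stop("no autosomal marker pair falls in any distance bin")
  mean_r2 <- ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_)
  mean_r2_adj <- mean_r2 - 1 / (2 * n)
  mid <- (bins_M[-1L] + bins_M[-length(bins_M)]) / 2
  ne <- sved_ne(mean_r2_adj, mid)
  data.frame(c_morgans = mid, n_pairs = n_pair, mean_r2 = mean_r2,
             mean_r2_adj = mean_r2_adj, ne = ne)
}

#' Invert Sved's relation
#'
#' `Ne = (1/r2 - 1) / (4 c)`; non-positive or >= 1 adjusted r-squared gives
#' `NA`.
#'
#' @param r2_adj Adjusted mean r-squared per bin.
#' @param c_morgans Genetic distance (Morgans) per bin.
#' @return Effective population size per bin.
#' @export
sved_ne <- function(r2_adj, c_morgans) {
  ne <- (1 / r2_adj - 1) / (4 * c_morgans)
  ne[!is.na(r2_adj) & (r2_adj <= 0)] <- NA_real_
  ne
}

#' @rdname estimate_ne
#' @export
default_ne_bins <- function() exp(seq(log(0.5), log(10), length.out = 11))
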