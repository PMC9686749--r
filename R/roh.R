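#' Runs-of-homozygosity scanning parameters
#'
#' Defaults are the PLINK 1.9 `--homozyg` defaults: 50-SNP scanning windows
#' allowing at most 1 heterozygote and 5 missing calls, a 5% window hit
#' fraction, and segments of at least 100 SNPs and 1000 kb, split at gaps
#' over 1000 kb, with at most 50 kb per SNP on average.
#'
#' @param window_snp Scanning window size in SNPs.
#' @param window_het_max Maximum heterozygote calls per homozygous window.
#' @param window_missing_max Maximum missing calls per homozygous window.
#' @param window_hit_fraction A marker is "in run" when the fraction of
#'   homozygous windows covering it exceeds this value.
#' @param min_snp Minimum SNPs per reported segment.
#' @param min_length_kb Minimum segment length (kb).
#' @param max_gap_kb Split a run where adjacent in-run markers are further
#'   apart than this (kb).
#' @param min_density_kb_per_snp Maximum average kb per SNP in a segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het_max = 1L,
                       window_missing_max = 5L, window_hit_fraction = 0.05,
                       min_snp = 100L, min_length_kb = 1000,
                       max_gap_kb = 1000, min_density_kb_per_snp = 50) {
  vals <- c(window_snp, window_het_max + 1, window_missing_max + 1,
            window_hit_fraction, min_snp, min_length_kb, max_gap_kb,
            min_density_kb_per_snp)
  if (any(vals <= 0)) stop("ROH parameters must be positive")
  structure(list(window_snp = as.integer(window_snp),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_fraction = window_hit_fraction,
                 min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb,
                 max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' PLINK-style scanning-window ROH caller, per sample and autosome. A
#' window of `window_snp` consecutive markers is homozygous when it holds
#' at most `window_het_max` heterozygote and `window_missing_max` missing
#' calls. Each marker's hit fraction is the proportion of windows covering
#' it that are homozygous; markers exceeding `window_hit_fraction` are
#' in-run. Maximal in-run stretches are trimmed to start and end on
#' homozygous non-missing calls, split where adjacent markers are more than
#' `max_gap_kb` apart (each piece re-trimmed), and filtered by `min_snp`,
#' `min_length_kb` and the kb-per-SNP density ceiling. Chromosomes with
#' fewer than `window_snp` markers are skipped with a message. Segment
#' length is `end_bp - start_bp`.
#'
#' @param g A [genotype_matrix()].
#' @param params A [roh_params()].
#' @param autosomes Chromosome labels scanned (sex chromosomes and unplaced
#'   markers are never scanned).
#' @return Data frame: `sample_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, params = roh_params(),
                       autosomes = cattle_autosomes()) {
  res <- list()
  chroms <- intersect(unique(g$markers$chromosome), autosomes)
  for (chr in chroms) {
    mi <- which(g$markers$chromosome == chr)
    pos <- g$markers$position_bp[mi]
    if (is.unsorted(pos)) stop("markers on chromosome ", chr,
                               " are not position-sorted")
    if (length(mi) < params$window_snp) {
      message("chromosome ", chr, ": fewer than ", params$window_snp,
              " markers, skipped")
      next
    }
    for (i in seq_len(n_samples(g))) {
      d <- g$dosage[i, mi]
      segs <- scan_sample_chromosome(d, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- g$samples$id[i]
        segs$chromosome <- chr
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[, c("sample_id", "chromosome", "start_bp", "end_bp",
                 "n_snps", "length_bp")]
  out <- out[order(out$sample_id, chrom_rank(out$chromosome), out$start_bp), ]
  rownames(out) <- NULL
  out
}

## core scanner for one sample on one chromosome (vectorised via cumsums)
scan_sample_chromosome <- function(d, pos, p) {
  m <- length(d)
  w <- p$window_snp
  het <- !is.na(d) & d == 1L
  mis <- is.na(d)
  hom <- !is.na(d) & d != 1L

  nwin <- m - w + 1L
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  k <- seq_len(nwin)
  H <- (cs_het[k + w] - cs_het[k]) <= p$window_het_max &
       (cs_mis[k + w] - cs_mis[k]) <= p$window_missing_max
  cs_H <- c(0L, cumsum(H))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nwin)
  n_cov <- hi - lo + 1L
  n_hom_win <- cs_H[hi + 1L] - cs_H[lo]
  in_run <- n_hom_win / n_cov > p$window_hit_fraction

  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer())
  if (!any(in_run)) return(empty)

  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (s in which(r$values)) {
    a <- starts[s]; b <- ends[s]
    for (piece in split_and_trim(a, b, hom, pos, p$max_gap_kb * 1000)) {
      a2 <- piece[1L]; b2 <- piece[2L]
      n_snps <- b2 - a2 + 1L
      len <- pos[b2] - pos[a2]
      if (n_snps >= p$min_snp && len >= p$min_length_kb * 1000 &&
          (len / 1000) / n_snps <= p$min_density_kb_per_snp)
        out[[length(out) + 1L]] <- data.frame(
          start_bp = pos[a2], end_bp = pos[b2],
          n_snps = n_snps, length_bp = len)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

## trim [a, b] to homozygous non-missing endpoints, split at gaps larger
## than max_gap_bp, re-trim each piece; returns list of c(start, end)
split_and_trim <- function(a, b, hom, pos, max_gap_bp) {
  trim <- function(a, b) {
    idx <- seq.int(a, b)
    h <- idx[hom[idx]]
    if (!length(h)) return(NULL)
    c(h[1L], h[length(h)])
  }
  t0 <- trim(a, b)
  if (is.null(t0)) return(list())
  a <- t0[1L]; b <- t0[2L]
  if (a == b) return(list(c(a, b)))
  gaps <- which(diff(pos[a:b]) > max_gap_bp)
  cut_pts <- c(a - 1L, a - 1L + gaps, b)
  pieces <- list()
  for (k in seq_len(length(cut_pts) - 1L)) {
    t1 <- trim(cut_pts[k] + 1L, cut_pts[k + 1L])
    if (!is.null(t1)) pieces[[length(pieces) + 1L]] <- t1
  }
  pieces
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` is the total ROH length of an individual divided by the length
#' of the autosomal genome. With `autosome_length_bp = "from-map"` the
#' denominator is the mapped autosome extent, summed over autosomes as
#' (max position - min position). Samples with no segment get 0.
#'
#' @param segments Data frame from [detect_roh()].
#' @param g The [genotype_matrix()] the segments came from.
#' @param autosome_length_bp Either `"from-map"` or an explicit length.
#' @param autosomes Autosome labels used for the map extent.
#' @return Data frame: `sample_id`, `n_segments`, `total_roh_bp`,
#'   `autosome_length_bp`, `froh`.
#' @export
froh <- function(segments, g, autosome_length_bp = "from-map",
                 autosomes = cattle_autosomes()) {
  if (identical(autosome_length_bp, "from-map")) {
    auto <- g$markers[g$markers$chromosome %in% autosomes, , drop = FALSE]
    if (!nrow(auto)) stop("no autosomal markers to derive the map extent")
    autosome_length_bp <- sum(tapply(auto$position_bp, auto$chromosome,
                                     function(x) max(x) - min(x)))
  }
  if (autosome_length_bp <= 0) stop("autosome length must be positive")
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  cnt <- tapply(segments$length_bp, segments$sample_id, length)
  ids <- g$samples$id
  total <- ifelse(ids %in% names(tot), as.numeric(tot[ids]), 0)
  nseg <- ifelse(ids %in% names(cnt), as.integer(cnt[ids]), 0L)
  data.frame(sample_id = ids, n_segments = nseg, total_roh_bp = total,
             autosome_length_bp = autosome_length_bp,
             froh = total / autosome_length_bp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROH summary tables
#'
#' Three deterministic tables: segment counts per length bin
#' ([1,5), [5,10), [10,20), [20,40), [40, Inf) Mb), per chromosome, and the
#' distribution of per-sample total ROH length in 50 Mb bins starting at 0.
#'
#' @param segments Data frame from [detect_roh()].
#' @return A list with `by_length`, `by_chromosome`, `by_sample_total`.
#' @export
roh_summaries <- function(segments) {
  mb <- segments$length_bp / 1e6
  breaks <- c(1, 5, 10, 20, 40, Inf)
  lab <- c("[1,5)", "[5,10)", "[10,20)", "[20,40)", "[40,Inf)")
  by_length <- data.frame(
    length_mb = lab,
    count = as.integer(table(cut(mb, breaks, right = FALSE, labels = lab))),
    stringsAsFactors = FALSE)
  by_chromosome <- as.data.frame(table(chromosome = segments$chromosome),
                                 responseName = "count",
                                 stringsAsFactors = FALSE)
  if (nrow(by_chromosome))
    by_chromosome <- by_chromosome[order(chrom_rank(by_chromosome$chromosome)), ]
  rownames(by_chromosome) <- NULL
  if (nrow(segments)) {
    tot_mb <- tapply(segments$length_bp, segments$sample_id, sum) / 1e6
    bin_lo <- floor(tot_mb / 50) * 50
    by_sample_total <- as.data.frame(table(total_mb_bin =
      paste0("[", bin_lo, ",", bin_lo + 50, ")")),
      responseName = "n_samples", stringsAsFactors = FALSE)
  } else {
    by_sample_total <- data.frame(total_mb_bin = character(),
                                  n_samples = integer(),
                                  stringsAsFactors = FALSE)
  }
  list(by_length = by_length, by_chromosome = by_chromosome,
       by_sample_total = by_sample_total)
}
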