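#' Simulation configuration for a pedigree-structured SNP cohort
#'
#' Describes a cohort with known ground truth: founders drawn in linkage
#' equilibrium from a uniform allele-frequency law, non-founders produced
#' by meiosis with Poisson-distributed crossovers (no interference), plus
#' injected QC artifacts (duplicate samples, low-MAF markers,
#' heterozygote-deficit markers, sex-chromosome / unplaced / indel decoy
#' markers, low-call-rate markers, uniform missingness).
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param n_chromosomes Number of autosomes simulated.
#' @param chromosome_length_bp Length of each autosome (bp).
#' @param markers_per_chromosome Pedigree-informative markers per autosome,
#'   evenly spaced.
#' @param founder_maf_range Uniform law for founder allele-b frequencies.
#' @param pedigree Data frame with columns `child`, `sire`, `dam`,
#'   `child_sex` ("male"/"female"). Founders are the ids appearing as
#'   parents but never as children; every non-founder's parents must be
#'   defined before use. `NULL` gives an unrelated-founder cohort via
#'   `n_founders`.
#' @param n_founders Number of unrelated founders when `pedigree` is NULL
#'   (ids "F1"..., alternating male/female).
#' @param family_truth Named character vector mapping sample id to a true
#'   family label (optional; used to score family recovery).
#' @param genotyped_ids Ids genotyped on the chip; default all pedigree
#'   ids. Ungenotyped ids (e.g. unchipped dams) are simulated but dropped
#'   from the output matrix.
#' @param recomb_rate_cM_per_Mb Constant map rate.
#' @param missing_rate I.i.d. missing-call rate applied last.
#' @param n_duplicate_pairs Exact genotype copies injected with fresh ids.
#' @param n_rare_markers Appended autosomal markers with MAF < 0.01.
#' @param n_hwe_violating_markers Pedigree markers overwritten with a
#'   heterozygote-deficit law (het probability x 0.1).
#' @param n_lowcall_markers Pedigree markers whose call rate is forced
#'   below 0.9.
#' @param n_x_markers,n_y_markers,n_unplaced_markers Decoy markers on X, Y
#'   and chromosome 0 (autosomal-like genotype noise, no inheritance).
#' @param n_indel_markers Appended autosomal insertion/deletion markers.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 29L,
                       chromosome_length_bp = 1e8,
                       markers_per_chromosome = 200L,
                       founder_maf_range = c(0.05, 0.5),
                       pedigree = NULL,
                       n_founders = 20L,
                       family_truth = NULL,
                       genotyped_ids = NULL,
                       recomb_rate_cM_per_Mb = 1,
                       missing_rate = 0,
                       n_duplicate_pairs = 0L,
                       n_rare_markers = 0L,
                       n_hwe_violating_markers = 0L,
                       n_lowcall_markers = 0L,
                       n_x_markers = 0L,
                       n_y_markers = 0L,
                       n_unplaced_markers = 0L,
                       n_indel_markers = 0L) {
  if (missing(seed)) stop("a seed is mandatory")
  counts <- c(n_duplicate_pairs, n_rare_markers, n_hwe_violating_markers,
              n_lowcall_markers, n_x_markers, n_y_markers,
              n_unplaced_markers, n_indel_markers)
  if (any(counts < 0)) stop("artifact counts must be >= 0")
  if (n_chromosomes * markers_per_chromosome == 0 && any(counts[-1] > 0))
    stop("artifact markers require a nonzero marker budget")
  if (is.null(pedigree)) {
    sexes <- rep(c("male", "female"), length.out = n_founders)
    pedigree <- data.frame(child = character(), sire = character(),
                           dam = character(), child_sex = character(),
                           stringsAsFactors = FALSE)
    attr(pedigree, "founders") <-
      data.frame(id = paste0("F", seq_len(n_founders)), sex = sexes,
                 stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 founder_maf_range = founder_maf_range,
                 pedigree = pedigree,
                 family_truth = family_truth,
                 genotyped_ids = genotyped_ids,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 missing_rate = missing_rate,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 n_rare_markers = as.integer(n_rare_markers),
                 n_hwe_violating_markers = as.integer(n_hwe_violating_markers),
                 n_lowcall_markers = as.integer(n_lowcall_markers),
                 n_x_markers = as.integer(n_x_markers),
                 n_y_markers = as.integer(n_y_markers),
                 n_unplaced_markers = as.integer(n_unplaced_markers),
                 n_indel_markers = as.integer(n_indel_markers)),
            class = "sim_config")
}

## founders of a pedigree: ids used as parents but never as children,
## plus any explicitly attached founder table
pedigree_founders <- function(ped) {
  explicit <- attr(ped, "founders")
  sires <- unique(stats::na.omit(ped$sire))
  dams <- unique(stats::na.omit(ped$dam))
  implied_s <- setdiff(sires, ped$child)
  implied_d <- setdiff(dams, ped$child)
  clash <- intersect(implied_s, implied_d)
  if (length(clash))
    stop("id used as both sire and dam: ", paste(clash, collapse = ", "))
  f <- data.frame(id = c(implied_s, implied_d),
                  sex = c(rep("male", length(implied_s)),
                          rep("female", length(implied_d))),
                  stringsAsFactors = FALSE)
  if (!is.null(explicit)) f <- rbind(explicit[!(explicit$id %in% f$id), ], f)
  f
}

#' Pedigree inbreeding coefficients
#'
#' Computes F for every pedigree member by the tabular (numerator
#' relationship matrix) method; F of a child equals the kinship of its
#' parents. Founders are unrelated and non-inbred.
#'
#' @param pedigree Data frame with `child`, `sire`, `dam` columns; parents
#'   must be defined before their offspring.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  founders <- pedigree_founders(pedigree)
  ids <- c(founders$id, pedigree$child)
  if (anyDuplicated(ids)) stop("duplicate id in pedigree")
  n <- length(ids)
  sire_idx <- c(rep(NA_integer_, nrow(founders)),
                match(pedigree$sire, ids))
  dam_idx <- c(rep(NA_integer_, nrow(founders)),
               match(pedigree$dam, ids))
  kids <- seq_len(nrow(pedigree)) + nrow(founders)
  if (any(is.na(sire_idx[kids]) | is.na(dam_idx[kids])))
    stop("pedigree references an unknown parent id")
  if (any(sire_idx[kids] >= kids | dam_idx[kids] >= kids))
    stop("every parent must precede its offspring in the pedigree")
  A <- diag(n)
  for (i in seq_len(n)) {
    s <- sire_idx[i]; d <- dam_idx[i]
    if (!is.na(s)) {
      A[i, i] <- 1 + A[s, d] / 2
      for (j in seq_len(i - 1L)) {
        A[i, j] <- A[j, i] <- (A[j, s] + A[j, d]) / 2
      }
    }
  }
  stats::setNames(diag(A) - 1, ids)
}

#' Simulate a pedigree-structured SNP cohort with ground truth
#'
#' Founders receive two independent haplotypes per chromosome with
#' allele-b frequencies drawn uniformly from `founder_maf_range` (linkage
#' equilibrium); offspring haplotypes are produced by meiosis with
#' `Poisson(length_Mb * rate / 100)` crossovers at uniform positions.
#' Artifact markers and samples are then injected (see [sim_config()]):
#' heterozygote-deficit markers overwrite pedigree markers, rare / indel
#' markers are appended on autosomes, X / Y / unplaced decoys carry
#' autosomal-like noise, duplicates are exact copies with fresh ids, and
#' missingness is applied i.i.d. last. Identical configs give identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `sim_truth`: `samples` data frame with `id`, `f_ped`, `family`;
#'   `markers` data frame with `id`, `class` in clean/rare/hwe/lowcall/X/Y/
#'   unplaced/indel and `founder_freq`, the generating allele-b frequency
#'   in the coding of the emitted matrix; `duplicate_pairs` data frame).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  founders <- pedigree_founders(cfg$pedigree)
  f_ped <- pedigree_inbreeding(cfg$pedigree)
  ids <- names(f_ped)
  sex <- stats::setNames(c(founders$sex, cfg$pedigree$child_sex), ids)
  n <- length(ids)
  nchr <- cfg$n_chromosomes
  mpc <- cfg$markers_per_chromosome
  L <- cfg$chromosome_length_bp
  morgans <- L / 1e6 * cfg$recomb_rate_cM_per_Mb / 100

  sire_idx <- match(cfg$pedigree$sire, ids)
  dam_idx <- match(cfg$pedigree$dam, ids)
  n_found <- nrow(founders)

  dos_tabs <- list()
  marker_tabs <- list()
  for (chr in seq_len(nchr)) {
    pos <- as.integer(round(seq(L / (mpc + 1), L * mpc / (mpc + 1),
                                length.out = mpc)))
    pos <- unique(pos)
    m <- length(pos)
    p <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    hap1 <- matrix(0L, n, m)
    hap2 <- matrix(0L, n, m)
    for (i in seq_len(n_found)) {
      hap1[i, ] <- stats::rbinom(m, 1L, p)
      hap2[i, ] <- stats::rbinom(m, 1L, p)
    }
    for (r in seq_len(nrow(cfg$pedigree))) {
      i <- n_found + r
      hap1[i, ] <- meiosis(hap1[sire_idx[r], ], hap2[sire_idx[r], ],
                           pos, L, morgans)
      hap2[i, ] <- meiosis(hap1[dam_idx[r], ], hap2[dam_idx[r], ],
                           pos, L, morgans)
    }
    dos_tabs[[chr]] <- hap1 + hap2
    marker_tabs[[chr]] <- data.frame(
      id = sprintf("snp_%d_%d", chr, seq_len(m)),
      chromosome = as.character(chr), position_bp = pos,
      allele_a = "A", allele_b = "B", class = "clean",
      founder_freq = p, stringsAsFactors = FALSE)
  }
  dosage <- if (length(dos_tabs)) do.call(cbind, dos_tabs)
            else matrix(0L, n, 0L)
  markers <- do.call(rbind, marker_tabs)

  ## heterozygote-deficit (HWE-violating) markers: overwrite pedigree
  ## markers with independent draws whose het probability is scaled by 0.1
  if (cfg$n_hwe_violating_markers > 0L) {
    cand <- which(markers$class == "clean")
    if (length(cand) < cfg$n_hwe_violating_markers)
      stop("not enough pedigree markers to host HWE-violating markers")
    pick <- sort(sample(cand, cfg$n_hwe_violating_markers))
    for (j in pick) {
      p <- stats::runif(1, 0.2, 0.5)
      ph <- 2 * p * (1 - p) * 0.1
      s <- (1 - ph) / (p^2 + (1 - p)^2)
      dosage[, j] <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                            prob = c((1 - p)^2 * s, ph, p^2 * s))
      markers$founder_freq[j] <- p
    }
    markers$class[pick] <- "hwe"
  }

  ## low-call-rate markers: force >10% missing later; mark now
  lowcall_j <- integer()
  if (cfg$n_lowcall_markers > 0L) {
    cand <- which(markers$class == "clean")
    if (length(cand) < cfg$n_lowcall_markers)
      stop("not enough pedigree markers to host low-call-rate markers")
    lowcall_j <- sort(sample(cand, cfg$n_lowcall_markers))
    markers$class[lowcall_j] <- "lowcall"
  }

  ## appended decoy markers
  app <- function(k, chrom, cls, alleles = c("A", "B"), freq = NULL) {
    if (k == 0L) return(NULL)
    chr_pick <- if (chrom == "auto")
      as.character(sample(nchr, k, replace = TRUE)) else rep(chrom, k)
    p <- if (is.null(freq)) stats::runif(k, 0.05, 0.5) else freq
    list(dos = matrix(stats::rbinom(n * k, 2L, rep(p, each = n)), n, k),
         mk = data.frame(
           id = sprintf("%s_%d", cls, seq_len(k)), chromosome = chr_pick,
           position_bp = as.integer(sample.int(as.integer(L), k)),
           allele_a = alleles[1], allele_b = alleles[2], class = cls,
           founder_freq = p, stringsAsFactors = FALSE))
  }
  extras <- list(
    app(cfg$n_rare_markers, "auto", "rare",
        freq = stats::runif(cfg$n_rare_markers, 0.0005, 0.008)),
    app(cfg$n_x_markers, "X", "X"),
    app(cfg$n_y_markers, "Y", "Y"),
    app(cfg$n_unplaced_markers, "0", "unplaced"),
    app(cfg$n_indel_markers, "auto", "indel", alleles = c("I", "D")))
  for (e in extras) {
    if (is.null(e)) next
    dosage <- cbind(dosage, e$dos)
    markers <- rbind(markers, e$mk)
  }

  ## restrict to genotyped samples
  keep <- if (is.null(cfg$genotyped_ids)) ids else {
    miss <- setdiff(cfg$genotyped_ids, ids)
    if (length(miss)) stop("genotyped_ids not in pedigree: ",
                           paste(miss, collapse = ", "))
    ids[ids %in% cfg$genotyped_ids]
  }
  ki <- match(keep, ids)
  dosage <- dosage[ki, , drop = FALSE]
  samp <- data.frame(id = keep, sex = unname(sex[keep]),
                     f_ped = unname(f_ped[keep]),
                     stringsAsFactors = FALSE)

  ## duplicates: exact copies, fresh ids, added before missingness
  dup_pairs <- data.frame(original = character(), duplicate = character(),
                          stringsAsFactors = FALSE)
  if (cfg$n_duplicate_pairs > 0L) {
    if (cfg$n_duplicate_pairs > nrow(samp))
      stop("more duplicate pairs than samples")
    src <- sample(nrow(samp), cfg$n_duplicate_pairs)
    dup_ids <- paste0(samp$id[src], "_dup")
    dosage <- rbind(dosage, dosage[src, , drop = FALSE])
    samp <- rbind(samp, data.frame(id = dup_ids, sex = samp$sex[src],
                                   f_ped = samp$f_ped[src],
                                   stringsAsFactors = FALSE))
    dup_pairs <- data.frame(original = samp$id[src], duplicate = dup_ids,
                            stringsAsFactors = FALSE)
  }

  ## i.i.d. missingness, then extra missingness on low-call markers
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[drop] <- NA_integer_
  }
  if (length(lowcall_j)) {
    for (j in lowcall_j) {
      k <- ceiling(nrow(dosage) * 0.15)
      dosage[sample(nrow(dosage), k), j] <- NA_integer_
    }
  }

  fam <- if (is.null(cfg$family_truth)) rep(NA_character_, nrow(samp)) else {
    f <- cfg$family_truth[samp$id]
    ## duplicates inherit the truth of their source
    di <- match(dup_pairs$duplicate, samp$id)
    if (length(di)) f[di] <- cfg$family_truth[dup_pairs$original]
    unname(f)
  }
  g <- genotype_matrix(dosage, samp[, c("id", "sex")],
                       markers[, c("id", "chromosome", "position_bp",
                                   "allele_a", "allele_b")])
  ## founder frequencies in the coding of the emitted matrix: coding
  ## normalisation may have flipped markers whose first call is hom-b
  mi <- match(g$markers$id, markers$id)
  flipped <- !is.na(g$markers$allele_a) &
             g$markers$allele_a != markers$allele_a[mi]
  freq_out <- ifelse(flipped, 1 - markers$founder_freq[mi],
                     markers$founder_freq[mi])
  mk_truth <- data.frame(id = g$markers$id, class = markers$class[mi],
                         founder_freq = freq_out, stringsAsFactors = FALSE)
  truth <- structure(list(
    samples = data.frame(id = samp$id, f_ped = samp$f_ped, family = fam,
                         stringsAsFactors = FALSE),
    markers = mk_truth,
    duplicate_pairs = dup_pairs), class = "sim_truth")
  list(genotypes = g, truth = truth)
}

## one gamete: recombine two parental haplotypes over marker positions
meiosis <- function(h1, h2, pos, chrom_len, morgans) {
  k <- stats::rpois(1L, morgans)
  start <- sample(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(k, 0, chrom_len))
  phase <- (findInterval(pos, xo) + start) %% 2L
  ifelse(phase == 1L, h1, h2)
}

#' Write a simulated fixture to disk
#'
#' PED/MAP (the [read_ped_map()] dialect) plus three TSV truth files:
#' `sample_truth.tsv`, `marker_truth.tsv`, `duplicate_pairs.tsv`.
#'
#' @param g A [genotype_matrix()].
#' @param truth A `sim_truth` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for the PED/MAP files.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(g, truth, dir, basename = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- file.path(dir, paste0(basename, ".ped"))
  map <- file.path(dir, paste0(basename, ".map"))
  write_ped_map(g, ped, map)
  paths <- c(ped = ped, map = map,
             sample_truth = file.path(dir, "sample_truth.tsv"),
             marker_truth = file.path(dir, "marker_truth.tsv"),
             duplicate_pairs = file.path(dir, "duplicate_pairs.tsv"))
  utils::write.table(truth$samples, paths["sample_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$markers, paths["marker_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$duplicate_pairs, paths["duplicate_pairs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Study-condition simulation config
#'
#' The default cohort the pipeline is demonstrated on: 46 genotyped animals
#' (9 bulls, 37 cows) in 3 paternal half-sib families of unequal size plus
#' unrelated "other" cows, a few offspring of close matings carrying long
#' autozygous tracts, 2 duplicate samples, 2% missingness, and a ~101k
#' marker panel whose artifact classes mirror a published chip-QC table
#' (3157 rare, 66 heterozygote-deficit, 1010 low-call-rate, 3785 X, 330 Y,
#' 6267 unplaced, 174 indel markers).
#'
#' @param seed Integer seed.
#' @param markers_per_chromosome Clean pedigree markers per autosome.
#' @return A [sim_config()].
#' @export
sim_config_study_like <- function(seed, markers_per_chromosome = 3017L) {
  ped <- study_pedigree()
  sim_config(seed = seed,
             n_chromosomes = 29L,
             chromosome_length_bp = 1e8,
             markers_per_chromosome = markers_per_chromosome,
             pedigree = ped$pedigree,
             family_truth = ped$family_truth,
             genotyped_ids = ped$genotyped_ids,
             missing_rate = 0.02,
             n_duplicate_pairs = 2L,
             n_rare_markers = 3157L,
             n_hwe_violating_markers = 66L,
             n_lowcall_markers = 1010L,
             n_x_markers = 3785L,
             n_y_markers = 330L,
             n_unplaced_markers = 6267L,
             n_indel_markers = 174L)
}

## pedigree of the study-like cohort: 3 sire lines of unequal size, a few
## close matings, unrelated "other" cows; dams are unchipped
study_pedigree <- function() {
  ped <- list()
  truth <- character()
  add <- function(child, sire, dam, sex, fam) {
    ped[[length(ped) + 1L]] <<- data.frame(
      child = child, sire = sire, dam = dam, child_sex = sex,
      stringsAsFactors = FALSE)
    truth[child] <<- fam
  }
  ## family sires (founders, genotyped) and their unchipped mates
  sires <- c("B1", "B2", "B3")
  truth[sires] <- paste0("fam", 1:3)
  ## family 1: large — sire B1, 4 sons, 14 daughters
  for (k in 1:4) add(paste0("B1s", k), "B1", paste0("D1_", k), "male", "fam1")
  for (k in 1:14) add(paste0("C1_", k), "B1", paste0("D1_", 4 + k),
                      "female", "fam1")
  ## family 2: sire B2, 2 sons, 6 daughters; two daughters from a
  ## sire-daughter backcross carry long autozygous tracts (F = 0.25)
  for (k in 1:2) add(paste0("B2s", k), "B2", paste0("D2_", k), "male", "fam2")
  for (k in 1:4) add(paste0("C2_", k), "B2", paste0("D2_", 2 + k),
                     "female", "fam2")
  for (k in 1:2) add(paste0("C2x", k), "B2", paste0("C2_", k),
                     "female", "fam2")
  ## family 3: small — sire B3, 3 daughters
  for (k in 1:3) add(paste0("C3_", k), "B3", paste0("D3_", k),
                     "female", "fam3")
  ## unrelated cows ("other"): founders of their own
  other <- paste0("CO", 1:14)
  truth[other] <- "other"
  pedigree <- do.call(rbind, ped)
  ## register genotyped founders explicitly (sires + other cows)
  attr(pedigree, "founders") <- NULL
  genotyped <- c(sires, pedigree$child, other)
  ## founders implied by the pedigree are the sires and the dams; the
  ## "other" cows never appear, so attach them as explicit founders
  extra <- data.frame(id = other, sex = "female", stringsAsFactors = FALSE)
  attr(pedigree, "founders") <- extra
  list(pedigree = pedigree, family_truth = truth, genotyped_ids = genotyped)
}
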