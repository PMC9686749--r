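#' @keywords internal
"_PACKAGE"

## Chromosome conventions: cattle autosomes are labelled "1".."29"; "X", "Y"
## are sex chromosomes and "0" marks unplaced markers. All labels are kept as
## character strings throughout.

#' Cattle autosome labels
#'
#' The autosome set used by quality control and by all autosome-restricted
#' statistics (ROH, F_ROH, LD-based Ne): chromosomes 1 to 29.
#'
#' @return Character vector of autosome labels.
#' @export
cattle_autosomes <- function() as.character(1:29)

# Canonical sort order for chromosome labels: autosomes numerically,
# then X, Y, then unplaced ("0"); unknown labels go last.
chrom_rank <- function(chrom) {
  ord <- c(as.character(1:29), "X", "Y", "0")
  r <- match(chrom, ord)
  r[is.na(r)] <- length(ord) + 1L
  r
}

#' Construct a genotype matrix
#'
#' The backbone container of the pipeline: an integer matrix of alternate
#' allele dosages (counts of `allele_b`, values 0/1/2, `NA` = missing call)
#' with per-sample and per-marker metadata. Rows are samples, columns are
#' markers. Markers are sorted by (chromosome, position, id); per-marker
#' allele coding is normalised to observation order so that writing to
#' PED/MAP and reading back is the identity (see Details).
#'
#' @details Coding normalisation: scanning samples in row order, the first
#'   allele observed at a marker becomes `allele_a`. If the first non-missing
#'   genotype is homozygous for `allele_b`, the coding is flipped
#'   (`dosage <- 2 - dosage`, alleles swapped). If `allele_b` is never
#'   observed (the marker is monomorphic in the cohort), `allele_b` is set to
#'   `NA`. This makes the dosage coding a pure function of the genotype
#'   content, independent of how the matrix was built.
#'
#' @param dosage Integer matrix, samples x markers, entries in {0,1,2,NA}.
#' @param samples Data frame with columns `id` (unique character) and `sex`
#'   (one of "male", "female", "unknown").
#' @param markers Data frame with columns `id` (unique character),
#'   `chromosome` (label in 1..29, X, Y, 0), `position_bp` (integer >= 0),
#'   `allele_a`, `allele_b` (character, `allele_b` may be `NA`), and
#'   optionally `is_indel` (logical; derived from the alleles if absent).
#' @param normalize Normalise allele coding to observation order (see
#'   Details). [subset_genotypes()] turns this off so that filtering never
#'   changes the coding of surviving markers.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `samples` (with computed `call_rate` column) and `markers`.
#' @export
genotype_matrix <- function(dosage, samples, markers, normalize = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)

  if (nrow(dosage) != nrow(samples))
    stop("dosage has ", nrow(dosage), " rows but ", nrow(samples),
         " samples are described")
  if (ncol(dosage) != nrow(markers))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(markers),
         " markers are described")
  if (anyDuplicated(samples$id))
    stop("duplicate sample id: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("duplicate marker id: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (!all(samples$sex %in% c("male", "female", "unknown")))
    stop("sample sex must be 'male', 'female' or 'unknown'")
  if (!all(markers$position_bp >= 0))
    stop("marker positions must be >= 0")

  if (is.null(markers$is_indel)) {
    markers$is_indel <- infer_indel(markers$allele_a, markers$allele_b)
  }
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)

  ## sort markers by (chromosome, position, id)
  ord <- order(chrom_rank(markers$chromosome), markers$position_bp, markers$id)
  markers <- markers[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]

  ## normalise per-marker allele coding to observation order: a het written
  ## "a b" exposes allele_a first, so the only case needing a flip is a
  ## leading hom-allele_b genotype
  if (normalize) for (j in seq_len(ncol(dosage))) {
    d <- dosage[, j]
    obs <- d[!is.na(d)]
    if (length(obs) && obs[1L] == 2L) {
      d <- 2L - d
      dosage[, j] <- d
      ab <- markers$allele_a[j]
      markers$allele_a[j] <- markers$allele_b[j]
      markers$allele_b[j] <- ab
      obs <- 2L - obs
    }
    if (!any(obs %in% c(1L, 2L))) markers$allele_b[j] <- NA_character_
  }

  samples$call_rate <- rowMeans(!is.na(dosage))
  rownames(dosage) <- samples$id
  colnames(dosage) <- markers$id
  rownames(samples) <- NULL
  rownames(markers) <- NULL

  structure(list(dosage = dosage, samples = samples, markers = markers),
            class = "genotype_matrix")
}

infer_indel <- function(a, b) {
  one <- function(x) !is.na(x) & (nchar(x) != 1L | x %in% c("I", "D"))
  one(a) | one(b)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosage), " samples x ",
      ncol(x$dosage), " markers\n", sep = "")
  cat("  chromosomes: ",
      paste(unique(x$markers$chromosome), collapse = " "), "\n", sep = "")
  cat("  missing calls: ",
      format(mean(is.na(x$dosage)) * 100, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / markers
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$dosage)

#' Subset a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @param samples Indices, logical mask or ids of samples to keep.
#' @param markers Indices, logical mask or ids of markers to keep.
#' @return A new `genotype_matrix`; allele coding of surviving markers is
#'   carried over unchanged so that filtering is coding-stable.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- resolve_index(samples, g$samples$id)
  mi <- resolve_index(markers, g$markers$id)
  genotype_matrix(g$dosage[si, mi, drop = FALSE],
                  g$samples[si, c("id", "sex"), drop = FALSE],
                  g$markers[mi, , drop = FALSE], normalize = FALSE)
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown id: ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  idx
}

#' Autosomal marker mask
#'
#' @param g A `genotype_matrix`.
#' @param autosomes Autosome label set.
#' @return Logical vector over markers.
#' @export
is_autosomal <- function(g, autosomes = cattle_autosomes()) {
  g$markers$chromosome %in% autosomes
}
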