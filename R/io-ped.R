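#' Read PLINK text PED/MAP genotypes
#'
#' Parses the PLINK text dialect: a MAP file with one row per marker
#' (chromosome, marker id, genetic distance — ignored on read — and physical
#' position in bp) and a PED file with six leading columns
#' (FID IID PAT MAT SEX PHENO) followed by two allele columns per marker.
#' Dosage counts copies of `allele_b`, the second allele observed per marker
#' scanning samples in file order; `0 0` allele pairs become missing calls;
#' `A B` and `B A` both code as heterozygous. The SEX column maps 1 to male,
#' 2 to female and anything else to unknown.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"),
                           col.names = c("chromosome", "id", "cm",
                                         "position_bp"))
  if (anyDuplicated(map$id))
    stop("duplicate marker id in MAP: ",
         paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)

  if (n == 0L) {
    return(genotype_matrix(
      matrix(NA_integer_, 0L, m),
      data.frame(id = character(), sex = character(),
                 stringsAsFactors = FALSE),
      data.frame(id = map$id, chromosome = map$chromosome,
                 position_bp = map$position_bp,
                 allele_a = NA_character_, allele_b = NA_character_,
                 stringsAsFactors = FALSE)))
  }
  lens <- lengths(fields)
  bad <- which(lens != 6L + 2L * m)
  if (length(bad))
    stop("PED row ", bad[1L], " has ", lens[bad[1L]] - 6L,
         " marker columns but MAP describes ", m,
         " markers (expected ", 2L * m, " allele columns)")
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  sample_id <- ped[, 2L]
  sex <- c("1" = "male", "2" = "female")[ped[, 5L]]
  sex[is.na(sex)] <- "unknown"

  dosage <- matrix(NA_integer_, n, m)
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)

  for (j in seq_len(m)) {
    x <- ped[, 5L + 2L * j]
    y <- ped[, 6L + 2L * j]
    miss <- x == "0" | y == "0"
    if (any(miss & x != y))
      stop("half-missing genotype at marker ", map$id[j],
           ", sample ", sample_id[which(miss & x != y)[1L]])
    ## alleles in observation order: per sample first x then y
    obs <- as.vector(rbind(x, y))[rep(!miss, each = 2L)]
    al <- unique(obs)
    if (length(al) > 2L)
      stop("third allele '", al[3L], "' at marker ", map$id[j])
    if (length(al)) {
      allele_a[j] <- al[1L]
      if (length(al) == 2L) allele_b[j] <- al[2L]
      d <- (!is.na(allele_b[j]) & x == allele_b[j]) +
           (!is.na(allele_b[j]) & y == allele_b[j])
      d[miss] <- NA_integer_
      dosage[, j] <- d
    }
  }
  if (anyDuplicated(sample_id))
    stop("duplicate sample id in PED: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))

  genotype_matrix(dosage,
                  data.frame(id = sample_id, sex = sex,
                             stringsAsFactors = FALSE),
                  data.frame(id = map$id, chromosome = map$chromosome,
                             position_bp = map$position_bp,
                             allele_a = allele_a, allele_b = allele_b,
                             stringsAsFactors = FALSE))
}

#' Write PLINK text PED/MAP genotypes
#'
#' Emits the dialect [read_ped_map()] consumes: missing calls as `0 0`,
#' heterozygotes as `allele_a allele_b`, the MAP genetic-distance column as 0.
#' Reading the written files back reproduces the matrix exactly.
#'
#' @param g A [genotype_matrix()].
#' @param ped_path Output PED path.
#' @param map_path Output MAP path.
#' @return Invisibly, `NULL`.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  mk <- g$markers
  utils::write.table(
    data.frame(mk$chromosome, mk$id, 0L, mk$position_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  a <- mk$allele_a
  b <- mk$allele_b
  a[is.na(a)] <- "A"  # fully-missing marker: placeholder never emitted
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_samples(g))) {
    d <- g$dosage[i, ]
    gt <- character(length(d))
    gt[is.na(d)] <- "0 0"
    gt[!is.na(d) & d == 0L] <- paste(a, a)[!is.na(d) & d == 0L]
    gt[!is.na(d) & d == 1L] <- paste(a, b)[!is.na(d) & d == 1L]
    gt[!is.na(d) & d == 2L] <- paste(b, b)[!is.na(d) & d == 2L]
    sex_code <- switch(g$samples$sex[i], male = "1", female = "2", "0")
    writeLines(paste(c(g$samples$id[i], g$samples$id[i], "0", "0",
                       sex_code, "-9", gt), collapse = " "), con)
  }
  invisible(NULL)
}

#' Read genotypes from a VCF file
#'
#' Convenience importer for plain-text VCF v4.x with biallelic records and a
#' GT field: `0/0` codes 0, `0/1` and `1/0` code 1, `1/1` codes 2, `./.` is
#' missing (`|`-phased separators are accepted). Multiallelic records are
#' rejected. The indel flag is set when REF or ALT is longer than one base.
#'
#' @param vcf_path Path to an uncompressed VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(vcf_path) {
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in VCF")
  hcols <- strsplit(lines[hdr[1L]], "\t")[[1L]]
  if (length(hcols) < 10L) stop("VCF has no sample columns")
  sample_id <- hcols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[nzchar(body) & !startsWith(body, "#")]

  n <- length(sample_id)
  m <- length(body)
  dosage <- matrix(NA_integer_, n, m)
  chrom <- character(m); id <- character(m); pos <- integer(m)
  ref <- character(m); alt <- character(m)

  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t")[[1L]]
    if (grepl(",", f[5L], fixed = TRUE))
      stop("multiallelic record at ", f[1L], ":", f[2L])
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("no GT field in FORMAT at ", f[1L], ":", f[2L])
    chrom[j] <- f[1L]; pos[j] <- as.integer(f[2L])
    id[j] <- if (f[3L] == ".") paste0(f[1L], "_", f[2L]) else f[3L]
    ref[j] <- f[4L]; alt[j] <- f[5L]
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gti)
    al <- strsplit(gts, "[/|]")
    dosage[, j] <- vapply(al, function(x) {
      if (any(x == ".")) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1L))
  }
  genotype_matrix(dosage,
                  data.frame(id = sample_id, sex = "unknown",
                             stringsAsFactors = FALSE),
                  data.frame(id = id, chromosome = chrom, position_bp = pos,
                             allele_a = ref, allele_b = alt,
                             stringsAsFactors = FALSE))
}
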