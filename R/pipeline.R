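#' Run the full conservation-genomics pipeline
#'
#' Orchestrates the stages in a fixed order on PED/MAP (or VCF) input:
#' genotype input -> sample/marker QC -> diversity statistics (PN on the
#' post-sample-QC marker set, means on QC survivors) -> LD-based Ne ->
#' runs of homozygosity and F_ROH -> IBS distance and VanRaden G matrix ->
#' PCA -> neighbor-joining trees (all samples, bulls only) -> family
#' construction from genomic kinship. All tables are written as TSV, trees
#' as Newick, plus a run manifest (package version, configuration echo,
#' input checksums). The pipeline is deterministic: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param ped_path,map_path PED/MAP input paths (used unless `vcf_path`
#'   is given).
#' @param vcf_path Optional VCF input path.
#' @param out_dir Output directory, created if needed.
#' @param thresholds A [qc_thresholds()].
#' @param roh A [roh_params()].
#' @param ne_bins_cM Distance-bin breakpoints for [estimate_ne()] (cM).
#' @param map_rate_cM_per_Mb Constant map rate.
#' @param kinship_threshold Family-construction kinship threshold.
#' @return Invisibly, a list of class `report_bundle` with every stage
#'   result and the paths written.
#' @export
run_pipeline <- function(ped_path = NULL, map_path = NULL, vcf_path = NULL,
                         out_dir,
                         thresholds = qc_thresholds(),
                         roh = roh_params(),
                         ne_bins_cM = default_ne_bins(),
                         map_rate_cM_per_Mb = 1,
                         kinship_threshold = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- if (!is.null(vcf_path)) c(vcf = vcf_path)
            else c(ped = ped_path, map = map_path)
  g <- stage("input", {
    if (!is.null(vcf_path)) read_vcf(vcf_path)
    else read_ped_map(ped_path, map_path)
  })

  qc <- stage("qc", apply_qc(g, thresholds))
  gq <- qc$genotypes

  ## PN is defined on the post-sample-QC, pre-marker-QC marker set
  div <- stage("diversity", {
    g_samples <- subset_genotypes(
      g, samples = intersect(g$samples$id, gq$samples$id))
    pre_stats <- marker_stats(g_samples, maf_min = thresholds$maf_min)
    pn <- cohort_diversity(pre_stats)$pn
    post <- cohort_diversity(marker_stats(gq, maf_min = thresholds$maf_min))
    post$pn_pre_marker_qc <- pn
    post
  })
  indiv_ho <- stage("diversity", individual_heterozygosity(gq))

  ne <- stage("ne", tryCatch(
    estimate_ne(gq, bins_cM = ne_bins_cM,
                map_rate_cM_per_Mb = map_rate_cM_per_Mb),
    error = function(e) {
      message("Ne estimation skipped: ", conditionMessage(e))
      NULL
    }))

  segments <- stage("roh", detect_roh(gq, roh))
  froh_tab <- stage("roh", froh(segments, gq))
  roh_sum <- stage("roh", roh_summaries(segments))

  ibs <- stage("relatedness", ibs_distance(gq))
  grm <- stage("relatedness", grm_vanraden(gq))
  pca <- stage("relatedness", grm_pca(grm, k = min(10L, n_samples(gq))))

  tree_all <- stage("clustering", nj_tree(ibs))
  bulls <- gq$samples$id[gq$samples$sex == "male"]
  tree_bulls <- if (length(bulls) >= 3L)
    stage("clustering", nj_tree(ibs[bulls, bulls])) else NULL

  fam <- if (length(bulls) >= 1L && all(gq$samples$sex != "unknown"))
    stage("families", build_families(grm, gq$samples,
                                     threshold = kinship_threshold))
  else NULL

  paths <- write_report_bundle(out_dir, qc$report, div, indiv_ho, ne,
                               segments, froh_tab, roh_sum, ibs, grm, pca,
                               tree_all, tree_bulls, fam, inputs,
                               thresholds, roh, ne_bins_cM,
                               map_rate_cM_per_Mb, kinship_threshold)
  invisible(structure(list(
    qc_report = qc$report, genotypes = gq, diversity = div,
    individual_ho = indiv_ho, ne = ne, roh_segments = segments,
    froh = froh_tab, roh_summaries = roh_sum, ibs = ibs, grm = grm,
    pca = pca, tree_all = tree_all, tree_bulls = tree_bulls,
    families = fam, paths = paths), class = "report_bundle"))
}

write_tsv <- function(x, path, rn = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rn, col.names = TRUE)
  path
}

write_report_bundle <- function(out_dir, qc_report, div, indiv_ho, ne,
                                segments, froh_tab, roh_sum, ibs, grm, pca,
                                tree_all, tree_bulls, fam, inputs,
                                thresholds, roh, ne_bins_cM, map_rate,
                                kinship_threshold) {
  p <- function(f) file.path(out_dir, f)
  paths <- character()

  qc_tab <- data.frame(
    rule = c("total", names(qc_report$excluded), "kept"),
    n_markers = c(qc_report$n_markers_total,
                  unname(qc_report$excluded), qc_report$n_markers_kept))
  paths["qc"] <- write_tsv(qc_tab, p("qc_report.tsv"))
  con <- file(p("qc_report.txt"), "w")
  sink(con); print(qc_report); sink()
  close(con)
  paths["qc_duplicates"] <- write_tsv(qc_report$duplicate_pairs,
                                      p("qc_duplicates.tsv"))

  div_tab <- data.frame(
    statistic = c("PN (pre-marker-QC)", "mean MAF", "mean Ho", "mean He",
                  "mean PIC", "mean Ae", "markers"),
    value = c(div$pn_pre_marker_qc, div$mean_maf, div$mean_ho, div$mean_he,
              div$mean_pic, div$mean_ae, div$n_markers))
  paths["diversity"] <- write_tsv(div_tab, p("diversity.tsv"))
  paths["maf_hist"] <- write_tsv(div$maf_histogram, p("maf_histogram.tsv"))
  paths["pic_hist"] <- write_tsv(div$pic_histogram, p("pic_histogram.tsv"))
  paths["indiv_ho"] <- write_tsv(indiv_ho, p("individual_ho.tsv"))
  if (!is.null(ne)) paths["ne"] <- write_tsv(ne, p("ne_estimates.tsv"))

  paths["roh"] <- write_tsv(segments, p("roh_segments.tsv"))
  paths["froh"] <- write_tsv(froh_tab, p("froh.tsv"))
  paths["roh_len"] <- write_tsv(roh_sum$by_length, p("roh_by_length.tsv"))
  paths["roh_chr"] <- write_tsv(roh_sum$by_chromosome,
                                p("roh_by_chromosome.tsv"))
  paths["roh_tot"] <- write_tsv(roh_sum$by_sample_total,
                                p("roh_by_sample_total.tsv"))

  paths["ibs"] <- write_tsv(as.data.frame(ibs), p("ibs_matrix.tsv"),
                            rn = TRUE)
  paths["grm"] <- write_tsv(as.data.frame(grm$G), p("grm.tsv"), rn = TRUE)
  pca_tab <- data.frame(id = rownames(pca$coordinates), pca$coordinates)
  paths["pca"] <- write_tsv(pca_tab, p("pca_coordinates.tsv"))
  paths["eigen"] <- write_tsv(
    data.frame(component = seq_along(pca$eigenvalues),
               eigenvalue = pca$eigenvalues,
               var_explained = pca$var_explained),
    p("pca_eigenvalues.tsv"))

  writeLines(to_newick(tree_all), p("tree_all_samples.nwk"))
  paths["tree_all"] <- p("tree_all_samples.nwk")
  if (!is.null(tree_bulls)) {
    writeLines(to_newick(tree_bulls), p("tree_bulls.nwk"))
    paths["tree_bulls"] <- p("tree_bulls.nwk")
  }
  if (!is.null(fam)) {
    paths["families"] <- write_tsv(fam$assignments, p("families.tsv"))
  }

  manifest <- c(
    paste0("herdgen version: ",
           as.character(utils::packageVersion("herdgen"))),
    paste0("input md5: ",
           paste(names(inputs), unname(tools::md5sum(inputs)),
                 sep = "=", collapse = " ")),
    paste0("thresholds: ", deparse1(unclass(thresholds))),
    paste0("roh_params: ", deparse1(unclass(roh))),
    paste0("ne_bins_cM: ", deparse1(ne_bins_cM)),
    paste0("map_rate_cM_per_Mb: ", map_rate),
    paste0("kinship_threshold: ", kinship_threshold))
  writeLines(manifest, p("manifest.txt"))
  paths["manifest"] <- p("manifest.txt")
  paths
}

#' Simulate a cohort and write it as a pipeline-ready fixture
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
simulate_command <- function(cfg, out_dir) {
  if (cfg$n_chromosomes * cfg$markers_per_chromosome == 0L)
    stop("refusing to simulate a cohort with zero markers")
  sim <- simulate_cohort(cfg)
  paths <- write_fixture(sim$genotypes, sim$truth, out_dir)
  fams <- unique(stats::na.omit(sim$truth$samples$family))
  cat(sprintf("simulated %d samples x %d markers (%d true families) -> %s\n",
              n_samples(sim$genotypes), n_markers(sim$genotypes),
              length(setdiff(fams, "other")), out_dir))
  invisible(paths)
}
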