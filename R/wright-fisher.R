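#' Forward Wright-Fisher simulation of drift-generated LD
#'
#' Simulates a closed random-mating diploid population of constant size on
#' one chromosome: haplotypes start in linkage equilibrium at frequency
#' `init_freq`, and each generation every offspring haplotype is a
#' recombinant of a random parent's two haplotypes (Poisson crossovers at a
#' constant map rate, no interference, no mutation, no selection). After
#' `n_generations` of drift, `n_sampled` diploids are drawn without
#' replacement. Linkage disequilibrium at genetic distance c then follows
#' Sved's expectation `E[r2] ~ 1/(1 + 4 N c)`, which is what
#' [estimate_ne()] inverts; this simulator is the independent ground truth
#' for that estimator.
#'
#' @param n_diploid Population size N.
#' @param n_generations Generations of drift (of order 2N to approach
#'   equilibrium).
#' @param n_markers Markers, evenly spaced.
#' @param chromosome_length_bp Chromosome length (bp).
#' @param recomb_rate_cM_per_Mb Constant map rate.
#' @param n_sampled Diploids genotyped at the end.
#' @param init_freq Initial allele-b frequency.
#' @param seed Integer seed (mandatory).
#' @return A [genotype_matrix()] of the sampled diploids (monomorphic
#'   markers retained; chromosome label "1").
#' @export
sim_wright_fisher <- function(n_diploid = 100L, n_generations = 200L,
                              n_markers = 2000L,
                              chromosome_length_bp = 1e8,
                              recomb_rate_cM_per_Mb = 1,
                              n_sampled = 50L, init_freq = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  if (n_sampled > n_diploid) stop("cannot sample more diploids than exist")
  L <- chromosome_length_bp
  m <- as.integer(n_markers)
  pos <- as.integer(round(seq(L / (m + 1), L * m / (m + 1),
                              length.out = m)))
  pos <- unique(pos)
  m <- length(pos)
  morgans <- L / 1e6 * recomb_rate_cM_per_Mb / 100
  nh <- 2L * n_diploid

  haps <- matrix(stats::rbinom(nh * m, 1L, init_freq), nh, m)
  for (gen in seq_len(n_generations)) {
    parent <- sample.int(n_diploid, nh, replace = TRUE)
    k <- stats::rpois(nh, morgans)
    start <- sample.int(2L, nh, replace = TRUE)
    nxt <- matrix(0L, nh, m)
    plain <- which(k == 0L)
    if (length(plain))
      nxt[plain, ] <- haps[2L * parent[plain] - 2L + start[plain], ,
                           drop = FALSE]
    for (h in which(k > 0L)) {
      xo <- sort(stats::runif(k[h], 0, L))
      phase <- (findInterval(pos, xo) + start[h]) %% 2L  # 0 or 1
      rows <- 2L * parent[h] - 1L + phase
      nxt[h, ] <- haps[cbind(rows, seq_len(m))]
    }
    haps <- nxt
  }
  pick <- sort(sample.int(n_diploid, n_sampled))
  dosage <- haps[2L * pick - 1L, , drop = FALSE] +
            haps[2L * pick, , drop = FALSE]
  genotype_matrix(dosage,
                  data.frame(id = sprintf("wf%03d", pick), sex = "unknown",
                             stringsAsFactors = FALSE),
                  data.frame(id = sprintf("m%05d", seq_len(m)),
                             chromosome = "1", position_bp = pos,
                             allele_a = "A", allele_b = "B",
                             stringsAsFactors = FALSE))
}
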