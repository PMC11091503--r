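#' Configuration for the synthetic reciprocal-cross study generator
#'
#' Collects every tunable of the synthetic-data generator.  The defaults
#' emulate the reciprocal White Leghorn (WW) x Beijing You (YY) layer design:
#' four genetic groups (WW, YY and the reciprocal crosses WY, YW), four
#' tissues with eight birds per group per tissue (six for ovary),
#' negative-binomial counts with planted inheritance patterns,
#' tissue-specific expression masks, single-parent-expressed (SPE) circRNAs,
#' circRNA/host-gene co-expression coupling, and one latent co-expression
#' module whose members track residual feed intake (RFI).
#'
#' @param seed Integer seed.  One global seed is expanded into fixed
#'   per-stage substreams so phenotypes, counts and annotation can be
#'   regenerated independently.
#' @param group_sizes Named integer vector, number of phenotyped birds per
#'   genetic group.  Defaults to the study population (198 WW, 245 YY,
#'   238 YW, 223 WY).
#' @param birds_per_group_per_tissue Named integer vector (per tissue),
#'   number of birds per group sequenced in that tissue; >= 3.  Default 8
#'   per tissue and 6 for ovary.
#' @param tissues Character vector of tissue names.
#' @param n_circ,n_gene Numbers of circRNA and gene features.
#' @param nb_dispersion Negative-binomial dispersion alpha in
#'   Var = mu + alpha * mu^2, constant per feature.  `0` switches the
#'   generator to its deterministic noise-free mode (counts = rounded means).
#' @param baseline_mean_range Length-2 positive range of baseline expression
#'   (CPM units); per-feature baselines are drawn log-uniformly.
#' @param pattern_proportions Named fractions of features planted per
#'   inheritance class (`additive`, `dominant`, `overdominant`,
#'   `underdominant`); must sum to <= 1, remainder is conserved.
#' @param lfc_effect Planted log2 fold change magnitude between groups
#'   (default 1.5, comfortably above the |log2FC| > 1 calling gate).
#' @param heterosis_delta Named list, trait -> named numeric
#'   `c(WY = , YW = )` fractional mid-parent heterosis planted for that
#'   trait.  Traits not listed get zero heterosis.
#' @param module_spec List describing the planted RFI-linked module:
#'   `size` (members), `n_circ` (circRNA members), `target_r` (target
#'   |correlation| between module eigengene and RFI; default 0.62),
#'   `tissue` (where the coupling acts), `loading` (log-scale amplitude of
#'   the latent factor on member means).
#' @param spe_fraction Fraction of circRNAs planted as single-parent
#'   expressed (half SPE_W, half SPE_Y).
#' @param tissue_specific_fraction Fraction of circRNAs expressed in a
#'   single tissue only (zero mean elsewhere).
#' @param host_coupling_rho Correlation in `[0, 1]` between the latent
#'   log-scale factor of an exonic/intronic circRNA and its host gene.
#' @param host_coupling_sd Standard deviation of the shared log-normal
#'   factor behind circRNA/host coupling.
#' @param depth_mean,depth_cv Mean and coefficient of variation of
#'   per-sample mapped-read totals.
#' @param phenotype_params Group-level phenotype means/SDs and the linear
#'   coefficients generating daily feed consumption (DFC) from metabolic
#'   body weight (MBW), body weight gain (BWG) and daily egg mass (DEM);
#'   see [default_phenotype_params()].
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [generate_phenotypes()], [generate_counts()],
#'   [generate_annotation()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_circ = 50, n_gene = 100)
#' cfg$module_spec$target_r
sim_config <- function(seed = 1L,
                       group_sizes = c(WW = 198L, YY = 245L, YW = 238L, WY = 223L),
                       birds_per_group_per_tissue = c(hypothalamus = 8L, liver = 8L,
                                                      duodenum = 8L, ovary = 6L),
                       tissues = c("hypothalamus", "liver", "duodenum", "ovary"),
                       n_circ = 300L,
                       n_gene = 700L,
                       nb_dispersion = 0.1,
                       baseline_mean_range = c(0.5, 50),
                       pattern_proportions = c(additive = 0.05, dominant = 0.10,
                                               overdominant = 0.05, underdominant = 0.05),
                       lfc_effect = 1.5,
                       heterosis_delta = list(DFC = c(WY = 0.01, YW = -0.04),
                                              DEM = c(WY = 0.05, YW = 0)),
                       module_spec = list(size = 60L, n_circ = 10L, target_r = 0.62,
                                          tissue = "hypothalamus", loading = 1.0),
                       spe_fraction = 0.05,
                       tissue_specific_fraction = 0.4,
                       host_coupling_rho = 0.7,
                       host_coupling_sd = 0.5,
                       depth_mean = 2e7,
                       depth_cv = 0.2,
                       phenotype_params = default_phenotype_params()) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  if (is.null(names(group_sizes)) || !all(PARENTS %in% names(group_sizes)))
    stop("'group_sizes' must be named and include WW and YY")
  if (any(group_sizes < 0)) stop("'group_sizes' must be non-negative")
  if (length(tissues) < 1L) stop("at least one tissue required")
  bpg <- birds_per_group_per_tissue
  if (is.null(names(bpg))) {
    if (length(bpg) == 1L) bpg <- setNames(rep(bpg, length(tissues)), tissues)
    else stop("'birds_per_group_per_tissue' must be named by tissue")
  }
  if (!all(tissues %in% names(bpg)))
    stop("'birds_per_group_per_tissue' missing tissues: ",
         paste(setdiff(tissues, names(bpg)), collapse = ", "))
  bpg <- bpg[tissues]
  if (any(bpg < 3L)) stop("'birds_per_group_per_tissue' must be >= 3")
  if (n_circ < 0 || n_gene < 0) stop("feature counts must be >= 0")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0)
    stop("'nb_dispersion' must be a non-negative real")
  if (length(baseline_mean_range) != 2L || any(baseline_mean_range <= 0) ||
      diff(baseline_mean_range) < 0)
    stop("'baseline_mean_range' must be an increasing positive range")
  if (any(pattern_proportions < 0) || sum(pattern_proportions) > 1 + 1e-12)
    stop("'pattern_proportions' must be non-negative and sum to <= 1")
  bad <- setdiff(names(pattern_proportions),
                 c("additive", "dominant", "overdominant", "underdominant"))
  if (length(bad)) stop("unknown pattern classes: ", paste(bad, collapse = ", "))
  hd <- lapply(heterosis_delta, function(d) {
    if (length(d) == 1L && is.null(names(d))) d <- c(WY = unname(d), YW = unname(d))
    if (!all(CROSSES %in% names(d))) stop("heterosis_delta entries need WY and YW")
    if (any(!is.finite(d))) stop("heterosis_delta must be finite")
    d[CROSSES]
  })
  ms <- module_spec
  ms$size <- as.integer(ms$size)
  if (is.null(ms$loading)) ms$loading <- 1.0
  if (ms$size > n_circ + n_gene)
    stop("module size exceeds the number of features")
  if (ms$n_circ > ms$size) stop("module_spec$n_circ exceeds module size")
  if (!ms$tissue %in% tissues) stop("module_spec$tissue not in 'tissues'")
  if (abs(ms$target_r) > 1) stop("module_spec$target_r must be in [-1, 1]")
  if (spe_fraction < 0 || spe_fraction > 1) stop("'spe_fraction' in [0, 1]")
  if (tissue_specific_fraction < 0 || tissue_specific_fraction > 1)
    stop("'tissue_specific_fraction' in [0, 1]")
  if (host_coupling_rho < 0 || host_coupling_rho > 1)
    stop("'host_coupling_rho' must lie in [0, 1]")
  .validate_phenotype_params(phenotype_params)

  structure(list(seed = as.integer(seed),
                 group_sizes = group_sizes,
                 birds_per_group_per_tissue = bpg,
                 tissues = tissues,
                 n_circ = as.integer(n_circ), n_gene = as.integer(n_gene),
                 nb_dispersion = nb_dispersion,
                 baseline_mean_range = baseline_mean_range,
                 pattern_proportions = pattern_proportions,
                 lfc_effect = lfc_effect,
                 heterosis_delta = hd,
                 module_spec = ms,
                 spe_fraction = spe_fraction,
                 tissue_specific_fraction = tissue_specific_fraction,
                 host_coupling_rho = host_coupling_rho,
                 host_coupling_sd = host_coupling_sd,
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 phenotype_params = phenotype_params),
            class = "sim_config")
}

#' Default group-level phenotype parameters for the generator
#'
#' Means and standard deviations of body weight (BW, kg), body weight gain
#' (BWG, g/d) and daily egg mass (DEM, g/d) for the two parental lines, and
#' the linear coefficients producing daily feed consumption (DFC, g/d) from
#' MBW, BWG and DEM.  The within-group variances are the package's own
#' choices (not reported values); the implied group DFC means fall inside
#' the published 90.84-103.27 g/d range and DEM means inside
#' 36.85-52.85 g/d.
#'
#' @return A list with elements `means` (per-trait named vectors for WW and
#'   YY), `sds` (per-trait SDs, `DFC` being the residual SD around the
#'   linear model) and `dfc_beta` (intercept and coefficients on MBW, BWG,
#'   DEM).
#' @export
default_phenotype_params <- function() {
  list(means = list(BW  = c(WW = 1.75, YY = 2.05),
                    BWG = c(WW = 2.0,  YY = 3.0),
                    DEM = c(WW = 52,   YY = 37)),
       sds = c(BW = 0.15, BWG = 0.8, DEM = 4, DFC = 7),
       dfc_beta = c(intercept = 8, MBW = 40, BWG = 0.8, DEM = 0.5))
}

.validate_phenotype_params <- function(p) {
  stopifnot(is.list(p), all(c("means", "sds", "dfc_beta") %in% names(p)))
  if (any(p$sds < 0)) stop("phenotype standard deviations must be non-negative")
  for (tr in c("BW", "BWG", "DEM"))
    if (!all(PARENTS %in% names(p$means[[tr]])))
      stop("phenotype means for ", tr, " must include WW and YY")
  if (!all(c("intercept", "MBW", "BWG", "DEM") %in% names(p$dfc_beta)))
    stop("dfc_beta must name intercept, MBW, BWG, DEM")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sum(x$group_sizes), "birds in", length(x$group_sizes), "groups;",
      length(x$tissues), "tissues;",
      x$n_circ, "circRNAs +", x$n_gene, "genes\n")
  cat("  planted classes:",
      paste(sprintf("%s=%.0f%%", names(x$pattern_proportions),
                    100 * x$pattern_proportions), collapse = ", "),
      sprintf("| lfc=%.2g, dispersion=%.2g\n", x$lfc_effect, x$nb_dispersion))
  cat(sprintf("  module: %d members (%d circ) in %s, target |r|=%.2f with RFI\n",
              x$module_spec$size, x$module_spec$n_circ,
              x$module_spec$tissue, abs(x$module_spec$target_r)))
  invisible(x)
}

# Per-stage substream of the global seed, kept below 2^31.
.stage_seed <- function(seed, stage) {
  off <- c(plan = 11L, phenotypes = 23L, counts = 37L, annotation = 53L)[stage]
  as.integer((abs(seed) %% 2000000L) * 1000L + off)
}
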