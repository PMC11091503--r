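#' Generate phenotypes with planted mid-parent heterosis
#'
#' Draws per-bird body weight (BW), body weight gain (BWG) and daily egg
#' mass (DEM) from group-level normals, then builds daily feed consumption
#' (DFC) as a linear function of metabolic body weight (MBW = BW^0.75), BWG
#' and DEM plus a cross-specific heterosis shift and Gaussian noise -- the
#' generative inverse of the residual-feed-intake regression, so that with
#' zero noise and zero planted heterosis the fitted RFI is exactly zero for
#' every bird.  Cross group means for BW/BWG/DEM are mid-parent values
#' scaled by `1 + heterosis_delta[[trait]][cross]`; planted DFC heterosis is
#' an additive shift of `delta * mid-parent DFC` on top of the linear
#' predictor, making the expected cross mean `(1 + delta) * mid-parent DFC`
#' up to the (negligible) curvature of `BW^0.75` across groups.
#'
#' @param config A [sim_config()].
#' @return A list with `phenotypes` (data frame: `bird_id`, `group`, `BW`,
#'   `BWG`, `DEM`, `DFC`) and `truth` (list: `heterosis` -- data frame of
#'   true fractional heterosis per trait x cross; `dfc_residual` -- the true
#'   per-bird noise term of the DFC model, used downstream to couple module
#'   expression to RFI; `dfc_beta` -- the generating coefficients).
#' @export
#' @examples
#' sim <- generate_phenotypes(sim_config(seed = 7))
#' aggregate(DFC ~ group, sim$phenotypes, mean)
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$phenotype_params
  if (any(p$sds < 0)) stop("non-positive variance parameters are invalid")
  set.seed(.stage_seed(config$seed, "phenotypes"))

  delta <- function(tr, g) {
    d <- config$heterosis_delta[[tr]]
    if (!is.null(d) && g %in% names(d)) unname(d[g]) else 0
  }
  # expected group means (MBW approximated at the mean BW; the Jensen gap is
  # negligible at the default SDs and is absorbed by test tolerances)
  beta <- p$dfc_beta
  mean_of <- function(tr, g) {
    if (g %in% PARENTS) return(unname(p$means[[tr]][g]))
    mp <- mean(p$means[[tr]][PARENTS])
    mp * (1 + delta(tr, g))
  }
  exp_dfc <- function(g) {
    unname(beta["intercept"] + beta["MBW"] * mean_of("BW", g)^0.75 +
             beta["BWG"] * mean_of("BWG", g) + beta["DEM"] * mean_of("DEM", g))
  }
  mp_dfc <- (exp_dfc("WW") + exp_dfc("YY")) / 2

  rows <- list()
  resid_all <- list()
  for (g in names(config$group_sizes)) {
    n <- config$group_sizes[[g]]
    if (n == 0L) next
    BW  <- pmax(rnorm(n, mean_of("BW", g),  p$sds["BW"]),  1e-6)
    BWG <- rnorm(n, mean_of("BWG", g), p$sds["BWG"])
    DEM <- pmax(rnorm(n, mean_of("DEM", g), p$sds["DEM"]), 0)
    # planted DFC heterosis enters additively on top of the linear predictor,
    # so zero delta leaves DFC exactly linear in (MBW, BWG, DEM)
    shift <- if (g %in% CROSSES) delta("DFC", g) * mp_dfc else 0
    eps <- rnorm(n, 0, p$sds["DFC"])
    DFC <- pmax(beta["intercept"] + beta["MBW"] * BW^0.75 +
                  beta["BWG"] * BWG + beta["DEM"] * DEM + shift + eps, 0)
    rows[[g]] <- data.frame(bird_id = sprintf("%s_%03d", g, seq_len(n)),
                            group = g, BW = BW, BWG = BWG, DEM = DEM,
                            DFC = unname(DFC), stringsAsFactors = FALSE)
    resid_all[[g]] <- setNames(eps, rows[[g]]$bird_id)
  }
  phen <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  truth_h <- do.call(rbind, lapply(c("BW", "BWG", "DEM", "DFC"), function(tr) {
    data.frame(trait = tr, cross = CROSSES,
               H_true = vapply(CROSSES, delta, numeric(1), tr = tr),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  list(phenotypes = phen,
       truth = list(heterosis = truth_h,
                    dfc_residual = unlist(unname(resid_all)),
                    dfc_beta = beta))
}
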