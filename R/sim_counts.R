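# Feature plan: everything that must agree between the count generator and
# the annotation generator (region classes, host pairing, planted patterns,
# SPE labels, tissue masks, module membership).  Derived from its own seed
# substream so both stages reproduce it independently.
.feature_plan <- function(config) {
  set.seed(.stage_seed(config$seed, "plan"))
  n_circ <- config$n_circ
  n_gene <- config$n_gene
  n_feat <- n_circ + n_gene
  circ_ids <- if (n_circ) sprintf("circ_%04d", seq_len(n_circ)) else character(0)
  gene_ids <- if (n_gene) sprintf("gene_%04d", seq_len(n_gene)) else character(0)

  # genomic region classes for circRNAs (defaults mirror the observed
  # predominance of exonic circRNAs)
  region_props <- c(exonic = 0.80, intronic = 0.132,
                    intergenic = 0.055, antisense = 0.013)
  region <- character(n_circ)
  if (n_circ) {
    k <- floor(region_props * n_circ)
    k["exonic"] <- n_circ - sum(k[-1])
    region <- sample(rep(names(k), k))
    if (n_gene == 0 && any(region != "intergenic"))
      region[] <- "intergenic"
  }
  host <- rep(NA_character_, n_circ)
  asense <- rep(NA_character_, n_circ)
  if (n_gene) {
    hosted <- region %in% c("exonic", "intronic")
    host[hosted] <- sample(gene_ids, sum(hosted), replace = TRUE)
    asense[region == "antisense"] <- sample(gene_ids, sum(region == "antisense"),
                                            replace = TRUE)
  }

  # planted inheritance classes over all features
  props <- config$pattern_proportions
  class_pool <- c("additive", "dominant", "overdominant", "underdominant")
  k_class <- round(props[class_pool] * n_feat)
  k_class[is.na(k_class)] <- 0
  class_vec <- rep("conserved", n_feat)
  if (sum(k_class) > 0 && n_feat > 0) {
    idx <- sample.int(n_feat, sum(k_class))
    class_vec[idx] <- rep(class_pool, k_class)
  }
  roman_by_class <- list(additive = c("IV", "X"),
                         dominant = c("III", "V", "IX", "XI"),
                         overdominant = c("I", "II", "XII"),
                         underdominant = c("VI", "VII", "VIII"))
  pattern_vec <- rep("conserved", n_feat)
  for (cl in class_pool) {
    at <- which(class_vec == cl)
    if (length(at))
      pattern_vec[at] <- sample(roman_by_class[[cl]], length(at), replace = TRUE)
  }

  kind <- c(rep("circ", n_circ), rep("gene", n_gene))
  ids <- c(circ_ids, gene_ids)

  # SPE circRNAs drawn from conserved circRNAs
  spe <- rep("none", n_feat)
  n_spe <- round(config$spe_fraction * n_circ)
  cand <- which(kind == "circ" & class_vec == "conserved")
  n_spe <- min(n_spe, length(cand))
  if (n_spe > 0) {
    at <- sample(cand, n_spe)
    spe[at] <- rep(c("SPE_W", "SPE_Y"), length.out = n_spe)
  }

  # planted RFI-linked module from conserved, non-SPE features
  ms <- config$module_spec
  module <- rep(FALSE, n_feat)
  free_c <- which(kind == "circ" & class_vec == "conserved" & spe == "none")
  free_g <- which(kind == "gene" & class_vec == "conserved" & spe == "none")
  n_mc <- min(ms$n_circ, length(free_c))
  n_mg <- min(ms$size - n_mc, length(free_g))
  if (ms$size > 0) {
    if (n_mc + n_mg < ms$size)
      warning("not enough conserved features for the full planted module; ",
              "planting ", n_mc + n_mg, " members")
    module[c(if (n_mc) sample(free_c, n_mc),
             if (n_mg) sample(free_g, n_mg))] <- TRUE
  }

  # tissue masks: a fraction of non-module, non-SPE circRNAs are
  # tissue-specific; everything else is expressed in all tissues
  masks <- rep(list(config$tissues), n_feat)
  ts_cand <- which(kind == "circ" & !module & spe == "none")
  n_ts <- round(config$tissue_specific_fraction * n_circ)
  n_ts <- min(n_ts, length(ts_cand))
  if (n_ts > 0) {
    at <- sample(ts_cand, n_ts)
    for (i in at) masks[[i]] <- sample(config$tissues, 1L)
  }

  baseline <- 10^runif(n_feat, log10(config$baseline_mean_range[1]),
                       log10(config$baseline_mean_range[2]))

  list(feature_id = ids, kind = kind,
       region = c(region, rep(NA_character_, n_gene)),
       host = c(host, rep(NA_character_, n_gene)),
       asense = c(asense, rep(NA_character_, n_gene)),
       class = class_vec, pattern = pattern_vec, spe = spe,
       module = module, masks = masks, baseline = baseline,
       circ_ids = circ_ids, gene_ids = gene_ids)
}

# Group mean multipliers realizing a planted pattern; L = 2^lfc_effect.
# The cross multiplier applies to both WY and YW.
.pattern_multipliers <- function(pattern, L) {
  m <- switch(pattern,
              conserved = c(1, 1, 1),
              IV   = c(L, 1, (L + 1) / 2),
              X    = c(1, L, (L + 1) / 2),
              V    = c(1, L, 1),
              XI   = c(L, 1, L),
              III  = c(1, L, L),
              IX   = c(L, 1, 1),
              I    = c(1, 1, L),
              II   = c(L, 1, L^2),
              XII  = c(1, L, L^2),
              VII  = c(1, 1, 1 / L),
              VI   = c(L, 1, 1 / L),
              VIII = c(1, L, 1 / L),
              stop("unknown pattern: ", pattern))
  c(WW = m[1], YY = m[2], WY = m[3], YW = m[3])
}

#' Generate circRNA/gene count matrices with planted ground truth
#'
#' Produces negative-binomial back-spliced-junction (circRNA) and gene count
#' matrices over the configured groups and tissues.  Group mean multipliers
#' encode the planted inheritance pattern of each feature; SPE circRNAs are
#' expressed in one parent only; tissue-specific features have zero mean
#' outside their tissue; members of the planted module load on a latent
#' factor linearly tied to each bird's true feed-intake residual at the
#' configured correlation; exonic/intronic circRNAs share a log-normal
#' latent factor with their host gene at `host_coupling_rho`.
#'
#' @param config A [sim_config()].
#' @param phenotypes Result of [generate_phenotypes()] (the module coupling
#'   uses its true DFC residuals).
#' @return List with `circ_counts` and `gene_counts` (integer matrices,
#'   features x samples), `meta` (data frame: `sample_id`, `bird_id`,
#'   `tissue`, `group`, `mapped_reads`) and `truth` (list: `features` data
#'   frame with planted pattern/class per cross, SPE label, tissue mask,
#'   module membership, host gene and baseline CPM; `module` with members,
#'   tissue, target correlation and the latent factor per sample).
#' @export
generate_counts <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(phenotypes$phenotypes) || is.null(phenotypes$truth$dfc_residual))
    stop("'phenotypes' must be the result of generate_phenotypes()")
  plan <- .feature_plan(config)
  set.seed(.stage_seed(config$seed, "counts"))

  phen <- phenotypes$phenotypes
  n_need <- max(config$birds_per_group_per_tissue)
  birds_by_group <- lapply(setNames(GROUPS, GROUPS), function(g) {
    ids <- phen$bird_id[phen$group == g]
    if (length(ids) < n_need)
      stop("group ", g, " has fewer phenotyped birds (", length(ids),
           ") than required per tissue (", n_need, ")")
    head(ids, n_need)
  })

  meta <- do.call(rbind, lapply(config$tissues, function(t) {
    k <- config$birds_per_group_per_tissue[[t]]
    do.call(rbind, lapply(GROUPS, function(g) {
      b <- head(birds_by_group[[g]], k)
      data.frame(sample_id = paste(b, t, sep = "."), bird_id = b,
                 tissue = t, group = g, stringsAsFactors = FALSE)
    }))
  }))
  n_samp <- nrow(meta)
  n_feat <- length(plan$feature_id)

  # per-group expected CPM per feature
  L <- 2^config$lfc_effect
  cpm_group <- t(vapply(seq_len(n_feat), function(i) {
    if (plan$spe[i] != "none") {
      hi <- max(plan$baseline[i], 2)
      on <- if (plan$spe[i] == "SPE_W") "WW" else "YY"
      off <- setdiff(PARENTS, on)
      m <- c(WW = 0, YY = 0, WY = hi / 2, YW = hi / 2)
      m[on] <- hi; m[off] <- 0.02
      m[GROUPS]
    } else {
      plan$baseline[i] * .pattern_multipliers(plan$pattern[i], L)[GROUPS]
    }
  }, numeric(4)))
  colnames(cpm_group) <- GROUPS

  mask <- vapply(config$tissues, function(t)
    vapply(plan$masks, function(m) t %in% m, logical(1)),
    logical(n_feat))
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = n_feat)
  colnames(mask) <- config$tissues

  # latent log-scale factors ------------------------------------------------
  sdlat <- config$host_coupling_sd
  rho <- config$host_coupling_rho
  fac <- matrix(0, n_feat, n_samp)
  gi <- which(plan$kind == "gene")
  if (length(gi)) {
    h <- matrix(rnorm(length(gi) * n_samp, 0, sdlat), length(gi), n_samp)
    rownames(h) <- plan$feature_id[gi]
    fac[gi, ] <- h
    for (i in which(plan$kind == "circ")) {
      hg <- plan$host[i]
      if (!is.na(hg) && hg %in% rownames(h)) {
        fac[i, ] <- rho * h[hg, ] +
          sqrt(1 - rho^2) * rnorm(n_samp, 0, sdlat)
      } else {
        fac[i, ] <- rnorm(n_samp, 0, sdlat)
      }
    }
  } else {
    fac[] <- rnorm(n_feat * n_samp, 0, sdlat)
  }

  # planted module: members load on a latent factor tied to the bird's true
  # DFC residual (the generative RFI) in the module tissue.  The noise
  # component is orthogonalized against the standardized residual so the
  # latent's in-sample correlation with the residual equals target_r exactly.
  ms <- config$module_spec
  latent <- rep(NA_real_, n_samp)
  mem <- which(plan$module)
  if (length(mem)) {
    at <- which(meta$tissue == ms$tissue)
    res <- phenotypes$truth$dfc_residual[meta$bird_id[at]]
    z <- if (sd(res) > 0) (res - mean(res)) / sd(res) else res * 0
    eta <- rnorm(length(at))
    eta <- eta - mean(eta)
    if (sd(res) > 0) eta <- eta - z * sum(eta * z) / sum(z * z)
    if (sd(eta) > 0) eta <- eta / sd(eta)
    g <- ms$target_r * z + sqrt(max(0, 1 - ms$target_r^2)) * eta
    latent[at] <- g
    fac[mem, at] <- fac[mem, at] +
      matrix(ms$loading * g, length(mem), length(at), byrow = TRUE)
  }

  sdlog <- sqrt(log(1 + config$depth_cv^2))
  depth <- round(config$depth_mean * exp(rnorm(n_samp, -sdlog^2 / 2, sdlog)))

  mu <- cpm_group[, meta$group, drop = FALSE] *
    mask[, meta$tissue, drop = FALSE] * exp(fac) *
    matrix(depth / 1e6, n_feat, n_samp, byrow = TRUE)

  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           n_feat, n_samp)
  } else {
    round(mu)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(plan$feature_id, meta$sample_id)

  meta$mapped_reads <- pmax(depth, colSums(counts) + 1L)

  features <- data.frame(feature_id = plan$feature_id, kind = plan$kind,
                         pattern_WY = plan$pattern, pattern_YW = plan$pattern,
                         class = plan$class, spe = plan$spe,
                         tissues = vapply(plan$masks, paste, "", collapse = ";"),
                         module = plan$module,
                         host_gene = plan$host, region_class = plan$region,
                         baseline_cpm = plan$baseline,
                         stringsAsFactors = FALSE)

  list(circ_counts = counts[plan$kind == "circ", , drop = FALSE],
       gene_counts = counts[plan$kind == "gene", , drop = FALSE],
       meta = meta,
       truth = list(features = features,
                    module = list(members = plan$feature_id[mem],
                                  tissue = ms$tissue, target_r = ms$target_r,
                                  latent = setNames(latent, meta$sample_id))))
}
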