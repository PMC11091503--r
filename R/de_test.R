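#' Median-of-ratios size factors
#'
#' Per-sample normalization factors against the geometric-mean
#' pseudo-reference, computed over features with all-positive counts.  If
#' no feature is positive in every sample, total-count factors (scaled to
#' geometric mean 1) are used with a warning.
#'
#' @param counts Count matrix, features x samples (>= 2 samples).
#' @return Named positive numeric vector of factors, one per sample.
#' @export
normalize_size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with positive counts in every sample; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample(s) with zero total counts")
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(counts)))
  }
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - ref)))
  setNames(sf, colnames(counts))
}

# Wald test on the log ratio of group means of (already normalized) counts.
# Per-feature dispersion by method of moments within each group, averaged
# across groups, moderated halfway toward the across-feature median (the
# raw n=8 moment estimate is very noisy; moderation keeps the small-sample
# type-I error centred on nominal -- checked by simulation in the test
# suite) and floored.  The statistic is referred to a t distribution with
# nA + nB - 2 df.
.nb_wald <- function(normA, normB, pseudo = 0.5, disp_floor = 1e-8,
                     disp_moderation = 0.5) {
  nA <- ncol(normA); nB <- ncol(normB)
  mA <- rowMeans(normA); mB <- rowMeans(normB)
  vA <- apply(normA, 1, var); vB <- apply(normB, 1, var)
  dispA <- (vA - mA) / mA^2
  dispB <- (vB - mB) / mB^2
  w <- function(d) ifelse(is.finite(d), d, NA_real_)
  disp <- rowMeans(cbind(w(dispA), w(dispB)), na.rm = TRUE)
  disp[!is.finite(disp)] <- 0
  expressed <- is.finite(disp) & (mA + mB) > 0
  if (any(expressed)) {
    med <- median(disp[expressed])
    disp <- (1 - disp_moderation) * disp + disp_moderation * med
  }
  disp <- pmax(disp, disp_floor)
  log2fc <- log2((mA + pseudo) / (mB + pseudo))
  seA <- (mA + disp * mA^2) / (nA * (mA + pseudo)^2)
  seB <- (mB + disp * mB^2) / (nB * (mB + pseudo)^2)
  se <- sqrt(seA + seB)
  z <- ifelse(se > 0, (log(mA + pseudo) - log(mB + pseudo)) / se, 0)
  p <- 2 * pt(-abs(z), df = nA + nB - 2)
  zero <- mA == 0 & mB == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  data.frame(feature_id = rownames(normA), log2FC = unname(log2fc),
             p = unname(p), base_mean_1 = unname(mA), base_mean_2 = unname(mB),
             stringsAsFactors = FALSE)
}

#' Negative-binomial Wald test between two groups
#'
#' Size-factor-normalized two-group comparison: per-feature
#' method-of-moments dispersion (floored at 1e-8) on normalized counts and
#' a Wald test on the group log fold change, with
#' `log2FC = log2((meanA + 0.5) / (meanB + 0.5))` on the normalized scale,
#' oriented first group over second.  All-zero features get `p = 1`,
#' `log2FC = 0`.
#'
#' @param counts Count matrix, features x samples.
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param groupA,groupB Group labels to contrast (>= 3 samples each).
#' @param size_factors Optional precomputed per-sample factors (defaults to
#'   [normalize_size_factors()] over all samples of `counts`).
#' @return Data frame: `feature_id`, `log2FC`, `p`, `base_mean_1`,
#'   `base_mean_2`, with the contrast name as attribute `"contrast"`.
#' @export
nb_differential_test <- function(counts, meta, groupA, groupB,
                                 size_factors = NULL) {
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  group <- meta$group[idx]
  sA <- which(group == groupA); sB <- which(group == groupB)
  if (length(sA) < 3L) stop("group ", groupA, " has fewer than 3 samples")
  if (length(sB) < 3L) stop("group ", groupB, " has fewer than 3 samples")
  if (is.null(size_factors)) size_factors <- normalize_size_factors(counts)
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  out <- .nb_wald(norm[, sA, drop = FALSE], norm[, sB, drop = FALSE])
  attr(out, "contrast") <- paste0(groupA, "_vs_", groupB)
  out
}

#' Cross versus pseudo-mid-parent test
#'
#' Operationalizes "cross equal to the average of WW and YY": builds
#' per-feature pseudo-mid-parent samples as the average of one WW and one
#' YY sample's normalized counts (random pairing under `seed`; unequal
#' parental sample counts are paired down to the minimum with a warning)
#' and applies the same Wald machinery to cross vs pseudo-mid-parent.
#'
#' @inheritParams nb_differential_test
#' @param cross `"WY"` or `"YW"` (>= 3 samples, as for both parents).
#' @param seed Integer controlling the random parental pairing.
#' @return As [nb_differential_test()], contrast `"<cross>_vs_midparent"`.
#' @export
midparent_test <- function(counts, meta, cross, size_factors = NULL,
                           seed = 1L) {
  if (!cross %in% CROSSES) stop("'cross' must be WY or YW")
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  group <- meta$group[idx]
  sW <- which(group == "WW"); sY <- which(group == "YY")
  sC <- which(group == cross)
  if (length(sW) < 3L || length(sY) < 3L || length(sC) < 3L)
    stop("need >= 3 samples in WW, YY and ", cross)
  if (is.null(size_factors)) size_factors <- normalize_size_factors(counts)
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  k <- min(length(sW), length(sY))
  if (length(sW) != length(sY))
    warning("unequal parental sample counts; pairing down to ", k)
  set.seed(as.integer(seed))
  pw <- sample(sW, k); py <- sample(sY, k)
  pseudo <- (norm[, pw, drop = FALSE] + norm[, py, drop = FALSE]) / 2
  colnames(pseudo) <- paste0("midparent_", seq_len(k))
  out <- .nb_wald(norm[, sC, drop = FALSE], pseudo)
  attr(out, "contrast") <- paste0(cross, "_vs_midparent")
  attr(out, "pairing") <- data.frame(WW = colnames(norm)[pw],
                                     YY = colnames(norm)[py])
  out
}
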