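#' MAD filter combining circRNA and gene expression
#'
#' Retains circRNAs with median absolute deviation (MAD, [stats::mad()])
#' greater than zero and genes in the top 25% by MAD, and concatenates the
#' two into one joint matrix for module detection; feature kind is kept
#' alongside for downstream network filtering.
#'
#' @param circ_expr,gene_expr Expression matrices (features x samples,
#'   same sample columns).
#' @param gene_top Fraction of genes kept (default 0.25).
#' @return List with `expr` (joint filtered matrix) and `kind` (named
#'   `"circ"`/`"gene"` vector over its rows).
#' @export
mad_filter <- function(circ_expr, gene_expr, gene_top = 0.25) {
  stopifnot(is.matrix(circ_expr), is.matrix(gene_expr),
            identical(colnames(circ_expr), colnames(gene_expr)))
  mad_c <- apply(circ_expr, 1, mad)
  keep_c <- mad_c > 0
  mad_g <- apply(gene_expr, 1, mad)
  n_keep <- ceiling(gene_top * nrow(gene_expr))
  keep_g <- rank(-mad_g, ties.method = "first") <= n_keep
  expr <- rbind(circ_expr[keep_c, , drop = FALSE],
                gene_expr[keep_g, , drop = FALSE])
  kind <- setNames(c(rep("circ", sum(keep_c)), rep("gene", sum(keep_g))),
                   rownames(expr))
  if (nrow(expr) < 50L)
    warning("fewer than 50 features retained; module detection will be ",
            "degenerate")
  list(expr = expr, kind = kind)
}

# Scale-free topology fit: R^2 of log10(frequency) vs log10(connectivity)
# over equal-width connectivity bins, plus the regression slope.
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2L) return(c(rsq = 0, slope = 0))
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3L) return(c(rsq = 0, slope = 0))
  x <- log10(kmean[keep]); y <- log10(freq[keep])
  fit <- lm(y ~ x)
  c(rsq = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Soft-thresholding power for a signed network
#'
#' Scans powers beta = 1..30 with the signed adjacency
#' `a_ij = ((1 + cor_ij) / 2)^beta` and returns the smallest beta whose
#' scale-free topology fit reaches `R^2 >= rsq_cut` with a negative slope.
#' If none fits, falls back on the sample-size rule: 18 if n < 20, 16 if
#' n < 30, 14 if n < 40, else 12.
#'
#' @param expr Filtered expression matrix, features x samples (> 2
#'   features).
#' @param powers Candidate powers (default 1:30).
#' @param rsq_cut Scale-free fit threshold (default 0.85).
#' @param n_samples Sample size used by the fallback rule (defaults to
#'   `ncol(expr)`).
#' @return List with `power`, `power_estimate` (`NA` when the fallback was
#'   used) and `fit_indices` (per-power R^2 and slope).
#' @export
pick_soft_threshold <- function(expr, powers = 1:30, rsq_cut = 0.85,
                                n_samples = ncol(expr)) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) <= 2L) stop("degenerate matrix: need more than 2 features")
  C <- cor(t(expr))
  S <- (1 + C) / 2
  diag(S) <- 0
  fits <- t(vapply(powers, function(b) .scale_free_fit(rowSums(S^b)),
                   c(rsq = 0, slope = 0)))
  fit_ind <- data.frame(power = powers, rsq = fits[, "rsq"],
                        slope = fits[, "slope"])
  ok <- fit_ind$rsq >= rsq_cut & fit_ind$slope < 0
  est <- if (any(ok)) powers[which(ok)[1]] else NA_integer_
  power <- if (!is.na(est)) est
           else if (n_samples < 20) 18L
           else if (n_samples < 30) 16L
           else if (n_samples < 40) 14L
           else 12L
  list(power = power, power_estimate = est, fit_indices = fit_ind)
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with unit diagonal.
#'
#' @param expr Expression matrix, features x samples.
#' @param power Soft-thresholding power beta.
#' @return Symmetric adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, power) {
  A <- ((1 + cor(t(expr))) / 2)^power
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`, the sum excluding `u = i, j`, and
#' `TOM_ii = 1`.
#'
#' @param adjacency Symmetric matrix, entries in `[0, 1]`, unit diagonal.
#' @return The TOM, symmetric with unit diagonal, entries in `[0, 1]`.
#' @export
compute_tom <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < -1e-12) || any(adjacency > 1 + 1e-12))
    stop("adjacency entries must lie in [0, 1]")
  A <- adjacency
  diag(A) <- 0
  L <- A %*% A                       # zero diagonal makes this sum_{u != i,j}
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Module eigengenes
#'
#' For each module, standardizes member profiles and takes the first right
#' singular vector of the standardized matrix (the first principal
#' component over samples), unit norm, with its sign aligned so that the
#' correlation with the module's mean standardized profile is
#' non-negative.
#'
#' @param expr Expression matrix, features x samples.
#' @param assignment Module assignment: data frame with `feature_id` and
#'   `module`, or a named vector; module `0`/`"grey"` is ignored.
#' @return Matrix samples x modules (columns `ME<label>`), with per-module
#'   variance explained as attribute `"var_explained"`.
#' @export
module_eigengene <- function(expr, assignment) {
  mods <- .as_assignment(assignment)
  mods <- mods[names(mods) %in% rownames(expr)]
  labs <- setdiff(sort(unique(mods)), c("0", "grey"))
  if (!length(labs)) stop("no assigned modules")
  me <- matrix(NA_real_, ncol(expr), length(labs),
               dimnames = list(colnames(expr), paste0("ME", labs)))
  ve <- setNames(numeric(length(labs)), paste0("ME", labs))
  for (j in seq_along(labs)) {
    rows <- names(mods)[mods == labs[j]]
    X <- expr[rows, , drop = FALSE]
    sds <- apply(X, 1, sd)
    if (all(sds == 0)) stop("module ", labs[j], " is all-constant")
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant profile(s) from module ",
              labs[j])
      X <- X[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    Z <- (X - rowMeans(X)) / sds
    sv <- svd(Z)
    v <- sv$v[, 1]
    if (cor(v, colMeans(Z)) < 0) v <- -v
    me[, j] <- v
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- ve
  me
}

.as_assignment <- function(assignment) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("feature_id", "module") %in% names(assignment)))
    setNames(as.character(assignment$module), assignment$feature_id)
  } else {
    stopifnot(!is.null(names(assignment)))
    setNames(as.character(assignment), names(assignment))
  }
}

#' Module detection by average-linkage clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a
#' configurable quantile of the merge heights (a static-height tree cut);
#' clusters smaller than `min_size` are unassigned (module 0); module
#' pairs whose eigengene Pearson correlation is at least `merge_cor` are
#' merged iteratively until stable.  Modules are labelled `1, 2, ...` by
#' decreasing size, 0 meaning unassigned.
#'
#' @param tom TOM from [compute_tom()], dimnames = feature ids.
#' @param expr Expression matrix (features x samples) used for eigengene
#'   merging and kME.
#' @param min_size Minimum module size (default 50, the design's rule that
#'   a module contains at least 50 circRNAs/genes).
#' @param merge_cor Eigengene correlation at or above which modules are
#'   merged (default 0.75, i.e. eigengene dissimilarity 0.25).
#' @param cut_quantile Quantile of merge heights where the tree is cut
#'   (default 0.99).
#' @return Data frame: `feature_id`, `module`, `kme` (correlation of the
#'   feature with its module eigengene; `NA` when unassigned).
#' @export
detect_modules <- function(tom, expr, min_size = 50L, merge_cor = 0.75,
                           cut_quantile = 0.99) {
  stopifnot(is.matrix(tom), !is.null(rownames(tom)),
            all(rownames(tom) %in% rownames(expr)))
  hc <- hclust(as.dist(1 - tom), method = "average")
  h <- quantile(hc$height, cut_quantile)
  cl <- cutree(hc, h = h)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_size])] <- 0L
  cl <- .relabel_by_size(cl)

  repeat {
    labs <- setdiff(unique(cl), 0L)
    if (length(labs) < 2L) break
    me <- module_eigengene(expr[rownames(tom), , drop = FALSE],
                           setNames(cl, rownames(tom)))
    cm <- cor(me)
    diag(cm) <- -Inf
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (max(cm) < merge_cor) break
    a <- as.integer(sub("^ME", "", colnames(cm)[top[1]]))
    b <- as.integer(sub("^ME", "", colnames(cm)[top[2]]))
    cl[cl == max(a, b)] <- min(a, b)
    cl <- .relabel_by_size(cl)
  }

  out <- data.frame(feature_id = rownames(tom), module = unname(cl),
                    kme = NA_real_, stringsAsFactors = FALSE)
  labs <- setdiff(unique(cl), 0L)
  if (length(labs)) {
    me <- module_eigengene(expr[rownames(tom), , drop = FALSE],
                           setNames(cl, rownames(tom)))
    for (l in labs) {
      rows <- which(cl == l)
      out$kme[rows] <- apply(expr[rownames(tom)[rows], , drop = FALSE], 1,
                             cor, y = me[, paste0("ME", l)])
    }
  }
  out
}

.relabel_by_size <- function(cl) {
  labs <- setdiff(unique(cl), 0L)
  if (!length(labs)) return(cl)
  sizes <- vapply(labs, function(l) sum(cl == l), 0L)
  map <- setNames(seq_along(labs), labs[order(-sizes)])
  out <- cl
  out[cl != 0L] <- map[as.character(cl[cl != 0L])]
  out
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and each trait, with
#' the Student-t p-value `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (two-sided); significance is declared at `p < 0.01`.
#'
#' @param eigengenes Matrix samples x modules from [module_eigengene()].
#' @param traits Data frame or matrix samples x traits, rows aligned to
#'   (or named by) the eigengene rows; >= 4 samples.
#' @param sig_level Significance level (default 0.01).
#' @return Data frame: `module`, `trait`, `r`, `p`, `significant`.
#'   Constant traits give `NA` correlations and are reported missing.
#' @export
module_trait_correlation <- function(eigengenes, traits, sig_level = 0.01) {
  traits <- as.data.frame(traits)
  if (!is.null(rownames(eigengenes)) && !is.null(rownames(traits)) &&
      all(rownames(eigengenes) %in% rownames(traits)))
    traits <- traits[rownames(eigengenes), , drop = FALSE]
  n <- nrow(eigengenes)
  if (n < 4L) stop("need at least 4 samples")
  if (n != nrow(traits)) stop("traits not aligned to eigengene samples")
  out <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    y <- traits[[out$trait[i]]]
    if (!is.numeric(y) || sd(y, na.rm = TRUE) == 0) next
    r <- cor(eigengenes[, out$module[i]], y, use = "complete.obs")
    r <- max(min(r, 1), -1)
    tval <- if (abs(r) < 1) r * sqrt(n - 2) / sqrt(1 - r^2) else
      sign(r) * Inf
    out$r[i] <- r
    out$p[i] <- 2 * pt(-abs(tval), n - 2)
  }
  out$significant <- !is.na(out$p) & out$p < sig_level
  out
}
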