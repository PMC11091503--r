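#' Counts per million mapped reads
#'
#' `CPM[f, s] = counts[f, s] / mapped_reads[s] * 1e6`, the depth
#' normalization used for back-spliced-junction counts.
#'
#' @param counts Integer matrix, features x samples (columns named by
#'   sample id).
#' @param meta Sample metadata data frame with `sample_id` and
#'   `mapped_reads`.
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
compute_cpm <- function(counts, meta) {
  stopifnot(is.matrix(counts), is.data.frame(meta))
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  mr <- meta$mapped_reads[idx]
  bad <- !is.finite(mr) | mr <= 0
  if (any(bad))
    stop("missing or non-positive mapped_reads for sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "))
  sweep(counts, 2, mr, "/") * 1e6
}

#' Expression flags from CPM thresholds
#'
#' A feature is `expressed` if CPM > 0.01 in at least one sample;
#' `expressed_<tissue>` if CPM > 0.01 in strictly more than 30% of that
#' tissue's samples; `highly_expressed` if CPM > 0.01 in at least half
#' (`ceiling(N/2)`) of all samples.
#'
#' @param cpm CPM matrix from [compute_cpm()].
#' @param meta Sample metadata with `sample_id` and `tissue`.
#' @param cpm_threshold Detection threshold (default 0.01 CPM).
#' @return Data frame: `feature_id`, `expressed`, `highly_expressed`, and
#'   one `expressed_<tissue>` column per tissue.
#' @export
flag_expressed <- function(cpm, meta, cpm_threshold = 0.01) {
  stopifnot(is.matrix(cpm))
  idx <- match(colnames(cpm), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  tissue <- meta$tissue[idx]
  det <- cpm > cpm_threshold
  n <- ncol(cpm)
  out <- data.frame(feature_id = rownames(cpm),
                    expressed = rowSums(det) >= 1L,
                    highly_expressed = rowSums(det) >= ceiling(n / 2),
                    stringsAsFactors = FALSE)
  for (t in unique(tissue)) {
    cols <- tissue == t
    if (!any(cols)) stop("tissue ", t, " has no samples")
    out[[paste0("expressed_", t)]] <- rowSums(det[, cols, drop = FALSE]) >
      0.3 * sum(cols)
  }
  out
}

#' Single-parent-expressed (SPE) circRNA calls
#'
#' Per tissue, on parental group-mean CPM: mean >= 1 in WW and < 0.1 in YY
#' gives `SPE_W`; mean < 0.1 in WW and >= 1 in YY gives `SPE_Y`; anything
#' else `none`.  Cross-expression of the SPE circRNAs is summarized per
#' cross as the count whose mean CPM in that cross reaches the same
#' expression gate (mean CPM >= 1).
#'
#' @param cpm CPM matrix.
#' @param meta Sample metadata with `sample_id`, `tissue`, `group`.
#' @param on_threshold,off_threshold Expressed / silent mean-CPM gates
#'   (defaults 1 and 0.1).
#' @return List with `calls` (feature x tissue SPE labels and group mean
#'   CPMs) and `cross_summary` (per tissue x cross counts of SPE_W/SPE_Y
#'   circRNAs expressed in that cross).
#' @export
classify_spe <- function(cpm, meta, on_threshold = 1, off_threshold = 0.1) {
  idx <- match(colnames(cpm), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  tissue <- meta$tissue[idx]; group <- meta$group[idx]
  calls <- list(); summ <- list()
  for (t in unique(tissue)) {
    for (g in PARENTS)
      if (!any(tissue == t & group == g))
        stop("parental group ", g, " absent in tissue ", t)
    gm <- vapply(GROUPS, function(g) {
      cols <- tissue == t & group == g
      if (any(cols)) rowMeans(cpm[, cols, drop = FALSE]) else
        rep(NA_real_, nrow(cpm))
    }, numeric(nrow(cpm)))
    spe <- rep("none", nrow(cpm))
    spe[gm[, "WW"] >= on_threshold & gm[, "YY"] < off_threshold] <- "SPE_W"
    spe[gm[, "WW"] < off_threshold & gm[, "YY"] >= on_threshold] <- "SPE_Y"
    calls[[t]] <- data.frame(feature_id = rownames(cpm), tissue = t,
                             spe = spe,
                             mean_cpm_WW = gm[, "WW"], mean_cpm_YY = gm[, "YY"],
                             mean_cpm_WY = gm[, "WY"], mean_cpm_YW = gm[, "YW"],
                             stringsAsFactors = FALSE)
    for (cr in CROSSES) {
      if (!all(is.finite(gm[, cr]))) next
      summ[[paste(t, cr)]] <- data.frame(
        tissue = t, cross = cr,
        n_SPE_W = sum(spe == "SPE_W"),
        n_SPE_Y = sum(spe == "SPE_Y"),
        n_SPE_W_expressed = sum(spe == "SPE_W" & gm[, cr] >= on_threshold),
        n_SPE_Y_expressed = sum(spe == "SPE_Y" & gm[, cr] >= on_threshold),
        stringsAsFactors = FALSE)
    }
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       cross_summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

#' Spearman correlation between circRNAs and their host genes
#'
#' For each exonic/intronic circRNA with an annotated host gene present in
#' the gene expression matrix, computes the Spearman correlation between
#' circRNA and host expression over the samples of one tissue
#' ([spearman_test()]; exact permutation p for n <= 9).  The summary
#' reports, separately for exonic and intronic pairs, the fraction with
#' r > 0 and p < 0.05.
#'
#' @param circ_cpm,gene_expr Expression matrices (features x samples,
#'   shared sample columns).
#' @param annotation Data frame with `circ_id`, `region_class`,
#'   `host_gene`.
#' @param meta Sample metadata with `sample_id` and `tissue`.
#' @param tissue Tissue whose samples are used (>= 5 samples required).
#' @return List with `pairs` (per-pair r and p) and `summary` (per region
#'   class: number of pairs and positive-significant fraction).
#' @export
host_gene_correlation <- function(circ_cpm, gene_expr, annotation, meta,
                                  tissue) {
  samp <- meta$sample_id[meta$tissue == tissue]
  samp <- intersect(samp, intersect(colnames(circ_cpm), colnames(gene_expr)))
  if (length(samp) < 5L) stop("need >= 5 samples in tissue ", tissue)
  ann <- annotation[annotation$region_class %in% c("exonic", "intronic") &
                      !is.na(annotation$host_gene) &
                      annotation$host_gene %in% rownames(gene_expr) &
                      annotation$circ_id %in% rownames(circ_cpm), ,
                    drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(ann))) {
    x <- circ_cpm[ann$circ_id[k], samp]
    y <- gene_expr[ann$host_gene[k], samp]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant expression for pair ", ann$circ_id[k], " / ",
              ann$host_gene[k], "; skipped")
      next
    }
    st <- spearman_test(x, y)
    rows[[k]] <- data.frame(circ_id = ann$circ_id[k],
                            host_gene = ann$host_gene[k],
                            region_class = ann$region_class[k],
                            r = st$r, p = st$p, n = st$n,
                            stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else data.frame(circ_id = character(0), host_gene = character(0),
                           region_class = character(0), r = numeric(0),
                           p = numeric(0), n = integer(0))
  summary <- do.call(rbind, lapply(c("exonic", "intronic"), function(cl) {
    sub <- pairs[pairs$region_class == cl, , drop = FALSE]
    data.frame(region_class = cl, n_pairs = nrow(sub),
               frac_positive_significant =
                 if (nrow(sub)) mean(sub$r > 0 & sub$p < 0.05) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summary)
}

#' Log-scale principal component analysis of expression profiles
#'
#' `log2(x + 1)`-transforms an expression matrix (CPM recommended), centers
#' each feature, and computes sample coordinates on the first two principal
#' components by singular value decomposition.  This is a descriptive
#' stand-in for variance-stabilized PCA.
#'
#' @param x Expression matrix, features x samples (>= 2 features, >= 3
#'   samples).
#' @param n_components Number of components to return (default 2).
#' @return List with `coordinates` (samples x components), `var_explained`
#'   (fraction per component, non-increasing).
#' @export
log_transform_pca <- function(x, n_components = 2L) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("need at least 2 features for PCA")
  if (ncol(x) < 3L) stop("need at least 3 samples for PCA")
  lx <- log2(x + 1)
  cx <- lx - rowMeans(lx)
  sv <- svd(cx)
  k <- min(n_components, length(sv$d))
  coords <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords, var_explained = sv$d^2 / sum(sv$d^2))
}
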