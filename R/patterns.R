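PATTERNS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
              "XI", "XII")

#' Inheritance class of a pattern label
#'
#' Patterns IV and X are additive, III/V/IX/XI dominant, I/II/XII
#' overdominant, VI/VII/VIII underdominant; `"conserved"` and
#' `"unclassified"` map to themselves.
#'
#' @param pattern Character vector of pattern labels.
#' @return Character vector of classes.
#' @export
pattern_class <- function(pattern) {
  map <- c(IV = "additive", X = "additive",
           III = "dominant", V = "dominant", IX = "dominant", XI = "dominant",
           I = "overdominant", II = "overdominant", XII = "overdominant",
           VI = "underdominant", VII = "underdominant", VIII = "underdominant",
           conserved = "conserved", unclassified = "unclassified")
  unname(map[pattern])
}

#' Classify the inheritance pattern of each feature in one cross
#'
#' Applies the twelve-pattern rule set to the four contrasts of a cross.
#' Two gates are used, matching how the rules are phrased: a contrast shows
#' a *significant difference* when `p < alpha` and
#' `|log2FC| > lfc_threshold` (the differential-expression definition;
#' strict inequalities, ties not significant), while two groups are *equal*
#' when `p >= alpha` alone.  A contrast can therefore be neither (small but
#' reliable fold change); features hinging on such a contrast fall through
#' to `unclassified`.  With `pp` = WW vs YY, `cw` = cross vs WW, `cy` =
#' cross vs YY and `mp` = cross vs mid-parent, the rules are applied in
#' this order:
#'
#' * additive: `pp` significantly different, cross equal to the
#'   mid-parent, and the cross point estimate lying between the parental
#'   means (opposite signs of the `cw` and `cy` fold changes -- additivity
#'   is intermediate expression by definition) -> IV if WW > YY else X;
#' * dominant: cross equal to WW and significantly different from YY ->
#'   XI if cross > YY else V; cross equal to YY and significantly
#'   different from WW -> III if cross > WW else IX;
#' * overdominant: cross significantly above both parents -> II if WW
#'   significantly > YY, XII if YY significantly > WW, I if parents do not
#'   differ significantly; underdominant: significantly below both ->
#'   VI / VIII / VII respectively;
#' * conserved when no contrast shows a significant difference and no rule
#'   fired, otherwise unclassified.
#'
#' The additive rule is evaluated first because a cross sitting exactly at
#' the mid-parent of two well-separated parents is typically within the
#' fold-change gate of the nearer parent, which would otherwise satisfy a
#' dominance rule.
#'
#' @param parent,cross_vs_ww,cross_vs_yy,cross_vs_mid Contrast results (as
#'   from [nb_differential_test()] / [midparent_test()]) for WW vs YY,
#'   cross vs WW, cross vs YY and cross vs mid-parent; matched by
#'   `feature_id`.
#' @param cross Cross label carried into the output.
#' @param alpha,lfc_threshold Significance gate (defaults 0.05 and 1.0).
#' @return Data frame: `feature_id`, `cross`, `pattern`, `pattern_class`.
#' @export
classify_pattern <- function(parent, cross_vs_ww, cross_vs_yy, cross_vs_mid,
                             cross = NA_character_, alpha = 0.05,
                             lfc_threshold = 1.0) {
  for (nm in c("parent", "cross_vs_ww", "cross_vs_yy", "cross_vs_mid")) {
    obj <- get(nm)
    if (is.null(obj) || !is.data.frame(obj))
      stop("missing contrast: ", nm)
  }
  ids <- parent$feature_id
  for (obj in list(cross_vs_ww, cross_vs_yy, cross_vs_mid))
    if (!setequal(obj$feature_id, ids))
      stop("contrasts cover different feature sets")
  al <- function(x) x[match(ids, x$feature_id), ]
  cw <- al(cross_vs_ww); cy <- al(cross_vs_yy); mp <- al(cross_vs_mid)
  sig <- function(x) x$p < alpha & abs(x$log2FC) > lfc_threshold
  eq <- function(x) x$p >= alpha
  s_pp <- sig(parent); s_cw <- sig(cw); s_cy <- sig(cy); s_mp <- sig(mp)
  e_cw <- eq(cw); e_cy <- eq(cy); e_mp <- eq(mp)
  up_pp <- parent$log2FC > 0; up_cw <- cw$log2FC > 0; up_cy <- cy$log2FC > 0

  pat <- rep("unclassified", length(ids))
  # additive (cross between the parents and at the mid-parent)
  add <- s_pp & e_mp & (up_cw != up_cy)
  pat[add & up_pp] <- "IV"
  pat[add & !up_pp] <- "X"
  # dominant (cross resembles one parent, differs from the other)
  rem <- pat == "unclassified"
  dWW <- rem & e_cw & s_cy
  pat[dWW & up_cy] <- "XI"
  pat[dWW & !up_cy] <- "V"
  rem <- pat == "unclassified"
  dYY <- rem & e_cy & s_cw
  pat[dYY & up_cw] <- "III"
  pat[dYY & !up_cw] <- "IX"
  # over-/under-dominant (cross beyond both parents)
  rem <- pat == "unclassified"
  over <- rem & s_cw & s_cy & up_cw & up_cy
  pat[over & s_pp & up_pp] <- "II"
  pat[over & s_pp & !up_pp] <- "XII"
  pat[over & !s_pp] <- "I"
  under <- rem & s_cw & s_cy & !up_cw & !up_cy
  pat[under & s_pp & up_pp] <- "VI"
  pat[under & s_pp & !up_pp] <- "VIII"
  pat[under & !s_pp] <- "VII"
  # conserved: nothing fired and no contrast significant
  rem <- pat == "unclassified"
  pat[rem & !s_pp & !s_cw & !s_cy & !s_mp] <- "conserved"

  data.frame(feature_id = ids, cross = cross, pattern = pat,
             pattern_class = pattern_class(pat), stringsAsFactors = FALSE)
}

#' All five group contrasts plus the mid-parent contrast for one cross
#'
#' Convenience wrapper running [nb_differential_test()] for WW vs YY, cross
#' vs WW and cross vs YY, [midparent_test()] for cross vs mid-parent, and
#' [classify_pattern()] on the result.
#'
#' @inheritParams nb_differential_test
#' @param cross `"WY"` or `"YW"`.
#' @param alpha,lfc_threshold Passed to [classify_pattern()].
#' @param seed Pairing seed for [midparent_test()].
#' @return List with `contrasts` (named list of the four contrast tables)
#'   and `calls` (the pattern calls).
#' @export
call_patterns <- function(counts, meta, cross, alpha = 0.05,
                          lfc_threshold = 1.0, seed = 1L,
                          size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- normalize_size_factors(counts)
  ctr <- list(
    parent = nb_differential_test(counts, meta, "WW", "YY", size_factors),
    cross_vs_ww = nb_differential_test(counts, meta, cross, "WW", size_factors),
    cross_vs_yy = nb_differential_test(counts, meta, cross, "YY", size_factors),
    cross_vs_mid = midparent_test(counts, meta, cross, size_factors, seed))
  calls <- classify_pattern(ctr$parent, ctr$cross_vs_ww, ctr$cross_vs_yy,
                            ctr$cross_vs_mid, cross = cross, alpha = alpha,
                            lfc_threshold = lfc_threshold)
  list(contrasts = ctr, calls = calls)
}

#' Summaries of pattern calls per tissue and cross
#'
#' Counts and proportions of each inheritance class per tissue x cross;
#' nonadditive features split into breed-common (nonadditive in both
#' crosses), WY-specific and YW-specific per tissue; WW-biased (cross
#' resembling WW: V, XI) versus YY-biased (III, IX) dominance counts; and
#' per-feature tissue-sharing counts for additive and nonadditive calls.
#'
#' @param calls Pattern-call data frame with columns `feature_id`,
#'   `tissue`, `cross`, `pattern`, `pattern_class` (concatenate
#'   [call_patterns()] results over tissues/crosses, adding a `tissue`
#'   column).
#' @return List with `by_tissue_cross`, `breed_split`, `dominance_bias`,
#'   `tissue_sharing`.
#' @export
summarize_patterns <- function(calls) {
  stopifnot(all(c("feature_id", "tissue", "cross", "pattern",
                  "pattern_class") %in% names(calls)))
  classes <- c("additive", "dominant", "overdominant", "underdominant")
  nonadd <- c("dominant", "overdominant", "underdominant")

  by_tc <- do.call(rbind, lapply(split(calls, calls[c("tissue", "cross")]),
                                 function(d) {
    if (!nrow(d)) return(NULL)
    n <- nrow(d)
    cnt <- vapply(classes, function(cl) sum(d$pattern_class == cl), 0)
    data.frame(tissue = d$tissue[1], cross = d$cross[1], n_features = n,
               t(cnt), prop_de = sum(cnt) / n,
               prop_nonadditive = sum(cnt[nonadd]) / n,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  breed <- do.call(rbind, lapply(split(calls, calls$tissue), function(d) {
    na_by_cross <- lapply(setNames(CROSSES, CROSSES), function(cr)
      unique(d$feature_id[d$cross == cr & d$pattern_class %in% nonadd]))
    common <- intersect(na_by_cross$WY, na_by_cross$YW)
    data.frame(tissue = d$tissue[1],
               n_common = length(common),
               n_WY_specific = length(setdiff(na_by_cross$WY, common)),
               n_YW_specific = length(setdiff(na_by_cross$YW, common)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  bias <- do.call(rbind, lapply(split(calls, calls[c("tissue", "cross")]),
                                function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(tissue = d$tissue[1], cross = d$cross[1],
               n_WW_biased = sum(d$pattern %in% c("V", "XI")),
               n_YY_biased = sum(d$pattern %in% c("III", "IX")),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  sharing <- do.call(rbind, lapply(CROSSES, function(cr) {
    do.call(rbind, lapply(c(additive = "additive", nonadditive = "nonadd"),
                          function(kind) {
      keep <- calls$cross == cr &
        (if (kind == "additive") calls$pattern_class == "additive"
         else calls$pattern_class %in% nonadd)
      d <- calls[keep, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      per_feat <- table(tapply(d$tissue, d$feature_id,
                               function(t) length(unique(t))))
      n_single <- if ("1" %in% names(per_feat)) per_feat[["1"]] else 0L
      data.frame(cross = cr,
                 set = if (kind == "additive") "additive" else "nonadditive",
                 n_features = length(unique(d$feature_id)),
                 n_tissue_specific = n_single,
                 prop_tissue_specific = n_single / length(unique(d$feature_id)),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))

  list(by_tissue_cross = by_tc, breed_split = breed,
       dominance_bias = bias, tissue_sharing = sharing)
}
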