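#' Derive metabolic body weight and feed conversion ratio
#'
#' Adds `MBW = BW^0.75` (metabolic body weight, kg^0.75) and
#' `FCR = DFC / DEM` (feed conversion ratio, dimensionless) to a phenotype
#' table.  FCR is `NA` where `DEM <= 0` (no egg mass, ratio undefined).
#'
#' @param records Data frame with at least columns `BW` (kg), `DFC` and
#'   `DEM` (g/day).
#' @return `records` with columns `MBW` and `FCR` added.
#' @export
#' @examples
#' compute_derived_traits(data.frame(BW = 16, DFC = 100, DEM = 50))
compute_derived_traits <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("BW", "DFC", "DEM")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  if (any(records$BW < 0, na.rm = TRUE)) stop("negative BW is invalid")
  if (any(records$DFC < 0, na.rm = TRUE) || any(records$DEM < 0, na.rm = TRUE))
    stop("DFC and DEM must be non-negative")
  records$MBW <- records$BW^0.75
  records$FCR <- ifelse(records$DEM > 0, records$DFC / records$DEM, NA_real_)
  records
}

#' Residual feed intake from the pooled feed-intake regression
#'
#' Fits one ordinary least squares regression of daily feed consumption on
#' metabolic body weight, body weight gain and daily egg mass, pooled over
#' all genetic groups, and defines residual feed intake (RFI, g/day) as
#' observed minus fitted DFC.  Lower RFI means a more efficient bird.
#'
#' @param records Data frame with columns `DFC`, `MBW`, `BWG`, `DEM`
#'   (run [compute_derived_traits()] first if `MBW` is missing).
#' @return `records` with an `RFI` column; the fitted coefficients are
#'   attached as `attr(, "rfi_coefficients")`.
#' @export
fit_rfi <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("DFC", "MBW", "BWG", "DEM")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns for RFI model: ",
                         paste(miss, collapse = ", "))
  ok <- complete.cases(records[need])
  if (sum(ok) < 5L) stop("need at least 5 birds with complete DFC, MBW, BWG, DEM")
  X <- cbind(intercept = 1, as.matrix(records[ok, c("MBW", "BWG", "DEM")]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient RFI design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, records$DFC[ok])
  res <- records$DFC[ok] - drop(X %*% beta)
  records$RFI <- NA_real_
  records$RFI[ok] <- res
  attr(records, "rfi_coefficients") <- beta
  records
}

#' Mid-parent heterosis with its significance test
#'
#' Computes fractional mid-parent heterosis
#' `H = (Fbar - MP) / MP`, `MP = (Pw + Py) / 2`, where `Fbar` is the cross
#' mean and `Pw`, `Py` the parental (WW, YY) means, and tests its
#' significance.  The default test is a one-sample Student t of the cross
#' against the fixed mid-parent value,
#' `t = (Fbar - MP) / (s_F / sqrt(n))` with `s_F^2 = sum((Fi - Fbar)^2) /
#' (n - 1)`, `df = n - 1`, two-sided p; algebraically
#' `t = H * MP / (s_F / sqrt(n))`, and its type-I error is correct under
#' the null of no heterosis against a fixed mid-parent value (verified by
#' simulation in the test suite).  `method = "literal"` instead evaluates
#' the alternative printed form
#' `t = H^2 * s_F^2 / ((Pw + Py) * n)`; it is provided for comparison only
#' and makes no calibration claim.
#'
#' @param trait_values_by_group Named list with numeric vectors for `WW`,
#'   `YY` and the cross under test.
#' @param cross `"WY"` or `"YW"`.
#' @param trait Optional trait name carried into the result.
#' @param method `"calibrated"` (default) or `"literal"` (see above).
#' @return One-row data frame: `trait`, `cross`, `H`, `t`, `df`, `p`, `n`,
#'   `parent_mean_WW`, `parent_mean_YY`.
#' @export
#' @examples
#' compute_heterosis(list(WW = rep(100, 5), YY = rep(100, 5),
#'                        WY = c(108, 110, 112, 109, 111)), "WY")
compute_heterosis <- function(trait_values_by_group, cross,
                              trait = NA_character_,
                              method = c("calibrated", "literal")) {
  method <- match.arg(method)
  if (!cross %in% CROSSES) stop("'cross' must be one of WY, YW")
  v <- trait_values_by_group
  for (g in c(PARENTS, cross))
    if (is.null(v[[g]]) || !length(v[[g]]))
      stop("group ", g, " is empty")
  pw <- mean(v$WW, na.rm = TRUE)
  py <- mean(v$YY, na.rm = TRUE)
  mp <- (pw + py) / 2
  if (!is.finite(mp) || mp == 0)
    stop("mid-parent value is zero or undefined; heterosis is not defined")
  f <- v[[cross]][!is.na(v[[cross]])]
  n <- length(f)
  if (n < 2L) stop("insufficient data: cross ", cross, " has fewer than 2 birds")
  fbar <- mean(f)
  H <- (fbar - mp) / mp
  s2 <- sum((f - fbar)^2) / (n - 1)
  s <- sqrt(s2)
  if (method == "calibrated") {
    tval <- if (s == 0) {
      if (fbar == mp) 0 else sign(fbar - mp) * Inf
    } else (fbar - mp) / (s / sqrt(n))
  } else {
    tval <- H^2 * s2 / ((pw + py) * n)
  }
  df <- n - 1L
  p <- 2 * pt(-abs(tval), df = df)
  data.frame(trait = trait, cross = cross, H = H, t = tval, df = df,
             p = min(p, 1), n = n, parent_mean_WW = pw, parent_mean_YY = py,
             stringsAsFactors = FALSE)
}

#' Heterosis for every trait and cross of a phenotype table
#'
#' @param records Phenotype data frame with a `group` column (WW, YY, WY,
#'   YW) and the trait columns.
#' @param traits Trait columns to test (defaults to every derived and raw
#'   trait present).
#' @param method Passed to [compute_heterosis()].
#' @return Data frame, one row per trait x cross.
#' @export
heterosis_table <- function(records,
                            traits = intersect(c("DFC", "DEM", "BW", "BWG",
                                                 "MBW", "FCR", "RFI"),
                                               names(records)),
                            method = c("calibrated", "literal")) {
  method <- match.arg(method)
  stopifnot("group" %in% names(records))
  out <- list()
  for (tr in traits) {
    vals <- split(records[[tr]], records$group)
    for (cr in intersect(CROSSES, names(vals))) {
      out[[paste(tr, cr)]] <- compute_heterosis(vals, cr, trait = tr,
                                                method = method)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
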