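# Exact permutation null of Spearman's S = sum(d^2) for small n, cached.
# Returns a named table: counts of each achievable S over all n! rank
# permutations.
.spearman_null <- function(n) {
  key <- paste0("spearman_null_", n)
  if (!is.null(.hetcirc_cache[[key]])) return(.hetcirc_cache[[key]])
  perms <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    p <- perms(k - 1L)
    out <- matrix(0L, k * nrow(p), k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * nrow(p) + seq_len(nrow(p))
      out[rows, pos] <- k
      out[rows, -pos] <- p
    }
    out
  }
  pm <- perms(n)
  s <- rowSums((pm - matrix(seq_len(n), nrow(pm), n, byrow = TRUE))^2)
  tab <- table(s)
  .hetcirc_cache[[key]] <- tab
  tab
}

#' Spearman correlation with small-sample exact p-values
#'
#' Spearman's rank correlation with a two-sided p-value from the exact
#' permutation null of the rank statistic for `n <= 9` without ties, and
#' from the usual t approximation (`t = r * sqrt((n - 2) / (1 - r^2))`,
#' `n - 2` df) otherwise.  Per-tissue sample sizes in this design are 6-8
#' per group, where the t approximation is poor, hence the exact branch.
#'
#' @param x,y Numeric vectors of equal length (pairs with `NA` dropped).
#' @return List with `r`, `p`, `n` and `method` (`"exact"` or `"t"`).
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    S <- sum((rx - ry)^2)
    smax <- n * (n^2 - 1) / 3
    tab <- .spearman_null(n)
    sv <- as.numeric(names(tab))
    cnt <- as.numeric(tab)
    # |r| >= |r_obs|  <=>  S <= S_obs or S >= smax - S_obs
    p <- (sum(cnt[sv <= S + 1e-9]) + sum(cnt[sv >= smax - S - 1e-9])) / sum(cnt)
    list(r = r, p = min(p, 1), n = n, method = "exact")
  } else {
    if (abs(r) >= 1) return(list(r = r, p = 0, n = n, method = "t"))
    tval <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(tval), n - 2), n = n, method = "t")
  }
}
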