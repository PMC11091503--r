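# Independent oracles used across the suite.  Everything here is written as
# plainly as possible (loops, explicit tables) and never calls the package
# path it is checking.

# Brute-force topological overlap: triple loop, u excluded from {i, j}.
brute_tom <- function(A) {
  n <- nrow(A)
  k <- vapply(seq_len(n), function(i) sum(A[i, -i]), 0)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# Independent, table-driven reimplementation of the pattern rules.  A
# contrast state is one of: "eq+" / "eq-" (p >= alpha, point fold change up
# or down), "amb+"/"amb-" (p < alpha but |lfc| <= gate), "sig+"/"sig-".
pattern_oracle <- function(pp, cw, cy, mp) {
  is_sig <- function(s) s %in% c("sig+", "sig-")
  is_eq <- function(s) s %in% c("eq+", "eq-")
  up <- function(s) endsWith(s, "+")
  if (is_sig(pp) && is_eq(mp) && (up(cw) != up(cy)))
    return(if (up(pp)) "IV" else "X")
  if (is_eq(cw) && is_sig(cy)) return(if (up(cy)) "XI" else "V")
  if (is_eq(cy) && is_sig(cw)) return(if (up(cw)) "III" else "IX")
  if (is_sig(cw) && is_sig(cy) && up(cw) && up(cy)) {
    if (is_sig(pp)) return(if (up(pp)) "II" else "XII")
    return("I")
  }
  if (is_sig(cw) && is_sig(cy) && !up(cw) && !up(cy)) {
    if (is_sig(pp)) return(if (up(pp)) "VI" else "VIII")
    return("VII")
  }
  if (!is_sig(pp) && !is_sig(cw) && !is_sig(cy) && !is_sig(mp))
    return("conserved")
  "unclassified"
}

# Representative (p, log2FC) pairs realizing each contrast state under the
# default gates alpha = 0.05, |lfc| > 1.
state_row <- function(state, id) {
  p <- switch(substr(state, 1, nchar(state) - 1),
              eq = 0.5, amb = 0.01, sig = 0.001)
  lfc <- switch(substr(state, 1, nchar(state) - 1),
                eq = 0.2, amb = 0.5, sig = 1.5)
  if (endsWith(state, "-")) lfc <- -lfc
  data.frame(feature_id = id, log2FC = lfc, p = p,
             base_mean_1 = 10, base_mean_2 = 10, stringsAsFactors = FALSE)
}

ALL_STATES <- c("eq+", "eq-", "amb+", "amb-", "sig+", "sig-")

# Documented WW <-> YY relabeling involution on pattern labels.
relabel_involution <- c(I = "I", II = "XII", III = "XI", IV = "X", V = "IX",
                        VI = "VIII", VII = "VII", VIII = "VI", IX = "V",
                        X = "IV", XI = "III", XII = "II",
                        conserved = "conserved", unclassified = "unclassified")

# Small simulated dataset shared by several tests.
small_sim <- function(seed = 101, ...) {
  args <- list(...)
  if (is.null(args$n_circ)) args$n_circ <- 60
  if (is.null(args$n_gene)) args$n_gene <- 140
  cfg <- do.call(sim_config, c(list(seed = seed), args))
  phen <- generate_phenotypes(cfg)
  cnt <- generate_counts(cfg, phen)
  list(cfg = cfg, phen = phen, cnt = cnt)
}

# Expression matrix with planted correlated blocks over a latent factor.
planted_block_expr <- function(n_per_block = c(60, 60, 30), n_samples = 32,
                               load = 0.8, seed = 41) {
  set.seed(seed)
  lat <- matrix(rnorm(length(n_per_block) * n_samples),
                length(n_per_block), n_samples)
  X <- do.call(rbind, lapply(seq_along(n_per_block), function(b) {
    t(sapply(seq_len(n_per_block[b]), function(i)
      sqrt(load) * lat[b, ] + sqrt(1 - load) * rnorm(n_samples)))
  }))
  dimnames(X) <- list(sprintf("f%03d", seq_len(nrow(X))),
                      sprintf("s%02d", seq_len(n_samples)))
  list(expr = X, truth = rep(seq_along(n_per_block), n_per_block), lat = lat)
}

# Mean silhouette width for a 2-group labelling of points (rows).
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# Adjusted Rand index (mclust if present, otherwise direct formula).
ari <- function(x, y) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(x, y))
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  sij <- comb2(as.vector(tab)); n2 <- choose(sum(tab), 2)
  exp_ind <- si * sj / n2
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}
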