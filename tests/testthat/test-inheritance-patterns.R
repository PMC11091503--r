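test_that("median-of-ratios size factors respond to depth, not composition", {
  set.seed(31)
  base <- matrix(rnbinom(100 * 4, mu = 50, size = 5), 100, 4,
                 dimnames = list(paste0("f", 1:100), paste0("s", 1:4)))
  expect_equal(unname(normalize_size_factors(cbind(base[, 1], base[, 1],
                                                   base[, 1]))),
               rep(1, 3))
  doubled <- cbind(base, 2L * base[, 1])
  colnames(doubled) <- paste0("s", 1:5)
  sf <- normalize_size_factors(doubled)
  expect_equal(unname(sf[5] / sf[1]), 2, tolerance = 1e-10)
})

test_that("size factors recover known depth multipliers within 5%", {
  set.seed(32)
  mult <- c(0.5, 0.8, 1, 1.25, 2, 1, 0.9, 1.5)
  mu <- 10^runif(800, 1, 3)
  counts <- sapply(mult, function(m) rnbinom(800, mu = mu * m, size = 10))
  dimnames(counts) <- list(paste0("f", 1:800), paste0("s", 1:8))
  sf <- normalize_size_factors(counts)
  rel <- (sf / exp(mean(log(sf)))) / (mult / exp(mean(log(mult))))
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("all-zero-feature fallback emits a warning and total-count factors", {
  counts <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(sf <- normalize_size_factors(counts), "total-count")
  expect_equal(unname(sf[1] / sf[2]), 1, tolerance = 1e-10)
})

test_that("the NB Wald test is symmetric and handles degenerate features", {
  set.seed(33)
  counts <- matrix(rnbinom(200 * 12, mu = 40, size = 10), 200, 12)
  counts[1, ] <- 0L
  dimnames(counts) <- list(paste0("f", 1:200), paste0("s", 1:12))
  meta <- data.frame(sample_id = colnames(counts),
                     group = rep(c("WW", "YY"), each = 6))
  ab <- nb_differential_test(counts, meta, "WW", "YY")
  ba <- nb_differential_test(counts, meta, "YY", "WW")
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$p[1], 1)
  expect_equal(ab$log2FC[1], 0)

  # identical groups: log2FC exactly zero
  dup <- cbind(counts[, 1:6], counts[, 1:6])
  colnames(dup) <- paste0("s", 1:12)
  same <- nb_differential_test(dup, meta, "WW", "YY",
                               size_factors = setNames(rep(1, 12),
                                                       colnames(dup)))
  expect_true(all(same$log2FC == 0))
  expect_error(nb_differential_test(counts[, 1:8], meta[1:8, ], "WW", "YY"),
               "fewer than 3")
})

test_that("the mid-parent test is null when crosses equal parent-pair
           averages and powered when the cross sits at a distant parent", {
  set.seed(34)
  nf <- 400
  mu <- 10^runif(nf, 1.5, 3)
  ww <- sapply(1:8, function(i) rnbinom(nf, mu = mu, size = 10))
  yy <- sapply(1:8, function(i) rnbinom(nf, mu = mu, size = 10))
  cross <- round((ww + yy) / 2)      # cross = parent-pair average
  counts <- cbind(ww, yy, cross)
  dimnames(counts) <- list(paste0("f", 1:nf), paste0("s", 1:24))
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample_id = colnames(counts),
                     group = rep(c("WW", "YY", "WY"), each = 8))
  sf <- setNames(rep(1, 24), colnames(counts))
  res <- midparent_test(counts, meta, "WY", size_factors = sf, seed = 2)
  expect_lt(abs(mean(res$log2FC)), 0.05)
  expect_gt(mean(res$p >= 0.05), 0.85)

  # cross = high parent, parents 4-fold apart: power >= 0.8
  yy4 <- sapply(1:8, function(i) rnbinom(nf, mu = mu / 4, size = 10))
  hi <- sapply(1:8, function(i) rnbinom(nf, mu = mu, size = 10))
  counts2 <- cbind(ww, yy4, hi)
  dimnames(counts2) <- dimnames(counts)
  storage.mode(counts2) <- "integer"
  res2 <- midparent_test(counts2, meta, "WY", size_factors = sf, seed = 2)
  expect_gt(mean(res2$p < 0.05), 0.8)

  # constant identical groups: p = 1
  const <- matrix(5L, 4, 24, dimnames = list(paste0("g", 1:4),
                                             colnames(counts)))
  res3 <- midparent_test(const, meta, "WY", size_factors = sf)
  expect_true(all(res3$p == 1))

  # unequal parental counts are paired down with a warning
  expect_warning(midparent_test(counts[, -1], meta[-1, ], "WY",
                                size_factors = sf[-1]),
                 "pairing down")
})

test_that("pattern rules fire on hand-built contrast tables", {
  ctr <- function(p, lfc) data.frame(feature_id = "f", log2FC = lfc, p = p,
                                     base_mean_1 = 10, base_mean_2 = 10)
  # parents differ (WW high), cross at mid-parent: additive IV
  call <- classify_pattern(parent = ctr(0.001, 1.5),
                           cross_vs_ww = ctr(0.2, -0.6),
                           cross_vs_yy = ctr(0.01, 0.9),
                           cross_vs_mid = ctr(0.6, 0.1), cross = "WY")
  expect_equal(call$pattern, "IV")
  expect_equal(call$pattern_class, "additive")
  # cross equal to WW, significantly below YY: dominance V
  call <- classify_pattern(parent = ctr(0.001, -2),
                           cross_vs_ww = ctr(0.4, 0.1),
                           cross_vs_yy = ctr(0.01, -1.2),
                           cross_vs_mid = ctr(0.001, -1.1), cross = "WY")
  expect_equal(call$pattern, "V")
  expect_equal(call$pattern_class, "dominant")
  # cross above both parents, parents equal: overdominance I
  call <- classify_pattern(parent = ctr(0.8, 0.05),
                           cross_vs_ww = ctr(0.001, 1.4),
                           cross_vs_yy = ctr(0.001, 1.5),
                           cross_vs_mid = ctr(0.001, 1.4), cross = "WY")
  expect_equal(call$pattern, "I")
  # nothing significant anywhere: conserved
  call <- classify_pattern(parent = ctr(0.5, 0.1),
                           cross_vs_ww = ctr(0.5, 0.1),
                           cross_vs_yy = ctr(0.5, -0.1),
                           cross_vs_mid = ctr(0.5, 0.1), cross = "WY")
  expect_equal(call$pattern, "conserved")
  expect_error(classify_pattern(parent = ctr(0.5, 0.1),
                                cross_vs_ww = NULL,
                                cross_vs_yy = ctr(0.5, 0.1),
                                cross_vs_mid = ctr(0.5, 0.1)),
               "cross_vs_ww")
})

test_that("every significance/direction state maps to exactly one label that
           matches the independent rule table", {
  grid <- expand.grid(pp = ALL_STATES, cw = ALL_STATES, cy = ALL_STATES,
                      mp = ALL_STATES, stringsAsFactors = FALSE)
  ids <- sprintf("state_%04d", seq_len(nrow(grid)))
  mk <- function(col) do.call(rbind, Map(state_row, grid[[col]], ids))
  calls <- classify_pattern(mk("pp"), mk("cw"), mk("cy"), mk("mp"),
                            cross = "WY")
  expect_equal(nrow(calls), nrow(grid))
  vocab <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII", "conserved", "unclassified")
  expect_true(all(calls$pattern %in% vocab))
  want <- mapply(pattern_oracle, grid$pp, grid$cw, grid$cy, grid$mp)
  expect_identical(calls$pattern, unname(want))
})

test_that("relabeling WW and YY induces the documented label involution", {
  grid <- expand.grid(pp = ALL_STATES, cw = ALL_STATES, cy = ALL_STATES,
                      mp = ALL_STATES, stringsAsFactors = FALSE)
  ids <- sprintf("state_%04d", seq_len(nrow(grid)))
  mk <- function(states) do.call(rbind, Map(state_row, states, ids))
  flip <- function(s) ifelse(endsWith(s, "+"),
                             sub("\\+$", "-", s), sub("-$", "+", s))
  orig <- classify_pattern(mk(grid$pp), mk(grid$cw), mk(grid$cy),
                           mk(grid$mp), cross = "WY")
  swap <- classify_pattern(mk(flip(grid$pp)), mk(grid$cy), mk(grid$cw),
                           mk(grid$mp), cross = "WY")
  expect_identical(swap$pattern, unname(relabel_involution[orig$pattern]))
})

test_that("planted inheritance classes are recovered from simulated counts", {
  cfg <- sim_config(seed = 35, n_circ = 300, n_gene = 900, lfc_effect = 2,
                    nb_dispersion = 0.1, tissue_specific_fraction = 0,
                    spe_fraction = 0, host_coupling_sd = 0)
  cnt <- generate_counts(cfg, generate_phenotypes(cfg))
  counts <- rbind(cnt$circ_counts, cnt$gene_counts)
  m <- cnt$meta[cnt$meta$tissue == "liver", ]
  res <- call_patterns(counts[, m$sample_id], m, "WY", seed = 4)
  tr <- cnt$truth$features
  truth <- tr$class[match(res$calls$feature_id, tr$feature_id)]
  for (cl in c("additive", "dominant", "overdominant", "underdominant"))
    expect_gt(mean(res$calls$pattern_class[truth == cl] == cl), 0.8)
  expect_lt(mean(res$calls$pattern_class[truth == "additive"] ==
                   "overdominant"), 0.05)
})

test_that("pattern summaries count breed-common and breed-specific features", {
  calls <- data.frame(
    feature_id = c("a", "a", "b", "c", "c", "d"),
    tissue = c("liver", "liver", "liver", "liver", "hypothalamus", "liver"),
    cross = c("WY", "YW", "WY", "YW", "YW", "WY"),
    pattern = c("V", "III", "IV", "II", "II", "conserved"),
    stringsAsFactors = FALSE)
  calls$pattern_class <- pattern_class(calls$pattern)
  s <- summarize_patterns(calls)
  liver <- s$breed_split[s$breed_split$tissue == "liver", ]
  expect_equal(liver$n_common, 1)        # a nonadditive in both crosses
  expect_equal(liver$n_WY_specific, 0)
  expect_equal(liver$n_YW_specific, 1)   # c
  bias <- s$dominance_bias
  expect_equal(bias$n_WW_biased[bias$tissue == "liver" & bias$cross == "WY"], 1)
  expect_equal(bias$n_YY_biased[bias$tissue == "liver" & bias$cross == "YW"], 1)
  # all-conserved input: zero proportions
  cons <- calls; cons$pattern <- "conserved"
  cons$pattern_class <- "conserved"
  s0 <- summarize_patterns(cons)
  expect_true(all(s0$by_tissue_cross$prop_de == 0))
})
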