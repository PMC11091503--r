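test_that("the MAD filter keeps exactly the brute-force ranking", {
  set.seed(42)
  circ <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(paste0("c", 1:20), paste0("s", 1:10)))
  circ[3, ] <- 7                       # constant row: MAD 0
  gene <- matrix(rnorm(100 * 10, sd = rep(1:100, 10)), 100, 10,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  mf <- suppressWarnings(mad_filter(circ, gene))
  expect_false("c3" %in% rownames(mf$expr))
  expect_equal(sum(mf$kind == "gene"), 25)
  manual <- names(sort(apply(gene, 1, mad), decreasing = TRUE))[1:25]
  expect_setequal(rownames(mf$expr)[mf$kind == "gene"], manual)
})

test_that("soft-threshold fallback returns the sample-size rule exactly", {
  set.seed(43)
  prof <- rnorm(45)
  for (spec in list(c(16, 18), c(25, 16), c(35, 14), c(45, 12))) {
    n <- spec[1]
    # near-constant correlation structure: connectivity collapses into one
    # bin, no power can fit a scale-free curve
    X <- matrix(rep(prof[1:n], each = 60), 60, n) +
      matrix(rnorm(60 * n, 0, 1e-3), 60, n)
    dimnames(X) <- list(paste0("f", 1:60), paste0("s", 1:n))
    st <- pick_soft_threshold(X, n_samples = n)
    expect_true(is.na(st$power_estimate))
    expect_equal(st$power, spec[2])
  }
  expect_error(pick_soft_threshold(matrix(rnorm(8), 2, 4)), "degenerate")
})

test_that("a modular matrix yields the same power as an independent grid
           scan", {
  set.seed(44)
  # heterogeneous block sizes give a skewed connectivity distribution
  sizes <- c(40, 25, 15, 10, 6)
  pb <- planted_block_expr(sizes, n_samples = 30, load = 0.9, seed = 44)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(paste0("n", 1:40), colnames(pb$expr)))
  expr <- rbind(pb$expr, noise)
  st <- pick_soft_threshold(expr)
  # independent scan: recompute R^2/slope per power from scratch
  C <- cor(t(expr)); S <- (1 + C) / 2; diag(S) <- 0
  pick <- NA_integer_
  for (b in 1:30) {
    k <- rowSums(S^b)
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- as.vector(table(bin)) / length(k)
    km <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(km)
    fit <- lm(log10(freq[ok]) ~ log10(km[ok]))
    if (summary(fit)$r.squared >= 0.85 && coef(fit)[2] < 0) {
      pick <- as.integer(b); break
    }
  }
  expect_equal(st$power_estimate, pick)
})

test_that("TOM matches the brute-force triple loop and its closed forms", {
  set.seed(45)
  for (rep in 1:5) {
    A <- matrix(runif(15 * 15), 15, 15)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    tom <- compute_tom(A)
    expect_lt(max(abs(tom - brute_tom(A))), 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(unname(diag(tom)), rep(1, 15))
  }
  # identity adjacency: no edges, TOM = identity
  expect_equal(compute_tom(diag(5)), diag(5))
  # two nodes with identical binary neighborhoods and a_ij = 1: TOM = 1
  A <- matrix(0, 4, 4); diag(A) <- 1
  A[1, 2] <- A[2, 1] <- 1
  A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1
  expect_equal(compute_tom(A)[1, 2], 1)
  expect_error(compute_tom(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("planted blocks are recovered as modules; undersized blocks stay
           unassigned; same-latent blocks merge", {
  pb <- planted_block_expr(c(60, 60, 30), seed = 46)
  st <- pick_soft_threshold(pb$expr)
  tom <- compute_tom(signed_adjacency(pb$expr, st$power))
  mod <- detect_modules(tom, pb$expr, min_size = 50)
  expect_gt(ari(pb$truth, mod$module), 0.9)
  small <- mod$module[pb$truth == 3]
  expect_true(all(small == 0))
  expect_true(all(mod$kme[mod$module != 0] > 0.5, na.rm = TRUE))

  # two blocks driven by one latent factor collapse into one module
  set.seed(47)
  lat <- rnorm(32)
  X <- t(sapply(1:120, function(i) sqrt(0.8) * lat + sqrt(0.2) * rnorm(32)))
  dimnames(X) <- list(sprintf("f%03d", 1:120), sprintf("s%02d", 1:32))
  tom2 <- compute_tom(signed_adjacency(X, 12))
  mod2 <- detect_modules(tom2, X, min_size = 50)
  expect_equal(length(setdiff(unique(mod2$module), 0L)), 1)
})

test_that("module labels are invariant under feature reordering", {
  pb <- planted_block_expr(c(60, 60), seed = 48)
  tom <- compute_tom(signed_adjacency(pb$expr, 12))
  mod1 <- detect_modules(tom, pb$expr, min_size = 50)
  perm <- sample(nrow(pb$expr))
  mod2 <- detect_modules(tom[perm, perm], pb$expr[perm, ], min_size = 50)
  m1 <- setNames(mod1$module, mod1$feature_id)
  m2 <- setNames(mod2$module, mod2$feature_id)[names(m1)]
  expect_equal(ari(m1, m2), 1)
})

test_that("eigengenes equal the leading principal component", {
  set.seed(49)
  prof <- rnorm(12)
  X <- t(sapply(1:10, function(i) 2 + i * prof))  # identical standardized rows
  dimnames(X) <- list(paste0("f", 1:10), paste0("s", 1:12))
  me <- module_eigengene(X, setNames(rep(1, 10), rownames(X)))
  zp <- (prof - mean(prof)) / sd(prof)
  expect_gt(abs(cor(me[, "ME1"], zp)), 1 - 1e-10)
  expect_equal(unname(attr(me, "var_explained")["ME1"]), 1, tolerance = 1e-10)

  # brute-force check: first eigenvector of the sample covariance
  Y <- matrix(rnorm(8 * 15), 8, 15,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:15)))
  me2 <- module_eigengene(Y, setNames(rep(1, 8), rownames(Y)))
  Z <- t(scale(t(Y)))
  ev <- eigen(crossprod(Z))$vectors[, 1]
  expect_gt(abs(cor(me2[, "ME1"], ev)), 1 - 1e-10)
  # PC1 explains at least as much variance as any single member direction
  ve <- attr(me2, "var_explained")["ME1"]
  for (i in 1:8) {
    d <- Z[i, ] / sqrt(sum(Z[i, ]^2))
    expect_gte(ve + 1e-12, sum((Z %*% d)^2) / sum(Z^2))
  }
  # permuting members leaves the eigengene unchanged up to sign
  pm <- sample(8)
  me3 <- module_eigengene(Y[pm, ], setNames(rep(1, 8), rownames(Y)[pm]))
  expect_equal(abs(cor(me2[, 1], me3[, 1])), 1, tolerance = 1e-10)
  expect_error(module_eigengene(matrix(1, 3, 5,
                                       dimnames = list(letters[1:3], NULL)),
                                setNames(rep(1, 3), letters[1:3])),
               "all-constant")
})

test_that("module-trait correlation reproduces the Student-t p-value", {
  set.seed(50)
  me <- matrix(rnorm(20), 20, 1, dimnames = list(paste0("s", 1:20), "ME1"))
  traits <- data.frame(flat = rep(1, 20), same = me[, 1],
                       noisy = me[, 1] + rnorm(20),
                       row.names = rownames(me))
  mt <- module_trait_correlation(me, traits)
  expect_true(is.na(mt$r[mt$trait == "flat"]))
  expect_false(mt$significant[mt$trait == "flat"])
  expect_equal(mt$r[mt$trait == "same"], 1)
  expect_lt(mt$p[mt$trait == "same"], 1e-12)
  row <- mt[mt$trait == "noisy", ]
  tval <- row$r * sqrt(18) / sqrt(1 - row$r^2)
  expect_equal(row$p, 2 * pt(-abs(tval), 18), tolerance = 1e-12)
  # r = 0 gives p = 1
  me0 <- matrix(rep(c(-1, 1), 10), 20, 1,
                dimnames = list(paste0("s", 1:20), "ME1"))
  t0 <- data.frame(orth = rep(c(1, 1, -1, -1), 5), row.names = rownames(me0))
  mt0 <- module_trait_correlation(me0, t0)
  expect_equal(mt0$p, 1, tolerance = 1e-12)
})

test_that("the planted RFI-linked module is detected and significantly
           correlated with RFI", {
  s <- small_sim(seed = 51, n_circ = 30, n_gene = 200,
                 pattern_proportions = c(additive = 0, dominant = 0,
                                         overdominant = 0, underdominant = 0),
                 spe_fraction = 0, tissue_specific_fraction = 0)
  phen <- fit_rfi(compute_derived_traits(s$phen$phenotypes))
  m <- s$cnt$meta[s$cnt$meta$tissue == "hypothalamus", ]
  cpm <- compute_cpm(rbind(s$cnt$circ_counts, s$cnt$gene_counts),
                     s$cnt$meta)[, m$sample_id]
  expr <- log2(cpm + 1)
  mf <- mad_filter(expr[rownames(s$cnt$circ_counts), ],
                   expr[rownames(s$cnt$gene_counts), ])
  st <- pick_soft_threshold(mf$expr)
  tom <- compute_tom(signed_adjacency(mf$expr, st$power))
  mod <- detect_modules(tom, mf$expr, min_size = 40)
  members <- s$cnt$truth$module$members
  inmod <- mod$module[mod$feature_id %in% members]
  best <- as.integer(names(which.max(table(inmod[inmod != 0]))))
  expect_gt(mean(inmod == best), 0.8)
  me <- module_eigengene(mf$expr, mod)
  traits <- data.frame(RFI = phen$RFI[match(m$bird_id, phen$bird_id)],
                       row.names = m$sample_id)
  mt <- module_trait_correlation(me, traits)
  row <- mt[mt$module == paste0("ME", best), ]
  expect_lt(row$p, 0.01)
  expect_gt(abs(row$r), 0.3)
})
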