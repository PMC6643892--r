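test_that("scan designs satisfy the model constraints", {
  sm <- build_design(4, "noDR")
  expect_equal(dim(sm$X), c(36, 6))
  expect_true(all(sm$X %in% 0:1))
  smd <- build_design(4, "DR")
  expect_equal(dim(smd$X), c(100, 6))
  expect_true(all(smd$X %in% 0:2))
  expect_true(any(smd$X == 2))
  ## per-state maternal and paternal sums (incl. dropped X1/X5) equal 2
  for (m in list(sm, smd)) {
    cts <- m$states$counts
    expect_true(all(colSums(cts[1:4, ]) == 2))
    expect_true(all(colSums(cts[5:8, ]) == 2))
  }
  h6 <- build_design(6, "noDR")
  expect_equal(dim(h6$X), c(400, 10))
  expect_error(build_design(8, "noDR"), "ploidy")
})

test_that("weighted LOD reproduces the formula and an independent oracle", {
  fx <- even_pipeline()
  sm <- fx$sm
  set.seed(11)
  ## formula arithmetic: RSS1 = RSS0 => 0; known ratio => (N/2) log10 ratio
  W <- matrix(1 / 36, 36, 20)                 # uniform weights: no signal
  y <- rnorm(20)
  expect_equal(weighted_lod(y, W, sm), 0, tolerance = 1e-9)
  expect_warning(weighted_lod(rep(1, 20), W, sm), "zero phenotypic")
  ## oracle: state-expanded weighted lm on 100 random instances
  st <- sm$states
  for (i in 1:100) {
    N <- sample(15:40, 1)
    W <- matrix(stats::rexp(36 * N), 36, N)
    W <- W / rep(colSums(W), each = 36)
    y <- rnorm(N, sd = 2) + 3
    fit <- stats::lm(rep(y, each = 36) ~ sm$X[rep(1:36, N), ],
                     weights = as.vector(W))
    rss1 <- sum(as.vector(W) * stats::residuals(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    oracle <- max(0, (N / 2) * log10(rss0 / rss1))
    expect_equal(weighted_lod(y, W, sm), oracle, tolerance = 1e-8)
  }
})

test_that("LOD is invariant under affine transformations of the phenotype", {
  fx <- even_pipeline()
  set.seed(12)
  y <- rnorm(120)
  W <- fx$grd$prob[, , 40]
  l1 <- weighted_lod(y, W, fx$sm)
  l2 <- weighted_lod(3.5 * y - 11, W, fx$sm)
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("the scan localizes a strong QTL and zeroes a constant phenotype", {
  fx <- even_pipeline()
  ## phenotype = exact inheritance of homolog 2 at 30 cM (noise-free)
  truth <- true_ibd(fx$pop, 30)[2, , 1]
  sc <- qtl_scan(as.numeric(truth), fx$grd, fx$sm)
  expect_lte(abs(sc$peak_position - 30), 1)
  expect_s3_class(sc, "QTLScanResult")
  expect_equal(sc$peak_lod, max(sc$lod))
  expect_true(all(sc$lod >= 0))
  suppressWarnings(sc0 <- qtl_scan(rep(2, 120), fx$grd, fx$sm))
  expect_true(all(sc0$lod == 0))
})

test_that("permutation thresholds are order statistics of the maxima", {
  fx <- even_pipeline()
  set.seed(13)
  y <- rnorm(120)
  thr <- permutation_threshold(y, fx$grd, fx$sm, n_perm = 200,
                               alpha = 0.05, seed = 99)
  maxima <- attr(thr, "maxima")
  expect_length(maxima, 200)
  expect_equal(as.numeric(thr),
               stats::quantile(maxima, 0.95, names = FALSE))
  ## deterministic given seed
  thr2 <- permutation_threshold(y, fx$grd, fx$sm, n_perm = 200,
                                alpha = 0.05, seed = 99)
  expect_equal(as.numeric(thr), as.numeric(thr2))
  ## constant phenotype -> threshold 0
  suppressWarnings(
    thr0 <- permutation_threshold(rep(1, 120), fx$grd, fx$sm,
                                  n_perm = 100, seed = 1))
  expect_equal(as.numeric(thr0), 0)
  expect_error(permutation_threshold(y, fx$grd, fx$sm, n_perm = 10),
               "n_perm")
})

test_that("thresholds grow with grid density", {
  fx <- even_pipeline()
  set.seed(14)
  y <- rnorm(120)
  post <- fx$post
  coarse <- spline_to_grid(post, step = 10)
  fine <- spline_to_grid(post, step = 1)
  t_coarse <- permutation_threshold(y, coarse, fx$sm, 200, seed = 5)
  t_fine <- permutation_threshold(y, fine, fx$sm, 200, seed = 5)
  expect_gte(as.numeric(t_fine), as.numeric(t_coarse))
})

test_that("support intervals follow the full-range convention", {
  mk <- function(lod) list(positions = seq_along(lod) - 1, lod = lod)
  flat <- mk(rep(3, 11))
  expect_equal(support_interval(flat, 1), c(0, 10))
  spike <- mk(c(1, 1, 1, 9, 1, 1))
  expect_equal(support_interval(spike, 2), c(3, 3))
  ## secondary peak within 2 LOD spans the interval
  multi <- mk(c(0, 8, 1, 1, 7, 0.5))
  expect_equal(support_interval(multi, 2), c(1, 4))
  expect_equal(support_interval(multi, 1), c(1, 1))
})

test_that("LOD interpolation is linear and bounded to the span", {
  sc <- list(positions = c(0, 10, 20), lod = c(2, 4, 0))
  expect_equal(interpolate_lod(sc, 10), 4)
  expect_equal(interpolate_lod(sc, 5), 3)
  expect_error(interpolate_lod(sc, 25), "outside")
  ## agreement with a dense rescan on a smooth profile
  fx <- even_pipeline()
  truth <- true_ibd(fx$pop, 30)[2, , 1]
  y <- truth + rnorm(120, sd = 0.8)
  sc1 <- qtl_scan(y, spline_to_grid(fx$post, step = 1), fx$sm)
  sc4 <- qtl_scan(y, spline_to_grid(fx$post, step = 0.25), fx$sm)
  at <- seq(5, 95, by = 2.5)
  expect_lt(max(abs(interpolate_lod(sc1, at) - interpolate_lod(sc4, at))),
            0.1)
})

test_that("single-marker scans behave at the edge cases", {
  fx <- even_pipeline()
  set.seed(15)
  dos <- fx$dos
  ## marker identical to a dosage-coded QTL, no noise -> maximal LOD there
  y <- as.numeric(dos[25, ])
  res <- single_marker_scan(y, dos)
  expect_equal(res$marker[which.max(res$lod)], 25)
  ## permuted dosages: LOD near zero
  yp <- sample(y)
  resp <- single_marker_scan(yp, dos[25, , drop = FALSE])
  expect_lt(resp$lod, 2)
  ## all-missing marker excluded with warning; monomorphic -> 0
  dos2 <- rbind(dos[1:2, ], NA, c(rep(2L, 120)))
  ## last row is monomorphic but must pass the map-free path
  expect_warning(r2 <- single_marker_scan(y, dos2), "all-missing")
  expect_equal(nrow(r2), 3)
  expect_equal(r2$lod[r2$marker == 4], 0)
})

test_that("allele effects recover carrier contrasts", {
  ## pi identical across individuals -> all zero
  pim <- matrix(0.5, 8, 30)
  hp <- structure(list(pi = array(pim, c(8, 30, 1)), positions = 5,
                       model = "noDR", ploidy = 4, N = 30),
                  class = "HaplotypeProbs")
  set.seed(16)
  y <- rnorm(30)
  expect_true(all(abs(allele_effects(y, hp, 5)) < 1e-12))
  ## indicator pi, carriers shifted by +1:
  ## effect = mean difference x (1 - carrier fraction)
  carriers <- rep(c(1, 0), 15)
  pim2 <- matrix(0.5, 8, 30); pim2[1, ] <- carriers
  hp2 <- hp; hp2$pi <- array(pim2, c(8, 30, 1))
  y2 <- rnorm(30, sd = 0.01) + carriers
  eff <- allele_effects(y2, hp2, 5)
  expect_equal(unname(eff[1, 1]),
               (mean(y2[carriers == 1]) - mean(y2[carriers == 0])) *
                 (1 - mean(carriers)), tolerance = 1e-2)
  ## zero total weight -> NA
  pim3 <- pim2; pim3[2, ] <- 0
  hp3 <- hp; hp3$pi <- array(pim3, c(8, 30, 1))
  expect_true(is.na(allele_effects(y2, hp3, 5)[2, 1]))
  ## algebraic identity: one parent's effects, weighted by the mean pi of
  ## each homolog, sum to exactly zero (per-parent pi sums are fixed)
  pim4 <- matrix(stats::runif(8 * 30), 8, 30)
  pim4[1:4, ] <- 2 * pim4[1:4, ] / rep(colSums(pim4[1:4, ]), each = 4)
  pim4[5:8, ] <- 2 * pim4[5:8, ] / rep(colSums(pim4[5:8, ]), each = 4)
  hp4 <- hp; hp4$pi <- array(pim4, c(8, 30, 1))
  eff4 <- allele_effects(y, hp4, 5)
  expect_lt(abs(sum(rowMeans(pim4[1:4, ]) * eff4[1:4, 1])), 1e-9)
  expect_lt(abs(sum(rowMeans(pim4[5:8, ]) * eff4[5:8, 1])), 1e-9)
})

test_that("the hexaploid pipeline runs end to end under noDR", {
  map <- generate_phased_map(6, 30, 60, "uniform", seed = 61)
  pop <- simulate_population(map, 40, q = 0.5, seed = 62)
  dos <- genotype_population(pop, eps = 0.001, seed = 63)
  expect_true(all(dos %in% 0:6))
  post <- ibd_posterior(dos, map, "noDR", eps = 0.001)
  expect_equal(dim(post$prob)[1], 400)
  expect_lt(max(abs(colSums(post$prob) - 1)), 1e-9)
  hp <- haplotype_probs(post)
  expect_lt(max(abs(apply(hp$pi[1:6, , ], c(2, 3), sum) - 3)), 1e-9)
  grd <- spline_to_grid(post)
  truth <- true_ibd(pop, 30)[2, , 1]
  y <- truth + rnorm(40, sd = 0.5)
  sc <- qtl_scan(y, grd, build_design(6, "noDR"))
  expect_length(sc$lod, length(grd$positions))
  expect_gt(sc$peak_lod, 0)
})

test_that("noDR and DR scans agree on bivalent-only populations", {
  map <- dense_informative_map(30)
  pop <- simulate_population(map, 80, q = 0, seed = 41)
  dos <- genotype_population(pop, eps = 0.001, seed = 42)
  gn <- spline_to_grid(ibd_posterior(dos, map, "noDR"))
  gd <- spline_to_grid(ibd_posterior(dos, map, "DR", q = 0.5))
  truth <- true_ibd(pop, 15)[2, , 1]
  y <- truth + rnorm(80, sd = 1)
  sn <- qtl_scan(y, gn, build_design(4, "noDR"))
  sd_ <- qtl_scan(y, gd, build_design(4, "DR"))
  expect_lt(abs(sn$peak_lod - sd_$peak_lod), 0.5)
})
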