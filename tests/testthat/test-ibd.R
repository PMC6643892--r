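test_that("ancestry state-space counts match the combinatorial identities", {
  expect_equal(enumerate_ibd_states(4, FALSE)$n, 36)
  expect_equal(enumerate_ibd_states(4, TRUE)$n, 100)
  expect_equal(enumerate_ibd_states(6, FALSE)$n, 400)
  expect_warning(s6 <- enumerate_ibd_states(6, TRUE), "large DR")
  expect_equal(s6$n, 3136)                    # 56^2 multiset pairs
  expect_error(enumerate_ibd_states(5), "even")
  st <- enumerate_ibd_states(4, FALSE)
  expect_true(all(colSums(st$counts) == 4))
  expect_true(all(st$counts[, !st$dup] <= 1))
  std <- enumerate_ibd_states(4, TRUE)
  expect_equal(sum(std$dup), 100 - 36)        # 64 extra DR classes
})

test_that("transition matrices are stochastic, identity at d = 0, and factorized", {
  for (model in c(FALSE, TRUE)) {
    st <- enumerate_ibd_states(4, model)
    expect_equal(transition_matrix(st, 0, 0.4), diag(st$n))
    for (d in c(0.01, 1, 10, 100)) {
      Tm <- transition_matrix(st, d, 0.4)
      expect_true(all(Tm >= 0))
      expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
    }
  }
  expect_error(transition_matrix(enumerate_ibd_states(4, FALSE), -1), ">= 0")
})

test_that("the stationary distribution is preserved at every distance", {
  ## eigen-analysis oracle: the principal left eigenvector of T(d)
  ## satisfies pi T = pi; for noDR the kernel is doubly stochastic so pi
  ## is uniform at all d. (T(d) itself tends to the fixed r = 1/2 kernel,
  ## not to a rank-one matrix: chromosome-long pairing keeps a 1 - r
  ## self-persistence.)
  st <- enumerate_ibd_states(4, FALSE)
  for (d in c(1, 10, 1e4)) {
    Tm <- transition_matrix(st, d, 0)
    expect_lt(max(abs(colSums(Tm) - 1)), 1e-10)      # uniform stationary
  }
  Tinf <- transition_matrix(st, 1e4, 0)
  r <- 0.5 * (1 - exp(-0.02 * 1e4))
  expect_equal(r, 0.5, tolerance = 1e-12)
  ## DR model: compute the stationary eigenvector per distance
  std <- enumerate_ibd_states(4, TRUE)
  for (d in c(2, 50)) {
    Tm <- transition_matrix(std, d, 0.3)
    e <- eigen(t(Tm))
    v <- Re(e$vectors[, 1]); v <- v / sum(v)
    expect_lt(max(abs(drop(v %*% Tm) - v)), 1e-9)
    expect_true(all(v > -1e-12))
  }
})

test_that("DR transitions starve duplicated states as q -> 0", {
  std <- enumerate_ibd_states(4, TRUE)
  Tm <- transition_matrix(std, 5, 0)
  expect_true(all(Tm[!std$dup, std$dup] == 0))
  Tq <- transition_matrix(std, 5, 0.5)
  expect_gt(sum(Tq[!std$dup, std$dup]), 0)
})

test_that("emission probabilities follow the eps error model", {
  alle <- c(1, 0, 0, 0, 1, 1, 0, 0)
  state <- c(1, 2, 5, 6)                       # expected dosage 1+1+1 = 3
  expect_equal(emission_prob(state, alle, 3, 0), 1)
  expect_equal(emission_prob(state, alle, 2, 0), 0)
  expect_equal(emission_prob(state, alle, NA, 0.5), 1)
  expect_equal(emission_prob(state, alle, 1, 0.001), 0.00025)  # eps/ploidy
  expect_equal(emission_prob(state, alle, 3, 0.001), 0.999)
  ## DR state with duplicated homolog counts multiplicity
  expect_equal(emission_prob(c(1, 1, 5, 6), alle, 4, 0), 1)
})

test_that("forward-backward equals the exhaustive-path oracle on tiny maps", {
  set.seed(5)
  cases <- list(list(p = 2, M = 4, model = "noDR", q = 0),
                list(p = 4, M = 3, model = "noDR", q = 0),
                list(p = 4, M = 3, model = "DR", q = 0.4),
                list(p = 4, M = 2, model = "DR", q = 0.15))
  for (cs in cases) {
    map <- random_tiny_map(cs$p, cs$M)
    dos <- matrix(sample(c(0:cs$p, NA), 2 * cs$M, replace = TRUE), cs$M, 2)
    post <- ibd_posterior(dos, map, cs$model, q = cs$q, eps = 0.001)
    oracle <- brute_posterior(dos, map, cs$model, cs$q, 0.001)
    expect_lt(max(abs(post$prob - oracle)), 1e-10)
  }
})

test_that("posteriors normalize and haplotypic probabilities conserve ploidy", {
  fx <- even_pipeline()
  expect_lt(max(abs(colSums(fx$post$prob) - 1)), 1e-9)
  hp <- haplotype_probs(fx$post)
  m_sum <- apply(hp$pi[1:4, , ], c(2, 3), sum)
  p_sum <- apply(hp$pi[5:8, , ], c(2, 3), sum)
  expect_lt(max(abs(m_sum - 2)), 1e-9)
  expect_lt(max(abs(p_sum - 2)), 1e-9)
  expect_true(all(hp$pi >= -1e-12 & hp$pi <= 1 + 1e-12))
})

test_that("all-missing data returns the prior with a warning", {
  map <- random_tiny_map(4, 5)
  dos <- matrix(NA_integer_, 5, 2)
  expect_warning(post <- ibd_posterior(dos, map, "noDR"), "all-missing")
  expect_lt(max(abs(post$prob - 1 / 36)), 1e-12)
  hp <- haplotype_probs(post)
  expect_lt(max(abs(hp$pi - 0.5)), 1e-12)      # tetraploid noDR prior
})

test_that("haplotype probabilities respond to point-mass posteriors", {
  st <- enumerate_ibd_states(4, FALSE)
  target <- which(apply(st$counts, 2, function(z)
    all(z[c(1, 2, 5, 6)] == 1) && sum(z) == 4))
  prob <- array(0, c(36, 1, 1)); prob[target, 1, 1] <- 1
  fake <- structure(list(prob = prob, positions = 0, states = st,
                         model = "noDR"), class = "IBDProbabilities")
  hp <- haplotype_probs(fake)
  expect_equal(drop(hp$pi), c(1, 1, 0, 0, 1, 1, 0, 0),
               ignore_attr = TRUE)
  ## conservation under random posteriors
  set.seed(6)
  P <- matrix(stats::runif(36 * 1000), 36)
  P <- P / rep(colSums(P), each = 36)
  fake$prob <- array(P, c(36, 1000, 1))
  hp2 <- haplotype_probs(fake)
  expect_lt(max(abs(colSums(hp2$pi[1:4, , 1]) - 2)), 1e-9)
  expect_lt(max(abs(colSums(hp2$pi[5:8, , 1]) - 2)), 1e-9)
})

test_that("modal posterior state recovers the truth on a dense informative map", {
  map <- dense_informative_map(20)
  pop <- simulate_population(map, 40, q = 0, seed = 31)
  dos <- genotype_population(pop, eps = 0.001, seed = 32)
  post <- ibd_posterior(dos, map, "noDR", eps = 0.001)
  truth <- true_ibd(pop, map$marker$position)
  keys <- apply(post$states$counts, 2, paste, collapse = ",")
  hits <- 0L; tot <- 0L
  for (i in seq_len(40)) for (l in seq_len(nrow(map$marker))) {
    tk <- paste(truth[, i, l], collapse = ",")
    hits <- hits + (keys[which.max(post$prob[, i, l])] == tk)
    tot <- tot + 1L
  }
  expect_gte(hits / tot, 0.99)
})

test_that("posterior concentration on the truth increases with marker density", {
  set.seed(33)
  mean_truth_prob <- vapply(c(16, 40, 80, 160), function(nm) {
    map <- generate_phased_map(4, nm, 100, "uniform", seed = 40 + nm)
    pop <- simulate_population(map, 40, q = 0, seed = 50 + nm)
    dos <- genotype_population(pop, eps = 0.001, seed = 60 + nm)
    post <- ibd_posterior(dos, map, "noDR", eps = 0.001)
    truth <- true_ibd(pop, map$marker$position)
    keys <- apply(post$states$counts, 2, paste, collapse = ",")
    tp <- 0
    for (i in seq_len(40)) for (l in seq_len(nm)) {
      s <- match(paste(truth[, i, l], collapse = ","), keys)
      tp <- tp + post$prob[s, i, l]
    }
    tp / (40 * nm)
  }, 0)
  expect_true(all(diff(mean_truth_prob) > 0))
})

test_that("the DR model puts little mass on DR states when meiosis is bivalent", {
  map <- map_even_coverage(seed = 7)
  pop <- simulate_population(map, 80, q = 0, seed = 21)
  dos <- genotype_population(pop, eps = 0.001, seed = 22)
  post <- ibd_posterior(dos, map, "DR", q = 0.5, eps = 0.001)
  dup_mass <- mean(colSums(post$prob[post$states$dup, , ]))
  expect_lt(dup_mass, 0.02)
})

test_that("spline interpolation preserves constants, lines and normalization", {
  fx <- even_pipeline()
  grd <- fx$grd
  expect_lt(max(abs(colSums(grd$prob) - 1)), 1e-9)
  expect_false(grd$extrapolated)
  ## constant posterior stays constant
  st <- enumerate_ibd_states(4, FALSE)
  M <- 12
  const <- structure(list(prob = array(1 / 36, c(36, 3, M)),
                          positions = seq(2, 90, length.out = M),
                          states = st, model = "noDR"),
                     class = "IBDProbabilities")
  g1 <- spline_to_grid(const)
  expect_lt(max(abs(g1$prob - 1 / 36)), 1e-12)
  ## linear-in-position synthetic posterior recovered exactly
  x <- seq(0, 50, length.out = 11)
  w <- x / 50
  prob <- array(0, c(36, 2, 11))
  prob[1, , ] <- rep(0.2 + 0.3 * w, each = 2)
  prob[2, , ] <- rep(0.8 - 0.3 * w, each = 2)
  lin <- structure(list(prob = prob, positions = x, states = st,
                        model = "noDR"), class = "IBDProbabilities")
  g2 <- spline_to_grid(lin, step = 0.5)
  expected <- 0.2 + 0.3 * g2$positions / 50
  expect_lt(max(abs(g2$prob[1, 1, ] - expected)), 1e-3)
  ## values at marker positions close to the input
  on_marker <- g1$positions %in% const$positions
  expect_lt(max(abs(g1$prob[, , on_marker] - 1 / 36)), 0.05)
  ## explicit out-of-span grid flags extrapolation
  g3 <- spline_to_grid(lin, grid = seq(-5, 55, 5))
  expect_true(g3$extrapolated)
  expect_error(spline_to_grid(structure(list(prob = array(1, c(36, 1, 1)),
                                             positions = 3, states = st,
                                             model = "noDR"),
                                        class = "IBDProbabilities")),
               "at least 2")
})
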