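## Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

## fully informative map: every homolog uniquely tagged by an SxN-type
## marker once per cM
dense_informative_map <- function(length_cM = 20, ploidy = 4) {
  pos <- rep(seq(0.5, length_cM - 0.5, by = 1), each = 2 * ploidy)
  alle <- matrix(0L, 2 * ploidy, length(pos))
  for (i in seq_along(pos)) alle[(i - 1) %% (2 * ploidy) + 1L, i] <- 1L
  phased_map("dense", length_cM, pos, alle, ploidy)
}

## small analysed population on the even-coverage benchmark map:
## map, population, dosages, noDR/DR gridded IBD and scan operators
even_pipeline <- function() {
  fixture("even_pipeline", function() {
    map <- map_even_coverage(seed = 7)
    pop <- simulate_population(map, 120, q = 0, seed = 11)
    dos <- genotype_population(pop, eps = 0.001, seed = 12)
    post <- ibd_posterior(dos, map, "noDR", eps = 0.001)
    grd <- spline_to_grid(post)
    list(map = map, pop = pop, dos = dos, post = post, grd = grd,
         sm = build_design(4, "noDR"))
  })
}

## random valid tiny map for oracle tests
random_tiny_map <- function(ploidy, n_markers, length_cM = 30) {
  alle <- matrix(stats::rbinom(2 * ploidy * n_markers, 1, 0.5),
                 2 * ploidy, n_markers)
  for (m in seq_len(n_markers)) {
    d1 <- sum(alle[seq_len(ploidy), m])
    d2 <- sum(alle[ploidy + seq_len(ploidy), m])
    if (d1 %in% c(0, ploidy) && d2 %in% c(0, ploidy))
      alle[1, m] <- 1L - alle[1, m]
  }
  phased_map("tiny", length_cM, sort(stats::runif(n_markers, 0, length_cM)),
             alle, ploidy)
}

## exhaustive state-path posterior (independent oracle for the HMM)
brute_posterior <- function(dosages, map, model, q, eps) {
  st <- enumerate_ibd_states(map$ploidy, allow_dr = model == "DR")
  n <- st$n; M <- nrow(map$marker); N <- ncol(dosages)
  pos <- map$marker$position
  Ts <- lapply(seq_len(M - 1), function(i)
    transition_matrix(st, pos[i + 1] - pos[i], q))
  prior <- ibdqtl:::state_prior(st, q)
  ED <- crossprod(st$counts, map$alleles)
  post <- array(0, c(n, N, M))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), M)))
  for (ind in seq_len(N)) {
    w <- prior[paths[, 1]]
    for (m in seq_len(M)) {
      obs <- dosages[m, ind]
      e <- if (is.na(obs)) rep(1, nrow(paths)) else
        ifelse(ED[paths[, m], m] == obs, 1 - eps, eps / map$ploidy)
      w <- w * e
      if (m > 1) w <- w * Ts[[m - 1]][cbind(paths[, m - 1], paths[, m])]
    }
    for (m in seq_len(M)) {
      p <- tapply(w, paths[, m], sum)
      post[, ind, m] <- p / sum(p)
    }
  }
  post
}

## match truth copy-count columns to state ids of an enumeration
state_id_of_counts <- function(states, counts_vec) {
  keys <- apply(states$counts, 2, paste, collapse = ",")
  match(paste(counts_vec, collapse = ","), keys)
}
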