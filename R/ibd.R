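#' Enumerate ancestry (IBD) states
#'
#' An ancestry state records which parental homologs an offspring
#' inherited at a locus: a multiset of `ploidy/2` maternal homologs
#' (indices `1..ploidy`) and `ploidy/2` paternal homologs
#' (`ploidy+1..2*ploidy`). Under the bivalent-only model (`noDR`) the
#' indices within a parent are all distinct, giving
#' `choose(ploidy, ploidy/2)^2` states (36 in a tetraploid). Allowing
#' double reduction adds duplicated-index states, giving `M^2` states
#' where `M` is the number of multisets of size `ploidy/2` from `ploidy`
#' (100 in a tetraploid: 64 extra classes).
#'
#' @param ploidy even integer >= 2.
#' @param allow_dr include duplicated-homolog (double-reduction) states?
#' @return an object of class `AncestryStates` with elements `n` (state
#'   count), `counts` (a `2*ploidy x n` homolog copy-count matrix),
#'   `maternal`/`paternal` (per-parent multiset matrices), `dup` (logical,
#'   state contains a duplicated index) and `labels`.
#' @export
enumerate_ibd_states <- function(ploidy, allow_dr = FALSE) {
  check_ploidy(ploidy)
  m <- ploidy / 2
  per <- parent_multisets(ploidy, allow_dr)
  np <- nrow(per)
  if (allow_dr && np^2 > 1500)
    warning("large DR state space (", np^2, " states); expect heavy ",
            "memory/time use", call. = FALSE)
  im <- rep(seq_len(np), each = np)   # maternal-major joint ordering
  ip <- rep(seq_len(np), times = np)
  n <- np^2
  counts <- matrix(0L, 2 * ploidy, n,
                   dimnames = list(paste0("h", seq_len(2 * ploidy)), NULL))
  for (s in seq_len(n)) {
    hm <- per[im[s], ]; hp <- per[ip[s], ] + ploidy
    for (h in hm) counts[h, s] <- counts[h, s] + 1L
    for (h in hp) counts[h, s] <- counts[h, s] + 1L
  }
  dup_per <- apply(per, 1, anyDuplicated) > 0L
  lab_per <- apply(per, 1, paste, collapse = "")
  labels <- paste0(lab_per[im], "|",
                   apply(per + ploidy, 1, paste, collapse = "")[ip])
  structure(list(ploidy = as.integer(ploidy), dr = allow_dr, n = n,
                 per_parent = per, n_per = np, im = im, ip = ip,
                 counts = counts, dup_per = dup_per,
                 dup = dup_per[im] | dup_per[ip], labels = labels),
            class = "AncestryStates")
}

#' @export
print.AncestryStates <- function(x, ...) {
  cat(sprintf("AncestryStates: ploidy %d, %s model, %d states (%d per parent)\n",
              x$ploidy, if (x$dr) "DR" else "noDR", x$n, x$n_per))
  invisible(x)
}

## sorted multisets (or sets) of size ploidy/2 from 1..ploidy,
## lexicographic order
parent_multisets <- function(ploidy, allow_dr) {
  m <- ploidy / 2
  g <- as.matrix(expand.grid(rev(rep(list(seq_len(ploidy)), m))))[, m:1,
                                                                  drop = FALSE]
  ok <- rowSums(g[, -1, drop = FALSE] >= g[, -m, drop = FALSE]) == (m - 1) |
    m == 1
  if (!allow_dr)
    ok <- ok & (m == 1 |
                  rowSums(g[, -1, drop = FALSE] > g[, -m, drop = FALSE]) ==
                  (m - 1))
  g <- g[ok, , drop = FALSE]
  dimnames(g) <- NULL
  g
}

haldane_r <- function(d_cM) 0.5 * (1 - exp(-0.02 * d_cM))

## per-parent transition matrix over the multisets of `states`
## (model-adjusted: noDR restricted+renormalized, DR q-weighted)
transition_parent <- function(states, d_cM, q) {
  p <- states$ploidy
  m <- p / 2
  r <- haldane_r(d_cM)
  K <- matrix(r / (p - 1), p, p); diag(K) <- 1 - r
  per <- states$per_parent
  np <- states$n_per
  tb <- tuple_bins(p, m)
  O <- tb$O; bin <- tb$bin
  ## full multiset list (including duplicated) in lexicographic order
  full <- tb$full
  nf <- nrow(full)
  Tfull <- matrix(0, np, nf)
  for (s in seq_len(np)) {
    a <- per[s, ]
    pr <- K[a[1], O[, 1]]
    if (m > 1) for (j in 2:m) pr <- pr * K[a[j], O[, j]]
    Tfull[s, ] <- rowsum(pr, bin)[, 1]
  }
  dup_full <- apply(full, 1, anyDuplicated) > 0L
  if (!states$dr) {
    Tm <- Tfull[, !dup_full, drop = FALSE]
  } else {
    Tfull[, dup_full] <- Tfull[, dup_full, drop = FALSE] * q
    Tm <- Tfull
  }
  rs <- rowSums(Tm)
  zero <- rs <= 0
  if (any(zero)) {               # unreachable rows (e.g. DR source at q = 0)
    Tm[zero, ] <- 0
    Tm[cbind(which(zero), which(zero))] <- 1
    rs[zero] <- 1
  }
  Tm / rs
}

## memoized ordered-tuple table and multiset bin ids per (ploidy, m)
tuple_bins <- local({
  cache <- list()
  function(p, m) {
    id <- paste(p, m)
    if (is.null(cache[[id]])) {
      O <- as.matrix(expand.grid(rep(list(seq_len(p)), m)))
      dimnames(O) <- NULL
      full <- parent_multisets(p, TRUE)
      keys <- apply(full, 1, paste, collapse = ",")
      okey <- apply(O, 1, function(z) paste(sort(z), collapse = ","))
      cache[[id]] <<- list(O = O, bin = match(okey, keys), full = full)
    }
    cache[[id]]
  }
})

#' Ancestry transition matrix between two loci
#'
#' Per-parent factorized kernel: each inherited chromatid origin persists
#' with probability `1 - r` and moves to each other homolog with
#' probability `r/(ploidy - 1)`, `r = ` Haldane recombination fraction of
#' the distance. Under `noDR` the kernel is restricted to distinct-index
#' states and row-renormalized; under `DR`, duplicated-index target
#' states are down-weighted by the multivalent rate `q` before
#' renormalization (so at `q = 0` no mass ever reaches them). The joint
#' matrix is the Kronecker product of the maternal and paternal kernels
#' (the two meioses are independent). At `d = 0` it is the identity.
#'
#' @param states an [enumerate_ibd_states()] object.
#' @param d_cM inter-locus distance in cM (>= 0).
#' @param q multivalent formation rate (used by the DR model only).
#' @return row-stochastic `n x n` matrix.
#' @export
transition_matrix <- function(states, d_cM, q = 0) {
  if (d_cM < 0) stop("d_cM must be >= 0")
  Tp <- transition_parent(states, d_cM, q)
  kronecker(Tp, Tp)
}

## per-parent prior: uniform over ordered chromatid tuples, DR states
## q-weighted, renormalized; reduces to uniform over distinct sets at q=0
prior_parent <- function(states, q) {
  m <- states$ploidy / 2
  mult <- apply(states$per_parent, 1, function(z)
    factorial(m) / prod(factorial(tabulate(z, nbins = states$ploidy))))
  pr <- mult / states$ploidy^m
  if (states$dr) pr[states$dup_per] <- pr[states$dup_per] * q
  pr / sum(pr)
}

state_prior <- function(states, q) {
  pp <- prior_parent(states, q)
  as.vector(pp[states$ip] * pp[states$im])
}

#' Emission probability of an observed dosage given an ancestry state
#'
#' The expected dosage of a state is the sum of the parental marker
#' alleles over the state's homolog origins (with multiplicity). The
#' observation matches it with probability `1 - eps` and is any one of
#' the other `ploidy` dosage classes with probability `eps/ploidy`;
#' missing observations are uninformative (probability 1).
#'
#' @param state integer vector of inherited homolog indices (length
#'   `ploidy`, maternal 1..ploidy and paternal ploidy+1..2*ploidy), or a
#'   `2*ploidy` copy-count vector.
#' @param marker_alleles 0/1 vector of length `2*ploidy`.
#' @param observed_dosage integer in `0..ploidy`, or `NA`.
#' @param eps dosage error probability.
#' @return emission probability.
#' @export
emission_prob <- function(state, marker_alleles, observed_dosage, eps) {
  p <- length(marker_alleles) / 2
  counts <- if (length(state) == p) tabulate(state, nbins = 2 * p) else state
  if (is.na(observed_dosage)) return(1)
  if (observed_dosage < 0 || observed_dosage > p)
    stop("observed dosage out of range")
  expected <- sum(counts * marker_alleles)
  if (observed_dosage == expected) 1 - eps else eps / p
}

#' Multipoint IBD posterior probabilities
#'
#' Forward–backward posteriors of the ancestry state of every offspring
#' at every marker, given observed dosages and the known phased parental
#' map. Offspring are conditionally independent given the map, so the
#' HMM is run jointly (vectorized) across individuals. Ancestry is
#' treated as Markov over consecutive marker intervals with the
#' [transition_matrix()] kernel — the standard multipoint approximation.
#'
#' @param dosages `markers x individuals` integer matrix (`NA` missing).
#' @param map a [phased_map()].
#' @param model `"noDR"` (bivalent-only, 36 tetraploid states) or `"DR"`
#'   (multivalent-aware, 100 tetraploid states).
#' @param q multivalent rate assumed by the DR model.
#' @param eps offspring dosage error probability (default 0.001; parental
#'   dosages are taken as error-free).
#' @return an `IBDProbabilities` object: `prob` is an
#'   `n_states x N x n_loci` array whose columns each sum to 1.
#' @export
ibd_posterior <- function(dosages, map, model = c("noDR", "DR"), q = 0,
                          eps = 0.001) {
  model <- match.arg(model)
  dosages <- as.matrix(dosages)
  M <- n_markers(map)
  if (nrow(dosages) != M)
    stop("dosage matrix must have one row per map marker")
  N <- ncol(dosages)
  st <- enumerate_ibd_states(map$ploidy, allow_dr = model == "DR")
  n <- st$n
  all_missing <- colSums(!is.na(dosages)) == 0L
  if (any(all_missing))
    warning(sum(all_missing), " individual(s) with all-missing data: ",
            "posterior equals the prior", call. = FALSE)
  ED <- crossprod(st$counts, map$alleles)       # n x M expected dosages
  emis <- function(m) {
    E <- matrix(eps / map$ploidy, n, N)
    obs <- dosages[m, ]
    E[outer(ED[, m], obs, "==") %in% TRUE] <- 1 - eps
    E[, is.na(obs)] <- 1
    E
  }
  pos <- map$marker$position
  Tlist <- lapply(seq_len(M - 1), function(i) {
    Tp <- transition_parent(st, pos[i + 1] - pos[i], q)
    kronecker(Tp, Tp)
  })
  prior <- state_prior(st, q)
  norm_cols <- function(a) {
    s <- colSums(a)
    bad <- s <= 0
    if (any(bad)) { a[, bad] <- 1 / n; s[bad] <- 1 }
    a / rep(s, each = n)
  }
  A <- array(0, dim = c(n, N, M))
  a <- norm_cols(prior * emis(1))
  A[, , 1] <- a
  if (M > 1) for (m in 2:M) {
    a <- norm_cols(crossprod(Tlist[[m - 1]], a) * emis(m))
    A[, , m] <- a
  }
  post <- array(0, dim = c(n, N, M))
  b <- matrix(1, n, N)
  post[, , M] <- norm_cols(A[, , M, drop = FALSE][, , 1] * b)
  if (M > 1) for (m in (M - 1):1) {
    b <- norm_cols(Tlist[[m]] %*% (b * emis(m + 1)))
    post[, , m] <- norm_cols(matrix(A[, , m], n, N) * b)
  }
  structure(list(prob = post, positions = pos, states = st, model = model,
                 eps = eps, q = q, gridded = FALSE, extrapolated = FALSE),
            class = "IBDProbabilities")
}

#' @export
print.IBDProbabilities <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf(
    "IBDProbabilities: %s model, %d states x %d individuals x %d %s\n",
    x$model, d[1], d[2], d[3],
    if (x$gridded) "grid positions" else "marker loci"))
  invisible(x)
}

#' Haplotypic IBD probabilities
#'
#' Collapses the state posterior to the expected copy number of each
#' parental homolog per individual and locus:
#' `pi(h) = sum_s count_s(h) * P(s)`. Under `noDR` these are inheritance
#' probabilities in `[0, 1]`; under `DR` expected copy counts in
#' `[0, 2]`. Within each parent the values sum to `ploidy/2`.
#'
#' @param ibd an [ibd_posterior()] (or gridded) object.
#' @return a `HaplotypeProbs` object; `pi` is `2*ploidy x N x n_loci`.
#' @export
haplotype_probs <- function(ibd) {
  st <- ibd$states
  d <- dim(ibd$prob)
  pm <- st$counts %*% matrix(ibd$prob, d[1], d[2] * d[3])
  structure(list(pi = array(pm, dim = c(2 * st$ploidy, d[2], d[3]),
                            dimnames = list(rownames(st$counts), NULL, NULL)),
                 positions = ibd$positions, model = ibd$model,
                 ploidy = st$ploidy, N = d[2]),
            class = "HaplotypeProbs")
}

#' Interpolate IBD probabilities to a cM grid
#'
#' Natural cubic spline interpolation of each state's posterior across
#' marker positions, evaluated at a regular grid, then clipped to
#' `[0, 1]` and renormalized so each (individual, position) distribution
#' sums to 1. Interpolation is a fixed linear operator in the marker
#' values, so the whole array is splined with one matrix product.
#'
#' @param ibd an [ibd_posterior()] result (>= 2 distinct marker
#'   positions).
#' @param step grid spacing in cM (default 1).
#' @param grid optional explicit grid; positions outside the marker span
#'   are extrapolated and flagged in the `extrapolated` field.
#' @return an `IBDProbabilities` object on the grid (`gridded = TRUE`).
#' @export
spline_to_grid <- function(ibd, step = 1, grid = NULL) {
  x <- ibd$positions
  prob <- ibd$prob
  if (anyDuplicated(x)) {   # average co-located markers for distinct knots
    ux <- unique(x)
    idx <- match(x, ux)
    d <- dim(prob)
    newp <- array(0, dim = c(d[1], d[2], length(ux)))
    for (k in seq_along(ux)) {
      sel <- which(idx == k)
      newp[, , k] <- if (length(sel) == 1L) prob[, , sel] else
        apply(prob[, , sel, drop = FALSE], c(1, 2), mean)
    }
    prob <- newp; x <- ux
  }
  if (length(x) < 2L) stop("need at least 2 distinct marker positions")
  if (is.null(grid)) grid <- seq(ceiling(min(x)), floor(max(x)), by = step)
  extrapolated <- any(grid < min(x) | grid > max(x))
  ## spline basis: column j = natural interpolating spline through e_j
  S <- vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- 1
    stats::spline(x, e, xout = grid, method = "natural")$y
  }, numeric(length(grid)))                      # n_grid x n_markers
  d <- dim(prob)
  G <- tcrossprod(matrix(prob, d[1] * d[2], d[3]), S)  # (n*N) x n_grid
  G[G < 0] <- 0; G[G > 1] <- 1
  G <- array(G, dim = c(d[1], d[2], length(grid)))
  cs <- colSums(G)                                # N x n_grid
  bad <- cs <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      G[, idx[r, 1], idx[r, 2]] <- 1 / d[1]
    cs[bad] <- 1
  }
  G <- G / rep(cs, each = d[1])
  out <- ibd
  out$prob <- G
  out$positions <- grid
  out$gridded <- TRUE
  out$step <- step
  out$extrapolated <- extrapolated
  out
}
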