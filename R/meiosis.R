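#' Simulate one polysomic meiosis (a gamete)
#'
#' A gamete carries `ploidy/2` chromatids, each an ordered list of
#' segments `(start, end, homolog-of-origin)` tiling `[0, length_cM]`.
#'
#' With probability `1 - q` the homologs form random bivalents: each
#' gamete chromatid is a recombinant product of one bivalent, switching
#' between the two paired homologs at crossover points placed by a
#' Poisson process of rate 1/100 per cM (Haldane, no interference).
#'
#' With probability `q` a cross-type multivalent forms: the homologs
#' pair head-to-tail in a ring, with pairing partners swapping at a
#' single random exchange point along the chromosome (so each homolog
#' pairs with one ring neighbour proximal to the exchange point and
#' with the other neighbour distal to it). At first division the
#' centromeres disjoin into two random poles of `ploidy/2`; the gamete
#' receives one chromatid from each centromere at its pole, each an
#' origin walk outward from the centromere that switches to the
#' position-specific pairing partner at crossover points. Because the
#' gamete's chromatids anchor on distinct centromeres but can both walk
#' onto (a sister copy of) the same homolog distal to a crossover,
#' double reduction arises with rate zero at the centromere, increasing
#' with distance from it — the classical multivalent profile.
#'
#' @param ploidy even integer >= 2.
#' @param length_cM chromosome length in cM.
#' @param q multivalent (e.g. quadrivalent) formation rate in `[0, 1]`.
#' @param centromere_cM centromere position.
#' @return list of `ploidy/2` chromatids, each a list with parallel
#'   vectors `start`, `end`, `homolog` (1..ploidy, relative to the
#'   parent).
#' @export
simulate_gamete <- function(ploidy, length_cM, q,
                            centromere_cM = length_cM / 2) {
  check_ploidy(ploidy)
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  n_chromatid <- ploidy / 2
  if (ploidy > 2 && stats::runif(1) < q) {
    ## cross-type multivalent: ring pairing with one partner-exchange
    ## point; see above
    ring <- sample.int(ploidy)
    xpt <- stats::runif(1, 0, length_cM)
    prox <- distal <- integer(ploidy)
    for (k in seq(1, ploidy, by = 2)) {        # proximal pairs: (1,2),(3,4),..
      prox[ring[k]] <- ring[k + 1]; prox[ring[k + 1]] <- ring[k]
    }
    for (k in seq(2, ploidy, by = 2)) {        # distal pairs: (2,3),..,(p,1)
      kk <- if (k == ploidy) 1L else k + 1L
      distal[ring[k]] <- ring[kk]; distal[ring[kk]] <- ring[k]
    }
    partner <- function(org, y) if (y < xpt) prox[org] else distal[org]
    pole <- sample.int(ploidy, n_chromatid)    # first-division disjunction
    lapply(pole, function(o)
      walk_chromatid(partner, o, length_cM, centromere_cM))
  } else {
    ## random bivalents: partition homologs into pairs, one recombinant
    ## chromatid from each of ploidy/2 bivalents
    perm <- sample.int(ploidy)
    lapply(seq_len(n_chromatid), function(k) {
      pair <- perm[c(2 * k - 1, 2 * k)]
      fixed <- integer(ploidy)
      fixed[pair] <- rev(pair)
      walk_chromatid(function(org, y) fixed[org], sample(pair, 1),
                     length_cM, centromere_cM)
    })
  }
}

## One chromatid: origin walk anchored at the centromere, switching to
## partner(origin, position) at Poisson(rate 0.01/cM) crossover points.
walk_chromatid <- function(partner, origin, length_cM, centromere_cM) {
  nx <- stats::rpois(1, length_cM / 100)
  xs <- sort(stats::runif(nx, 0, length_cM))
  brk <- c(0, xs, length_cM)
  n_seg <- length(brk) - 1L
  org <- integer(n_seg)
  anchor <- findInterval(centromere_cM, brk, rightmost.closed = TRUE)
  org[anchor] <- origin
  if (anchor < n_seg) for (i in (anchor + 1):n_seg)
    org[i] <- partner(org[i - 1], brk[i])      # crossover at brk[i]
  if (anchor > 1) for (i in (anchor - 1):1)
    org[i] <- partner(org[i + 1], brk[i + 1])  # crossover at brk[i + 1]
  ## merge runs of identical origin into segments (plain list: this is a
  ## hot path)
  keep <- c(TRUE, org[-1] != org[-n_seg])
  list(start = brk[-length(brk)][keep],
       end = brk[-1][c(which(keep)[-1] - 1L, n_seg)],
       homolog = org[keep])
}

#' Simulate an F1 population
#'
#' Each offspring receives one maternal and one paternal gamete,
#' simulated independently under [simulate_gamete()]. The returned truth
#' record (chromatid mosaics) is the oracle for IBD-estimation accuracy
#' and the source of QTL genotypes for phenotype simulation.
#'
#' @param map a [phased_map()].
#' @param N population size (>= 1).
#' @param q multivalent formation rate.
#' @param seed integer seed; the population is deterministic given it.
#' @return an object of class `Population`.
#' @export
simulate_population <- function(map, N, q, seed = NULL) {
  if (N < 1) stop("N must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- map$ploidy
  offspring <- lapply(seq_len(N), function(i) list(
    maternal = simulate_gamete(p, map$length_cM, q, map$centromere_cM),
    paternal = simulate_gamete(p, map$length_cM, q, map$centromere_cM)))
  structure(list(offspring = offspring, map = map, q = q, N = as.integer(N),
                 seed = seed),
            class = "Population")
}

#' @export
print.Population <- function(x, ...) {
  cat(sprintf("Population: N = %d offspring, q = %.2f, map %s (%d markers)\n",
              x$N, x$q, x$map$chrom, n_markers(x$map)))
  invisible(x)
}

## homolog-of-origin of each chromatid of a gamete at given positions
gamete_origins_at <- function(gamete, positions) {
  out <- vapply(gamete, function(ch) {
    idx <- findInterval(positions, ch$start, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    ch$homolog[idx]
  }, integer(length(positions)))
  matrix(out, nrow = length(positions)) # positions x chromatids
}

#' True ancestry (IBD) state of every offspring at given positions
#'
#' Extracts, from the simulation truth record, the multiset of inherited
#' parental homolog origins per individual and position. Paternal
#' homologs are offset by ploidy (so a tetraploid individual carries
#' origins from 1..4 maternally and 5..8 paternally).
#'
#' @param population a [simulate_population()] result.
#' @param positions cM positions within the map length.
#' @return integer copy-count array `homolog x individual x position`
#'   (dimensions `2*ploidy x N x length(positions)`); each individual's
#'   column sums to `ploidy`.
#' @export
true_ibd <- function(population, positions) {
  map <- population$map
  if (any(positions < 0 | positions > map$length_cM))
    stop("positions must lie within [0, map length]")
  p <- map$ploidy
  N <- population$N
  L <- length(positions)
  counts <- array(0L, dim = c(2 * p, N, L),
                  dimnames = list(paste0("h", seq_len(2 * p)), NULL, NULL))
  for (i in seq_len(N)) {
    om <- gamete_origins_at(population$offspring[[i]]$maternal, positions)
    op <- gamete_origins_at(population$offspring[[i]]$paternal, positions) + p
    for (k in seq_len(p / 2)) {
      mk <- cbind(om[, k], i, seq_len(L))
      pk <- cbind(op[, k], i, seq_len(L))
      counts[mk] <- counts[mk] + 1L
      counts[pk] <- counts[pk] + 1L
    }
  }
  counts
}

#' Per-locus double-reduction rate
#'
#' Fraction of gametes (2N per population) carrying a duplicated homolog
#' origin at each position. Zero everywhere when `q = 0`; zero at the
#' centromere and increasing distally when multivalents form.
#'
#' @inheritParams true_ibd
#' @return numeric vector of rates in `[0, 1]`, one per position.
#' @export
dr_rate <- function(population, positions) {
  map <- population$map
  if (any(positions < 0 | positions > map$length_cM))
    stop("positions must lie within [0, map length]")
  dup <- matrix(0L, length(positions), 2 * population$N)
  j <- 0L
  for (ind in population$offspring) for (g in list(ind$maternal, ind$paternal)) {
    j <- j + 1L
    o <- gamete_origins_at(g, positions)
    dup[, j] <- as.integer(apply(o, 1, anyDuplicated) > 0L)
  }
  rowMeans(dup)
}

#' Observed SNP dosages of a simulated population
#'
#' The true dosage of an individual at a marker is the sum of the
#' parental marker alleles over its inherited chromatid origins. With
#' probability `eps` the observed dosage is replaced by a uniform draw
#' from the other `ploidy` dosage classes; with probability
#' `missing_rate` the entry is set to `NA`.
#'
#' @param population a [simulate_population()] result.
#' @param eps genotyping error rate in `[0, 1)`.
#' @param missing_rate missing-data rate in `[0, 1)`.
#' @param seed integer seed for the error/missingness draws.
#' @return integer matrix `markers x individuals` (class `DosageMatrix`)
#'   with attributes `eps` and `missing_rate`.
#' @export
genotype_population <- function(population, eps = 0, missing_rate = 0,
                                seed = NULL) {
  if (eps < 0 || eps >= 1 || missing_rate < 0 || missing_rate >= 1)
    stop("eps and missing_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  map <- population$map
  p <- map$ploidy
  counts <- true_ibd(population, map$marker$position)  # 2p x N x M
  M <- n_markers(map); N <- population$N
  D <- matrix(0L, M, N, dimnames = list(map$marker$name, NULL))
  for (h in seq_len(2 * p)) {
    ah <- map$alleles[h, ]                     # length M
    ch <- matrix(counts[h, , ], N, M)          # robust to N = 1 or M = 1
    D <- D + t(ch) * ah
  }
  storage.mode(D) <- "integer"
  if (eps > 0) {
    err <- matrix(stats::runif(M * N) < eps, M, N)
    if (any(err)) {
      shift <- matrix(sample.int(p, sum(err), replace = TRUE), ncol = 1)
      D[err] <- (D[err] + shift) %% (p + 1L)   # uniform over the other classes
    }
  }
  if (missing_rate > 0)
    D[matrix(stats::runif(M * N) < missing_rate, M, N)] <- NA_integer_
  structure(D, eps = eps, missing_rate = missing_rate,
            class = c("DosageMatrix", class(D)))
}

#' Write / read simulation truth and dosage TSV files
#'
#' Truth: one row per inherited chromatid segment
#' (`individual parent chromatid start_cM end_cM homolog`). Dosages:
#' `marker` rows x individual columns, missing as `NA`.
#'
#' @param population a `Population`.
#' @param path file path.
#' @rdname sim_io
#' @export
write_truth_segments <- function(population, path) {
  rows <- list()
  for (i in seq_along(population$offspring)) {
    ind <- population$offspring[[i]]
    for (par in c("maternal", "paternal")) {
      g <- ind[[par]]
      for (k in seq_along(g)) {
        seg <- g[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          individual = i, parent = par, chromatid = k,
          start_cM = seg$start, end_cM = seg$end, homolog = seg$homolog)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param dosages a `DosageMatrix`.
#' @rdname sim_io
#' @export
write_dosage_matrix <- function(dosages, path) {
  df <- data.frame(marker = rownames(dosages), dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_dosage_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$marker
  storage.mode(m) <- "integer"
  m
}
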