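#' Simulate phenotypes for a QTL in a simulated population
#'
#' The QTL genotype of individual `i` is its true Q-allele copy count
#' `d_i` at the QTL position, read from the meiosis truth record (for a
#' dominant QTL, `d_i` is recoded 0/1). Phenotypes are drawn as
#' `P_i ~ N(mu + Q * d_i, sigma_e^2)` with `mu = 10`, `Q = 1`; the
#' environmental variance is `sigma_e^2 = ((1 - h2)/h2) * sigma_g^2`
#' where `sigma_g^2` is the genotypic variance of `Q * d` realized in
#' the population, so the realized broad-sense heritability is `h2`.
#'
#' @param population a [simulate_population()] result.
#' @param qtl_position QTL position in cM (within the map).
#' @param qtl_homologs homolog indices (1..2*ploidy) carrying the
#'   positive allele; ignored when `effects` is given.
#' @param action `"additive"` or `"dominant"` (simplex dominant: one
#'   copy gives full expression).
#' @param h2 broad-sense heritability in (0, 1).
#' @param seed optional integer seed.
#' @param mu,Q phenotype mean and allele substitution effect.
#' @param effects optional multi-allelic per-homolog effect vector
#'   (length `2*ploidy`); the genotypic value is then the sum of effects
#'   over inherited homolog copies.
#' @return a `TraitSet`: `y`, `d` (QTL dosages), truth metadata.
#' @export
simulate_phenotypes <- function(population, qtl_position, qtl_homologs,
                                action = c("additive", "dominant"),
                                h2, seed = NULL, mu = 10, Q = 1,
                                effects = NULL) {
  action <- match.arg(action)
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  counts <- true_ibd(population, qtl_position)[, , 1]    # 2p x N
  if (is.null(effects)) {
    d <- colSums(counts[qtl_homologs, , drop = FALSE])
    if (action == "dominant") d <- as.numeric(d >= 1)
    g <- Q * d
  } else {
    if (length(effects) != nrow(counts))
      stop("effects must have one entry per parental homolog")
    d <- as.vector(crossprod(counts, effects))
    g <- d
  }
  sigma_g2 <- stats::var(g)
  if (sigma_g2 == 0)
    stop(structure(class = c("ibdqtl_nonsegregating", "error", "condition"),
                   list(message = "QTL does not segregate in this population",
                        call = sys.call())))
  sigma_e2 <- (1 - h2) / h2 * sigma_g2
  y <- stats::rnorm(population$N, mu + g, sqrt(sigma_e2))
  structure(list(y = y, d = d, qtl_position = qtl_position,
                 qtl_homologs = if (is.null(effects)) qtl_homologs else
                   which(effects != 0),
                 action = action, h2 = h2, mu = mu, Q = Q,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
            class = "TraitSet")
}

#' Study configuration for the power/precision engine
#'
#' Factor levels mirror the simulation designs of autopolyploid QTL
#' power studies: multivalent rates `q`, population sizes `N`,
#' heritabilities `h2`, QTL segregation types (`SxN` simplex x
#' nulliplex, `DxN` duplex x nulliplex, `SxS` simplex x simplex), gene
#' actions, QTL positions (`"random"` within the scanned span, or fixed
#' cM values cycled over phenotype sets), and IBD models. Replication
#' defaults are desk-scale (10 populations x 20 phenotype sets x 200
#' permutations); raise them for paper-scale runs.
#'
#' @param map a [phased_map()].
#' @param q,N,h2,seg,action,qtl_position,models factor levels (vectors).
#' @param n_pops populations per (q, N) combination.
#' @param n_pheno phenotype sets per population and cell.
#' @param n_perm permutations per phenotype set.
#' @param alpha significance level for the permutation threshold.
#' @param eps,missing_rate genotyping error and missingness.
#' @param grid_step scan grid spacing (cM).
#' @param seed master seed; the whole study is deterministic given it.
#' @return a `StudyConfig` list.
#' @export
study_config <- function(map, q = 0, N = 200, h2 = 0.1, seg = "SxN",
                         action = "additive", qtl_position = "random",
                         models = "noDR", n_pops = 10, n_pheno = 20,
                         n_perm = 200, alpha = 0.05, eps = 0.001,
                         missing_rate = 0, grid_step = 1, seed = 1) {
  stopifnot(inherits(map, "PhasedMap"),
            all(seg %in% c("SxN", "DxN", "SxS")),
            all(action %in% c("additive", "dominant")),
            all(models %in% c("noDR", "DR")),
            n_pops >= 1, n_pheno >= 1, n_perm >= 100)
  structure(list(map = map, q = q, N = N, h2 = h2, seg = seg,
                 action = action, qtl_position = qtl_position,
                 models = models, n_pops = n_pops, n_pheno = n_pheno,
                 n_perm = n_perm, alpha = alpha, eps = eps,
                 missing_rate = missing_rate, grid_step = grid_step,
                 seed = seed),
            class = "StudyConfig")
}

## draw a QTL configuration for a segregation type (positive-effect
## homolog indices)
draw_qtl_homologs <- function(seg, ploidy) {
  par_off <- function() if (stats::runif(1) < 0.5) 0L else ploidy
  switch(seg,
         SxN = par_off() + sample.int(ploidy, 1),
         DxN = par_off() + sample.int(ploidy, 2),
         SxS = c(sample.int(ploidy, 1), ploidy + sample.int(ploidy, 1)),
         stop("unknown segregation type ", seg))
}

#' Run a factorial power/precision study
#'
#' For every cell of the factor grid: simulate populations, genotype
#' them, estimate IBD probabilities under the requested model(s),
#' interpolate to the cM grid, then for each phenotype set draw a QTL
#' configuration and position, simulate phenotypes, scan, set a
#' permutation threshold and record detection (interpolated LOD at the
#' true QTL position vs. threshold — the conservative definition — and
#' the significant-peak alternative), peak-to-truth distance, LOD-1 and
#' LOD-2 support interval membership and widths, and the GIC underlying
#' the QTL alleles (noDR model). Populations and phenotype sets are
#' shared across cells and models where the factors allow, so
#' noDR-vs-DR comparisons are paired. Per-cell failures (e.g. a QTL
#' that does not segregate in the realized population) are recorded and
#' the run continues.
#'
#' @param config a [study_config()].
#' @param verbose print progress?
#' @return a `PowerResult`: `replicates` (one row per phenotype set x
#'   model) and `cells` (aggregated power/precision per cell x model).
#' @export
run_study <- function(config, verbose = FALSE) {
  cfg <- config
  map <- cfg$map
  ploidy <- map$ploidy
  cells <- expand.grid(q = cfg$q, N = cfg$N, h2 = cfg$h2, seg = cfg$seg,
                       action = cfg$action, stringsAsFactors = FALSE)
  groups <- unique(cells[, c("q", "N")])
  designs <- lapply(stats::setNames(cfg$models, cfg$models),
                    function(m) build_design(ploidy, m))
  ## all sub-seeds drawn up-front in a fixed order => full replay
  ## determinism regardless of evaluation order
  set.seed(cfg$seed)
  pop_seeds <- array(sample.int(2147483646L, nrow(groups) * cfg$n_pops * 2),
                     dim = c(nrow(groups), cfg$n_pops, 2))
  pheno_seeds <- array(
    sample.int(2147483646L, nrow(cells) * cfg$n_pops * cfg$n_pheno),
    dim = c(nrow(cells), cfg$n_pops, cfg$n_pheno))
  rows <- vector("list", 0L)
  for (gi in seq_len(nrow(groups))) {
    q <- groups$q[gi]; N <- groups$N[gi]
    if (verbose) message("populations for q = ", q, ", N = ", N)
    pops <- vector("list", cfg$n_pops)
    for (r in seq_len(cfg$n_pops)) {
      pop <- simulate_population(map, N, q, seed = pop_seeds[gi, r, 1])
      dos <- genotype_population(pop, cfg$eps, cfg$missing_rate,
                                 seed = pop_seeds[gi, r, 2])
      ent <- list(pop = pop, ops = list(), gic = NULL)
      for (mod in cfg$models) {
        post <- ibd_posterior(dos, map, mod, q = q, eps = cfg$eps)
        grd <- spline_to_grid(post, cfg$grid_step)
        ent$ops[[mod]] <- scan_operators(grd, designs[[mod]])
        if (mod == "noDR")
          ent$gic <- gic_per_homolog(haplotype_probs(grd))
      }
      pops[[r]] <- ent
    }
    grid_pos <- pops[[1]]$ops[[1]]$positions
    span <- range(grid_pos)
    for (ci in which(cells$q == q & cells$N == N)) {
      cell <- cells[ci, ]
      if (verbose) message("  cell ", paste(unlist(cell), collapse = " "))
      for (r in seq_len(cfg$n_pops)) for (j in seq_len(cfg$n_pheno)) {
        set.seed(pheno_seeds[ci, r, j])
        homs <- draw_qtl_homologs(cell$seg, ploidy)
        qtl_pos <- if (identical(cfg$qtl_position, "random")) {
          min(max(round(stats::runif(1, span[1], span[2]), 2), span[1]),
              span[2])
        } else {
          cfg$qtl_position[(j - 1) %% length(cfg$qtl_position) + 1]
        }
        ts <- tryCatch(
          simulate_phenotypes(pops[[r]]$pop, qtl_pos, homs, cell$action,
                              cell$h2),
          ibdqtl_nonsegregating = function(e) NULL)
        base <- data.frame(q = q, N = N, h2 = cell$h2, seg = cell$seg,
                           action = cell$action, pop = r, pheno = j,
                           qtl_pos = qtl_pos,
                           homologs = paste(homs, collapse = ","),
                           n_alleles = length(homs),
                           stringsAsFactors = FALSE)
        if (is.null(ts)) {
          for (mod in cfg$models)
            rows[[length(rows) + 1L]] <- cbind(
              base, model = mod, skipped = TRUE, gic1 = NA, gic2 = NA,
              threshold = NA, peak_lod = NA, lod_at_qtl = NA,
              detected = NA, sig_peak = NA, peak_pos = NA, dist = NA,
              lod1_lo = NA, lod1_hi = NA, lod1_contains = NA,
              lod1_width = NA, lod2_lo = NA, lod2_hi = NA,
              lod2_contains = NA, lod2_width = NA)
          next
        }
        Y <- cbind(ts$y, vapply(seq_len(cfg$n_perm),
                                function(i) sample(ts$y),
                                numeric(N)))
        g1 <- g2 <- NA_real_
        if (!is.null(pops[[r]]$gic)) {
          gi_idx <- which.min(abs(pops[[r]]$gic$positions - qtl_pos))
          gv <- pops[[r]]$gic$values[homs, gi_idx]
          g1 <- gv[1]; g2 <- if (length(gv) > 1) gv[2] else NA_real_
        }
        for (mod in cfg$models) {
          lodmat <- lod_profile_matrix(pops[[r]]$ops[[mod]], Y)
          lod <- lodmat[, 1]
          maxima <- apply(lodmat[, -1, drop = FALSE], 2, max)
          thr <- stats::quantile(maxima, 1 - cfg$alpha, names = FALSE)
          sc <- list(positions = grid_pos, lod = lod)
          lod_at <- stats::approx(grid_pos, lod, xout = qtl_pos)$y
          pk <- which.max(lod)
          i1 <- support_interval(sc, 1); i2 <- support_interval(sc, 2)
          rows[[length(rows) + 1L]] <- cbind(
            base, model = mod, skipped = FALSE, gic1 = g1, gic2 = g2,
            threshold = thr, peak_lod = max(lod), lod_at_qtl = lod_at,
            detected = lod_at >= thr, sig_peak = max(lod) >= thr,
            peak_pos = grid_pos[pk], dist = abs(grid_pos[pk] - qtl_pos),
            lod1_lo = i1[1], lod1_hi = i1[2],
            lod1_contains = qtl_pos >= i1[1] & qtl_pos <= i1[2],
            lod1_width = i1[2] - i1[1],
            lod2_lo = i2[1], lod2_hi = i2[2],
            lod2_contains = qtl_pos >= i2[1] & qtl_pos <= i2[2],
            lod2_width = i2[2] - i2[1])
        }
      }
    }
  }
  reps <- do.call(rbind, rows)
  structure(list(replicates = reps, cells = aggregate_cells(reps),
                 config = cfg),
            class = "PowerResult")
}

aggregate_cells <- function(reps) {
  key <- interaction(reps$q, reps$N, reps$h2, reps$seg, reps$action,
                     reps$model, drop = TRUE)
  agg <- lapply(split(reps, key), function(d) {
    det <- d$detected & !d$skipped
    data.frame(
      q = d$q[1], N = d$N[1], h2 = d$h2[1], seg = d$seg[1],
      action = d$action[1], model = d$model[1],
      n_reps = nrow(d), n_skipped = sum(d$skipped),
      power = mean(d$detected[!d$skipped]),
      power_peak = mean(d$sig_peak[!d$skipped]),
      mean_dist_detected = if (any(det, na.rm = TRUE))
        mean(d$dist[which(det)]) else NA_real_,
      lod1_cover = if (any(det, na.rm = TRUE))
        mean(d$lod1_contains[which(det)]) else NA_real_,
      lod2_cover = if (any(det, na.rm = TRUE))
        mean(d$lod2_contains[which(det)]) else NA_real_,
      lod1_width = mean(d$lod1_width[!d$skipped]),
      lod2_width = mean(d$lod2_width[!d$skipped]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' @export
print.PowerResult <- function(x, ...) {
  cat("PowerResult:", nrow(x$replicates), "replicate rows,",
      nrow(x$cells), "cells\n")
  print(x$cells)
  invisible(x)
}

#' Detection power by GIC category
#'
#' For two-allele QTL (DxN, SxS), classifies each replicate by the GIC
#' underlying its two positive alleles at each High-GIC threshold and
#' tabulates detection power per category, pooling `LH` with `HL`.
#' Empty categories are reported as `NA`, not zero.
#'
#' @param result a [run_study()] result.
#' @param thresholds High-GIC thresholds (default `c(0.9, 0.95)`).
#' @return data frame `threshold, category, power, n`.
#' @export
gic_power_table <- function(result, thresholds = c(0.9, 0.95)) {
  d <- result$replicates
  d <- d[!d$skipped & d$n_alleles == 2 & !is.na(d$gic1), , drop = FALSE]
  if (nrow(d) == 0L) stop("no two-allele QTL replicates with GIC values")
  out <- list()
  for (t in thresholds) {
    lh <- paste0(ifelse(d$gic1 >= t, "H", "L"),
                 ifelse(d$gic2 >= t, "H", "L"))
    cat3 <- ifelse(lh %in% c("LH", "HL"), "LH/HL", lh)
    for (cc in c("LL", "LH/HL", "HH")) {
      sel <- cat3 == cc
      out[[length(out) + 1L]] <- data.frame(
        threshold = t, category = cc,
        power = if (any(sel)) mean(d$detected[sel]) else NA_real_,
        n = sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Read a study configuration from JSON
#'
#' Scalar/vector fields match [study_config()] arguments; the map is
#' given either as `map_tsv` (+ `length_cM`, `ploidy`, `centromere_cM`)
#' or as `map_fixture` (`"even"` / `"uneven"`) with `map_seed`.
#'
#' @param path JSON file.
#' @return a `StudyConfig`.
#' @export
read_study_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- if (!is.null(j$map_tsv)) {
    read_phased_map(j$map_tsv, length_cM = j$length_cM, ploidy = j$ploidy,
                    centromere_cM = j$centromere_cM)
  } else if (identical(j$map_fixture, "uneven")) {
    map_uneven_coverage(seed = if (is.null(j$map_seed)) 1 else j$map_seed)
  } else {
    map_even_coverage(seed = if (is.null(j$map_seed)) 1 else j$map_seed)
  }
  args <- j[intersect(names(j), setdiff(names(formals(study_config)), "map"))]
  do.call(study_config, c(list(map = map), args))
}
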