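#' Homolog main-effects design for the IBD-weighted QTL scan
#'
#' One row per ancestry state; columns are the indicator (noDR, values
#' 0/1) or copy-count (DR, values 0/1/2) variables of the parental
#' homolog main effects. Because each offspring inherits exactly
#' `ploidy/2` homolog copies from each parent, the indicators within a
#' parent sum to `ploidy/2`; the first homolog of each parent (X1 and
#' X_{ploidy+1}) is dropped to remove this collinearity, leaving e.g.
#' `alpha2..alpha4, alpha6..alpha8` in a tetraploid. The intercept is
#' added at fit time.
#'
#' @param ploidy 4 or 6.
#' @param model `"noDR"` or `"DR"`.
#' @return a `ScanModel`: `X` is the `n_states x (2*ploidy - 2)` design,
#'   `states` the matching state enumeration.
#' @export
build_design <- function(ploidy, model = c("noDR", "DR")) {
  model <- match.arg(model)
  if (!ploidy %in% c(4, 6))
    stop("scan models are implemented for ploidy 4 and 6")
  st <- enumerate_ibd_states(ploidy, allow_dr = model == "DR")
  drop_h <- c(1L, ploidy + 1L)
  X <- t(st$counts[-drop_h, , drop = FALSE])
  storage.mode(X) <- "double"
  colnames(X) <- paste0("alpha", setdiff(seq_len(2 * ploidy), drop_h))
  ## constraint check: per-parent indicator sums (incl. dropped terms)
  stopifnot(all(colSums(st$counts[seq_len(ploidy), ]) == ploidy / 2),
            all(colSums(st$counts[ploidy + seq_len(ploidy), ]) == ploidy / 2))
  structure(list(ploidy = as.integer(ploidy), model = model, states = st,
                 X = X, dropped = drop_h),
            class = "ScanModel")
}

## Moore-Penrose pseudo-inverse (rank-deficient weighted designs)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Precompute, per grid locus, the weighted normal-equation operators:
## A = Xf' diag(state totals) Xf (pseudo-inverted) and B = Xf' W, where W
## is the states x N posterior at the locus and Xf the design with
## intercept. For any phenotype vector (or matrix of permuted
## phenotypes) Y the fit is beta = pinv(A) B Y and the weighted RSS is
## colSums(Y^2) - colSums(beta * (B Y)), because each individual's
## weights sum to 1.
scan_operators <- function(gridded_ibd, scan_model) {
  stopifnot(inherits(gridded_ibd, "IBDProbabilities"))
  if (!identical(gridded_ibd$model, scan_model$model))
    stop("IBD probabilities (", gridded_ibd$model,
         ") and scan model (", scan_model$model, ") disagree")
  prob <- gridded_ibd$prob
  n <- dim(prob)[1]; N <- dim(prob)[2]; L <- dim(prob)[3]
  Xf <- cbind(`(Intercept)` = 1, scan_model$X)
  Ainv <- vector("list", L); B <- vector("list", L)
  for (l in seq_len(L)) {
    W <- matrix(prob[, , l], n, N)
    Ws <- rowSums(W)
    A <- crossprod(Xf, Xf * Ws)
    Ainv[[l]] <- pinv(A)
    B[[l]] <- crossprod(Xf, W)
  }
  list(Ainv = Ainv, B = B, N = N, positions = gridded_ibd$positions,
       k = ncol(Xf))
}

## LOD profiles for a matrix of phenotype columns (original + permuted)
lod_profile_matrix <- function(ops, Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != ops$N) stop("phenotype length must match population size")
  N <- ops$N
  cs2 <- colSums(Y^2)
  rss0 <- cs2 - N * colMeans(Y)^2
  L <- length(ops$positions)
  lod <- matrix(0, L, ncol(Y))
  ok <- rss0 > 0
  if (!any(ok)) return(lod)
  for (l in seq_len(L)) {
    By <- ops$B[[l]] %*% Y
    beta <- ops$Ainv[[l]] %*% By
    rss1 <- cs2 - colSums(beta * By)
    rss1 <- pmin(pmax(rss1, 1e-300), rss0 + abs(rss0) * 1e-12)
    lod[l, ok] <- pmax(0, (N / 2) * log10(rss0[ok] / rss1[ok]))
  }
  lod
}

#' IBD-weighted regression LOD score at one locus
#'
#' Fits the homolog main-effects model by weighted least squares, each
#' individual expanded into one pseudo-observation per ancestry state
#' with weight equal to its posterior IBD probability, and returns
#' `LOD = (N/2) log10(RSS0/RSS1)` where `RSS0 = sum (y - ybar)^2` is the
#' no-QTL residual sum of squares. Rank-deficient designs are resolved
#' by pseudo-inverse (the LOD is invariant to the choice of minimum-norm
#' solution); zero phenotypic variance gives LOD 0 with a warning.
#'
#' @param y numeric phenotype vector (length N).
#' @param state_probs_at_locus `n_states x N` posterior matrix (columns
#'   sum to 1).
#' @param scan_model a [build_design()] result.
#' @return LOD score (>= 0).
#' @export
weighted_lod <- function(y, state_probs_at_locus, scan_model) {
  W <- as.matrix(state_probs_at_locus)
  N <- ncol(W)
  if (length(y) != N) stop("length(y) must equal the number of individuals")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::var(y) == 0) {
    warning("zero phenotypic variance; LOD defined as 0", call. = FALSE)
    return(0)
  }
  Xf <- cbind(1, scan_model$X)
  Ws <- rowSums(W)
  A <- crossprod(Xf, Xf * Ws)
  b <- drop(crossprod(Xf, W %*% y))
  beta <- drop(pinv(A) %*% b)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(y^2) - sum(beta * b)
  rss1 <- min(max(rss1, 1e-300), rss0)
  max(0, (N / 2) * log10(rss0 / rss1))
}

#' Chromosome-wide QTL scan
#'
#' Computes the [weighted_lod()] profile along the interpolated 1 cM
#' grid. The peak is the leftmost position attaining the maximum LOD
#' (ties are flagged in `ties`).
#'
#' @param y phenotype vector.
#' @param gridded_ibd gridded IBD probabilities ([spline_to_grid()]).
#' @param scan_model a [build_design()] matching the IBD model.
#' @return a `QTLScanResult` with `positions`, `lod`, `peak_position`,
#'   `peak_lod`, `N` and `RSS0`.
#' @export
qtl_scan <- function(y, gridded_ibd, scan_model) {
  ops <- scan_operators(gridded_ibd, scan_model)
  if (length(ops$positions) < 1L) stop("empty scan grid")
  lod <- drop(lod_profile_matrix(ops, matrix(y, ncol = 1)))
  peaks <- which(lod >= max(lod) - 1e-9)
  structure(list(positions = ops$positions, lod = lod,
                 peak_position = ops$positions[peaks[1]],
                 peak_lod = max(lod), ties = length(peaks) > 1L,
                 N = ops$N, RSS0 = sum((y - mean(y))^2),
                 model = scan_model$model, threshold = NULL),
            class = "QTLScanResult")
}

#' @export
print.QTLScanResult <- function(x, ...) {
  cat(sprintf("QTLScanResult (%s): peak LOD %.2f at %.1f cM over %d positions (N = %d)\n",
              x$model, x$peak_lod, x$peak_position, length(x$positions), x$N))
  if (!is.null(x$threshold))
    cat(sprintf("permutation threshold: %.2f\n", x$threshold))
  invisible(x)
}

#' Experiment-wise LOD threshold by permutation
#'
#' Permutes the phenotype vector `n_perm` times, records the
#' chromosome-wide maximum LOD of each permutation and returns the
#' empirical `1 - alpha` quantile of the sorted maxima.
#'
#' @inheritParams qtl_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha experiment-wise significance level (default 0.05, i.e.
#'   the 0.95 quantile).
#' @param seed integer seed; the threshold is deterministic given it.
#' @return LOD threshold (numeric scalar) with attribute `maxima`.
#' @export
permutation_threshold <- function(y, gridded_ibd, scan_model,
                                  n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ops <- scan_operators(gridded_ibd, scan_model)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  lod <- lod_profile_matrix(ops, Y)
  maxima <- apply(lod, 2, max)
  structure(stats::quantile(maxima, 1 - alpha, names = FALSE),
            maxima = maxima)
}

#' LOD support interval
#'
#' The full range of grid positions whose LOD score differs from the
#' profile maximum by strictly less than `drop` (1 or 2) — including
#' positions between disjoint qualifying peaks, per the "full range"
#' convention.
#'
#' @param scan a `QTLScanResult` (or list with `positions` and `lod`).
#' @param drop LOD drop, usually 1 or 2.
#' @return numeric `c(lo, hi)` in cM.
#' @export
support_interval <- function(scan, drop = 1) {
  lod <- scan$lod
  if (length(lod) < 1L) stop("empty LOD profile")
  sel <- which(lod > max(lod) - drop)   # difference strictly less than drop
  range(scan$positions[sel])
}

#' Interpolate a LOD profile at an off-grid position
#'
#' Linear interpolation between the flanking grid LOD values; positions
#' outside the grid span are rejected.
#'
#' @inheritParams support_interval
#' @param position cM position within the grid span.
#' @return interpolated LOD.
#' @export
interpolate_lod <- function(scan, position) {
  pos <- scan$positions
  if (any(position < min(pos) | position > max(pos)))
    stop("position outside the scanned grid span")
  stats::approx(pos, scan$lod, xout = position)$y
}

#' Single-marker ANOVA scan
#'
#' Regresses the phenotype on the raw dosage score of each marker
#' (`Y = mu + a D + e`), dropping missing dosages per marker, and reports
#' the LOD via the same `(n/2) log10(RSS0/RSS1)` formula with the
#' per-marker sample size. Monomorphic markers get LOD 0; markers with
#' no non-missing data are excluded with a warning.
#'
#' @param y phenotype vector.
#' @param dosages `markers x individuals` dosage matrix (`NA` missing).
#' @return data frame `marker`, `n`, `lod`.
#' @export
single_marker_scan <- function(y, dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1L) stop("need at least one marker")
  if (ncol(dosages) != length(y))
    stop("dosage columns must match phenotype length")
  res <- lapply(seq_len(nrow(dosages)), function(m) {
    d <- dosages[m, ]
    keep <- !is.na(d)
    n <- sum(keep)
    if (n == 0L) return(NULL)
    dd <- d[keep]; yy <- y[keep]
    rss0 <- sum((yy - mean(yy))^2)
    if (stats::var(dd) == 0 || rss0 == 0)
      return(data.frame(marker = m, n = n, lod = 0))
    fit <- stats::lm.fit(cbind(1, dd), yy)
    rss1 <- sum(fit$residuals^2)
    rss1 <- min(max(rss1, 1e-300), rss0)
    data.frame(marker = m, n = n, lod = max(0, (n / 2) * log10(rss0 / rss1)))
  })
  dropped <- vapply(res, is.null, TRUE)
  if (any(dropped))
    warning(sum(dropped), " marker(s) with all-missing dosages excluded",
            call. = FALSE)
  out <- do.call(rbind, res[!dropped])
  if (!is.null(rownames(dosages))) out$name <- rownames(dosages)[out$marker]
  out
}

#' Average allele effects per homolog
#'
#' For each parental homolog and position, the IBD-weighted mean
#' phenotype of its carriers minus the overall mean:
#' `hbar - ybar` with `hbar = sum(pi_i y_i) / sum(pi_i)`. Homologs with
#' zero total weight get `NA`.
#'
#' @param y phenotype vector.
#' @param haplotype_probs a noDR [haplotype_probs()] object.
#' @param positions cM positions (must be in the object's grid; nearest
#'   point used otherwise).
#' @return matrix `2*ploidy x length(positions)` of effects.
#' @export
allele_effects <- function(y, haplotype_probs, positions) {
  if (!identical(haplotype_probs$model, "noDR"))
    stop("allele effects use noDR haplotypic probabilities")
  idx <- vapply(positions, function(p)
    which.min(abs(haplotype_probs$positions - p)), 0L)
  ybar <- mean(y)
  out <- vapply(idx, function(l) {
    P <- haplotype_probs$pi[, , l]      # 2p x N
    tw <- rowSums(P)
    eff <- as.vector(P %*% y) / tw - ybar
    eff[tw <= 0] <- NA_real_
    eff
  }, numeric(dim(haplotype_probs$pi)[1]))
  rownames(out) <- dimnames(haplotype_probs$pi)[[1]]
  colnames(out) <- haplotype_probs$positions[idx]
  out
}
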