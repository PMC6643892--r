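#' Bi-allelic QTL configurations
#'
#' A configuration assigns each of the `2*ploidy` parental homologs a
#' QTL allele label: `o` (no effect) or `Q` (effect), displayed as e.g.
#' `"oooo x oooQ"` (maternal x paternal). Gene action is either
#' `additive` (phenotype proportional to the number of inherited Q
#' copies) or simplex `dominant` (a single Q copy gives full
#' expression).
#'
#' @param labels character vector of `"o"`/`"Q"` of length `2*ploidy`.
#' @param action `"additive"` or `"dominant"`.
#' @return a `QTLConfiguration`.
#' @export
qtl_config <- function(labels, action = c("additive", "dominant")) {
  action <- match.arg(action)
  if (!all(labels %in% c("o", "Q")) || length(labels) %% 2 != 0)
    stop("labels must be an even-length vector of \"o\"/\"Q\"")
  p <- length(labels) / 2
  structure(list(labels = labels, action = action, ploidy = p,
                 display = paste0(paste(labels[seq_len(p)], collapse = ""),
                                  " x ",
                                  paste(labels[p + seq_len(p)], collapse = ""))),
            class = "QTLConfiguration")
}

#' @export
print.QTLConfiguration <- function(x, ...) {
  cat(sprintf("QTLConfiguration: %s (%s)\n", x$display, x$action))
  invisible(x)
}

#' Predicted genotypic value of an ancestry state under a configuration
#'
#' Additive: the number of Q-labelled homolog copies in the state
#' (counted with multiplicity under double reduction, so values up to 2
#' per homolog). Dominant: 1 if at least one Q copy is present, else 0.
#'
#' @param state integer vector of inherited homolog indices (length
#'   `ploidy`) or a `2*ploidy` copy-count vector.
#' @param configuration a [qtl_config()].
#' @return predicted value (numeric scalar).
#' @export
class_predictor <- function(state, configuration) {
  p2 <- 2 * configuration$ploidy
  counts <- if (length(state) == configuration$ploidy)
    tabulate(state, nbins = p2) else state
  q <- sum(counts[configuration$labels == "Q"])
  if (configuration$action == "dominant") as.numeric(q >= 1) else q
}

## predictor vector over all states of an enumeration (vectorized)
predictor_vector <- function(states, configuration) {
  v <- as.vector(crossprod(states$counts,
                           as.numeric(configuration$labels == "Q")))
  if (configuration$action == "dominant") as.numeric(v >= 1) else v
}

## affine-invariant canonical key of a predictor vector: two models with
## predictors related by v' = a + b*v (b != 0) have identical fits and
## BIC, so they are one model
predictor_key <- function(v) {
  v <- v - min(v)
  m <- max(v)
  if (m > 0) v <- v / m
  w <- 1 - v                                  # sign flip (Q <-> o)
  kv <- paste(round(v, 10), collapse = ",")
  kw <- paste(round(w, 10), collapse = ",")
  if (kw < kv) kw else kv
}

#' Catalogue of bi-allelic QTL models
#'
#' Enumerates every segregating assignment of `Q`/`o` to the `2*ploidy`
#' homologs for the requested gene actions, de-duplicated so that no two
#' entries induce the same fit over the noDR state space: predictor
#' vectors related by an affine map (which includes the `Q <-> o`
#' complement of an additive configuration, and a single-Q dominant
#' coinciding with its additive counterpart) are collapsed to one
#' representative, the first in a canonical order (fewest Q alleles,
#' additive before dominant). At ploidy 4 this yields 112 additive +
#' 112 dominant = 224 distinct bi-allelic models; counts are recorded in
#' the `meta` field.
#'
#' @param ploidy 4 or 6.
#' @param actions subset of `c("additive", "dominant")`.
#' @return a `ModelCatalogue`: `configs` (list of [qtl_config()]),
#'   `predictors` (`n_states x n_models` over the noDR states), `meta`.
#' @export
model_catalogue <- function(ploidy = 4, actions = c("additive", "dominant")) {
  if (!ploidy %in% c(4, 6)) stop("ploidy must be 4 or 6")
  actions <- match.arg(actions, several.ok = TRUE)
  st <- enumerate_ibd_states(ploidy, allow_dr = FALSE)
  p2 <- 2 * ploidy
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), p2)))
  ## canonical enumeration order: by number of Q alleles, then binary code
  grid <- grid[order(rowSums(grid),
                     apply(grid, 1, function(z)
                       sum(z * 2^(seq_len(p2) - 1)))), , drop = FALSE]
  configs <- list(); preds <- list()
  n_by_action <- c(additive = 0L, dominant = 0L)
  seen <- character(0)
  for (act in actions) {
    for (i in seq_len(nrow(grid))) {
      labels <- ifelse(grid[i, ] == 1, "Q", "o")
      cfg <- qtl_config(labels, act)
      v <- predictor_vector(st, cfg)
      if (length(unique(v)) < 2L) next          # non-segregating predictor
      key <- predictor_key(v)
      if (key %in% seen) next
      seen <- c(seen, key)
      configs[[length(configs) + 1L]] <- cfg
      preds[[length(preds) + 1L]] <- v
      n_by_action[act] <- n_by_action[act] + 1L
    }
  }
  structure(list(ploidy = as.integer(ploidy),
                 configs = configs,
                 predictors = do.call(cbind, preds),
                 meta = list(n_models = length(configs),
                             n_by_action = n_by_action,
                             dedup = paste("affine-equivalent predictor",
                                           "vectors over the noDR states",
                                           "collapsed; additive",
                                           "representative preferred"))),
            class = "ModelCatalogue")
}

#' @export
print.ModelCatalogue <- function(x, ...) {
  cat(sprintf("ModelCatalogue: ploidy %d, %d models (%s)\n", x$ploidy,
              x$meta$n_models,
              paste(sprintf("%s %d", names(x$meta$n_by_action),
                            x$meta$n_by_action), collapse = ", ")))
  invisible(x)
}

#' IBD-weighted phenotype means per ancestry state
#'
#' `mean_s = sum_i P(s | i) y_i / sum_i P(s | i)` at a locus (typically
#' the QTL peak). States whose total weight falls below `1e-6 * N` are
#' flagged and excluded from subsequent model fits.
#'
#' @param y phenotype vector.
#' @param state_probs_at_peak `n_states x N` posterior matrix.
#' @param states optional [enumerate_ibd_states()] enumeration matching
#'   the rows (used by [select_model()] to compute predictors).
#' @return a `ClassMeans`: `mean`, `weight`, logical `excluded`,
#'   `n_states`.
#' @export
class_means <- function(y, state_probs_at_peak, states = NULL) {
  W <- as.matrix(state_probs_at_peak)
  N <- ncol(W)
  if (length(y) != N) stop("length(y) must match the number of individuals")
  tw <- rowSums(W)
  excluded <- tw < 1e-6 * N
  if (all(excluded)) stop("all ancestry classes have (near-)zero weight")
  mu <- as.vector(W %*% y) / tw
  mu[excluded] <- NA_real_
  structure(list(mean = mu, weight = tw, excluded = excluded,
                 n_states = nrow(W), states = states),
            class = "ClassMeans")
}

#' Bayesian information criterion for a QTL model fit
#'
#' `BIC = n log(RSS/n) + p log(n)` (natural logarithm; only BIC
#' differences matter for model ranking and those are base-invariant up
#' to a positive factor). A perfect fit (`RSS = 0`) returns `-Inf` with
#' attribute `perfect = TRUE`.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of data points (36 or 100 for the noDR / DR class
#'   means).
#' @param p number of model parameters (2 for bi-allelic
#'   additive/dominant).
#' @return BIC value.
#' @export
bic <- function(rss, n, p) {
  if (n <= 0 || p < 0) stop("n must be > 0 and p >= 0")
  if (rss < 0) stop("rss must be >= 0")
  if (rss == 0) return(structure(-Inf, perfect = TRUE))
  n * log(rss / n) + p * log(n)
}

#' Diagnose the QTL configuration by BIC
#'
#' Fits each catalogue model to the ancestry-class phenotype means at
#' the QTL peak by ordinary least squares of the means on the model's
#' predicted genotypic values (p = 2: intercept + effect), and ranks the
#' models by BIC (ascending); the top-ranked model is the inferred QTL
#' configuration and mode of action.
#'
#' @param cm a [class_means()] result (its `states` field, or the
#'   `states` argument, supplies the state space: 36 noDR or 100 DR).
#' @param catalogue a [model_catalogue()].
#' @param n number of data points entering the BIC (defaults to the full
#'   state count, 36 or 100).
#' @param states state enumeration matching `cm` (defaults to
#'   `cm$states`).
#' @return data frame `rank, config, action, p, n, RSS, BIC`, sorted by
#'   BIC.
#' @export
select_model <- function(cm, catalogue, n = NULL, states = NULL) {
  if (is.null(states)) states <- cm$states
  if (is.null(states)) stop("supply the state enumeration (states =)")
  if (length(catalogue$configs) == 0L) stop("empty model catalogue")
  if (is.null(n)) n <- cm$n_states
  keep <- !cm$excluded
  mu <- cm$mean[keep]
  fits <- lapply(catalogue$configs, function(cfg) {
    v <- predictor_vector(states, cfg)[keep]
    rss <- if (stats::var(v) == 0) sum((mu - mean(mu))^2) else
      sum(stats::lm.fit(cbind(1, v), mu)$residuals^2)
    data.frame(config = cfg$display, action = cfg$action, p = 2L, n = n,
               RSS = rss, BIC = as.numeric(bic(rss, n, 2L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  out <- out[order(out$BIC), , drop = FALSE]
  out$rank <- rank(out$BIC, ties.method = "min")
  rownames(out) <- NULL
  out[, c("rank", "config", "action", "p", "n", "RSS", "BIC")]
}
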