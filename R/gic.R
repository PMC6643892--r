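#' Per-homolog genotypic information coefficient (GIC)
#'
#' For homolog `j` at a locus,
#' `GIC_j = 1 - (4/N) * sum_n pi_n (1 - pi_n)` where `pi_n` is the
#' (noDR) probability that individual `n` inherited homolog `j` there.
#' GIC is 1 exactly when every `pi_n` is 0 or 1 (inheritance fully
#' resolved) and 0 exactly when every `pi_n = 0.5` (no information); the
#' definition is independent of ploidy. It is only defined for the noDR
#' model — with double reduction an offspring can inherit more than one
#' copy of a homolog and a homolog-specific GIC is no longer meaningful,
#' so DR input is rejected.
#'
#' @param haplotype_probs a [haplotype_probs()] object with
#'   `model = "noDR"`.
#' @return a `GICTrack`: `values` is a `2*ploidy x n_positions` matrix in
#'   `[0, 1]`.
#' @export
gic_per_homolog <- function(haplotype_probs) {
  if (!inherits(haplotype_probs, "HaplotypeProbs"))
    stop("input must be a HaplotypeProbs object")
  if (!identical(haplotype_probs$model, "noDR"))
    stop("GIC is defined for noDR haplotypic probabilities only")
  pi <- haplotype_probs$pi
  N <- dim(pi)[2]
  v <- pi * (1 - pi)
  values <- 1 - (4 / N) * apply(v, c(1, 3), sum)
  structure(list(values = values, positions = haplotype_probs$positions,
                 N = N, model = "noDR", ploidy = haplotype_probs$ploidy),
            class = "GICTrack")
}

#' @export
print.GICTrack <- function(x, ...) {
  cat(sprintf("GICTrack: %d homologs x %d positions (N = %d), mean GIC %.3f\n",
              nrow(x$values), ncol(x$values), x$N, mean(x$values)))
  invisible(x)
}

#' Classify a QTL by the GIC underlying its positive alleles
#'
#' Each positive-effect QTL allele is classed High if the GIC of its
#' homolog at the QTL position reaches `high_threshold`, else Low.
#' Two-allele QTL (duplex or simplex x simplex) get two-letter codes in
#' homolog order; `LH` and `HL` are reported distinctly but are
#' conventionally pooled when tabulating power.
#'
#' @param gic_track a [gic_per_homolog()] result.
#' @param qtl_homologs homolog indices (1..2*ploidy) carrying
#'   positive-effect alleles.
#' @param qtl_position QTL position in cM; off-grid positions use the
#'   nearest grid point (with a warning).
#' @param high_threshold High/Low cut-off in (0, 1), conventionally 0.9
#'   or 0.95.
#' @return character scalar: `"L"`/`"H"` per allele, concatenated (e.g.
#'   `"LH"`).
#' @export
classify_qtl_gic <- function(gic_track, qtl_homologs, qtl_position,
                             high_threshold = 0.9) {
  if (high_threshold <= 0 || high_threshold >= 1)
    stop("high_threshold must lie in (0, 1)")
  i <- which.min(abs(gic_track$positions - qtl_position))
  if (abs(gic_track$positions[i] - qtl_position) > 1e-8)
    warning("QTL position off the GIC grid; using nearest grid point ",
            gic_track$positions[i], " cM", call. = FALSE)
  g <- gic_track$values[qtl_homologs, i]
  paste(ifelse(g >= high_threshold, "H", "L"), collapse = "")
}
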