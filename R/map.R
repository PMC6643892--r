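#' Phased parental linkage maps
#'
#' A `PhasedMap` holds an ordered set of SNP markers on one chromosome with
#' genetic (cM) positions and the phased 0/1 alleles of every parental
#' homolog. Homologs are numbered 1..ploidy for parent 1 (the mother) and
#' ploidy+1..2*ploidy for parent 2 (the father). The map is the ground
#' truth for meiosis simulation and the known phase input for IBD
#' estimation.
#'
#' @param chrom chromosome identifier (character scalar).
#' @param length_cM chromosome length in centiMorgans.
#' @param positions numeric vector of marker positions (non-decreasing,
#'   within `[0, length_cM]`).
#' @param alleles 0/1 matrix with `2 * ploidy` rows (homologs) and one
#'   column per marker.
#' @param ploidy even integer >= 2.
#' @param names optional marker names; defaults to `M0001`, ...
#' @param centromere_cM centromere position, used by the meiosis
#'   simulator to anchor double reduction; defaults to the midpoint.
#' @return An object of class `PhasedMap`.
#' @export
phased_map <- function(chrom, length_cM, positions, alleles, ploidy,
                       names = NULL, centromere_cM = length_cM / 2) {
  check_ploidy(ploidy)
  positions <- as.numeric(positions)
  if (length(positions) < 1L) stop("a PhasedMap needs at least one marker")
  if (is.unsorted(positions)) stop("marker positions must be non-decreasing")
  if (any(positions < 0 | positions > length_cM))
    stop("marker positions must lie within [0, length_cM]")
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != 2L * ploidy || ncol(alleles) != length(positions))
    stop("alleles must be a (2*ploidy) x n_markers matrix")
  if (!all(alleles %in% c(0L, 1L))) stop("allele entries must be 0 or 1")
  storage.mode(alleles) <- "integer"
  if (centromere_cM < 0 || centromere_cM > length_cM)
    stop("centromere_cM must lie within [0, length_cM]")
  d1 <- colSums(alleles[seq_len(ploidy), , drop = FALSE])
  d2 <- colSums(alleles[ploidy + seq_len(ploidy), , drop = FALSE])
  seg <- (d1 > 0L & d1 < ploidy) | (d2 > 0L & d2 < ploidy)
  if (!all(seg))
    stop("non-segregating marker(s): ", paste(which(!seg), collapse = ", "),
         " (both parents homozygous)")
  if (is.null(names)) names <- sprintf("M%04d", seq_along(positions))
  dimnames(alleles) <- list(paste0("h", seq_len(2L * ploidy)), names)
  structure(
    list(chrom = as.character(chrom), length_cM = as.numeric(length_cM),
         ploidy = as.integer(ploidy), centromere_cM = as.numeric(centromere_cM),
         marker = data.frame(name = names, position = positions,
                             stringsAsFactors = FALSE),
         alleles = alleles),
    class = "PhasedMap")
}

#' @export
print.PhasedMap <- function(x, ...) {
  cat(sprintf("PhasedMap: chrom %s, ploidy %d, %d markers over %.1f cM (centromere %.1f cM)\n",
              x$chrom, x$ploidy, nrow(x$marker), x$length_cM, x$centromere_cM))
  tab <- table(marker_type_labels(x))
  cat("segregation types:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

n_markers <- function(map) nrow(map$marker)

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1L || ploidy < 2 || ploidy %% 2 != 0)
    stop("ploidy must be a single even integer >= 2")
  invisible(as.integer(ploidy))
}

#' Maternal and paternal dosages of every marker
#'
#' @param map a [phased_map()].
#' @return data frame with columns `d1`, `d2` (parental dosages of the
#'   alternative allele).
#' @export
marker_dosages <- function(map) {
  p <- map$ploidy
  data.frame(
    d1 = colSums(map$alleles[seq_len(p), , drop = FALSE]),
    d2 = colSums(map$alleles[p + seq_len(p), , drop = FALSE]))
}

marker_type_labels <- function(map) {
  d <- marker_dosages(map)
  cc <- convert_marker_type(d$d1, d$d2, map$ploidy)
  paste0(cc$d1, "x", cc$d2)
}

#' Convert a marker segregation type to its fundamental form
#'
#' A marker is described by its maternal x paternal dosages of the
#' alternative allele (e.g. `1x0` = simplex x nulliplex). Dosage pairs that
#' carry identical linkage information are equivalence classes under two
#' moves: (i) a homozygous parent (dosage 0 or ploidy) is recoded as 0, and
#' (ii) both dosages may be complemented jointly (relabelling which SNP
#' allele is counted). The canonical representative is the
#' lexicographically smallest pair reachable by these moves, so e.g.
#' `1x4`, `3x0` and `3x4` all convert to `1x0`.
#'
#' @param d1,d2 integer vectors of maternal / paternal dosages in
#'   `0..ploidy`.
#' @param ploidy even integer >= 2.
#' @return data frame with canonical `d1`, `d2`.
#' @export
convert_marker_type <- function(d1, d2, ploidy) {
  check_ploidy(ploidy)
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (length(d1) != length(d2)) stop("d1 and d2 must have equal length")
  if (any(d1 < 0 | d1 > ploidy | d2 < 0 | d2 > ploidy))
    stop("dosages must lie in 0..ploidy")
  norm <- function(d) ifelse(d == 0L | d == ploidy, 0L, d)
  a1 <- norm(d1); a2 <- norm(d2)              # normalized
  b1 <- norm(ploidy - d1); b2 <- norm(ploidy - d2)  # complemented, normalized
  use_b <- (b1 < a1) | (b1 == a1 & b2 < a2)
  data.frame(d1 = as.integer(ifelse(use_b, b1, a1)),
             d2 = as.integer(ifelse(use_b, b2, a2)))
}

#' Enumerate the fundamental marker segregation types
#'
#' All distinct canonical classes of segregating dosage pairs under
#' [convert_marker_type()]: nine in an autotetraploid (`1x0`, `0x1`, `2x0`,
#' `0x2`, `1x1`, `1x2`, `2x1`, `1x3`, `2x2`), nineteen in an autohexaploid.
#'
#' @param ploidy even integer >= 2.
#' @return data frame of canonical `d1`, `d2` pairs with a `label` column,
#'   sorted lexicographically.
#' @export
enumerate_segregation_types <- function(ploidy) {
  check_ploidy(ploidy)
  g <- expand.grid(d1 = 0:ploidy, d2 = 0:ploidy)
  seg <- (g$d1 > 0 & g$d1 < ploidy) | (g$d2 > 0 & g$d2 < ploidy)
  cc <- convert_marker_type(g$d1[seg], g$d2[seg], ploidy)
  cc <- unique(cc)
  cc <- cc[order(cc$d1, cc$d2), , drop = FALSE]
  rownames(cc) <- NULL
  cc$label <- paste0(cc$d1, "x", cc$d2)
  cc
}

parse_type_label <- function(label, ploidy) {
  m <- regmatches(label, regexec("^([0-9]+)x([0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("invalid segregation type label: ", label)
  d <- c(as.integer(m[2]), as.integer(m[3]))
  canon <- enumerate_segregation_types(ploidy)
  if (!any(canon$d1 == d[1] & canon$d2 == d[2]))
    stop("segregation type ", label, " is not a fundamental type at ploidy ",
         ploidy, "; convert it first (see convert_marker_type)")
  d
}

## positions drawn iid from a coverage profile: "uniform" or
## list(type = "clustered", centers =, sd =, weights =) -- a truncated
## Gaussian-mixture marker density on [0, L].
profile_sample <- function(n, length_cM, profile) {
  if (identical(profile, "uniform"))
    return(sort(stats::runif(n, 0, length_cM)))
  if (is.list(profile) && identical(profile$type, "clustered")) {
    centers <- profile$centers
    sd <- if (is.null(profile$sd)) length_cM / 50 else profile$sd
    w <- if (is.null(profile$weights)) rep(1, length(centers)) else profile$weights
    w <- w / sum(w)
    out <- numeric(0)
    while (length(out) < n) {   # rejection on the truncation to [0, L]
      k <- sample.int(length(centers), n, replace = TRUE, prob = w)
      x <- stats::rnorm(n, centers[k], sd)
      out <- c(out, x[x >= 0 & x <= length_cM])
    }
    return(sort(out[seq_len(n)]))
  }
  stop("coverage_profile must be \"uniform\" or list(type = \"clustered\", ...)")
}

#' CDF of a coverage profile
#'
#' Used to check realized marker positions against the generating density
#' (positions are drawn iid from the profile).
#'
#' @param profile `"uniform"` or a clustered profile list.
#' @param length_cM chromosome length.
#' @return a vectorized CDF function on `[0, length_cM]`.
#' @export
profile_cdf <- function(profile, length_cM) {
  if (identical(profile, "uniform"))
    return(function(x) pmin(pmax(x / length_cM, 0), 1))
  centers <- profile$centers
  sd <- if (is.null(profile$sd)) length_cM / 50 else profile$sd
  w <- if (is.null(profile$weights)) rep(1, length(centers)) else profile$weights
  w <- w / sum(w)
  lo <- sum(w * stats::pnorm(0, centers, sd))
  hi <- sum(w * stats::pnorm(length_cM, centers, sd))
  function(x) {
    raw <- vapply(x, function(xi) sum(w * stats::pnorm(xi, centers, sd)), 0)
    pmin(pmax((raw - lo) / (hi - lo), 0), 1)
  }
}

#' Generate a synthetic phased parental map
#'
#' Marker positions are drawn iid from a coverage profile; each marker is
#' assigned a fundamental segregation type sampled from `segregation_mix`
#' and its alternative alleles are placed on randomly chosen parental
#' homologs (optionally biased by `homolog_weights` to emulate uneven
#' per-homolog coverage).
#'
#' @param ploidy even integer >= 2.
#' @param n_markers number of markers (>= 1).
#' @param length_cM chromosome length in cM.
#' @param coverage_profile `"uniform"` or
#'   `list(type = "clustered", centers =, sd =, weights =)`.
#' @param segregation_mix named numeric vector of sampling weights over
#'   fundamental type labels (e.g. `c("1x0" = 1)`); default: equal weights
#'   over all fundamental types.
#' @param seed integer seed; the map is deterministic given the seed.
#' @param homolog_weights optional positive weights of length `2 * ploidy`
#'   biasing which homologs carry marker alleles.
#' @param centromere_cM centromere position (default midpoint).
#' @param chrom chromosome name.
#' @return a [phased_map()].
#' @export
generate_phased_map <- function(ploidy, n_markers, length_cM,
                                coverage_profile = "uniform",
                                segregation_mix = NULL, seed = NULL,
                                homolog_weights = NULL,
                                centromere_cM = length_cM / 2,
                                chrom = "chr1") {
  check_ploidy(ploidy)
  if (n_markers < 1) stop("n_markers must be >= 1 (empty maps are rejected)")
  if (!is.null(seed)) set.seed(seed)
  canon <- enumerate_segregation_types(ploidy)
  if (is.null(segregation_mix)) {
    segregation_mix <- stats::setNames(rep(1, nrow(canon)), canon$label)
  }
  types <- vapply(names(segregation_mix), parse_type_label, integer(2),
                  ploidy = ploidy)
  pos <- round(profile_sample(n_markers, length_cM, coverage_profile), 4)
  pick <- sample.int(ncol(types), n_markers, replace = TRUE,
                     prob = segregation_mix)
  if (is.null(homolog_weights)) homolog_weights <- rep(1, 2 * ploidy)
  if (length(homolog_weights) != 2 * ploidy || any(homolog_weights <= 0))
    stop("homolog_weights must be ", 2 * ploidy, " positive values")
  alleles <- matrix(0L, 2 * ploidy, n_markers)
  for (m in seq_len(n_markers)) {
    d <- types[, pick[m]]
    if (d[1] > 0)
      alleles[sample.int(ploidy, d[1], prob = homolog_weights[1:ploidy]), m] <- 1L
    if (d[2] > 0)
      alleles[ploidy + sample.int(ploidy, d[2],
                                  prob = homolog_weights[ploidy + 1:ploidy]), m] <- 1L
  }
  phased_map(chrom, length_cM, pos, alleles, ploidy,
             centromere_cM = centromere_cM)
}

#' Generate a map from a restricted founder-haplotype pool
#'
#' Parental homologs are drawn with replacement from a pool of
#' `n_founders` distinct haplotypes; markers that are monomorphic across
#' the chosen `2 * ploidy` homologs (or that do not segregate in the
#' cross) are dropped. Smaller pools are more inbred and yield fewer
#' segregating markers on average.
#'
#' @param ploidy even integer >= 2.
#' @param n_founders number of founder haplotypes (>= 2).
#' @param n_markers candidate markers before filtering.
#' @param length_cM chromosome length.
#' @param seed integer seed.
#' @param maf minor-allele frequency of founder alleles (default 0.5).
#' @return a [phased_map()]; its `founder_of_homolog` attribute records
#'   which founder each homolog was drawn from.
#' @export
generate_map_from_founders <- function(ploidy, n_founders, n_markers,
                                       length_cM, seed = NULL, maf = 0.5) {
  check_ploidy(ploidy)
  if (n_founders < 2)
    stop("n_founders must be >= 2: a single founder cannot segregate")
  if (!is.null(seed)) set.seed(seed)
  founders <- matrix(stats::rbinom(n_founders * n_markers, 1L, maf),
                     n_founders, n_markers)
  draw <- sample.int(n_founders, 2 * ploidy, replace = TRUE)
  alleles <- founders[draw, , drop = FALSE]
  pos <- round(sort(stats::runif(n_markers, 0, length_cM)), 4)
  d1 <- colSums(alleles[seq_len(ploidy), , drop = FALSE])
  d2 <- colSums(alleles[ploidy + seq_len(ploidy), , drop = FALSE])
  seg <- (d1 > 0L & d1 < ploidy) | (d2 > 0L & d2 < ploidy)
  if (!any(seg))
    stop("all candidate markers are monomorphic/non-segregating; ",
         "use a larger founder pool or more markers")
  map <- phased_map("chr1", length_cM, pos[seg],
                    alleles[, seg, drop = FALSE], ploidy)
  attr(map, "founder_of_homolog") <- draw
  map
}

#' Write / read a phased map as TSV
#'
#' Column layout: `marker chrom position_cM h1 ... h{2*ploidy}`; positions
#' are printed with 4 decimals and alleles as 0/1, so generated maps
#' round-trip losslessly.
#'
#' @param map a [phased_map()].
#' @param path file path.
#' @rdname map_io
#' @export
write_phased_map <- function(map, path) {
  df <- data.frame(marker = map$marker$name, chrom = map$chrom,
                   position_cM = sprintf("%.4f", map$marker$position),
                   t(map$alleles), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ## length / centromere / ploidy travel in a comment-free side-car header
  ## would break plain TSV; they are re-supplied on read.
  invisible(path)
}

#' @param length_cM,ploidy,centromere_cM map attributes not stored in the
#'   TSV body; `ploidy` is inferred from the homolog columns if omitted.
#' @rdname map_io
#' @export
read_phased_map <- function(path, length_cM = NULL, ploidy = NULL,
                            centromere_cM = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  hcols <- grep("^h[0-9]+$", names(df), value = TRUE)
  if (is.null(ploidy)) ploidy <- length(hcols) / 2
  if (is.null(length_cM)) length_cM <- max(df$position_cM)
  if (is.null(centromere_cM)) centromere_cM <- length_cM / 2
  phased_map(df$chrom[1], length_cM, df$position_cM,
             t(as.matrix(df[, hcols])), ploidy, names = df$marker,
             centromere_cM = centromere_cM)
}

#' Benchmark map fixtures
#'
#' `map_even_coverage()` emulates a well-covered chromosome (uniform
#' marker density, all nine fundamental types, ~1 marker/cM over 100 cM)
#' of the kind used for power studies; its centromere sits at 49 cM so
#' that a QTL at 49 cM is centromeric (no double reduction) and one at
#' 14 cM is telomeric, the contrast used in power designs.
#' `map_uneven_coverage()` emulates a chromosome with clustered markers
#' and strongly biased per-homolog coverage, the regime where
#' per-homolog information (GIC) varies.
#'
#' @param seed integer seed.
#' @param n_markers number of markers.
#' @param length_cM chromosome length.
#' @param centromere_cM centromere position.
#' @rdname map_fixtures
#' @export
map_even_coverage <- function(seed = 1, n_markers = 100, length_cM = 100,
                              centromere_cM = 49) {
  generate_phased_map(4, n_markers, length_cM, "uniform", seed = seed,
                      centromere_cM = centromere_cM, chrom = "chrE")
}

#' @rdname map_fixtures
#' @export
map_uneven_coverage <- function(seed = 1, n_markers = 80, length_cM = 100) {
  generate_phased_map(
    4, n_markers, length_cM,
    coverage_profile = list(type = "clustered",
                            centers = c(10, 35, 60, 85),
                            sd = 6, weights = c(3, 1, 2, 1)),
    seed = seed,
    homolog_weights = c(4, 4, 1, 0.5, 4, 2, 1, 0.5),
    chrom = "chrU")
}
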