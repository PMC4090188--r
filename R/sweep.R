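#' Genotype-class frequencies and expected heterozygosity in a breed panel
#'
#' @param panel a [geno_matrix()] for one breed.
#' @param marker marker id or index.
#' @return [genotype_frequencies()]: named vector `(hom1, het, hom2)`
#'   summing to 1 over non-missing calls; [heterozygosity()]: `2 f (1 - f)`
#'   with `f` the allele2 frequency, for one marker or (default) all.
#' @export
genotype_frequencies <- function(panel, marker) {
  stopifnot(inherits(panel, "geno_matrix"))
  j <- resolve_markers(panel, marker)
  x <- panel$dosage[, j]
  x <- x[!is.na(x)]
  if (!length(x)) stop("all genotypes missing at marker ",
                       panel$map$marker_id[j])
  c(hom1 = mean(x == 0L), het = mean(x == 1L), hom2 = mean(x == 2L))
}

#' @rdname genotype_frequencies
#' @export
heterozygosity <- function(panel, marker = NULL) {
  stopifnot(inherits(panel, "geno_matrix"))
  d <- panel$dosage
  if (!is.null(marker)) d <- d[, resolve_markers(panel, marker),
                               drop = FALSE]
  if (any(colSums(!is.na(d)) == 0)) stop("all genotypes missing at a marker")
  f <- colMeans(d, na.rm = TRUE) / 2
  stats::setNames(2 * f * (1 - f),
                  if (is.null(marker)) panel$map$marker_id else NULL)
}

#' Detect selective-sweep intervals by fixation runs
#'
#' Finds maximal runs of consecutive markers at which the case panel is
#' fixed for one allele (observed minor allele frequency exactly 0, judged
#' on non-missing calls), keeps runs of at least `min_run` markers, and
#' requires every control panel to remain polymorphic at the run markers
#' (`control_mode = "any"`: at >= 1 run marker; `"all"`: at every run
#' marker).  Each reported interval is bounded by the nearest non-fixed case
#' markers on either side, both exclusive; its bp length is the distance
#' between those flanking markers (`NA` at the panel edges).
#'
#' @param case a [geno_matrix()] of the selected breed.
#' @param controls list of [geno_matrix()] control panels sharing the same
#'   ordered marker set.
#' @param min_run minimum run length (default 4, i.e. strictly more than
#'   three consecutive fixed markers).
#' @param control_mode `"any"` (default) or `"all"`.
#' @return `data.frame` with one row per sweep: run first/last marker and
#'   index, exclusive flanking markers and their positions, `length_bp`
#'   between the flanks, `n_markers`, and the case missing-call fraction
#'   over the run.
#' @export
detect_sweep <- function(case, controls, min_run = 4L,
                         control_mode = c("any", "all")) {
  stopifnot(inherits(case, "geno_matrix"))
  control_mode <- match.arg(control_mode)
  for (ctl in controls) {
    if (!identical(ctl$map$marker_id, case$map$marker_id))
      stop("control panel marker set does not match the case panel")
  }
  maf <- minor_allele_frequency(case)
  called <- colSums(!is.na(case$dosage)) > 0
  fixed <- called & !is.na(maf) & maf == 0
  empty <- data.frame(first_marker = character(0), last_marker = character(0),
                      first_index = integer(0), last_index = integer(0),
                      left_flank = character(0), right_flank = character(0),
                      left_flank_bp = numeric(0), right_flank_bp = numeric(0),
                      length_bp = numeric(0), n_markers = integer(0),
                      missing_fraction = numeric(0), stringsAsFactors = FALSE)
  r <- rle(as.vector(fixed))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) return(empty)
  map <- case$map
  rows <- list()
  for (k in keep) {
    a <- starts[k]; b <- ends[k]
    run <- a:b
    ok <- vapply(controls, function(ctl) {
      cmaf <- minor_allele_frequency(ctl)[run]
      poly <- !is.na(cmaf) & cmaf > 0
      if (control_mode == "any") any(poly) else all(poly)
    }, logical(1))
    if (!all(ok)) next
    lf <- if (a > 1) a - 1L else NA_integer_
    rf <- if (b < ncol(case$dosage)) b + 1L else NA_integer_
    rows[[length(rows) + 1]] <- data.frame(
      first_marker = map$marker_id[a], last_marker = map$marker_id[b],
      first_index = a, last_index = b,
      left_flank = if (is.na(lf)) NA_character_ else map$marker_id[lf],
      right_flank = if (is.na(rf)) NA_character_ else map$marker_id[rf],
      left_flank_bp = if (is.na(lf)) NA_real_ else map$position_bp[lf],
      right_flank_bp = if (is.na(rf)) NA_real_ else map$position_bp[rf],
      length_bp = if (is.na(lf) || is.na(rf)) NA_real_ else
        map$position_bp[rf] - map$position_bp[lf],
      n_markers = b - a + 1L,
      missing_fraction = mean(is.na(case$dosage[, run])),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
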