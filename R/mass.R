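#' Assign the transmitted paternal homolog for each offspring
#'
#' For each marker at which the sire is heterozygous, the allele transmitted
#' by the sire is inferred from the offspring genotype (directly when the
#' offspring is homozygous, via the dam's genotype when the dam is homozygous
#' at that marker).  Each informative marker casts one vote for the sire
#' homolog carrying the transmitted allele; offspring are labelled by the
#' majority, and a tie or absence of informative markers leaves them
#' unassigned.
#'
#' @param sire_phase list with `h1`, `h2`: 0/1 allele2-count vectors of the
#'   sire's two homologs over the marker set.
#' @param offspring a [geno_matrix()] restricted to the marker set (columns
#'   aligned with `sire_phase`).
#' @param dam_dosage optional matrix of dam dosages aligned with `offspring`
#'   rows/columns (each offspring's dam's genotype).
#' @return character vector (`"H1"`, `"H2"`, `"unassigned"`) named by
#'   offspring id.
#' @export
assign_transmitted_homolog <- function(sire_phase, offspring,
                                       dam_dosage = NULL) {
  stopifnot(inherits(offspring, "geno_matrix"))
  h1 <- sire_phase$h1; h2 <- sire_phase$h2
  m <- length(h1)
  stopifnot(length(h2) == m, ncol(offspring$dosage) == m)
  het <- which(h1 != h2)
  if (!length(het)) stop("uninformative sire: homozygous at all markers")
  D <- offspring$dosage
  n <- nrow(D)
  labels <- rep("unassigned", n)
  names(labels) <- rownames(D)
  for (i in seq_len(n)) {
    v1 <- 0L; v2 <- 0L
    for (j in het) {
      d <- D[i, j]
      if (is.na(d)) next
      pat <- NA_integer_
      if (d == 0L) pat <- 0L
      else if (d == 2L) pat <- 1L
      else if (!is.null(dam_dosage) && !is.na(dam_dosage[i, j])) {
        if (dam_dosage[i, j] == 0L) pat <- 1L     # dam gave 0, sire gave 1
        else if (dam_dosage[i, j] == 2L) pat <- 0L
      }
      if (is.na(pat)) next
      if (pat == h1[j]) v1 <- v1 + 1L else v2 <- v2 + 1L
    }
    if (v1 > v2) labels[i] <- "H1"
    else if (v2 > v1) labels[i] <- "H2"
  }
  labels
}

#' MASS likelihood-ratio Z score
#'
#' `Z = log10(L_H1 / L_H0)` with Gaussian likelihoods: under H1 (sire Qq)
#' each homolog group has its own mean with a pooled maximum-likelihood
#' variance; under H0 (sire QQ or qq) all offspring share one mean and
#' variance.  With maximum-likelihood variances this reduces to
#' `Z = (n / 2) * log10(RSS0 / RSS1)`.
#'
#' @param pheno1,pheno2 trait values of the two homolog groups (each needs at
#'   least 2 records; otherwise `NA` is returned and the sire is
#'   undetermined).
#' @return the Z score (log10 likelihood ratio), or `NA_real_`.
#' @export
mass_z <- function(pheno1, pheno2) {
  n1 <- length(pheno1); n2 <- length(pheno2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  n <- n1 + n2
  rss1 <- sum((pheno1 - mean(pheno1))^2) + sum((pheno2 - mean(pheno2))^2)
  all <- c(pheno1, pheno2)
  rss0 <- sum((all - mean(all))^2)
  if (rss1 <= 0) return(Inf)
  (n / 2) * log10(rss0 / rss1)
}

#' Classify a sire from its MASS Z score
#'
#' Qq when `Z > 2`; homozygous (QQ or qq) when `Z < -2`; undetermined
#' otherwise (including the boundaries and a missing Z).
#'
#' @param Z the log10 likelihood-ratio score.
#' @return `"Qq"`, `"homozygous"` or `"undetermined"`.
#' @export
classify_sire <- function(Z) {
  if (is.na(Z)) return("undetermined")
  if (Z > 2) "Qq" else if (Z < -2) "homozygous" else "undetermined"
}

#' Marker-assisted segregation analysis of one sire
#'
#' Sorts the sire's offspring into two groups by the transmitted paternal
#' homolog over a marker set, compares the group phenotype means via the
#' log10 likelihood-ratio Z score, and classifies the sire as heterozygous
#' (Qq) or homozygous at the QTL.
#'
#' @param sire_id sire identifier.
#' @param sire_phase list with `h1`, `h2` homolog allele vectors (allele2
#'   counts) over `markers`.
#' @param offspring a [geno_matrix()] of the sire's offspring.
#' @param pheno phenotype table covering the offspring.
#' @param markers marker ids (or indices) defining the sorting window.
#' @param dam_dosage optional dam dosages (see
#'   [assign_transmitted_homolog()]).
#' @return list of class `mass_result`: per-offspring labels, group sizes,
#'   means and standard errors, `Z` and the classification.
#' @export
mass_analysis <- function(sire_id, sire_phase, offspring, pheno, markers,
                          dam_dosage = NULL) {
  if (is.character(markers)) {
    jj <- match(markers, offspring$map$marker_id)
    if (anyNA(jj)) stop("marker not in genotype matrix: ",
                        markers[is.na(jj)][1])
  } else jj <- markers
  off <- subset_geno(offspring, markers = jj)
  phase <- list(h1 = sire_phase$h1[jj], h2 = sire_phase$h2[jj])
  dd <- if (is.null(dam_dosage)) NULL else dam_dosage[, jj, drop = FALSE]
  labels <- assign_transmitted_homolog(phase, off, dd)
  y <- pheno$ear_area[match(names(labels), pheno$id)]
  y1 <- y[labels == "H1" & !is.na(y)]
  y2 <- y[labels == "H2" & !is.na(y)]
  Z <- mass_z(y1, y2)
  grp <- function(v) c(n = length(v), mean = mean(v),
                       se = stats::sd(v) / sqrt(length(v)))
  structure(list(sire_id = sire_id, labels = labels,
                 n1 = length(y1), n2 = length(y2),
                 n_unassigned = sum(labels == "unassigned"),
                 group1 = grp(y1), group2 = grp(y2), Z = Z,
                 classification = classify_sire(Z)),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat("<mass_result> sire ", x$sire_id, ": H1 n=", x$n1, " mean=",
      round(x$group1[["mean"]], 1), "; H2 n=", x$n2, " mean=",
      round(x$group2[["mean"]], 1), "; Z=", round(x$Z, 2), " -> ",
      x$classification, "\n", sep = "")
  invisible(x)
}
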