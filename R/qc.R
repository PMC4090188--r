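#' Per-marker and per-individual call rates
#'
#' @param g a [geno_matrix()].
#' @return numeric vector of proportions of non-missing calls, named by
#'   marker id ([snp_call_rate()]) or individual id ([sample_call_rate()]).
#' @export
snp_call_rate <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0)
    stop("empty genotype matrix")
  colMeans(!is.na(g$dosage))
}

#' @rdname snp_call_rate
#' @export
sample_call_rate <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0)
    stop("empty genotype matrix")
  rowMeans(!is.na(g$dosage))
}

#' Minor allele frequency
#'
#' `min(f, 1 - f)` where `f = (2 * hom2 + het) / (2 * n_nonmissing)` is the
#' allele2 frequency among non-missing genotypes.
#'
#' @param g a [geno_matrix()].
#' @param marker optional marker id or index; `NULL` returns all markers.
#' @return named numeric vector of MAFs (NA for all-missing markers).
#' @export
minor_allele_frequency <- function(g, marker = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosage
  if (!is.null(marker)) {
    if (is.character(marker)) marker <- match(marker, g$map$marker_id)
    d <- d[, marker, drop = FALSE]
  }
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[colSums(!is.na(d)) == 0] <- NA
  maf
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each possible heterozygote count is evaluated and the P-value is the
#' sum of probabilities of heterozygote counts no more probable than the
#' observed one (two-sided).
#'
#' @param hom1,het,hom2 genotype counts (allele1 homozygotes, heterozygotes,
#'   allele2 homozygotes).
#' @return exact two-sided P-value in (0, 1].
#' @export
hwe_test <- function(hom1, het, hom2) {
  if (any(c(hom1, het, hom2) < 0)) stop("negative genotype counts")
  n <- hom1 + het + hom2
  if (n < 1) stop("no genotypes")
  n_minor <- 2 * min(hom1, hom2) + het      # rarer allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele counts) up to a constant:
  # n! / (n1! h! n2!) * 2^h with n2 = (n_minor - h)/2
  lp <- vapply(hets, function(h) {
    nb <- (n_minor - h) / 2
    na_ <- n - h - nb
    lgamma(n + 1) - lgamma(na_ + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

hwe_pvalues <- function(g) {
  d <- g$dosage
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
}

#' Two-step iterative genotype quality control
#'
#' Repeats, until a full pass removes nothing: (1) exclude markers with call
#' rate below `snp_call`, then MAF below `maf`, then exact HWE P-value below
#' `hwe` (a marker failing several filters is recorded under the first, in
#' that order); (2) exclude individuals with call rate below `sample_call`.
#' All statistics are recomputed on the surviving data at each pass.
#'
#' Sex-linkage screening (reassignment of X-linked markers) is not supported:
#' it needs array intensity and sex-call data outside this package's inputs;
#' the report notes this.
#'
#' @param g a [geno_matrix()].
#' @param thresholds named list/vector with `snp_call`, `maf`, `hwe`,
#'   `sample_call` (defaults 0.90, 0.03, 1e-6, 0.90).
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (class `qc_report`: excluded SNPs/samples with reasons in application
#'   order, number of iterations, surviving dimensions).
#' @export
iterative_qc <- function(g, thresholds = list(snp_call = 0.90, maf = 0.03,
                                              hwe = 1e-6,
                                              sample_call = 0.90)) {
  stopifnot(inherits(g, "geno_matrix"))
  th <- thresholds
  stopifnot(all(c("snp_call", "maf", "hwe", "sample_call") %in% names(th)))
  excluded_snps <- data.frame(marker_id = character(0), reason = character(0),
                              iteration = integer(0),
                              stringsAsFactors = FALSE)
  excluded_samples <- data.frame(id = character(0), reason = character(0),
                                 iteration = integer(0),
                                 stringsAsFactors = FALSE)
  it <- 0L
  repeat {
    it <- it + 1L
    removed <- FALSE
    # step 1: marker filters in order call rate, MAF, HWE
    cr <- snp_call_rate(g)
    drop_cr <- which(cr < th$snp_call)
    keep <- setdiff(seq_len(ncol(g$dosage)), drop_cr)
    maf <- rep(NA_real_, ncol(g$dosage))
    maf[keep] <- minor_allele_frequency(subset_geno(g, markers = keep))
    drop_maf <- setdiff(which(!is.na(maf) & maf < th$maf), drop_cr)
    keep <- setdiff(keep, drop_maf)
    hwe <- rep(NA_real_, ncol(g$dosage))
    if (length(keep))
      hwe[keep] <- hwe_pvalues(subset_geno(g, markers = keep))
    drop_hwe <- setdiff(which(!is.na(hwe) & hwe < th$hwe),
                        c(drop_cr, drop_maf))
    drops <- list(call_rate = drop_cr, maf = drop_maf, hwe = drop_hwe)
    for (reason in names(drops)) {
      jj <- drops[[reason]]
      if (length(jj)) {
        removed <- TRUE
        excluded_snps <- rbind(excluded_snps, data.frame(
          marker_id = g$map$marker_id[jj], reason = reason, iteration = it,
          stringsAsFactors = FALSE))
      }
    }
    jkeep <- setdiff(seq_len(ncol(g$dosage)), unlist(drops))
    if (length(jkeep) == 0) stop("no data survive QC")
    g <- subset_geno(g, markers = jkeep)
    # step 2: sample call-rate filter on surviving markers
    scr <- sample_call_rate(g)
    drop_s <- which(scr < th$sample_call)
    if (length(drop_s)) {
      removed <- TRUE
      excluded_samples <- rbind(excluded_samples, data.frame(
        id = rownames(g$dosage)[drop_s], reason = "call_rate",
        iteration = it, stringsAsFactors = FALSE))
      ikeep <- setdiff(seq_len(nrow(g$dosage)), drop_s)
      if (length(ikeep) == 0) stop("no data survive QC")
      g <- subset_geno(g, individuals = ikeep)
    }
    if (!removed) break
  }
  report <- structure(list(excluded_snps = excluded_snps,
                           excluded_samples = excluded_samples,
                           n_iterations = it,
                           n_snps = ncol(g$dosage),
                           n_samples = nrow(g$dosage),
                           thresholds = th,
                           sex_linkage_check = "unsupported"),
                      class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_iterations, " iteration(s); surviving ",
      x$n_samples, " samples x ", x$n_snps, " SNPs\n", sep = "")
  if (nrow(x$excluded_snps))
    print(table(x$excluded_snps$reason))
  cat("excluded samples: ", nrow(x$excluded_samples), "\n", sep = "")
  invisible(x)
}
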