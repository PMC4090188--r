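#' Configuration for the F2 intercross simulator
#'
#' Defaults mirror the design of the mapping population the package targets:
#' 314 F2 animals in 47 litters from 9 F1 sires mated to 34 F1 dams, founders
#' drawn from two breeds (Minzhu-like QQ, Large White-like qq) that are
#' alternatively fixed for the QTL allele, an ear-area trait with mean
#' 244 cm^2 and coefficient of variation 22%, and a QTL explaining half the
#' phenotypic variance.  The marker panel is a desk-scale stand-in for a 60K
#' chip: 200 markers on one 60-Mb chromosome (~1 marker / 300 kb) with a
#' 1 cM/Mb genetic map.
#'
#' Variance is budgeted as fractions of the phenotypic variance implied by
#' `trait_mean * trait_cv`: QTL `qtl_variance_fraction`, polygenic 0.14,
#' litter 0.05, residual 0.29, sex 0.005, parity 0.003, batch 0.010 and body
#' weight 0.002 (the non-QTL fractions are rescaled so everything sums to 1
#' when `qtl_variance_fraction` differs from 0.5).  Explicit `sigma2_*`
#' values override the budget.
#'
#' @param n_f2,n_litters,n_f1_sires,n_f1_dams design counts.
#' @param n_markers,chromosome_length_bp,chromosome marker panel layout.
#' @param qtl_marker_index index of the QTL marker in the map.
#' @param qtl_variance_fraction fraction of phenotypic variance from the QTL.
#' @param trait_mean,trait_cv trait mean (cm^2) and coefficient of variation.
#' @param sigma2_a,sigma2_c,sigma2_e optional explicit polygenic, litter and
#'   residual variances (cm^4); `NULL` uses the budget above.
#' @param n_batches,n_parity,n_sexes numbers of fixed-effect levels
#'   (28 slaughter groups, 3 parities, 2 sexes by default).
#' @param body_weight_mean,body_weight_sd body-weight covariate (kg).
#' @param diff_halfwidth_bp half-width of the window around the QTL with
#'   elevated between-breed allele-frequency differentiation.
#' @param founder_breed_freqs optional 2 x n_markers matrix of allele2
#'   frequencies (rows `minzhu`, `large_white`); `NULL` draws them.
#' @param seed integer seed; the simulator is deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_f2 = 314L, n_litters = 47L, n_f1_sires = 9L,
                       n_f1_dams = 34L, n_markers = 200L,
                       chromosome_length_bp = 60e6, chromosome = "5",
                       qtl_marker_index = NULL, qtl_variance_fraction = 0.5,
                       trait_mean = 244, trait_cv = 0.22,
                       sigma2_a = NULL, sigma2_c = NULL, sigma2_e = NULL,
                       n_batches = 28L, n_parity = 3L, n_sexes = 2L,
                       body_weight_mean = 100, body_weight_sd = 10,
                       diff_halfwidth_bp = 2e6,
                       founder_breed_freqs = NULL, seed = 1L) {
  if (n_f2 < n_litters)
    stop("impossible litter partition: n_f2 < n_litters")
  if (n_litters < n_f1_dams)
    stop("impossible litter partition: fewer litters than dams")
  stopifnot(n_f1_sires >= 1, n_f1_dams >= 1, n_markers >= 2)
  if (is.null(qtl_marker_index)) qtl_marker_index <- round(n_markers / 2)
  if (qtl_marker_index < 1 || qtl_marker_index > n_markers)
    stop("qtl_marker_index out of range")
  if (qtl_variance_fraction < 0 || qtl_variance_fraction >= 1)
    stop("qtl_variance_fraction must be in [0, 1)")
  var_p <- (trait_mean * trait_cv)^2
  # non-QTL budget fractions at the default half-variance QTL
  base <- c(a = 0.14, c = 0.05, e = 0.29,
            sex = 0.005, parity = 0.003, batch = 0.010, weight = 0.002)
  scale <- (1 - qtl_variance_fraction) / sum(base)
  fr <- base * scale
  cfg <- list(
    n_f2 = as.integer(n_f2), n_litters = as.integer(n_litters),
    n_f1_sires = as.integer(n_f1_sires), n_f1_dams = as.integer(n_f1_dams),
    n_markers = as.integer(n_markers),
    chromosome_length_bp = chromosome_length_bp, chromosome = chromosome,
    qtl_marker_index = as.integer(qtl_marker_index),
    qtl_variance_fraction = qtl_variance_fraction,
    trait_mean = trait_mean, trait_cv = trait_cv, var_p = var_p,
    sigma2_a = if (is.null(sigma2_a)) fr[["a"]] * var_p else sigma2_a,
    sigma2_c = if (is.null(sigma2_c)) fr[["c"]] * var_p else sigma2_c,
    sigma2_e = if (is.null(sigma2_e)) fr[["e"]] * var_p else sigma2_e,
    sex_effect = sqrt(fr[["sex"]] * var_p),
    parity_effect = sqrt(1.5 * fr[["parity"]] * var_p),
    batch_sd = sqrt(fr[["batch"]] * var_p),
    body_weight_slope = sqrt(fr[["weight"]] * var_p) / body_weight_sd,
    n_batches = as.integer(n_batches), n_parity = as.integer(n_parity),
    n_sexes = as.integer(n_sexes),
    body_weight_mean = body_weight_mean, body_weight_sd = body_weight_sd,
    diff_halfwidth_bp = diff_halfwidth_bp,
    founder_breed_freqs = founder_breed_freqs,
    seed = as.integer(seed))
  if (cfg$sigma2_a < 0 || cfg$sigma2_c < 0 || cfg$sigma2_e < 0)
    stop("variance components must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

# One meiosis: Poisson crossovers (Haldane, no interference) on the cM map,
# uniform placement; returns the founder-chromosome origin id per marker.
meiosis_origin <- function(o1, o2, cm) {
  len <- cm[length(cm)] - cm[1]
  n_co <- stats::rpois(1L, len / 100)
  start <- sample.int(2L, 1L)
  if (n_co == 0L) {
    use1 <- rep(start == 1L, length(cm))
  } else {
    xo <- sort(stats::runif(n_co, cm[1], cm[length(cm)]))
    seg <- findInterval(cm, xo)           # crossovers before each marker
    use1 <- ((seg + start) %% 2L) == 1L
  }
  ifelse(use1, o1, o2)
}

#' Simulate a two-breed F2 intercross
#'
#' Generates founder haplotypes from breed allele frequencies (with elevated
#' between-breed differentiation around the QTL and the QTL allele
#' alternatively fixed in the two breeds), drops gametes down the pedigree by
#' crossover sampling on the cM map, and builds the ear-area phenotype as
#'
#' `y = mu + sex + parity + batch + slope * weight + litter + polygenic +
#' QTL + residual`
#'
#' with polygenic values from a Mendelian-sampling cascade consistent with
#' the pedigree relationship matrix.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cross` with elements `genotypes`
#'   (phased [geno_matrix()] over all pedigree members), `pedigree`,
#'   `phenotypes` (F2 only) and `truth` (founder haplotypes, origin labels,
#'   true QTL genotypes, breeding values, realized components).
#' @export
simulate_cross <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  pos <- as.integer(round(seq_len(m) * config$chromosome_length_bp / m))
  map <- data.frame(marker_id = sprintf("M%04d", seq_len(m)),
                    chromosome = config$chromosome, position_bp = pos,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  cm <- pos / 1e6                          # 1 cM per Mb
  qi <- config$qtl_marker_index

  freqs <- config$founder_breed_freqs
  if (is.null(freqs)) {
    p0 <- stats::runif(m, 0.2, 0.8)
    d <- pmax(0, 1 - abs(pos - pos[qi]) / config$diff_halfwidth_bp) * 0.8
    f_mz <- pmin(0.98, pmax(0.02, p0 + d / 2 + stats::rnorm(m, 0, 0.03)))
    f_lw <- pmin(0.98, pmax(0.02, p0 - d / 2 + stats::rnorm(m, 0, 0.03)))
    f_mz[qi] <- 1; f_lw[qi] <- 0           # Q fixed in Minzhu, q in LW
    freqs <- rbind(minzhu = f_mz, large_white = f_lw)
  }
  if (!identical(dim(freqs), c(2L, m)) &&
      !(nrow(freqs) == 2 && ncol(freqs) == m))
    stop("founder_breed_freqs must be a 2 x n_markers matrix")

  # --- pedigree ------------------------------------------------------------
  n_f1 <- config$n_f1_sires + config$n_f1_dams
  lw_ids <- sprintf("LW%03d", seq_len(n_f1))
  mz_ids <- sprintf("MZ%03d", seq_len(n_f1))
  f1_ids <- c(sprintf("F1S%02d", seq_len(config$n_f1_sires)),
              sprintf("F1D%02d", seq_len(config$n_f1_dams)))
  dam_sire <- rep(seq_len(config$n_f1_sires),
                  length.out = config$n_f1_dams)  # sire assigned per dam
  extra <- config$n_litters - config$n_f1_dams
  litter_dam <- c(seq_len(config$n_f1_dams),
                  sample(config$n_f1_dams, extra))
  sizes <- rep(config$n_f2 %/% config$n_litters, config$n_litters)
  r <- config$n_f2 - sum(sizes)
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  f2_ids <- sprintf("F2_%04d", seq_len(config$n_f2))
  f2_litter <- rep(seq_len(config$n_litters), times = sizes)
  f2_dam <- litter_dam[f2_litter]
  f2_sire <- dam_sire[f2_dam]
  ped <- data.frame(
    id = c(lw_ids, mz_ids, f1_ids, f2_ids),
    sire = c(rep(NA, 2 * n_f1), lw_ids,
             sprintf("F1S%02d", f2_sire)),
    dam = c(rep(NA, 2 * n_f1), mz_ids,
            sprintf("F1D%02d", f2_dam)),
    sex = c(rep("M", n_f1), rep("F", n_f1),
            rep(c("M", "F"), c(config$n_f1_sires, config$n_f1_dams)),
            sample(c("M", "F"), config$n_f2, replace = TRUE)),
    generation = c(rep("F0", 2 * n_f1), rep("F1", n_f1),
                   rep("F2", config$n_f2)),
    breed = c(rep("large_white", n_f1), rep("minzhu", n_f1),
              rep(NA, n_f1 + config$n_f2)),
    stringsAsFactors = FALSE)
  ped <- as_pedigree(ped)
  n_all <- nrow(ped)
  idx <- seq_len(n_all); names(idx) <- ped$id

  # --- founder haplotypes and gamete dropping (origin labels) --------------
  is_f0 <- ped$generation == "F0"
  n_chrom <- 2L * sum(is_f0)
  founder_hap <- matrix(0L, n_chrom, m)
  chrom_of <- matrix(NA_integer_, n_all, 2)  # F0 row -> its 2 chromosome ids
  k <- 0L
  for (i in which(is_f0)) {
    f <- freqs[if (ped$breed[i] == "minzhu") 1L else 2L, ]
    founder_hap[k + 1L, ] <- stats::rbinom(m, 1L, f)
    founder_hap[k + 2L, ] <- stats::rbinom(m, 1L, f)
    chrom_of[i, ] <- c(k + 1L, k + 2L)
    k <- k + 2L
  }
  o1 <- matrix(NA_integer_, n_all, m)   # paternal-origin chromosome ids
  o2 <- matrix(NA_integer_, n_all, m)   # maternal
  for (i in seq_len(n_all)) {
    if (is_f0[i]) {
      o1[i, ] <- chrom_of[i, 1]; o2[i, ] <- chrom_of[i, 2]
    } else {
      s <- idx[[ped$sire[i]]]; d <- idx[[ped$dam[i]]]
      o1[i, ] <- meiosis_origin(o1[s, ], o2[s, ], cm)
      o2[i, ] <- meiosis_origin(o1[d, ], o2[d, ], cm)
    }
  }
  rownames(o1) <- rownames(o2) <- ped$id

  h <- haps_from_origin(founder_hap, o1, o2)
  dosage <- h$h1 + h$h2
  geno <- geno_matrix(dosage, map, phase = h)

  # --- polygenic cascade ---------------------------------------------------
  a <- numeric(n_all); names(a) <- ped$id
  sa <- config$sigma2_a
  for (i in seq_len(n_all)) {
    if (is.na(ped$sire[i])) {
      a[i] <- stats::rnorm(1, 0, sqrt(sa))
    } else {
      a[i] <- 0.5 * (a[idx[[ped$sire[i]]]] + a[idx[[ped$dam[i]]]]) +
        stats::rnorm(1, 0, sqrt(sa / 2))
    }
  }

  # --- phenotypes (F2 only) ------------------------------------------------
  f2 <- which(ped$generation == "F2")
  n <- length(f2)
  sex <- ped$sex[f2]
  parity_l <- sample.int(config$n_parity, config$n_litters, replace = TRUE)
  parity <- parity_l[f2_litter]
  batch <- sample(rep_len(seq_len(config$n_batches), n))
  batch_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  litter_eff <- stats::rnorm(config$n_litters, 0, sqrt(config$sigma2_c))
  weight <- stats::rnorm(n, config$body_weight_mean, config$body_weight_sd)
  qtl_dosage <- dosage[f2, qi]
  a_q <- sqrt(2 * config$qtl_variance_fraction * config$var_p)
  parity_levels <- seq(-1, 1, length.out = config$n_parity) *
    config$parity_effect
  mu <- config$trait_mean -
    config$body_weight_slope * config$body_weight_mean
  e <- stats::rnorm(n, 0, sqrt(config$sigma2_e))
  y <- mu + ifelse(sex == "M", 1, -1) * config$sex_effect +
    parity_levels[parity] + batch_eff[batch] +
    config$body_weight_slope * weight + litter_eff[f2_litter] +
    a[f2] + a_q * (qtl_dosage - 1) + e
  pheno <- data.frame(id = ped$id[f2], ear_area = y, sex = sex,
                      parity = paste0("P", parity),
                      batch = sprintf("B%02d", batch),
                      litter_id = sprintf("L%02d", f2_litter),
                      body_weight = weight, stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")

  truth <- list(
    founder_hap = founder_hap, origin = list(o1 = o1, o2 = o2),
    chrom_breed = rep(ped$breed[is_f0], each = 2),
    chrom_founder = rep(ped$id[is_f0], each = 2),
    qtl_marker = map$marker_id[qi], qtl_marker_index = qi,
    qtl_position_bp = pos[qi], qtl_effect = a_q,
    qtl_genotype = qtl_dosage, breeding_values = a,
    litter_effects = litter_eff, residuals = e,
    founder_breed_freqs = freqs,
    realized = c(sigma2_a = stats::var(a[f2]),
                 sigma2_e = stats::var(e),
                 var_qtl = stats::var(a_q * (qtl_dosage - 1))))
  structure(list(genotypes = geno, pedigree = ped, phenotypes = pheno,
                 truth = truth, config = config),
            class = "sim_cross")
}

# Rebuild every haplotype from founder chromosomes + origin labels.
haps_from_origin <- function(founder_hap, o1, o2) {
  m <- ncol(o1)
  jj <- rep(seq_len(m), each = nrow(o1))
  h1 <- matrix(founder_hap[cbind(as.vector(o1), jj)], nrow(o1), m)
  h2 <- matrix(founder_hap[cbind(as.vector(o2), jj)], nrow(o2), m)
  rownames(h1) <- rownames(h2) <- rownames(o1)
  list(h1 = h1, h2 = h2)
}

#' Plant an identical haplotype on all Q-bearing founder chromosomes
#'
#' Overwrites the allele sequence of every Minzhu (Q-bearing) founder
#' chromosome over a contiguous marker interval with a single shared pattern,
#' then regenerates all descendant haplotypes from the stored
#' founder-of-origin labels, so Mendelian consistency is preserved.  Used to
#' create a ground-truth identity-by-descent segment for the haplotype
#' sharing detector.
#'
#' @param sim a `sim_cross` object from [simulate_cross()].
#' @param interval integer vector of marker indices (contiguous).
#' @return the modified `sim_cross` object.
#' @export
plant_shared_haplotype <- function(sim, interval) {
  stopifnot(inherits(sim, "sim_cross"))
  if (length(interval) == 0) stop("interval is empty")
  interval <- sort(as.integer(interval))
  m <- ncol(sim$truth$founder_hap)
  if (interval[1] < 1 || interval[length(interval)] > m)
    stop("interval outside marker map")
  if (!all(diff(interval) == 1L)) stop("interval must be contiguous")
  q_rows <- which(sim$truth$chrom_breed == "minzhu")
  pattern <- sim$truth$founder_hap[q_rows[1], interval]
  # keep the QTL allele itself intact (Q chromosomes are fixed there anyway)
  qi <- sim$truth$qtl_marker_index
  if (qi %in% interval) pattern[match(qi, interval)] <- 1L
  sim$truth$founder_hap[q_rows, interval] <-
    matrix(pattern, length(q_rows), length(interval), byrow = TRUE)
  h <- haps_from_origin(sim$truth$founder_hap, sim$truth$origin$o1,
                        sim$truth$origin$o2)
  sim$genotypes <- geno_matrix(h$h1 + h$h2, sim$genotypes$map, phase = h)
  sim$truth$planted_interval <- interval
  sim$truth$qtl_genotype <-
    sim$genotypes$dosage[names(sim$truth$qtl_genotype), qi]
  sim
}

#' Extract the phased haplotypes of a set of individuals
#'
#' @param sim a `sim_cross` object.
#' @param ids individual ids; defaults to the Minzhu founders (the Q-bearing
#'   animals).
#' @return 0/1 matrix with two rows (homologs) per individual.
#' @export
founder_haplotypes <- function(sim, ids = NULL) {
  stopifnot(inherits(sim, "sim_cross"))
  if (is.null(ids))
    ids <- sim$pedigree$id[!is.na(sim$pedigree$breed) &
                             sim$pedigree$breed == "minzhu"]
  h1 <- sim$genotypes$phase$h1[ids, , drop = FALSE]
  h2 <- sim$genotypes$phase$h2[ids, , drop = FALSE]
  out <- rbind(h1, h2)
  rownames(out) <- c(paste0(ids, ".1"), paste0(ids, ".2"))
  out[order(rep(seq_along(ids), 2)), , drop = FALSE]
}

#' Configuration for simulated breed panels (selective-sweep fixtures)
#'
#' Defaults follow the sweep design the package targets: a candidate region
#' genotyped in one case breed with extremely large ears (Erhualian-like,
#' n = 32) versus three control breeds (Duroc 38, Landrace 69, Large White
#' 95), with a contiguous run of markers fixed for one allele in the case
#' panel only.
#'
#' @param n_markers markers in the candidate region (default 40).
#' @param region_start_bp,region_end_bp region bounds (bp).
#' @param chromosome chromosome label.
#' @param run_start index of the first fixed-run marker (`NA` for no run).
#' @param run_length number of fixed markers (0 for no run).
#' @param panel_sizes named integer vector; first element is the case breed.
#' @param seed integer seed.
#' @return a list of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_markers = 40L, region_start_bp = 30.1e6,
                             region_end_bp = 40.9e6, chromosome = "5",
                             run_start = 17L, run_length = 6L,
                             panel_sizes = c(erhualian = 32L, duroc = 38L,
                                             landrace = 69L,
                                             large_white = 95L),
                             seed = 1L) {
  run <- if (is.na(run_start) || run_length == 0L) integer(0) else
    seq.int(run_start, run_start + run_length - 1L)
  if (length(run) && (run[1] < 1 || run[length(run)] > n_markers))
    stop("fixed run outside marker range")
  structure(list(n_markers = as.integer(n_markers),
                 region_start_bp = region_start_bp,
                 region_end_bp = region_end_bp, chromosome = chromosome,
                 run = run, panel_sizes = panel_sizes,
                 seed = as.integer(seed)),
            class = "sweep_sim_config")
}

#' Simulate case/control breed genotype panels for sweep detection
#'
#' The case panel is monomorphic (allele2 frequency 1) at every marker of the
#' configured run and polymorphic elsewhere; control panels are drawn from
#' allele frequencies bounded away from fixation everywhere.
#'
#' @param config a [sweep_sim_config()].
#' @return named list of [geno_matrix()], one per breed, case first.
#' @export
simulate_breed_panels <- function(config = sweep_sim_config()) {
  stopifnot(inherits(config, "sweep_sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  pos <- as.integer(round(seq(config$region_start_bp, config$region_end_bp,
                              length.out = m)))
  map <- data.frame(marker_id = sprintf("S%03d", seq_len(m)),
                    chromosome = config$chromosome, position_bp = pos,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  out <- list()
  for (b in seq_along(config$panel_sizes)) {
    n <- config$panel_sizes[[b]]
    f <- stats::runif(m, 0.25, 0.75)
    if (b == 1L && length(config$run)) f[config$run] <- 1
    dos <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), n, m)
    rownames(dos) <- sprintf("%s_%03d", names(config$panel_sizes)[b],
                             seq_len(n))
    out[[names(config$panel_sizes)[b]]] <- geno_matrix(dos, map)
  }
  out
}
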