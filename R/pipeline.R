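#' Annotate markers with their nearest feature
#'
#' A deliberately small BED-based annotator: each marker is matched against
#' the features on its chromosome and reported as `"within"` (distance 0)
#' when it falls inside one, otherwise with the bp distance to the nearest
#' feature edge.  BED input is 0-based half-open and converted to the
#' package's 1-based inclusive convention.
#'
#' @param map a marker map (`marker_id`, `chromosome`, `position_bp`, ...).
#' @param features BED file path or data.frame with columns `chr`, `start`,
#'   `end` and optionally `name`.
#' @return `data.frame` with `marker`, `chr`, `pos`, `feature`, `distance`
#'   (0 when inside), `within` (logical; `NA` feature/distance when the
#'   chromosome has no features).
#' @export
annotate_nearest <- function(map, features) {
  if (is.character(features)) {
    if (!file.exists(features)) stop("feature file not found: ", features)
    bed <- utils::read.table(features, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    features <- data.frame(chr = as.character(bed[[1]]),
                           start = as.numeric(bed[[2]]) + 1,
                           end = as.numeric(bed[[3]]),
                           name = if (ncol(bed) >= 4) bed[[4]] else
                             paste0("feature", seq_len(nrow(bed))),
                           stringsAsFactors = FALSE)
  }
  out <- data.frame(marker = map$marker_id, chr = map$chromosome,
                    pos = map$position_bp, feature = NA_character_,
                    distance = NA_real_, within = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(map))) {
    f <- features[features$chr == map$chromosome[i], , drop = FALSE]
    if (nrow(f) == 0) next
    p <- map$position_bp[i]
    d <- ifelse(p < f$start, f$start - p, ifelse(p > f$end, p - f$end, 0))
    k <- which.min(d)
    out$feature[i] <- f$name[k]
    out$distance[i] <- d[k]
    out$within[i] <- d[k] == 0
  }
  out
}

#' Run the full fine-mapping pipeline on synthetic data
#'
#' Orchestrates simulation, quality control, GRAMMAR-GC association,
#' conditional analysis, MASS sire classification, haplotype-block /
#' haplotype-sharing interval refinement and selective-sweep detection as
#' one configured, seeded run.  Stage outputs feed the next stage; the
#' returned report records significant-marker counts, sire classifications,
#' the refined interval(s) and sweep intervals.  Identical config and seed
#' give identical reports.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised fields: `seed` (master seed; per-stage seeds are derived by
#'   fixed offsets), `stages` (subset of `c("qc", "gwas", "conditional",
#'   "mass", "haplotypes", "sweep")`), `alpha` (genome-wide level, default
#'   0.01), `qc` (threshold list for [iterative_qc()]), `min_run`,
#'   `sim` / `sweep_sim` (argument lists for [sim_config()] /
#'   [sweep_sim_config()]), `out_dir` (optional; TSV outputs are written
#'   there), `features_bed` (optional BED for annotation).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("qc", "gwas", "conditional", "mass", "haplotypes", "sweep")
  stages <- config$stages %||% stages_all
  if (!length(stages)) stop("no stages enabled")
  stages <- match.arg(stages, stages_all, several.ok = TRUE)
  if (any(c("conditional", "mass", "haplotypes") %in% stages) &&
      !"gwas" %in% stages)
    stop("stages conditional/mass/haplotypes require the gwas stage")
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.01
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(seed = seed, stages = stages)

  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  sim <- simulate_cross(do.call(sim_config, sim_args))
  # founder identity-by-descent around the QTL: the Q-bearing founder
  # chromosomes share a segment, as the haplotype-sharing stage assumes
  if (isTRUE(config$plant_shared %||% TRUE)) {
    qi <- sim$truth$qtl_marker_index
    span <- config$plant_span %||% 10L
    iv <- max(1, qi - ceiling(span / 2) + 1):min(ncol(sim$genotypes$dosage),
                                                 qi + floor(span / 2))
    sim <- plant_shared_haplotype(sim, iv)
  }
  ped <- sim$pedigree
  pheno <- sim$phenotypes
  g_f2 <- subset_geno(sim$genotypes, individuals = pheno$id)
  report$input_dim <- dim(g_f2)

  if ("qc" %in% stages) {
    qc <- iterative_qc(g_f2, config$qc %||%
                         list(snp_call = 0.90, maf = 0.03, hwe = 1e-6,
                              sample_call = 0.90))
    g_f2 <- qc$genotypes
    pheno <- pheno[pheno$id %in% rownames(g_f2$dosage), , drop = FALSE]
    report$qc <- list(n_iterations = qc$report$n_iterations,
                      n_excluded_snps = nrow(qc$report$excluded_snps),
                      n_excluded_samples = nrow(qc$report$excluded_samples),
                      surviving = c(qc$report$n_samples, qc$report$n_snps))
    emit(qc$report$excluded_snps, "qc_excluded_snps")
  }

  results <- NULL; threshold <- NULL; top <- NULL
  A <- relationship_matrix(ped)
  if ("gwas" %in% stages) {
    gw <- grammar_gwas(pheno, ped, g_f2, A = A)
    results <- gw$results
    threshold <- bonferroni_threshold(alpha, sum(results$tested))
    sig <- results[results$tested & results$P < threshold, , drop = FALSE]
    top <- if (nrow(sig)) sig$marker[which.min(sig$P)] else
      results$marker[which.min(results$P)]
    report$gwas <- list(lambda = gw$lambda, threshold = threshold,
                        n_tested = sum(results$tested),
                        n_significant = nrow(sig), top_marker = top,
                        varcomp = gw$fit$varcomp)
    report$significant_markers <- sig$marker
    emit(results, "gwas_results")
  }

  if ("conditional" %in% stages) {
    cs <- conditional_scan(pheno, ped, g_f2, top, A = A)
    csig <- cs$results[cs$results$tested & cs$results$P < threshold, ,
                       drop = FALSE]
    report$conditional <- list(conditioned_on = top, lambda = cs$lambda,
                               n_significant = nrow(csig),
                               significant_markers = csig$marker)
    emit(cs$results, "conditional_results")
  }

  if ("mass" %in% stages) {
    sires <- ped$id[ped$generation == "F1" & ped$sex == "M"]
    ji <- match(top, g_f2$map$marker_id)
    jwin <- resolve_markers(sim$genotypes, g_f2$map$marker_id[
      max(1, ji - 5):min(ncol(g_f2$dosage), ji + 5)])
    mass <- lapply(sires, function(s) {
      off_ids <- ped$id[!is.na(ped$sire) & ped$sire == s]
      off_ids <- intersect(off_ids, pheno$id)
      phase <- list(h1 = sim$genotypes$phase$h1[s, ],
                    h2 = sim$genotypes$phase$h2[s, ])
      dams <- ped$dam[match(off_ids, ped$id)]
      dd <- sim$genotypes$dosage[dams, , drop = FALSE]
      mass_analysis(s, phase, subset_geno(sim$genotypes,
                                          individuals = off_ids),
                    pheno, jwin, dam_dosage = dd)
    })
    calls <- vapply(mass, function(x) x$classification, "")
    report$mass <- data.frame(
      sire = sires, n1 = vapply(mass, function(x) x$n1, 0L),
      n2 = vapply(mass, function(x) x$n2, 0L),
      Z = vapply(mass, function(x) x$Z, 0),
      classification = calls, stringsAsFactors = FALSE)
    emit(report$mass, "mass_results")
  }

  if ("haplotypes" %in% stages) {
    sig_id <- report$significant_markers
    refined <- NULL
    if (length(sig_id) >= 2) {
      jj <- resolve_markers(g_f2, sig_id)
      pos <- g_f2$map$position_bp[jj]
      gwas_iv <- data.frame(start = min(pos), end = max(pos))
      q_haps <- founder_haplotypes(sim)[, jj, drop = FALSE]
      segs <- shared_segments(q_haps, g_f2$map[jj, , drop = FALSE])
      share_iv <- segs[segs$n_markers >= 2, c("start_bp", "end_bp"),
                       drop = FALSE]
      names(share_iv) <- c("start", "end")
      refined <- if (nrow(share_iv)) intersect_intervals(gwas_iv, share_iv)
      else gwas_iv
      ji <- match(top, g_f2$map$marker_id)
      win <- intersect(jj, max(1, ji - 2):min(ncol(g_f2$dosage), ji + 2))
      if (length(win) < 2) win <- max(1, ji - 1):min(ncol(g_f2$dosage),
                                                     ji + 1)
      hs <- hap_score_test(g_f2, win,
                           trait = stats::setNames(pheno$ear_area, pheno$id))
      report$haplotypes <- list(n_shared_segments = nrow(segs),
                                shared_segments = segs,
                                refined_interval = refined,
                                hap_global_stat = hs$global_stat,
                                hap_global_P = hs$global_P, hap_df = hs$df)
      emit(segs, "shared_segments")
      if (!is.null(refined)) emit(refined, "refined_interval")
    } else {
      report$haplotypes <- list(n_shared_segments = 0L,
                                refined_interval = NULL)
    }
  }

  if ("sweep" %in% stages) {
    sw_args <- config$sweep_sim %||% list()
    sw_args$seed <- seed + 1000L
    panels <- simulate_breed_panels(do.call(sweep_sim_config, sw_args))
    sweeps <- detect_sweep(panels[[1]], panels[-1],
                           min_run = config$min_run %||% 4L)
    report$sweep <- sweeps
    emit(sweeps, "sweep_intervals")
  }

  if (!is.null(config$features_bed) && !is.null(results)) {
    ann <- annotate_nearest(g_f2$map, config$features_bed)
    report$annotation <- ann
    emit(ann, "annotation")
  }

  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "| stages:",
      paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$gwas))
    cat("  gwas: lambda=", round(x$gwas$lambda, 3), ", ",
        x$gwas$n_significant, " significant (P < ",
        signif(x$gwas$threshold, 3), "), top ", x$gwas$top_marker, "\n",
        sep = "")
  if (!is.null(x$conditional))
    cat("  conditional:", x$conditional$n_significant,
        "significant after conditioning on", x$conditional$conditioned_on,
        "\n")
  if (!is.null(x$mass))
    cat("  mass:", sum(x$mass$classification == "Qq"), "of",
        nrow(x$mass), "sires Qq\n")
  if (!is.null(x$haplotypes$refined_interval) &&
      nrow(x$haplotypes$refined_interval))
    cat("  refined interval:",
        paste(sprintf("%.2f-%.2f Mb",
                      x$haplotypes$refined_interval$start / 1e6,
                      x$haplotypes$refined_interval$end / 1e6),
              collapse = "; "), "\n")
  if (!is.null(x$sweep))
    cat("  sweep intervals:", nrow(x$sweep), "\n")
  invisible(x)
}
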