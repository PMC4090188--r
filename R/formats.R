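#' Construct a genotype matrix
#'
#' The central genotype container of the package: an individuals x markers
#' matrix of allele dosages (copies of `allele2`, so 0/1/2 with `NA` for
#' missing calls) together with its marker map and, optionally, phased
#' haplotypes.
#'
#' @param dosage integer matrix, individuals in rows (rownames are individual
#'   ids), markers in columns (colnames are marker ids); entries in
#'   `c(0, 1, 2, NA)` counting copies of `allele2`.
#' @param map marker map `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based), `allele1`, `allele2`; one row per dosage column,
#'   same order.
#' @param phase optional list with elements `h1` and `h2`: 0/1 matrices of the
#'   same shape as `dosage` giving the allele2 count carried by each homolog,
#'   so `h1 + h2 == dosage` wherever `dosage` is non-missing.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, phase = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  validate_marker_map(map)
  if (ncol(dosage) != nrow(map))
    stop("dosage has ", ncol(dosage), " marker columns but map has ",
         nrow(map), " rows", call. = FALSE)
  if (is.null(rownames(dosage)) && nrow(dosage) > 0)
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  colnames(dosage) <- map$marker_id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(phase)) {
    stopifnot(is.list(phase), all(c("h1", "h2") %in% names(phase)))
    h <- phase$h1 + phase$h2
    ok <- is.na(dosage) | h == dosage
    if (!all(ok))
      stop("phase haplotypes do not sum to dosage", call. = FALSE)
    dimnames(phase$h1) <- dimnames(phase$h2) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, map = map, phase = phase),
            class = "geno_matrix")
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_bp", "allele1", "allele2")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker id: ",
         map$marker_id[duplicated(map$marker_id)][1], call. = FALSE)
  if (any(map$position_bp <= 0))
    stop("position_bp must be positive", call. = FALSE)
  for (chr in unique(map$chromosome)) {
    p <- map$position_bp[map$chromosome == chr]
    if (is.unsorted(p, strictly = TRUE))
      stop("markers on chromosome ", chr,
           " are not in strictly increasing bp order", call. = FALSE)
  }
  invisible(map)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " markers",
      if (!is.null(x$phase)) " (phased)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or markers
#'
#' @param g a [geno_matrix()].
#' @param individuals,markers index vectors (logical, integer or names);
#'   `NULL` keeps everything.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ii <- if (is.null(individuals)) seq_len(nrow(g$dosage)) else individuals
  if (is.character(ii)) ii <- match(ii, rownames(g$dosage))
  jj <- if (is.null(markers)) seq_len(ncol(g$dosage)) else markers
  if (is.character(jj)) jj <- match(jj, g$map$marker_id)
  phase <- g$phase
  if (!is.null(phase))
    phase <- list(h1 = phase$h1[ii, jj, drop = FALSE],
                  h2 = phase$h2[ii, jj, drop = FALSE])
  geno_matrix(g$dosage[ii, jj, drop = FALSE],
              g$map[jj, , drop = FALSE], phase = phase)
}

#' Read genotypes from PED/MAP text files
#'
#' Whitespace-delimited PED with the six standard leading columns
#' (family, individual, sire, dam, sex, phenotype) followed by two allele
#' characters per marker; MAP with columns chromosome, marker id, cM
#' (optional), bp position, and optionally the two allele labels.  Unknown
#' allele characters (`"0"`, `"N"`) become missing.  Dosage counts copies of
#' `allele2`; when the MAP does not carry allele labels they are taken from
#' the data, sorted so `allele1 < allele2`.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(mp) == 3L)
    mp <- data.frame(V1 = mp[[1]], V2 = mp[[2]], V3 = "0", V4 = mp[[3]])
  if (ncol(mp) < 4L) stop("MAP file must have at least 3 columns")
  map <- data.frame(marker_id = mp[[2]], chromosome = mp[[1]],
                    position_bp = as.integer(mp[[4]]),
                    allele1 = if (ncol(mp) >= 6L) mp[[5]] else NA_character_,
                    allele2 = if (ncol(mp) >= 6L) mp[[6]] else NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker id in MAP: ",
         map$marker_id[duplicated(map$marker_id)][1])
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("PED file is empty: ", ped_path)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 6L)
      stop("PED line ", i, ": fewer than 6 leading columns")
    gcols <- length(f) - 6L
    if (gcols %% 2L != 0L)
      stop("PED line ", i, ": odd number of allele columns (", gcols, ")")
    if (gcols / 2L != m)
      stop("PED line ", i, ": ", gcols / 2L,
           " markers but MAP has ", m)
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, gcols, by = 2L)]
    a2[i, ] <- al[seq(2L, gcols, by = 2L)]
  }
  a1[a1 %in% c("0", "N", ".")] <- NA
  a2[a2 %in% c("0", "N", ".")] <- NA
  dosage <- matrix(NA_integer_, n, m, dimnames = list(ids, map$marker_id))
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2L)
      stop("marker ", map$marker_id[j], ": more than two alleles observed")
    if (is.na(map$allele1[j])) {
      map$allele1[j] <- if (length(obs) >= 1L) obs[1] else "A"
      map$allele2[j] <- if (length(obs) == 2L) obs[2] else "0"
    }
    dosage[, j] <- (a1[, j] == map$allele2[j]) + (a2[, j] == map$allele2[j])
  }
  geno_matrix(dosage, map)
}

#' Write genotypes as PED/MAP text files
#'
#' Inverse of [read_genotypes()]: the MAP is written with six columns
#' (chromosome, id, cM=0, bp, allele1, allele2) so that a round trip
#' reproduces the dosage coding exactly; missing dosages become `0 0`.
#'
#' @param g a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @export
write_genotypes <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- g$map
  utils::write.table(
    data.frame(map$chromosome, map$marker_id, 0L, map$position_bp,
               map$allele1, map$allele2),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage)
  out <- character(n)
  for (i in seq_len(n)) {
    d <- g$dosage[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, map$allele2, map$allele1))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, map$allele2, map$allele1))
    out[i] <- paste(c("FAM", rownames(g$dosage)[i], "0", "0", "0", "-9",
                      as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(NULL)
}

#' Read a pedigree table
#'
#' Delimited text with header; required columns `id`, `sire`, `dam`, `sex`,
#' `generation`; optional `breed` (founder breed of F0 animals).  Unknown
#' parents are coded `"0"`, `""` or `NA`.  Records are returned topologically
#' sorted (parents before offspring) and every named parent must itself have
#' a record.
#'
#' @param path file path (comma- or tab-separated, autodetected).
#' @return a `data.frame` of class `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- read_delimited(path)
  need <- c("id", "sire", "dam", "sex", "generation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree file is missing column(s): ", paste(miss, collapse = ", "))
  if (!"breed" %in% names(df)) df$breed <- NA_character_
  as_pedigree(df)
}

#' Coerce a data frame to a pedigree
#'
#' @param df data frame with columns `id`, `sire`, `dam`, `sex`,
#'   `generation`, optionally `breed`.
#' @return topologically sorted `data.frame` of class `pedigree`.
#' @export
as_pedigree <- function(df) {
  df$id <- as.character(df$id)
  for (col in c("sire", "dam")) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "") | is.na(v)] <- NA
    df[[col]] <- v
  }
  if (anyDuplicated(df$id))
    stop("duplicate individual id in pedigree: ",
         df$id[duplicated(df$id)][1])
  for (col in c("sire", "dam")) {
    orphan <- setdiff(stats::na.omit(df[[col]]), df$id)
    if (length(orphan))
      stop("pedigree ", col, " '", orphan[1], "' has no record of its own")
  }
  ord <- pedigree_toposort(df$id, df$sire, df$dam)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn's algorithm; errors on cycles.
pedigree_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  parents <- cbind(unname(idx[sire]), unname(idx[dam]))
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[i, ]) if (!is.na(p))
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("pedigree contains a cycle")
  out
}

#' Read a phenotype/covariate table
#'
#' Required columns: `id`, `ear_area` (cm^2, positive), `sex`, `parity`,
#' `batch` (slaughter group), `litter_id`, `body_weight` (kg).  Category
#' labels are kept verbatim as character columns.
#'
#' @param path file path.
#' @param pedigree optional [as_pedigree()] object; if given, every
#'   phenotyped individual must appear in it.
#' @return a `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  df <- read_delimited(path)
  need <- c("id", "ear_area", "sex", "parity", "batch", "litter_id",
            "body_weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file is missing column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$ear_area <- as.numeric(df$ear_area)
  df$body_weight <- as.numeric(df$body_weight)
  for (col in c("sex", "parity", "batch", "litter_id"))
    df[[col]] <- as.character(df[[col]])
  if (any(!is.finite(df$ear_area)) || any(df$ear_area <= 0))
    stop("ear_area must be positive and finite")
  if (anyDuplicated(df$id))
    stop("duplicate individual in phenotype table: ",
         df$id[duplicated(df$id)][1])
  if (!is.null(pedigree)) {
    missing_ind <- setdiff(df$id, pedigree$id)
    if (length(missing_ind))
      stop("phenotyped individual absent from pedigree: ", missing_ind[1])
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write association results as TSV
#'
#' Fixed column order `marker, chr, pos, effect, se, T2, T2_gc, P, var_pct`;
#' P-values written with 15 significant digits so that a round trip through
#' [read_results()] is numerically faithful.
#'
#' @param results association result `data.frame` (see [residual_scan()]).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- c("marker", "chr", "pos", "effect", "se", "T2", "T2_gc", "P",
            "var_pct")
  miss <- setdiff(cols, names(results))
  if (length(miss))
    stop("results are missing column(s): ", paste(miss, collapse = ", "))
  out <- results[cols]
  for (col in c("effect", "se", "T2", "T2_gc", "P", "var_pct"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.15g", out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read association results written by [write_results()]
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("effect", "se", "T2", "T2_gc", "P", "var_pct"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

# Autodetect comma vs tab; header always present.
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a significant-SNP summary table
#'
#' Reads the tab-separated summary tables shipped under `inst/extdata`
#' (columns `marker, chr, pos, nearest_gene, distance, P, var_pct`), typing
#' the numeric columns.
#'
#' @param path file path; see
#'   `system.file("extdata", "table1_snps.tsv", package = "earmap")`.
#' @return a typed `data.frame`.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$pos <- as.numeric(df$pos)
  df$P <- as.numeric(df$P)
  df$var_pct <- as.numeric(df$var_pct)
  df
}

#' Recode haplotype alleles to the major/minor display convention
#'
#' For a set of haplotypes under joint display, the more frequent allele at
#' each marker is written `1` and the other `2` (frequency computed over the
#' displayed haplotypes; ties resolve to the allele2 coding being `2`).
#'
#' @param haps 0/1 matrix, haplotypes in rows (allele2 count per marker).
#' @return integer matrix of 1/2 codes, same shape.
#' @export
recode_major_minor <- function(haps) {
  stopifnot(is.matrix(haps))
  out <- matrix(0L, nrow(haps), ncol(haps), dimnames = dimnames(haps))
  for (j in seq_len(ncol(haps))) {
    f2 <- mean(haps[, j])           # frequency of allele2
    major_is_2 <- f2 > 0.5
    out[, j] <- ifelse(haps[, j] == as.integer(major_is_2), 1L, 2L)
  }
  out
}
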