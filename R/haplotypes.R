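# Symmetric generalized inverse via eigendecomposition; also reports rank.
sym_ginv <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-300)
  rank <- sum(keep)
  if (rank == 0) return(list(inv = M * 0, rank = 0L))
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, rank = rank)
}

resolve_markers <- function(g, markers) {
  if (is.character(markers)) {
    jj <- match(markers, g$map$marker_id)
    if (anyNA(jj)) stop("marker not in map: ", markers[is.na(jj)][1])
    jj
  } else as.integer(markers)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Enumerates, per individual, every diplotype compatible with the observed
#' multilocus genotype (individuals with a missing call in the window are
#' excluded), starts from a flat frequency vector over the observed
#' haplotypes, and iterates expectation-maximization until the largest
#' frequency change falls below `tol`.  The log-likelihood is non-decreasing
#' across iterations.
#'
#' @param g a [geno_matrix()].
#' @param markers marker ids or indices of the window (at most 12; wider
#'   windows must be split).
#' @param tol convergence tolerance on the frequency vector (default 1e-8).
#' @param max_iter iteration cap.
#' @return list of class `hap_freq`: `freq` (named by allele string),
#'   `hap_alleles` (0/1 matrix, one row per haplotype), `posterior` (matrix
#'   with columns `individual`, `h1`, `h2`, `prob` as indices into the
#'   haplotype table), `individuals`, `logLik`, `n_iter`, `converged`.
#' @export
em_haplotype_frequencies <- function(g, markers, tol = 1e-8,
                                     max_iter = 5000L) {
  stopifnot(inherits(g, "geno_matrix"))
  jj <- resolve_markers(g, markers)
  L <- length(jj)
  if (L > 12) stop("window too large (", L, " markers); split into <= 12")
  D <- g$dosage[, jj, drop = FALSE]
  ok <- rowSums(is.na(D)) == 0
  D <- D[ok, , drop = FALSE]
  if (nrow(D) == 0) stop("no individuals completely genotyped in window")
  pow2 <- 2L^(seq_len(L) - 1L)

  # enumerate compatible ordered-up-to-swap diplotypes per individual
  ind <- integer(0); c1 <- integer(0); c2 <- integer(0)
  for (i in seq_len(nrow(D))) {
    d <- D[i, ]
    het <- which(d == 1L)
    base <- sum(pow2[d == 2L])
    if (!length(het)) {
      ind <- c(ind, i); c1 <- c(c1, base); c2 <- c(c2, base)
    } else {
      k <- length(het)
      # fix first het allele on h1 to avoid double counting swapped pairs
      combos <- if (k == 1L) matrix(1L, 1, 1) else
        as.matrix(expand.grid(rep(list(0:1), k - 1L)))
      for (r in seq_len(nrow(combos))) {
        bits <- c(1L, if (k > 1L) as.integer(combos[r, ]))
        h1 <- base + sum(pow2[het][bits == 1L])
        h2 <- base + sum(pow2[het][bits == 0L])
        ind <- c(ind, i); c1 <- c(c1, h1); c2 <- c(c2, h2)
      }
    }
  }
  codes <- sort(unique(c(c1, c2)))
  i1 <- match(c1, codes); i2 <- match(c2, codes)
  H <- length(codes)
  mult <- ifelse(i1 == i2, 1, 2)
  p <- rep(1 / H, H)
  ll_old <- -Inf
  n <- nrow(D)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- mult * p[i1] * p[i2]
    tot <- rowsum(w, ind)[, 1]
    ll <- sum(log(tot))
    wn <- w / tot[match(ind, sort(unique(ind)))]
    cnt <- rowsum(c(wn, wn), c(i1, i2))[, 1]
    idx <- sort(unique(c(i1, i2)))
    p_new <- numeric(H)
    p_new[idx] <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; converged <- TRUE;
      ll_old <- ll; break }
    p <- p_new
    ll_old <- ll
  }
  hap_alleles <- matrix(0L, length(codes), L)
  for (j in seq_len(L))
    hap_alleles[, j] <- as.integer(bitwAnd(codes, pow2[j]) > 0)
  a1 <- g$map$allele1[jj]; a2 <- g$map$allele2[jj]
  hap_str <- vapply(seq_len(nrow(hap_alleles)), function(r)
    paste(ifelse(hap_alleles[r, ] == 1L, a2, a1), collapse = ""),
    character(1))
  names(p) <- hap_str
  post_w <- mult * p[i1] * p[i2]
  tot <- rowsum(post_w, ind)[, 1]
  post_w <- post_w / tot[match(ind, sort(unique(ind)))]
  structure(list(freq = p, hap_alleles = hap_alleles,
                 posterior = cbind(individual = ind, h1 = i1, h2 = i2,
                                   prob = post_w),
                 individuals = rownames(D), logLik = ll_old, n_iter = iter,
                 converged = converged, markers = g$map$marker_id[jj]),
            class = "hap_freq")
}

# Expected per-individual haplotype dosages from the EM posterior.
hap_dosages <- function(hf) {
  n <- length(hf$individuals)
  H <- length(hf$freq)
  X <- matrix(0, n, H, dimnames = list(hf$individuals, names(hf$freq)))
  po <- hf$posterior
  for (r in seq_len(nrow(po))) {
    i <- po[r, "individual"]
    X[i, po[r, "h1"]] <- X[i, po[r, "h1"]] + po[r, "prob"]
    X[i, po[r, "h2"]] <- X[i, po[r, "h2"]] + po[r, "prob"]
  }
  X
}

#' Pairwise linkage disequilibrium statistics
#'
#' Two-locus haplotype frequencies are estimated by EM from unphased
#' dosages; `D = p_22 - f1 * f2` (frequency of the allele2/allele2
#' haplotype minus the product of allele2 frequencies), `D' = D / Dmax`, and
#' `r^2 = D^2 / (f1 (1 - f1) f2 (1 - f2))`.
#'
#' @param g a [geno_matrix()].
#' @param m1,m2 marker ids or indices.
#' @return list of class `ld_stats`: `D`, `Dprime`, `r2`, `hap_freq`,
#'   allele2 frequencies `f1`, `f2`, and `n` individuals used.
#' @export
ld_pair <- function(g, m1, m2) {
  jj <- sort(resolve_markers(g, c(m1, m2)))
  sub <- subset_geno(g, markers = jj)
  maf <- minor_allele_frequency(sub)
  if (any(is.na(maf)) || any(maf == 0))
    stop("LD undefined: monomorphic marker in pair")
  hf <- em_haplotype_frequencies(sub, 1:2)
  pfull <- numeric(4)                     # order: 00, 10, 01, 11 (allele2)
  codes <- hf$hap_alleles[, 1] + 2 * hf$hap_alleles[, 2]
  pfull[codes + 1] <- hf$freq
  f1 <- pfull[2] + pfull[4]
  f2 <- pfull[3] + pfull[4]
  D <- pfull[4] - f1 * f2
  dmax <- if (D >= 0) min(f1 * (1 - f2), (1 - f1) * f2) else
    min(f1 * f2, (1 - f1) * (1 - f2))
  structure(list(D = D, Dprime = if (dmax > 0) D / dmax else 0,
                 r2 = D^2 / (f1 * (1 - f1) * f2 * (1 - f2)),
                 hap_freq = hf$freq, f1 = f1, f2 = f2,
                 n = length(hf$individuals)),
            class = "ld_stats")
}

# Likelihood-grid confidence bounds on |D'| for one marker pair
# (Haploview-style): the multinomial likelihood of the 3x3 genotype table is
# evaluated on a grid of |D'| values with allele frequencies fixed at their
# estimates and the sign of D at its EM estimate, normalized, and the 5th /
# 95th percentiles of the resulting distribution are returned.
dprime_ci <- function(x1, x2, grid = seq(0, 1, by = 0.01)) {
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  f1 <- mean(x1) / 2; f2 <- mean(x2) / 2
  if (f1 %in% c(0, 1) || f2 %in% c(0, 1)) return(c(low = NA, high = NA))
  counts <- table(factor(x1, 0:2), factor(x2, 0:2))
  # EM estimate of D for the sign
  p11 <- em2_p11(x1, x2, f1, f2)
  s <- if (p11 - f1 * f2 >= 0) 1 else -1
  dmax <- if (s > 0) min(f1 * (1 - f2), (1 - f1) * f2) else
    min(f1 * f2, (1 - f1) * (1 - f2))
  # ordered hap-pair -> genotype cell bookkeeping
  hb1 <- c(0, 1, 0, 1); hb2 <- c(0, 0, 1, 1)
  pair1 <- rep(1:4, times = 4); pair2 <- rep(1:4, each = 4)
  cell <- (hb1[pair1] + hb1[pair2]) + 3 * (hb2[pair1] + hb2[pair2]) + 1
  ll <- vapply(grid, function(dp) {
    D <- s * dp * dmax
    p <- c(1 - f1 - f2 + f1 * f2 + D, f1 - f1 * f2 - D,
           f2 - f1 * f2 - D, f1 * f2 + D)      # 00, 10, 01, 11
    if (any(p < -1e-12)) return(-Inf)
    p <- pmax(p, 1e-12)
    gp <- rowsum(p[pair1] * p[pair2], cell)[, 1]
    sum(as.vector(counts) * log(gp))
  }, numeric(1))
  like <- exp(ll - max(ll))
  cum <- cumsum(like) / sum(like)
  c(low = grid[which(cum >= 0.05)[1]], high = grid[which(cum >= 0.95)[1]])
}

# two-locus EM for the allele2/allele2 haplotype frequency (fast path used
# for the sign of D in dprime_ci)
em2_p11 <- function(x1, x2, f1, f2) {
  n <- length(x1)
  n11 <- sum(x1 == 2 & x2 == 2); n12 <- sum(x1 == 2 & x2 == 1)
  n21 <- sum(x1 == 1 & x2 == 2); ndh <- sum(x1 == 1 & x2 == 1)
  p11 <- f1 * f2
  for (it in 1:200) {
    p10 <- f1 - p11; p01 <- f2 - p11; p00 <- 1 - f1 - f2 + p11
    num <- p11 * p00
    den <- num + p10 * p01
    frac <- if (den > 0) num / den else 0.5
    p11_new <- (2 * n11 + n12 + n21 + frac * ndh) / (2 * n)
    p11_new <- min(max(p11_new, max(0, f1 + f2 - 1)), min(f1, f2))
    if (abs(p11_new - p11) < 1e-10) { p11 <- p11_new; break }
    p11 <- p11_new
  }
  p11
}

#' Detect haplotype blocks by D' confidence intervals
#'
#' Gabriel-style confidence-interval method: for every marker pair a
#' likelihood-grid confidence interval on |D'| classifies it as strong LD
#' (lower bound >= `strong_low`, upper >= `strong_high`), strong evidence of
#' recombination (upper < `recomb_high`), or uninformative.  A contiguous
#' marker run is a block when its outermost pair is in strong LD and at
#' least `min_frac` of its informative pairs are; blocks are taken greedily,
#' longest bp span first, non-overlapping.
#'
#' @param g a [geno_matrix()].
#' @param markers marker ids/indices to consider (default: all), in map
#'   order.
#' @param strong_low,strong_high,recomb_high CI bounds (defaults 0.70, 0.98,
#'   0.90).
#' @param min_frac minimum fraction of informative pairs in strong LD
#'   (default 0.95).
#' @param min_maf markers below this MAF are ignored (default 0.05).
#' @return `data.frame` with one row per block: first/last marker id and
#'   index, start/end bp, `span_bp = end - start`, `n_markers`.
#' @export
detect_blocks <- function(g, markers = NULL, strong_low = 0.70,
                          strong_high = 0.98, recomb_high = 0.90,
                          min_frac = 0.95, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  jj <- if (is.null(markers)) seq_len(ncol(g$dosage)) else
    resolve_markers(g, markers)
  maf <- minor_allele_frequency(subset_geno(g, markers = jj))
  usable <- !is.na(maf) & maf >= min_maf
  m <- length(jj)
  if (m < 2) stop("need at least 2 markers")
  state <- matrix(NA_integer_, m, m)      # 1 strong, -1 recomb, 0 uninf
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (!usable[a] || !usable[b]) { state[a, b] <- 0L; next }
    ci <- dprime_ci(g$dosage[, jj[a]], g$dosage[, jj[b]])
    state[a, b] <- if (anyNA(ci)) 0L
    else if (ci["low"] >= strong_low && ci["high"] >= strong_high) 1L
    else if (ci["high"] < recomb_high) -1L
    else 0L
  }
  cand <- list()
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (state[a, b] != 1L) next
    sub <- state[a:b, a:b]
    vals <- sub[upper.tri(sub)]
    ninf <- sum(vals != 0L)
    if (ninf == 0) next
    if (sum(vals == 1L) / ninf >= min_frac)
      cand[[length(cand) + 1]] <- c(a, b)
  }
  if (!length(cand))
    return(data.frame(first_marker = character(0), last_marker = character(0),
                      first_index = integer(0), last_index = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      span_bp = integer(0), n_markers = integer(0)))
  pos <- g$map$position_bp[jj]
  spans <- vapply(cand, function(ab) pos[ab[2]] - pos[ab[1]], numeric(1))
  ord <- order(-spans)
  taken <- rep(FALSE, m)
  out <- list()
  for (k in ord) {
    ab <- cand[[k]]
    if (any(taken[ab[1]:ab[2]])) next
    taken[ab[1]:ab[2]] <- TRUE
    out[[length(out) + 1]] <- ab
  }
  out <- out[order(vapply(out, `[`, numeric(1), 1))]
  data.frame(
    first_marker = vapply(out, function(ab) g$map$marker_id[jj[ab[1]]], ""),
    last_marker = vapply(out, function(ab) g$map$marker_id[jj[ab[2]]], ""),
    first_index = vapply(out, `[`, numeric(1), 1),
    last_index = vapply(out, `[`, numeric(1), 2),
    start_bp = vapply(out, function(ab) pos[ab[1]], numeric(1)),
    end_bp = vapply(out, function(ab) pos[ab[2]], numeric(1)),
    span_bp = vapply(out, function(ab) pos[ab[2]] - pos[ab[1]], numeric(1)),
    n_markers = vapply(out, function(ab) ab[2] - ab[1] + 1, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Haplotype score test for a quantitative trait
#'
#' Gaussian score test in the spirit of the classical haplotype-score
#' method: haplotype frequencies and posterior diplotype probabilities come
#' from [em_haplotype_frequencies()], each individual gets an expected
#' dosage of every common haplotype, and the score vector of the linear
#' model `trait ~ covariates + haplotype dosages` evaluated at the null fit
#' gives a per-haplotype z score (the hap-score; positive means the
#' haplotype increases the trait) with a normal P-value, plus a global
#' statistic `U' V^- U` compared to chi-square with `df = rank(V)` (one less
#' than the number of scored haplotypes when they jointly exhaust the
#' chromosomes).
#'
#' @param g a [geno_matrix()].
#' @param markers window marker ids or indices (<= 12).
#' @param trait named numeric vector (e.g. GRAMMAR residuals or raw trait);
#'   matched to individual ids.
#' @param covariates optional numeric matrix with rownames = ids.
#' @param min_freq haplotypes rarer than this are pooled out of scoring
#'   (default 0.02).
#' @return list of class `hap_score_result`: `scores` data.frame
#'   (`haplotype`, `freq`, `hap_score`, `P`), `global_stat`, `df`,
#'   `global_P`, `n`.
#' @export
hap_score_test <- function(g, markers, trait, covariates = NULL,
                           min_freq = 0.02) {
  hf <- em_haplotype_frequencies(g, markers)
  if (!hf$converged) stop("haplotype EM did not converge")
  ids <- intersect(hf$individuals, names(trait))
  if (length(ids) < 5) stop("too few individuals with trait and genotypes")
  Xh_all <- hap_dosages(hf)[ids, , drop = FALSE]
  keep <- hf$freq >= min_freq
  if (sum(keep) < 1) stop("no haplotype above the pooling frequency")
  Xh <- Xh_all[, keep, drop = FALSE]
  y <- trait[ids]
  X <- cbind(`(Intercept)` = rep(1, length(ids)))
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
  XtXinv <- solve(crossprod(X))
  bhat <- XtXinv %*% crossprod(X, y)
  r <- y - drop(X %*% bhat)
  s2 <- sum(r^2) / (length(y) - ncol(X))
  U <- drop(crossprod(Xh, r)) / s2
  M <- crossprod(Xh) - crossprod(Xh, X) %*% XtXinv %*% crossprod(X, Xh)
  V <- M / s2
  z <- U / sqrt(pmax(diag(V), 1e-300))
  gi <- sym_ginv(V)
  stat <- drop(t(U) %*% gi$inv %*% U)
  structure(list(
    scores = data.frame(haplotype = colnames(Xh),
                        freq = unname(hf$freq[keep]), hap_score = z,
                        P = 2 * stats::pnorm(-abs(z)),
                        stringsAsFactors = FALSE, row.names = NULL),
    global_stat = stat, df = gi$rank,
    global_P = stats::pchisq(stat, df = gi$rank, lower.tail = FALSE),
    n = length(ids), pooled = names(hf$freq)[!keep]),
    class = "hap_score_result")
}

#' @export
print.hap_score_result <- function(x, ...) {
  print(transform(x$scores, freq = round(freq, 4),
                  hap_score = round(hap_score, 4), P = signif(P, 3)))
  cat("global score statistic = ", round(x$global_stat, 4), " (df = ",
      x$df, "), P = ", signif(x$global_P, 3), "\n", sep = "")
  invisible(x)
}

#' Maximal shared segments among a set of phased haplotypes
#'
#' Finds every maximal run of consecutive markers at which all input
#' haplotypes carry the identical allele; segment length is the bp span
#' between its first and last marker.  Segments are maximal, hence pairwise
#' non-adjacent.
#'
#' @param haps allele matrix (haplotypes in rows); any coding, no missing
#'   values (unphased/missing input is an error).
#' @param map marker map aligned with the columns.
#' @return `data.frame` with first/last marker, indices, bp bounds,
#'   `length_bp = end - start` and `n_markers` per segment.
#' @export
shared_segments <- function(haps, map) {
  if (!is.matrix(haps) || nrow(haps) < 2)
    stop("need a matrix of at least 2 phased haplotypes")
  if (anyNA(haps)) stop("haplotypes contain missing alleles; phase required")
  validate_marker_map(map)
  stopifnot(ncol(haps) == nrow(map))
  same <- colSums(haps != rep(haps[1, ], each = nrow(haps))) == 0
  r <- rle(same)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    first_marker = map$marker_id[starts[keep]],
    last_marker = map$marker_id[ends[keep]],
    first_index = starts[keep], last_index = ends[keep],
    start_bp = map$position_bp[starts[keep]],
    end_bp = map$position_bp[ends[keep]],
    length_bp = map$position_bp[ends[keep]] - map$position_bp[starts[keep]],
    n_markers = ends[keep] - starts[keep] + 1,
    stringsAsFactors = FALSE)
}

#' Intersect two interval lists
#'
#' Intervals are 1-based inclusive bp ranges on one chromosome; each list is
#' merged first, then the pairwise intersections are returned sorted.
#' Lengths are reported as `end - start`.
#'
#' @param a,b data.frames with columns `start` and `end` (bp).
#' @return `data.frame` with `start`, `end`, `length` (possibly 0 rows).
#' @export
intersect_intervals <- function(a, b) {
  merge_iv <- function(x) {
    if (nrow(x) == 0) return(x)
    x <- x[order(x$start), , drop = FALSE]
    out <- x[1, c("start", "end"), drop = FALSE]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], x$end[i])
      } else out <- rbind(out, x[i, c("start", "end")])
    }
    out
  }
  a <- merge_iv(as.data.frame(a)); b <- merge_iv(as.data.frame(b))
  res <- data.frame(start = numeric(0), end = numeric(0))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s <= e) res <- rbind(res, data.frame(start = s, end = e))
  }
  if (nrow(res)) {
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  res$length <- res$end - res$start
  res
}
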