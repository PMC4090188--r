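#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method on the topologically sorted pedigree: for individual i with
#' parents s and d, `A[i,i] = 1 + 0.5 * A[s,d]` and
#' `A[i,j] = 0.5 * (A[j,s] + A[j,d])` for earlier j; unknown parents
#' contribute zero (founders unrelated and non-inbred).
#'
#' @param ped a pedigree from [as_pedigree()] / [read_pedigree()].
#' @return symmetric matrix with individual ids as dimnames.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  if (any(si >= idx, na.rm = TRUE) || any(di >= idx, na.rm = TRUE))
    stop("pedigree is not topologically sorted")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}

# Fixed-effect design for the Step-1 model: intercept, sex, parity, batch
# dummies, body-weight covariate, plus optional extra columns (conditional
# analysis).  Reduced to full column rank by pivoted QR; warns when columns
# are dropped.
build_design <- function(pheno, extra_fixed = NULL) {
  X <- stats::model.matrix(~ sex + parity + batch,
                           data.frame(sex = factor(pheno$sex),
                                      parity = factor(pheno$parity),
                                      batch = factor(pheno$batch)))
  X <- cbind(X, body_weight = pheno$body_weight)
  if (!is.null(extra_fixed)) {
    extra_fixed <- as.matrix(extra_fixed)
    if (is.null(colnames(extra_fixed)))
      colnames(extra_fixed) <- paste0("cond", seq_len(ncol(extra_fixed)))
    X <- cbind(X, extra_fixed)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("rank-deficient fixed effects; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Fit the polygenic mixed model and return GRAMMAR residuals
#'
#' Step 1 of the GRAMMAR procedure: the trait is modelled as
#' `y = X b + w p + T c + Z a + e` with fixed effects sex, parity and batch,
#' body-weight covariate, a random litter effect `c ~ N(0, I sc2)`, an
#' additive polygenic effect `a ~ N(0, A sa2)` (A from the pedigree) and
#' residual `e ~ N(0, I se2)`.  Variance components are estimated by
#' average-information REML (step-halved to keep the restricted
#' log-likelihood non-decreasing, gradient fallback when the AI matrix is not
#' positive definite, components projected to be non-negative), fixed effects
#' by generalized least squares and random effects by BLUP; the returned
#' residual is `y* = y - X bhat - w phat - T chat - Z ahat`, which equals
#' `se2 * P y`.
#'
#' @param pheno a [read_phenotypes()] table.
#' @param ped a [as_pedigree()] pedigree containing every phenotyped id.
#' @param extra_fixed optional numeric matrix of additional fixed covariates
#'   (rows aligned with `pheno`), e.g. a top-marker dosage for conditional
#'   analysis.
#' @param A optional precomputed relationship matrix (dimnames = ids).
#' @param max_iter,tol REML iteration cap and log-likelihood convergence
#'   tolerance.
#' @return an object of class `grammar_fit`: named residual vector, variance
#'   components, REML log-likelihood trace, convergence flag, fixed-effect
#'   estimates and BLUPs.
#' @export
fit_polygenic <- function(pheno, ped, extra_fixed = NULL, A = NULL,
                          max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(pheno, "data.frame"))
  ids <- pheno$id
  missing_ind <- setdiff(ids, ped$id)
  if (length(missing_ind))
    stop("phenotyped individual absent from pedigree: ", missing_ind[1])
  if (length(unique(pheno$litter_id)) < 2)
    stop("need at least 2 litters")
  if (is.null(A)) A <- relationship_matrix(ped)
  Aff <- A[ids, ids]
  y <- pheno$ear_area
  n <- length(y)
  X <- build_design(pheno, extra_fixed)
  Tm <- stats::model.matrix(~ 0 + factor(pheno$litter_id))
  TTt <- tcrossprod(Tm)
  vy <- stats::var(y)
  lb <- 1e-8 * vy
  theta <- c(sigma2_a = vy / 3, sigma2_c = vy / 3, sigma2_e = vy / 3)
  Vs <- list(Aff, TTt, diag(n))

  eval_point <- function(theta) {
    V <- theta[1] * Vs[[1]] + theta[2] * Vs[[2]] + theta[3] * Vs[[3]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    XtVinv <- crossprod(X, Vinv)
    XtVX <- XtVinv %*% X
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    XtVXinv <- chol2inv(cX)
    P <- Vinv - t(XtVinv) %*% XtVXinv %*% XtVinv
    Py <- P %*% y
    logL <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                      drop(crossprod(y, Py)))
    list(V = V, Vinv = Vinv, XtVXinv = XtVXinv, XtVinv = XtVinv, P = P,
         Py = Py, logL = logL)
  }

  st <- eval_point(theta)
  if (is.null(st)) stop("initial variance matrix not positive definite")
  trace <- st$logL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    PVi <- lapply(Vs, function(Vi) st$P %*% Vi)
    ViPy <- lapply(Vs, function(Vi) Vi %*% st$Py)
    score <- vapply(seq_len(3), function(i) {
      -0.5 * (sum(diag(PVi[[i]])) - drop(crossprod(st$Py, ViPy[[i]])))
    }, numeric(1))
    AI <- matrix(0, 3, 3)
    PViPy <- lapply(ViPy, function(v) st$P %*% v)
    for (i in 1:3) for (j in i:3)
      AI[i, j] <- AI[j, i] <- 0.5 * drop(crossprod(ViPy[[i]], PViPy[[j]]))
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta)))
      delta <- score * theta^2 * 2 / n          # gradient fallback
    step <- 1
    repeat {
      cand <- pmax(theta + step * delta, lb)
      st2 <- eval_point(cand)
      if (!is.null(st2) && st2$logL >= st$logL - 1e-10) break
      step <- step / 2
      if (step < 1e-10) { st2 <- st; cand <- theta; break }
    }
    dl <- st2$logL - st$logL
    theta <- cand; st <- st2
    trace <- c(trace, st$logL)
    if (abs(dl) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter,
         " iterations; logLik trace: ",
         paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", "))
  beta <- drop(st$XtVXinv %*% st$XtVinv %*% y)
  names(beta) <- colnames(X)
  chat <- theta[2] * drop(crossprod(Tm, st$Py))
  ahat <- theta[1] * drop(Aff %*% st$Py)
  resid <- theta[3] * drop(st$Py)
  names(resid) <- names(ahat) <- ids
  structure(list(residuals = resid, varcomp = theta, logLik = st$logL,
                 logLik_trace = trace, converged = converged, beta = beta,
                 blup_litter = chat, blup_animal = ahat, n = n,
                 design = X, ids = ids),
            class = "grammar_fit")
}

#' @export
print.grammar_fit <- function(x, ...) {
  cat("<grammar_fit> n =", x$n, "\n")
  print(round(x$varcomp, 4))
  cat("REML logLik:", round(x$logLik, 4), "\n")
  invisible(x)
}

#' Single-locus regression of GRAMMAR residuals on marker dosage
#'
#' Step 2: for each marker, the residual trait `y*` is regressed on allele
#' dosage; the allelic substitution effect `k`, its sampling variance and the
#' unadjusted statistic `T2 = k^2 / var(k)` are returned together with the
#' variance explained (100 * R^2 of the regression on `y*`).  Missing
#' dosages are dropped pairwise; monomorphic or all-missing markers are
#' flagged untested, not errors.
#'
#' @param fit a [fit_polygenic()] object (or any list with named element
#'   `residuals`).
#' @param g a [geno_matrix()]; individuals matched by id.
#' @return `data.frame` with columns `marker, chr, pos, effect, se, T2,
#'   T2_gc, P, var_pct, n_used, tested` (`T2_gc`/`P` filled by
#'   [genomic_control()]).
#' @export
residual_scan <- function(fit, g) {
  stopifnot(inherits(g, "geno_matrix"))
  ystar <- fit$residuals
  common <- intersect(names(ystar), rownames(g$dosage))
  if (!length(common)) stop("no individuals shared between residuals and genotypes")
  ystar <- ystar[common]
  D <- g$dosage[common, , drop = FALSE]
  m <- ncol(D)
  eff <- se <- T2 <- r2 <- rep(NA_real_, m)
  nuse <- integer(m)
  for (j in seq_len(m)) {
    ok <- !is.na(D[, j])
    nuse[j] <- sum(ok)
    if (nuse[j] < 3) next
    x <- D[ok, j]; yv <- ystar[ok]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next                     # monomorphic: skip with flag
    sxy <- sum((x - mean(x)) * (yv - mean(yv)))
    syy <- sum((yv - mean(yv))^2)
    k <- sxy / sxx
    rss <- syy - k * sxy
    vark <- rss / (nuse[j] - 2) / sxx
    eff[j] <- k
    se[j] <- sqrt(vark)
    T2[j] <- if (vark > 0) k^2 / vark else if (k == 0) 0 else Inf
    r2[j] <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  }
  data.frame(marker = g$map$marker_id, chr = g$map$chromosome,
             pos = g$map$position_bp, effect = eff, se = se, T2 = T2,
             T2_gc = NA_real_, P = NA_real_, var_pct = 100 * r2,
             n_used = nuse, tested = !is.na(T2), stringsAsFactors = FALSE)
}

#' Genomic-control adjustment of a residual scan
#'
#' The scan-wide deflation factor is `lambda = median(T2) / 0.456` (0.456
#' being the conventional printed value for the median of chi-square with
#' 1 df; set `gc_constant = qchisq(0.5, 1)` for the exact constant), each
#' statistic is divided by it, and P-values are taken from the upper tail of
#' chi-square(1).  `lambda` is applied as estimated even when below 1.
#'
#' @param results a [residual_scan()] table.
#' @param gc_constant divisor for the median (default 0.456 as printed).
#' @return the table with `T2_gc` and `P` filled; the deflation factor is
#'   attached as `attr(, "lambda")`.
#' @export
genomic_control <- function(results, gc_constant = 0.456) {
  T2 <- results$T2[results$tested]
  if (!length(T2)) stop("no tested markers")
  lambda <- stats::median(T2) / gc_constant
  if (lambda <= 0) stop("degenerate scan: all statistics zero")
  results$T2_gc <- results$T2 / lambda
  results$P <- stats::pchisq(results$T2_gc, df = 1, lower.tail = FALSE)
  attr(results, "lambda") <- lambda
  results
}

#' Bonferroni significance threshold
#'
#' @param alpha nominal genome-wide level in (0, 1).
#' @param n_tests number of tests performed.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' GRAMMAR-GC genome-wide association scan
#'
#' Runs Steps 1-3: polygenic REML fit, residual single-locus regression, and
#' genomic control.
#'
#' @inheritParams fit_polygenic
#' @param g a [geno_matrix()] of the phenotyped individuals (extra
#'   individuals are ignored).
#' @param gc_constant see [genomic_control()].
#' @return list with `results` (scan table with `T2_gc`, `P`), `lambda`,
#'   and `fit` (the `grammar_fit`).
#' @export
grammar_gwas <- function(pheno, ped, g, extra_fixed = NULL, A = NULL,
                         gc_constant = 0.456, ...) {
  fit <- fit_polygenic(pheno, ped, extra_fixed = extra_fixed, A = A, ...)
  res <- residual_scan(fit, g)
  res <- genomic_control(res, gc_constant = gc_constant)
  list(results = res, lambda = attr(res, "lambda"), fit = fit)
}

#' Conditional association scan on a top marker
#'
#' The dosage of `top_marker` is added to the fixed effects of the Step-1
#' model, the full three-step GRAMMAR-GC procedure is re-run, and the top
#' marker itself is excluded from the rescan.  Individuals missing the top
#' marker's genotype are dropped.
#'
#' @inheritParams grammar_gwas
#' @param top_marker marker id to condition on (must be polymorphic).
#' @return as [grammar_gwas()].
#' @export
conditional_scan <- function(pheno, ped, g, top_marker, A = NULL,
                             gc_constant = 0.456, ...) {
  j <- match(top_marker, g$map$marker_id)
  if (is.na(j)) stop("top marker not in genotype matrix: ", top_marker)
  dos <- g$dosage[match(pheno$id, rownames(g$dosage)), j]
  keep <- !is.na(dos)
  if (stats::var(dos[keep]) == 0)
    stop("top marker is monomorphic: ", top_marker)
  ph <- pheno[keep, , drop = FALSE]
  extra <- matrix(dos[keep], ncol = 1,
                  dimnames = list(NULL, paste0("g_", top_marker)))
  out <- grammar_gwas(ph, ped, g, extra_fixed = extra, A = A,
                      gc_constant = gc_constant, ...)
  out$results <- out$results[out$results$marker != top_marker, , drop = FALSE]
  attr(out$results, "lambda") <- out$lambda
  out$conditioned_on <- top_marker
  out
}

#' Variance explained by a marker
#'
#' Default definition: 100 times the R-squared of the Step-2 regression of
#' the GRAMMAR residual on marker dosage (the definition recorded in the
#' output metadata of [write_results()] consumers).
#'
#' @param result one row of a [residual_scan()] table, or the whole table.
#' @return percent variance explained.
#' @export
variance_explained <- function(result) {
  result$var_pct
}
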