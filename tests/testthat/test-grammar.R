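test_that("relationship matrix reproduces hand-tabulated kinship values", {
  ped <- toy_pedigree()
  A <- relationship_matrix(ped)
  founders <- c("s1", "d1", "d2")
  expect_equal(A[founders, founders], diag(3), ignore_attr = TRUE)
  expect_equal(A["s1", "o1"], 0.5)     # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)     # full sibs
  expect_equal(A["o1", "o3"], 0.25)    # half sibs
  expect_equal(A["inb", "inb"], 1.25)  # offspring of full sibs
  expect_equal(A["inb", "o1"], 0.75)
  # F2 x its F1 sire in a simulated design
  sim <- simulate_cross(sim_config(seed = 2, n_markers = 20))
  As <- relationship_matrix(sim$pedigree)
  f2 <- sim$pedigree$id[sim$pedigree$generation == "F2"][1]
  expect_equal(As[f2, sim$pedigree$sire[sim$pedigree$id == f2]], 0.5)
  # cycle detection
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = "M", generation = "F0")
  expect_error(as_pedigree(bad), "cycle")
})

test_that("polygenic fit degenerates to least squares without random variance", {
  sim <- simulate_cross(sim_config(seed = 5, qtl_variance_fraction = 0,
                                   sigma2_a = 0, sigma2_c = 0))
  ph <- sim$phenotypes
  fit <- fit_polygenic(ph, sim$pedigree)
  vp <- var(ph$ear_area)
  expect_lt(fit$varcomp[["sigma2_a"]] / vp, 0.1)
  expect_lt(fit$varcomp[["sigma2_c"]] / vp, 0.1)
  ols <- resid(lm(ear_area ~ factor(sex) + factor(parity) + factor(batch) +
                    body_weight, ph))
  expect_gt(cor(fit$residuals, ols), 0.99)
  # residuals orthogonal to every fixed-effect column (normal equations)
  X <- fit$design
  for (j in seq_len(ncol(X)))
    expect_lt(abs(sum(fit$residuals * X[, j])) /
                sqrt(sum(fit$residuals^2) * sum(X[, j]^2) + 1e-300), 1e-8)
  # REML log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$logLik_trace) > -1e-8))
})

test_that("REML recovers the simulated variance components on average", {
  nrep <- 20
  est <- matrix(0, nrep, 3)
  truth <- NULL
  for (s in seq_len(nrep)) {
    cfg <- sim_config(seed = 400 + s, qtl_variance_fraction = 0)
    sim <- simulate_cross(cfg)
    fit <- fit_polygenic(sim$phenotypes, sim$pedigree)
    est[s, ] <- fit$varcomp
    truth <- c(cfg$sigma2_a, cfg$sigma2_c, cfg$sigma2_e)
  }
  for (k in 1:3) {
    mc_se <- sd(est[, k]) / sqrt(nrep)
    expect_lt(abs(mean(est[, k]) - truth[k]), 4 * mc_se + 0.05 * truth[k],
              label = paste("component", k))
  }
})

test_that("residual scan equals closed-form least squares", {
  # 8-point hand dataset
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- c(1.2, 2.3, 3.9, 2.2, 0.8, 4.4, 2.6, 1.9)
  names(y) <- paste0("i", 1:8)
  g <- geno_matrix(matrix(as.integer(x), 8, 1,
                          dimnames = list(names(y), NULL)), toy_map(1))
  res <- residual_scan(list(residuals = y), g)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  k <- sxy / sxx
  rss <- sum((y - mean(y) - k * (x - mean(x)))^2)
  expect_equal(res$effect, k, tolerance = 1e-12)
  expect_equal(res$se^2, rss / 6 / sxx, tolerance = 1e-12)
  expect_equal(res$T2, k^2 / (rss / 6 / sxx), tolerance = 1e-12)
  expect_equal(res$var_pct, 100 * sxy^2 / (sxx * sum((y - mean(y))^2)),
               tolerance = 1e-12)

  # zero residuals -> zero statistics; monomorphic marker skipped not error
  y0 <- setNames(rep(0, 8), names(y))
  d2 <- cbind(as.integer(x), 1L)
  rownames(d2) <- names(y)
  res0 <- residual_scan(list(residuals = y0), geno_matrix(d2, toy_map(2)))
  expect_equal(res0$effect[1], 0)
  expect_equal(res0$T2[1], 0)
  expect_false(res0$tested[2])
})

test_that("genomic control rescales by the median and preserves ranks", {
  res <- data.frame(marker = paste0("m", 1:5), chr = "5", pos = 1:5,
                    effect = 1, se = 1, T2 = rep(0.456, 5), T2_gc = NA,
                    P = NA, var_pct = 0, n_used = 10, tested = TRUE)
  out <- genomic_control(res)
  expect_equal(attr(out, "lambda"), 1)
  expect_equal(out$T2_gc, out$T2)
  # scale equivariance: T2 * kappa -> lambda * kappa, adjusted unchanged
  res2 <- res; res2$T2 <- res$T2 * 3.7
  out2 <- genomic_control(res2)
  expect_equal(attr(out2, "lambda"), 3.7)
  expect_equal(out2$T2_gc, out$T2_gc)
  # rank preservation on arbitrary statistics
  set.seed(1)
  res3 <- res; res3$T2 <- rchisq(5, 1)
  out3 <- genomic_control(res3)
  expect_equal(order(out3$T2_gc), order(res3$T2))
  expect_equal(order(out3$P), order(-res3$T2))
  # Monte Carlo null: lambda near 1 with the 0.456 constant
  set.seed(99)
  res4 <- data.frame(marker = paste0("m", 1:10000), chr = "1", pos = 1:10000,
                     effect = 0, se = 1, T2 = rchisq(10000, 1), T2_gc = NA,
                     P = NA, var_pct = 0, n_used = 10, tested = TRUE)
  lam <- attr(genomic_control(res4), "lambda")
  expect_gt(lam, 0.93); expect_lt(lam, 1.07)
  res4$T2 <- 0
  expect_error(genomic_control(res4), "degenerate")
})

test_that("conditional analysis removes linked signal but not independent signal", {
  sim <- simulate_cross(sim_config(seed = 21, qtl_marker_index = 60))
  ph <- sim$phenotypes
  g <- subset_geno(sim$genotypes, individuals = ph$id)
  # add a second planted effect at a distant marker (36 cM away)
  j2 <- 180
  a2 <- sqrt(2 * 0.25 * sim$config$var_p)
  ph2 <- ph
  ph2$ear_area <- ph$ear_area + a2 * (g$dosage[ph$id, j2] - 1)
  gw <- grammar_gwas(ph2, sim$pedigree, g)
  thr <- bonferroni_threshold(0.01, sum(gw$results$tested))
  top1 <- sim$truth$qtl_marker
  cs <- conditional_scan(ph2, sim$pedigree, g, top1)
  near2 <- abs(cs$results$pos - g$map$position_bp[j2]) <= 2e6
  expect_lt(min(cs$results$P[near2], na.rm = TRUE), thr)   # QTL-2 survives
  # the rescan peak moves to the second QTL's neighbourhood
  peak2 <- which.min(cs$results$P)
  expect_lt(abs(cs$results$pos[peak2] - g$map$position_bp[j2]), 2e6)

  # conditioning on a marker without effect leaves the peak unchanged
  simn <- simulate_cross(sim_config(seed = 22))
  phn <- simn$phenotypes
  gn <- subset_geno(simn$genotypes, individuals = phn$id)
  gwn <- grammar_gwas(phn, simn$pedigree, gn)
  peak <- gwn$results$marker[which.min(gwn$results$P)]
  csn <- conditional_scan(phn, simn$pedigree, gn, "M0005")
  expect_equal(csn$results$marker[which.min(csn$results$P)], peak)
  # monomorphic conditioning marker is an error
  gm <- gn
  gm$dosage[, 3] <- 1L
  expect_error(conditional_scan(phn, simn$pedigree, gm,
                                gm$map$marker_id[3]), "monomorphic")
})

test_that("Bonferroni thresholds follow alpha / n_tests", {
  expect_equal(signif(bonferroni_threshold(0.01, 48355), 3), 2.07e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 48355), 3), 1.03e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 10))
})
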