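test_that("EM haplotype frequencies equal direct counts on unambiguous data", {
  # haplotypes distinguishable without phase ambiguity: only individuals
  # homozygous or single-het are generated
  haps <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  g <- pop_from_haps(haps, c(0.7, 0.3), 400, seed = 2)
  hf <- em_haplotype_frequencies(g, 1:3)
  expect_true(hf$converged)
  # counting oracle: every individual's diplotype is unambiguous here
  d <- g$dosage
  n11 <- sum(d[, 1] == 2)
  het <- sum(d[, 1] == 1)
  f_counted <- (2 * n11 + het) / (2 * nrow(d))
  expect_equal(unname(hf$freq["GGG"]), f_counted, tolerance = 1e-7)
  expect_equal(sum(hf$freq), 1, tolerance = 1e-9)

  # single double-heterozygote with flat start stays at the symmetric fixed
  # point: both resolutions at posterior 0.5
  d1 <- matrix(c(1L, 1L), 1, 2, dimnames = list("x", NULL))
  hf2 <- em_haplotype_frequencies(geno_matrix(d1, toy_map(2)), 1:2)
  expect_equal(sort(unname(hf2$posterior[, "prob"])), c(0.5, 0.5))

  # simulated haplotypes at known frequencies, large n
  haps3 <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  fr <- c(0.5, 0.3, 0.2)
  g3 <- pop_from_haps(haps3, fr, 2000, seed = 3)
  hf3 <- em_haplotype_frequencies(g3, 1:2)
  for (k in 1:3) {
    hs <- paste(ifelse(haps3[k, ] == 1, "G", "A"), collapse = "")
    se <- sqrt(fr[k] * (1 - fr[k]) / 4000)
    expect_lt(abs(hf3$freq[[hs]] - fr[k]), 4 * se)
  }
  # log-likelihood is finite and EM respects the window cap
  expect_true(is.finite(hf3$logLik))
  expect_error(em_haplotype_frequencies(random_geno(5, 13, 0, 1), 1:13),
               "window too large")
})

test_that("pairwise LD statistics behave at the identity and independence limits", {
  set.seed(6)
  x <- rbinom(300, 2, 0.4)
  d <- cbind(x, x)
  g <- geno_matrix(d, toy_map(2))
  ld <- ld_pair(g, 1, 2)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(abs(ld$Dprime), 1, tolerance = 1e-6)
  # r2 symmetric in its arguments
  ld_ba <- ld_pair(g, 2, 1)
  expect_equal(ld$r2, ld_ba$r2, tolerance = 1e-12)

  # independent markers: small r2, D' near 0 on average
  r2s <- dps <- numeric(40)
  set.seed(7)
  for (k in 1:40) {
    d2 <- cbind(rbinom(500, 2, 0.5), rbinom(500, 2, 0.5))
    ldk <- ld_pair(geno_matrix(d2, toy_map(2)), 1, 2)
    r2s[k] <- ldk$r2; dps[k] <- abs(ldk$Dprime)
  }
  expect_lt(mean(r2s), 5 / (2 * 500))
  expect_lt(mean(dps), 0.3)

  # no double heterozygotes: EM equals direct gamete counting
  dd <- rbind(c(0L, 0L), c(2L, 2L), c(2L, 2L), c(0L, 2L), c(1L, 0L),
              c(2L, 1L))
  ldc <- ld_pair(geno_matrix(dd, toy_map(2)), 1, 2)
  # direct gamete counting (every row is phase-unambiguous):
  # (0,0)->00,00; (2,2)x2->11 x4; (0,2)->01,01; (1,0)->10,00; (2,1)->11,10
  counts <- c(`00` = 3, `10` = 2, `01` = 2, `11` = 5)
  p11 <- counts[["11"]] / 12
  f1 <- (counts[["10"]] + counts[["11"]]) / 12
  f2 <- (counts[["01"]] + counts[["11"]]) / 12
  expect_equal(ldc$hap_freq[["GG"]], p11, tolerance = 1e-7)
  expect_equal(ldc$D, p11 - f1 * f2, tolerance = 1e-7)
  expect_error(ld_pair(geno_matrix(cbind(rep(1L, 4), rep(2L, 4)),
                                   toy_map(2)), 1, 2), "monomorphic")
})

test_that("block detection finds perfect-LD runs and respects separators", {
  # two perfect-LD clusters separated by an independent marker
  set.seed(11)
  h <- rbinom(600, 1, 0.5)         # cluster haplotype indicator per gamete
  mk_geno <- function() {
    a <- matrix(h, 300, 2)         # two gametes per individual
    rowSums(a)
  }
  c1 <- mk_geno()
  sep <- rbinom(300, 2, 0.5)
  h2 <- rbinom(600, 1, 0.5)
  c2 <- rowSums(matrix(h2, 300, 2))
  d <- cbind(c1, c1, c1, sep, c2, c2, c2)
  g <- geno_matrix(d, toy_map(7))
  blocks <- detect_blocks(g)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$first_index, c(1, 5))
  expect_equal(blocks$last_index, c(3, 7))

  # markers in perfect LD -> one block spanning all
  gall <- geno_matrix(cbind(c1, c1, c1, c1), toy_map(4))
  ball <- detect_blocks(gall)
  expect_equal(nrow(ball), 1)
  expect_equal(ball$n_markers, 4)

  # mutually independent markers -> no blocks
  set.seed(12)
  gind <- geno_matrix(matrix(rbinom(300 * 5, 2, 0.5), 300, 5), toy_map(5))
  expect_equal(nrow(detect_blocks(gind)), 0)
})

test_that("haplotype score test reduces to the marker score test and keeps invariances", {
  set.seed(21)
  n <- 250
  x <- rbinom(n, 2, 0.4)
  y <- 0.8 * x + rnorm(n)
  names(y) <- sprintf("i%04d", 1:n)
  g <- geno_matrix(matrix(as.integer(x), n, 1,
                          dimnames = list(names(y), NULL)), toy_map(1))
  hs <- hap_score_test(g, 1, y)
  # oracle: squared score z of the marker itself
  r <- y - mean(y)
  s2 <- sum(r^2) / (n - 1)
  U <- sum(x * r) / s2
  V <- (sum(x^2) - sum(x)^2 / n) / s2
  expect_equal(hs$global_stat, U^2 / V, tolerance = 1e-8)
  expect_equal(hs$df, 1)
  # the allele2-bearing haplotype raises the trait: positive hap-score that
  # flips sign when the trait is negated
  zG <- hs$scores$hap_score[hs$scores$haplotype == "G"]
  expect_gt(zG, 0)
  hs_neg <- hap_score_test(g, 1, -y)
  expect_equal(hs_neg$scores$hap_score[hs_neg$scores$haplotype == "G"], -zG,
               tolerance = 1e-9)
  # affine invariance of the global statistic
  hs_aff <- hap_score_test(g, 1, 3.2 * y + 11)
  expect_equal(hs_aff$global_stat, hs$global_stat, tolerance = 1e-9)
})

test_that("the global score statistic is chi-square calibrated under permutation", {
  haps <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  g <- pop_from_haps(haps, c(0.5, 0.3, 0.2), 300, seed = 31)
  set.seed(32)
  y <- rnorm(300); names(y) <- rownames(g$dosage)
  stats <- numeric(300)
  for (b in seq_len(300)) {
    yp <- setNames(sample(y), names(y))
    stats[b] <- hap_score_test(g, 1:2, yp)$global_stat
  }
  df <- hap_score_test(g, 1:2, y)$df
  # mean of a chi-square(df) is df; SE of the mean is sqrt(2 df / B)
  expect_lt(abs(mean(stats) - df), 4 * sqrt(2 * df / 300))
  pvals <- pchisq(stats, df, lower.tail = FALSE)
  expect_gt(mean(pvals), 0.40); expect_lt(mean(pvals), 0.60)
})

test_that("a haplotype tagging a planted effect scores positive", {
  haps <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  g <- pop_from_haps(haps, c(0.5, 0.3, 0.2), 400, seed = 41)
  # the GG haplotype is the only one carrying allele2 at marker 2, so its
  # per-individual copy number equals the marker-2 dosage
  set.seed(42)
  y <- g$dosage[, 2] * 1.5 + rnorm(400)
  names(y) <- rownames(g$dosage)
  hs <- hap_score_test(g, 1:2, y)
  expect_gt(hs$scores$hap_score[hs$scores$haplotype == "GG"], 2)
  expect_lt(hs$global_P, 1e-4)
})

test_that("shared segments are maximal identity runs with bp spans", {
  map <- toy_map(6, spacing = 100000L)
  haps <- rbind(c(1L, 1L, 0L, 1L, 0L, 0L),
                c(1L, 1L, 0L, 1L, 1L, 0L),
                c(1L, 1L, 0L, 1L, 0L, 1L))
  segs <- shared_segments(haps, map)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$first_index, 1)
  expect_equal(segs$last_index, 4)
  expect_equal(segs$length_bp, 300000)
  # all identical -> one full-span segment
  segs2 <- shared_segments(haps[c(1, 1), ], map)
  expect_equal(segs2$n_markers, 6)
  # non-adjacency of maximal segments
  expect_true(all(diff(segs$first_index) > 1 | nrow(segs) <= 1))
  expect_error(shared_segments(haps[1, , drop = FALSE], map), "at least 2")
  hna <- haps; hna[1, 2] <- NA
  expect_error(shared_segments(hna, map), "missing")
})

test_that("interval intersection reproduces the candidate-region arithmetic", {
  gwas_iv <- data.frame(start = 30.23e6, end = 34.02e6)
  share_iv <- data.frame(start = 28.0e6, end = 33.30e6)
  ov <- intersect_intervals(gwas_iv, share_iv)
  expect_equal(ov$start, 30.23e6)
  expect_equal(ov$end, 33.30e6)
  expect_equal(ov$length, 3.07e6)
  # disjoint -> empty; identical -> identity
  expect_equal(nrow(intersect_intervals(data.frame(start = 1, end = 2),
                                        data.frame(start = 3, end = 4))), 0)
  same <- intersect_intervals(gwas_iv, gwas_iv)
  expect_equal(same$start, gwas_iv$start)
  expect_equal(same$end, gwas_iv$end)
})
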