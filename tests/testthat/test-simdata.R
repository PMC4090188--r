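test_that("simulated crosses are Mendelian-consistent and seed-deterministic", {
  sim <- simulate_cross(sim_config(seed = 11, n_f2 = 100, n_litters = 40,
                                   n_markers = 60))
  g <- sim$genotypes
  expect_true(all(g$phase$h1 + g$phase$h2 == g$dosage))
  # every haplotype allele traces to a founder chromosome
  expect_true(all(sim$truth$origin$o1 >= 1 &
                    sim$truth$origin$o1 <= nrow(sim$truth$founder_hap)))
  # QTL fixed alternatively in the founder breeds
  qi <- sim$truth$qtl_marker_index
  f0 <- sim$pedigree$id[sim$pedigree$generation == "F0"]
  mz <- f0[sim$pedigree$breed[match(f0, sim$pedigree$id)] == "minzhu"]
  lw <- setdiff(f0, mz)
  expect_true(all(g$dosage[mz, qi] == 2L))
  expect_true(all(g$dosage[lw, qi] == 0L))

  sim2 <- simulate_cross(sim_config(seed = 11, n_f2 = 100, n_litters = 40,
                                    n_markers = 60))
  expect_identical(sim2$genotypes$dosage, sim$genotypes$dosage)
  expect_identical(sim2$phenotypes$ear_area, sim$phenotypes$ear_area)
  sim3 <- simulate_cross(sim_config(seed = 12, n_f2 = 100, n_litters = 40,
                                    n_markers = 60))
  expect_false(identical(sim3$genotypes$dosage, sim$genotypes$dosage))
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_f2 = 30, n_litters = 47), "litter partition")
  expect_error(sim_config(qtl_marker_index = 500), "out of range")
  expect_error(sim_config(qtl_variance_fraction = 1.2), "qtl_variance_fraction")
})

test_that("trait mean and coefficient of variation match the configured design", {
  nseeds <- 12
  means <- cvs <- numeric(nseeds)
  for (s in seq_len(nseeds)) {
    ph <- simulate_cross(sim_config(seed = 100 + s))$phenotypes
    means[s] <- mean(ph$ear_area)
    cvs[s] <- sd(ph$ear_area) / mean(ph$ear_area)
  }
  # between-seed spread includes family/litter/batch cluster variation, so
  # the Monte-Carlo standard error is estimated empirically across seeds
  expect_lt(abs(mean(means) - 244), 3 * sd(means) / sqrt(nseeds))
  expect_lt(abs(mean(cvs) - 0.22), 3 * sd(cvs) / sqrt(nseeds) + 0.01)
})

test_that("QTL genotype classes explain the configured fraction of variance", {
  nseeds <- 25
  r2 <- numeric(nseeds)
  for (s in seq_len(nseeds)) {
    sim <- simulate_cross(sim_config(seed = 200 + s))
    fit <- lm(sim$phenotypes$ear_area ~ factor(sim$truth$qtl_genotype))
    r2[s] <- summary(fit)$r.squared
  }
  expect_lt(abs(mean(r2) - 0.5), 3 * sd(r2) / sqrt(nseeds) + 0.01)
})

test_that("a null configuration yields i.i.d. phenotypes and uniform scan P-values", {
  pvals <- c()
  for (s in 1:3) {
    sim <- simulate_cross(sim_config(seed = 300 + s,
                                     qtl_variance_fraction = 0,
                                     sigma2_a = 0, sigma2_c = 0))
    ph <- sim$phenotypes
    r <- resid(lm(ear_area ~ factor(sex) + factor(parity) + factor(batch) +
                    body_weight, ph))
    names(r) <- ph$id
    res <- residual_scan(list(residuals = r),
                         subset_geno(sim$genotypes, individuals = ph$id))
    pvals <- c(pvals, pchisq(res$T2[res$tested], 1, lower.tail = FALSE))
  }
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("breed panels carry the planted fixation run in the case breed only", {
  cfg <- sweep_sim_config(run_start = 17, run_length = 6, seed = 5)
  panels <- simulate_breed_panels(cfg)
  expect_named(panels, c("erhualian", "duroc", "landrace", "large_white"))
  run <- 17:22
  expect_equal(unname(heterozygosity(panels$erhualian)[run]), rep(0, 6))
  for (b in c("duroc", "landrace", "large_white")) {
    maf <- minor_allele_frequency(panels[[b]])
    expect_true(all(maf[run] > 0))
  }
  # empty run: all panels polymorphic, nothing downstream
  p0 <- simulate_breed_panels(sweep_sim_config(run_length = 0, seed = 5))
  expect_true(all(minor_allele_frequency(p0$erhualian) > 0))
  expect_equal(nrow(detect_sweep(p0$erhualian, p0[-1])), 0)
  expect_error(sweep_sim_config(run_start = 38, run_length = 6),
               "outside marker range")
})

test_that("planted shared haplotypes are recovered exactly by the segment detector", {
  sim <- simulate_cross(sim_config(seed = 42))
  qi <- sim$truth$qtl_marker_index
  interval <- (qi - 5):(qi + 4)                 # 10 markers
  sim <- plant_shared_haplotype(sim, interval)
  expect_true(all(sim$genotypes$phase$h1 + sim$genotypes$phase$h2 ==
                    sim$genotypes$dosage))
  haps <- founder_haplotypes(sim)               # all Minzhu founder homologs
  segs <- shared_segments(haps, sim$genotypes$map)
  segs <- segs[segs$n_markers >= 2, ]
  expect_equal(nrow(segs), 1)
  expect_equal(segs$first_index, interval[1])
  expect_equal(segs$last_index, interval[10])

  # whole chromosome -> one maximal segment spanning all markers
  sim2 <- plant_shared_haplotype(simulate_cross(sim_config(seed = 43)),
                                 seq_len(200))
  segs2 <- shared_segments(founder_haplotypes(sim2), sim2$genotypes$map)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$n_markers, 200)

  # breaking one Q haplotype at an internal marker splits the sharing
  haps3 <- founder_haplotypes(sim)[, interval, drop = FALSE]
  mid <- 5
  haps3[1, mid] <- 1L - haps3[1, mid]
  segs3 <- shared_segments(haps3, sim$genotypes$map[interval, ])
  expect_equal(nrow(segs3), 2)
  expect_equal(segs3$last_index[1], mid - 1)
  expect_equal(segs3$first_index[2], mid + 1)

  expect_error(plant_shared_haplotype(sim, integer(0)), "empty")
  expect_error(plant_shared_haplotype(sim, 195:205), "outside")
})

test_that("realized founder allele frequencies track the configured spectra", {
  cfg <- sim_config(seed = 77, n_f1_sires = 40, n_f1_dams = 160,
                    n_litters = 160, n_f2 = 160, n_markers = 50)
  sim <- simulate_cross(cfg)
  mz <- sim$pedigree$id[!is.na(sim$pedigree$breed) &
                          sim$pedigree$breed == "minzhu"]
  haps <- founder_haplotypes(sim, mz)
  realized <- colMeans(haps)
  expect_lt(mean(abs(realized - sim$truth$founder_breed_freqs[1, ])), 0.05)
})
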