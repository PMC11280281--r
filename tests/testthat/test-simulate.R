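test_that("configuration validation catches impossible variance structures", {
  expect_error(sim_config(sigma2_m = 4, sigma_am = -15), "positive definite")
  expect_error(sim_config(sigma2_m = 0, sigma_am = -1), "sigma_am")
  expect_error(sim_config(n_sires = 10, n_dams = 50, progeny_per_dam = 1,
                          n_generations = 2), "not enough progeny")
  cfg <- sim_config(n_sires = 10)
  expect_equal(cfg$n_dams, 50)  # 1:5 mating ratio by default
})

test_that("the generator reproduces the configured design exactly", {
  cfg <- sim_config(n_sires = 5, n_dams = 25, n_generations = 3,
                    progeny_per_dam = 2, n_hatches = 5, seed = 201)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$pedigree), 30 + 3 * 50)
  expect_equal(nrow(sim$records), 3 * 50)
  expect_equal(sort(unique(sim$records$generation)), 1:3)
  expect_true(all(sim$records$hatch %in% 1:5))
  expect_true(all(sim$records$dam > 0))
  # every generation-1 record's parents are founders
  g1 <- sim$records$animal[sim$records$generation == 1]
  expect_true(all(sim$pedigree$sire[g1] <= 5))
  # same seed, same world
  sim2 <- simulate_population(cfg)
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$pedigree, sim2$pedigree)
})

test_that("phenotypic variance matches the law of total variance", {
  cfg <- sim_config(n_sires = 25, n_dams = 125, n_generations = 2,
                    progeny_per_dam = 20, sigma2_a = 40, sigma2_e = 60,
                    gen_effects = c(0, 0), hatch_effects = rep(0, 5),
                    seed = 202)
  sim <- simulate_population(cfg)
  expect_gte(nrow(sim$records), 5000)
  expect_lt(abs(var(sim$records$value) / 100 - 1), 0.1)
})

test_that("full sibs covary by half the additive variance", {
  # one generation of full-sib pairs, no nuisance effects
  cfg <- sim_config(n_sires = 100, n_dams = 2000, mating_ratio = 20,
                    n_generations = 1, progeny_per_dam = 2,
                    sigma2_a = 40, sigma2_e = 60,
                    gen_effects = 0, hatch_effects = rep(0, 5), seed = 203)
  sim <- simulate_population(cfg)
  pairs <- sim$records |>
    dplyr::group_by(dam) |>
    dplyr::summarise(v1 = value[1], v2 = value[2], .groups = "drop")
  expect_equal(nrow(pairs), 2000)
  expect_lt(abs(stats::cov(pairs$v1, pairs$v2) - 20), 5)
})

test_that("offspring breeding values regress on mid-parent with slope one", {
  cfg <- sim_config(n_sires = 50, n_dams = 250, n_generations = 2,
                    progeny_per_dam = 10, sigma2_a = 40, sigma2_e = 60,
                    seed = 204)
  sim <- simulate_population(cfg)
  eff <- sim$truth$effects
  off <- which(sim$pedigree$sire > 0)
  mid <- 0.5 * (eff$u[sim$pedigree$sire[off]] + eff$u[sim$pedigree$dam[off]])
  slope <- stats::coef(stats::lm(eff$u[off] ~ mid))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("negative direct-maternal covariance shows up in the sampled effects", {
  cfg <- sim_config(n_sires = 30, n_dams = 150, n_generations = 2,
                    progeny_per_dam = 6, sigma2_a = 40, sigma2_m = 20,
                    sigma_am = -15, sigma2_e = 60, seed = 205)
  sim <- simulate_population(cfg)
  eff <- sim$truth$effects
  expect_lt(stats::cov(eff$u, eff$d), 0)
  # offspring direct values against their dam's maternal value
  off <- which(sim$pedigree$dam > 0)
  expect_lt(stats::cov(eff$u[off], eff$d[sim$pedigree$dam[off]]), 0)
})

test_that("missingness thinning is binomial and generation blanking is total", {
  cfg <- sim_config(n_sires = 10, n_dams = 50, n_generations = 2,
                    progeny_per_dam = 10, seed = 206)
  sim <- simulate_population(cfg)
  n0 <- nrow(sim$records)
  expect_identical(apply_missingness(sim$records, keep = 1), sim$records)

  thin <- apply_missingness(sim$records, keep = 0.5, seed = 207)
  expect_lt(abs(nrow(thin) - 0.5 * n0), 3 * sqrt(n0 * 0.25))

  blank <- apply_missingness(sim$records,
                             drop_generations = list(trait = 2))
  expect_false(any(blank$generation == 2))
  expect_error(apply_missingness(sim$records, keep = 0), "in \\(0, 1\\]")
})

test_that("multitrait simulation realises the requested correlations", {
  Sg <- 40 * matrix(c(1, 0.8, 0.8, 1), 2)
  Sr <- 60 * matrix(c(1, 0.3, 0.3, 1), 2)
  cfg <- sim_config(n_sires = 40, n_dams = 200, n_generations = 2,
                    progeny_per_dam = 8, seed = 208)
  sim <- simulate_multitrait(cfg, Sg, Sr, trait_names = c("x", "y"))
  eff <- sim$truth$effects
  expect_lt(abs(stats::cor(eff$u_x, eff$u_y) - 0.8), 0.1)
  wide <- tidyr::pivot_wider(sim$records[, c("animal", "trait_name", "value")],
                             names_from = "trait_name", values_from = "value")
  expect_gt(stats::cor(wide$x, wide$y), 0.2)
  expect_error(simulate_multitrait(cfg, matrix(c(1, 2, 2, 1), 2), Sr),
               "positive definite")
})
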