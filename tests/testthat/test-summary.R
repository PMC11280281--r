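test_that("variance ratios reproduce printed-table arithmetic", {
  # additive-only model
  r <- derived_ratios(list(sigma2_a = 15.64, sigma2_e = 63.76))
  expect_equal(r$sigma2_p, 79.4)
  expect_equal(round(r$h2_additive, 2), 0.20)

  # full maternal model with negative direct-maternal covariance
  r <- derived_ratios(list(sigma2_a = 27.26, sigma2_m = 5.87,
                           sigma_am = -9.52, sigma2_pe = 1.71,
                           sigma2_e = 60.11))
  expect_equal(r$sigma2_p, 85.43, tolerance = 1e-12)
  expect_equal(round(r$h2_additive, 2), 0.32)
  expect_equal(round(r$h2_maternal, 2), 0.07)
  expect_equal(round(r$c2_mpe, 2), 0.02)

  # degenerate edge: all variance additive
  r <- derived_ratios(list(sigma2_a = 1, sigma2_e = 0))
  expect_equal(r$h2_additive, 1)

  # excluding the covariance from sigma2_p is available behind a flag
  r2 <- derived_ratios(list(sigma2_a = 27.26, sigma2_m = 5.87,
                            sigma_am = -9.52, sigma2_pe = 1.71,
                            sigma2_e = 60.11), include_cov = FALSE)
  expect_equal(r2$sigma2_p, 94.95, tolerance = 1e-12)

  # non-positive phenotypic variance is flagged, not propagated
  bad <- derived_ratios(tibble::tibble(sigma2_a = c(1, 1),
                                       sigma_am = c(-3, 0),
                                       sigma2_m = c(1, 1),
                                       sigma2_e = c(0.5, 1)))
  expect_true(is.na(bad$h2_additive[1]))
  expect_equal(attr(bad, "n_flagged"), 1)
})

test_that("ratio components sum to one draw by draw", {
  withr::local_seed(8)
  draws <- tibble::tibble(sigma2_a = runif(50, 1, 5),
                          sigma2_m = runif(50, 0.5, 2),
                          sigma_am = runif(50, -1, 1),
                          sigma2_pe = runif(50, 0, 1),
                          sigma2_e = runif(50, 2, 6))
  r <- derived_ratios(draws)
  total <- r$h2_additive + r$h2_maternal + r$c2_mpe +
    draws$sigma_am / r$sigma2_p + draws$sigma2_e / r$sigma2_p
  expect_equal(total, rep(1, 50))
})

test_that("HPD interval is the shortest interval and matches closed forms", {
  # constant chain
  expect_equal(hpd_interval(rep(3, 500)), c(lower = 3, upper = 3))

  # standard normal: ~ (-1.96, 1.96); endpoint noise shrinks with n
  withr::local_seed(9)
  x <- rnorm(100000)
  h <- hpd_interval(x)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)

  # uniform: any 95% interval has width 0.95
  u <- runif(10000)
  h <- hpd_interval(u)
  expect_lt(abs(diff(h) - 0.95), 0.01)

  # never wider than the equal-tailed interval, here on a skewed sample
  s <- rexp(5000)
  h <- hpd_interval(s)
  et <- quantile(s, c(0.025, 0.975))
  expect_lte(diff(h), diff(unname(et)) + 1e-12)

  # agreement with the independent coda implementation up to the one
  # order statistic by which the two endpoint conventions can differ
  expect_equal(unname(hpd_interval(x)),
               as.numeric(coda::HPDinterval(coda::mcmc(x), prob = 0.95)),
               tolerance = 1e-3)
})

test_that("chain summaries are order-invariant and need enough draws", {
  withr::local_seed(10)
  draws <- tibble::tibble(sigma2_a = rgamma(400, 5), sigma2_e = rgamma(400, 8))
  s1 <- summarize_chain(draws)
  s2 <- summarize_chain(draws[sample(400), ])
  expect_equal(s1, s2)
  expect_equal(s1$mean[1], mean(draws$sigma2_a))
  expect_error(summarize_chain(draws[1:50, ]), "at least 100")
})

test_that("summaries of a fitted chain include per-draw ratios and cross-check", {
  sim <- simulate_population(sim_config(n_sires = 6, n_dams = 30,
                                        n_generations = 2, progeny_per_dam = 2,
                                        seed = 107))
  ch <- run_chain(sim$records, sim$pedigree, "M1", n_iter = 2000,
                  burn_in = 400, thin = 4, seed = 11)
  s <- summarize_chain(ch)
  expect_setequal(s$parameter,
                  c("sigma2_a", "sigma2_e", "sigma2_p", "h2_additive"))
  rh <- derived_ratios(ch$draws)
  expect_equal(s$mean[s$parameter == "h2_additive"], mean(rh$h2_additive))
  rom <- attr(s, "ratio_of_means")
  expect_equal(rom$h2_additive,
               mean(ch$draws$sigma2_a) /
                 mean(ch$draws$sigma2_a + ch$draws$sigma2_e))
  # per-draw mean and ratio-of-means agree to a couple of decimals here
  expect_lt(abs(rom$h2_additive - s$mean[s$parameter == "h2_additive"]), 0.05)
})

test_that("diagnostics behave on iid, autocorrelated and trending chains", {
  withr::local_seed(12)
  n <- 5000
  iid <- tibble::tibble(x = rnorm(n))
  d <- chain_diagnostics(iid)
  expect_lt(abs(d$ess / n - 1), 0.2)
  expect_lt(abs(d$geweke_z), 3)
  expect_equal(length(d$autocorrelation[[1]]), 10)

  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  dar <- chain_diagnostics(tibble::tibble(x = ar))
  expect_lt(abs(dar$ess / (n / 19) - 1), 0.3)
  expect_gt(dar$autocorrelation[[1]][1], 0.8)

  trend <- tibble::tibble(x = seq_len(n) / n + rnorm(n, 0, 0.05))
  expect_gt(abs(chain_diagnostics(trend)$geweke_z), 3)

  bad <- tibble::tibble(x = c(rnorm(300), NaN))
  expect_error(chain_diagnostics(bad), "non-finite")
  expect_error(chain_diagnostics(iid[1:100, ]), "at least 200")
})
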