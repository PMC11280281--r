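#' Genetic parameter ratios from variance components
#'
#' Computes the phenotypic variance and the variance ratios from a set of
#' (co)variance components, vectorised over rows:
#' `sigma2_p = sigma2_a + sigma2_m + sigma_am + sigma2_pe + sigma2_e`
#' (the direct-maternal covariance is part of the phenotypic variance by
#' default), `h2_additive = sigma2_a / sigma2_p`,
#' `h2_maternal = sigma2_m / sigma2_p`, `c2_mpe = sigma2_pe / sigma2_p`.
#' Components absent from the input count as zero. Rows with non-positive
#' phenotypic variance yield `NA` ratios and are counted in the
#' `"n_flagged"` attribute.
#'
#' @param components A data frame (or single named list/vector) with any of
#'   the columns `sigma2_a`, `sigma2_m`, `sigma_am`, `sigma2_pe`,
#'   `sigma2_e`.
#' @param include_cov Include `sigma_am` in the phenotypic variance
#'   (default `TRUE`).
#' @return A tibble with columns `sigma2_p`, `h2_additive`, `h2_maternal`,
#'   `c2_mpe`, one row per input row.
#' @export
derived_ratios <- function(components, include_cov = TRUE) {
  if (!is.data.frame(components)) components <- as_tibble(as.list(components))
  get0col <- function(nm) {
    if (nm %in% names(components)) components[[nm]] else rep(0, nrow(components))
  }
  s2a <- get0col("sigma2_a")
  s2m <- get0col("sigma2_m")
  sam <- get0col("sigma_am")
  s2pe <- get0col("sigma2_pe")
  s2e <- get0col("sigma2_e")
  s2p <- s2a + s2m + s2pe + s2e + if (include_cov) sam else 0
  bad <- !is.na(s2p) & s2p <= 0
  s2p[bad] <- NA_real_
  out <- tibble(
    sigma2_p = s2p,
    h2_additive = s2a / s2p,
    h2_maternal = s2m / s2p,
    c2_mpe = s2pe / s2p
  )
  attr(out, "n_flagged") <- sum(bad)
  out
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing
#' `ceiling(level * N)` of them; ties in width are broken toward the lower
#' start index. Never wider than the equal-tailed interval at the same
#' level.
#'
#' @param x Numeric vector of posterior draws.
#' @param level Credibility level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2, level > 0, level <= 1)
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(level * n)
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[k:n] - xs[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k - 1])
}

#' Posterior summary of a Gibbs chain
#'
#' Posterior mean, SD and HPDI for every variance component and, for
#' univariate chains, the derived ratios `h2_additive`, `h2_maternal`,
#' `c2_mpe` and `sigma2_p` — ratios are computed per draw and then
#' summarised. The ratio of posterior means (the convention used when
#' checking against printed variance-component tables) is attached as
#' attribute `"ratio_of_means"`.
#'
#' @param chain A `gibbs_chain` or `gibbs_chain_biv`, or a data frame of
#'   draws.
#' @param level HPDI credibility level.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `hpdi_low`,
#'   `hpdi_high`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  UseMethod("summarize_chain")
}

summarize_draws_tbl <- function(draws, level) {
  if (nrow(draws) < 100) stop("need at least 100 retained draws, got ",
                              nrow(draws))
  purrr::map_dfr(names(draws), function(nm) {
    x <- draws[[nm]]
    ok <- !is.na(x)
    h <- hpd_interval(x[ok], level)
    tibble(parameter = nm, mean = mean(x[ok]), sd = sd(x[ok]),
           hpdi_low = h[["lower"]], hpdi_high = h[["upper"]])
  })
}

#' @rdname summarize_chain
#' @export
summarize_chain.gibbs_chain <- function(chain, level = 0.95) {
  ratios <- derived_ratios(chain$draws)
  keep_ratio <- c("sigma2_p", "h2_additive",
                  if (chain$model$has_maternal_genetic) "h2_maternal",
                  if (chain$model$has_maternal_pe) "c2_mpe")
  draws <- dplyr::bind_cols(chain$draws, ratios[, keep_ratio])
  out <- summarize_draws_tbl(draws, level)
  pm <- colMeans(chain$draws)
  rom <- derived_ratios(as_tibble(as.list(pm)))
  attr(out, "ratio_of_means") <- rom[, keep_ratio]
  attr(out, "n_flagged") <- attr(ratios, "n_flagged")
  out
}

#' @rdname summarize_chain
#' @export
summarize_chain.gibbs_chain_biv <- function(chain, level = 0.95) {
  summarize_draws_tbl(chain$draws, level)
}

#' @rdname summarize_chain
#' @export
summarize_chain.data.frame <- function(chain, level = 0.95) {
  summarize_draws_tbl(as_tibble(chain), level)
}

#' Convergence diagnostics for a chain
#'
#' Geweke z (first 10% vs last 50% of the chain, spectral-density variance
#' estimates), effective sample size from the integrated autocorrelation
#' time, and autocorrelations at the first `n_lags` lags, per parameter.
#'
#' @param chain A `gibbs_chain`, `gibbs_chain_biv`, or data frame of draws.
#' @param n_lags Number of autocorrelation lags to report.
#' @return A tibble with columns `parameter`, `ess`, `geweke_z` and a
#'   list-column `autocorrelation` (numeric vector of lags `1..n_lags`).
#' @export
chain_diagnostics <- function(chain, n_lags = 10) {
  draws <- if (is.data.frame(chain)) as_tibble(chain) else chain$draws
  if (nrow(draws) < 200) stop("need at least 200 retained draws, got ",
                              nrow(draws))
  for (nm in names(draws)) {
    bad <- which(!is.finite(draws[[nm]]))
    if (length(bad)) stop("non-finite draw for ", nm, " at index ", bad[1])
  }
  keep <- vapply(draws, function(x) sd(x) > 0, logical(1))
  mc <- coda::mcmc(as.matrix(draws[, keep, drop = FALSE]))
  ess <- coda::effectiveSize(mc)
  gw <- coda::geweke.diag(mc, frac1 = 0.1, frac2 = 0.5)$z
  purrr::map_dfr(names(draws), function(nm) {
    if (!keep[[nm]]) {
      return(tibble(parameter = nm, ess = NA_real_, geweke_z = NA_real_,
                    autocorrelation = list(rep(NA_real_, n_lags))))
    }
    ac <- as.numeric(acf(draws[[nm]], lag.max = n_lags, plot = FALSE)$acf)[-1]
    tibble(parameter = nm, ess = unname(ess[nm]), geweke_z = unname(gw[nm]),
           autocorrelation = list(ac))
  })
}
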