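#' Tidy a fitted Gibbs chain
#'
#' One row per parameter with posterior mean, SD and HPDI bounds — the same
#' table as [summarize_chain()].
#'
#' @param x A `gibbs_chain` or `gibbs_chain_biv`.
#' @param level HPDI credibility level.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `hpdi_low`,
#'   `hpdi_high`.
#' @export
tidy.gibbs_chain <- function(x, level = 0.95, ...) {
  summarize_chain(x, level = level)
}

#' @rdname tidy.gibbs_chain
#' @export
tidy.gibbs_chain_biv <- function(x, level = 0.95, ...) {
  summarize_chain(x, level = level)
}

#' Glance at a fitted Gibbs chain
#'
#' @param x A `gibbs_chain`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `trait`, `n_records`, `n_draws`,
#'   `dbar`, `pd`, `dic`, `min_ess`.
#' @export
glance.gibbs_chain <- function(x, ...) {
  cmp <- suppressWarnings(dic(x))
  ess <- tryCatch(min(chain_diagnostics(x)$ess, na.rm = TRUE),
                  error = function(e) NA_real_)
  tibble(model = x$model$model_id, trait = x$trait,
         n_records = x$n_records, n_draws = nrow(x$draws),
         dbar = cmp$dbar, pd = cmp$pd, dic = cmp$dic, min_ess = ess)
}

chain_long <- function(x) {
  draws <- x$draws
  draws$.draw <- seq_len(nrow(draws))
  tidyr::pivot_longer(draws, -".draw", names_to = "parameter",
                      values_to = "value")
}

#' Trace and density plots for a Gibbs chain
#'
#' @param object A `gibbs_chain` or `gibbs_chain_biv`.
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @export
autoplot.gibbs_chain <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  long <- chain_long(object)
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.draw, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "retained draw", y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}

#' @rdname autoplot.gibbs_chain
#' @export
autoplot.gibbs_chain_biv <- autoplot.gibbs_chain

#' Posterior heritability summary plot
#'
#' Point-interval plot of the posterior means and HPDIs of the variance
#' ratios across one or more fitted chains.
#'
#' @param ... Named `gibbs_chain` objects (names label the panels).
#' @param level HPDI credibility level.
#' @return A ggplot object.
#' @export
plot_ratios <- function(..., level = 0.95) {
  chains <- list(...)
  if (is.null(names(chains)) || any(names(chains) == "")) {
    names(chains) <- vapply(chains, function(c) c$model$model_id, character(1))
  }
  tab <- purrr::imap_dfr(chains, function(ch, nm) {
    s <- summarize_chain(ch, level = level)
    s$fit <- nm
    s
  })
  tab <- tab[grepl("^(h2_|c2_)", tab$parameter), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$parameter, y = .data$mean,
                                    colour = .data$fit)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hpdi_low,
                                          ymax = .data$hpdi_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "posterior mean and HPDI")
}
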