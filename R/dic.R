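#' Deviance information criterion of a fitted chain
#'
#' Conditional-deviance DIC: `Dbar` is the mean of the per-draw deviances
#' `-2 log N(y | location effects, I sigma2_e)`, `D(theta_bar)` the deviance
#' at the posterior means of the location effects and of `sigma2_e`,
#' `pD = Dbar - D(theta_bar)` and `DIC = Dbar + pD = 2 Dbar - D(theta_bar)`.
#' A negative `pD` is flagged with a warning but not fatal.
#'
#' @param chain A `gibbs_chain` from [run_chain()].
#' @return A one-row tibble: `model`, `trait`, `n_records`, `dbar`,
#'   `d_at_mean`, `pd`, `dic`.
#' @export
dic <- function(chain) {
  stopifnot(inherits(chain, "gibbs_chain"))
  if (is.null(chain$deviance) || !length(chain$deviance)) {
    stop("chain carries no deviance trace")
  }
  dbar <- mean(chain$deviance)
  dhat <- chain$d_at_mean
  pd <- dbar - dhat
  if (pd < 0) warning("negative effective number of parameters (pD = ",
                      round(pd, 2), ")")
  tibble(model = chain$model$model_id, trait = chain$trait,
         n_records = chain$n_records,
         dbar = dbar, d_at_mean = dhat, pd = pd, dic = dbar + pd)
}

#' Select the best model by DIC
#'
#' Returns the model with the lowest DIC. Models whose DIC is within
#' `tie_tol` of the minimum are treated as tied and the simplest tied model
#' (lowest in `M1 < M2 < M3` order) is returned, with attribute
#' `"tie" = TRUE`. Models fitted to different record subsets are not
#' comparable and raise an error.
#'
#' @param comparisons A data frame with columns `model` and `dic`
#'   (e.g. rows from [dic()] bound together); an `n_records` column, if
#'   present, is checked for equality.
#' @param tie_tol Absolute DIC difference below which models tie.
#' @return The best model id (character scalar) with attribute `tie`.
#' @export
select_best <- function(comparisons, tie_tol = 0.5) {
  stopifnot(is.data.frame(comparisons),
            all(c("model", "dic") %in% names(comparisons)))
  if (nrow(comparisons) == 0) stop("no models to compare")
  if ("n_records" %in% names(comparisons) &&
      length(unique(comparisons$n_records)) > 1) {
    stop("models were fitted to different record subsets; DIC not comparable")
  }
  complexity <- match(comparisons$model, c("M1", "M2", "M3"))
  complexity[is.na(complexity)] <- seq_len(nrow(comparisons))[is.na(complexity)]
  tied <- comparisons$dic - min(comparisons$dic) < tie_tol
  best <- comparisons$model[tied][which.min(complexity[tied])]
  structure(as.character(best), tie = sum(tied) > 1)
}
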