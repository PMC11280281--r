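#' Default priors for the variance-component sampler
#'
#' Minimally informative conjugate priors: scaled-inverse-chi-square for
#' scalar variances and inverse-Wishart for the 2x2 direct/maternal genetic
#' covariance, with degrees of freedom `dimension + 1` and scale set so each
#' fitted component's prior guess is half the phenotypic variance split
#' evenly across components. `flat = TRUE` zeroes both df and scale, leaving
#' the data-only full conditionals (posteriors stay proper at the sample
#' sizes this package targets).
#'
#' @param var_p Sample phenotypic variance of the trait.
#' @param spec A [model_spec()].
#' @param flat Use improper flat priors.
#' @return A list consumed by [run_chain()].
#' @export
default_priors <- function(var_p, spec, flat = FALSE) {
  ncomp <- 2L + spec$has_maternal_genetic + spec$has_maternal_pe
  s <- 0.5 * var_p / ncomp
  if (flat) {
    list(nu_a = 0, ss_a = 0, nu_pe = 0, ss_pe = 0, nu_e = 0, ss_e = 0,
         Vg = matrix(0, 2, 2), nu_g = 0)
  } else {
    list(nu_a = 2, ss_a = 2 * s,
         nu_pe = 2, ss_pe = 2 * s,
         nu_e = 2, ss_e = 2 * s,
         Vg = diag(c(3 * s, 3 * s)), nu_g = 3)
  }
}

#' Gibbs sampler for univariate maternal-effects animal models
#'
#' Draws from the joint posterior of location effects and (co)variance
#' components for models `M1`-`M3`. Each round sweeps the mixed-model
#' unknowns one at a time from their normal full conditionals (using the
#' sparse coefficient structure with `A^-1 (x) G^-1` contributions for the
#' direct/maternal breeding values and `I/sigma2_pe` for the permanent
#' environmental effects), then updates the variance components from their
#' scaled-inverse-chi-square or 2x2 inverse-Wishart full conditionals. The
#' direct-maternal covariance is always sampled when maternal genetic
#' effects are in the model. The conditional deviance
#' `-2 log N(y | Xb + Zu + Wd + Mpe, I sigma2_e)` is recorded at every
#' retained draw for DIC.
#'
#' @param records Trait records (`animal`, `dam`, `generation`, `hatch`,
#'   `value`); one record per animal.
#' @param ped A renumbered `ped_tbl`.
#' @param model `"M1"`, `"M2"` or `"M3"` (or a [model_spec()]).
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning interval;
#'   defaults follow the common long-chain protocol (200000 / 2000 / 50).
#'   Retained draws: `floor((n_iter - burn_in) / thin)`.
#' @param seed Integer seed; identical seeds give bitwise-identical chains.
#' @param priors Optional prior list, see [default_priors()].
#' @param flat_priors Convenience switch for flat priors.
#' @param use_inbreeding Account for inbreeding in `A^-1`.
#' @return A `gibbs_chain` object: tibble `draws` (one row per retained
#'   draw, columns the fitted components), numeric `deviance`, the model
#'   spec, chain config, and the plug-in deviance pieces used by [dic()].
#' @export
run_chain <- function(records, ped, model = "M1",
                      n_iter = 200000, burn_in = 2000, thin = 50,
                      seed = NULL, priors = NULL, flat_priors = FALSE,
                      use_inbreeding = TRUE) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  stopifnot(burn_in < n_iter, thin >= 1)
  des <- build_design(records, ped, spec)
  y <- des$y
  var_p <- var(y)
  if (is.null(priors)) priors <- default_priors(var_p, spec, flat = flat_priors)

  Wfull <- des$X
  Wfull <- cbind(Wfull, des$Z)
  if (spec$has_maternal_genetic) Wfull <- cbind(Wfull, des$W)
  if (spec$has_maternal_pe) Wfull <- cbind(Wfull, des$Mpe)
  Wfull <- as(Wfull, "CsparseMatrix")
  C0 <- as(as(Matrix::crossprod(Wfull), "generalMatrix"), "CsparseMatrix")
  rhs <- as.numeric(Matrix::crossprod(Wfull, y))
  Ainv <- as(as(a_inverse(ped, use_inbreeding = use_inbreeding),
                "generalMatrix"), "CsparseMatrix")

  ncomp <- 2L + spec$has_maternal_genetic + spec$has_maternal_pe
  start <- list(sigma2_a = var_p / ncomp, sigma2_m = var_p / ncomp,
                sigma_am = 0, sigma2_pe = var_p / ncomp,
                sigma2_e = var_p / ncomp)
  nd <- length(des$dam_levels)

  if (!is.null(seed)) set.seed(seed)
  fit <- gibbs_uni_cpp(y, Wfull, C0, rhs, Ainv,
                       des$p, des$q, spec$has_maternal_genetic,
                       spec$has_maternal_pe, nd,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), priors, start)

  cols <- c("sigma2_a", "sigma2_m", "sigma_am", "sigma2_pe", "sigma2_e")
  draws <- as_tibble(setNames(as.data.frame(fit$draws), cols))
  keep_cols <- c("sigma2_a",
                 if (spec$has_maternal_genetic) c("sigma2_m", "sigma_am"),
                 if (spec$has_maternal_pe) "sigma2_pe",
                 "sigma2_e")
  draws <- draws[, keep_cols]

  structure(
    list(draws = draws,
         deviance = as.numeric(fit$deviance),
         d_at_mean = fit$d_at_mean,
         theta_mean = as.numeric(fit$theta_mean),
         sigma2_e_mean = fit$sigma2_e_mean,
         model = spec,
         config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       seed = seed, priors = priors),
         n_records = des$n,
         n_excluded = des$n_excluded,
         trait = if ("trait_name" %in% names(records))
           as.character(records$trait_name[1]) else "trait"),
    class = "gibbs_chain"
  )
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat("<gibbs_chain> model", x$model$model_id, "on", x$n_records,
      "records;", nrow(x$draws), "retained draws\n")
  print(summarize_chain(x), ...)
  invisible(x)
}

#' Bivariate animal-model Gibbs sampler
#'
#' Fits a two-trait animal model with direct additive effects per trait,
#' a 2x2 additive-genetic covariance `G0` and a 2x2 residual covariance
#' `R0`, both sampled from inverse-Wishart full conditionals. Animals with
#' a record for only one trait contribute through the pedigree; their
#' missing record is imputed each round from its conditional residual
#' distribution (data augmentation). Per retained draw the genetic and
#' environmental correlations are stored:
#' `r_g = G0[1,2] / sqrt(G0[1,1] G0[2,2])` and analogously for `r_e`.
#'
#' The trait pair is canonicalised internally (sorted by trait name) before
#' sampling and mapped back, so exchanging the trait labels under the same
#' seed transposes the covariance draws exactly.
#'
#' @param records Long trait records with a `trait_name` column holding
#'   exactly two traits.
#' @param ped A renumbered `ped_tbl`.
#' @inheritParams run_chain
#' @return A `gibbs_chain_biv` object whose `draws` tibble has columns
#'   `sigma2_a_t1`, `sigma2_a_t2`, `sigma_a12`, `sigma2_e_t1`,
#'   `sigma2_e_t2`, `sigma_e12`, `r_g`, `r_e`; `t1`/`t2` follow the order
#'   of `traits`.
#' @export
run_bivariate_chain <- function(records, ped,
                                n_iter = 50000, burn_in = 2000, thin = 20,
                                seed = NULL, priors = NULL,
                                use_inbreeding = TRUE) {
  stopifnot("trait_name" %in% names(records))
  traits <- unique(as.character(records$trait_name))
  if (length(traits) != 2L) stop("records must contain exactly 2 traits")
  ord <- order(traits)
  ctraits <- traits[ord]                      # canonical order
  records <- as_tibble(records)
  records$animal <- match_ids(records$animal, ped, "animal")

  wide <- records |>
    dplyr::select("animal", "generation", "hatch", "trait_name", "value") |>
    tidyr::pivot_wider(names_from = "trait_name", values_from = "value")
  y1 <- wide[[ctraits[1]]]
  y2 <- wide[[ctraits[2]]]
  both_missing <- is.na(y1) & is.na(y2)
  wide <- wide[!both_missing, ]
  y1 <- y1[!both_missing]; y2 <- y2[!both_missing]
  obs1 <- as.integer(!is.na(y1)); obs2 <- as.integer(!is.na(y2))
  if (sum(obs1) < 2 || sum(obs2) < 2) {
    stop("each trait needs at least 2 observed records")
  }
  n <- nrow(wide)
  q <- nrow(ped)

  fe <- tibble(generation = factor(wide$generation),
               hatch = factor(wide$hatch))
  keep <- vapply(fe, function(f) nlevels(droplevels(f)) > 1, logical(1))
  X <- if (any(keep)) {
    model.matrix(stats::reformulate(names(fe)[keep]), droplevels(fe))
  } else matrix(1, n, 1)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = wide$animal, x = 1,
                            dims = c(n, q))
  Wfull <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  Wfull <- as(as(Wfull, "generalMatrix"), "CsparseMatrix")
  C0 <- as(as(Matrix::crossprod(Wfull), "generalMatrix"), "CsparseMatrix")
  Ainv <- as(as(a_inverse(ped, use_inbreeding = use_inbreeding),
                "generalMatrix"), "CsparseMatrix")

  v1 <- var(y1[obs1 == 1]); v2 <- var(y2[obs2 == 1])
  if (is.null(priors)) {
    s <- 0.5 * sqrt(v1 * v2) / 2
    priors <- list(Vg = diag(c(3 * s, 3 * s)), nu_g = 3,
                   Vr = diag(c(3 * s, 3 * s)), nu_r = 3)
  }
  start <- list(G0 = diag(c(v1 / 2, v2 / 2)), R0 = diag(c(v1 / 2, v2 / 2)))
  y1f <- ifelse(is.na(y1), mean(y1, na.rm = TRUE), y1)
  y2f <- ifelse(is.na(y2), mean(y2, na.rm = TRUE), y2)

  if (!is.null(seed)) set.seed(seed)
  fit <- gibbs_biv_cpp(y1f, y2f, obs1, obs2, Wfull, C0, Ainv,
                       ncol(X), q, as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), priors, start)

  d <- as.data.frame(fit$draws)
  names(d) <- c("g11", "g22", "g12", "r11", "r22", "r12", "r_g", "r_e")
  # map canonical order back to the caller's trait order
  swap <- !identical(ctraits, traits)
  draws <- tibble(
    sigma2_a_t1 = if (swap) d$g22 else d$g11,
    sigma2_a_t2 = if (swap) d$g11 else d$g22,
    sigma_a12 = d$g12,
    sigma2_e_t1 = if (swap) d$r22 else d$r11,
    sigma2_e_t2 = if (swap) d$r11 else d$r22,
    sigma_e12 = d$r12,
    r_g = d$r_g,
    r_e = d$r_e
  )
  structure(
    list(draws = draws, traits = traits,
         config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       seed = seed, priors = priors),
         n_records = c(sum(obs1), sum(obs2))),
    class = "gibbs_chain_biv"
  )
}

#' @export
print.gibbs_chain_biv <- function(x, ...) {
  cat("<gibbs_chain_biv>", paste(x$traits, collapse = " / "), "on",
      paste(x$n_records, collapse = "/"), "records;", nrow(x$draws),
      "retained draws\n")
  print(summarize_chain(x), ...)
  invisible(x)
}
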