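#' Configuration for the synthetic pedigreed population
#'
#' Defaults emulate a closed layer flock regenerated by hierarchical
#' pedigreed matings: 50 sires each mated to 5 dams (250 dams), three
#' discrete offspring generations, five hatches per generation, and two
#' recorded progeny per dam, giving roughly 1500 records on about 1800
#' pedigree members. Parents of each new generation are drawn at random
#' from the previous one.
#'
#' Phenotypes follow the full maternal-effects generative law
#' `y = intercept + generation + hatch + u_animal + d_dam + pe_dam + e`
#' with `(u, d)` bivariate normal via the pedigree (Mendelian-sampling
#' variance shrunk by parental inbreeding), `pe ~ N(0, sigma2_pe)` per dam
#' and `e ~ N(0, sigma2_e)`. Generation and hatch effects default to evenly
#' spaced steps spanning plus/minus half a phenotypic SD, so ignoring them
#' is detectably wrong.
#'
#' @param n_sires,n_dams Numbers of sires and dams per generation; by
#'   default `n_dams = n_sires * mating_ratio`.
#' @param mating_ratio Dams mated per sire.
#' @param n_generations Number of offspring generations.
#' @param n_hatches Hatches, assigned uniformly within generation.
#' @param progeny_per_dam Recorded progeny per dam.
#' @param intercept Trait mean on the observed scale.
#' @param sigma2_a,sigma2_m,sigma_am,sigma2_pe,sigma2_e True (co)variance
#'   components; `[[sigma2_a, sigma_am], [sigma_am, sigma2_m]]` must be
#'   positive definite when `sigma2_m > 0`.
#' @param gen_effects,hatch_effects Optional explicit fixed-effect level
#'   values (numeric vectors of length `n_generations` / `n_hatches`).
#' @param trait_name Label for the simulated trait.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sires = 50, mating_ratio = 5,
                       n_dams = n_sires * mating_ratio,
                       n_generations = 3, n_hatches = 5,
                       progeny_per_dam = 2, intercept = 100,
                       sigma2_a = 40, sigma2_m = 0, sigma_am = 0,
                       sigma2_pe = 0, sigma2_e = 60,
                       gen_effects = NULL, hatch_effects = NULL,
                       trait_name = "trait", seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(sigma2_a > 0, sigma2_e > 0, sigma2_m >= 0, sigma2_pe >= 0)
  if (cfg$sigma2_m == 0 && cfg$sigma_am != 0) {
    stop("sigma_am requires sigma2_m > 0")
  }
  if (cfg$sigma2_m > 0 &&
      cfg$sigma2_a * cfg$sigma2_m - cfg$sigma_am^2 <= 0) {
    stop("direct-maternal covariance matrix is not positive definite")
  }
  n_off <- n_dams * progeny_per_dam
  if (n_generations > 1 && n_off < n_sires + n_dams) {
    stop("not enough progeny per generation (", n_off,
         ") to supply the next generation's ", n_sires + n_dams, " parents")
  }
  structure(cfg, class = "sim_config")
}

# Pedigree skeleton: founders then generation-by-generation matings.
# Returns integer vectors sire/dam and the generation of each animal
# (0 = founder).
build_sim_pedigree <- function(cfg) {
  n_found <- cfg$n_sires + cfg$n_dams
  sire <- rep(0L, n_found)
  dam <- rep(0L, n_found)
  gen <- rep(0L, n_found)
  sires <- seq_len(cfg$n_sires)
  dams <- cfg$n_sires + seq_len(cfg$n_dams)
  for (g in seq_len(cfg$n_generations)) {
    off_sire <- rep(rep(sires, each = cfg$mating_ratio), each = cfg$progeny_per_dam)
    off_dam <- rep(dams, each = cfg$progeny_per_dam)
    stopifnot(length(off_sire) == length(off_dam))
    first <- length(sire) + 1L
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    gen <- c(gen, rep(g, length(off_sire)))
    offspring <- seq(first, length(sire))
    if (g < cfg$n_generations) {
      parents <- sample(offspring, cfg$n_sires + cfg$n_dams)
      sires <- parents[seq_len(cfg$n_sires)]
      dams <- parents[cfg$n_sires + seq_len(cfg$n_dams)]
    }
  }
  list(sire = sire, dam = dam, generation = gen)
}

as_ped_tbl <- function(sire, dam) {
  q <- length(sire)
  out <- tibble(animal = seq_len(q), sire = as.integer(sire),
                dam = as.integer(dam),
                inbreeding = inbreeding_ml_cpp(as.integer(sire),
                                               as.integer(dam)))
  attr(out, "label_map") <- tibble(label = as.character(seq_len(q)),
                                   id = seq_len(q))
  class(out) <- c("ped_tbl", class(out))
  out
}

# Breeding values down the pedigree: founders from N(0, G0); offspring are
# the mid-parent mean plus a Mendelian-sampling deviate with covariance
# 0.5 * (1 - (F_s + F_d)/2) * G0.
drop_breeding_values <- function(sire, dam, f, G0) {
  q <- length(sire)
  k <- nrow(G0)
  L <- chol(G0)
  z <- matrix(rnorm(q * k), q, k) %*% L
  bv <- matrix(0, q, k)
  for (i in seq_len(q)) {
    s <- sire[i]; d <- dam[i]
    if (s == 0L && d == 0L) {
      bv[i, ] <- z[i, ]
    } else {
      pa <- if (s > 0L) bv[s, ] else 0
      pd <- if (d > 0L) bv[d, ] else 0
      fs <- if (s > 0L) f[s] else 0
      fd <- if (d > 0L) f[d] else 0
      shrink <- sqrt(0.5 * (1 - (fs + fd) / 2))
      half <- (if (s > 0L && d > 0L) 0.5 else if (s > 0L || d > 0L) 0.5 else 0)
      bv[i, ] <- half * (pa + pd) + shrink * z[i, ]
    }
  }
  bv
}

#' Simulate a pedigreed population with maternal effects
#'
#' Generates the pedigree, one record per non-founder animal, and a truth
#' manifest holding every sampled effect, under the generative law of the
#' full maternal-effects animal model (see [sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @return A list: `pedigree` (a renumbered `ped_tbl`), `records` (tibble
#'   `animal`, `dam`, `generation`, `hatch`, `value`, `trait_name`) and
#'   `truth` (list with per-animal `u`/`d`, per-dam `pe`, fixed-effect
#'   values and the config).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sk <- build_sim_pedigree(cfg)
  ped <- as_ped_tbl(sk$sire, sk$dam)
  q <- nrow(ped)

  var_p <- cfg$sigma2_a + cfg$sigma2_m + cfg$sigma_am + cfg$sigma2_pe +
    cfg$sigma2_e
  ge <- cfg$gen_effects %||%
    (seq(-0.5, 0.5, length.out = cfg$n_generations) * sqrt(var_p))
  he <- cfg$hatch_effects %||%
    (seq(-0.5, 0.5, length.out = cfg$n_hatches) * sqrt(var_p))
  stopifnot(length(ge) == cfg$n_generations, length(he) == cfg$n_hatches)

  if (cfg$sigma2_m > 0) {
    G0 <- matrix(c(cfg$sigma2_a, cfg$sigma_am, cfg$sigma_am, cfg$sigma2_m), 2)
  } else {
    G0 <- matrix(cfg$sigma2_a, 1)
  }
  bv <- drop_breeding_values(ped$sire, ped$dam, ped$inbreeding, G0)
  u <- bv[, 1]
  d <- if (cfg$sigma2_m > 0) bv[, 2] else rep(0, q)
  pe <- rnorm(q, 0, sqrt(cfg$sigma2_pe))   # drawn per animal, used per dam

  rec_idx <- which(sk$generation > 0L)
  n <- length(rec_idx)
  hatch <- sample.int(cfg$n_hatches, n, replace = TRUE)
  dam_of <- ped$dam[rec_idx]
  value <- cfg$intercept + ge[sk$generation[rec_idx]] + he[hatch] +
    u[rec_idx] + d[dam_of] + pe[dam_of] +
    rnorm(n, 0, sqrt(cfg$sigma2_e))

  records <- tibble(
    animal = rec_idx,
    dam = dam_of,
    generation = sk$generation[rec_idx],
    hatch = hatch,
    value = value,
    trait_name = cfg$trait_name
  )
  truth <- list(
    effects = tibble(animal = seq_len(q), generation = sk$generation,
                     u = u, d = d, pe = pe),
    gen_effects = ge, hatch_effects = he, config = cfg
  )
  list(pedigree = ped, records = records, truth = truth)
}

#' Simulate correlated traits under a direct-additive model
#'
#' Multi-trait companion to [simulate_population()]: each animal receives a
#' vector of breeding values with covariance `Sigma_g` via the pedigree and
#' residuals with covariance `Sigma_r` (no maternal effects). One record
#' per trait per non-founder animal, in long format.
#'
#' @param cfg A [sim_config()]; its `sigma2_*` fields are ignored in favour
#'   of the matrices.
#' @param Sigma_g,Sigma_r Genetic and residual covariance matrices
#'   (`k x k`, positive definite).
#' @param trait_names Length-`k` trait labels.
#' @return As [simulate_population()], with `records` holding `k` traits
#'   and `truth$effects` one `u_<trait>` column per trait.
#' @export
simulate_multitrait <- function(cfg, Sigma_g, Sigma_r,
                                trait_names = paste0("trait", seq_len(ncol(Sigma_g)))) {
  stopifnot(inherits(cfg, "sim_config"),
            is.matrix(Sigma_g), is.matrix(Sigma_r),
            all(dim(Sigma_g) == dim(Sigma_r)),
            length(trait_names) == ncol(Sigma_g))
  if (min(eigen(Sigma_g, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(Sigma_r, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("Sigma_g and Sigma_r must be positive definite")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- ncol(Sigma_g)
  sk <- build_sim_pedigree(cfg)
  ped <- as_ped_tbl(sk$sire, sk$dam)
  q <- nrow(ped)

  var_p <- diag(Sigma_g) + diag(Sigma_r)
  ge <- outer(seq(-0.5, 0.5, length.out = cfg$n_generations), sqrt(var_p))
  he <- outer(seq(-0.5, 0.5, length.out = cfg$n_hatches), sqrt(var_p))

  U <- drop_breeding_values(ped$sire, ped$dam, ped$inbreeding, Sigma_g)
  rec_idx <- which(sk$generation > 0L)
  n <- length(rec_idx)
  hatch <- sample.int(cfg$n_hatches, n, replace = TRUE)
  E <- matrix(rnorm(n * k), n, k) %*% chol(Sigma_r)

  vals <- sapply(seq_len(k), function(t) {
    cfg$intercept + ge[sk$generation[rec_idx], t] + he[hatch, t] +
      U[rec_idx, t] + E[, t]
  })
  records <- purrr::map_dfr(seq_len(k), function(t) {
    tibble(animal = rec_idx, dam = ped$dam[rec_idx],
           generation = sk$generation[rec_idx], hatch = hatch,
           value = vals[, t], trait_name = trait_names[t])
  })
  eff <- as_tibble(setNames(as.data.frame(U), paste0("u_", trait_names)))
  eff <- dplyr::bind_cols(tibble(animal = seq_len(q),
                                 generation = sk$generation), eff)
  list(pedigree = ped, records = records,
       truth = list(effects = eff, config = cfg,
                    Sigma_g = Sigma_g, Sigma_r = Sigma_r))
}

#' Thin records to emulate trait-specific missingness
#'
#' Random per-trait thinning plus optional blanking of whole generations
#' for chosen traits (as when late-cycle traits are only recorded in a
#' subset of generations).
#'
#' @param records Long trait records with a `trait_name` column.
#' @param keep Keep fraction in `(0, 1]`: a single number or a named vector
#'   per trait.
#' @param drop_generations Named list, trait -> generations to blank.
#' @param seed Optional seed.
#' @return The thinned records tibble.
#' @export
apply_missingness <- function(records, keep = 1, drop_generations = NULL,
                              seed = NULL) {
  stopifnot(is.data.frame(records), "trait_name" %in% names(records))
  if (any(keep <= 0) || any(keep > 1)) stop("keep fractions must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  records <- as_tibble(records)
  kf <- if (is.null(names(keep))) {
    setNames(rep(keep[1], length(unique(records$trait_name))),
             unique(records$trait_name))
  } else keep
  out <- records |>
    dplyr::group_by(.data$trait_name) |>
    dplyr::filter({
      f <- kf[[dplyr::cur_group()$trait_name]] %||% 1
      if (f >= 1) rep(TRUE, dplyr::n()) else stats::runif(dplyr::n()) < f
    }) |>
    dplyr::ungroup()
  for (tr in names(drop_generations)) {
    out <- out[!(out$trait_name == tr &
                   out$generation %in% drop_generations[[tr]]), ]
  }
  out
}
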