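#' Model specification for variance partitioning
#'
#' The three nested animal models for a maternally influenced trait:
#' * `M1` — direct additive effect only: `y = Xb + Zu + e`
#' * `M2` — adds a maternal genetic effect with a direct-maternal
#'   covariance: `y = Xb + Zu + Wd + e`
#' * `M3` — further adds a maternal permanent environmental effect of the
#'   dam: `y = Xb + Zu + Wd + Mpe + e`
#'
#' @param model One of `"M1"`, `"M2"`, `"M3"`.
#' @return A `model_spec` list with fields `model_id`,
#'   `has_maternal_genetic`, `has_maternal_pe`, `fixed_factors`.
#' @export
model_spec <- function(model = c("M1", "M2", "M3")) {
  model <- match.arg(model)
  structure(
    list(
      model_id = model,
      has_maternal_genetic = model %in% c("M2", "M3"),
      has_maternal_pe = model == "M3",
      fixed_factors = c("generation", "hatch")
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$model_id,
      if (x$has_maternal_genetic) "+ maternal genetic" else "",
      if (x$has_maternal_pe) "+ maternal permanent env." else "", "\n")
  invisible(x)
}

# Map record animal/dam labels onto renumbered pedigree ids.
match_ids <- function(x, ped, what = "animal") {
  map <- attr(ped, "label_map")
  id <- map$id[match(as.character(x), map$label)]
  if (anyNA(id)) {
    # already-renumbered integer ids pass through
    xi <- suppressWarnings(as.integer(x))
    if (!anyNA(xi) && all(xi >= 0) && all(xi <= nrow(ped))) return(xi)
    stop(sum(is.na(id)), " ", what, " id(s) in records not found in pedigree, e.g. ",
         as.character(x)[which(is.na(id))[1]])
  }
  id
}

#' Build incidence matrices for a model
#'
#' Assembles the fixed-effect matrix `X` (intercept plus reference-coded
#' generation and hatch dummies), the record-to-animal matrix `Z`, and — for
#' models with maternal effects — the record-to-dam matrices `W` (maternal
#' genetic, columns indexing pedigree animals) and `Mpe` (maternal permanent
#' environment, columns indexing the distinct dams with progeny records).
#' Under `M2`/`M3`, records whose dam is unknown are excluded with a logged
#' count, since their maternal link is undefined.
#'
#' @param records Trait records with columns `animal`, `dam`, `generation`,
#'   `hatch`, `value`.
#' @param ped A renumbered `ped_tbl`.
#' @param spec A [model_spec()].
#' @return A `design_matrices` list: `X`, `Z`, `W`, `Mpe` (sparse), `y`,
#'   `n`, `p`, `q`, `dam_levels`, `records` (rows actually used) and
#'   `n_excluded`.
#' @export
build_design <- function(records, ped, spec) {
  stopifnot(is.data.frame(records), inherits(ped, "ped_tbl"),
            inherits(spec, "model_spec"))
  records <- as_tibble(records)
  records$animal <- match_ids(records$animal, ped, "animal")
  if (any(records$animal == 0L)) stop("records reference unknown animal id 0")
  if ("dam" %in% names(records)) {
    dm <- as.character(records$dam)
    dm[is.na(dm) | dm == ""] <- "0"
    dam_id <- integer(nrow(records))
    known <- dm != "0"
    if (any(known)) dam_id[known] <- match_ids(dm[known], ped, "dam")
    records$dam <- dam_id
  } else {
    records$dam <- ped$dam[records$animal]
  }
  n_excluded <- 0L
  if (spec$has_maternal_genetic) {
    drop <- records$dam == 0L
    n_excluded <- sum(drop)
    if (n_excluded > 0L) {
      message(n_excluded, " record(s) with unknown dam excluded under ",
              spec$model_id)
      records <- records[!drop, , drop = FALSE]
    }
    if (nrow(records) == 0L) stop("all records excluded: every dam unknown")
  }
  n <- nrow(records)
  q <- nrow(ped)

  fe <- tibble(
    generation = factor(records$generation),
    hatch = factor(records$hatch)
  )
  keep <- vapply(fe, function(f) nlevels(droplevels(f)) > 1, logical(1))
  if (any(keep)) {
    fml <- stats::reformulate(names(fe)[keep])
    X <- model.matrix(fml, droplevels(fe))
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  Xs <- as(as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = records$animal, x = 1,
                            dims = c(n, q))
  W <- NULL
  Mpe <- NULL
  dam_levels <- integer(0)
  if (spec$has_maternal_genetic) {
    W <- Matrix::sparseMatrix(i = seq_len(n), j = records$dam, x = 1,
                              dims = c(n, q))
  }
  if (spec$has_maternal_pe) {
    dam_levels <- sort(unique(records$dam))
    Mpe <- Matrix::sparseMatrix(i = seq_len(n),
                                j = match(records$dam, dam_levels), x = 1,
                                dims = c(n, length(dam_levels)))
  }
  structure(
    list(X = Xs, Z = Z, W = W, Mpe = Mpe, y = records$value,
         n = n, p = ncol(X), q = q, dam_levels = dam_levels,
         records = records, n_excluded = n_excluded, spec = spec),
    class = "design_matrices"
  )
}
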