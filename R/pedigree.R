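#' Read a pedigree file
#'
#' Reads a three-column pedigree (animal, sire, dam) from whitespace- or
#' comma-delimited text. `0`, empty fields and `NA` denote unknown parents.
#' A header row is assumed when the first row contains any of the tokens
#' `animal`, `id`, `sire` or `dam` (case-insensitive); otherwise all rows are
#' data, so pedigrees with arbitrary string labels are read intact.
#'
#' @param path Path to the pedigree file.
#' @return A tibble with character columns `animal`, `sire`, `dam`
#'   (unknown parent = `"0"`), ready for [renumber_pedigree()].
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tokens <- tolower(strsplit(gsub("\"", "", first),
                             if (sep == ",") "," else "[[:space:]]+")[[1]])
  has_header <- any(tokens %in% c("animal", "id", "sire", "dam"))
  df <- read.table(path, header = has_header, sep = sep,
                   colClasses = "character", strip.white = TRUE,
                   blank.lines.skip = TRUE)
  if (ncol(df) < 3L) {
    stop("pedigree file must have at least 3 columns (animal, sire, dam)")
  }
  df <- df[, 1:3]
  names(df) <- c("animal", "sire", "dam")
  df$sire[is.na(df$sire) | df$sire == ""] <- "0"
  df$dam[is.na(df$dam) | df$dam == ""] <- "0"
  as_tibble(df)
}

#' Renumber a pedigree so parents precede offspring
#'
#' Validates and recodes a pedigree to consecutive integer ids `1..q` in an
#' order where every parent precedes its offspring (the convention required
#' by the tabular relationship-matrix method, Henderson's inverse and the
#' Meuwissen-Luo inbreeding algorithm). Animals that appear only as parents
#' are inserted as founders. Inbreeding coefficients are computed and stored.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam`; ids may be
#'   integers or arbitrary strings, `0`/`NA`/empty = unknown parent.
#' @param map_file Optional path; when given, the label-to-id map is written
#'   there as two-column text (`original_label`, `new_id`).
#' @return A `ped_tbl` tibble with integer columns `animal`, `sire`, `dam`
#'   (unknown = 0) and numeric `inbreeding`, rows ordered by `animal`. The
#'   original-label map is attached as attribute `"label_map"` (a tibble with
#'   columns `label`, `id`).
#' @export
renumber_pedigree <- function(ped, map_file = NULL) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  an <- as.character(ped$animal)
  si <- as.character(ped$sire)
  da <- as.character(ped$dam)
  unk <- function(x) is.na(x) | x == "0" | x == ""
  si[unk(si)] <- "0"
  da[unk(da)] <- "0"
  if (any(unk(an))) stop("animal id is missing or '0' in row ",
                         which(unk(an))[1])
  if (any(an == si | an == da)) {
    stop("animal is its own parent: ", an[which(an == si | an == da)[1]])
  }

  # duplicate rows: identical ones collapse, conflicting parents are an error
  key <- paste(an, si, da, sep = "\r")
  keep <- !duplicated(key)
  an <- an[keep]; si <- si[keep]; da <- da[keep]
  if (anyDuplicated(an)) {
    stop("duplicate animal rows with conflicting parents: ",
         an[duplicated(an)][1])
  }

  # parents never declared as animals become founders
  only_parents <- setdiff(setdiff(c(si, da), "0"), an)
  if (length(only_parents)) {
    an <- c(an, only_parents)
    si <- c(si, rep("0", length(only_parents)))
    da <- c(da, rep("0", length(only_parents)))
  }
  q <- length(an)
  idx <- setNames(seq_len(q), an)
  sidx <- ifelse(si == "0", 0L, idx[si])
  didx <- ifelse(da == "0", 0L, idx[da])

  # stable topological order: repeated passes in appearance order, so
  # renumbering an already-renumbered pedigree is the identity map
  ord <- integer(q)
  placed <- logical(q)
  nplaced <- 0L
  repeat {
    progress <- FALSE
    for (i in seq_len(q)) {
      if (placed[i]) next
      s_ok <- sidx[i] == 0L || placed[sidx[i]]
      d_ok <- didx[i] == 0L || placed[didx[i]]
      if (s_ok && d_ok) {
        nplaced <- nplaced + 1L
        ord[i] <- nplaced
        placed[i] <- TRUE
        progress <- TRUE
      }
    }
    if (nplaced == q) break
    if (!progress) {
      stop("pedigree contains a cycle involving animal: ",
           an[which(!placed)[1]])
    }
  }

  new_id <- ord
  new_sire <- integer(q)
  new_dam <- integer(q)
  new_sire[sidx > 0L] <- new_id[sidx[sidx > 0L]]
  new_dam[didx > 0L] <- new_id[didx[didx > 0L]]
  out <- tibble(animal = new_id, sire = new_sire, dam = new_dam)
  out <- out[order(out$animal), ]
  out$inbreeding <- inbreeding_ml_cpp(out$sire, out$dam)
  label_map <- tibble(label = an[order(new_id)], id = seq_len(q))
  attr(out, "label_map") <- label_map
  class(out) <- c("ped_tbl", class(out))
  if (!is.null(map_file)) {
    write.table(label_map, map_file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("original_label", "new_id"))
  }
  out
}

#' Load and renumber a pedigree file
#'
#' Convenience wrapper: [read_pedigree()] followed by [renumber_pedigree()].
#'
#' @inheritParams read_pedigree
#' @inheritParams renumber_pedigree
#' @return A renumbered `ped_tbl`; see [renumber_pedigree()].
#' @export
load_and_renumber <- function(path, map_file = NULL) {
  renumber_pedigree(read_pedigree(path), map_file = map_file)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' `F_i = 0.5 * a(sire_i, dam_i)`, the half-relationship of the parents;
#' founders and animals with an unknown parent have `F = 0` (unknown parents
#' are treated as unrelated, non-inbred base animals).
#'
#' @param ped A renumbered `ped_tbl` from [renumber_pedigree()].
#' @return Numeric vector of inbreeding coefficients, one per animal.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  inbreeding_ml_cpp(ped$sire, ped$dam)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A with
#' `a_ii = 1 + F_i` and `a_ij = 0.5 * (a_{j,sire(i)} + a_{j,dam(i)})`.
#'
#' @param ped A renumbered `ped_tbl`.
#' @param max_q Refuse to build the dense form above this many animals.
#' @return A dense symmetric `q x q` matrix.
#' @export
a_matrix <- function(ped, max_q = 5000) {
  stopifnot(inherits(ped, "ped_tbl"))
  q <- nrow(ped)
  if (q > max_q) {
    stop("dense A refused for q = ", q, " > max_q = ", max_q,
         "; raise max_q or use a_inverse()")
  }
  A <- matrix(0, q, q)
  s <- ped$sire
  d <- ped$dam
  for (i in seq_len(q)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      r <- numeric(i - 1L)
      if (s[i] > 0L) r <- r + 0.5 * A[s[i], j]
      if (d[i] > 0L) r <- r + 0.5 * A[d[i], j]
      A[i, j] <- r
      A[j, i] <- r
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' with the Mendelian-sampling variance adjusted for parental inbreeding
#' (the adjustment can be switched off for cross-checks against software
#' that ignores inbreeding).
#'
#' @param ped A renumbered `ped_tbl`.
#' @param use_inbreeding Account for parental inbreeding in the
#'   Mendelian-sampling terms (default `TRUE`).
#' @return A sparse symmetric `q x q` `Matrix::dgCMatrix`.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "ped_tbl"))
  q <- nrow(ped)
  s <- ped$sire
  d <- ped$dam
  f <- if (use_inbreeding) ped$inbreeding else rep(0, q)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  delta <- 0.5 - 0.25 * (fs + fd)
  if (any(delta <= 0)) {
    stop("non-positive Mendelian sampling variance for animal ",
         which(delta <= 0)[1], "; inbreeding input is corrupt")
  }
  alpha <- 1 / delta

  ii <- seq_len(q)
  ti <- ii; tj <- ii; tx <- alpha
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  ks <- which(s > 0L)
  kd <- which(d > 0L)
  kb <- which(s > 0L & d > 0L)
  if (length(ks)) {
    add(ks, s[ks], -alpha[ks] / 2); add(s[ks], ks, -alpha[ks] / 2)
    add(s[ks], s[ks], alpha[ks] / 4)
  }
  if (length(kd)) {
    add(kd, d[kd], -alpha[kd] / 2); add(d[kd], kd, -alpha[kd] / 2)
    add(d[kd], d[kd], alpha[kd] / 4)
  }
  if (length(kb)) {
    add(s[kb], d[kb], alpha[kb] / 4); add(d[kb], s[kb], alpha[kb] / 4)
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(q, q))
}
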