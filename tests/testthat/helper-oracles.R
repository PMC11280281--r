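# Independent oracles and fixture builders used across test files.

# Malecot kinship by direct recursion -- an implementation of the
# relationship structure independent of the package's tabular/Henderson
# paths. A_oracle = 2 * phi.
kinship_oracle <- function(sire, dam) {
  q <- length(sire)
  phi <- matrix(0, q, q)
  for (i in seq_len(q)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0
        if (s > 0) v <- v + 0.5 * phi[s, j]
        if (d > 0) v <- v + 0.5 * phi[d, j]
        phi[i, j] <- phi[j, i] <- v
      }
    }
    phi[i, i] <- 0.5 * (1 + if (s > 0 && d > 0) phi[s, d] else 0)
  }
  2 * phi
}

# ped_tbl from explicit sire/dam id vectors (already topological)
ped_from_vectors <- function(sire, dam) {
  renumber_pedigree(tibble::tibble(
    animal = seq_along(sire), sire = sire, dam = dam
  ))
}

# random valid pedigree: founders plus random earlier-animal matings
random_pedigree <- function(q, p_founder = 0.25) {
  sire <- integer(q)
  dam <- integer(q)
  for (i in seq_len(q)) {
    if (i <= 4 || stats::runif(1) < p_founder) next
    pick <- sample(i - 1L, 2L)
    sire[i] <- pick[1]
    dam[i] <- pick[2]
  }
  ped_from_vectors(sire, dam)
}

# minimal records table around a pedigree
records_for <- function(ped, animals, values, generation = 1, hatch = 1) {
  tibble::tibble(
    animal = animals,
    dam = if (is.null(ped)) 0L else ped$dam[animals],
    generation = generation,
    hatch = hatch,
    value = values,
    trait_name = "t"
  )
}
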