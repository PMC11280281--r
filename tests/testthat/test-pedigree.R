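test_that("loading and renumbering handles founders, implicit parents and labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a 0 0", "b 0 0", "c 0 0"), f)
  ped <- load_and_renumber(f)
  expect_s3_class(ped, "ped_tbl")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$inbreeding, rep(0, 3))
  expect_equal(attr(ped, "label_map")$label, c("a", "b", "c"))

  # animals appearing only as parents become founders placed first
  ped2 <- renumber_pedigree(tibble::tibble(animal = "C", sire = "A", dam = "B"))
  expect_equal(nrow(ped2), 3)
  map <- attr(ped2, "label_map")
  expect_equal(map$label[map$id == 3], "C")
  expect_true(all(map$id[map$label %in% c("A", "B")] < 3))
  expect_equal(ped2$sire[3], map$id[map$label == "A"])

  # sidecar map file round-trips
  mf <- withr::local_tempfile(fileext = ".txt")
  renumber_pedigree(tibble::tibble(animal = "C", sire = "A", dam = "B"),
                    map_file = mf)
  written <- read.table(mf, header = TRUE)
  expect_equal(nrow(written), 3)
  expect_equal(sort(written$new_id), 1:3)
})

test_that("pedigree validation rejects self-parents, cycles and conflicts", {
  expect_error(
    renumber_pedigree(tibble::tibble(animal = "A", sire = "A", dam = "0")),
    "its own parent"
  )
  expect_error(
    renumber_pedigree(tibble::tibble(animal = c("A", "B"),
                                     sire = c("B", "A"), dam = c("0", "0"))),
    "cycle"
  )
  expect_error(
    renumber_pedigree(tibble::tibble(animal = c("A", "A"),
                                     sire = c("B", "C"), dam = c("0", "0"))),
    "conflicting"
  )
})

test_that("renumbering an already-renumbered pedigree is the identity map", {
  withr::local_seed(11)
  ped <- random_pedigree(80)
  again <- renumber_pedigree(ped)
  expect_equal(again$animal, ped$animal)
  expect_equal(again$sire, ped$sire)
  expect_equal(again$dam, ped$dam)
  expect_equal(attr(again, "label_map")$label, as.character(1:80))
})

test_that("inbreeding matches classic values and the kinship oracle", {
  # offspring of unrelated founders
  ped <- ped_from_vectors(c(0, 0, 1), c(0, 0, 2))
  expect_equal(compute_inbreeding(ped), c(0, 0, 0))

  # offspring of full sibs: F = 0.25
  ped_fs <- ped_from_vectors(c(0, 0, 1, 1, 3), c(0, 0, 2, 2, 4))
  expect_equal(ped_fs$inbreeding[5], 0.25)

  # parent x offspring mating: F = 0.25
  ped_po <- ped_from_vectors(c(0, 0, 1, 1), c(0, 0, 2, 3))
  expect_equal(ped_po$inbreeding[4], 0.25)

  # random pedigrees agree with the recursive kinship oracle
  withr::local_seed(42)
  for (rep in 1:5) {
    ped <- random_pedigree(60)
    A <- kinship_oracle(ped$sire, ped$dam)
    expect_equal(ped$inbreeding, diag(A) - 1, tolerance = 1e-12)
  }
})

test_that("relationship matrix follows the tabular method", {
  # unrelated founders -> identity
  ped <- ped_from_vectors(rep(0, 4), rep(0, 4))
  expect_equal(a_matrix(ped), diag(4))

  # parent-offspring 0.5, full sibs 0.5, half sibs 0.25
  ped <- ped_from_vectors(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 2, 2, 3))
  A <- a_matrix(ped)
  expect_equal(A[1, 4], 0.5)   # parent-offspring
  expect_equal(A[4, 5], 0.5)   # full sibs
  expect_equal(A[4, 6], 0.25)  # half sibs (shared sire only)

  # diagonal is 1 + F elementwise; PSD; oracle equivalence
  withr::local_seed(7)
  ped <- random_pedigree(100)
  A <- a_matrix(ped)
  expect_equal(diag(A), 1 + ped$inbreeding)
  expect_equal(A, kinship_oracle(ped$sire, ped$dam), tolerance = 1e-12)
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  expect_error(a_matrix(ped, max_q = 50), "max_q")
})

test_that("Henderson's inverse matches hand pattern and dense inversion", {
  # founders -> identity
  ped <- ped_from_vectors(rep(0, 3), rep(0, 3))
  expect_equal(as.matrix(a_inverse(ped)), diag(3))

  # trio: two founders + offspring
  trio <- ped_from_vectors(c(0, 0, 1), c(0, 0, 2))
  Ai <- as.matrix(a_inverse(trio))
  expect_equal(diag(Ai), c(1.5, 1.5, 2))
  expect_equal(Ai[1, 2], 0.5)
  expect_equal(Ai[1, 3], -1)
  expect_equal(Ai[2, 3], -1)

  # random pedigrees: A^-1 A = I, and agreement with dense solve()
  withr::local_seed(99)
  for (rep in 1:5) {
    ped <- random_pedigree(50)
    A <- a_matrix(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(nrow(ped)))), 1e-8)
    expect_equal(Ai, solve(A), tolerance = 1e-8)
  }
})

test_that("inverse without inbreeding reproduces the simplified rules", {
  # animal 5 (F = 0.25, full-sib parents) is itself a parent of animal 6,
  # so its inbreeding enters animal 6's Mendelian-sampling term
  ped <- ped_from_vectors(c(0, 0, 1, 1, 3, 5), c(0, 0, 2, 2, 4, 2))
  Ai_f <- as.matrix(a_inverse(ped, use_inbreeding = TRUE))
  Ai_0 <- as.matrix(a_inverse(ped, use_inbreeding = FALSE))
  expect_equal(Ai_f[6, 6], 1 / (0.5 - 0.25 * 0.25))
  expect_equal(Ai_0[6, 6], 2)
})
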