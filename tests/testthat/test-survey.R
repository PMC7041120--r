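test_that("fixed-point classification and diagonal distances", {
  expect_identical(classify_fp(c(3L, 3L, 1L, 0L, 1L, 0L))$class, "M")
  expect_identical(classify_fp(c(3L, 3L, 1L, 0L, 1L, 0L))$distance_from_M, 0L)
  expect_identical(classify_fp(c(0L, 0L, 2L, 1L, 0L, 2L))$class, "E")
  expect_identical(classify_fp(c(0L, 0L, 2L, 1L, 0L, 2L))$distance_from_E, 0L)
  mid <- classify_fp(c(2L, 0L, 1L, 1L, 0L, 1L))
  expect_identical(mid$class, "intermediate")
  expect_identical(mid$distance_from_E, 3L)
  expect_error(classify_fp(c(4L, 0L, 0L, 0L, 0L, 0L)), "EMT state space")
  expect_error(classify_fp(c(1L, 1L, 1L)), "EMT state space")
})

test_that("distance_from_E + distance_from_M = 8 on every cell", {
  cells <- expand.grid(0:3, 0:3, 0:2, 0:1, 0:1, 0:2)
  cl <- classify_fp(as.matrix(cells))
  expect_identical(nrow(cl), 576L)
  expect_true(all(cl$distance_from_E + cl$distance_from_M == 8L))
  expect_identical(sum(cl$class == "E"), 12L)   # (0,0,*,*,*,2): 3*2*2 cells
  expect_identical(sum(cl$class == "M"), 12L)
})

test_that("layer surveys reproduce the hallmark TGFb presence profile", {
  sv <- survey_layers(emt(), "TGFb", n_per_layer = 200, seed = 0,
                      layers = c(1L, 3L, 5L))
  expect_identical(sv$layer, c(1L, 3L, 5L))
  # E always present at the lowest TGFb layer, both states in the middle
  expect_identical(sv$E_present[1], 1)
  expect_identical(sv$E_present[2], 1)
  expect_identical(sv$M_present[2], 1)
  expect_identical(sv$M_present[3], 1)
  expect_lt(sv$E_present[3], 0.5)
  # k histogram rows sum to one; no non-FP stable nodes
  k_cols <- grep("^k_", names(sv), value = TRUE)
  expect_equal(unname(rowSums(sv[, k_cols])), rep(1, 3))
  expect_true(all(sv$non_fp_stable == 0))
})

test_that("stable fixed points tile the diagonals consistently", {
  pg <- emt_pg("essential")
  a <- sample_addresses(pg, 40, seed = 2)
  cen <- morse_census(pg, a)
  for (r in seq_len(nrow(cen))) {
    cells <- do.call(rbind, lapply(cen$labels[[r]], label_to_cell))
    cl <- classify_fp(cells)
    expect_identical(nrow(cl), cen$k[r])           # diagonals partition FPs
    expect_true(all(cl$distance_from_E %in% 0:8))
  }
})

test_that("multistability spectrum is a per-layer distribution", {
  sv <- survey_layers(emt(), "Ovol2", n_per_layer = 150, seed = 3,
                      layers = c(1L, 5L))
  sp <- multistability_spectrum(sv)
  tot <- tapply(sp$proportion, sp$layer, sum)
  expect_equal(as.numeric(tot), rep(1, 2))
  expect_identical(glance(sv)$gene, "Ovol2")
})

test_that("survey reports are deterministic and reject empty input", {
  sv1 <- survey_layers(emt(), "TGFb", n_per_layer = 50, seed = 4,
                       layers = 5L)
  sv2 <- survey_layers(emt(), "TGFb", n_per_layer = 50, seed = 4,
                       layers = 5L)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(sv1, d1); write_report(sv2, d2)
  expect_identical(readLines(paste0(d1, ".json")),
                   readLines(paste0(d2, ".json")))
  expect_identical(readLines(paste0(d1, ".csv")),
                   readLines(paste0(d2, ".csv")))
  empty <- sv1[0, ]
  class(empty) <- class(sv1)
  expect_error(write_report(empty, tempfile()), "empty")
})

test_that("domain occupancy is monotone and contains E and M families", {
  pg <- emt_pg("essential")
  a <- sample_addresses(pg, 60, seed = 6)
  occ_small <- domain_occupancy(pg, a[1:20, ])
  occ_big <- domain_occupancy(pg, a)
  expect_lte(occ_small$count, occ_big$count)
  expect_true(all(occ_small$labels %in% occ_big$labels))
  expect_identical(occ_big$fraction, occ_big$count / 576)
  cells <- do.call(rbind, lapply(occ_big$labels, label_to_cell))
  cl <- classify_fp(cells)
  expect_true(any(cl$class == "E"))
  expect_true(any(cl$class == "M"))
  # reports
  p <- tempfile()
  write_report(occ_big, p)
  expect_true(file.exists(paste0(p, ".csv")))
})

test_that("exhaustive surveys respect the work bound", {
  expect_error(
    survey_layers(emt(), "TGFb", exhaustive = TRUE, work_bound = 10),
    "work bound")
})

test_that("layer survey plots build", {
  sv <- survey_layers(emt(), "TGFb", n_per_layer = 30, seed = 9,
                      layers = c(1L, 5L))
  for (tp in c("em", "presence", "k", "diagonal")) {
    expect_s3_class(autoplot(sv, type = tp), "ggplot")
  }
})
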