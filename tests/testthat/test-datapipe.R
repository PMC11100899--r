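write_score_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("score tables load, drop bad rows with a report, and collapse duplicates", {
  path <- write_score_csv(data.frame(
    smiles = c("CCO", "CCN", "c1ccccc1", "CCC", "CC"),
    dG_kcal_mol = c(-7.1, -6.2, -8.3, -5.9, -6.6)))
  tab <- load_score_table(path)
  expect_equal(nrow(tab), 5L)

  # one bad SMILES among five is dropped and reported
  path <- write_score_csv(data.frame(
    smiles = c("CCO", "notasmiles$$", "CCN", "CCC", "CC"),
    dG_kcal_mol = c(-7.1, -6.2, -8.3, -5.9, -6.6)))
  expect_message(tab <- load_score_table(path), "1 row")
  expect_equal(nrow(tab), 4L)

  # duplicate molecule keeps the most negative energy ("C(C)O" is CCO)
  path <- write_score_csv(data.frame(
    smiles = c("CCO", "C(C)O", "CCN"),
    dG_kcal_mol = c(-7.0, -9.0, -6.0)))
  expect_message(tab <- load_score_table(path), "duplicate")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$dG_kcal_mol[tab$smiles == "CCO"], -9.0)

  expect_error(load_score_table(write_score_csv(
    data.frame(x = 1, y = 2))), "smiles")
})

test_that("splitting is 70/15/15 by floor rule, seeded, disjoint and exhaustive", {
  recs <- data.frame(smiles = sprintf("mol%03d", 1:100),
                     dG_kcal_mol = rnorm(100))
  s1 <- split_dataset(recs, seed = 42L)
  expect_equal(as.integer(table(s1$split)), c(70L, 15L, 15L))
  s2 <- split_dataset(recs, seed = 42L)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(recs, seed = 43L)
  expect_false(identical(s1$split, s3$split))

  # union = input, pairwise disjoint, on a larger random set
  recs <- data.frame(smiles = sprintf("m%04d", 1:1000),
                     dG_kcal_mol = rnorm(1000))
  sp <- split_dataset(recs, seed = 9L)
  ids <- split(sp$smiles, sp$split)
  expect_equal(sort(unname(unlist(ids))), sort(recs$smiles))
  expect_length(intersect(ids$train, ids$validation), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$validation, ids$test), 0L)

  expect_error(split_dataset(recs, fractions = c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("the percentile threshold marks exactly the most-negative fraction as hits", {
  energies <- c(-12, -11, -10, -9, -8, -7, -6, -5, -4, -3)
  thr <- compute_threshold(energies, 0.20)
  expect_equal(sum(energies < thr), 2L)
  expect_equal(sort(energies[energies < thr]), c(-12, -11))

  # hit_fraction 1 is the boundary: all records are hits
  thr_all <- compute_threshold(energies, 1.0)
  expect_gt(thr_all, max(energies))
  expect_equal(sum(energies < thr_all), 10L)

  # ties are excluded by strict inequality
  expect_equal(sum(rep(-5, 8) < compute_threshold(rep(-5, 8), 0.25)), 0L)

  expect_error(compute_threshold(numeric(0), 0.2), "no training energies")
})

test_that("thresholds are monotone in hit fraction with nested hit sets", {
  set.seed(3)
  energies <- rnorm(500, -7, 1.5)
  t05 <- compute_threshold(energies, 0.05)
  t10 <- compute_threshold(energies, 0.10)
  t20 <- compute_threshold(energies, 0.20)
  expect_lte(t05, t10)
  expect_lte(t10, t20)
  h05 <- which(energies < t05)
  h10 <- which(energies < t10)
  h20 <- which(energies < t20)
  expect_true(all(h05 %in% h10))
  expect_true(all(h10 %in% h20))
})

test_that("validation/test labels come from the training threshold, not their own quantiles", {
  set.seed(14)
  recs <- data.frame(smiles = sprintf("m%04d", 1:400),
                     dG_kcal_mol = rnorm(400, -7, 1.5))
  ds <- prepare_dataset(recs, hit_fraction = 0.20, seed = 14L)
  tr <- ds$records$split == "train"
  thr <- compute_threshold(ds$records$dG_kcal_mol[tr], 0.20)
  expect_equal(ds$energy_threshold, thr)
  expect_equal(ds$records$label,
               as.integer(ds$records$dG_kcal_mol < thr))
  # training realized fraction never exceeds the request
  expect_lte(mean(ds$records$label[tr]), 0.20)
})

test_that("oversampling balances training classes exactly without touching originals", {
  tr <- data.frame(smiles = sprintf("m%03d", 1:100),
                   dG_kcal_mol = c(rep(-10, 20), rep(-5, 80)),
                   label = c(rep(1L, 20), rep(0L, 80)))
  ov <- oversample_training(tr, seed = 21L)
  expect_equal(nrow(ov), 160L)
  expect_equal(sum(ov$label == 1L), 80L)
  expect_equal(sum(ov$label == 0L), 80L)

  # every original hit retained at multiplicity >= 1; duplicates drawn from
  # the original hit set only
  hits <- tr$smiles[tr$label == 1L]
  expect_true(all(hits %in% ov$smiles))
  expect_true(all(ov$smiles[ov$label == 1L] %in% hits))
  # non-hits untouched
  expect_identical(ov$smiles[ov$label == 0L], tr$smiles[tr$label == 0L])

  # balanced input is a fixed point
  bal <- data.frame(smiles = c("a", "b"), dG_kcal_mol = c(-9, -5),
                    label = c(1L, 0L))
  expect_identical(oversample_training(bal, seed = 1L), bal)

  no_hits <- data.frame(smiles = "a", dG_kcal_mol = -5, label = 0L)
  expect_error(oversample_training(no_hits), "hit_fraction")
})
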