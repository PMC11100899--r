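test_that("the head with zero weights outputs probability one half everywhere", {
  ann <- ann_params(8L, hidden = c(4L), seed = 1L)
  ann$W <- lapply(ann$W, function(w) w * 0)
  ann$b <- lapply(ann$b, function(b) b * 0)
  X <- matrix(rnorm(40), 5, 8)
  out <- nfscreen:::ann_forward(X, ann, training = FALSE)
  expect_equal(nfscreen:::sigmoid(out$logit), rep(0.5, 5))
})

test_that("a one-hidden-layer head reproduces a hand-composed forward pass", {
  set.seed(2)
  ann <- ann_params(6L, hidden = c(3L), seed = 2L)
  x <- rnorm(6)
  h <- pmax(drop(x %*% ann$W[[1]]) + ann$b[[1]], 0)
  z <- sum(h * ann$W[[2]]) + ann$b[[2]]
  out <- nfscreen:::ann_forward(matrix(x, 1), ann, training = FALSE)
  expect_equal(out$logit, z, tolerance = 1e-12)
})

test_that("evaluation-mode predictions are deterministic even for dropout-trained models", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)
  cfg <- train_config(n_epochs = 2L, fp_length = 16L, conv_width = 8L,
                      dropout = 0.3, batch_size = 64L, seed = 1L)
  m <- train(tr, config = cfg, energy_threshold = ds$energy_threshold)
  smi <- recs$smiles[recs$split == "test"][1:20]
  p1 <- predict(m, smi)
  p2 <- predict(m, smi)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # single-graph forward agrees with the vectorised path
  g <- smiles_to_graph(smi[1])
  expect_equal(forward(g, m), p1[1], tolerance = 1e-12)
})

test_that("one training example is memorized to near-zero loss", {
  one <- data.frame(smiles = "CCO", dG_kcal_mol = -10, label = 1L)
  cfg <- train_config(learning_rate = 0.01, n_epochs = 200L,
                      batch_size = 1L, fp_length = 16L, conv_width = 8L,
                      n_layers = 2L, seed = 5L)
  m <- train(one, config = cfg)
  expect_lt(tail(m$training_history$train_loss, 1), 1e-2)
})

test_that("a zero learning rate leaves every parameter at its initialization", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)[1:50, ]
  cfg <- train_config(learning_rate = 0, n_epochs = 3L, fp_length = 16L,
                      conv_width = 8L, seed = 9L)
  m <- train(tr, config = cfg)
  init <- neuralfp_params(n_layers = cfg$n_layers, fp_length = cfg$fp_length,
                          conv_width = cfg$conv_width, seed = cfg$seed)
  expect_equal(m$fp_params$W, init$W)
  expect_equal(m$fp_params$H, init$H)
  init_ann <- ann_params(cfg$fp_length, hidden = cfg$hidden, seed = cfg$seed)
  expect_equal(m$ann_params$W, init_ann$W)
})

test_that("the loss gradient reaches the fingerprint parameters (joint training)", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)[1:50, ]
  cfg <- train_config(learning_rate = 1e-3, n_epochs = 1L, fp_length = 16L,
                      conv_width = 8L, seed = 9L)
  m <- train(tr, config = cfg)
  init <- neuralfp_params(n_layers = cfg$n_layers, fp_length = cfg$fp_length,
                          conv_width = cfg$conv_width, seed = cfg$seed)
  moved <- function(a, b) max(abs(unlist(a) - unlist(b)))
  expect_gt(moved(m$fp_params$H, init$H), 0)
  expect_gt(moved(m$fp_params$W, init$W), 0)
})

test_that("weight decay shrinks parameter norms on an otherwise identical run", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)[1:80, ]
  norm_of <- function(m) {
    sqrt(sum(unlist(m$fp_params$H)^2) + sum(unlist(m$fp_params$W)^2) +
           sum(unlist(m$ann_params$W)^2))
  }
  base <- train_config(n_epochs = 5L, fp_length = 16L, conv_width = 8L,
                       batch_size = 16L, seed = 4L)
  decayed <- base
  decayed$weight_decay <- 1e-2
  m0 <- train(tr, config = base)
  m1 <- train(tr, config = decayed)
  expect_lt(norm_of(m1), norm_of(m0))
})

test_that("identical seed and data reproduce the training history exactly", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)[1:60, ]
  va <- recs[recs$split == "validation", ][1:30, ]
  cfg <- train_config(n_epochs = 3L, fp_length = 16L, conv_width = 8L,
                      dropout = 0.2, seed = 12L)
  h1 <- train(tr, va, config = cfg)$training_history
  h2 <- train(tr, va, config = cfg)$training_history
  expect_identical(h1, h2)
})

test_that("grid search trains the Cartesian product and validates its keys", {
  ds <- tiny_dataset()
  base <- train_config(n_epochs = 2L, fp_length = 16L, conv_width = 8L,
                       batch_size = 64L, seed = 2L, patience = Inf)
  one <- grid_search(ds, list(learning_rate = 1e-3), base_config = base)
  expect_length(one$models, 1L)

  six <- grid_search(ds, list(learning_rate = c(1e-3, 3e-3),
                              dropout = c(0, 0.1, 0.2)),
                     base_config = base)
  expect_length(six$models, 6L)
  expect_equal(nrow(six$results), 6L)
  # every model carries the combination it was trained with
  expect_setequal(
    vapply(six$models, function(m) m$config$dropout, numeric(1)),
    rep(c(0, 0.1, 0.2), 2))

  expect_error(grid_search(ds, list(momentum = 0.9), base_config = base),
               "unknown hyperparameter")
})

test_that("model ranking reproduces a brute-force sort of a hand-built metrics table", {
  tab <- data.frame(
    recall = c(0.90, 0.95, 0.95, 0.80, 0.95),
    precision = c(0.50, 0.40, 0.55, NA, 0.55),
    mean_hit_energy = c(-9.1, -9.0, -8.8, -9.5, -9.2))
  ord <- nfscreen:::selection_order(tab)
  # brute force: recall desc, then precision desc (NA last), then energy asc
  expect_equal(ord, c(5L, 3L, 2L, 1L, 4L))
})

test_that("checkpoints reload bit-exactly and predict identically", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- oversample_training(recs[recs$split == "train", ], seed = 1L)[1:40, ]
  cfg <- train_config(n_epochs = 2L, fp_length = 16L, conv_width = 8L,
                      seed = 3L)
  m <- train(tr, config = cfg, energy_threshold = ds$energy_threshold)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$fp_params, m$fp_params)
  expect_identical(m2$ann_params, m$ann_params)
  smi <- recs$smiles[1:10]
  expect_identical(predict(m2, smi), predict(m, smi))
  expect_error(load_checkpoint({
    p <- tempfile()
    saveRDS(list(1), p)
    p
  }), "not a screen_model")
})

test_that("training refuses empty or mislabelled input", {
  expect_error(train(data.frame(smiles = character(0),
                                dG_kcal_mol = numeric(0),
                                label = integer(0))))
  expect_error(train(data.frame(smiles = "C", dG_kcal_mol = -5, label = 2L)))
})
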