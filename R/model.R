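# Binary classification head and joint end-to-end training.
#
# The fingerprint feeds a small fully-connected network with a single
# sigmoid output. Crucially the loss gradient is propagated through the
# head *and* through the convolutional fingerprint, so both are optimized
# jointly by Adam against binary cross-entropy — the fingerprint adapts to
# the screening task instead of being a fixed encoding.

relu <- function(x) pmax(x, 0)

# --- parameter-tree helpers (nested lists of numeric arrays) ----------------

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) tree_sum(f, x), numeric(1)))
  else sum(f(a))
}

adam_init <- function(theta) {
  list(m = tree_map(function(x) x * 0, theta),
       v = tree_map(function(x) x * 0, theta),
       t = 0L)
}

# One Adam step with L2 weight decay folded into the gradient
# (the classical Adam + L2 coupling).
adam_step <- function(theta, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) {
    grads <- tree_map2(function(g, th) g + weight_decay * th, grads, theta)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  theta <- tree_map2(function(th, u) th - lr * u, theta, upd)
  list(theta = theta, state = state)
}

# --- ANN head ---------------------------------------------------------------

#' Initialize the classifier head
#'
#' Fully-connected network `input_dim -> hidden ... -> 1` with ReLU hidden
#' activations. Weights are Xavier-normal, biases the constant 0.01 —
#' the same initialization convention as the fingerprint.
#'
#' @param input_dim fingerprint length feeding the first layer.
#' @param hidden integer vector of hidden-layer widths.
#' @param seed integer seed.
#' @return An object of class `ann_params`.
#' @export
ann_params <- function(input_dim, hidden = c(100L, 100L), seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- c(input_dim, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- xavier_normal(sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0.01, sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = sizes), class = "ann_params")
}

# Forward pass; inverted dropout on hidden activations when training.
# Returns the pre-sigmoid logit vector plus the cache backprop needs.
ann_forward <- function(X, ann, dropout = 0, training = FALSE) {
  n_layers <- length(ann$W)
  acts <- vector("list", n_layers)      # layer inputs
  masks <- vector("list", n_layers)
  A <- X
  for (l in seq_len(n_layers)) {
    acts[[l]] <- A
    Z <- sweep(A %*% ann$W[[l]], 2L, ann$b[[l]], "+")
    if (l < n_layers) {
      A <- relu(Z)
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(A)) >= dropout,
                       nrow(A), ncol(A)) / (1 - dropout)
        A <- A * mask
        masks[[l]] <- mask
      }
    } else {
      A <- Z
    }
  }
  list(logit = drop(A), acts = acts, masks = masks)
}

# Backward pass from d(loss)/d(logit); returns head gradients and the
# gradient w.r.t. the input features (the fingerprint upstream gradient).
ann_backward <- function(ann, cache, dlogit) {
  n_layers <- length(ann$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  dA <- matrix(dlogit, ncol = 1L)
  for (l in n_layers:1) {
    A_in <- cache$acts[[l]]
    gW[[l]] <- crossprod(A_in, dA)
    gb[[l]] <- colSums(dA)
    dA <- dA %*% t(ann$W[[l]])
    if (l > 1L) {
      # gradient through dropout then ReLU of the previous layer
      if (!is.null(cache$masks[[l - 1L]])) dA <- dA * cache$masks[[l - 1L]]
      dA <- dA * (cache$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb, dX = dA)
}

# Numerically stable binary cross-entropy from logits.
bce_loss <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

# --- training configuration -------------------------------------------------

#' Training configuration
#'
#' Bundles every knob of the joint fingerprint + classifier optimization.
#' The five searched hyperparameters are `learning_rate`, `weight_decay`,
#' `dropout`, `batch_size` and `fp_length`; the rest are architecture and
#' bookkeeping choices.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient folded into the gradient.
#' @param dropout dropout probability on the head's hidden activations,
#'   active only during training; in `[0, 1)`.
#' @param batch_size minibatch size.
#' @param fp_length fingerprint length K.
#' @param n_epochs maximum number of epochs.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; identical seed + data reproduce the run exactly.
#' @param n_layers convolutional depth L of the fingerprint.
#' @param conv_width hidden atom-representation width of the fingerprint.
#' @param hidden head hidden-layer widths.
#' @param patience early-stopping patience, in epochs without validation
#'   loss improvement; `Inf` disables early stopping.
#' @param classification_threshold probability cutoff for hard labels.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 0,
                         dropout = 0, batch_size = 32L, fp_length = 512L,
                         n_epochs = 50L, seed = 1L, n_layers = 3L,
                         conv_width = 32L, hidden = c(100L, 100L),
                         patience = 10L, classification_threshold = 0.5) {
  stopifnot(learning_rate >= 0, weight_decay >= 0,
            dropout >= 0, dropout < 1,
            batch_size >= 1, fp_length >= 1, n_epochs >= 1,
            classification_threshold > 0, classification_threshold < 1)
  structure(list(
    learning_rate = learning_rate, weight_decay = weight_decay,
    dropout = dropout, batch_size = as.integer(batch_size),
    fp_length = as.integer(fp_length), n_epochs = as.integer(n_epochs),
    seed = as.integer(seed), n_layers = as.integer(n_layers),
    conv_width = as.integer(conv_width), hidden = as.integer(hidden),
    patience = patience,
    classification_threshold = classification_threshold),
    class = "train_config")
}

# --- the shared training loop ----------------------------------------------
#
# A "frontend" turns record indices into a feature matrix and, if it has
# trainable parameters, backpropagates into them. The neural fingerprint
# and the fixed Morgan baseline are the two frontends; the epoch loop,
# Adam state, early stopping and history bookkeeping are identical.

train_loop <- function(frontend, y_train, y_val, config, verbose = FALSE) {
  n <- length(y_train)
  if (n == 0L) stop("empty training set", call. = FALSE)
  set.seed(config$seed)
  front_theta <- frontend$init()
  ann <- ann_params(frontend$dim, hidden = config$hidden, seed = config$seed)
  theta <- list(front = front_theta, ann = list(W = ann$W, b = ann$b))
  opt <- adam_init(theta)
  history <- data.frame()
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  wait <- 0L
  n_batches <- ceiling(n / config$batch_size)
  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
      fwd <- frontend$forward(theta$front, idx)
      ann$W <- theta$ann$W
      ann$b <- theta$ann$b
      head <- ann_forward(fwd$X, ann, dropout = config$dropout,
                          training = TRUE)
      y <- y_train[idx]
      loss <- bce_loss(head$logit, y)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
             "; consider lowering the learning rate", call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      dlogit <- (sigmoid(head$logit) - y) / length(idx)
      back <- ann_backward(ann, head, dlogit)
      front_grads <- frontend$backward(theta$front, fwd$ctx, back$dX)
      grads <- list(front = front_grads,
                    ann = list(W = back$W, b = back$b))
      step <- adam_step(theta, grads, opt,
                        lr = config$learning_rate,
                        weight_decay = config$weight_decay)
      theta <- step$theta
      opt <- step$state
    }
    row <- data.frame(epoch = epoch, train_loss = epoch_loss / n,
                      val_loss = NA_real_, val_recall = NA_real_,
                      val_precision = NA_real_, val_roc_auc = NA_real_)
    if (!is.null(y_val)) {
      vf <- frontend$forward_val(theta$front)
      ann$W <- theta$ann$W
      ann$b <- theta$ann$b
      vh <- ann_forward(vf, ann, training = FALSE)
      row$val_loss <- bce_loss(vh$logit, y_val)
      prob <- sigmoid(vh$logit)
      pred <- as.integer(prob >= config$classification_threshold)
      cc <- confusion(pred, y_val)
      row$val_recall <- recall_score(cc)
      row$val_precision <- precision_score(cc)
      if (length(unique(y_val)) == 2L) {
        row$val_roc_auc <- roc_curve(prob, y_val)$auc
      }
      if (row$val_loss < best$loss - 1e-12) {
        best <- list(loss = row$val_loss, theta = theta, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch,
                      row$train_loss,
                      ifelse(is.na(row$val_loss), "-",
                             sprintf("%.4f", row$val_loss))))
    }
    if (!is.null(y_val) && wait >= config$patience) break
  }
  if (!is.null(y_val) && is.finite(best$loss)) theta <- best$theta
  list(theta = theta, history = history,
       best_epoch = if (is.null(y_val)) nrow(history) else best$epoch)
}

neural_frontend <- function(graphs, train_graph_idx, val_graph_idx, config) {
  val_batch <- if (length(val_graph_idx)) {
    stack_graphs(graphs[val_graph_idx])
  }
  list(
    dim = config$fp_length,
    init = function() {
      p <- neuralfp_params(n_layers = config$n_layers,
                           fp_length = config$fp_length,
                           conv_width = config$conv_width,
                           seed = config$seed)
      list(H = p$H, Hb = p$Hb, W = p$W, Wb = p$Wb)
    },
    forward = function(theta, idx) {
      batch <- stack_graphs(graphs[train_graph_idx[idx]])
      p <- rebuild_fp_params(theta, config)
      fwd <- fp_forward(batch, p, keep_cache = TRUE)
      list(X = fwd$fp, ctx = list(batch = batch, cache = fwd$cache))
    },
    backward = function(theta, ctx, dX) {
      p <- rebuild_fp_params(theta, config)
      fp_backward(ctx$batch, p, ctx$cache, dX)
    },
    forward_val = function(theta) {
      fp_forward(val_batch, rebuild_fp_params(theta, config))$fp
    })
}

rebuild_fp_params <- function(theta, config) {
  structure(list(n_layers = config$n_layers, fp_length = config$fp_length,
                 conv_width = config$conv_width,
                 d_atom = atom_feature_dim(), d_bond = bond_feature_dim(),
                 H = theta$H, Hb = theta$Hb, W = theta$W, Wb = theta$Wb),
            class = "neuralfp_params")
}

feature_frontend <- function(X_train, X_val, dim) {
  list(
    dim = dim,
    init = function() NULL,
    forward = function(theta, idx) {
      list(X = X_train[idx, , drop = FALSE], ctx = NULL)
    },
    backward = function(theta, ctx, dX) NULL,
    forward_val = function(theta) X_val)
}

# --- the user-facing trainers ----------------------------------------------

#' Train the neural-fingerprint screening model
#'
#' Joint end-to-end optimization: Adam minimizes binary cross-entropy and
#' its gradient flows through the classifier head *and* every weight and
#' bias of the convolutional fingerprint. Expects the training split to be
#' oversampled upstream (see [oversample_training()]); validation records
#' are used unaltered, for per-epoch metrics and early stopping.
#'
#' @param train_records data.frame with columns `smiles`, `dG_kcal_mol`,
#'   `label` (the oversampled training split).
#' @param val_records optional validation data.frame, same columns.
#' @param config a [train_config()].
#' @param energy_threshold the kcal/mol threshold that produced the labels;
#'   stored with the model.
#' @param graphs optional precomputed named list of `molgraph` objects
#'   keyed by canonical SMILES (avoids re-parsing across grid-search runs).
#' @param verbose print per-epoch losses.
#' @return An object of class `screen_model`.
#' @export
train <- function(train_records, val_records = NULL, config = train_config(),
                  energy_threshold = NA_real_, graphs = NULL,
                  verbose = FALSE) {
  stopifnot(is.data.frame(train_records), nrow(train_records) > 0L,
            all(train_records$label %in% c(0L, 1L)))
  all_smiles <- unique(c(train_records$smiles, val_records$smiles))
  if (is.null(graphs)) {
    graphs <- smiles_to_graphs(all_smiles)
    names(graphs) <- vapply(graphs, function(g) g$source_smiles, character(1))
  }
  tr_idx <- match(train_records$smiles, names(graphs))
  va_idx <- if (!is.null(val_records)) match(val_records$smiles, names(graphs)) else integer(0)
  if (anyNA(tr_idx) || anyNA(va_idx)) stop("missing graphs for some records")
  frontend <- neural_frontend(graphs, tr_idx, va_idx, config)
  fit <- train_loop(frontend, train_records$label,
                    if (is.null(val_records)) NULL else val_records$label,
                    config, verbose = verbose)
  new_screen_model("neural", fit, config, energy_threshold)
}

new_screen_model <- function(type, fit, config, energy_threshold,
                             morgan_config = NULL) {
  fp_params <- if (type == "neural") rebuild_fp_params(fit$theta$front, config)
  ann <- structure(list(W = fit$theta$ann$W, b = fit$theta$ann$b),
                   class = "ann_params")
  structure(list(type = type, fp_params = fp_params,
                 morgan_config = morgan_config, ann_params = ann,
                 config = config, energy_threshold = energy_threshold,
                 training_history = fit$history, best_epoch = fit$best_epoch),
            class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat("<screen_model> frontend:", x$type, "\n")
  cat("  fingerprint length:", x$config$fp_length,
      " epochs run:", nrow(x$training_history),
      " best epoch:", x$best_epoch, "\n")
  if (!is.na(x$energy_threshold)) {
    cat("  energy threshold:", x$energy_threshold, "kcal/mol\n")
  }
  invisible(x)
}

#' Predict hit probabilities
#'
#' Deterministic evaluation-mode forward pass (dropout off): the frontend
#' fingerprint feeds the trained head and the final scalar goes through a
#' sigmoid.
#'
#' @param object a `screen_model`.
#' @param smiles character vector of SMILES.
#' @param type `"prob"` for probabilities, `"label"` for hard 0/1 calls at
#'   the model's classification threshold.
#' @param graphs optional precomputed graph list keyed by SMILES.
#' @param ... unused.
#' @return numeric (or integer) vector, one value per molecule.
#' @export
predict.screen_model <- function(object, smiles, type = c("prob", "label"),
                                 graphs = NULL, ...) {
  type <- match.arg(type)
  if (object$type == "neural") {
    if (is.null(graphs)) {
      gl <- smiles_to_graphs(smiles)
    } else {
      gl <- graphs[match(smiles, names(graphs))]
    }
    X <- fp_forward(stack_graphs(gl), object$fp_params)$fp
  } else {
    X <- morgan_fingerprint_matrix(smiles, object$morgan_config)
  }
  out <- ann_forward(X, object$ann_params, training = FALSE)
  prob <- sigmoid(out$logit)
  if (type == "prob") prob
  else as.integer(prob >= object$config$classification_threshold)
}

#' Hit probability for a single molecular graph
#'
#' @param graph a `molgraph`.
#' @param model a neural `screen_model`.
#' @return probability in (0, 1).
#' @export
forward <- function(graph, model) {
  stopifnot(inherits(graph, "molgraph"), model$type == "neural")
  X <- fp_forward(stack_graphs(list(graph)), model$fp_params)$fp
  sigmoid(ann_forward(X, model$ann_params, training = FALSE)$logit)
}

# --- grid search ------------------------------------------------------------

GRID_KEYS <- c("weight_decay", "learning_rate", "dropout", "batch_size",
               "fp_length")

#' Hyperparameter grid search
#'
#' Trains one model per combination of the Cartesian product of the given
#' value lists (allowed keys: weight decay, learning rate, dropout, batch
#' size, fingerprint length), evaluates each on the validation split, and
#' ranks them. The default selection policy maximizes recall, breaking ties
#' on precision and then on the mean binding free energy of the predicted
#' hits (more negative is better) — the recall-first policy of a screening
#' funnel, where losing a true binder costs more than carrying a decoy.
#'
#' @param dataset a `labeled_dataset` from [prepare_dataset()].
#' @param grid named list mapping hyperparameter names to value vectors.
#' @param base_config a [train_config()] supplying every non-searched value.
#' @param oversample_seed seed for the one-off training-split oversampling
#'   shared by all combinations.
#' @param verbose print progress.
#' @return A list with `results` (one ranked row per combination, with
#'   validation metrics), `models` (in the same order), and `best`.
#' @export
grid_search <- function(dataset, grid, base_config = train_config(),
                        oversample_seed = base_config$seed,
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"), length(grid) >= 1L)
  bad <- setdiff(names(grid), GRID_KEYS)
  if (length(bad)) {
    stop("unknown hyperparameter key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(GRID_KEYS, collapse = ", "), call. = FALSE)
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  recs <- dataset$records
  tr <- oversample_training(recs[recs$split == "train", , drop = FALSE],
                            seed = oversample_seed)
  va <- recs[recs$split == "validation", , drop = FALSE]
  graphs <- smiles_to_graphs(unique(c(tr$smiles, va$smiles)))
  names(graphs) <- vapply(graphs, function(g) g$source_smiles, character(1))
  models <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    for (k in names(combos)) cfg[[k]] <- combos[[k]][i]
    if (verbose) {
      message("combination ", i, "/", nrow(combos), ": ",
              paste(names(combos), unlist(combos[i, , drop = FALSE]),
                    sep = "=", collapse = " "))
    }
    m <- train(tr, va, config = cfg,
               energy_threshold = dataset$energy_threshold, graphs = graphs)
    prob <- predict(m, va$smiles, graphs = graphs)
    pred <- as.integer(prob >= cfg$classification_threshold)
    cc <- confusion(pred, va$label)
    mean_hit_energy <- if (any(pred == 1L)) {
      mean(va$dG_kcal_mol[pred == 1L])
    } else {
      NA_real_
    }
    rows[[i]] <- cbind(combos[i, , drop = FALSE], data.frame(
      recall = recall_score(cc), precision = precision_score(cc),
      f1 = f1_score(cc),
      roc_auc = if (length(unique(va$label)) == 2L) roc_curve(prob, va$label)$auc else NA_real_,
      mean_hit_energy = mean_hit_energy))
    models[[i]] <- m
  }
  results <- do.call(rbind, rows)
  rank_order <- selection_order(results)
  results <- results[rank_order, , drop = FALSE]
  rownames(results) <- NULL
  list(results = results, models = models[rank_order],
       best = models[[rank_order[1L]]])
}

# Ranking policy: maximize recall, tie-break on precision, then on the
# mean predicted-hit binding free energy (more negative first). Undefined
# precision (no predicted hits) ranks below any defined value.
selection_order <- function(results) {
  order(-results$recall,
        -ifelse(is.na(results$precision), -Inf, results$precision),
        ifelse(is.na(results$mean_hit_energy), Inf, results$mean_hit_energy))
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a trained model checkpoint
#'
#' Checkpoints carry the full parameter set, the creating configuration and
#' the energy threshold, and reload bit-exactly.
#'
#' @param model a `screen_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the `screen_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "screen_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "screen_model")) {
    stop("not a screen_model checkpoint: ", path, call. = FALSE)
  }
  model
}
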