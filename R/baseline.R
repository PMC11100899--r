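# Fixed Morgan/ECFP baseline: the classical hashed circular fingerprint
# feeding the same classifier head. Its fingerprint has no trainable
# parameters, so training touches only the head — the single-iteration
# comparison partner for the trainable neural fingerprint.

#' Morgan fingerprint configuration
#'
#' @param radius circular radius (ECFP diameter / 2); default 2 (ECFP4).
#' @param n_bits fingerprint length; must be a positive power of two.
#' @return list of class `morgan_config`.
#' @export
morgan_config <- function(radius = 2L, n_bits = 1024L) {
  stopifnot(radius >= 0L, n_bits >= 1L)
  if (bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0L) {
    stop("n_bits must be a power of two", call. = FALSE)
  }
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "morgan_config")
}

#' Hashed Morgan (ECFP) fingerprint
#'
#' Deterministic binary circular fingerprint via RDKit; identical molecules
#' (same canonical SMILES) always give identical bit vectors.
#'
#' @param smiles a single SMILES string.
#' @param config a [morgan_config()].
#' @return integer 0/1 vector of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, config = morgan_config()) {
  stopifnot(length(smiles) == 1L)
  drop(morgan_fingerprint_matrix(smiles, config))
}

#' @rdname morgan_fingerprint
#' @return `morgan_fingerprint_matrix`: 0/1 matrix, one molecule per row.
#' @export
morgan_fingerprint_matrix <- function(smiles, config = morgan_config()) {
  recs <- featurize_smiles(smiles, mode = "morgan",
                           radius = config$radius, n_bits = config$n_bits)
  X <- matrix(0L, length(smiles), config$n_bits)
  for (i in seq_along(recs)) {
    if (!is.null(recs[[i]]$error)) {
      stop("cannot parse SMILES '", smiles[i], "': ", recs[[i]]$error,
           call. = FALSE)
    }
    bits <- unlist(recs[[i]]$bits)
    X[i, bits + 1L] <- 1L
  }
  X
}

#' Train the Morgan-baseline model
#'
#' Same head, loss, optimizer, oversampling convention and early stopping
#' as the neural model, but the features are the fixed hashed fingerprint:
#' no gradient flows into fingerprint space.
#'
#' @param train_records oversampled training data.frame (`smiles`, `label`).
#' @param val_records optional validation data.frame.
#' @param config a [train_config()]; `fp_length`-related fields are ignored
#'   in favour of `morgan$n_bits`.
#' @param morgan a [morgan_config()].
#' @param energy_threshold stored with the model.
#' @param verbose print per-epoch losses.
#' @return a `screen_model` with `type = "morgan"`.
#' @export
train_morgan <- function(train_records, val_records = NULL,
                         config = train_config(), morgan = morgan_config(),
                         energy_threshold = NA_real_, verbose = FALSE) {
  stopifnot(nrow(train_records) > 0L)
  uniq <- unique(c(train_records$smiles, val_records$smiles))
  Xu <- morgan_fingerprint_matrix(uniq, morgan)
  X_train <- Xu[match(train_records$smiles, uniq), , drop = FALSE]
  X_val <- if (!is.null(val_records)) {
    Xu[match(val_records$smiles, uniq), , drop = FALSE]
  }
  frontend <- feature_frontend(X_train, X_val, morgan$n_bits)
  cfg <- config
  cfg$fp_length <- morgan$n_bits
  fit <- train_loop(frontend, train_records$label,
                    if (is.null(val_records)) NULL else val_records$label,
                    cfg, verbose = verbose)
  new_screen_model("morgan", fit, cfg, energy_threshold,
                   morgan_config = morgan)
}

#' Compare the neural and Morgan architectures on one dataset
#'
#' Trains both frontends on the identical oversampled training split, with
#' the identical threshold and validation/test records, and reports
#' precision, recall and ROC-AUC for each on the shared test set.
#'
#' @param dataset a `labeled_dataset`.
#' @param neural_config [train_config()] for the neural model.
#' @param morgan_cfg [morgan_config()] for the baseline.
#' @param morgan_train_config optional separate [train_config()] for the
#'   baseline head (defaults to `neural_config`).
#' @param seed seed for the shared oversampling.
#' @return list of class `architecture_comparison`: per-architecture lists
#'   with keys `precision`, `recall`, `roc_auc`, plus the two models.
#' @export
compare_architectures <- function(dataset, neural_config = train_config(),
                                  morgan_cfg = morgan_config(),
                                  morgan_train_config = neural_config,
                                  seed = neural_config$seed) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  recs <- dataset$records
  tr <- oversample_training(recs[recs$split == "train", , drop = FALSE],
                            seed = seed)
  va <- recs[recs$split == "validation", , drop = FALSE]
  te <- recs[recs$split == "test", , drop = FALSE]
  neural_model <- train(tr, va, config = neural_config,
                        energy_threshold = dataset$energy_threshold)
  morgan_model <- train_morgan(tr, va, config = morgan_train_config,
                               morgan = morgan_cfg,
                               energy_threshold = dataset$energy_threshold)
  report_one <- function(model) {
    m <- evaluate_model(model, te)
    list(precision = m$precision, recall = m$recall, roc_auc = m$roc_auc)
  }
  structure(list(neural = report_one(neural_model),
                 morgan = report_one(morgan_model),
                 models = list(neural = neural_model, morgan = morgan_model),
                 n_test = nrow(te)),
            class = "architecture_comparison")
}

#' @export
print.architecture_comparison <- function(x, ...) {
  cat("<architecture_comparison> test n =", x$n_test, "\n")
  for (arch in c("neural", "morgan")) {
    m <- x[[arch]]
    cat(sprintf("  %-7s precision %.3f  recall %.3f  ROC-AUC %.3f\n",
                arch, m$precision, m$recall, m$roc_auc))
  }
  invisible(x)
}
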