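# Score-table ingestion and dataset preparation: percentile threshold,
# 70/15/15 split, binary hit labels, and training-split oversampling.

#' Load a docking score table
#'
#' Reads a CSV with a SMILES column and a binding free energy column
#' (kcal/mol). Rows with unparsable SMILES or non-numeric energies are
#' dropped (and reported via `message`); duplicate molecules — identical
#' canonical SMILES — collapse to a single record keeping the most negative
#' energy.
#'
#' @param path CSV file path.
#' @param smiles_col,energy_col column names.
#' @return data.frame with columns `smiles` (canonical) and `dG_kcal_mol`.
#' @export
load_score_table <- function(path, smiles_col = "smiles",
                             energy_col = "dG_kcal_mol") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty score table: ", path, call. = FALSE)
  missing <- setdiff(c(smiles_col, energy_col), names(df))
  if (length(missing)) {
    stop("score table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  smiles <- as.character(df[[smiles_col]])
  energy <- suppressWarnings(as.numeric(df[[energy_col]]))
  bad_energy <- !is.finite(energy)
  val <- validate_smiles(smiles)
  bad_smiles <- is.na(val$canonical)
  keep <- !bad_energy & !bad_smiles
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) dropped (", sum(bad_smiles),
            " unparsable SMILES, ", sum(bad_energy & !bad_smiles),
            " non-numeric energies)")
  }
  out <- data.frame(smiles = val$canonical[keep],
                    dG_kcal_mol = energy[keep],
                    stringsAsFactors = FALSE)
  # duplicates keep the most negative (tightest-binding) energy
  ord <- order(out$smiles, out$dG_kcal_mol)
  out <- out[ord, , drop = FALSE]
  dup <- duplicated(out$smiles)
  if (any(dup)) {
    message(sum(dup), " duplicate molecule(s) collapsed to their most ",
            "negative energy")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Randomly assign train/validation/test splits
#'
#' Disjoint, exhaustive random assignment with sizes
#' `floor(f1 * n)` / `floor(f2 * n)` / remainder.
#'
#' @param records data.frame of molecules.
#' @param fractions length-3 numeric summing to 1 (default 70/15/15).
#' @param seed integer seed.
#' @return the data.frame with an added `split` factor column.
#' @export
split_dataset <- function(records, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) >= 3L,
            length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  n <- nrow(records)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[n_train + seq_len(n_val)]] <- "validation"
  split[ord[(n_train + n_val + 1L):n]] <- "test"
  records$split <- factor(split, levels = c("train", "validation", "test"))
  records
}

#' Percentile energy threshold for hit labelling
#'
#' Returns the threshold below which a record counts as a hit, computed so
#' that the `hit_fraction` most negative training energies fall (strictly)
#' below it: with `k = floor(hit_fraction * n)` the threshold is the
#' `(k+1)`-th order statistic of the training energies. A record is a hit
#' iff `energy < threshold` (strict, so under ties the realized hit
#' fraction never exceeds the requested one). Compute this on the training
#' split only and apply it unchanged to validation and test.
#'
#' @param training_energies numeric vector of training-split energies,
#'   kcal/mol.
#' @param hit_fraction proportion in (0, 1].
#' @return threshold in kcal/mol.
#' @export
compute_threshold <- function(training_energies, hit_fraction) {
  if (length(training_energies) == 0L) {
    stop("no training energies supplied", call. = FALSE)
  }
  stopifnot(hit_fraction > 0, hit_fraction <= 1,
            all(is.finite(training_energies)))
  n <- length(training_energies)
  k <- floor(hit_fraction * n)
  if (k >= n) return(max(training_energies) + 1)
  sort(training_energies)[k + 1L]
}

#' Prepare a labelled dataset from a score table
#'
#' Splits 70/15/15, computes the percentile threshold from the training
#' split only, and labels every record by strict comparison against it.
#'
#' @param records data.frame with `smiles`, `dG_kcal_mol` (e.g. from
#'   [load_score_table()]).
#' @param hit_fraction requested training hit proportion (e.g. 0.05, 0.10,
#'   0.20).
#' @param seed integer seed for the split.
#' @param fractions split fractions, see [split_dataset()].
#' @return An object of class `labeled_dataset`: list with `records`
#'   (adds `label`, `split`), `energy_threshold`, `hit_fraction`,
#'   `split_counts`, `seed`.
#' @export
prepare_dataset <- function(records, hit_fraction = 0.20, seed = 1L,
                            fractions = c(0.70, 0.15, 0.15)) {
  recs <- split_dataset(records, fractions = fractions, seed = seed)
  threshold <- compute_threshold(
    recs$dG_kcal_mol[recs$split == "train"], hit_fraction)
  recs$label <- as.integer(recs$dG_kcal_mol < threshold)
  structure(list(
    records = recs,
    energy_threshold = threshold,
    hit_fraction = hit_fraction,
    split_counts = table(recs$split),
    seed = as.integer(seed)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> n =", nrow(x$records), "\n")
  cat("  threshold:", format(x$energy_threshold), "kcal/mol",
      " (requested hit fraction", x$hit_fraction, ")\n")
  cat("  splits:", paste(names(x$split_counts), as.integer(x$split_counts),
                         sep = "=", collapse = " "), "\n")
  cat("  hits:", sum(x$records$label), "of", nrow(x$records), "\n")
  invisible(x)
}

#' Oversample training hits to a 50/50 class balance
#'
#' Duplicates hits uniformly at random (with replacement) until the hit
#' count equals the non-hit count. Every original record is retained;
#' non-hits are never touched, and validation/test splits must never pass
#' through this function.
#'
#' @param train_records training-split data.frame with a `label` column.
#' @param seed integer seed.
#' @return the augmented data.frame (original rows first, duplicates
#'   appended).
#' @export
oversample_training <- function(train_records, seed = 1L) {
  stopifnot(is.data.frame(train_records), "label" %in% names(train_records))
  hit_idx <- which(train_records$label == 1L)
  n_non <- sum(train_records$label == 0L)
  if (length(hit_idx) == 0L) {
    stop("training split contains no hits; increase hit_fraction",
         call. = FALSE)
  }
  n_extra <- n_non - length(hit_idx)
  if (n_extra <= 0L) return(train_records)
  set.seed(as.integer(seed))
  extra <- sample(hit_idx, n_extra, replace = TRUE)
  out <- rbind(train_records, train_records[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}
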