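# Batch interface to the RDKit featurizer (inst/python/featurize.py).
# One subprocess per batch; results are cached per session so repeated
# lookups of the same SMILES never relaunch the interpreter.

.nfscreen_cache <- new.env(parent = emptyenv())

python_binary <- function() {
  bin <- Sys.getenv("NFSCREEN_PYTHON", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("No python interpreter found on PATH; RDKit-backed SMILES ",
         "parsing is unavailable.", call. = FALSE)
  }
  bin
}

featurizer_script <- function() {
  path <- system.file("python", "featurize.py", package = "nfscreen")
  if (!nzchar(path)) {
    # during devtools::load_all() the inst/ prefix is still present
    path <- system.file("inst", "python", "featurize.py", package = "nfscreen")
  }
  if (!nzchar(path)) stop("featurize.py not found in the installed package")
  path
}

#' Run the RDKit featurizer on a batch of SMILES
#'
#' Low-level bridge used by [smiles_to_graph()], [morgan_fingerprint()] and
#' the synthetic-data generator. Launches one RDKit subprocess for the whole
#' batch and returns one record per input SMILES (a list with `canonical`
#' plus the mode-specific fields, or `error`).
#'
#' @param smiles character vector of SMILES strings.
#' @param mode character vector, subset of `c("graph", "morgan", "smarts")`.
#' @param radius,n_bits Morgan fingerprint parameters (mode `"morgan"`).
#' @param smarts character vector of SMARTS patterns (mode `"smarts"`).
#' @return A list of per-molecule records, same length and order as `smiles`.
#' @keywords internal
#' @export
featurize_smiles <- function(smiles, mode = "graph", radius = 2L,
                             n_bits = 1024L, smarts = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  args <- c(featurizer_script(),
            "--infile", infile, "--outfile", outfile,
            "--mode", paste(mode, collapse = ","),
            "--radius", as.integer(radius), "--nbits", as.integer(n_bits))
  for (s in smarts) args <- c(args, "--smarts", s)
  log <- suppressWarnings(
    system2(python_binary(), shQuote(args), stdout = TRUE, stderr = TRUE))
  if (!file.exists(outfile)) {
    stop("RDKit featurizer failed:\n", paste(log, collapse = "\n"),
         call. = FALSE)
  }
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

# Fetch graph records for `smiles`, filling the session cache for misses
# with a single subprocess call.
graph_records <- function(smiles) {
  keys <- paste0("g:", smiles)
  miss <- !vapply(keys, exists, logical(1), envir = .nfscreen_cache)
  if (any(miss)) {
    miss_smiles <- unique(smiles[miss])
    recs <- featurize_smiles(miss_smiles, mode = "graph")
    for (i in seq_along(miss_smiles)) {
      assign(paste0("g:", miss_smiles[i]), recs[[i]], envir = .nfscreen_cache)
    }
  }
  lapply(keys, get, envir = .nfscreen_cache)
}
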