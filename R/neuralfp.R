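# Differentiable convolutional molecular fingerprint.
#
# The construction mirrors the circular (Morgan/ECFP) algorithm with its two
# non-differentiable steps replaced by smooth surrogates: the neighbourhood
# hash becomes a sigmoid-activated linear map, and the array-indexing step
# that sets a fingerprint bit becomes a softmax over fingerprint positions.
# At every depth l = 0..L each atom emits a softmax "index" vector of length
# K; the fingerprint is the vector sum of all of them, so its entries total
# n_atoms * (L + 1) exactly and the whole map is differentiable end to end.

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

xavier_normal <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / (nrow + ncol))), nrow, ncol)
}

#' Initialize convolutional fingerprint parameters
#'
#' Weights are drawn from the Xavier (Glorot) normal distribution with
#' variance 2 / (fan_in + fan_out); every bias entry is the constant 0.01.
#' One hidden ("hash") weight block per convolutional layer l = 1..L maps
#' the concatenation of an atom's own features, the sum of its neighbours'
#' features, and the sum of its incident bond features to the next layer's
#' atom representation; one output ("index") block per depth l = 0..L maps
#' atom representations to fingerprint space.
#'
#' @param n_layers convolutional depth L (the ECFP-radius analog); L >= 0.
#' @param fp_length fingerprint length K.
#' @param conv_width width of the hidden atom representation at layers >= 1.
#' @param d_atom,d_bond feature dimensionalities; defaults match
#'   [atom_feature_dim()] and [bond_feature_dim()].
#' @param seed integer seed; the same seed reproduces the parameters exactly.
#' @return An object of class `neuralfp_params`.
#' @export
neuralfp_params <- function(n_layers = 3L, fp_length = 512L, conv_width = 32L,
                            d_atom = atom_feature_dim(),
                            d_bond = bond_feature_dim(),
                            seed = 1L) {
  stopifnot(n_layers >= 0L)
  if (fp_length < 1L) stop("fp_length must be a positive count", call. = FALSE)
  set.seed(as.integer(seed))
  dims <- c(d_atom, rep(conv_width, n_layers))  # d_0 .. d_L
  H <- vector("list", n_layers)
  Hb <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- 2L * dims[l] + d_bond
    H[[l]] <- xavier_normal(fan_in, dims[l + 1L])
    Hb[[l]] <- rep(0.01, dims[l + 1L])
  }
  W <- vector("list", n_layers + 1L)
  Wb <- vector("list", n_layers + 1L)
  for (l in seq_len(n_layers + 1L)) {
    W[[l]] <- xavier_normal(dims[l], fp_length)
    Wb[[l]] <- rep(0.01, fp_length)
  }
  structure(
    list(n_layers = as.integer(n_layers), fp_length = as.integer(fp_length),
         conv_width = as.integer(conv_width), d_atom = as.integer(d_atom),
         d_bond = as.integer(d_bond),
         H = H, Hb = Hb, W = W, Wb = Wb),
    class = "neuralfp_params")
}

#' @export
print.neuralfp_params <- function(x, ...) {
  cat("<neuralfp_params> depth L =", x$n_layers,
      " fp_length K =", x$fp_length,
      " conv_width =", x$conv_width, "\n")
  cat("  trainable values:", n_param_values(x), "\n")
  invisible(x)
}

n_param_values <- function(params) {
  sum(vapply(c(params$H, params$Hb, params$W, params$Wb), length, numeric(1)))
}

# --- batch stacking ---------------------------------------------------------

# Stack a list of molgraphs into one block structure: all atoms concatenated,
# a sparse symmetric adjacency over the stacked atom index, the per-atom sum
# of incident bond features (constant across layers), and a sparse pooling
# matrix summing atoms per molecule.
stack_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  total <- sum(n_atoms)
  A <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  nbf <- do.call(rbind, lapply(graphs, function(g) g$nbf))
  edge_list <- lapply(seq_along(graphs), function(k) graphs[[k]]$edges + offsets[k])
  edges <- do.call(rbind, edge_list)
  adj <- Matrix::sparseMatrix(i = edges[, 1L], j = edges[, 2L], x = 1,
                              dims = c(total, total))
  pool <- Matrix::sparseMatrix(i = rep(seq_along(graphs), n_atoms),
                               j = seq_len(total), x = 1,
                               dims = c(length(graphs), total))
  list(A = A, adj = adj, nbf = nbf, pool = pool,
       n_atoms = n_atoms, total_atoms = total, n_mol = length(graphs))
}

check_dims <- function(batch, params) {
  if (ncol(batch$A) != params$d_atom) {
    stop("atom feature dimension mismatch: graph has ", ncol(batch$A),
         ", params expect ", params$d_atom, call. = FALSE)
  }
  if (ncol(batch$nbf) != params$d_bond) {
    stop("bond feature dimension mismatch: graph has ", ncol(batch$nbf),
         ", params expect ", params$d_bond, call. = FALSE)
  }
}

# Forward pass over a stacked batch. Returns the n_mol x K fingerprint
# matrix and, if keep_cache, the per-layer quantities backprop needs.
fp_forward <- function(batch, params, keep_cache = FALSE) {
  check_dims(batch, params)
  L <- params$n_layers
  R <- batch$A                       # layer-0 atom representation
  R_layers <- vector("list", L + 1L)
  V_layers <- vector("list", L)
  I_layers <- vector("list", L + 1L)
  R_layers[[1L]] <- R
  FP <- matrix(0, batch$n_mol, params$fp_length)
  for (l in 0:L) {
    if (l > 0L) {
      nbr <- as.matrix(batch$adj %*% R)
      V <- cbind(R, nbr, batch$nbf)
      R <- sigmoid(sweep(V %*% params$H[[l]], 2L, params$Hb[[l]], "+"))
      V_layers[[l]] <- V
      R_layers[[l + 1L]] <- R
    }
    I <- row_softmax(sweep(R %*% params$W[[l + 1L]], 2L, params$Wb[[l + 1L]], "+"))
    I_layers[[l + 1L]] <- I
    FP <- FP + as.matrix(batch$pool %*% I)
  }
  cache <- if (keep_cache) {
    list(R = R_layers, V = V_layers, I = I_layers)
  }
  list(fp = FP, cache = cache)
}

zero_like_params <- function(params) {
  params$H <- lapply(params$H, function(m) m * 0)
  params$Hb <- lapply(params$Hb, function(v) v * 0)
  params$W <- lapply(params$W, function(m) m * 0)
  params$Wb <- lapply(params$Wb, function(v) v * 0)
  params
}

# Reverse-mode pass. g_fp is the n_mol x K upstream gradient dLoss/dFP.
# Returns gradients with the same list shapes as the parameters. The
# adjacency matrix is symmetric, so scattering a neighbour-sum gradient
# back onto neighbours is another multiplication by adj.
fp_backward <- function(batch, params, cache, g_fp) {
  L <- params$n_layers
  grads <- list(H = vector("list", max(L, 0L)),
                Hb = vector("list", max(L, 0L)),
                W = vector("list", L + 1L),
                Wb = vector("list", L + 1L))
  d_prev <- c(params$d_atom, rep(params$conv_width, L))
  G_atom <- as.matrix(Matrix::crossprod(batch$pool, g_fp))
  dR <- vector("list", L + 1L)
  for (l in 0:L) {
    I <- cache$I[[l + 1L]]
    dS <- I * (G_atom - rowSums(G_atom * I))
    grads$W[[l + 1L]] <- crossprod(cache$R[[l + 1L]], dS)
    grads$Wb[[l + 1L]] <- colSums(dS)
    dR[[l + 1L]] <- dS %*% t(params$W[[l + 1L]])
  }
  if (L > 0L) {
    for (l in L:1) {
      Rl <- cache$R[[l + 1L]]
      dZ <- dR[[l + 1L]] * Rl * (1 - Rl)
      grads$H[[l]] <- crossprod(cache$V[[l]], dZ)
      grads$Hb[[l]] <- colSums(dZ)
      dV <- dZ %*% t(params$H[[l]])
      d <- d_prev[l]
      dR[[l]] <- dR[[l]] + dV[, seq_len(d), drop = FALSE] +
        as.matrix(batch$adj %*% dV[, d + seq_len(d), drop = FALSE])
      # bond features are constants: their slice of dV carries no gradient
    }
  }
  grads
}

#' Compute the neural fingerprint of one molecule
#'
#' Runs the convolutional fingerprint forward pass: at depth 0 each atom's
#' raw feature vector, and at each further depth the sigmoid-hashed
#' combination of the atom, its neighbour sum, and its incident-bond sum,
#' are mapped through a per-depth softmax output layer; the fingerprint is
#' the sum of every atom's softmax vector over all depths. Entries are
#' non-negative and total exactly `n_atoms * (n_layers + 1)`.
#'
#' @param graph a `molgraph` from [smiles_to_graph()].
#' @param params a `neuralfp_params` object.
#' @return An object of class `neural_fp`: list with `values` (length-K
#'   numeric), `n_atoms`, and `n_layers_used`.
#' @export
neural_fingerprint <- function(graph, params) {
  stopifnot(inherits(graph, "molgraph"), inherits(params, "neuralfp_params"))
  batch <- stack_graphs(list(graph))
  fwd <- fp_forward(batch, params)
  structure(list(values = drop(fwd$fp), n_atoms = graph$n_atoms,
                 n_layers_used = params$n_layers),
            class = "neural_fp")
}

#' @export
print.neural_fp <- function(x, ...) {
  cat("<neural_fp> K =", length(x$values),
      " sum =", format(sum(x$values)),
      " (n_atoms * (L+1) =", x$n_atoms * (x$n_layers_used + 1), ")\n")
  invisible(x)
}

#' Gradients of the fingerprint parameters for one molecule
#'
#' Exact reverse-mode gradients of `sum(upstream_gradient * fingerprint)`
#' with respect to every hidden and output weight and bias of the
#' convolutional fingerprint. This is the path through which the binary
#' classification loss trains the fingerprint jointly with the network head.
#'
#' @param graph a `molgraph`.
#' @param params a `neuralfp_params`.
#' @param upstream_gradient numeric vector of length `fp_length`
#'   (dLoss/dFingerprint).
#' @return A list with components `H`, `Hb`, `W`, `Wb` shaped like `params`.
#' @export
fingerprint_gradients <- function(graph, params, upstream_gradient) {
  stopifnot(length(upstream_gradient) == params$fp_length,
            all(is.finite(upstream_gradient)))
  batch <- stack_graphs(list(graph))
  fwd <- fp_forward(batch, params, keep_cache = TRUE)
  fp_backward(batch, params, fwd$cache,
              matrix(upstream_gradient, 1L, params$fp_length))
}

#' Neural fingerprints for a batch of molecules
#'
#' @param graphs list of `molgraph` objects.
#' @param params a `neuralfp_params`.
#' @return numeric matrix, one fingerprint per row.
#' @export
neural_fingerprint_matrix <- function(graphs, params) {
  fp_forward(stack_graphs(graphs), params)$fp
}
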