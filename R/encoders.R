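#' Initialise a pair of pocket/ligand encoders
#'
#' Both encoders map a feature vector to a shared embedding space of
#' dimension `d`; all affinity scoring is cosine similarity in that space.
#' Reference encoders are linear maps or single-hidden-layer perceptrons
#' (ReLU), deliberately lightweight so they are trainable on a CPU; heavier
#' encoders can be plugged in behind the same contract.
#'
#' @param ligand_dim,pocket_dim Input feature dimensions.
#' @param d Shared embedding dimension.
#' @param hidden Hidden width (`NULL` for a linear encoder).
#' @param seed Seed for weight initialisation.
#' @param init `"random"` (scaled Gaussian) or `"identity"` (requires
#'   `d == input dim` and no hidden layer; embedding equals features).
#' @return An `encoder_params` object.
#' @export
init_encoders <- function(ligand_dim, pocket_dim, d = 32, hidden = NULL,
                          seed = 1, init = c("random", "identity")) {
  init <- match.arg(init)
  mk_side <- function(input_dim, salt) {
    if (init == "identity") {
      if (!is.null(hidden)) abort("identity init requires a linear encoder",
                                  class = "ligspace_config_error")
      if (d != input_dim) abort("identity init requires d == input dim",
                                class = "ligspace_config_error")
      return(list(W1 = diag(input_dim), b1 = rep(0, d)))
    }
    withr::with_seed(derive_seed(seed, salt), {
      if (is.null(hidden)) {
        list(W1 = matrix(rnorm(input_dim * d, sd = 1 / sqrt(input_dim)),
                         input_dim, d),
             b1 = rep(0, d))
      } else {
        list(W1 = matrix(rnorm(input_dim * hidden, sd = sqrt(2 / input_dim)),
                         input_dim, hidden),
             b1 = rep(0, hidden),
             W2 = matrix(rnorm(hidden * d, sd = sqrt(2 / hidden)), hidden, d),
             b2 = rep(0, d))
      }
    })
  }
  structure(list(ligand = mk_side(ligand_dim, 11), pocket = mk_side(pocket_dim, 13),
                 d = d, hidden = hidden,
                 ligand_dim = ligand_dim, pocket_dim = pocket_dim),
            class = "encoder_params")
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("<encoder_params> d = %d, %s; ligand in %d, pocket in %d\n",
              x$d, if (is.null(x$hidden)) "linear"
                   else paste0("hidden ", x$hidden), x$ligand_dim, x$pocket_dim))
  invisible(x)
}

#' Encode feature vectors into the shared embedding space
#'
#' @param params An `encoder_params`.
#' @param fv Feature vector or matrix (rows = entities).
#' @param side `"pocket"` or `"ligand"`.
#' @return Embedding matrix (rows = entities, `d` columns); row names are
#'   preserved.
#' @export
encode <- function(params, fv, side = c("pocket", "ligand")) {
  side <- match.arg(side)
  stopifnot(inherits(params, "encoder_params"))
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1)
  w <- params[[side]]
  expected <- if (side == "ligand") params$ligand_dim else params$pocket_dim
  if (ncol(fv) != expected) {
    abort(sprintf("%s feature length %d does not match encoder input %d",
                  side, ncol(fv), expected), class = "ligspace_contract_error")
  }
  h <- sweep(fv %*% w$W1, 2, w$b1, "+")
  if (!is.null(params$hidden)) {
    h <- pmax(h, 0)
    h <- sweep(h %*% w$W2, 2, w$b2, "+")
  }
  rownames(h) <- rownames(fv)
  h
}

#' Cosine similarity between a pocket and a ligand embedding
#'
#' The predicted affinity score of the shared-space model.
#'
#' @param p,l Numeric vectors of equal length (nonzero).
#' @return Cosine similarity in \[-1, 1\].
#' @export
score_pair <- function(p, l) {
  p <- as.numeric(p); l <- as.numeric(l)
  stopifnot(length(p) == length(l))
  np <- sqrt(sum(p^2)); nl <- sqrt(sum(l^2))
  if (np == 0 || nl == 0) abort("zero embedding vector",
                                class = "ligspace_domain_error")
  sum(p * l) / (np * nl)
}

# Row-wise cosine similarity matrix between two embedding matrices.
cosine_matrix <- function(P, L) {
  if (any(rowSums(P^2) == 0) || any(rowSums(L^2) == 0)) {
    abort("zero embedding vector", class = "ligspace_domain_error")
  }
  row_normalize(P) %*% t(row_normalize(L))
}

# Stable content hash of encoder parameters (FNV-1a over serialized bytes).
params_hash <- function(params) {
  bytes <- as.double(serialize(params, connection = NULL, version = 2))
  idx <- seq_along(bytes)
  s1 <- sum(bytes * ((idx %% 97) + 1)) %% 2147483647
  s2 <- sum(bytes * ((idx %% 89) + 3)) %% 2147483647
  sprintf("%08x%08x", as.integer(s1), as.integer(s2))
}
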