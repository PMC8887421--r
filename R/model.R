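#' Network architecture specification
#'
#' Describes the encoder/decoder multilayer perceptrons of the conditional
#' variational autoencoder. The encoder maps normalized expression to the mean
#' and variance of the Gaussian variational posterior over the d-dimensional
#' latent factor; the decoder maps the latent factor concatenated with a
#' dataset-specific batch code back to expression space. Hidden layers are
#' affine maps followed (in the default \code{"relu"} mode) by batch
#' normalization, ReLU, and dropout. The decoder output head composes a
#' softplus layer with a hard-sigmoid gate scaled by a per-gene maximum, so
#' outputs are bounded in \code{[0, s_max]} and non-negative. With
#' \code{activation = "linear"} all hidden non-linearities, batch norm and
#' dropout are disabled and the output head is a single affine map — the
#' probabilistic-PCA limit of the model.
#'
#' @param latent_dim dimension d of the latent factor (default 16).
#' @param code_dim dimension of the batch code (default 16; 0 disables
#'   conditioning, as in the probabilistic-PCA limit).
#' @param encoder_widths,decoder_widths hidden-layer sizes (defaults
#'   \code{c(128, 32)} and \code{c(32, 128)}).
#' @param dropout_rate dropout probability after each hidden activation
#'   (default 0.1; inactive at inference).
#' @param use_batch_norm insert batch normalization before each activation
#'   (default TRUE).
#' @param activation \code{"relu"} (default) or \code{"linear"}.
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(latent_dim = 16, code_dim = 16,
                         encoder_widths = c(128, 32),
                         decoder_widths = c(32, 128),
                         dropout_rate = 0.1, use_batch_norm = TRUE,
                         activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  stopifnot(latent_dim >= 1, code_dim >= 0,
            all(encoder_widths > 0), all(decoder_widths > 0),
            dropout_rate >= 0, dropout_rate < 1)
  if (activation == "linear") {
    use_batch_norm <- FALSE
    dropout_rate <- 0
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 code_dim = as.integer(code_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 dropout_rate = dropout_rate,
                 use_batch_norm = use_batch_norm,
                 activation = activation),
            class = "network_spec")
}

#' Generate dataset-specific batch codes
#'
#' Each dataset gets a fixed integer code vector of length \code{code_dim},
#' entries drawn i.i.d. from the discrete uniform distribution on
#' \code{0..10}. The decoder consumes the code; the encoder never sees it,
#' which is what makes the latent embedding batch-free.
#'
#' @param k number of datasets.
#' @param spec a [network_spec()] (only \code{code_dim} is used).
#' @param seed integer seed; the same (k, spec, seed) always produces the
#'   same codes.
#' @return List of \code{k} integer vectors of length \code{code_dim}.
#' @export
make_batch_codes <- function(k, spec = network_spec(), seed = 1) {
  stopifnot(k >= 1)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  lapply(seq_len(k), function(m)
    sample(0:10, spec$code_dim, replace = TRUE))
}

## swap the global RNG state in/out so exported functions are seed-pure
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

hidden_block <- function(n_in, widths, spec) {
  layers <- list()
  prev <- n_in
  for (w in widths) {
    layers <- c(layers, list(layer_dense(prev, w, init = "he")))
    if (spec$activation == "relu") {
      if (spec$use_batch_norm) layers <- c(layers, list(layer_bn(w)))
      layers <- c(layers, list(layer_act("relu")))
      if (spec$dropout_rate > 0)
        layers <- c(layers, list(layer_dropout(spec$dropout_rate)))
    }
    prev <- w
  }
  list(layers = layers, n_out = prev)
}

#' Initialize generative parameters
#'
#' Variance-scaled random initialization (He for hidden layers feeding ReLU,
#' Xavier for linear heads). The log-variance head starts at zero so the
#' initial posterior variance is 1. Draws from the current RNG unless
#' \code{seed} is given.
#'
#' @param spec a [network_spec()].
#' @param n_genes number of features p.
#' @param seed optional integer seed.
#' @return An object of class \code{generative_params}: encoder/decoder layer
#'   lists, output head, per-gene output scale \code{s_max} (initialized to
#'   1), and residual noise variance \code{sigma2} (fixed at 1).
#' @export
init_params <- function(spec, n_genes, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_rng(seed)
    on.exit(restore_rng(old))
  }
  enc <- hidden_block(n_genes, spec$encoder_widths, spec)
  mu_head <- list(layer_dense(enc$n_out, spec$latent_dim, init = "xavier"))
  logvar_head <- list(layer_dense(enc$n_out, spec$latent_dim, init = "zero"))
  dec <- hidden_block(spec$latent_dim + spec$code_dim, spec$decoder_widths, spec)
  out_head <- if (spec$activation == "relu") {
    list(layer_dense(dec$n_out, n_genes, init = "xavier"),
         layer_act("softplus"),
         layer_dense(n_genes, n_genes, init = "xavier"),
         layer_act("hardsig"))
  } else {
    list(layer_dense(dec$n_out, n_genes, init = "xavier"),
         layer_act("identity"))
  }
  structure(list(spec = spec, n_genes = as.integer(n_genes),
                 encoder = enc$layers, mu_head = mu_head,
                 logvar_head = logvar_head,
                 decoder = c(dec$layers, out_head),
                 s_max = rep(1, n_genes), sigma2 = 1),
            class = "generative_params")
}

LOGVAR_CLAMP <- 15

#' Encode cells to the Gaussian variational posterior
#'
#' Deterministic at inference: maps each normalized expression row to the
#' mean and variance of its latent posterior. The variance head is
#' exponentiated so variances are strictly positive.
#'
#' @param params a \code{generative_params} object (or a fitted
#'   \code{ccalign} model, whose parameters are used).
#' @param x numeric matrix (cells x genes) or [cell_matrix()], gene order
#'   matching training.
#' @return An object of class \code{latent_gaussian}: list with \code{mean}
#'   and \code{var}, both n x d matrices.
#' @export
encode <- function(params, x) {
  params <- as_params(params)
  X <- if (inherits(x, "cell_matrix")) as_dense(x) else as.matrix(x)
  if (ncol(X) != params$n_genes)
    stop("gene dimension mismatch: input has ", ncol(X), " genes, model expects ",
         params$n_genes)
  h <- net_forward(params$encoder, X, training = FALSE)$out
  mu <- net_forward(params$mu_head, h, training = FALSE)$out
  logvar <- net_forward(params$logvar_head, h, training = FALSE)$out
  logvar <- pmin(pmax(logvar, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  structure(list(mean = mu, var = exp(logvar)), class = "latent_gaussian")
}

expand_code <- function(code, n, spec) {
  if (spec$code_dim == 0) return(matrix(0, n, 0))
  if (is.matrix(code)) {
    stopifnot(nrow(code) == n, ncol(code) == spec$code_dim)
    code
  } else {
    stopifnot(length(code) == spec$code_dim)
    matrix(rep(as.numeric(code), each = n), n, spec$code_dim)
  }
}

#' Decode latent factors to expression space
#'
#' Maps \code{[Z, code]} through the decoder. In the default architecture the
#' output is \code{s_max * hardsig(dense(softplus(dense(h))))}, elementwise
#' bounded in \code{[0, s_max]} and non-negative.
#'
#' @param params a \code{generative_params} object (or fitted \code{ccalign}
#'   model).
#' @param z n x d matrix of latent factors.
#' @param code batch code: vector of length \code{code_dim} (shared by all
#'   rows) or an n x \code{code_dim} matrix (per-cell codes).
#' @return n x p matrix of decoded expression values.
#' @export
decode <- function(params, z, code = NULL) {
  params <- as_params(params)
  z <- as.matrix(z)
  stopifnot(all(is.finite(z)), ncol(z) == params$spec$latent_dim)
  if (is.null(code)) code <- numeric(params$spec$code_dim)
  inp <- cbind(z, expand_code(code, nrow(z), params$spec))
  out <- net_forward(params$decoder, inp, training = FALSE)$out
  if (params$spec$activation == "relu") rowbc(out, params$s_max, `*`) else out
}

as_params <- function(x) {
  if (inherits(x, "ccalign")) x$params
  else if (inherits(x, "generative_params")) x
  else stop("expected a 'generative_params' or fitted 'ccalign' object")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Per cell: \code{0.5 * sum_j (var_j + mean_j^2 - 1 - log var_j)}; always
#' non-negative, zero exactly at the prior (mean 0, variance 1).
#'
#' @param q a \code{latent_gaussian} (list with \code{mean}, \code{var}).
#' @return Numeric vector, one value per cell.
#' @export
kl_to_standard_normal <- function(q) {
  mu <- as.matrix(q$mean); v <- as.matrix(q$var)
  if (any(v <= 0)) stop("non-positive posterior variance")
  0.5 * rowSums(v + mu^2 - 1 - log(v))
}

#' Gaussian reconstruction loss
#'
#' Per cell: \code{sum_genes (x - xhat)^2 / (2 sigma2)} (the constant log
#' normalizer of the Gaussian likelihood is dropped).
#'
#' @param x,xhat observed and reconstructed matrices of equal shape.
#' @param sigma2 residual noise variance (default 1).
#' @return Numeric vector, one value per cell.
#' @export
reconstruction_loss <- function(x, xhat, sigma2 = 1) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) stop("shape mismatch between x and xhat")
  rowSums((x - xhat)^2) / (2 * sigma2)
}

#' Evidence-lower-bound loss on a minibatch
#'
#' Draws one reparameterized sample \code{z = mu + sqrt(var) * eps} per cell,
#' decodes it with the cell's batch code, and returns the mean over cells of
#' \code{reconstruction + beta * KL}, together with the two components.
#' Deterministic for a fixed seed. Inference-mode forward passes (no dropout,
#' running batch-norm statistics) are used; the internal training step uses
#' its own training-mode pass.
#'
#' @param params a \code{generative_params} object.
#' @param x normalized expression matrix or [cell_matrix()].
#' @param batches per-cell batch labels (taken from \code{x} if it is a
#'   \code{cell_matrix}); must map into \code{names(codes)} or be indices.
#' @param codes list of batch codes as from [make_batch_codes()].
#' @param beta KL weight (default 1).
#' @param seed integer seed for the reparameterization draw.
#' @return List with \code{total}, \code{recon}, \code{kl} (means over cells).
#' @export
elbo_loss <- function(params, x, batches = NULL, codes, beta = 1, seed = 1) {
  params <- as_params(params)
  if (inherits(x, "cell_matrix")) {
    if (is.null(batches)) batches <- x$batch
    x <- as_dense(x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(batches)) batches <- rep(1L, n)
  idx <- batch_code_index(batches, codes)
  q <- encode(params, x)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  eps <- matrix(stats::rnorm(n * params$spec$latent_dim), n)
  z <- q$mean + sqrt(q$var) * eps
  code_mat <- do.call(rbind, lapply(idx, function(i)
    as.numeric(codes[[i]])))
  if (params$spec$code_dim == 0) code_mat <- matrix(0, n, 0)
  xhat <- decode(params, z, code_mat)
  recon <- mean(reconstruction_loss(x, xhat, params$sigma2))
  kl <- mean(kl_to_standard_normal(q))
  list(total = recon + beta * kl, recon = recon, kl = kl)
}

batch_code_index <- function(batches, codes) {
  if (is.numeric(batches)) {
    idx <- as.integer(batches)
    if (any(idx < 1 | idx > length(codes))) stop("batch index out of range")
    return(idx)
  }
  lv <- names(codes)
  if (is.null(lv)) lv <- as.character(seq_along(codes))
  idx <- match(as.character(batches), lv)
  if (anyNA(idx))
    stop("missing batch code for label(s): ",
         paste(unique(batches[is.na(idx)]), collapse = ", "))
  idx
}
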