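#' Training configuration
#'
#' @param epochs maximum passes over the data (default 100).
#' @param minibatch_size cells per gradient step (default 256; the last,
#'   possibly smaller, minibatch of each epoch is used, not dropped).
#' @param learning_rate Adam step size (default 3e-3; chosen so that
#'   desk-scale problems, which see only a handful of gradient steps per
#'   epoch, reach convergence within the early-stopping budget).
#' @param early_stop_patience epochs without improvement of the epoch loss by
#'   at least \code{early_stop_min_delta} before training stops (default 10).
#' @param early_stop_min_delta minimum decrease of the epoch loss that counts
#'   as improvement (default 0.01).
#' @param lr_reduce_factor multiplier applied to the learning rate when the
#'   loss plateaus (default 0.8).
#' @param lr_reduce_patience plateau epochs before the learning rate is
#'   reduced (default 4).
#' @param kl_warmup_epochs the KL weight ramps linearly from 0 to \code{beta}
#'   over this many epochs (default 10).
#' @param beta weight of the KL term at full strength (default 1).
#' @param seed integer seed; every source of randomness in a fit
#'   (initialization, shuffling, dropout, reparameterization draws, batch
#'   codes) is derived from it.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 100, minibatch_size = 256,
                         learning_rate = 3e-3, early_stop_patience = 10,
                         early_stop_min_delta = 1e-2, lr_reduce_factor = 0.8,
                         lr_reduce_patience = 4, kl_warmup_epochs = 10,
                         beta = 1, seed = 1) {
  stopifnot(epochs >= 1, minibatch_size >= 1, learning_rate > 0,
            lr_reduce_factor > 0, lr_reduce_factor < 1, beta >= 0)
  structure(list(epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 beta = beta, seed = as.integer(seed)),
            class = "train_config")
}

## deterministic fan-out of a user seed into independent sub-seeds, kept
## well below 2^31
sub_seed <- function(seed, i) ((as.numeric(seed) %% 1000003) * 1009 + i) %% 2147483647

## one gradient step on a minibatch; returns updated params/adam state and
## the loss components (sums over cells, for exact epoch averaging)
vae_step <- function(params, X, code_mat, beta, adam_state, lr, t) {
  n <- nrow(X)
  spec <- params$spec
  enc <- net_forward(params$encoder, X, training = TRUE)
  mu_f <- net_forward(params$mu_head, enc$out, training = TRUE)
  lv_f <- net_forward(params$logvar_head, enc$out, training = TRUE)
  mu <- mu_f$out
  lv_raw <- lv_f$out
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  v <- exp(lv)
  eps <- matrix(stats::rnorm(n * spec$latent_dim), n)
  z <- mu + sqrt(v) * eps
  inp <- cbind(z, code_mat)
  dec <- net_forward(params$decoder, inp, training = TRUE)
  xhat <- if (spec$activation == "relu") rowbc(dec$out, params$s_max, `*`)
          else dec$out
  recon <- rowSums((X - xhat)^2) / (2 * params$sigma2)
  kl <- 0.5 * rowSums(v + mu^2 - 1 - lv)
  loss <- mean(recon + beta * kl)
  if (!is.finite(loss)) return(list(loss = NA_real_))

  dxhat <- (xhat - X) / (params$sigma2 * n)
  dout <- if (spec$activation == "relu") rowbc(dxhat, params$s_max, `*`) else dxhat
  bdec <- net_backward(dec$layers, dec$caches, dout)
  dz <- bdec$dX[, seq_len(spec$latent_dim), drop = FALSE]
  dmu <- dz + beta * mu / n
  dlv <- dz * eps * 0.5 * sqrt(v) + beta * 0.5 * (v - 1) / n
  ## outside the clamp, pass only gradient components that point back inside
  ## (Adam update is -lr * g, so g < 0 raises the parameter)
  dlv[lv_raw <= -LOGVAR_CLAMP & dlv >= 0] <- 0
  dlv[lv_raw >= LOGVAR_CLAMP & dlv <= 0] <- 0
  bmu <- net_backward(mu_f$layers, mu_f$caches, dmu)
  blv <- net_backward(lv_f$layers, lv_f$caches, dlv)
  benc <- net_backward(enc$layers, enc$caches, bmu$dX + blv$dX)

  nets <- list(enc$layers, mu_f$layers, lv_f$layers, dec$layers)
  grads <- list(benc$grads, bmu$grads, blv$grads, bdec$grads)
  upd <- adam_step(nets, grads, adam_state, lr, t)
  params$encoder <- upd$nets[[1]]
  params$mu_head <- upd$nets[[2]]
  params$logvar_head <- upd$nets[[3]]
  params$decoder <- upd$nets[[4]]
  list(params = params, adam_state = upd$state, loss = loss,
       recon_sum = sum(recon), kl_sum = sum(kl), n = n)
}

## data-dependent initialization: start the decoder's output at the per-gene
## training means so optimization spends its budget on structure, not offsets
init_output_bias <- function(params, X) {
  mu_g <- colMeans(X)
  nl <- length(params$decoder)
  if (params$spec$activation == "relu") {
    ## invert the hard-sigmoid gate: hardsig(b) = mean/s_max on its linear part
    frac <- ifelse(params$s_max > 0, mu_g / params$s_max, 0.5)
    params$decoder[[nl - 1]]$b <- pmin(pmax((frac - 0.5) / 0.2, -2.4), 2.4)
  } else {
    params$decoder[[nl - 1]]$b <- mu_g
  }
  params
}

## set every batch-norm layer's running statistics to the exact full-data
## statistics of its input (dropout off), returning updated layers + output
recalibrate_bn <- function(layers, X) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "dropout") next
    if (l$kind == "bn") {
      m <- colMeans(X)
      layers[[i]]$running_mean <- m
      layers[[i]]$running_var <- colMeans(rowbc(X, m, `-`)^2)
    }
    X <- layer_forward(layers[[i]], X, training = FALSE)$out
  }
  list(layers = layers, out = X)
}

## center the initial posterior means at zero (where the prior lives); the
## same pass primes the batch-norm running averages with full-data statistics
center_mu_head <- function(params, X) {
  rc <- recalibrate_bn(params$encoder, X)
  params$encoder <- rc$layers
  mu0 <- net_forward(params$mu_head, rc$out, training = FALSE)$out
  params$mu_head[[1]]$b <- params$mu_head[[1]]$b - colMeans(mu0)
  params
}

#' Fit the conditional variational autoencoder
#'
#' Mini-batch stochastic gradient training of the generative parameters with
#' adaptive-moment (Adam) updates, a linear KL warm-up, learning-rate
#' reduction on plateau, and early stopping on the epoch loss. The parameters
#' achieving the best epoch loss are returned (not the last-epoch ones).
#'
#' @param data a normalized, gene-filtered [cell_matrix()] (layer
#'   \code{cpm_log}, \code{activity} or \code{recovered}) holding all cells of
#'   all datasets, with per-cell batch labels.
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @param codes optional list of batch codes named by batch label; generated
#'   from the config seed when \code{NULL}.
#' @return List with \code{params} (class \code{generative_params}),
#'   \code{codes}, and \code{history} (data.frame with per-epoch total,
#'   reconstruction and KL losses, KL weight and learning rate, plus a
#'   \code{stop_reason} attribute).
#' @export
fit_ccalign <- function(data, spec = network_spec(), config = train_config(),
                        codes = NULL) {
  stopifnot(inherits(data, "cell_matrix"))
  if (data$layer == "counts")
    stop("fit_ccalign expects normalized data; run cpm_log_normalize() first")
  X_all <- as_dense(data)
  n <- nrow(X_all)
  if (n < 2) stop("need at least 2 cells")
  batch_levels <- unique(data$batch)
  if (is.null(codes)) {
    codes <- make_batch_codes(length(batch_levels), spec,
                              seed = sub_seed(config$seed, 1))
    names(codes) <- batch_levels
  }
  code_idx <- batch_code_index(data$batch, codes)
  code_rows <- do.call(rbind, lapply(codes, as.numeric))
  if (spec$code_dim == 0) code_rows <- matrix(0, length(codes), 0)

  old <- local_rng(sub_seed(config$seed, 2))
  on.exit(restore_rng(old))

  params <- init_params(spec, ncol(X_all))
  smax <- apply(X_all, 2, max)
  params$s_max <- smax
  params <- init_output_bias(params, X_all)
  params <- center_mu_head(params, X_all)
  adam_state <- adam_init(list(params$encoder, params$mu_head,
                               params$logvar_head, params$decoder))
  lr <- config$learning_rate
  best_loss <- Inf
  best_params <- params
  no_improve <- 0L
  lr_no_improve <- 0L
  t <- 0L
  hist <- list()
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$epochs)) {
    beta_e <- config$beta *
      if (config$kl_warmup_epochs > 0) min(1, epoch / config$kl_warmup_epochs) else 1
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$minibatch_size)
    recon_sum <- 0; kl_sum <- 0
    for (s in starts) {
      rows <- ord[s:min(s + config$minibatch_size - 1L, n)]
      t <- t + 1L
      step <- vae_step(params, X_all[rows, , drop = FALSE],
                       code_rows[code_idx[rows], , drop = FALSE],
                       beta_e, adam_state, lr, t)
      if (is.na(step$loss))
        stop("non-finite loss at epoch ", epoch)
      params <- step$params
      adam_state <- step$adam_state
      recon_sum <- recon_sum + step$recon_sum
      kl_sum <- kl_sum + step$kl_sum
    }
    epoch_recon <- recon_sum / n
    epoch_kl <- kl_sum / n
    epoch_loss <- epoch_recon + beta_e * epoch_kl
    hist[[epoch]] <- c(total = epoch_loss, recon = epoch_recon, kl = epoch_kl,
                       beta = beta_e, lr = lr)
    if (epoch_loss < best_loss - config$early_stop_min_delta) {
      best_loss <- epoch_loss
      best_params <- params
      no_improve <- 0L
      lr_no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      lr_no_improve <- lr_no_improve + 1L
      if (lr_no_improve >= config$lr_reduce_patience) {
        lr <- lr * config$lr_reduce_factor
        lr_no_improve <- 0L
      }
      if (no_improve >= config$early_stop_patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  history <- as.data.frame(do.call(rbind, hist))
  history$epoch <- seq_len(nrow(history))
  attr(history, "stop_reason") <- stop_reason
  list(params = best_params, codes = codes, history = history)
}

#' Align single-cell datasets in a shared latent space
#'
#' The main fitting function. Takes one or more cell-by-gene count (or
#' already-normalized) matrices, normalizes them (counts per million followed
#' by \code{log1p}), concatenates them over their shared genes, fits the
#' conditional variational autoencoder, and returns the fitted model together
#' with the batch-free latent embedding and the recovered (batch-corrected)
#' expression matrix decoded with one common reference batch code.
#'
#' @param datasets a [cell_matrix()] or a list of them (each list element is
#'   one batch/dataset).
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @param hvg optional character vector of genes to restrict to before
#'   fitting (e.g. from [select_hvg_consensus()]).
#' @param normalize apply [cpm_log_normalize()] to count layers (default
#'   TRUE).
#' @param reference_batch index (or name) of the batch whose code is used for
#'   recovered expression (default 1, the first batch).
#' @param codes optional pre-generated batch codes.
#' @param recover compute the recovered expression matrix (default TRUE).
#' @return An object of class \code{ccalign} with components \code{params},
#'   \code{spec}, \code{config}, \code{codes}, \code{history},
#'   \code{embedding} (n x d matrix), \code{recovered} ([cell_matrix()] or
#'   NULL), \code{data} (the normalized training matrix) and
#'   \code{reference_batch}. Supports \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot} and \code{simulate}.
#' @seealso [get_embedding()], [recover_expression()], [transfer_labels()]
#' @export
ccalign <- function(datasets, spec = network_spec(), config = train_config(),
                    hvg = NULL, normalize = TRUE, reference_batch = 1,
                    codes = NULL, recover = TRUE) {
  cl <- match.call()
  data <- if (inherits(datasets, "cell_matrix")) datasets
          else if (length(datasets) == 1) datasets[[1]]
          else concat_datasets(datasets)
  if (!is.null(hvg)) {
    keep <- data$gene_ids %in% hvg
    if (!any(keep)) stop("none of the requested HVGs are present")
    data <- subset_genes(data, keep)
  }
  if (normalize && data$layer == "counts") data <- cpm_log_normalize(data)
  res <- fit_ccalign(data, spec, config, codes = codes)
  embedding <- get_embedding(res$params, data)
  obj <- structure(list(params = res$params, spec = spec, config = config,
                        codes = res$codes, history = res$history,
                        embedding = embedding, recovered = NULL,
                        data = data, reference_batch = reference_batch,
                        call = cl),
                   class = "ccalign")
  if (recover) obj$recovered <- recover_expression(obj, reference_batch = reference_batch)
  obj
}

#' @export
print.ccalign <- function(x, ...) {
  cat("Conditional VAE alignment of single-cell datasets\n")
  cat("Call: ", deparse(x$call), "\n\n")
  bt <- table(x$data$batch)
  cat(sprintf("  %d cells, %d genes, %d batch(es): %s\n",
              nrow(x$data$values), ncol(x$data$values), length(bt),
              paste(sprintf("%s (%d)", names(bt), bt), collapse = ", ")))
  cat(sprintf("  latent dimension %d, code dimension %d\n",
              x$spec$latent_dim, x$spec$code_dim))
  h <- x$history
  cat(sprintf("  trained %d epoch(s), final loss %.4f (recon %.4f, KL %.4f), stop: %s\n",
              nrow(h), h$total[nrow(h)], h$recon[nrow(h)], h$kl[nrow(h)],
              attr(h, "stop_reason")))
  invisible(x)
}

#' @export
summary.ccalign <- function(object, ...) {
  h <- object$history
  structure(list(call = object$call,
                 n_cells = nrow(object$data$values),
                 n_genes = ncol(object$data$values),
                 batches = table(object$data$batch),
                 latent_dim = object$spec$latent_dim,
                 epochs = nrow(h),
                 best_loss = min(h$total),
                 stop_reason = attr(h, "stop_reason"),
                 history_tail = utils::tail(h, 5)),
            class = "summary.ccalign")
}

#' @export
print.summary.ccalign <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d cells x %d genes in %d batch(es); latent dimension %d\n",
              x$n_cells, x$n_genes, length(x$batches), x$latent_dim))
  cat(sprintf("Trained %d epochs (stop: %s), best loss %.4f\n",
              x$epochs, x$stop_reason, x$best_loss))
  cat("\nLast epochs:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ccalign <- function(object, ...) {
  list(encoder = object$params$encoder, mu_head = object$params$mu_head,
       logvar_head = object$params$logvar_head,
       decoder = object$params$decoder, s_max = object$params$s_max,
       codes = object$codes)
}

#' Predict from a fitted alignment model
#'
#' @param object a fitted \code{ccalign} model.
#' @param newdata optional [cell_matrix()] (normalized, on the training gene
#'   set) or matrix; defaults to the training data.
#' @param type \code{"embedding"} (posterior means), \code{"recovered"}
#'   (decoded with the reference batch code: batch-free expression) or
#'   \code{"reconstruction"} (decoded with each cell's own batch code;
#'   requires batch labels).
#' @param ... unused.
#' @return A matrix (\code{embedding}) or [cell_matrix()] otherwise.
#' @export
predict.ccalign <- function(object, newdata = NULL,
                            type = c("embedding", "recovered", "reconstruction"),
                            ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  emb <- get_embedding(object$params, data)
  if (type == "embedding") return(emb)
  if (type == "recovered")
    return(recover_expression(object, data = data,
                              reference_batch = object$reference_batch))
  if (!inherits(data, "cell_matrix"))
    stop("reconstruction requires a cell_matrix with batch labels")
  idx <- batch_code_index(data$batch, object$codes)
  code_mat <- do.call(rbind, lapply(object$codes, as.numeric))[idx, , drop = FALSE]
  vals <- decode(object$params, emb, code_mat)
  cell_matrix(vals, cell_ids = data$cell_ids, gene_ids = data$gene_ids,
              batch = data$batch, type = data$type, layer = "recovered")
}

#' @export
fitted.ccalign <- function(object, ...) {
  as_dense(predict(object, type = "reconstruction"))
}

#' @export
residuals.ccalign <- function(object, ...) {
  as_dense(object$data) - fitted(object)
}

#' Plot training history or embedding of a fitted model
#'
#' @param x a fitted \code{ccalign} model.
#' @param type \code{"history"} (loss curves) or \code{"embedding"} (first two
#'   latent dimensions colored by batch).
#' @param ... passed to the underlying plotting function.
#' @export
plot.ccalign <- function(x, type = c("history", "embedding"), ...) {
  type <- match.arg(type)
  if (type == "history") {
    h <- x$history
    graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                   ylab = "loss", main = "Training loss", ...)
    graphics::lines(h$epoch, h$recon, lty = 2)
    graphics::legend("topright", legend = c("total", "reconstruction"),
                     lty = c(1, 2), bty = "n")
  } else {
    b <- factor(x$data$batch)
    graphics::plot(x$embedding[, 1], x$embedding[, 2], col = as.integer(b),
                   pch = 16, cex = 0.5, xlab = "latent 1", ylab = "latent 2",
                   main = "Latent embedding", ...)
    graphics::legend("topright", legend = levels(b), col = seq_along(levels(b)),
                     pch = 16, bty = "n")
  }
  invisible(x)
}

#' Simulate cells from the fitted generative model
#'
#' Draws latent factors from the standard-normal prior and decodes them with
#' the reference batch code.
#'
#' @param object a fitted \code{ccalign} model.
#' @param nsim number of cells to draw (default the training size).
#' @param seed integer seed.
#' @param ... unused.
#' @return Matrix of simulated expression values (\code{nsim} x genes).
#' @export
simulate.ccalign <- function(object, nsim = nrow(object$data$values),
                             seed = 1, ...) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  z <- matrix(stats::rnorm(nsim * object$spec$latent_dim), nsim)
  ref <- object$reference_batch
  code <- if (is.character(ref)) object$codes[[ref]] else object$codes[[ref]]
  out <- decode(object$params, z, code)
  colnames(out) <- object$data$gene_ids
  out
}
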