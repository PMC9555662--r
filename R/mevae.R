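#' Per-channel latent allocation for a target concatenated latent size
#'
#' Each of the `n_inputs` encoders gets an equal latent dimension `k`; since
#' `n * k` cannot always hit the target exactly, `k` is chosen to minimize
#' `|n * k - target|`, ties going to the larger `k`.
#'
#' @param n_inputs number of input channels (encoders).
#' @param target target concatenated latent size (default 128).
#' @return integer per-channel latent dimension.
#' @export
latent_allocation <- function(n_inputs, target = 128) {
  stopifnot(n_inputs >= 1)
  k0 <- max(1L, as.integer(floor(target / n_inputs)))
  cands <- unique(c(k0, k0 + 1L))
  d <- abs(cands * n_inputs - target)
  best <- cands[d == min(d)]
  as.integer(max(best))   # tie -> larger k
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

dense_init <- function(n_in, n_out) list(W = glorot(n_in, n_out),
                                         b = numeric(n_out))
dense_fwd <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, "+")

# backward through a dense layer: returns grads and upstream delta
dense_bwd <- function(delta, x, layer) {
  list(dW = crossprod(x, delta), db = colSums(delta),
       dx = tcrossprod(delta, layer$W))
}

mevae_init_params <- function(D, n_in, n_out, k, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  enc <- lapply(seq_len(n_in), function(i)
    list(l1 = dense_init(D, h1), l2 = dense_init(h1, h2),
         mu = dense_init(h2, k), lv = dense_init(h2, k)))
  dec <- list(l1 = dense_init(n_in * k, h2), l2 = dense_init(h2, h1),
              out = dense_init(h1, n_out * D))
  list(enc = enc, dec = dec)
}

# walk two parallel param-shaped structures applying f to matching leaves
param_walk <- function(p, g, f) {
  if (is.list(p) && !is.null(p$W)) return(f(p, g))
  out <- vector("list", length(p))
  names(out) <- names(p)
  for (nm in seq_along(p)) out[[nm]] <- param_walk(p[[nm]], g[[nm]], f)
  out
}

adam_state_like <- function(p) {
  param_walk(p, p, function(layer, .)
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
      s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
      s$mb <- beta1 * s$mb + (1 - beta1) * g$db
      s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
      p$W <- p$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
      p$b <- p$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
      return(list(p = p, s = s))
    }
    for (i in seq_along(p)) {
      r <- walk(p[[i]], g[[i]], s[[i]])
      p[[i]] <- r$p; s[[i]] <- r$s
    }
    list(p = p, s = s)
  }
  r <- walk(params, grads, state)
  list(params = r$p, state = r$s)
}

# flatten each channel of a cell list into an n_cells x (crop^2) matrix
cells_to_channel_matrices <- function(cells, markers) {
  stopifnot(length(cells) > 0)
  idx <- match(markers, cells[[1]]$marker_names)
  if (anyNA(idx)) stop("channel mismatch: markers missing from cells")
  D <- prod(dim(cells[[1]]$pixels)[2:3])
  lapply(idx, function(ch) {
    t(vapply(cells, function(cell) as.numeric(cell$pixels[ch, , ]),
             numeric(D)))
  })
}

mevae_forward <- function(params, Xb, sample_z = FALSE, eps_list = NULL) {
  n_in <- length(Xb)
  encs <- vector("list", n_in)
  zs <- vector("list", n_in)
  for (i in seq_len(n_in)) {
    e <- params$enc[[i]]
    a1 <- dense_fwd(Xb[[i]], e$l1); h1 <- relu(a1)
    a2 <- dense_fwd(h1, e$l2); h2 <- relu(a2)
    mu <- dense_fwd(h2, e$mu)
    lv <- pmin(pmax(dense_fwd(h2, e$lv), -10), 10)
    z <- if (sample_z) mu + eps_list[[i]] * exp(0.5 * lv) else mu
    encs[[i]] <- list(h1 = h1, h2 = h2, mu = mu, lv = lv)
    zs[[i]] <- z
  }
  z_all <- do.call(cbind, zs)
  d <- params$dec
  da1 <- dense_fwd(z_all, d$l1); dh1 <- relu(da1)
  da2 <- dense_fwd(dh1, d$l2); dh2 <- relu(da2)
  logits <- dense_fwd(dh2, d$out)
  P <- sigmoid(logits)
  list(encs = encs, zs = zs, z_all = z_all, dh1 = dh1, dh2 = dh2, P = P)
}

# decoder backward from dLogits to dz_all; returns decoder grads + dz_all
mevae_decoder_bwd <- function(params, fw, dLogits) {
  d <- params$dec
  g_out <- dense_bwd(dLogits, fw$dh2, d$out)
  d2 <- g_out$dx * (fw$dh2 > 0)
  g_l2 <- dense_bwd(d2, fw$dh1, d$l2)
  d1 <- g_l2$dx * (fw$dh1 > 0)
  g_l1 <- dense_bwd(d1, fw$z_all, d$l1)
  list(grads = list(l1 = list(dW = g_l1$dW, db = g_l1$db),
                    l2 = list(dW = g_l2$dW, db = g_l2$db),
                    out = list(dW = g_out$dW, db = g_out$db)),
       dz_all = g_l1$dx)
}

#' Fit a multi-encoder variational autoencoder for panel imputation
#'
#' One encoder per input channel maps that channel's pixels to the mean and
#' log-variance of its own latent block; the blocks are concatenated and a
#' single decoder emits all output channels through a sigmoid. Encoders and
#' the decoder are each 3 dense layers deep with ReLU activations. The
#' training loss is pixelwise binary cross-entropy between the cell's full
#' panel and the decoded output, plus the mean over encoders of the KL
#' divergence of each encoder's posterior from a unit Gaussian prior.
#' Optimized with Adam; all randomness (init, shuffling, reparameterization)
#' comes from one stream seeded by `seed`, so training is deterministic.
#'
#' @param cells list of preprocessed `single_cell_image` (aligned, oriented,
#'   intensities in \[0,1\]) used for training.
#' @param input_markers ordered character vector: the reduced panel fed to
#'   the encoders.
#' @param output_markers full panel emitted by the decoder (default: the
#'   cells' full marker set).
#' @param latent_total target concatenated latent size (default 128); the
#'   per-encoder dimension is [latent_allocation()].
#' @param hidden widths of the two hidden dense layers (encoder
#'   `D -> hidden[1] -> hidden[2] -> latent`, decoder mirrored).
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return object of class `mevae`: fitted weights, config, and `history`
#'   (data.frame epoch/bce/kl/total).
#' @seealso [predict.mevae()], [impute_full()], [encoding_gradients()]
#' @export
mevae <- function(cells, input_markers, output_markers = NULL,
                  latent_total = 128, hidden = c(128, 64), epochs = 10,
                  batch_size = 64, learning_rate = 1e-3, seed = 1,
                  verbose = FALSE) {
  if (!length(cells)) stop("empty training set")
  if (is.null(output_markers)) output_markers <- cells[[1]]$marker_names
  stopifnot(all(input_markers %in% cells[[1]]$marker_names),
            all(output_markers %in% cells[[1]]$marker_names))
  crop <- dim(cells[[1]]$pixels)[2]
  D <- crop * crop
  n_in <- length(input_markers)
  n_out <- length(output_markers)
  k <- latent_allocation(n_in, latent_total)
  Xin <- cells_to_channel_matrices(cells, input_markers)
  Xout_list <- cells_to_channel_matrices(cells, output_markers)
  Tgt <- do.call(cbind, Xout_list)
  if (min(Tgt) < 0 || max(Tgt) > 1) {
    warning("targets outside [0,1]; clipping")
    Tgt <- clip01(Tgt)
  }
  n <- nrow(Tgt)
  with_local_seed(seed, {
    params <- mevae_init_params(D, n_in, n_out, k, hidden)
    state <- adam_state_like(params)
    t_step <- 0
    history <- data.frame(epoch = integer(0), bce = numeric(0),
                          kl = numeric(0), total = numeric(0))
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_bce <- 0; ep_kl <- 0; n_batches <- 0
      for (start in seq(1, n, by = batch_size)) {
        ix <- perm[start:min(start + batch_size - 1, n)]
        bn <- length(ix)
        Xb <- lapply(Xin, function(m) m[ix, , drop = FALSE])
        Tb <- Tgt[ix, , drop = FALSE]
        eps_list <- lapply(seq_len(n_in), function(i)
          matrix(rnorm(bn * k), bn, k))
        fw <- mevae_forward(params, Xb, sample_z = TRUE,
                            eps_list = eps_list)
        P <- pmin(pmax(fw$P, 1e-7), 1 - 1e-7)
        bce <- -sum(Tb * log(P) + (1 - Tb) * log(1 - P)) / bn
        kl_terms <- vapply(fw$encs, function(e)
          0.5 * sum(e$mu^2 + exp(e$lv) - 1 - e$lv) / bn, numeric(1))
        kl <- mean(kl_terms)
        if (!is.finite(bce) || !is.finite(kl))
          stop(sprintf("NaN/Inf loss at epoch %d (bce=%g, kl=%g); lower the learning rate",
                       ep, bce, kl))
        dLogits <- (fw$P - Tb) / bn
        dec_b <- mevae_decoder_bwd(params, fw, dLogits)
        grads <- list(enc = vector("list", n_in), dec = dec_b$grads)
        for (i in seq_len(n_in)) {
          e <- params$enc[[i]]
          enc_f <- fw$encs[[i]]
          dz <- dec_b$dz_all[, ((i - 1) * k + 1):(i * k), drop = FALSE]
          dmu <- dz + enc_f$mu / (n_in * bn)
          dlv <- dz * eps_list[[i]] * 0.5 * exp(0.5 * enc_f$lv) +
            0.5 * (exp(enc_f$lv) - 1) / (n_in * bn)
          g_mu <- dense_bwd(dmu, enc_f$h2, e$mu)
          g_lv <- dense_bwd(dlv, enc_f$h2, e$lv)
          dh2 <- (g_mu$dx + g_lv$dx) * (enc_f$h2 > 0)
          g_l2 <- dense_bwd(dh2, enc_f$h1, e$l2)
          dh1 <- g_l2$dx * (enc_f$h1 > 0)
          g_l1 <- dense_bwd(dh1, Xb[[i]], e$l1)
          grads$enc[[i]] <- list(
            l1 = list(dW = g_l1$dW, db = g_l1$db),
            l2 = list(dW = g_l2$dW, db = g_l2$db),
            mu = list(dW = g_mu$dW, db = g_mu$db),
            lv = list(dW = g_lv$dW, db = g_lv$db))
        }
        t_step <- t_step + 1
        res <- adam_step(params, grads, state, learning_rate, t_step)
        params <- res$params; state <- res$state
        ep_bce <- ep_bce + bce; ep_kl <- ep_kl + kl
        n_batches <- n_batches + 1
      }
      history <- rbind(history, data.frame(
        epoch = ep, bce = ep_bce / n_batches, kl = ep_kl / n_batches,
        total = (ep_bce + ep_kl) / n_batches))
      if (verbose)
        message(sprintf("epoch %d: bce %.2f kl %.3f", ep,
                        ep_bce / n_batches, ep_kl / n_batches))
    }
    structure(list(params = params, history = history, trained = TRUE,
                   config = list(input_markers = input_markers,
                                 output_markers = output_markers,
                                 per_channel_latent = k,
                                 total_latent = k * n_in,
                                 hidden = hidden, crop = crop,
                                 epochs = epochs, batch_size = batch_size,
                                 learning_rate = learning_rate, seed = seed)),
              class = "mevae")
  })
}

#' @export
print.mevae <- function(x, ...) {
  cf <- x$config
  cat(sprintf("mevae: %d input -> %d output channels (%dx%d px)\n",
              length(cf$input_markers), length(cf$output_markers),
              cf$crop, cf$crop))
  cat(sprintf("  latent: %d per channel (total %d), hidden %s\n",
              cf$per_channel_latent, cf$total_latent,
              paste(cf$hidden, collapse = "/")))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; final loss %.3f (bce %.3f, kl %.3f)\n",
                nrow(x$history), x$history$total[nrow(x$history)],
                x$history$bce[nrow(x$history)],
                x$history$kl[nrow(x$history)]))
  invisible(x)
}

#' @export
plot.mevae <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$total, type = "b", xlab = "epoch", ylab = "loss",
       main = "ME-VAE training loss", ...)
  lines(h$epoch, h$bce, type = "b", col = "grey50")
  legend("topright", c("total", "bce"), col = c("black", "grey50"), lty = 1)
  invisible(x)
}

#' Impute full-panel images from reduced-panel cells
#'
#' Inference uses the encoder means (no latent sampling), so repeated calls
#' are identical. Output pixels are sigmoid activations, strictly in (0,1).
#'
#' @param object a fitted [mevae()].
#' @param cells list of `single_cell_image` carrying at least the model's
#'   input channels.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return list of `single_cell_image` with the model's output channels and
#'   the input cells' masks and ids.
#' @export
predict.mevae <- function(object, cells, batch_size = 256, ...) {
  cf <- object$config
  Xin <- cells_to_channel_matrices(cells, cf$input_markers)
  n <- length(cells)
  crop <- cf$crop
  n_out <- length(cf$output_markers)
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    Xb <- lapply(Xin, function(m) m[ix, , drop = FALSE])
    fw <- mevae_forward(object$params, Xb, sample_z = FALSE)
    for (r in seq_along(ix)) {
      px <- array(0, c(n_out, crop, crop))
      for (ch in seq_len(n_out))
        px[ch, , ] <- matrix(fw$P[r, ((ch - 1) * crop * crop + 1):
                                      (ch * crop * crop)], crop, crop)
      cell <- cells[[ix[r]]]
      out[[ix[r]]] <- single_cell_image(px, cell$mask, cell$cell_id,
                                        cf$output_markers, cell$metadata)
    }
  }
  out
}

#' @rdname predict.mevae
#' @export
impute_full <- function(object, cells, batch_size = 256) {
  predict.mevae(object, cells, batch_size)
}

#' Per-channel importance from encoding-layer gradients
#'
#' For a model trained with the full panel as both input and output (one
#' encoder per channel), the gradient of the reconstruction (BCE) loss with
#' respect to each channel's latent encoding measures how much that channel
#' contributes to reconstructing the whole panel. The importance of channel
#' `i` is the mean absolute gradient over its latent dimensions and over
#' cells; absolute values are taken before averaging so opposite-signed
#' gradients cannot cancel.
#'
#' @param model a fitted [mevae()]; a warning is issued if it was not trained
#'   or if its input panel differs from its output panel.
#' @param cells cells over which to average (typically the training split).
#' @param batch_size batch size.
#' @return named nonnegative numeric vector, one importance per input
#'   channel, suitable for [select_panel_gradient()].
#' @export
encoding_gradients <- function(model, cells, batch_size = 256) {
  cf <- model$config
  if (!isTRUE(model$trained))
    warning("model is untrained; importances reflect initialization")
  if (!setequal(cf$input_markers, cf$output_markers))
    warning("gradient ranking expects a model trained full panel -> full panel")
  Xin <- cells_to_channel_matrices(cells, cf$input_markers)
  Tgt <- do.call(cbind, cells_to_channel_matrices(cells, cf$output_markers))
  n <- length(cells)
  n_in <- length(cf$input_markers)
  k <- cf$per_channel_latent
  acc <- numeric(n_in)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    Xb <- lapply(Xin, function(m) m[ix, , drop = FALSE])
    fw <- mevae_forward(model$params, Xb, sample_z = FALSE)
    dLogits <- (fw$P - Tgt[ix, , drop = FALSE])   # per-cell BCE gradient
    dz <- mevae_decoder_bwd(model$params, fw, dLogits)$dz_all
    for (i in seq_len(n_in))
      acc[i] <- acc[i] +
        sum(abs(dz[, ((i - 1) * k + 1):(i * k), drop = FALSE]))
  }
  imp <- acc / (n * k)
  names(imp) <- cf$input_markers
  imp
}
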