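## LSTM sequence classifier with full backpropagation-through-time and Adam,
## in vectorised base R. Architecture: stacked LSTM layers, each followed by
## (inverted) dropout, a dense layer on the last time step's hidden state,
## softmax, class-weighted cross-entropy. Gradients are validated against
## numerical differentiation in the test suite.
##
## Sequences are passed as a 3-D array [batch, time, features].

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(input_size, layer_sizes, n_classes) {
  layers <- list()
  d <- input_size
  for (h in layer_sizes) {
    r_w <- sqrt(6 / (d + 4 * h)); r_u <- sqrt(6 / (h + 4 * h))
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1     # forget-gate bias init
    layers[[length(layers) + 1]] <- list(
      W = matrix(runif(d * 4 * h, -r_w, r_w), d, 4 * h),
      U = matrix(runif(h * 4 * h, -r_u, r_u), h, 4 * h),
      b = b)
    d <- h
  }
  r_o <- sqrt(6 / (d + n_classes))
  list(layers = layers,
       out_W = matrix(runif(d * n_classes, -r_o, r_o), d, n_classes),
       out_b = numeric(n_classes))
}

# forward pass; returns posteriors and (optionally) caches for backprop
lstm_forward <- function(params, X, dropout_p = 0, training = FALSE,
                         keep_cache = FALSE) {
  B <- dim(X)[1]; Tt <- dim(X)[2]; D <- dim(X)[3]
  inp <- lapply(seq_len(Tt), function(t) matrix(X[, t, ], B, D))
  caches <- list()
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    H <- nrow(p$U)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache_t <- if (keep_cache) vector("list", Tt) else NULL
    out <- vector("list", Tt)
    bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
    for (t in seq_len(Tt)) {
      z <- inp[[t]] %*% p$W + h %*% p$U + bmat
      s_all <- sigmoid(z[, 1:(3 * H), drop = FALSE])
      i_g <- s_all[, 1:H, drop = FALSE]
      f_g <- s_all[, (H + 1):(2 * H), drop = FALSE]
      o_g <- s_all[, (2 * H + 1):(3 * H), drop = FALSE]
      g_g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc
      cc <- f_g * c_prev + i_g * g_g
      tc <- tanh(cc)
      h <- o_g * tc
      if (keep_cache) {
        cache_t[[t]] <- list(x = inp[[t]], h_prev = if (t == 1) matrix(0, B, H) else out[[t - 1]],
                             i = i_g, f = f_g, o = o_g, g = g_g,
                             c_prev = c_prev, tc = tc)
      }
      out[[t]] <- h
    }
    mask <- NULL
    if (training && dropout_p > 0) {
      mask <- lapply(seq_len(Tt), function(t)
        matrix(stats::rbinom(B * H, 1, 1 - dropout_p), B, H) / (1 - dropout_p))
      out <- lapply(seq_len(Tt), function(t) out[[t]] * mask[[t]])
    }
    if (keep_cache) caches[[l]] <- list(steps = cache_t, mask = mask)
    inp <- out
  }
  h_last <- inp[[Tt]]
  logits <- h_last %*% params$out_W +
    matrix(params$out_b, B, length(params$out_b), byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  post <- e / rowSums(e)
  list(posterior = post, h_last = h_last, caches = caches)
}

# loss and full gradient for one minibatch; y is an integer class in 1..K,
# w a per-class weight vector
lstm_loss_grad <- function(params, X, y, class_weights, dropout_p = 0,
                           training = TRUE) {
  B <- dim(X)[1]; Tt <- dim(X)[2]
  fw <- lstm_forward(params, X, dropout_p, training = training,
                     keep_cache = TRUE)
  post <- fw$posterior
  wy <- class_weights[y]
  wsum <- sum(wy)
  py <- post[cbind(seq_len(B), y)]
  loss <- -sum(wy * log(pmax(py, 1e-12))) / wsum

  dlogits <- post
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits * (wy / wsum)

  grads <- list(layers = vector("list", length(params$layers)))
  grads$out_W <- crossprod(fw$h_last, dlogits)
  grads$out_b <- colSums(dlogits)

  # gradient w.r.t. the top layer's output sequence: only the last step
  n_layers <- length(params$layers)
  H_top <- nrow(params$layers[[n_layers]]$U)
  d_out <- lapply(seq_len(Tt), function(t) matrix(0, B, H_top))
  d_out[[Tt]] <- dlogits %*% t(params$out_W)

  for (l in rev(seq_len(n_layers))) {
    p <- params$layers[[l]]
    ch <- fw$caches[[l]]
    H <- nrow(p$U)
    if (!is.null(ch$mask)) {
      d_out <- lapply(seq_len(Tt), function(t) d_out[[t]] * ch$mask[[t]])
    }
    dW <- matrix(0, nrow(p$W), ncol(p$W))
    dU <- matrix(0, H, 4 * H)
    db <- numeric(4 * H)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    d_below <- lapply(seq_len(Tt), function(t) matrix(0, B, nrow(p$W)))
    for (t in rev(seq_len(Tt))) {
      s <- ch$steps[[t]]
      dh <- d_out[[t]] + dh_next
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      do_g <- dh * s$tc
      di_g <- dc * s$g
      dg_g <- dc * s$i
      df_g <- dc * s$c_prev
      dc_next <- dc * s$f
      dz <- cbind(di_g * s$i * (1 - s$i),
                  df_g * s$f * (1 - s$f),
                  do_g * s$o * (1 - s$o),
                  dg_g * (1 - s$g^2))
      dW <- dW + crossprod(s$x, dz)
      dU <- dU + crossprod(s$h_prev, dz)
      db <- db + colSums(dz)
      d_below[[t]] <- dz %*% t(p$W)
      dh_next <- dz %*% t(p$U)
    }
    grads$layers[[l]] <- list(W = dW, U = dU, b = db)
    d_out <- d_below
  }
  list(loss = loss, grads = grads, posterior = post)
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  rapply(params, zero_like, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr = 2e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m1, v1) {
    m1 <- beta1 * m1 + (1 - beta1) * g
    v1 <- beta2 * v1 + (1 - beta2) * g^2
    mh <- m1 / (1 - beta1^t); vh <- v1 / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m1, v = v1)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "U", "b")) {
      r <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               m$layers[[l]][[nm]], v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- r$p
      m$layers[[l]][[nm]] <- r$m
      v$layers[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("out_W", "out_b")) {
    r <- upd(params[[nm]], grads[[nm]], m[[nm]], v[[nm]])
    params[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
  }
  list(params = params, m = m, v = v)
}

#' Train an LSTM sequence classifier
#'
#' Stacked LSTM layers with dropout after each layer, a dense softmax read-out
#' on the last time step, class-weighted cross-entropy and Adam. Training is
#' bit-reproducible given the seed.
#'
#' @param X numeric array `[n, time, features]` of training sequences.
#' @param y integer class labels in `1..n_classes`.
#' @param x_val,y_val optional validation set; per-epoch validation Cohen's
#'   kappa is logged when provided.
#' @param layer_sizes hidden units per LSTM layer.
#' @param n_classes number of classes.
#' @param epochs full passes over the training data.
#' @param dropout_p dropout probability after each LSTM layer.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param class_weights per-class loss weights; default inverse class
#'   frequency.
#' @param seed integer seed controlling initialisation, shuffling and dropout.
#' @return An object of class `lstm_net`.
#' @export
train_lstm <- function(X, y, x_val = NULL, y_val = NULL,
                       layer_sizes = c(32, 32), n_classes = 2,
                       epochs = 6, dropout_p = 0.1, lr = 2e-3,
                       batch_size = 128, class_weights = NULL, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    abort("training data must contain both classes")
  }
  n <- dim(X)[1]
  if (is.null(class_weights)) {
    tab <- tabulate(y, n_classes)
    class_weights <- n / (n_classes * pmax(tab, 1))
  }
  history <- list()
  params <- NULL
  withr::with_seed(seed, {
    params <- init_lstm_params(dim(X)[3], layer_sizes, n_classes)
    m <- adam_init(params); v <- adam_init(params)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        lg <- lstm_loss_grad(params, X[idx, , , drop = FALSE], y[idx],
                             class_weights, dropout_p, training = TRUE)
        step <- step + 1L
        st <- adam_step(params, lg$grads, m, v, step, lr = lr)
        params <- st$params; m <- st$m; v <- st$v
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      val_kappa <- NA_real_
      if (!is.null(x_val)) {
        pv <- lstm_predict_params(params, x_val)
        pred <- max.col(pv)
        if (length(unique(y_val)) > 1) {
          val_kappa <- cohens_kappa(confusion_from_labels(pred == 2, y_val == 2))$kappa
        }
      }
      history[[ep]] <- tibble(epoch = ep, train_loss = ep_loss / nb,
                              val_kappa = val_kappa)
    }
  })
  structure(
    list(params = params, layer_sizes = layer_sizes,
         input_size = dim(X)[3], n_classes = n_classes,
         dropout_p = dropout_p, lr = lr, batch_size = batch_size,
         epochs = epochs, seed = seed,
         class_weights = class_weights,
         history = dplyr::bind_rows(history)),
    class = "lstm_net"
  )
}

lstm_predict_params <- function(params, X, chunk = 8192L) {
  n <- dim(X)[1]
  out <- matrix(0, n, ncol(params$out_W))
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    out[idx, ] <- lstm_forward(params, X[idx, , , drop = FALSE])$posterior
  }
  out
}

#' Posterior class probabilities from a trained LSTM
#' @param net an `lstm_net` from [train_lstm()].
#' @param X array `[n, time, features]`.
#' @param chunk prediction chunk size.
#' @return matrix `[n, n_classes]` of posteriors.
#' @export
predict_lstm <- function(net, X, chunk = 8192L) {
  lstm_predict_params(net$params, X, chunk)
}

#' @export
print.lstm_net <- function(x, ...) {
  cat(sprintf("<lstm_net> input %d -> LSTM(%s) -> %d classes, %d epochs, seed %d\n",
              x$input_size, paste(x$layer_sizes, collapse = ", "),
              x$n_classes, x$epochs, x$seed))
  if (nrow(x$history)) {
    cat(sprintf("final train loss %.4f, val kappa %s\n",
                tail(x$history$train_loss, 1),
                format(tail(x$history$val_kappa, 1), digits = 3)))
  }
  invisible(x)
}

#' Serialize / restore an LSTM model as JSON
#'
#' Weights, architecture, seed and training configuration are embedded so a
#' model file fully identifies the network that produced a report.
#'
#' @param net an `lstm_net`.
#' @param path output file.
#' @return `path` (write) or an `lstm_net` (read).
#' @export
write_lstm <- function(net, path) {
  pack <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else if (is.numeric(x)) list(dim = integer(0), data = x)
    else lapply(x, pack)
  }
  obj <- unclass(net)
  obj$params <- pack(obj$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lstm
#' @export
read_lstm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      if (!is.null(x$dim) && length(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    } else if (is.list(x)) lapply(x, rebuild) else x
  }
  obj$params <- rebuild(obj$params)
  obj$history <- dplyr::bind_rows(lapply(obj$history, function(r) {
    tibble(epoch = r$epoch, train_loss = r$train_loss,
           val_kappa = r$val_kappa %||% NA_real_)
  }))
  class(obj) <- "lstm_net"
  obj
}
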