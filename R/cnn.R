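# A small 1D convolutional network for multi-class sequence classification,
# implemented directly on BLAS matrix products (im2col): two valid Conv1D
# layers, dropout, and three dense layers ending in 7 class scores. Trained
# with Adam on softmax cross-entropy, optionally class-weighted.

#' Convolutional classifier specification
#'
#' Defaults mirror the engagement network: Conv1D(64, kernel 3) ->
#' Conv1D(128, kernel 3) -> dropout 20% -> flatten -> dense 256 -> dense 256
#' -> dense 7 (one score per engagement class), on input sequences of 5 time
#' steps x 71 feature channels. Epochs and batch size are training-budget
#' knobs (defaults 100 and 64, with early stopping on validation loss,
#' patience 10); class imbalance is countered by inverse-frequency class
#' weights in the loss.
#'
#' @param conv_filters integer vector of filters per Conv1D layer.
#' @param kernel_size convolution kernel length.
#' @param dropout dropout rate after the last convolution, in [0, 1).
#' @param dense_sizes dense layer widths; the last must equal 7, the number
#'   of engagement classes.
#' @param seq_len,n_features input shape (time steps, channels).
#' @param lr Adam learning rate.
#' @param epochs,batch_size,patience training budget; `patience` is the
#'   early-stopping patience on validation loss (`Inf` disables it).
#' @param class_weights `"inverse"` for inverse-frequency weights,
#'   `"none"` for unweighted loss.
#' @param standardize standardize each feature channel inside the network
#'   using training-set statistics (stored with the fit and applied at
#'   prediction time). Raw keypoint features span several orders of
#'   magnitude, which conditions gradient descent poorly without this.
#' @return object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_filters = c(64L, 128L), kernel_size = 3L,
                     dropout = 0.2, dense_sizes = c(256L, 256L, 7L),
                     seq_len = 5L, n_features = 71L,
                     lr = 1e-3, epochs = 100L, batch_size = 64L,
                     patience = 10L, class_weights = c("inverse", "none"),
                     standardize = TRUE) {
  class_weights <- match.arg(class_weights)
  if (utils::tail(dense_sizes, 1) != N_CLASSES) {
    stop("validation error: final dense size must be ", N_CLASSES,
         " (number of engagement classes)")
  }
  out_len <- seq_len
  for (f in conv_filters) out_len <- out_len - kernel_size + 1L
  if (out_len < 1) {
    stop("validation error: seq_len ", seq_len, " too short for ",
         length(conv_filters), " convolutions of kernel ", kernel_size)
  }
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 dropout = dropout, dense_sizes = as.integer(dense_sizes),
                 seq_len = as.integer(seq_len), n_features = as.integer(n_features),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 class_weights = class_weights, standardize = standardize),
            class = "cnn_spec")
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / nrow)), nrow, ncol)
}

#' Build an untrained convolutional classifier
#'
#' Initializes all layer parameters (He-scaled Gaussians, zero biases)
#' reproducibly from `seed`.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for the initialization.
#' @return object of class `cnn_net` with a `n_params` field.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  in_ch <- spec$n_features
  len <- spec$seq_len
  for (i in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[i]
    params[[paste0("Wc", i)]] <- he_init(spec$kernel_size * in_ch, f)
    params[[paste0("bc", i)]] <- numeric(f)
    in_ch <- f
    len <- len - spec$kernel_size + 1L
  }
  in_dim <- len * in_ch
  for (i in seq_along(spec$dense_sizes)) {
    d <- spec$dense_sizes[i]
    params[[paste0("Wd", i)]] <- he_init(in_dim, d)
    params[[paste0("bd", i)]] <- numeric(d)
    in_dim <- d
  }
  n_params <- sum(vapply(params, length, numeric(1)))
  structure(list(spec = spec, params = params, n_params = n_params,
                 seed = seed, history = NULL),
            class = "cnn_net")
}

#' @export
print.cnn_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<cnn_net> input %d x %d | conv %s (k=%d) | dropout %.2f | dense %s | %s parameters%s\n",
              s$seq_len, s$n_features,
              paste(s$conv_filters, collapse = "-"), s$kernel_size, s$dropout,
              paste(s$dense_sizes, collapse = "-"),
              format(x$n_params, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# im2col gather index for array x of dim (N, L, C): rows are t-major blocks
# (row (t-1)*N + n is the patch of sample n at output position t), columns
# (k-1)*C + c.
im2col_index <- function(n, L, C, k) {
  out_len <- L - k + 1L
  idx <- matrix(0L, n * out_len, k * C)
  for (t in seq_len(out_len)) {
    for (kk in seq_len(k)) {
      idx[(t - 1L) * n + seq_len(n), (kk - 1L) * C + seq_len(C)] <-
        outer(seq_len(n), (seq_len(C) - 1L), function(nn, cc) {
          nn + (t + kk - 2L) * n + cc * n * L
        })
    }
  }
  idx
}

im2col <- function(x, k, idx = NULL) {
  d <- dim(x)
  if (is.null(idx)) idx <- im2col_index(d[1], d[2], d[3], k)
  matrix(x[idx], nrow = nrow(idx))
}

# Regroup a t-major (N*T) x C activation matrix into N x (T*C) columns.
blocks_to_wide <- function(a, n, out_len) {
  do.call(cbind, lapply(seq_len(out_len), function(t) a[(t - 1L) * n + seq_len(n), , drop = FALSE]))
}

wide_to_blocks <- function(a, n, out_len, C) {
  do.call(rbind, lapply(seq_len(out_len), function(t) a[, (t - 1L) * C + seq_len(C), drop = FALSE]))
}

cnn_forward <- function(net, x, dropout_mask = NULL) {
  s <- net$spec; p <- net$params
  n <- dim(x)[1]
  cache <- list(n = n)
  a <- x  # N x L x C array
  len <- s$seq_len
  for (i in seq_along(s$conv_filters)) {
    col <- im2col(a, s$kernel_size)             # (N*outlen) x (k*C)
    z <- sweep(col %*% p[[paste0("Wc", i)]], 2, p[[paste0("bc", i)]], "+")
    r <- pmax(z, 0)
    out_len <- len - s$kernel_size + 1L
    cache[[paste0("col", i)]] <- col
    cache[[paste0("relu", i)]] <- z > 0
    len <- out_len
    wide <- blocks_to_wide(r, n, out_len)       # N x (outlen*filters)
    cache[[paste0("outlen", i)]] <- out_len
    a <- array(0, c(n, out_len, s$conv_filters[i]))
    for (t in seq_len(out_len)) a[, t, ] <- wide[, (t - 1L) * s$conv_filters[i] + seq_len(s$conv_filters[i])]
    cache[[paste0("wide", i)]] <- wide
  }
  h <- cache[[paste0("wide", length(s$conv_filters))]]  # N x (len*filters)
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  cache$flat <- h
  for (i in seq_along(s$dense_sizes)) {
    z <- sweep(h %*% p[[paste0("Wd", i)]], 2, p[[paste0("bd", i)]], "+")
    cache[[paste0("dz", i)]] <- z
    cache[[paste0("din", i)]] <- h
    h <- if (i < length(s$dense_sizes)) pmax(z, 0) else z
  }
  cache$logits <- h
  cache
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted cross-entropy loss and logit gradient.
ce_loss_grad <- function(logits, y, w) {
  probs <- softmax(logits)
  n <- nrow(probs)
  iy <- cbind(seq_len(n), y + 1L)
  wi <- w[y + 1L]
  loss <- mean(wi * -log(pmax(probs[iy], 1e-12)))
  g <- probs
  g[iy] <- g[iy] - 1
  g <- g * (wi / n)
  list(loss = loss, grad = g, probs = probs)
}

cnn_backward <- function(net, x, cache, dlogits, dropout_mask = NULL) {
  s <- net$spec; p <- net$params
  n <- cache$n
  grads <- list()
  dh <- dlogits
  for (i in rev(seq_along(s$dense_sizes))) {
    if (i < length(s$dense_sizes)) dh <- dh * (cache[[paste0("dz", i)]] > 0)
    grads[[paste0("Wd", i)]] <- crossprod(cache[[paste0("din", i)]], dh)
    grads[[paste0("bd", i)]] <- colSums(dh)
    dh <- dh %*% t(p[[paste0("Wd", i)]])
  }
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  nc <- length(s$conv_filters)
  for (i in rev(seq_len(nc))) {
    C <- s$conv_filters[i]
    out_len <- cache[[paste0("outlen", i)]]
    dr <- wide_to_blocks(dh, n, out_len, C)           # (N*outlen) x filters
    dz <- dr * cache[[paste0("relu", i)]]
    grads[[paste0("Wc", i)]] <- crossprod(cache[[paste0("col", i)]], dz)
    grads[[paste0("bc", i)]] <- colSums(dz)
    if (i > 1) {
      # gradient w.r.t. the previous layer's wide activations via col scatter
      dcol <- dz %*% t(p[[paste0("Wc", i)]])          # (N*outlen) x (k*Cprev)
      prev_len <- cache[[paste0("outlen", i - 1L)]]
      Cp <- s$conv_filters[i - 1L]
      dwide <- matrix(0, n, prev_len * Cp)
      for (t in seq_len(out_len)) {
        rows <- (t - 1L) * n + seq_len(n)
        for (kk in seq_len(s$kernel_size)) {
          pos <- t + kk - 1L
          dwide[, (pos - 1L) * Cp + seq_len(Cp)] <-
            dwide[, (pos - 1L) * Cp + seq_len(Cp)] +
            dcol[rows, (kk - 1L) * Cp + seq_len(Cp), drop = FALSE]
        }
      }
      dh <- dwide
    }
  }
  grads
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

cnn_eval <- function(net, x, y, w) {
  cache <- cnn_forward(net, x)
  lg <- ce_loss_grad(cache$logits, y, w)
  pred <- max.col(lg$probs, ties.method = "first") - 1L
  list(loss = lg$loss, acc = mean(pred == y))
}

#' Train a convolutional classifier
#'
#' Mini-batch Adam on (optionally class-weighted) softmax cross-entropy,
#' with per-epoch train/validation accuracy and loss recorded in the history
#' and early stopping on validation loss. Fully reproducible under `seed`
#' (shuffling, dropout and initialization all derive from R's RNG).
#'
#' @param net an untrained or previously trained `cnn_net`.
#' @param x array `N x L x C` of training sequences (must match the spec's
#'   input shape).
#' @param y integer labels 0-6.
#' @param x_val,y_val optional validation data (required for early stopping).
#' @param epochs,batch_size,lr,patience overrides of the spec's training
#'   budget.
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return the trained `cnn_net` with a `history` data frame.
#' @export
cnn_train <- function(net, x, y, x_val = NULL, y_val = NULL,
                      epochs = NULL, batch_size = NULL, lr = NULL,
                      patience = NULL, seed = 1, verbose = FALSE) {
  s <- net$spec
  if (!identical(dim(x)[2:3], c(s$seq_len, s$n_features)) &&
      !all(dim(x)[2:3] == c(s$seq_len, s$n_features))) {
    stop("shape error: input is ", dim(x)[2], " x ", dim(x)[3],
         ", spec expects ", s$seq_len, " x ", s$n_features)
  }
  epochs <- if (is.null(epochs)) s$epochs else epochs
  batch_size <- if (is.null(batch_size)) s$batch_size else batch_size
  lr <- if (is.null(lr)) s$lr else lr
  patience <- if (is.null(patience)) s$patience else patience
  n <- dim(x)[1]
  stopifnot(n >= 1, length(y) == n)

  if (isTRUE(s$standardize)) {
    flat <- matrix(x, nrow = n * s$seq_len)
    mu <- colMeans(flat)
    sdv <- apply(flat, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    net$norm <- list(mu = mu, sd = sdv)
  }
  x <- cnn_apply_norm(net, x)
  if (!is.null(x_val)) x_val <- cnn_apply_norm(net, x_val)

  w <- rep(1, N_CLASSES)
  if (s$class_weights == "inverse") {
    cnt <- tabulate(y + 1L, N_CLASSES)
    pres <- cnt > 0
    w[pres] <- (n / cnt[pres])
    w[!pres] <- 0
    w <- w / mean(w[pres])  # normalize to mean 1 over observed classes
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  flat_dim <- ncol_flat(s)
  hist <- NULL
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      xb <- x[b, , , drop = FALSE]
      mask <- if (s$dropout > 0) {
        matrix(stats::rbinom(length(b) * flat_dim, 1, 1 - s$dropout),
               length(b), flat_dim) / (1 - s$dropout)
      } else NULL
      cache <- cnn_forward(net, xb, dropout_mask = mask)
      lg <- ce_loss_grad(cache$logits, y[b], w)
      grads <- cnn_backward(net, xb, cache, lg$grad, dropout_mask = mask)
      t_step <- t_step + 1L
      upd <- adam_step(net$params, grads, state, lr, t_step)
      net$params <- upd$params; state <- upd$state
    }
    tr <- cnn_eval(net, x, y, w)
    va <- if (!is.null(x_val) && length(y_val) > 0) {
      cnn_eval(net, x_val, y_val, w)
    } else list(loss = NA_real_, acc = NA_real_)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr$loss,
                                   train_acc = tr$acc, val_loss = va$loss,
                                   val_acc = va$acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f/%.4f  val %.4f/%.4f",
                      ep, tr$loss, tr$acc, va$loss, va$acc))
    }
    monitor <- if (is.na(va$loss)) tr$loss else va$loss
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, params = net$params, epoch = ep)
    } else if (is.finite(patience) && ep - best$epoch >= patience) {
      break
    }
  }
  if (best$epoch > 0) net$params <- best$params
  net$history <- hist
  net
}

ncol_flat <- function(s) {
  len <- s$seq_len
  for (f in s$conv_filters) len <- len - s$kernel_size + 1L
  len * utils::tail(s$conv_filters, 1)
}

#' Class scores or labels from a convolutional classifier
#'
#' Deterministic (dropout disabled). Scores are softmax-normalized, finite
#' and sum to 1 per window.
#'
#' @param net a `cnn_net`.
#' @param x array `N x L x C`.
#' @param type `"class"` for integer labels 0-6, `"prob"` for the `N x 7`
#'   score matrix.
#' @return integer vector or numeric matrix.
#' @export
cnn_predict <- function(net, x, type = c("class", "prob")) {
  type <- match.arg(type)
  if (dim(x)[1] == 0) {
    return(if (type == "class") integer(0) else matrix(0, 0, N_CLASSES))
  }
  s <- net$spec
  if (!all(dim(x)[2:3] == c(s$seq_len, s$n_features))) {
    stop("shape error: input is ", dim(x)[2], " x ", dim(x)[3],
         ", spec expects ", s$seq_len, " x ", s$n_features)
  }
  probs <- softmax(cnn_forward(net, cnn_apply_norm(net, x))$logits)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

cnn_apply_norm <- function(net, x) {
  if (is.null(net$norm)) return(x)
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - net$norm$mu[c]) / net$norm$sd[c]
  }
  x
}
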