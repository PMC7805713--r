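# Interchangeable engagement classifiers behind one S3 fitting interface:
# the convolutional network plus four classical baselines (fitted on
# flattened 5 x 71 = 355-length window vectors).

MODEL_KINDS <- c("cnn", "svc", "rf", "dt", "knn")

flatten_windows <- function(x) matrix(x, nrow = dim(x)[1])

#' Fit an engagement classifier
#'
#' One fitting function for all five classifier kinds: `"cnn"` (the 1D
#' convolutional network, see [cnn_spec()]), `"svc"` (RBF support vector
#' classifier, cost 1), `"rf"` (random forest, 100 trees), `"dt"` (decision
#' tree grown without complexity penalty, effectively unlimited depth) and
#' `"knn"` (k-nearest neighbours, k = 5). Baselines see each window as a
#' flattened `seq_len * 71` vector. A single-class training set raises a
#' degenerate-data warning and yields a constant predictor.
#'
#' @param train a `windowed_dataset` to fit on.
#' @param kind classifier kind, one of `"cnn"`, `"svc"`, `"rf"`, `"dt"`,
#'   `"knn"`.
#' @param validation optional `windowed_dataset` monitored during CNN
#'   training (early stopping).
#' @param spec a [cnn_spec()] for the CNN (training-budget fields apply).
#' @param seed integer seed; given identical data and seed the whole
#'   fit/predict path is reproducible.
#' @param epochs optional override of the CNN epoch budget.
#' @param ... further arguments passed to the underlying fitting routine.
#' @return object of class `engagement_model` with fields `kind`, `fit`,
#'   `history` (CNN only), `seed`, `levels`.
#' @export
fit_engagement_model <- function(train, kind = c("cnn", "svc", "rf", "dt", "knn"),
                                 validation = NULL, spec = NULL, seed = 1,
                                 epochs = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "windowed_dataset"))
  n <- length(train)
  if (n == 0) stop("empty training set")
  # baselines fit on the observed classes only (labels are preserved in the
  # factor levels, so predictions map back to 0-6)
  y <- factor(train$y)
  history <- NULL

  if (length(unique(train$y)) < 2 && kind != "cnn") {
    warning("degenerate-data warning: single-class training set; fitting a constant predictor")
    fit <- list(constant = train$y[1])
    kind_fitted <- "constant"
    return(structure(list(kind = kind, fit = fit, fitted_as = kind_fitted,
                          history = NULL, seed = seed, seq_len = train$seq_len,
                          n_features = dim(train$x)[3]),
                     class = "engagement_model"))
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (kind == "cnn") {
    if (is.null(spec)) {
      spec <- cnn_spec(seq_len = train$seq_len, n_features = dim(train$x)[3])
    }
    if (length(unique(train$y)) < 2) {
      warning("degenerate-data warning: single-class training set")
    }
    net <- build_cnn(spec, seed = seed)
    net <- cnn_train(net, train$x, train$y,
                     x_val = if (!is.null(validation)) validation$x,
                     y_val = if (!is.null(validation)) validation$y,
                     epochs = epochs, seed = seed + 1L, ...)
    fit <- net
    history <- net$history
  } else {
    xm <- flatten_windows(train$x)
    fit <- switch(kind,
      svc = e1071::svm(x = xm, y = y, kernel = "radial", cost = 1,
                       scale = FALSE, ...),
      rf = randomForest::randomForest(x = xm, y = y, ntree = 100, ...),
      dt = {
        df <- data.frame(.y = y, xm)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                    minbucket = 1, xval = 0,
                                                    maxdepth = 30), ...)
      },
      knn = list(x = xm, y = y, k = 5)
    )
  }
  structure(list(kind = kind, fit = fit, fitted_as = kind, history = history,
                 seed = seed, seq_len = train$seq_len,
                 n_features = dim(train$x)[3]),
            class = "engagement_model")
}

#' Predict engagement classes
#'
#' @param object an `engagement_model`.
#' @param newdata a `windowed_dataset` or an `N x L x C` array; an empty
#'   dataset yields an empty prediction.
#' @param type `"class"` (default) for integer labels 0-6 or `"prob"` for
#'   the CNN's normalized score matrix.
#' @param ... unused.
#' @return integer vector of classes, or a numeric matrix for
#'   `type = "prob"`.
#' @export
predict.engagement_model <- function(object, newdata, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  if (dim(x)[1] == 0) {
    return(if (type == "class") integer(0) else matrix(0, 0, N_CLASSES))
  }
  if (!all(dim(x)[2:3] == c(object$seq_len, object$n_features))) {
    stop("shape error: input is ", dim(x)[2], " x ", dim(x)[3],
         ", model expects ", object$seq_len, " x ", object$n_features)
  }
  if (object$fitted_as == "constant") {
    if (type == "prob") {
      p <- matrix(0, dim(x)[1], N_CLASSES)
      p[, object$fit$constant + 1L] <- 1
      return(p)
    }
    return(rep(object$fit$constant, dim(x)[1]))
  }
  if (object$kind == "cnn") return(cnn_predict(object$fit, x, type = type))
  if (type == "prob") stop("class scores are available for the CNN only")
  xm <- flatten_windows(x)
  cls <- switch(object$kind,
    svc = as.integer(as.character(stats::predict(object$fit, xm))),
    rf = as.integer(as.character(stats::predict(object$fit, xm))),
    dt = {
      df <- data.frame(xm)
      names(df) <- paste0("X", seq_len(ncol(xm)))
      as.integer(as.character(stats::predict(object$fit, df, type = "class")))
    },
    knn = as.integer(as.character(
      class::knn(object$fit$x, xm, object$fit$y, k = object$fit$k)
    ))
  )
  cls
}

#' @export
print.engagement_model <- function(x, ...) {
  cat(sprintf("<engagement_model> kind = %s (input %d x %d)\n",
              x$kind, x$seq_len, x$n_features))
  if (x$kind == "cnn" && !is.null(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final train acc %.4f, val acc %s\n",
                nrow(x$history), h$train_acc,
                if (is.na(h$val_acc)) "-" else sprintf("%.4f", h$val_acc)))
  }
  invisible(x)
}

#' @export
summary.engagement_model <- function(object, ...) {
  print(object)
  if (object$kind == "cnn") print(object$fit)
  invisible(object)
}

#' Training curves of a fitted CNN
#'
#' Plots per-epoch accuracy and loss for training and validation data.
#'
#' @param x an `engagement_model` of kind `"cnn"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.engagement_model <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot (CNN models only)")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1, col = 1:2)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1, col = 1:2)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Plain `saveRDS`/`readRDS` wrappers kept as named entry points so runs can
#' checkpoint models alongside their reports.
#'
#' @param model an `engagement_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_engagement_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_engagement_model
#' @export
load_engagement_model <- function(path) readRDS(path)
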