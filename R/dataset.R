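# Assembly of the 71-dimensional feature matrix and its windowed,
# labelled form consumed by the classifiers.

N_FEATURES <- 71L   # 34 facial points x 2 coordinates + 3 Laban features
N_CLASSES <- 7L

#' Facial coordinate features
#'
#' Extracts the x and y coordinates of the 34 facial keypoints used by the
#' engagement models: the 12 eye-contour points, the 20 outer/inner lip
#' points and the 2 pupils of the 70-point face model (the unique
#' lips+eyes+pupils subset of size 34). Coordinates are raw pixels.
#'
#' @param track a `keypoint_track`.
#' @return numeric matrix `T x 68` with columns `face<id>_x`, `face<id>_y`
#'   per point, and a `frame_index` attribute.
#' @export
facial_features <- function(track) {
  sel <- FACIAL_POINT_IDS + 1L
  conf <- track$face[, sel, 3, drop = FALSE]
  xy <- track$face[, sel, 1:2, drop = FALSE]
  if (all(conf <= 0) && all(xy == 0)) {
    stop("missing-face error: no facial keypoints detected in any frame")
  }
  n <- dim(track$face)[1]
  out <- matrix(NA_real_, n, 2L * length(sel))
  out[, seq(1, 68, by = 2)] <- track$face[, sel, 1]
  out[, seq(2, 68, by = 2)] <- track$face[, sel, 2]
  colnames(out) <- as.vector(rbind(paste0("face", FACIAL_POINT_IDS, "_x"),
                                   paste0("face", FACIAL_POINT_IDS, "_y")))
  attr(out, "frame_index") <- track$frame_index
  out
}

#' Assemble the 71-column feature matrix
#'
#' Concatenates facial coordinates (68 columns) with the three Laban effort
#' series, aligned by original frame index. Frames present on only one side,
#' or with missing (NA) values on either side, are dropped and counted.
#'
#' @param facial output of [facial_features()].
#' @param laban a `laban_series` over the same track.
#' @return object of class `feature_matrix`: list with `values` (`T x 71`
#'   matrix), `frame_index`, `dropped` (count of discarded frames).
#' @export
assemble_features <- function(facial, laban) {
  fi_f <- attr(facial, "frame_index")
  fi_l <- laban$frame_index
  common <- intersect(fi_f, fi_l)
  if (length(common) == 0) stop("alignment error: no overlapping frames")
  rf <- match(common, fi_f)
  rl <- match(common, fi_l)
  values <- cbind(facial[rf, , drop = FALSE],
                  space = laban$space[rl],
                  weight = laban$weight[rl],
                  time = laban$time[rl])
  if (ncol(values) != N_FEATURES) {
    stop("assembly error: expected ", N_FEATURES, " columns, got ", ncol(values))
  }
  ok <- stats::complete.cases(values)
  dropped <- (length(fi_f) - length(common)) + (length(fi_l) - length(common)) +
    sum(!ok)
  structure(list(values = values[ok, , drop = FALSE],
                 frame_index = common[ok],
                 dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d features (%d dropped in assembly)\n",
              nrow(x$values), ncol(x$values), x$dropped))
  invisible(x)
}

#' Construct a windowed dataset
#'
#' Low-level constructor; most code should use [make_windows()].
#'
#' @param x numeric array `N x L x 71` of feature sequences.
#' @param y integer class labels 0-6, length `N`.
#' @param subject_id,group provenance tags (`group` is `"TD"`, `"ASD"` or
#'   `NA`).
#' @param final_frame original frame index of each window's last frame.
#' @return object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(x, y, subject_id = "subject", group = NA_character_,
                             final_frame = NULL) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(y))
  stopifnot(all(y >= 0 & y <= 6))
  structure(list(x = x, y = as.integer(y), subject_id = subject_id,
                 group = group, seq_len = dim(x)[2],
                 final_frame = final_frame),
            class = "windowed_dataset")
}

#' @export
length.windowed_dataset <- function(x) dim(x$x)[1]

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %s%s: %d windows of %d x %d; class counts: %s\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              paste(tabulate(x$y + 1L, 7L), collapse = " ")))
  invisible(x)
}

#' Subset a windowed dataset by window index
#' @param ds a `windowed_dataset`.
#' @param idx integer indices.
#' @return a `windowed_dataset`.
#' @export
subset_windows <- function(ds, idx) {
  windowed_dataset(ds$x[idx, , , drop = FALSE], ds$y[idx],
                   subject_id = ds$subject_id, group = ds$group,
                   final_frame = ds$final_frame[idx])
}

#' Pool several windowed datasets
#' @param datasets list of `windowed_dataset`s with equal window shape.
#' @param subject_id,group tags for the pooled set.
#' @return a `windowed_dataset`.
#' @export
pool_windows <- function(datasets, subject_id = "pooled", group = NA_character_) {
  stopifnot(length(datasets) >= 1)
  L <- dim(datasets[[1]]$x)[2]; C <- dim(datasets[[1]]$x)[3]
  ns <- vapply(datasets, function(d) dim(d$x)[1], integer(1))
  x <- array(0, c(sum(ns), L, C))
  at <- 0L
  for (d in datasets) {
    stopifnot(dim(d$x)[2] == L, dim(d$x)[3] == C)
    x[at + seq_len(dim(d$x)[1]), , ] <- d$x
    at <- at + dim(d$x)[1]
  }
  windowed_dataset(x, unlist(lapply(datasets, `[[`, "y")),
                   subject_id = subject_id, group = group,
                   final_frame = unlist(lapply(datasets, `[[`, "final_frame")))
}

#' Slice a feature matrix into labelled windows
#'
#' Stride-1 sliding windows of `seq_len` consecutive frames within each
#' contiguous segment (windows never span a gap-split boundary). Each
#' window's label is the engagement class of its final frame (a causal
#' convention that supports streaming prediction). The default length of 5
#' gives the classifier 5 time steps x 71 feature channels.
#'
#' @param features a `feature_matrix`.
#' @param labels an `engagement_series` covering the original frame range, or
#'   an integer vector indexed by 0-based frame.
#' @param seq_len window length in frames, at least 1.
#' @param subject_id,group provenance tags.
#' @return a `windowed_dataset` with `N = T - seq_len + 1` windows per
#'   contiguous segment of length `T`.
#' @export
make_windows <- function(features, labels, seq_len = 5, subject_id = "subject",
                         group = NA_character_) {
  stopifnot(seq_len >= 1)
  klass <- if (inherits(labels, "engagement_series")) labels$klass else as.integer(labels)
  fi <- features$frame_index
  if (max(fi) + 1L > length(klass)) {
    stop("labels cover ", length(klass), " frames but features reach frame ", max(fi))
  }
  seg <- cumsum(c(1L, diff(fi) != 1L))
  starts <- integer(0)
  for (s in unique(seg)) {
    rows <- which(seg == s)
    if (length(rows) < seq_len) next
    starts <- c(starts, rows[seq_len(length(rows) - seq_len + 1L)])
  }
  if (length(starts) == 0) stop("empty-dataset error: no segment of length >= ", seq_len)
  n <- length(starts)
  x <- array(0, c(n, seq_len, ncol(features$values)))
  for (l in seq_len(seq_len)) {
    x[, l, ] <- features$values[starts + l - 1L, , drop = FALSE]
  }
  fin <- fi[starts + seq_len - 1L]
  windowed_dataset(x, klass[fin + 1L], subject_id = subject_id, group = group,
                   final_frame = fin)
}

#' Random train/validation/test split
#'
#' Random partition by window, reproducible under `seed`: `floor(N *
#' test_fraction)` windows go to test, then `floor(val_fraction)` of the
#' remainder to validation, the rest to train. Partitions are disjoint and
#' exhaustive. Adjacent stride-1 windows are nearly identical, so random
#' splitting leaks temporal context between partitions; `blocked = TRUE`
#' instead takes contiguous blocks (test from the end, validation before it),
#' which is the leakage-free alternative. Random is the default, matching the
#' per-subject evaluation protocol the reference tables were produced with.
#'
#' @param ds a `windowed_dataset` with at least 10 windows.
#' @param test_fraction fraction held out for test, in (0, 1).
#' @param val_fraction fraction of the remaining train windows held out for
#'   validation, in [0, 1).
#' @param seed integer seed.
#' @param blocked use contiguous blocks instead of random assignment.
#' @return list with elements `train`, `validation`, `test` (each a
#'   `windowed_dataset`) and `indices` (the three index vectors, for audits).
#' @export
split_windows <- function(ds, test_fraction = 0.2, val_fraction = 0.1,
                          seed = 1, blocked = FALSE) {
  n <- length(ds)
  if (n < 10) stop("need at least 10 windows to split, got ", n)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("parameter error: test_fraction must be in (0, 1)")
  }
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("parameter error: val_fraction must be in [0, 1)")
  }
  n_test <- floor(n * test_fraction)
  if (blocked) {
    test_idx <- seq(n - n_test + 1L, n)
    rest <- seq_len(n - n_test)
    n_val <- floor(length(rest) * val_fraction)
    val_idx <- if (n_val > 0) rest[seq(length(rest) - n_val + 1L, length(rest))] else integer(0)
    train_idx <- setdiff(rest, val_idx)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perm <- sample.int(n)
    test_idx <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    n_val <- floor(length(rest) * val_fraction)
    val_idx <- if (n_val > 0) rest[seq_len(n_val)] else integer(0)
    train_idx <- if (n_val > 0) rest[-seq_len(n_val)] else rest
  }
  list(train = subset_windows(ds, train_idx),
       validation = subset_windows(ds, val_idx),
       test = subset_windows(ds, test_idx),
       indices = list(train = train_idx, validation = val_idx, test = test_idx))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Optional feature standardization
#'
#' Z-scores every feature column using statistics estimated on `ref`
#' (typically the training split) and applies them to each dataset in `...`.
#' No scaling is applied anywhere by default in the pipeline; this helper is
#' provided for experiments that need it.
#'
#' @param ref reference `windowed_dataset` supplying means and sds.
#' @param ... further `windowed_dataset`s to transform with the same
#'   statistics.
#' @return a list of transformed datasets (`ref` first).
#' @export
standardize_windows <- function(ref, ...) {
  flat <- matrix(ref$x, nrow = dim(ref$x)[1] * dim(ref$x)[2])
  mu <- colMeans(flat)
  sd <- apply(flat, 2, stats::sd)
  sd[sd == 0] <- 1
  tr <- function(ds) {
    for (c in seq_len(dim(ds$x)[3])) {
      ds$x[, , c] <- (ds$x[, , c] - mu[c]) / sd[c]
    }
    ds
  }
  lapply(c(list(ref), list(...)), tr)
}
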