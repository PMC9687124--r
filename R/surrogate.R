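# Multilayer-perceptron surrogate: palpation position (x, y) and contact
# force -> maximum-principal-stress vector over the liver-edge ROI.
# Full-batch gradient descent with momentum and an adaptive learning rate
# (raise on improvement, cut and reject on a large worsening), the classical
# variable-learning-rate backpropagation recipe.

relu <- function(x) (x > 0) * x

#' Build the stress-surrogate network
#'
#' Architecture: 3 inputs (x, y, force) -> hidden layers with
#' positive-linear (poslin, i.e. max(0, x)) activations -> linear output
#' layer with one node per ROI element.  Weights are initialized with a
#' seeded scaled-uniform draw (bounds \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}});
#' biases start at zero.
#'
#' @param roi_size number of output nodes (>= 1).
#' @param seed RNG seed for the weight draw.
#' @param hidden hidden layer widths.
#' @return An object of class `palp_surrogate` (untrained: no input/output
#'   normalization yet).
#' @export
build_network <- function(roi_size, seed = 1,
                          hidden = c(64, 128, 256, 512)) {
  if (roi_size < 1) stop("roi_size must be >= 1")
  sizes <- c(3, hidden, roi_size)
  set.seed(seed)
  W <- b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    fi <- sizes[l]; fo <- sizes[l + 1]
    r <- sqrt(6 / (fi + fo))
    W[[l]] <- matrix(runif(fi * fo, -r, r), fi, fo)
    b[[l]] <- numeric(fo)
  }
  structure(list(sizes = sizes, W = W, b = b, norm = NULL,
                 seed = seed, version = 1L),
            class = "palp_surrogate")
}

#' @export
print.palp_surrogate <- function(x, ...) {
  cat("MLP stress surrogate:", paste(x$sizes, collapse = "-"),
      if (is.null(x$norm)) "(untrained)" else "(trained)", "\n")
  invisible(x)
}

#' Training configuration
#'
#' @param lr initial learning rate.
#' @param momentum momentum coefficient in [0, 1).
#' @param lr_inc learning-rate increase factor on improvement (> 1).
#' @param lr_dec learning-rate decrease factor on rejection (< 1).
#' @param max_perf_inc largest tolerated relative MSE worsening before a
#'   step is rejected (e.g. 1.04 = 4 percent).
#' @param epochs maximum number of epochs.
#' @param mse_goal early-stop threshold on the normalized training MSE.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, lr_inc = 1.05,
                         lr_dec = 0.7, max_perf_inc = 1.04,
                         epochs = 20000, mse_goal = 1e-6) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1, lr_inc > 1, lr_dec < 1,
            lr_dec > 0, max_perf_inc > 1, epochs >= 1, mse_goal >= 0)
  structure(list(lr = lr, momentum = momentum, lr_inc = lr_inc,
                 lr_dec = lr_dec, max_perf_inc = max_perf_inc,
                 epochs = epochs, mse_goal = mse_goal),
            class = "train_config")
}

dataset_xy <- function(ds, partition) {
  d <- ds$data[ds$data$partition == partition, , drop = FALSE]
  list(X = as.matrix(d[, c("x_mm", "y_mm", "force_N")]),
       Y = as.matrix(d[, paste0("sigma3_", ds$roi), drop = FALSE]))
}

forward_pass <- function(model, Xn) {
  L <- length(model$W)
  A <- vector("list", L + 1)
  A[[1]] <- Xn
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% model$W[[l]] + rep(model$b[[l]], each = nrow(A[[l]]))
    A[[l + 1]] <- if (l < L) relu(Z) else Z
  }
  A
}

#' Train the surrogate on a palpation dataset
#'
#' Full-batch backpropagation with momentum and adaptive learning rate:
#' after each epoch the learning rate is multiplied by `lr_inc` if the MSE
#' decreased; if the MSE worsened by more than `max_perf_inc` the step is
#' rejected (weights restored, momentum reset) and the rate is multiplied by
#' `lr_dec`.  Inputs are min-max normalized to [0, 1] and outputs
#' standardized (pooled mean/sd), both fitted on the training partition
#' only.  Training is deterministic given the dataset and the seed used in
#' [build_network()].
#'
#' @param model a `palp_surrogate` from [build_network()].
#' @param ds a `palp_dataset`; the `train` partition is used.
#' @param config a [train_config()].
#' @param verbose print progress every 1000 epochs.
#' @return list with `model` (trained) and `history` (data.frame: `epoch`,
#'   `mse`, `lr`).
#' @export
train_surrogate <- function(model, ds, config = train_config(),
                            verbose = FALSE) {
  stopifnot(inherits(model, "palp_surrogate"), inherits(ds, "palp_dataset"))
  xy <- dataset_xy(ds, "train")
  if (nrow(xy$X) < 1) stop("no training records")
  if (ncol(xy$Y) != model$sizes[length(model$sizes)])
    stop("ROI size does not match the network output layer")
  x_min <- apply(xy$X, 2, min)
  x_rng <- apply(xy$X, 2, max) - x_min
  x_rng[x_rng == 0] <- 1
  y_mu <- mean(xy$Y)
  y_sd <- stats::sd(as.vector(xy$Y))
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  model$norm <- list(x_min = x_min, x_rng = x_rng, y_mu = y_mu, y_sd = y_sd)

  Xn <- sweep(sweep(xy$X, 2, x_min), 2, x_rng, "/")
  Yn <- (xy$Y - y_mu) / y_sd
  nrec <- nrow(Xn)
  L <- length(model$W)
  V_W <- lapply(model$W, function(w) w * 0)
  V_b <- lapply(model$b, function(bb) bb * 0)

  mse_of <- function(m) {
    P <- forward_pass(m, Xn)[[L + 1]]
    mean((P - Yn)^2)
  }
  mse <- mse_of(model)
  lr <- config$lr
  hist_e <- hist_m <- hist_l <- numeric(config$epochs)
  nh <- 0
  for (ep in seq_len(config$epochs)) {
    if (mse <= config$mse_goal) break
    A <- forward_pass(model, Xn)
    delta <- 2 * (A[[L + 1]] - Yn) / (nrec * ncol(Yn))   # dMSE/dZ_out
    prev_W <- model$W; prev_b <- model$b
    for (l in L:1) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(model$W[[l]])) * (A[[l]] > 0)
      V_W[[l]] <- config$momentum * V_W[[l]] + lr * gW
      V_b[[l]] <- config$momentum * V_b[[l]] + lr * gb
      model$W[[l]] <- model$W[[l]] - V_W[[l]]
      model$b[[l]] <- model$b[[l]] - V_b[[l]]
    }
    new_mse <- mse_of(model)
    if (!is.finite(new_mse)) {
      warning("training diverged at epoch ", ep,
              "; returning last good model")
      model$W <- prev_W; model$b <- prev_b
      break
    }
    if (new_mse > mse * config$max_perf_inc) {
      model$W <- prev_W; model$b <- prev_b        # reject step
      V_W <- lapply(V_W, function(w) w * 0)
      V_b <- lapply(V_b, function(bb) bb * 0)
      lr <- lr * config$lr_dec
    } else {
      if (new_mse < mse) lr <- lr * config$lr_inc
      mse <- new_mse
    }
    nh <- nh + 1
    hist_e[nh] <- ep; hist_m[nh] <- mse; hist_l[nh] <- lr
    if (verbose && ep %% 1000 == 0)
      message(sprintf("epoch %d: mse %.3e lr %.3e", ep, mse, lr))
  }
  list(model = model,
       history = data.frame(epoch = hist_e[seq_len(nh)],
                            mse = hist_m[seq_len(nh)],
                            lr = hist_l[seq_len(nh)]))
}

#' Goodness-of-fit of predicted stress fields
#'
#' Pooled coefficient-of-determination expressed as a percentage,
#' \deqn{Fit = 100 (1 - \sum_k (y_k - \hat y_k)^2 / \sum_k (y_k - \bar y)^2)}
#' with the sums pooled over all elements and records.  A per-element
#' breakdown is attached as the `per_element` attribute.
#'
#' @param y actual values (vector or records x elements matrix).
#' @param yhat predicted values, same shape.
#' @return fit in percent (<= 100), with attribute `per_element`.
#' @export
fit_metric <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch between y and yhat")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero variance in y: fit metric undefined")
  fit <- 100 * (1 - sum((y - yhat)^2) / sst)
  per <- if (ncol(y) > 1) {
    vapply(seq_len(ncol(y)), function(k) {
      s <- sum((y[, k] - mean(y))^2)
      if (s == 0) NA_real_ else 100 * (1 - sum((y[, k] - yhat[, k])^2) / s)
    }, numeric(1))
  } else fit
  attr(fit, "per_element") <- per
  fit
}

#' Predict the liver-edge stress field
#'
#' @param object a trained `palp_surrogate`.
#' @param x,y palpation position (mm).
#' @param force contact force (N).
#' @param ... unused.
#' @return numeric vector of \eqn{\sigma_3} (GPa), one entry per ROI
#'   element.  Inputs outside the training bounding box are clamped to it
#'   with a warning.
#' @export
predict.palp_surrogate <- function(object, x, y, force, ...) {
  if (is.null(object$norm)) stop("untrained model: call train_surrogate() first")
  nm <- object$norm
  v <- c(x, y, force)
  lo <- nm$x_min; hi <- nm$x_min + nm$x_rng
  if (any(v < lo - 1e-9) || any(v > hi + 1e-9)) {
    warning("input outside the training bounding box; clamped")
    v <- pmin(pmax(v, lo), hi)
  }
  Xn <- matrix((v - nm$x_min) / nm$x_rng, 1)
  out <- forward_pass(object, Xn)[[length(object$W) + 1]]
  as.vector(out) * nm$y_sd + nm$y_mu
}

#' Save / load a surrogate checkpoint (JSON)
#'
#' Lossless round-trip of architecture, weights and normalization, with a
#' format version field.
#'
#' @param model a `palp_surrogate`.
#' @param path file path.
#' @return `load_surrogate` returns the model.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "palp_surrogate"))
  x <- list(format = "palpsim_surrogate", version = model$version,
            sizes = model$sizes, seed = model$seed,
            W = lapply(model$W, function(w) as.vector(w)),
            b = model$b, norm = model$norm)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("unreadable surrogate checkpoint: ",
                                         conditionMessage(e)))
  if (!identical(x$format, "palpsim_surrogate"))
    stop("not a palpsim surrogate checkpoint: ", path)
  sizes <- as.integer(x$sizes)
  W <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(x$W[[l]], sizes[l], sizes[l + 1])
  }
  norm <- x$norm
  if (!is.null(norm)) {
    norm$x_min <- as.numeric(norm$x_min)
    norm$x_rng <- as.numeric(norm$x_rng)
  }
  structure(list(sizes = sizes, W = W,
                 b = lapply(x$b, as.numeric), norm = norm,
                 seed = x$seed, version = as.integer(x$version)),
            class = "palp_surrogate")
}

#' Evaluate a trained surrogate on the held-out partition
#'
#' @param model trained `palp_surrogate`.
#' @param ds a `palp_dataset` containing a `test` partition.
#' @param partition which partition to score.
#' @return list with `fit` (percent), `per_element`, `n_records`.
#' @export
surrogate_fit_report <- function(model, ds, partition = "test") {
  xy <- dataset_xy(ds, partition)
  if (nrow(xy$X) == 0) stop("no records in partition '", partition, "'")
  P <- t(apply(xy$X, 1, function(r)
    suppressWarnings(predict(model, r[1], r[2], r[3]))))
  f <- fit_metric(xy$Y, P)
  list(fit = as.numeric(f), per_element = attr(f, "per_element"),
       n_records = nrow(xy$X))
}
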