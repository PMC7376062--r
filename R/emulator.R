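#' Latin hypercube experiment design
#'
#' Stratified one-sample-per-bin design per dimension with random pairing
#' across dimensions (via [lhs::randomLHS()]), scaled to the supplied ranges.
#'
#' @param n number of parameter sets (>= 1).
#' @param ranges 2 x d matrix (row 1 = lower, row 2 = upper bounds) with
#'   optional column names, or a named list of `c(lo, hi)` pairs.
#' @param seed integer seed; the design is reproducible given the seed.
#' @return list of class `lhc_design` with `matrix` (n x d), `ranges`, `seed`.
#' @export
latin_hypercube <- function(n, ranges, seed = NULL) {
  if (is.list(ranges)) ranges <- sapply(ranges, identity)
  ranges <- as.matrix(ranges)
  if (n < 1 || nrow(ranges) != 2L || any(ranges[1, ] >= ranges[2, ]))
    fs_stop("need n >= 1 and lo < hi in every dimension",
            "follisim_invalid_input")
  d <- ncol(ranges)
  u <- with_seed(seed, lhs::randomLHS(n, d))
  m <- sweep(sweep(u, 2, ranges[2, ] - ranges[1, ], "*"), 2, ranges[1, ], "+")
  colnames(m) <- colnames(ranges)
  structure(list(matrix = m, ranges = ranges, seed = seed),
            class = "lhc_design")
}

#' Default ranges for the 13 emulated simulation parameters
#' @return 2 x 13 matrix with columns [simulation_param_names()].
#' @export
default_param_ranges <- function() {
  # D brackets the measured soluble/immobilized medians (0.19 and 1.6
  # um^2/s); lam spans extracellular half-lives from ~19 h down to ~12 min,
  # bracketing both competing gradient-model parameterizations.
  r <- rbind(
    lo = c(D = 0.05, lam = 1e-5, secretion_fdc = 0.004, secretion_rc = 0.002,
           k_on_ecm = 0.0005, k_on = 20, k_off = 0.01, k_i = 0.002,
           k_re = 0.0005, R_total = 1e3, v_mean = 2, persistence = 0.5,
           chi = 0),
    hi = c(D = 2.0, lam = 1e-3, secretion_fdc = 0.04, secretion_rc = 0.02,
           k_on_ecm = 0.02, k_on = 300, k_off = 0.2, k_i = 0.05,
           k_re = 0.01, R_total = 1e5, v_mean = 15, persistence = 10,
           chi = 16))
  r[, simulation_param_names()]
}

# --- minimal feed-forward network with sigmoid hidden layers -----------------

mlp_init <- function(sizes, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                   sqrt(1 / fan_in)),
                      fan_in, sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

mlp_forward <- function(layers, X, keep = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- X
  a <- X
  for (l in seq_along(layers)) {
    z <- a %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(a))
    a <- if (l < length(layers)) 1 / (1 + exp(-z)) else z  # linear output
    acts[[l + 1L]] <- a
  }
  if (keep) acts else a
}

# Full-batch Adam on squared error; returns trained layers.
mlp_train <- function(X, y, hidden, epochs = 1500, lr = 0.01, seed = NULL) {
  sizes <- c(ncol(X), hidden, 1L)
  layers <- mlp_init(sizes, seed)
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mb <- lapply(layers, function(l) l$b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X); y <- matrix(y, ncol = 1L)
  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(layers, X, keep = TRUE)
    delta <- 2 * (acts[[length(acts)]] - y) / n
    for (l in rev(seq_along(layers))) {
      a_in <- acts[[l]]
      gW <- crossprod(a_in, delta)
      gb <- colSums(delta)
      if (l > 1L) {
        a_out <- acts[[l]]
        delta <- (delta %*% t(layers[[l]]$W)) * a_out * (1 - a_out)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr <- sqrt(1 - b2^ep) / (1 - b1^ep)
      layers[[l]]$W <- layers[[l]]$W -
        lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
    }
    if (!all(is.finite(layers[[1]]$W)))
      fs_stop("non-finite loss during emulator training; reduce lr",
              "follisim_training_failure")
  }
  layers
}

minmax_scale <- function(x, lo, hi) sweep(sweep(x, 2, lo), 2, hi - lo, "/")

#' Train a per-output neural emulator of the simulator
#'
#' Fits a feed-forward network (three sigmoidal hidden layers by default,
#' linear output) mapping min-max-normalized simulation parameters to one
#' median emergent statistic. When `cv_grid` is supplied, hidden-layer sizes
#' are selected by `k`-fold cross-validated RMSE on the training portion;
#' the data are otherwise split 75% / 15% / 10% into train / test /
#' validation sets and the error report carries the RMSE of each.
#'
#' @param design an [latin_hypercube()] design (or plain matrix plus `ranges`
#'   attribute).
#' @param responses numeric vector of per-parameter-set median responses.
#' @param hidden_sizes hidden layer widths (default `c(24, 16, 8)`).
#' @param k folds for cross-validation (>= 2; used with `cv_grid`).
#' @param cv_grid optional list of candidate `hidden_sizes` vectors.
#' @param epochs,lr optimizer settings (full-batch Adam).
#' @param split train/test/validation fractions.
#' @param seed integer seed.
#' @return object of class `emulator_net` with the weights, normalization
#'   bounds and an `error_report`.
#' @export
train_emulator <- function(design, responses, hidden_sizes = c(24, 16, 8),
                           k = 5, cv_grid = NULL, epochs = 1500, lr = 0.01,
                           split = c(0.75, 0.15, 0.10), seed = NULL) {
  X_raw <- if (inherits(design, "lhc_design")) design$matrix else as.matrix(design)
  ranges <- if (inherits(design, "lhc_design")) design$ranges else
    rbind(apply(X_raw, 2, min), apply(X_raw, 2, max))
  y_raw <- as.numeric(responses)
  if (!all(is.finite(y_raw)))
    fs_stop("responses must be finite", "follisim_invalid_input")
  if (length(y_raw) != nrow(X_raw))
    fs_stop("responses length must match design rows", "follisim_invalid_input")
  if (k < 2) fs_stop("k must be >= 2", "follisim_invalid_input")

  y_lo <- min(y_raw); y_hi <- max(y_raw)
  y_span <- if (y_hi > y_lo) y_hi - y_lo else 1
  X <- minmax_scale(X_raw, ranges[1, ], ranges[2, ])  # to [0, 1]
  y <- (y_raw - y_lo) / y_span

  seeds <- derive_seeds(seed %||% 1L, 4L)
  n <- nrow(X)
  idx <- with_seed(seeds[1], sample.int(n))
  n_tr <- max(2L, round(split[1] * n))
  n_te <- max(1L, round(split[2] * n))
  tr <- idx[seq_len(n_tr)]
  te <- idx[seq_len(min(n, n_tr + n_te))][-seq_len(n_tr)]
  va <- setdiff(idx, c(tr, te))

  cv_table <- NULL
  if (!is.null(cv_grid)) {
    folds <- with_seed(seeds[2], sample(rep(seq_len(k), length.out = length(tr))))
    cv_rmse <- vapply(cv_grid, function(hs) {
      errs <- vapply(seq_len(k), function(f) {
        hold <- tr[folds == f]; fit <- setdiff(tr, hold)
        lay <- mlp_train(X[fit, , drop = FALSE], y[fit], hs,
                         epochs = epochs, lr = lr, seed = seeds[3])
        pr <- mlp_forward(lay, X[hold, , drop = FALSE])
        sqrt(mean((pr - y[hold])^2))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    cv_table <- data.frame(hidden = vapply(cv_grid, paste, "", collapse = "-"),
                           cv_rmse = cv_rmse * y_span)
    hidden_sizes <- cv_grid[[which.min(cv_rmse)]]
  }

  layers <- mlp_train(X[tr, , drop = FALSE], y[tr], hidden_sizes,
                      epochs = epochs, lr = lr, seed = seeds[4])
  rmse <- function(rows) if (length(rows))
    sqrt(mean((mlp_forward(layers, X[rows, , drop = FALSE]) - y[rows])^2)) *
      y_span else NA_real_
  structure(list(
    layers = layers, hidden_sizes = hidden_sizes,
    x_lo = ranges[1, ], x_hi = ranges[2, ], y_lo = y_lo, y_span = y_span,
    error_report = list(train_rmse = rmse(tr), test_rmse = rmse(te),
                        validation_rmse = rmse(va), cv = cv_table)),
    class = "emulator_net")
}

#' Predict an emergent statistic from an emulator
#'
#' Deterministic forward pass; evaluating thousands of parameter sets per
#' second is the design contract. Inputs outside the trained ranges are
#' evaluated but flagged with a warning and an `extrapolated` attribute.
#'
#' @param object an `emulator_net`.
#' @param newdata 13-vector or n x 13 matrix of parameters (natural units).
#' @param ... unused.
#' @export
predict.emulator_net <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else
    as.matrix(newdata)
  if (ncol(X) != length(object$x_lo))
    fs_stop("parameter dimension mismatch", "follisim_invalid_input")
  out_lo <- sweep(X, 2, object$x_lo, "<")
  out_hi <- sweep(X, 2, object$x_hi, ">")
  extrap <- rowSums(out_lo | out_hi) > 0
  if (any(extrap))
    warning("predicting outside the trained parameter ranges (extrapolation)")
  Xn <- sweep(sweep(X, 2, object$x_lo), 2, object$x_hi - object$x_lo, "/")
  y <- drop(mlp_forward(object$layers, Xn)) * object$y_span + object$y_lo
  attr(y, "extrapolated") <- extrap
  y
}

#' @export
print.emulator_net <- function(x, ...) {
  cat("Feed-forward emulator:", length(x$x_lo), "inputs ->",
      paste(x$hidden_sizes, collapse = "-"), "-> 1 output\n")
  er <- x$error_report
  cat(sprintf("  RMSE  train: %.4g  test: %.4g  validation: %.4g\n",
              er$train_rmse, er$test_rmse, er$validation_rmse))
  invisible(x)
}

#' Serialize an emulator to JSON
#' @param em an `emulator_net`.
#' @param path output path (`read_emulator` reads it back).
#' @export
write_emulator <- function(em, path) {
  obj <- list(hidden_sizes = em$hidden_sizes,
              x_lo = em$x_lo, x_hi = em$x_hi,
              y_lo = em$y_lo, y_span = em$y_span,
              layers = lapply(em$layers, function(l)
                list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emulator
#' @export
read_emulator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(obj$layers, function(l) {
    d <- unlist(l$dim)
    list(W = matrix(unlist(l$W), d[1], d[2]), b = unlist(l$b))
  })
  structure(list(layers = layers, hidden_sizes = unlist(obj$hidden_sizes),
                 x_lo = unlist(obj$x_lo), x_hi = unlist(obj$x_hi),
                 y_lo = obj$y_lo, y_span = obj$y_span,
                 error_report = NULL), class = "emulator_net")
}
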