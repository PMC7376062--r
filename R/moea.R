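# --- NSGA-II machinery -------------------------------------------------------

# Fast nondominated sorting (minimization). Returns integer front index per row.
nondominated_sort <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dominates <- function(i, j)
    all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  S <- vector("list", n)
  ncount <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dominates(j, i)) ncount[i] <- ncount[i] + 1L
    }
  }
  front <- which(ncount == 0L)
  f <- 1L
  while (length(front)) {
    rank[front] <- f
    nxt <- integer(0)
    for (i in front) for (j in S[[i]]) {
      ncount[j] <- ncount[j] - 1L
      if (ncount[j] == 0L) nxt <- c(nxt, j)
    }
    front <- nxt
    f <- f + 1L
  }
  rank
}

crowding_distance <- function(F) {
  n <- nrow(F)
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    span <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && span > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / span
  }
  d
}

# Simulated binary crossover (per-variable, probability 0.9 per pair).
sbx_crossover <- function(p1, p2, lo, hi, eta = 15) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < 0.9) {
    do <- stats::runif(length(p1)) < 0.5
    u <- stats::runif(length(p1))
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    c1[do] <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)[do]
    c2[do] <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)[do]
  }
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

polynomial_mutation <- function(x, lo, hi, eta = 20, rate = NULL) {
  d <- length(x)
  rate <- rate %||% (1 / d)
  do <- stats::runif(d) < rate
  if (any(do)) {
    u <- stats::runif(d)
    span <- hi - lo
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[do] <- x[do] + delta[do] * span[do]
  }
  pmin(pmax(x, lo), hi)
}

#' NSGA-II multiobjective optimization over box bounds
#'
#' Nondominated sorting genetic algorithm II with binary tournament
#' selection, simulated binary crossover (`eta_c = 15`) and polynomial
#' mutation (`eta_m = 20`, rate `1/d`). Maximization objectives are handled
#' by an internal sign flip; reported objective values keep their natural
#' sense.
#'
#' @param objectives function mapping an n x d parameter matrix to an n x k
#'   objective matrix (natural sense).
#' @param bounds 2 x d matrix of box bounds (row 1 lower, row 2 upper).
#' @param sense character vector of `"min"` / `"max"` per objective.
#' @param pop even population size >= 4.
#' @param gens number of generations.
#' @param seed integer seed.
#' @param ref_point reference point for the hypervolume (minimization space);
#'   default = worst front value + 10% of span per objective.
#' @return list of class `pareto_result`: `par` (front parameters),
#'   `objectives` (natural sense), `objectives_min` (minimization form),
#'   `hypervolume`, `ref_point`, `sense`.
#' @export
nsga2 <- function(objectives, bounds, sense = "min", pop = 100, gens = 250,
                  seed = NULL, ref_point = NULL) {
  bounds <- as.matrix(bounds)
  d <- ncol(bounds)
  if (pop < 4 || pop %% 2 != 0)
    fs_stop("pop must be even and >= 4", "follisim_invalid_input")
  if (any(bounds[1, ] >= bounds[2, ]))
    fs_stop("degenerate bounds", "follisim_invalid_input")
  lo <- bounds[1, ]; hi <- bounds[2, ]

  with_seed(seed, {
    X <- sweep(sweep(matrix(stats::runif(pop * d), pop, d), 2,
                     hi - lo, "*"), 2, lo, "+")
    Fnat <- as.matrix(objectives(X))
    k <- ncol(Fnat)
    if (length(sense) == 1L) sense <- rep(sense, k)
    sgn <- ifelse(sense == "max", -1, 1)
    Fm <- sweep(Fnat, 2, sgn, "*")

    for (g in seq_len(gens)) {
      rank <- nondominated_sort(Fm)
      crowd <- numeric(pop)
      for (f in unique(rank)) {
        sel <- rank == f
        crowd[sel] <- crowding_distance(Fm[sel, , drop = FALSE])
      }
      tournament <- function() {
        ij <- sample.int(pop, 2L)
        i <- ij[1]; j <- ij[2]
        if (rank[i] < rank[j] || (rank[i] == rank[j] && crowd[i] > crowd[j]))
          i else j
      }
      kids <- matrix(NA_real_, pop, d)
      for (c2 in seq(1, pop, by = 2)) {
        cs <- sbx_crossover(X[tournament(), ], X[tournament(), ], lo, hi)
        kids[c2, ] <- polynomial_mutation(cs[[1]], lo, hi)
        kids[c2 + 1, ] <- polynomial_mutation(cs[[2]], lo, hi)
      }
      Fk <- sweep(as.matrix(objectives(kids)), 2, sgn, "*")
      Xall <- rbind(X, kids)
      Fall <- rbind(Fm, Fk)
      rank <- nondominated_sort(Fall)
      keep <- integer(0)
      f <- 1L
      while (length(keep) < pop) {
        sel <- which(rank == f)
        if (length(keep) + length(sel) <= pop) {
          keep <- c(keep, sel)
        } else {
          cd <- crowding_distance(Fall[sel, , drop = FALSE])
          keep <- c(keep, sel[order(cd, decreasing = TRUE)][
            seq_len(pop - length(keep))])
        }
        f <- f + 1L
      }
      X <- Xall[keep, , drop = FALSE]
      Fm <- Fall[keep, , drop = FALSE]
    }

    rank <- nondominated_sort(Fm)
    front <- rank == 1L
    Fm_f <- Fm[front, , drop = FALSE]
    ref <- ref_point %||%
      (apply(Fm_f, 2, max) + 0.1 * pmax(apply(Fm_f, 2, max) -
                                          apply(Fm_f, 2, min), 1e-9))
    structure(list(
      par = X[front, , drop = FALSE],
      objectives = sweep(Fm_f, 2, sgn, "*"),
      objectives_min = Fm_f,
      hypervolume = hypervolume(Fm_f, ref),
      ref_point = ref, sense = sense), class = "pareto_result")
  })
}

#' @export
print.pareto_result <- function(x, ...) {
  cat("Pareto front:", nrow(x$par), "nondominated solutions,",
      ncol(x$objectives), "objectives\n")
  cat(sprintf("  hypervolume vs reference point: %.5g\n", x$hypervolume))
  invisible(x)
}

#' Dominated hypervolume of a point set
#'
#' Volume (in minimization space) dominated by `points` and bounded by the
#' reference point: exact sweep in 2D, seeded Monte Carlo (`n_mc` samples)
#' in higher dimensions.
#'
#' @param points n x k matrix of minimization objectives.
#' @param ref reference point (length k), worse than every point.
#' @param n_mc Monte Carlo samples for k > 2.
#' @param seed seed for the Monte Carlo estimate.
#' @export
hypervolume <- function(points, ref, n_mc = 2e5, seed = 1) {
  P <- as.matrix(points)
  keep <- rowSums(sweep(P, 2, ref, ">=")) == 0
  P <- P[keep, , drop = FALSE]
  if (!nrow(P)) return(0)
  if (ncol(P) == 2L) {
    o <- order(P[, 1], P[, 2])
    P <- P[o, , drop = FALSE]
    hv <- 0; y_prev <- ref[2]
    for (i in seq_len(nrow(P))) {
      if (P[i, 2] < y_prev) {
        hv <- hv + (ref[1] - P[i, 1]) * (y_prev - P[i, 2])
        y_prev <- P[i, 2]
      }
    }
    return(hv)
  }
  lo <- apply(P, 2, min)
  box <- prod(ref - lo)
  U <- with_seed(seed, matrix(stats::runif(n_mc * ncol(P)), n_mc))
  U <- sweep(sweep(U, 2, ref - lo, "*"), 2, lo, "+")
  inside <- logical(n_mc)
  for (i in seq_len(nrow(P)))
    inside <- inside | rowSums(sweep(U, 2, P[i, ], "<")) == 0
  box * mean(inside)
}

#' Vargha–Delaney A effect size
#'
#' `A = P(X > Y) + 0.5 P(X = Y)`: the probability that a random draw from
#' `x` exceeds one from `y`. 0.5 = no effect; conventional thresholds 0.56 /
#' 0.64 / 0.71 mark small / medium / large effects (symmetric below 0.5).
#'
#' @param x,y nonempty numeric samples.
#' @return scalar A in `[0, 1]` with a `magnitude` attribute.
#' @export
vargha_delaney_A <- function(x, y) {
  if (!length(x) || !length(y))
    fs_stop("both samples must be nonempty", "follisim_invalid_input")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_along(x)])
  A <- (R1 / length(x) - (length(x) + 1) / 2) / length(y)
  mag <- abs(A - 0.5) + 0.5
  attr(A, "magnitude") <- if (mag >= 0.71) "large" else if (mag >= 0.64)
    "medium" else if (mag >= 0.56) "small" else "negligible"
  A
}

#' Objective trade-off (conflict) analysis of a Pareto front
#'
#' Spearman rank correlations, over front members, between the scanning-rate
#' objective and each fit objective, computed on the minimization-form
#' objective vectors (the scanning objective enters as its negative).
#' Negative correlation means the objectives are conflicting: improving
#' scanning worsens the fit.
#'
#' @param front a `pareto_result`; by convention the maximized scanning
#'   objective is the last column.
#' @param scan_col index of the scanning objective column.
#' @return data.frame of correlations (empty, with a warning, for fronts
#'   with < 3 members).
#' @export
conflict_analysis <- function(front, scan_col = ncol(front$objectives_min)) {
  Fm <- front$objectives_min
  if (nrow(Fm) < 3) {
    warning("front has fewer than 3 members; no trade-off report")
    return(data.frame(objective = character(0), rho = numeric(0)))
  }
  others <- setdiff(seq_len(ncol(Fm)), scan_col)
  rho <- vapply(others, function(j)
    stats::cor(Fm[, scan_col], Fm[, j], method = "spearman"), numeric(1))
  # aggregate fit: mean of rank-scaled fit objectives (overall agreement)
  agg <- rowMeans(apply(Fm[, others, drop = FALSE], 2, rank))
  rho_agg <- stats::cor(Fm[, scan_col], agg, method = "spearman")
  data.frame(objective = c(colnames(Fm)[others] %||% paste0("f", others),
                           "aggregate_fit"),
             rho = c(rho, rho_agg))
}

#' Four-objective setup for gradient optimization
#'
#' Builds the objective function used by [nsga2()] from four trained
#' emulators: squared-error fit to the experimental calibration targets for
#' speed, meandering index and motility coefficient (minimized) and the
#' predicted scanning rate (maximized). Shipped default targets are
#' placeholder two-photon values and should be replaced by study-specific
#' measurements.
#'
#' @param emulators named list with elements `speed`, `meandering_index`,
#'   `motility_coefficient`, `scanning_rate` (each an `emulator_net`).
#' @param targets named numeric calibration targets (positive, finite).
#' @return list with `fn`, `sense`, `targets` ready for [nsga2()].
#' @export
objective_spec <- function(emulators,
                           targets = c(speed = 6, meandering_index = 0.4,
                                       motility_coefficient = 20)) {
  if (any(!is.finite(targets)) || any(targets <= 0))
    fs_stop("targets must be finite and positive", "follisim_invalid_input")
  need <- c("speed", "meandering_index", "motility_coefficient",
            "scanning_rate")
  if (!all(need %in% names(emulators)))
    fs_stop(paste("emulators must be named:", paste(need, collapse = ", ")),
            "follisim_invalid_input")
  fn <- function(X) {
    pr <- suppressWarnings(vapply(need, function(nm)
      as.numeric(predict(emulators[[nm]], X)), numeric(nrow(X))))
    if (nrow(X) == 1L) pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, need))
    out <- cbind(
      fit_speed = sqrt((pr[, "speed"] - targets[["speed"]])^2),
      fit_meandering = sqrt((pr[, "meandering_index"] -
                               targets[["meandering_index"]])^2),
      fit_motility = sqrt((pr[, "motility_coefficient"] -
                             targets[["motility_coefficient"]])^2),
      scanning_rate = pr[, "scanning_rate"])
    out
  }
  list(fn = fn, sense = c("min", "min", "min", "max"), targets = targets)
}
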