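#' Emergent migration statistics of a set of B-cell tracks
#'
#' Per-cell statistics after resampling to `dt_sample`, summarized by the
#' median over cells, matching the four optimization objectives:
#' \describe{
#'   \item{speed}{mean step displacement / `dt_sample`, µm min^-1.}
#'   \item{meandering_index}{net displacement / path length, in `[0, 1]`.}
#'   \item{motility_coefficient}{slope of the time-averaged MSD over the
#'     first quarter of lags (ordinary least squares through the origin)
#'     divided by `2 * dim`, µm^2 min^-1.}
#'   \item{scanning_rate}{unique stromal contacts / (cells x hours).}
#' }
#'
#' @param tracks a `bcell_tracks` object from [run_simulation()], or a plain
#'   list of track objects.
#' @param dt_sample resampling interval, s (default 30, a typical two-photon
#'   acquisition cadence).
#' @param dim spatial dimension used for the MSD normalization (default 3).
#' @return list of class `migration_summary` with the four medians, the
#'   per-cell table, and `n_excluded` (tracks shorter than 2 samples).
#' @export
summarize_tracks <- function(tracks, dt_sample = 30, dim = 3) {
  dt <- attr(tracks, "dt") %||% {
    ts <- tracks[[1]]$t
    if (length(ts) > 1) diff(ts[1:2]) else dt_sample
  }
  stride <- max(1L, round(dt_sample / dt))
  dt_eff <- dt * stride

  per_cell <- lapply(tracks, function(tr) {
    if (length(tr$t) < 2) return(NULL)
    keep <- seq(1L, length(tr$t), by = stride)
    if (length(keep) < 2) return(NULL)
    p <- tr$pos[keep, , drop = FALSE]
    steps <- diff(p)
    seg <- sqrt(rowSums(steps^2))
    path <- sum(seg)
    net_disp <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    n_lag <- max(1L, floor((nrow(p) - 1L) / 4))
    msd <- vapply(seq_len(n_lag), function(k) {
      d <- p[seq_len(nrow(p) - k) + k, , drop = FALSE] -
        p[seq_len(nrow(p) - k), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
    tau <- seq_len(n_lag) * dt_eff
    slope <- sum(tau * msd) / sum(tau^2)  # OLS through the origin
    data.frame(cell_id = tr$cell_id,
               speed = mean(seg) / dt_eff * 60,
               meandering_index = if (path > 0) net_disp / path else 0,
               motility_coefficient = slope / (2 * dim) * 60,
               n_contacts = nrow(tr$contacts))
  })
  n_excluded <- sum(vapply(per_cell, is.null, logical(1)))
  tab <- do.call(rbind, per_cell)
  if (is.null(tab))
    fs_stop("no track has >= 2 samples at dt_sample", "follisim_invalid_input")
  duration <- attr(tracks, "duration") %||% max(tracks[[1]]$t)
  scanning <- sum(tab$n_contacts) / nrow(tab) / (duration / 3600)
  structure(list(
    speed = stats::median(tab$speed),
    meandering_index = stats::median(tab$meandering_index),
    motility_coefficient = stats::median(tab$motility_coefficient),
    scanning_rate = scanning,
    per_cell = tab, n_excluded = n_excluded,
    dt_sample = dt_eff), class = "migration_summary")
}

#' @export
print.migration_summary <- function(x, ...) {
  cat("Migration summary (medians over", nrow(x$per_cell), "cells)\n")
  cat(sprintf("  speed:                %.3f um/min\n", x$speed))
  cat(sprintf("  meandering index:     %.3f\n", x$meandering_index))
  cat(sprintf("  motility coefficient: %.3f um^2/min\n", x$motility_coefficient))
  cat(sprintf("  scanning rate:        %.3f nodes/cell/h\n", x$scanning_rate))
  invisible(x)
}

#' Extract the four objective statistics as a named vector
#' @param s a `migration_summary`.
#' @export
summary_vector <- function(s) {
  c(speed = s$speed, meandering_index = s$meandering_index,
    motility_coefficient = s$motility_coefficient,
    scanning_rate = s$scanning_rate)
}
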