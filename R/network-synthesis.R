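#' Parameters of the follicular network generator
#'
#' The generator places FDCs in a dense central core and CD21- RCs in an
#' outer shell plus a subcapsular rim cap of a follicle embedded in a thin
#' imaging-style slab, then connects nearby cells with a distance-decaying
#' probability and adds a small fraction of long-range shortcut edges.
#' Default values are the shipped calibration against the measured follicle
#' statistics (198 nodes, 1163 edges, C_local 0.60, C_global 0.57, L 4.17);
#' see the methods vignette for the calibration protocol.
#'
#' @param n_fdc,n_rc node counts per subtype.
#' @param follicle_radius follicle radius in the slab plane, µm.
#' @param fdc_core_fraction radius fraction of the central FDC zone.
#' @param rc_shell_thickness thickness of the subcapsular rim band, µm.
#' @param cap_fraction fraction of RCs placed on the subcapsular rim cap.
#' @param connect_radius maximum length of non-shortcut edges, µm.
#' @param connect_decay length scale of the distance-decaying connection
#'   probability `exp(-d / connect_decay)`, µm.
#' @param shortcut_fraction additional long-range edges as a fraction of the
#'   geometric edge count, in `[0, 1]`.
#' @param slab_dims domain dimensions (x, y, z), µm.
#' @param secretion_fdc,secretion_rc per-node secretion rates (amount s^-1).
#' @return list of class `synthesis_params`.
#' @export
synthesis_params <- function(n_fdc = 89, n_rc = 109,
                             follicle_radius = 140,
                             fdc_core_fraction = 0.62,
                             rc_shell_thickness = 25,
                             cap_fraction = 0.3,
                             connect_radius = 39,
                             connect_decay = 800,
                             shortcut_fraction = 0.005,
                             slab_dims = c(500, 500, 35),
                             secretion_fdc = 2, secretion_rc = 1) {
  p <- list(n_fdc = n_fdc, n_rc = n_rc, follicle_radius = follicle_radius,
            fdc_core_fraction = fdc_core_fraction,
            rc_shell_thickness = rc_shell_thickness,
            cap_fraction = cap_fraction,
            connect_radius = connect_radius, connect_decay = connect_decay,
            shortcut_fraction = shortcut_fraction, slab_dims = slab_dims,
            secretion_fdc = secretion_fdc, secretion_rc = secretion_rc)
  if (n_fdc + n_rc < 1 || n_fdc < 0 || n_rc < 0)
    fs_stop("need at least one node", "follisim_invalid_input")
  if (follicle_radius <= 0 || connect_radius <= 0 || connect_decay <= 0)
    fs_stop("radii and decay length must be positive", "follisim_invalid_input")
  if (shortcut_fraction < 0 || shortcut_fraction > 1)
    fs_stop("shortcut_fraction must lie in [0, 1]", "follisim_invalid_input")
  if (rc_shell_thickness > connect_radius)
    message("note: rc_shell_thickness exceeds connect_radius; rim may detach")
  class(p) <- "synthesis_params"
  p
}

#' Synthesize a follicular reticular cell network
#'
#' @param params a [synthesis_params()] object.
#' @param seed integer seed; networks are reproducible given the seed.
#' @return a [reticular_network()] with per-edge `shortcut` flags.
#' @export
synthesize_follicle_network <- function(params = synthesis_params(),
                                        seed = NULL) {
  p <- params
  with_seed(seed, {
    ctr <- p$slab_dims / 2
    R <- p$follicle_radius
    r_core <- p$fdc_core_fraction * R
    n <- p$n_fdc + p$n_rc

    sample_disc <- function(k, r0, r1) {
      # uniform by area in the annulus [r0, r1]
      r <- sqrt(stats::runif(k, r0^2, r1^2))
      th <- stats::runif(k, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    }
    xy_fdc <- sample_disc(p$n_fdc, 0, r_core)
    n_cap <- stats::rbinom(1, p$n_rc, p$cap_fraction)
    xy_rc <- sample_disc(p$n_rc - n_cap, r_core, R)
    if (n_cap > 0) {
      # subcapsular rim: thin band at the outer radius, upper arc only
      r <- stats::runif(n_cap, R - p$rc_shell_thickness, R)
      th <- stats::runif(n_cap, pi / 6, 5 * pi / 6)
      xy_rc <- rbind(xy_rc, cbind(r * cos(th), r * sin(th)))
    }
    xy <- rbind(xy_fdc, xy_rc)
    pos <- cbind(xy[, 1] + ctr[1], xy[, 2] + ctr[2],
                 stats::runif(n, 0, p$slab_dims[3]))
    subtype <- rep(c("FDC", "CD21neg_RC"), c(p$n_fdc, p$n_rc))
    nodes <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], subtype = subtype,
                        secretion_rate = ifelse(subtype == "FDC",
                                                p$secretion_fdc, p$secretion_rc))
    d <- as.matrix(stats::dist(pos))
    cand <- which(upper.tri(d) & d <= p$connect_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      keep <- stats::runif(nrow(cand)) < exp(-d[cand] / p$connect_decay)
      edges <- cand[keep, , drop = FALSE]
    } else edges <- matrix(integer(0), ncol = 2L)
    n_geom <- nrow(edges)
    n_short <- round(p$shortcut_fraction * n_geom)
    shortcut <- rep(FALSE, n_geom)
    if (n_short > 0 && n > 2) {
      adj <- matrix(FALSE, n, n)
      adj[edges] <- TRUE; adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
      added <- 0L
      while (added < n_short) {
        ij <- sort(sample.int(n, 2L))
        if (!adj[ij[1], ij[2]]) {
          edges <- rbind(edges, ij)
          adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
          shortcut <- c(shortcut, TRUE)
          added <- added + 1L
        }
      }
    }
    attr(edges, "shortcut") <- shortcut
    net <- reticular_network(nodes, edges,
                             rbind(c(0, 0, 0), p$slab_dims))
    if (n >= 2) {
      lcc <- topology_report(net)$lcc_fraction
      if (lcc < 0.5)
        fs_stop(sprintf(
          "synthesis failed: largest component covers only %.0f%% of nodes (n=%d, edges=%d); increase connect_radius/connect_decay",
          100 * lcc, n, nrow(edges)), "follisim_synthesis_failure")
    }
    net
  })
}

# Mean topology statistics of the generator at `params` over `seeds`.
generator_stats <- function(params, seeds) {
  out <- vapply(seeds, function(s) {
    net <- tryCatch(synthesize_follicle_network(params, seed = s),
                    follisim_synthesis_failure = function(e) NULL)
    if (is.null(net)) return(rep(NA_real_, 5))
    r <- topology_report(net)
    c(r$n_nodes, r$n_edges, r$C_local, r$C_global, r$L)
  }, numeric(5))
  stats <- rowMeans(out, na.rm = TRUE)
  names(stats) <- c("n_nodes", "n_edges", "C_local", "C_global", "L")
  attr(stats, "fail_fraction") <- mean(is.na(out[1, ]))
  stats
}

#' Calibrate the network generator against target topology statistics
#'
#' Random search followed by local refinement over the geometric parameters
#' (`connect_radius`, `connect_decay`, `shortcut_fraction`,
#' `fdc_core_fraction`), minimizing a weighted squared relative error between
#' generator mean statistics and the targets `n_edges`, `C_local`, `C_global`
#' and `L` (node counts are matched exactly from `target$n_nodes`).
#'
#' @param target list/`topology_report` with `n_nodes`, `n_edges`, `C_local`,
#'   `C_global`, `L`.
#' @param search_budget number of candidate parameterizations evaluated.
#' @param seed integer seed.
#' @param n_seeds generator replicates per candidate (default 20).
#' @param base a `synthesis_params` supplying fixed fields.
#' @param tol relative-error tolerance for declaring success.
#' @return list with `params` (a `synthesis_params`), `error` (achieved
#'   objective), `achieved` (mean statistics) and `converged` flag.
#' @export
calibrate_generator <- function(target, search_budget = 200, seed = NULL,
                                n_seeds = 20, base = synthesis_params(),
                                tol = 0.02) {
  need <- c("n_nodes", "n_edges", "C_local", "C_global", "L")
  if (!all(need %in% names(target)))
    fs_stop("target must contain n_nodes, n_edges, C_local, C_global, L",
            "follisim_invalid_input")
  if (target$n_edges > target$n_nodes * (target$n_nodes - 1) / 2)
    fs_stop("target edge count exceeds n(n-1)/2", "follisim_invalid_target")
  tgt <- unlist(target[need[-1]])
  w <- c(n_edges = 1, C_local = 2, C_global = 2, L = 2)
  ratio <- base$n_fdc / (base$n_fdc + base$n_rc)
  n_fdc <- round(ratio * target$n_nodes)
  n_rc <- target$n_nodes - n_fdc

  obj <- function(theta, seeds) {
    p <- base
    p$n_fdc <- n_fdc; p$n_rc <- n_rc
    p$connect_radius <- theta[1]; p$connect_decay <- theta[2]
    p$shortcut_fraction <- theta[3]; p$fdc_core_fraction <- theta[4]
    s <- generator_stats(p, seeds)
    if (attr(s, "fail_fraction") > 0.2) return(list(err = Inf, stats = s, p = p))
    err <- sum(w * ((s[names(tgt)] - tgt) / tgt)^2)
    list(err = err, stats = s, p = p)
  }

  with_seed(seed, {
    lo <- c(10, 5, 0, 0.3); hi <- c(60, 120, 0.08, 0.85)
    n_explore <- ceiling(search_budget * 0.6)
    seeds_eval <- sample.int(.Machine$integer.max - 1L, n_seeds)
    best <- NULL
    start <- c(base$connect_radius, base$connect_decay,
               base$shortcut_fraction, base$fdc_core_fraction)
    cands <- rbind(start,
                   t(replicate(n_explore - 1L, stats::runif(4, lo, hi))))
    for (i in seq_len(nrow(cands))) {
      res <- obj(cands[i, ], seeds_eval)
      if (is.null(best) || res$err < best$err) { best <- res; best$theta <- cands[i, ] }
    }
    # local refinement: shrinking Gaussian perturbations around the incumbent
    n_refine <- search_budget - n_explore
    for (i in seq_len(n_refine)) {
      scale <- 0.25 * (1 - i / (n_refine + 1))
      theta <- pmin(hi, pmax(lo, best$theta * (1 + stats::rnorm(4, 0, scale))))
      res <- obj(theta, seeds_eval)
      if (res$err < best$err) { best <- res; best$theta <- theta }
    }
    converged <- is.finite(best$err) &&
      all(abs(best$stats[names(tgt)] - tgt) / tgt < 10 * tol)
    if (!converged)
      warning("calibration budget exhausted above tolerance; returning best found")
    list(params = best$p, error = best$err, achieved = best$stats,
         converged = converged)
  })
}
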