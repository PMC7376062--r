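#' Bin a fluorescence-intensity image into an analysis grid
#'
#' Averages pixel intensities over square bins of area `bin_area` (default
#' 14.44 µm^2, i.e. 3.8 µm bins). Bins need not align with pixel edges:
#' pixels contribute to each bin in proportion to their overlap, so a 38 µm
#' image at 1 µm pixels yields an exact 10 x 10 grid of 3.8 µm bins.
#' Partial bins at the far edges are dropped.
#'
#' @param image 2D numeric matrix of nonnegative intensities.
#' @param pixel_size pixel edge length, µm.
#' @param bin_area bin area, µm^2.
#' @return list of class `intensity_grid` with `values` (bin means),
#'   `bin_side` (µm) and `bin_area`.
#' @export
bin_image <- function(image, pixel_size, bin_area = 14.44) {
  image <- as.matrix(image)
  if (!length(image) || bin_area <= 0 || pixel_size <= 0)
    fs_stop("image must be nonempty with positive pixel_size and bin_area",
            "follisim_invalid_input")
  side <- sqrt(bin_area)
  # overlap weights of each pixel with each whole bin along one axis
  axis_weights <- function(npix) {
    nbins <- floor(npix * pixel_size / side + 1e-9)
    if (nbins < 1L) return(NULL)
    W <- matrix(0, nbins, npix)
    for (b in seq_len(nbins)) {
      lo <- (b - 1) * side / pixel_size
      hi <- b * side / pixel_size
      p <- seq_len(npix)
      W[b, ] <- pmax(0, pmin(p, hi) - pmax(p - 1, lo))
    }
    W / rowSums(W)
  }
  Wr <- axis_weights(nrow(image))
  Wc <- axis_weights(ncol(image))
  if (is.null(Wr) || nrow(Wr) < 4L || is.null(Wc) || nrow(Wc) < 4L)
    fs_stop("need at least 4 bins per axis; use a smaller bin_area",
            "follisim_invalid_input")
  intensity_grid(unname(Wr %*% image %*% t(Wc)), bin_side = side)
}

#' @rdname bin_image
#' @param values pre-binned matrix of intensities.
#' @param bin_side bin edge length, µm.
#' @export
intensity_grid <- function(values, bin_side) {
  values <- as.matrix(values)
  if (any(values < 0) || bin_side <= 0)
    fs_stop("intensities must be nonnegative and bin_side > 0",
            "follisim_invalid_input")
  structure(list(values = values, bin_side = bin_side,
                 bin_area = bin_side^2), class = "intensity_grid")
}

#' Read a single-channel intensity image
#'
#' Accepts single-channel TIFF (first channel of multi-channel data, scaled
#' to its native range) or a CSV matrix of intensities.
#'
#' @param path image path (`.tif`/`.tiff` or `.csv`).
#' @return numeric matrix.
#' @export
read_intensity_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

# Moran's I for centered values z and a pair list (i, j counted once).
morans_i_pairs <- function(z, pi, pj) {
  n <- length(z)
  w_sum <- 2 * length(pi)                       # symmetric weights
  cross <- 2 * sum(z[pi] * z[pj])
  (n / w_sum) * cross / sum(z^2)
}

#' Moran's I correlogram with permutation testing
#'
#' Spatial autocorrelation of binned intensities per distance class (binary
#' weights for bin pairs whose center distance falls in the class), with
#' two-sided permutation p-values from `n_perm` random relabelings of the
#' bins. `D_uncorrelated` is the center of the first class whose p-value
#' rises above `alpha` — the distance at which intensities are no longer
#' significantly correlated.
#'
#' @param grid an [intensity_grid()] (positive variance).
#' @param class_width distance class width, µm; default one bin side.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param alpha per-class significance level (no multiplicity correction by
#'   default, matching the first-nonsignificant-class definition).
#' @param p_adjust optional [stats::p.adjust()] method applied before the
#'   `D_uncorrelated` scan (e.g. `"holm"`).
#' @param max_distance largest class edge, µm; default half the grid diagonal.
#' @return list of class `morans_correlogram`: `classes` data.frame
#'   (`distance`, `I`, `p`, `n_pairs`), `D_uncorrelated`, `censored` (`TRUE`
#'   when every analyzed class stays significant, in which case
#'   `D_uncorrelated` is censored at the largest analyzed distance),
#'   `n_perm`, `alpha`, `expected_I` (the null mean `-1/(N-1)`).
#' @export
morans_correlogram <- function(grid, class_width = NULL, n_perm = 999,
                               seed = NULL, alpha = 0.05, p_adjust = "none",
                               max_distance = NULL) {
  v <- grid$values
  if (stats::var(as.numeric(v)) == 0)
    fs_stop("intensity field has zero variance", "follisim_degenerate_field")
  if (n_perm < 99) fs_stop("n_perm must be >= 99", "follisim_invalid_input")
  nr <- nrow(v); nc <- ncol(v); N <- nr * nc
  cx <- (rep(seq_len(nr), nc) - 0.5) * grid$bin_side
  cy <- (rep(seq_len(nc), each = nr) - 0.5) * grid$bin_side
  cw <- class_width %||% grid$bin_side
  dmax <- max_distance %||% (sqrt((nr * grid$bin_side)^2 +
                                    (nc * grid$bin_side)^2) / 2)
  pi_ <- rep.int(seq_len(N - 1L), rev(seq_len(N - 1L)))
  pj_ <- unlist(lapply(seq_len(N - 1L), function(i) seq.int(i + 1L, N)))
  pd <- sqrt((cx[pi_] - cx[pj_])^2 + (cy[pi_] - cy[pj_])^2)
  # class k covers ((k-1) cw, k cw]; small tolerance so lattice distances that
  # fall exactly on a class edge are not split by floating-point noise
  cls <- ceiling(pd / cw - 1e-7)
  n_classes <- max(1L, floor(dmax / cw + 1e-7))
  keep <- cls >= 1L & cls <= n_classes
  pr <- cbind(pi_[keep], pj_[keep]); cls <- cls[keep]
  n_classes <- max(cls)
  z <- as.numeric(v) - mean(v)

  I_obs <- vapply(seq_len(n_classes), function(k) {
    sel <- cls == k
    if (!any(sel)) return(NA_real_)
    morans_i_pairs(z, pr[sel, 1], pr[sel, 2])
  }, numeric(1))
  n_pairs <- tabulate(cls, n_classes)

  perm_seeds <- derive_seeds(seed %||% 1L, 1L)
  I_perm <- with_seed(perm_seeds[1], {
    out <- matrix(NA_real_, n_perm, n_classes)
    ssz <- sum(z^2)
    for (b in seq_len(n_perm)) {
      zp <- z[sample.int(N)]
      cross <- zp[pr[, 1]] * zp[pr[, 2]]
      s <- rowsum(cross, cls)
      k_idx <- as.integer(rownames(s))
      out[b, k_idx] <- (N / (2 * n_pairs[k_idx])) * 2 * s[, 1] / ssz
    }
    out
  })
  p <- vapply(seq_len(n_classes), function(k) {
    if (!n_pairs[k] || is.na(I_obs[k])) return(NA_real_)
    lo <- mean(I_perm[, k] <= I_obs[k])
    hi <- mean(I_perm[, k] >= I_obs[k])
    min(1, 2 * min((lo * n_perm + 1) / (n_perm + 1),
                   (hi * n_perm + 1) / (n_perm + 1)))
  }, numeric(1))
  p_scan <- stats::p.adjust(p, method = p_adjust)
  centers <- (seq_len(n_classes) - 0.5) * cw
  first_ns <- which(!is.na(p_scan) & p_scan > alpha)[1]
  # significant out to the last analyzed class: censor at the largest distance
  d_unc <- if (is.na(first_ns)) n_classes * cw else centers[first_ns]
  structure(list(
    classes = data.frame(distance = centers, I = I_obs, p = p,
                         n_pairs = n_pairs),
    D_uncorrelated = d_unc,
    censored = is.na(first_ns),
    n_perm = n_perm, alpha = alpha, p_adjust = p_adjust,
    expected_I = -1 / (N - 1), class_width = cw), class = "morans_correlogram")
}

#' @export
print.morans_correlogram <- function(x, ...) {
  cat("Moran's I correlogram:", nrow(x$classes), "distance classes,",
      x$n_perm, "permutations\n")
  cat(sprintf("  D_uncorrelated: %s um (alpha = %g, adjust = %s)\n",
              format(x$D_uncorrelated), x$alpha, x$p_adjust))
  invisible(x)
}

#' Mid-slab intensity grid of a chemokine field
#'
#' Extracts the central z-slice of soluble + immobilized chemokine as an
#' [intensity_grid()], the simulation-side input to [morans_correlogram()].
#'
#' @param grid a `chemokine_grid`.
#' @export
field_intensity_grid <- function(grid) {
  zmid <- ceiling(grid$shape[3] / 2)
  intensity_grid(grid$soluble[, , zmid] + grid$immobilized[, , zmid],
                 bin_side = grid$spacing)
}

#' Write a correlogram result
#' @param cg a `morans_correlogram`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_correlogram <- function(cg, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(cg$classes, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(D_uncorrelated = cg$D_uncorrelated,
                              n_perm = cg$n_perm, alpha = cg$alpha,
                              p_adjust = cg$p_adjust,
                              class_width = cg$class_width,
                              classes = cg$classes),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(cg)
}
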