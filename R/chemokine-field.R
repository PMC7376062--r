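#' Chemokine field parameters
#'
#' Rate constants of the CXCL13 reaction-diffusion model: soluble diffusion
#' `D` (µm^2 s^-1), first-order decay `lam` (s^-1), reversible ECM
#' immobilization `k_on_ecm`/`k_off_ecm` (s^-1), the decay rate of the
#' immobilized pool `lam_immobilized` (defaults to `lam`), and per-node
#' secretion rates for the two stromal subtypes (amount s^-1).
#'
#' @export
field_params <- function(D = 0.19, lam = 8.44e-4,
                         k_on_ecm = 0, k_off_ecm = 0,
                         secretion_fdc = 2, secretion_rc = 1,
                         lam_immobilized = NULL) {
  p <- list(D = D, lam = lam, k_on_ecm = k_on_ecm, k_off_ecm = k_off_ecm,
            secretion_fdc = secretion_fdc, secretion_rc = secretion_rc,
            lam_immobilized = lam_immobilized %||% lam)
  if (any(unlist(p) < 0))
    fs_stop("all field parameters must be >= 0", "follisim_invalid_input")
  class(p) <- "field_params"
  p
}

#' Discretized chemokine grid
#'
#' Regular 3D lattice over an axis-aligned domain holding soluble and
#' immobilized chemokine (stored as amount per voxel) and a per-voxel
#' secretion rate. The immobilized pool is only active when `ecm_pool = TRUE`
#' (immobilization can otherwise be emulated by a low `D` and high `lam`).
#'
#' @param bounds 2 x 3 matrix (lower/upper corner, µm) or a length-3 vector of
#'   domain dimensions with origin 0.
#' @param spacing voxel edge length, µm.
#' @param params a [field_params()].
#' @param boundary `"reflective"` (zero flux; closed follicle) or
#'   `"absorbing"` (zero concentration outside; sinks at the domain edge).
#' @param ecm_pool logical; track an explicit immobilized pool.
#' @return list of class `chemokine_grid`.
#' @export
chemokine_grid <- function(bounds, spacing = 5, params = field_params(),
                           boundary = c("reflective", "absorbing"),
                           ecm_pool = FALSE) {
  boundary <- match.arg(boundary)
  if (spacing <= 0) fs_stop("spacing must be > 0", "follisim_invalid_input")
  if (is.null(dim(bounds))) bounds <- rbind(c(0, 0, 0), as.numeric(bounds))
  dims <- bounds[2, ] - bounds[1, ]
  shape <- pmax(1L, as.integer(ceiling(dims / spacing - 1e-9)))
  zero <- array(0, dim = shape)
  structure(list(spacing = spacing, shape = shape, origin = bounds[1, ],
                 soluble = zero, immobilized = zero, source = zero,
                 params = params, boundary = boundary, ecm_pool = ecm_pool),
            class = "chemokine_grid")
}

#' @export
print.chemokine_grid <- function(x, ...) {
  cat(sprintf("Chemokine grid %d x %d x %d voxels @ %g um (%s boundary)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing, x$boundary))
  cat(sprintf("  total soluble: %.4g  immobilized: %.4g  source rate: %.4g/s\n",
              sum(x$soluble), sum(x$immobilized), sum(x$source)))
  invisible(x)
}

#' Total chemokine mass on a grid
#' @param grid a `chemokine_grid`.
#' @export
total_mass <- function(grid) sum(grid$soluble) + sum(grid$immobilized)

# Voxel index (i, j, k) of each position row; errors if outside the grid.
position_to_voxel <- function(grid, pos) {
  idx <- floor(sweep(pos, 2, grid$origin) / grid$spacing) + 1L
  idx <- matrix(as.integer(idx), ncol = 3L)
  hi <- grid$origin + grid$shape * grid$spacing
  for (a in 1:3) {
    # the upper face belongs to the last voxel
    on_face <- idx[, a] == grid$shape[a] + 1L & pos[, a] <= hi[a] + 1e-9
    idx[on_face, a] <- grid$shape[a]
  }
  if (any(idx < 1L) || any(sweep(idx, 2, grid$shape) > 0L))
    fs_stop("position outside the grid extent", "follisim_out_of_bounds")
  idx
}

#' Deposit network secretion onto the grid
#'
#' Each stromal node's secretion rate is added to its nearest voxel; the total
#' deposited rate equals the sum of node rates. By default the
#' subtype-specific rates come from the grid's [field_params()]
#' (`secretion_fdc` / `secretion_rc`); with `use_node_rates = TRUE` the
#' per-node `secretion_rate` annotations are used instead.
#'
#' @param net a [reticular_network()].
#' @param grid a [chemokine_grid()] whose extent covers the network bounds.
#' @param use_node_rates take rates from the node table rather than the grid
#'   parameters.
#' @return the grid with an updated `source` field.
#' @export
rasterize_sources <- function(net, grid, use_node_rates = FALSE) {
  pos <- as.matrix(net$nodes[, c("x", "y", "z")])
  idx <- position_to_voxel(grid, pos)
  flat <- idx[, 1] + grid$shape[1] * (idx[, 2] - 1L) +
    grid$shape[1] * grid$shape[2] * (idx[, 3] - 1L)
  rates <- if (use_node_rates) net$nodes$secretion_rate else
    ifelse(net$nodes$subtype == "FDC", grid$params$secretion_fdc,
           grid$params$secretion_rc)
  add <- vapply(split(rates, flat), sum, numeric(1))
  grid$source[as.integer(names(add))] <- grid$source[as.integer(names(add))] + add
  grid
}

# Sum of the six face neighbors of a 3D array under the grid's boundary rule
# (reflective: missing neighbor = own value; absorbing: = 0).
neighbor_sum <- function(a, boundary) {
  d <- dim(a)
  s <- array(0, dim = d)
  pad <- function(x, axis, from) {
    # slab of `a` shifted by one voxel along `axis`; `from` = +1 or -1
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (from > 0) { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1L) }
    else { src[[axis]] <- 1:(d[axis] - 1L); dst[[axis]] <- 2:d[axis] }
    out <- array(0, dim = d)
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    if (boundary == "reflective") {
      edge <- idx; edge[[axis]] <- if (from > 0) d[axis] else 1L
      out[edge[[1]], edge[[2]], edge[[3]]] <-
        a[edge[[1]], edge[[2]], edge[[3]]]
    }
    out
  }
  for (axis in 1:3) {
    if (d[axis] == 1L) {
      # degenerate axis: both neighbors are the boundary
      s <- s + if (boundary == "reflective") 2 * a else 0
    } else {
      s <- s + pad(a, axis, +1L) + pad(a, axis, -1L)
    }
  }
  s
}

# Largest dt that keeps the forward-time central-space update positive.
stable_dt <- function(grid) {
  p <- grid$params
  k_on <- if (grid$ecm_pool) p$k_on_ecm else 0
  1 / (6 * p$D / grid$spacing^2 + p$lam + k_on + 1e-300)
}

#' Advance the chemokine field by one time step
#'
#' Forward-time central-space update of the soluble field (diffusion + source
#' - decay - immobilization + release) and, when the ECM pool is active, of
#' the immobilized field (immobilized chemokine does not diffuse). Refuses
#' steps that violate the positivity/stability bound and suggests a valid
#' `dt`.
#'
#' @param grid a [chemokine_grid()].
#' @param dt time step, s.
#' @return the updated grid.
#' @export
field_step <- function(grid, dt) {
  p <- grid$params
  h2 <- grid$spacing^2
  k_on <- if (grid$ecm_pool) p$k_on_ecm else 0
  k_off <- if (grid$ecm_pool) p$k_off_ecm else 0
  if (dt > h2 / (6 * p$D) + 1e-12 || dt * (p$lam + k_on) >= 1 ||
      (grid$ecm_pool && dt * (k_off + p$lam_immobilized) >= 1) ||
      dt > stable_dt(grid) + 1e-12)
    fs_stop(sprintf("dt = %g violates the stability bound; use dt <= %g",
                    dt, 0.95 * stable_dt(grid)), "follisim_stability")
  c0 <- grid$soluble
  lap <- (neighbor_sum(c0, grid$boundary) - 6 * c0) / h2
  grid$soluble <- c0 + dt * (p$D * lap + grid$source - p$lam * c0 -
                             k_on * c0 + k_off * grid$immobilized)
  if (grid$ecm_pool) {
    i0 <- grid$immobilized
    grid$immobilized <- i0 + dt * (k_on * c0 - k_off * i0 -
                                   p$lam_immobilized * i0)
  }
  grid
}

# Sparse 3D Laplacian (units 1/spacing^2) under the grid's boundary rule.
grid_laplacian <- function(grid) {
  one_d <- function(n) {
    if (n == 1L) {
      v <- if (grid$boundary == "reflective") 0 else -2
      return(Matrix::Matrix(v, 1, 1, sparse = TRUE))
    }
    M <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                            diagonals = list(rep(1, n - 1), rep(-2, n),
                                             rep(1, n - 1)))
    if (grid$boundary == "reflective") { M[1, 1] <- -1; M[n, n] <- -1 }
    M
  }
  s <- grid$shape
  I1 <- Matrix::Diagonal(s[1]); I2 <- Matrix::Diagonal(s[2])
  I3 <- Matrix::Diagonal(s[3])
  L <- Matrix::kronecker(I3, Matrix::kronecker(I2, one_d(s[1]))) +
    Matrix::kronecker(I3, Matrix::kronecker(one_d(s[2]), I1)) +
    Matrix::kronecker(one_d(s[3]), Matrix::kronecker(I2, I1))
  L / grid$spacing^2
}

#' Relax the chemokine field to steady state
#'
#' `method = "direct"` (default) solves the linear steady-state balance with a
#' sparse factorization, exploiting the model's linearity; `"iterate"` runs
#' the explicit scheme until the maximum relative change per simulated second
#' drops below `tol`. A steady state requires a loss pathway (`lam > 0`, loss
#' through the immobilized pool, or an absorbing boundary).
#'
#' @param grid a [chemokine_grid()] with sources set.
#' @param tol maximum relative change per second (iterative method).
#' @param max_t maximum simulated time, s (iterative method).
#' @param method `"direct"` or `"iterate"`.
#' @return the converged grid; attribute `elapsed` holds the simulated time
#'   for the iterative method.
#' @export
run_to_steady_state <- function(grid, tol = 1e-8, max_t = 1e6,
                                method = c("direct", "iterate")) {
  method <- match.arg(method)
  p <- grid$params
  loss_immob <- if (grid$ecm_pool && (p$k_off_ecm + p$lam_immobilized) > 0)
    p$k_on_ecm * p$lam_immobilized / (p$k_off_ecm + p$lam_immobilized)
  else if (grid$ecm_pool && p$k_on_ecm > 0) Inf else 0
  loss <- p$lam + loss_immob
  if (loss <= 0 && grid$boundary != "absorbing")
    fs_stop("no steady state: need decay, immobilized-pool loss, or an absorbing boundary",
            "follisim_invalid_input")
  if (all(grid$source == 0)) {
    grid$soluble[] <- 0; grid$immobilized[] <- 0
    attr(grid, "elapsed") <- 0
    return(grid)
  }
  if (method == "direct") {
    if (is.infinite(loss)) { # pure irreversible sink: everything immobilizes
      grid$soluble[] <- 0
    } else {
      A <- loss * Matrix::Diagonal(prod(grid$shape)) - p$D * grid_laplacian(grid)
      A <- Matrix::forceSymmetric(A)   # SPD: supernodal sparse Cholesky
      ch <- Matrix::Cholesky(A, super = TRUE)
      x <- Matrix::solve(ch, Matrix::Matrix(as.numeric(grid$source)))
      grid$soluble <- array(as.numeric(x), dim = grid$shape)
    }
    if (grid$ecm_pool && (p$k_off_ecm + p$lam_immobilized) > 0)
      grid$immobilized <- p$k_on_ecm * grid$soluble /
        (p$k_off_ecm + p$lam_immobilized)
    attr(grid, "elapsed") <- NA_real_
    return(grid)
  }
  dt <- 0.45 * stable_dt(grid)
  t <- 0
  repeat {
    old <- grid$soluble
    grid <- field_step(grid, dt)
    t <- t + dt
    rel <- max(abs(grid$soluble - old)) / (dt * max(grid$soluble, 1e-300))
    if (rel < tol) break
    if (t > max_t)
      fs_stop(sprintf("steady state not reached by t = %g s (residual %g /s)",
                      max_t, rel), "follisim_nonconvergence")
  }
  attr(grid, "elapsed") <- t
  grid
}

#' Fraction of chemokine within a distance of the secreting cells
#'
#' @param grid a converged `chemokine_grid`.
#' @param radius distance from the nearest source voxel, µm.
#' @export
fraction_near_sources <- function(grid, radius = 50) {
  src <- which(grid$source > 0, arr.ind = TRUE)
  if (!nrow(src)) return(NA_real_)
  vox <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                               j = seq_len(grid$shape[2]),
                               k = seq_len(grid$shape[3])))
  dmin <- rep(Inf, nrow(vox))
  for (s in seq_len(nrow(src))) {
    d2 <- (vox[, 1] - src[s, 1])^2 + (vox[, 2] - src[s, 2])^2 +
      (vox[, 3] - src[s, 3])^2
    dmin <- pmin(dmin, d2)
  }
  near <- sqrt(dmin) * grid$spacing <= radius
  tot <- as.numeric(grid$soluble) + as.numeric(grid$immobilized)
  sum(tot[near]) / sum(tot)
}

#' Parameterizations for the immobilized and soluble gradient models
#'
#' Model 1 (immobilized): low diffusion, high decay, high ECM binding -
#' short, sharp gradients proximal to the secreting cells. Model 2 (soluble):
#' high diffusion, low decay - a near-homogeneous pattern. Diffusion
#' coefficients are seeded from the measured single-molecule medians (0.19
#' and 1.6 µm^2 s^-1); the model-1 decay rate sets a screening length of
#' about 15 µm. Secretion is rescaled so that both steady states carry the
#' same total mass (`reference_mass`), holding the overall concentration
#' fixed between models.
#'
#' @param model_id 1 or 2.
#' @param reference_mass target steady-state total chemokine mass (amount).
#' @param n_fdc,n_rc node counts used to convert total secretion to per-node
#'   rates (defaults match [synthesis_params()]).
#' @param fdc_rc_ratio FDC : RC per-node secretion ratio.
#' @return a [field_params()].
#' @export
model_parameterization <- function(model_id, reference_mass = 2000,
                                   n_fdc = 89, n_rc = 109, fdc_rc_ratio = 2) {
  if (!model_id %in% c(1, 2))
    fs_stop("model_id must be 1 or 2", "follisim_invalid_input")
  if (reference_mass <= 0)
    fs_stop("reference_mass must be > 0", "follisim_invalid_input")
  if (model_id == 1) {
    D <- 0.19; lam <- 0.19 / 15^2        # screening length ~15 um
    k_on <- 0.01; k_off <- 1e-3
  } else {
    D <- 1.6; lam <- 1e-5                # screening length ~400 um
    k_on <- 2e-4; k_off <- 1e-2
  }
  s_total <- reference_mass * lam        # steady mass = secretion / decay
  s_rc <- s_total / (fdc_rc_ratio * n_fdc + n_rc)
  field_params(D = D, lam = lam, k_on_ecm = k_on, k_off_ecm = k_off,
               secretion_fdc = fdc_rc_ratio * s_rc, secretion_rc = s_rc)
}

#' Serialize a chemokine field to plain text
#'
#' Writes a JSON sidecar (`<path>.json`: spacing, shape, origin, parameters,
#' boundary) and a CSV (`<path>.csv`) with one row per voxel (`i`, `j`, `k`,
#' `soluble`, `immobilized`, `source`).
#'
#' @param grid a `chemokine_grid`.
#' @param path base path without extension.
#' @export
write_field <- function(grid, path) {
  meta <- list(spacing = grid$spacing, shape = grid$shape,
               origin = grid$origin, boundary = grid$boundary,
               ecm_pool = grid$ecm_pool, params = unclass(grid$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  vox <- expand.grid(i = seq_len(grid$shape[1]), j = seq_len(grid$shape[2]),
                     k = seq_len(grid$shape[3]))
  vox$soluble <- as.numeric(grid$soluble)
  vox$immobilized <- as.numeric(grid$immobilized)
  vox$source <- as.numeric(grid$source)
  utils::write.csv(vox, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- chemokine_grid(rbind(meta$origin, meta$origin + meta$shape * meta$spacing),
                         spacing = meta$spacing,
                         params = do.call(field_params, as.list(meta$params)),
                         boundary = meta$boundary, ecm_pool = meta$ecm_pool)
  vox <- utils::read.csv(paste0(path, ".csv"))
  grid$soluble <- array(vox$soluble, dim = grid$shape)
  grid$immobilized <- array(vox$immobilized, dim = grid$shape)
  grid$source <- array(vox$source, dim = grid$shape)
  grid
}
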