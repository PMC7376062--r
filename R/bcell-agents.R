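# The 13 emulated simulation inputs, in canonical order: five chemokine-field
# parameters, five CXCR5 receptor rate constants, three motility parameters.
#' Names of the 13 emulated simulation parameters
#' @export
simulation_param_names <- function() {
  c("D", "lam", "secretion_fdc", "secretion_rc", "k_on_ecm",
    "k_on", "k_off", "k_i", "k_re", "R_total",
    "v_mean", "persistence", "chi")
}

#' Agent simulation configuration
#'
#' Bundles the 13 emulated parameters (chemokine field, CXCR5 receptor
#' kinetics, motility) with the discretization and run settings. Chemokine
#' "concentration" seen by receptors is amount per µm^3 (voxel amount divided
#' by voxel volume), so `k_on` carries units µm^3 s^-1.
#'
#' @param D,lam,secretion_fdc,secretion_rc,k_on_ecm chemokine-field
#'   parameters; see [field_params()].
#' @param k_on,k_off,k_i,k_re receptor binding, unbinding, internalization and
#'   recycling rates (`k_on` in µm^3 s^-1, others s^-1).
#' @param R_total CXCR5 receptors per cell.
#' @param v_mean mean cell speed, µm min^-1 (per-step speeds are Gamma
#'   distributed with shape 4 around this mean).
#' @param persistence concentration weight on the previous orientation; larger
#'   values give straighter paths.
#' @param chi chemotactic bias weight.
#' @param sensing how the gradient is transduced into a bias.
#'   `"occupancy_difference"` (default): the bias magnitude is the
#'   equilibrium CXCR5 occupancy difference across the cell body,
#'   `K/(c+K)^2 * |grad c| * cell_diameter` with `K = k_off/k_on`, scaled by
#'   the cell's current surface-receptor fraction — saturated or
#'   desensitized cells cannot read gradients, which makes structured
#'   (short screening length) fields far more legible than an equally
#'   massive uniform background. `"occupancy_scaled"`: the unit gradient
#'   direction scaled by the bound fraction `R_b/R_total`.
#' @param grad_detect (`occupancy_scaled`) minimum detectable fractional
#'   concentration difference across one cell diameter.
#' @param occ_detect (`occupancy_difference`) minimum detectable occupancy
#'   difference across the cell (receptor-counting noise floor).
#' @param cell_diameter B-cell diameter used for gradient sensing, µm.
#' @param dt time step, s.
#' @param duration simulated time, s.
#' @param n_cells number of B-cell agents.
#' @param contact_radius stromal contact distance, µm.
#' @param spacing field voxel size, µm.
#' @param k_off_ecm ECM release rate, s^-1 (used when `ecm_pool = TRUE`).
#' @param ecm_pool,consumption,boundary,sense field/agent model switches;
#'   `sense` selects which pools the cells read chemotactically.
#' @param start_radius radius (µm, around the domain center in the slab
#'   plane) within which cells are seeded; `NULL` = the radial extent of the
#'   stromal network (B cells start inside the follicle).
#' @param save_every record positions every this many steps.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(D = 0.19, lam = 8.44e-4, secretion_fdc = 0.0125,
                              secretion_rc = 0.00625, k_on_ecm = 0,
                              k_on = 100, k_off = 0.05, k_i = 0.01,
                              k_re = 0.001, R_total = 1e4,
                              v_mean = 6.5, persistence = 6, chi = 8,
                              dt = 5, duration = 1800, n_cells = 20,
                              contact_radius = 6, spacing = 10,
                              k_off_ecm = 1e-3, ecm_pool = FALSE,
                              consumption = FALSE,
                              boundary = c("reflective", "absorbing"),
                              sense = c("both", "soluble", "immobilized"),
                              sensing = c("occupancy_difference",
                                          "occupancy_scaled"),
                              grad_detect = 0.01, occ_detect = 0.005,
                              cell_diameter = 10,
                              start_radius = NULL, save_every = 1L,
                              seed = NULL) {
  cfg <- list(D = D, lam = lam, secretion_fdc = secretion_fdc,
              secretion_rc = secretion_rc, k_on_ecm = k_on_ecm,
              k_on = k_on, k_off = k_off, k_i = k_i, k_re = k_re,
              R_total = R_total, v_mean = v_mean, persistence = persistence,
              chi = chi, dt = dt, duration = duration, n_cells = n_cells,
              contact_radius = contact_radius, spacing = spacing,
              k_off_ecm = k_off_ecm, ecm_pool = ecm_pool,
              consumption = consumption, boundary = match.arg(boundary),
              sense = match.arg(sense), sensing = match.arg(sensing),
              grad_detect = grad_detect, occ_detect = occ_detect,
              cell_diameter = cell_diameter, start_radius = start_radius,
              save_every = as.integer(save_every), seed = seed)
  rates <- unlist(cfg[c("D", "lam", "secretion_fdc", "secretion_rc",
                        "k_on_ecm", "k_on", "k_off", "k_i", "k_re",
                        "R_total", "chi", "persistence")])
  if (any(rates < 0))
    fs_stop("rates and weights must be >= 0", "follisim_invalid_input")
  if (n_cells < 1) fs_stop("n_cells must be >= 1", "follisim_invalid_input")
  if (dt <= 0 || duration < 0)
    fs_stop("dt must be > 0 and duration >= 0", "follisim_invalid_input")
  class(cfg) <- "simulation_config"
  cfg
}

#' Replace the 13 emulated parameters in a configuration
#'
#' @param theta named (or canonically ordered) numeric vector of length 13;
#'   see [simulation_param_names()].
#' @param base a [simulation_config()] supplying all other settings.
#' @export
config_with_params <- function(theta, base = simulation_config()) {
  nm <- simulation_param_names()
  if (length(theta) != 13L)
    fs_stop("theta must have length 13", "follisim_invalid_input")
  if (is.null(names(theta))) names(theta) <- nm
  base[nm] <- as.list(theta[nm])
  base
}

#' One explicit Euler step of the CXCR5 receptor pools
#'
#' Three-pool linear kinetics: free receptors bind local ligand at
#' `k_on * c`, bound receptors unbind (`k_off`) or internalize (`k_i`), and
#' internalized receptors recycle to the surface (`k_re`). Total receptor
#' number is conserved.
#'
#' @param state numeric vector `c(R_free, R_bound, R_internal)` or an n x 3
#'   matrix of per-cell states.
#' @param c_local ligand concentration(s), µm^-3.
#' @param dt time step, s; per-step fractional changes must stay below 0.5.
#' @param cfg a [simulation_config()] (source of the rate constants).
#' @return updated state with the same shape.
#' @export
receptor_step <- function(state, c_local, dt, cfg = simulation_config()) {
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1L)
  if (any(m < 0)) fs_stop("receptor pools must be >= 0", "follisim_invalid_input")
  fmax <- max(cfg$k_on * c_local, cfg$k_off + cfg$k_i, cfg$k_re) * dt
  if (fmax >= 0.5)
    fs_stop(sprintf(
      "per-step fractional change %.2f >= 0.5; reduce dt below %g s",
      fmax, 0.4 * dt / fmax), "follisim_step_size")
  bind <- cfg$k_on * c_local * m[, 1] * dt
  unbind <- cfg$k_off * m[, 2] * dt
  intern <- cfg$k_i * m[, 2] * dt
  recyc <- cfg$k_re * m[, 3] * dt
  out <- cbind(m[, 1] - bind + unbind + recyc,
               m[, 2] + bind - unbind - intern,
               m[, 3] + intern - recyc)
  if (any(out < 0))
    fs_stop("receptor pool went negative; reduce dt", "follisim_step_size")
  if (is.matrix(state)) out else drop(out)
}

# Unconditionally stable receptor update used inside the simulation loop:
# the fast binding/unbinding pair relaxes exactly (exponential update toward
# its equilibrium at the local concentration, holding the surface pool
# fixed), while the slow internalization/recycling rates advance by explicit
# Euler at the motility time step. Total receptor number is conserved
# exactly; agrees with the explicit-Euler [receptor_step()] as dt -> 0.
receptor_advance <- function(state, c_local, dt, cfg) {
  konc <- cfg$k_on * c_local
  lamf <- konc + cfg$k_off
  S <- state[, 1] + state[, 2]
  q <- ifelse(lamf > 0, konc / lamf, 0)
  Rb <- state[, 2] * exp(-lamf * dt) + S * q * (1 - exp(-lamf * dt))
  intern <- cfg$k_i * Rb * dt
  recyc <- cfg$k_re * state[, 3] * dt
  cbind(S - Rb + recyc, Rb - intern, state[, 3] + intern - recyc)
}

# Trilinear interpolation of a voxel field (amount per voxel) at arbitrary
# positions; voxel centers sit at origin + (i - 0.5) * spacing, and queries
# are clamped to the center lattice.
interp_field <- function(f, grid, pos) {
  h <- grid$spacing
  n <- nrow(pos)
  i0 <- matrix(0, n, 3L); frac <- matrix(0, n, 3L)
  for (a in 1:3) {
    ua <- (pos[, a] - grid$origin[a]) / h - 0.5
    ua[ua < 0] <- 0
    top <- grid$shape[a] - 1
    ua[ua > top] <- top
    ia <- floor(ua)
    ia[ia > top - 1 & top >= 1] <- top - 1   # keep ia + 1 a valid voxel
    if (top < 1) ia[] <- 0
    i0[, a] <- ia
    frac[, a] <- ua - ia
  }
  s1 <- grid$shape[1]; s12 <- grid$shape[1] * grid$shape[2]
  base <- 1 + i0[, 1] + s1 * i0[, 2] + s12 * i0[, 3]
  wx1 <- frac[, 1]; wx0 <- 1 - wx1
  wy1 <- frac[, 2]; wy0 <- 1 - wy1
  wz1 <- frac[, 3]; wz0 <- 1 - wz1
  dx1 <- if (grid$shape[1] > 1L) 1L else 0L
  dy1 <- if (grid$shape[2] > 1L) s1 else 0L
  dz1 <- if (grid$shape[3] > 1L) s12 else 0L
  wz0 * (wy0 * (wx0 * f[base] + wx1 * f[base + dx1]) +
         wy1 * (wx0 * f[base + dy1] + wx1 * f[base + dy1 + dx1])) +
  wz1 * (wy0 * (wx0 * f[base + dz1] + wx1 * f[base + dz1 + dx1]) +
         wy1 * (wx0 * f[base + dz1 + dy1] + wx1 * f[base + dz1 + dy1 + dx1]))
}

# Concentration difference sensed across the cell body: gradient component
# along each axis from interpolated field values one cell radius either side.
cell_scale_gradient <- function(f, grid, pos, diam) {
  g <- matrix(0, nrow(pos), 3L)
  for (a in 1:3) {
    up <- pos; up[, a] <- up[, a] + diam / 2
    dn <- pos; dn[, a] <- dn[, a] - diam / 2
    g[, a] <- (interp_field(f, grid, up) - interp_field(f, grid, dn)) / diam
  }
  g
}

# Chemotactically sensed field and its central-difference gradient arrays.
field_gradient <- function(grid, sense = "both") {
  f <- switch(sense,
              soluble = grid$soluble,
              immobilized = grid$immobilized,
              both = grid$soluble + grid$immobilized)
  h <- grid$spacing
  grad_axis <- function(a, axis) {
    d <- dim(a); n <- d[axis]
    if (n == 1L) return(array(0, dim = d))
    idx <- lapply(d, seq_len)
    up <- idx; dn <- idx
    up[[axis]] <- pmin(seq_len(n) + 1L, n)  # one-sided at faces
    dn[[axis]] <- pmax(seq_len(n) - 1L, 1L)
    span <- array(rep(ifelse(seq_len(n) %in% c(1L, n), h, 2 * h),
                      each = if (axis == 1L) 1L else prod(d[seq_len(axis - 1L)])),
                  dim = d)
    (a[up[[1]], up[[2]], up[[3]]] - a[dn[[1]], dn[[2]], dn[[3]]]) / span
  }
  list(value = f,
       gx = grad_axis(f, 1L), gy = grad_axis(f, 2L), gz = grad_axis(f, 3L))
}

# Reflect positions and orientations at the axis-aligned domain bounds.
reflect_bounds <- function(pos, ori, lo, hi) {
  for (a in 1:3) {
    under <- pos[, a] < lo[a]
    over <- pos[, a] > hi[a]
    pos[under, a] <- 2 * lo[a] - pos[under, a]
    pos[over, a] <- 2 * hi[a] - pos[over, a]
    flip <- under | over
    ori[flip, a] <- -ori[flip, a]
    # clamp pathological overshoots (step larger than the domain)
    pos[, a] <- pmin(pmax(pos[, a], lo[a]), hi[a])
  }
  list(pos = pos, ori = ori)
}

#' One motility step for a population of B-cell agents
#'
#' New orientation = normalize(persistence * previous orientation + random
#' unit perturbation + chemotactic bias), where the bias is the sensed
#' chemokine gradient transduced according to `cfg$sensing` (see
#' [simulation_config()]) and weighted by the cell's receptor state. The
#' gradient is read as the concentration difference across the cell body
#' (trilinear interpolation one cell radius either side of the center).
#' Displacement is `v * dt` with per-cell speeds drawn Gamma(4) around
#' `v_mean`; cells reflect off the domain boundary. Where the gradient is
#' undetectable the walk falls back to a pure persistent random walk.
#'
#' @param pos n x 3 matrix of positions, µm.
#' @param ori n x 3 matrix of unit orientations.
#' @param grid a converged [chemokine_grid()].
#' @param occupancy length-n receptor weights in `[0, 1]`: the surface
#'   fraction `(R_f + R_b)/R_total` under occupancy-difference sensing, the
#'   bound fraction `R_b/R_total` under occupancy-scaled sensing.
#' @param cfg a [simulation_config()].
#' @param gradient optional precomputed [field_gradient()] cache.
#' @param bounds optional 2 x 3 domain bounds for the reflective collision
#'   (defaults to the grid extent; the simulation passes the network domain,
#'   which the voxel grid may overhang by up to one voxel).
#' @return list with updated `pos` and `ori`.
#' @export
motility_step <- function(pos, ori, grid, occupancy, cfg,
                          gradient = NULL, bounds = NULL) {
  n <- nrow(pos)
  g <- gradient %||% field_gradient(grid, cfg$sense)
  gv <- cell_scale_gradient(g$value, grid, pos, cfg$cell_diameter)
  gn <- sqrt(rowSums(gv^2))
  cv <- interp_field(g$value, grid, pos)
  if (cfg$sensing == "occupancy_difference" && cfg$k_on > 0) {
    vol <- grid$spacing^3
    K <- cfg$k_off / cfg$k_on                 # conc units, amount / um^3
    slope <- K / (cv / vol + K)^2             # d occupancy / d concentration
    docc <- gv / vol * (slope * cfg$cell_diameter)
    mag <- pmin(sqrt(rowSums(docc^2)), 1)
    ok <- is.finite(mag) & mag >= cfg$occ_detect
    mag[!ok] <- 0
    bias <- cfg$chi * occupancy * mag * normalize_rows(docc)
    bias[!ok, ] <- 0
  } else {
    # unit gradient scaled by bound fraction, with a relative-gradient
    # detectability floor across the cell body
    rel <- gn * cfg$cell_diameter / (cv + 1e-300)
    ok <- is.finite(gn) & gn > 1e-300 & rel >= cfg$grad_detect
    unit_g <- matrix(0, n, 3L)
    unit_g[ok, ] <- gv[ok, , drop = FALSE] / gn[ok]
    bias <- cfg$chi * occupancy * unit_g
  }
  new_ori <- normalize_rows(cfg$persistence * ori + random_unit_vectors(n) + bias)
  v <- stats::rgamma(n, shape = 4, scale = cfg$v_mean / 4) / 60  # um/s
  new_pos <- pos + new_ori * (v * cfg$dt)
  if (is.null(bounds))
    bounds <- rbind(grid$origin, grid$origin + grid$shape * grid$spacing)
  reflect_bounds(new_pos, new_ori, bounds[1, ], bounds[2, ])
}

# Build and relax the chemokine field implied by a configuration.
build_field <- function(cfg, net) {
  fp <- field_params(D = cfg$D, lam = cfg$lam, k_on_ecm = cfg$k_on_ecm,
                     k_off_ecm = cfg$k_off_ecm,
                     secretion_fdc = cfg$secretion_fdc,
                     secretion_rc = cfg$secretion_rc)
  grid <- chemokine_grid(net$bounds, spacing = cfg$spacing, params = fp,
                         boundary = cfg$boundary, ecm_pool = cfg$ecm_pool)
  grid <- rasterize_sources(net, grid)  # subtype rates from the config
  run_to_steady_state(grid)
}

#' Run the agent-based B-cell migration simulation
#'
#' Relaxes the chemokine field to steady state (unless a converged `grid` is
#' supplied), seeds `n_cells` agents uniformly within the follicle region,
#' and steps receptor kinetics and biased persistent random-walk motility for
#' `duration` seconds. A stromal contact is recorded the first time a cell
#' center comes within `contact_radius` of a node (including at t = 0).
#' Inside the loop receptor kinetics use an unconditionally stable update
#' (exact exponential relaxation of the fast binding pair, explicit Euler for
#' the slow internalization/recycling rates), so arbitrarily high local
#' concentrations do not constrain the motility time step.
#'
#' @param config a [simulation_config()].
#' @param net a [reticular_network()].
#' @param grid optional pre-converged [chemokine_grid()] matching `config`.
#' @return list of class `bcell_tracks`: per-cell track objects (`cell_id`,
#'   `t`, `pos`, `receptors`, `contacts` data.frame) with the run settings
#'   attached as attributes.
#' @export
run_simulation <- function(config, net, grid = NULL) {
  cfg <- config
  if (is.null(grid)) grid <- build_field(cfg, net)
  vol <- grid$spacing^3
  n <- cfg$n_cells
  n_steps <- floor(cfg$duration / cfg$dt)
  npos <- as.matrix(net$nodes[, c("x", "y", "z")])
  dom <- net$bounds
  lo <- dom[1, ]; hi <- dom[2, ]
  ctr <- (lo + hi) / 2
  r_start <- cfg$start_radius %||%
    (max(sqrt((npos[, 1] - ctr[1])^2 + (npos[, 2] - ctr[2])^2)) +
       cfg$contact_radius)
  grad <- field_gradient(grid, cfg$sense)
  conc <- grad$value / vol

  if (n_steps == 0L) {
    tracks <- lapply(seq_len(n), function(ci)
      list(cell_id = ci, t = numeric(0),
           pos = matrix(numeric(0), ncol = 3L),
           receptors = matrix(numeric(0), ncol = 3L),
           contacts = data.frame(node_id = integer(0), t = numeric(0))))
    return(structure(tracks, class = "bcell_tracks", duration = 0,
                     dt = cfg$dt * cfg$save_every, n_nodes = nrow(npos),
                     config = cfg))
  }

  with_seed(cfg$seed, {
    rr <- sqrt(stats::runif(n)) * r_start
    th <- stats::runif(n, 0, 2 * pi)
    pos <- cbind(pmin(pmax(ctr[1] + rr * cos(th), lo[1]), hi[1]),
                 pmin(pmax(ctr[2] + rr * sin(th), lo[2]), hi[2]),
                 stats::runif(n, lo[3], hi[3]))
    ori <- random_unit_vectors(n)
    rec <- cbind(rep(cfg$R_total, n), 0, 0)

    n_rec <- n_steps %/% cfg$save_every + 1L
    pos_hist <- array(NA_real_, c(n_rec, n, 3L))
    rec_hist <- array(NA_real_, c(n_rec, n, 3L))
    t_hist <- numeric(n_rec)
    seen <- matrix(FALSE, n, nrow(npos))
    contacts <- vector("list", n)

    log_contacts <- function(pos, t) {
      d2 <- outer(rowSums(pos^2), rowSums(npos^2), "+") -
        2 * pos %*% t(npos)
      hit <- d2 <= cfg$contact_radius^2 & !seen
      if (any(hit)) {
        w <- which(hit, arr.ind = TRUE)
        for (ci in unique(w[, 1])) {
          nd <- w[w[, 1] == ci, 2]
          contacts[[ci]] <<- rbind(contacts[[ci]],
                                   data.frame(node_id = net$nodes$id[nd], t = t))
        }
        seen[hit] <<- TRUE
      }
    }

    pos_hist[1, , ] <- pos; rec_hist[1, , ] <- rec; t_hist[1] <- 0
    log_contacts(pos, 0)

    {
      ri <- 1L
      for (s in seq_len(n_steps)) {
        c_local <- interp_field(grad$value, grid, pos) / vol
        rec <- receptor_advance(rec, c_local, cfg$dt, cfg)
        if (cfg$consumption) {
          idx <- position_to_voxel(grid, pos)
          flat <- idx[, 1] + grid$shape[1] * (idx[, 2] - 1L) +
            grid$shape[1] * grid$shape[2] * (idx[, 3] - 1L)
          take <- pmin(cfg$k_i * rec[, 2] * cfg$dt, grid$soluble[flat])
          grid$soluble[flat] <- pmax(0, grid$soluble[flat] - take)
          grad <- field_gradient(grid, cfg$sense)
        }
        occ_w <- if (cfg$sensing == "occupancy_difference")
          (rec[, 1] + rec[, 2]) / cfg$R_total    # surface-receptor fraction
        else rec[, 2] / cfg$R_total              # bound fraction
        mv <- motility_step(pos, ori, grid, occ_w, cfg,
                            gradient = grad, bounds = dom)
        pos <- mv$pos; ori <- mv$ori
        t_now <- s * cfg$dt
        log_contacts(pos, t_now)
        if (s %% cfg$save_every == 0L) {
          ri <- ri + 1L
          pos_hist[ri, , ] <- pos; rec_hist[ri, , ] <- rec
          t_hist[ri] <- t_now
        }
      }
    }

    tracks <- lapply(seq_len(n), function(ci) {
      list(cell_id = ci, t = t_hist,
           pos = pos_hist[, ci, , drop = TRUE],
           receptors = rec_hist[, ci, , drop = TRUE],
           contacts = contacts[[ci]] %||%
             data.frame(node_id = integer(0), t = numeric(0)))
    })
    structure(tracks, class = "bcell_tracks",
              duration = cfg$duration, dt = cfg$dt * cfg$save_every,
              n_nodes = nrow(net$nodes), config = cfg)
  })
}

#' Write tracks and contacts as CSV
#'
#' @param tracks a `bcell_tracks` object.
#' @param track_path,contact_path output CSV paths (either may be `NULL`).
#' @export
write_tracks <- function(tracks, track_path = NULL, contact_path = NULL) {
  if (!is.null(track_path)) {
    tab <- do.call(rbind, lapply(tracks, function(tr)
      data.frame(cell_id = tr$cell_id, t = tr$t,
                 x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3],
                 R_free = tr$receptors[, 1], R_bound = tr$receptors[, 2],
                 R_internal = tr$receptors[, 3])))
    utils::write.csv(tab, track_path, row.names = FALSE)
  }
  if (!is.null(contact_path)) {
    tab <- do.call(rbind, lapply(tracks, function(tr)
      if (nrow(tr$contacts))
        data.frame(cell_id = tr$cell_id, tr$contacts) else NULL))
    if (is.null(tab))
      tab <- data.frame(cell_id = integer(0), node_id = integer(0),
                        t = numeric(0))
    utils::write.csv(tab, contact_path, row.names = FALSE)
  }
  invisible(tracks)
}
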