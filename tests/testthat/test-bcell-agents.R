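# algebraic steady state of the three-pool receptor system at constant c
receptor_equilibrium <- function(cfg, c_local) {
  konc <- cfg$k_on * c_local
  # solve M r = 0 with conservation r1 + r2 + r3 = R_total
  M <- rbind(c(-konc, cfg$k_off, cfg$k_re),
             c(konc, -(cfg$k_off + cfg$k_i), 0),
             c(1, 1, 1))
  drop(solve(M, c(0, 0, cfg$R_total)))
}

test_that("receptor kinetics conserve totals and reach the algebraic equilibrium", {
  cfg <- simulation_config()
  s0 <- c(cfg$R_total, 0, 0)
  # c = 0 with empty bound/internal pools is a fixed point
  expect_equal(receptor_step(s0, 0, 1, cfg), s0)

  # long-run explicit Euler matches the 3x3 linear-system steady state
  c_loc <- 3e-4
  s <- s0
  for (i in 1:40000) s <- receptor_step(s, c_loc, 0.5, cfg)
  expect_equal(s, receptor_equilibrium(cfg, c_loc), tolerance = 1e-5)
  expect_equal(sum(s), cfg$R_total, tolerance = 1e-9)

  # k_i = k_re = 0: two-pool detailed balance R_b / R_f = k_on c / k_off
  cfg2 <- simulation_config(k_i = 0, k_re = 0)
  s <- c(cfg2$R_total, 0, 0)
  for (i in 1:20000) s <- receptor_step(s, c_loc, 0.5, cfg2)
  expect_equal(s[2] / s[1], cfg2$k_on * c_loc / cfg2$k_off, tolerance = 1e-6)

  # step-size guard
  expect_error(receptor_step(s0, 1, 100, cfg), class = "follisim_step_size")

  # the fast in-loop update agrees with explicit Euler as dt -> 0
  st <- matrix(c(8000, 1500, 500), 1)
  euler <- st
  for (i in 1:2000) euler <- receptor_step(euler, c_loc, 0.0025, cfg)
  fast <- st
  for (i in 1:10) fast <- follisim:::receptor_advance(fast, c_loc, 0.5, cfg)
  expect_equal(as.numeric(fast), as.numeric(euler), tolerance = 5e-3)
  expect_equal(sum(fast), sum(st), tolerance = 1e-12)
})

test_that("receptor totals are conserved along every simulated track", {
  net <- default_net()
  fields <- model_fields()
  sim <- fields[[1]]$sim; sim$seed <- 9; sim$n_cells <- 5; sim$duration <- 600
  tracks <- run_simulation(sim, net, grid = fields[[1]]$grid)
  for (tr in tracks) {
    tot <- rowSums(tr$receptors)
    expect_lt(max(abs(tot - sim$R_total)) / sim$R_total, 1e-9)
  }
})

test_that("unbiased motility is symmetric and persistence straightens paths", {
  g <- chemokine_grid(c(2000, 2000, 2000), spacing = 100,
                      params = field_params(secretion_fdc = 0, secretion_rc = 0))
  cfg <- simulation_config(chi = 0, persistence = 4, v_mean = 6)
  set.seed(21)
  n <- 1000
  pos <- matrix(1000, n, 3)
  ori <- follisim:::random_unit_vectors(n)
  p0 <- pos
  for (i in 1:20) {
    mv <- motility_step(pos, ori, g, rep(0, n), cfg)
    pos <- mv$pos; ori <- mv$ori
  }
  drift <- colMeans(pos - p0)
  step_sd <- apply(pos - p0, 2, sd)
  expect_true(all(abs(drift) < 3.5 * step_sd / sqrt(n)))

  # persistence -> infinity: nearly straight motion (meandering -> 1)
  cfg_straight <- simulation_config(chi = 0, persistence = 1e6, v_mean = 6)
  set.seed(22)
  pos <- matrix(1000, 50, 3); ori <- follisim:::random_unit_vectors(50)
  path <- 0; start <- pos
  for (i in 1:40) {
    mv <- motility_step(pos, ori, g, rep(0, 50), cfg_straight)
    path <- path + sqrt(rowSums((mv$pos - pos)^2))
    pos <- mv$pos; ori <- mv$ori
  }
  mi <- sqrt(rowSums((pos - start)^2)) / path
  expect_gt(min(mi), 0.99)
})

test_that("occupied cells drift up a detectable linear gradient", {
  g <- chemokine_grid(c(3000, 1000, 1000), spacing = 100,
                      params = field_params(secretion_fdc = 0, secretion_rc = 0))
  co <- expand.grid(i = seq_len(g$shape[1]), j = seq_len(g$shape[2]),
                    k = seq_len(g$shape[3]))
  drift_cos <- function(cfg, field_scale) {
    g$soluble <- array(field_scale * co$i, dim = g$shape)  # ramp along +x
    set.seed(23)
    n <- 500
    pos <- cbind(rep(400, n), rep(500, n), rep(500, n))
    ori <- follisim:::random_unit_vectors(n)
    p0 <- pos
    for (i in 1:30) {
      mv <- motility_step(pos, ori, g, rep(1, n), cfg)
      pos <- mv$pos; ori <- mv$ori
    }
    drift <- colMeans(pos - p0)
    drift[1] / sqrt(sum(drift^2))
  }
  # occupancy-scaled unit-gradient sensing
  expect_gt(drift_cos(simulation_config(chi = 10, persistence = 1, v_mean = 6,
                                        sensing = "occupancy_scaled"), 5), 0.5)
  # occupancy-difference sensing: concentrations around K = k_off/k_on
  expect_gt(drift_cos(simulation_config(chi = 10, persistence = 1, v_mean = 6),
                      200), 0.5)
})

test_that("a persistent random walk reproduces the analytic motility coefficient", {
  # Fuerth relation: M = <v^2> tau_p / dim, with tau_p from the mean turn
  # cosine of the orientation update (independent quadrature oracle)
  cfg <- simulation_config(chi = 0, persistence = 6, v_mean = 8,
                           duration = 3600, n_cells = 150, dt = 5,
                           secretion_fdc = 0, secretion_rc = 0, lam = 1e-3,
                           seed = 31)
  nodes <- data.frame(id = 1, x = 5000, y = 5000, z = 5000, subtype = "FDC",
                      secretion_rate = 0)
  net <- reticular_network(nodes, NULL, rbind(c(0, 0, 0), c(10000, 10000, 10000)))
  cfg$spacing <- 500; cfg$start_radius <- 100
  tracks <- run_simulation(cfg, net)
  s <- summarize_tracks(tracks, dt_sample = 30)

  # discrete-time correlated walk, exact finite-lag MSD:
  #   MSD(n) = dt^2 [ n E[v^2] + 2 E[v]^2 (n a/(1-a) - a(1-a^n)/(1-a)^2) ]
  # with a = E[cos(turn angle)] from quadrature over the orientation update;
  # the oracle pushes this through the same OLS-through-origin estimator
  kappa <- cfg$persistence
  a <- stats::integrate(function(u) (kappa + u) / sqrt(1 + kappa^2 + 2 * kappa * u),
                        -1, 1)$value / 2
  Ev <- cfg$v_mean / 60; Ev2 <- (cfg$v_mean / 60)^2 * 1.25  # um/s, Gamma(4)
  msd_exact <- function(n) cfg$dt^2 *
    (n * Ev2 + 2 * Ev^2 * (n * a / (1 - a) - a * (1 - a^n) / (1 - a)^2))
  n_samples <- cfg$duration / 30
  lags_s <- 30 * seq_len(floor((n_samples) / 4))
  tau <- lags_s
  slope <- sum(tau * msd_exact(lags_s / cfg$dt)) / sum(tau^2)  # um^2/s per s
  M_pred <- slope / 6 * 60                                     # um^2/min
  expect_lt(abs(s$motility_coefficient - M_pred) / M_pred, 0.15)
})

test_that("simulation contracts: empty runs, t = 0 contacts, containment", {
  net <- default_net()
  fields <- model_fields()
  sim <- fields[[1]]$sim

  sim0 <- sim; sim0$duration <- 0; sim0$seed <- 1
  tr0 <- run_simulation(sim0, net, grid = fields[[1]]$grid)
  expect_true(all(vapply(tr0, function(t) length(t$t) == 0, logical(1))))
  expect_true(all(vapply(tr0, function(t) nrow(t$contacts) == 0, logical(1))))

  # stationary cell seeded within contact radius of a node: 1 contact at t = 0
  sim1 <- sim; sim1$n_cells <- 1; sim1$v_mean <- 0; sim1$chi <- 0
  sim1$duration <- 60; sim1$seed <- 2; sim1$start_radius <- 1e-9
  sim1$contact_radius <- 20  # covers the cell's random z within the slab
  node1 <- net$nodes[which.min((net$nodes$x - 250)^2 + (net$nodes$y - 250)^2), ]
  net1 <- net
  net1$nodes <- data.frame(id = 1L, x = 250, y = 250, z = 17.5,
                           subtype = "FDC", secretion_rate = 1)
  net1$edges <- matrix(integer(0), ncol = 2)
  tr1 <- run_simulation(sim1, net1, grid = fields[[1]]$grid)
  expect_identical(nrow(tr1[[1]]$contacts), 1L)
  expect_equal(tr1[[1]]$contacts$t, 0)

  # tracks never escape the domain; runs are seed-reproducible
  sim2 <- sim; sim2$n_cells <- 10; sim2$duration <- 600; sim2$seed <- 3
  tr2 <- run_simulation(sim2, net, grid = fields[[1]]$grid)
  for (tr in tr2) {
    expect_true(all(tr$pos >= rep(net$bounds[1, ], each = nrow(tr$pos))))
    expect_true(all(tr$pos <= rep(net$bounds[2, ], each = nrow(tr$pos))))
  }
  tr2b <- run_simulation(sim2, net, grid = fields[[1]]$grid)
  expect_identical(tr2[[5]]$pos, tr2b[[5]]$pos)
})
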