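test_that("degenerate and invalid synthesis inputs are handled", {
  p <- synthesis_params(n_fdc = 1, n_rc = 0)
  net <- synthesize_follicle_network(p, seed = 1)
  expect_identical(nrow(net$nodes), 1L)
  expect_identical(nrow(net$edges), 0L)
  expect_error(synthesis_params(n_fdc = 0, n_rc = 0),
               class = "follisim_invalid_input")
  expect_error(synthesis_params(shortcut_fraction = 1.5),
               class = "follisim_invalid_input")
  # geometry too sparse to connect: majority disconnected
  expect_error(
    synthesize_follicle_network(
      synthesis_params(n_fdc = 10, n_rc = 10, follicle_radius = 140,
                       connect_radius = 12, connect_decay = 5), seed = 2),
    class = "follisim_synthesis_failure")
})

test_that("generated networks satisfy all structural invariants", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:1000) {
    p <- synthesis_params(
      n_fdc = sample(3:30, 1), n_rc = sample(3:30, 1),
      follicle_radius = runif(1, 40, 110),
      fdc_core_fraction = runif(1, 0.3, 0.8),
      rc_shell_thickness = runif(1, 5, 25),
      connect_radius = runif(1, 15, 50),
      connect_decay = runif(1, 20, 400),
      shortcut_fraction = runif(1, 0, 0.05),
      slab_dims = c(280, 280, 35))
    net <- tryCatch(synthesize_follicle_network(p, seed = i),
                    follisim_synthesis_failure = function(e) NULL)
    if (is.null(net)) next
    n_checked <- n_checked + 1
    # re-validation through the constructor asserts every invariant
    ok_valid <- !inherits(tryCatch(reticular_network(net$nodes, net$edges,
                                                     net$bounds),
                                   error = identity), "error")
    # geometric edges bounded by connect_radius; only shortcuts may exceed it
    len <- follisim:::edge_lengths(net)
    ok_len <- all(len[!net$shortcut] <= p$connect_radius + 1e-9)
    if (!ok_valid || !ok_len) expect_true(FALSE, label = paste("draw", i))
  }
  expect_gt(n_checked, 500)
})

test_that("mean degree is nondecreasing in connect_radius", {
  seeds <- 1:8
  mean_deg <- vapply(c(25, 35, 45), function(cr) {
    mean(vapply(seeds, function(s) {
      p <- synthesis_params(n_fdc = 30, n_rc = 30, follicle_radius = 70,
                            connect_radius = cr, connect_decay = 400,
                            slab_dims = c(220, 220, 35))
      r <- topology_report(synthesize_follicle_network(p, seed = s))
      mean(r$degree_per_node)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_deg) >= 0))
})

test_that("shortcut edges shorten the mean path length", {
  seeds <- 1:8
  L_of <- function(sf) mean(vapply(seeds, function(s) {
    p <- synthesis_params(shortcut_fraction = sf)
    topology_report(synthesize_follicle_network(p, seed = s))$L
  }, numeric(1)))
  expect_lt(L_of(0.05), L_of(0))
})

test_that("default calibrated parameters reproduce the measured topology", {
  stats <- vapply(1:25, function(s) {
    r <- topology_report(synthesize_follicle_network(seed = s))
    c(r$n_nodes, r$n_edges, r$C_local, r$C_global, r$L)
  }, numeric(5))
  m <- rowMeans(stats)
  expect_equal(m[1], 198)
  expect_lt(abs(m[2] - 1163), 242)     # published SD band
  expect_lt(abs(m[3] - 0.60), 0.04)
  expect_lt(abs(m[4] - 0.57), 0.04)
  expect_lt(abs(m[5] - 4.17), 0.26)
})

test_that("calibration recovers the statistics of a known generator family", {
  truth <- synthesis_params(n_fdc = 28, n_rc = 32, follicle_radius = 80,
                            connect_radius = 30, connect_decay = 300,
                            shortcut_fraction = 0.01,
                            slab_dims = c(220, 220, 35))
  tgt_stats <- follisim:::generator_stats(truth, 1:12)
  target <- list(n_nodes = 60, n_edges = tgt_stats[["n_edges"]],
                 C_local = tgt_stats[["C_local"]],
                 C_global = tgt_stats[["C_global"]], L = tgt_stats[["L"]])
  base <- truth
  base$connect_radius <- 20; base$connect_decay <- 50
  cal <- suppressWarnings(
    calibrate_generator(target, search_budget = 40, seed = 5, n_seeds = 8,
                        base = base))
  rel <- abs(cal$achieved[c("n_edges", "C_local", "C_global", "L")] -
               unlist(target[-1])) / unlist(target[-1])
  expect_true(all(rel < 0.10))

  bad <- target; bad$n_edges <- 60 * 59   # > n(n-1)/2
  expect_error(calibrate_generator(bad, 10, seed = 1),
               class = "follisim_invalid_target")
})
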