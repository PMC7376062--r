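test_that("clustering and path length match hand-enumerated small graphs", {
  tri <- topology_report(triangle_net())
  expect_equal(tri$C_local, 1.0)
  expect_equal(tri$C_global, 1.0)
  expect_equal(tri$L, 1.0)

  star <- topology_report(star_net())
  expect_equal(star$C_local, 0.0)
  expect_equal(star$C_global, 0.0)

  # A-B-C path: pairs at distance 1, 1, 2
  expect_equal(topology_report(path3_net())$L, 4 / 3)

  one <- reticular_network(
    data.frame(id = 1, x = 0, y = 0, z = 0, subtype = "FDC",
               secretion_rate = 0), NULL, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(topology_report(one), class = "follisim_invalid_input")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:6) {
    net <- random_net(n = 10 + 5 * seed, p_edge = 0.12, seed = seed)
    rep0 <- topology_report(net)
    expect_equal(rep0$C_global, oracle_global_clustering(net),
                 tolerance = 1e-12)
    expect_equal(rep0$C_local, oracle_local_clustering(net),
                 tolerance = 1e-12)
    L_fw <- oracle_mean_path(net)
    if (!is.na(L_fw)) expect_equal(rep0$L, L_fw, tolerance = 1e-12)
  }
})

test_that("G(n, m) nulls have exactly m edges, no self loops, and are seeded", {
  for (seed in 1:1000) {
    net <- erdos_renyi_null(20, 30, seed = seed)
    expect_identical(nrow(net$edges), 30L)
    expect_true(all(net$edges[, 1] != net$edges[, 2]))
    expect_false(anyDuplicated(net$edges) > 0)
  }
  expect_equal(erdos_renyi_null(7, 11, seed = 42)$edges,
               erdos_renyi_null(7, 11, seed = 42)$edges)
  # n=3, m=3 forces the triangle
  expect_equal(topology_report(erdos_renyi_null(3, 3, seed = 1))$C_global, 1)
  expect_error(erdos_renyi_null(4, 7, seed = 1),
               class = "follisim_invalid_input")
})

test_that("Watts-Strogatz reference matches lattice closed forms", {
  # p = 0 ring lattice clustering: 3(k-2) / (4(k-1))
  for (k in c(4, 6)) {
    ws <- watts_strogatz_reference(40, k, 0)
    expect_equal(topology_report(ws)$C_local, 3 * (k - 2) / (4 * (k - 1)),
                 tolerance = 1e-12)
  }
  # C10 cycle: mean over the 45 pairs of enumerated distances = 125/45
  expect_equal(topology_report(watts_strogatz_reference(10, 2, 0))$L, 25 / 9)
  # p = 1: clustering falls to the random-graph level ~ k/n
  cl <- vapply(1:100, function(s)
    topology_report(watts_strogatz_reference(100, 4, 1, seed = s))$C_local,
    numeric(1))
  expect_lt(abs(mean(cl) - 4 / 100), 0.03)
  expect_error(watts_strogatz_reference(10, 3, 0),
               class = "follisim_invalid_input")
  expect_error(watts_strogatz_reference(10, 12, 0),
               class = "follisim_invalid_input")
})

test_that("small-world indices behave as expected on reference graphs", {
  er <- erdos_renyi_null(120, 700, seed = 3)
  swi_er <- small_world_indices(er, n_null = 20, seed = 4)
  expect_lt(abs(swi_er$sigma - 1), 0.15)
  expect_lt(abs(swi_er$omega - (1 - swi_er$C / swi_er$C_latt)), 0.1)

  latt <- watts_strogatz_reference(120, 6, 0)
  swi_lat <- small_world_indices(latt, n_null = 20, seed = 5)
  expect_lt(swi_lat$omega, -0.5)                 # lattice-like: strongly negative
  expect_gt(swi_lat$sigma, swi_er$sigma)         # ordering property
})

test_that("subtype comparison separates an FDC hub from peripheral RCs", {
  nodes <- data.frame(id = 1:6, x = c(0, 1, -1, 0, 0, 2), y = c(0, 0, 0, 1, -1, 0),
                      z = 0, subtype = c("FDC", rep("CD21neg_RC", 5)),
                      secretion_rate = 0)
  net <- reticular_network(nodes, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6)),
                           rbind(c(-1, -1, 0), c(2, 1, 1)))
  cmp <- subtype_comparison(net)
  expect_gt(cmp$summary$mean_degree[1], cmp$summary$mean_degree[2])

  allf <- triangle_net()
  expect_error(subtype_comparison(allf),
               class = "follisim_degenerate_comparison")
})

test_that("subtype comparison p-values are near-uniform under the null", {
  set.seed(11)
  pvals <- replicate(300, {
    net <- random_net(n = 40, p_edge = 0.15, seed = sample.int(1e6, 1))
    if (length(unique(net$nodes$subtype)) < 2) return(NA_real_)
    subtype_comparison(net)$p_degree
  })
  pvals <- pvals[!is.na(pvals)]
  # rejection rate at alpha = 0.05 should be near nominal
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_gt(mean(pvals > 0.5), 0.3)
})
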