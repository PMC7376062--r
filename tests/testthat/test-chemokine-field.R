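zero_secretion <- function(...) field_params(secretion_fdc = 0,
                                             secretion_rc = 0, ...)

test_that("source rasterization conserves the total secretion rate", {
  nodes <- data.frame(id = 1:2, x = c(2, 3), y = c(2, 3), z = c(2, 3),
                      subtype = c("FDC", "CD21neg_RC"), secretion_rate = 0)
  net <- reticular_network(nodes, NULL, rbind(c(0, 0, 0), c(20, 20, 20)))
  g <- chemokine_grid(c(20, 20, 20), spacing = 5,
                      params = field_params(secretion_fdc = 3, secretion_rc = 2))
  g <- rasterize_sources(net, g)
  # both nodes fall in the same voxel: rates sum
  expect_equal(max(g$source), 5)
  expect_equal(sum(g$source), 5)

  net2 <- default_net()
  g2 <- rasterize_sources(net2, chemokine_grid(net2$bounds, spacing = 10,
                                               params = field_params()))
  n_fdc <- sum(net2$nodes$subtype == "FDC")
  expect_equal(sum(g2$source), n_fdc * 2 + (198 - n_fdc) * 1,
               tolerance = 1e-12)

  out <- reticular_network(
    data.frame(id = 1, x = 40, y = 40, z = 40, subtype = "FDC",
               secretion_rate = 1), NULL, rbind(c(0, 0, 0), c(50, 50, 50)))
  expect_error(rasterize_sources(out, chemokine_grid(c(20, 20, 20), 5)),
               class = "follisim_out_of_bounds")
})

test_that("explicit stepping conserves mass and matches exponential decay", {
  # pure diffusion, reflective boundary: exact conservation
  g <- chemokine_grid(c(50, 50, 25), spacing = 5,
                      params = zero_secretion(D = 1, lam = 0))
  set.seed(4); g$soluble[] <- runif(length(g$soluble))
  m0 <- total_mass(g)
  dt <- 0.9 * follisim:::stable_dt(g)
  for (i in 1:400) g <- field_step(g, dt)
  expect_lt(abs(total_mass(g) - m0) / m0, 1e-9)
  expect_true(all(g$soluble >= 0))

  # pure decay: total mass follows c0 V exp(-lam t) within 1%
  g <- chemokine_grid(c(20, 20, 20), spacing = 5,
                      params = zero_secretion(D = 0, lam = 0.01))
  g$soluble[] <- 1
  for (i in 1:1000) g <- field_step(g, 0.1)
  expect_lt(abs(total_mass(g) / (64 * exp(-0.01 * 100)) - 1), 0.01)

  expect_error(field_step(g, 1e6), class = "follisim_stability")
})

test_that("nonnegativity holds over many random pre-checked steps", {
  set.seed(7)
  for (cfg in 1:20) {
    p <- field_params(D = runif(1, 0, 2), lam = runif(1, 0, 0.01),
                      k_on_ecm = runif(1, 0, 0.01),
                      k_off_ecm = runif(1, 0, 0.01),
                      secretion_fdc = 0, secretion_rc = 0)
    g <- chemokine_grid(c(30, 30, 15), spacing = 5, params = p,
                        ecm_pool = TRUE)
    g$soluble[] <- runif(length(g$soluble), 0, 5)
    g$immobilized[] <- runif(length(g$immobilized), 0, 5)
    g$source[sample(length(g$source), 4)] <- runif(4, 0, 1)
    dt <- 0.95 * follisim:::stable_dt(g)
    ok <- TRUE
    for (i in 1:5000) {
      g <- field_step(g, dt)
      if (min(g$soluble) < 0 || min(g$immobilized) < 0) { ok <- FALSE; break }
    }
    expect_true(ok)
  }
})

test_that("steady state obeys mass balance, linearity, and the pool ratio", {
  # single source, reflective, no ECM: steady mass = rate / lam
  g <- chemokine_grid(c(100, 100, 35), spacing = 10,
                      params = zero_secretion(D = 0.5, lam = 1e-3))
  g$source[5, 5, 2] <- 2
  gs <- run_to_steady_state(g)
  expect_lt(abs(total_mass(gs) - 2 / 1e-3) / 2e3, 0.01)

  # zero source -> zero field
  g0 <- run_to_steady_state(chemokine_grid(c(50, 50, 20), spacing = 5,
                                           params = zero_secretion(D = 1, lam = 1e-3)))
  expect_equal(total_mass(g0), 0)

  # linearity: field(source A + source B) = field(A) + field(B)
  base <- chemokine_grid(c(100, 100, 35), spacing = 10,
                         params = zero_secretion(D = 0.3, lam = 5e-4))
  ga <- base; ga$source[2, 3, 1] <- 1
  gb <- base; gb$source[8, 7, 3] <- 3
  gab <- base; gab$source <- ga$source + gb$source
  fa <- run_to_steady_state(ga)$soluble
  fb <- run_to_steady_state(gb)$soluble
  fab <- run_to_steady_state(gab)$soluble
  expect_lt(max(abs(fab - (fa + fb))) / max(fab), 1e-6)

  # no loss pathway at all: no steady state exists
  expect_error(
    run_to_steady_state(chemokine_grid(c(50, 50, 20), spacing = 5,
                                       params = zero_secretion(D = 1, lam = 0))),
    class = "follisim_invalid_input")

  # immobilized/soluble steady ratio = k_on / (k_off + lam_immobilized),
  # reached by the dynamic scheme (iterative route, not the direct solve)
  p <- field_params(D = 0.2, lam = 2e-3, k_on_ecm = 5e-3, k_off_ecm = 2e-3,
                    secretion_fdc = 0, secretion_rc = 0)
  g2 <- chemokine_grid(c(40, 40, 20), spacing = 5, params = p, ecm_pool = TRUE)
  g2$source[4, 4, 2] <- 1
  g2 <- run_to_steady_state(g2, tol = 1e-10, max_t = 1e6, method = "iterate")
  sel <- g2$soluble > max(g2$soluble) * 1e-3
  ratio <- g2$immobilized[sel] / g2$soluble[sel]
  expect_equal(mean(ratio), 5e-3 / (2e-3 + 2e-3), tolerance = 1e-3)
})

test_that("a screened point source matches the analytic profile within 5%", {
  # screening length 25 um; compare shell-averaged concentration over
  # r in [3h, 8h] where boundary images are negligible
  p <- zero_secretion(D = 1, lam = 1 / 625)
  g <- chemokine_grid(c(165, 165, 165), spacing = 5, params = p)
  ctr <- 17L
  g$source[ctr, ctr, ctr] <- 1
  g <- run_to_steady_state(g)
  vox <- as.matrix(expand.grid(i = 1:33, j = 1:33, k = 1:33))
  r <- sqrt(rowSums(sweep(vox, 2, c(ctr, ctr, ctr))^2)) * 5
  theory <- 125 / (4 * pi * 1 * r) * exp(-r / 25)
  sel <- r >= 15 & r <= 40
  shell <- cut(r[sel], seq(12.5, 42.5, by = 5))
  obs <- tapply(as.numeric(g$soluble)[sel], shell, mean)
  th <- tapply(theory[sel], shell, mean)
  expect_true(all(abs(obs - th) / th < 0.05))
})

test_that("model parameterizations give equal mass but contrasting structure", {
  net <- default_net()
  fields <- model_fields()
  m1 <- total_mass(fields[[1]]$grid); m2 <- total_mass(fields[[2]]$grid)
  expect_lt(abs(m1 - m2) / m1, 0.01)        # overall concentration fixed
  expect_lt(abs(m1 - 2000) / 2000, 0.01)

  v1 <- var(as.numeric(fields[[1]]$grid$soluble))
  v2 <- var(as.numeric(fields[[2]]$grid$soluble))
  expect_gt(v1, v2)                          # sharp vs homogeneous

  expect_gt(fraction_near_sources(fields[[1]]$grid, 50), 0.8)
  expect_lt(fraction_near_sources(fields[[2]]$grid, 50), 0.5)

  # doubling the reference mass doubles both steady masses
  fp <- model_parameterization(1, 4000)
  g <- rasterize_sources(net, chemokine_grid(net$bounds, spacing = 10,
                                             params = fp))
  expect_lt(abs(total_mass(run_to_steady_state(g)) - 4000) / 4000, 0.01)

  expect_error(model_parameterization(3, 1), class = "follisim_invalid_input")
  expect_error(model_parameterization(1, -5), class = "follisim_invalid_input")
})

test_that("field text serialization round-trips", {
  fields <- model_fields()
  path <- file.path(tempdir(), "field1")
  write_field(fields[[1]]$grid, path)
  back <- read_field(path)
  expect_equal(back$soluble, fields[[1]]$grid$soluble, tolerance = 1e-12)
  expect_equal(back$spacing, fields[[1]]$grid$spacing)
  expect_equal(sum(back$source), sum(fields[[1]]$grid$source))
})
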