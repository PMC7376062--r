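test_that("track ingest enforces length and consecutiveness rules", {
  tab <- rbind(
    data.frame(track_id = 1, frame = 1:6, t = (0:5) / 513,
               x = rnorm(6), y = rnorm(6)),
    data.frame(track_id = 2, frame = 1:4, t = (0:3) / 513,
               x = rnorm(4), y = rnorm(4)),          # too short
    data.frame(track_id = 3, frame = c(1:3, 5:7), t = (0:5) / 513,
               x = rnorm(6), y = rnorm(6)))          # gap
  path <- file.path(tempdir(), "tracks.csv")
  write.csv(tab, path, row.names = FALSE)
  kept <- read_tracks(path)
  expect_setequal(unique(kept$track_id), 1)

  gap <- tab[tab$track_id == 3, ]
  expect_error(track_diffusion(gap), class = "follisim_invalid_input")
  expect_error(track_diffusion(tab[tab$track_id == 2, ]),
               class = "follisim_invalid_input")
})

test_that("diffusion estimates behave on deterministic tracks", {
  still <- data.frame(track_id = 1, frame = 1:10, t = (0:9) / 513,
                      x = 1.5, y = -2)
  D0 <- track_diffusion(still)
  expect_equal(as.numeric(D0), 0)
  expect_false(attr(D0, "super_diffusive"))

  ball <- data.frame(track_id = 1, frame = 1:20, t = (0:19) / 513,
                     x = 5 * (0:19) / 513, y = 0)
  Db <- track_diffusion(ball)
  expect_true(attr(Db, "super_diffusive"))  # MSD ~ v^2 t^2: log-log slope 2
  expect_gt(as.numeric(Db), 0)
})

test_that("simulated ensembles recover the true diffusion coefficient", {
  # frame interval at 513 Hz
  tr <- simulate_tracks(1.0, 5, 10, frame_rate = 513, seed = 20)
  expect_equal(diff(tr$t[1:2]), 1 / 513, tolerance = 1e-12)
  expect_equal(1 / 513, 0.0019493, tolerance = 1e-4)

  # D = 0: per-axis scatter equals the localization precision
  noise <- simulate_tracks(0, 400, 10, sigma_loc = 0.04, seed = 21)
  expect_lt(abs(sd(noise$x) - 0.04) / 0.04, 0.1)

  # ensemble MSD at lag k: 4 D k dt + 4 sigma^2
  tr2 <- simulate_tracks(0.5, 2000, 12, sigma_loc = 0.04, seed = 22)
  dt <- 1 / 513
  for (k in c(1, 3)) {
    msd_k <- mean(vapply(split(tr2, tr2$track_id), function(d) {
      n <- nrow(d) - k
      mean((d$x[seq_len(n) + k] - d$x[seq_len(n)])^2 +
             (d$y[seq_len(n) + k] - d$y[seq_len(n)])^2)
    }, numeric(1)))
    expect_lt(abs(msd_k - (4 * 0.5 * k * dt + 4 * 0.04^2)) /
                (4 * 0.5 * k * dt + 4 * 0.04^2), 0.05)
  }

  # parameter recovery with the noise-floor correction
  tr3 <- simulate_tracks(1.0, 1000, 20, sigma_loc = 0.04, seed = 23)
  D_hat <- track_diffusion_table(tr3, correct_noise = TRUE)$D
  expect_lt(abs(median(D_hat) - 1.0), 0.15)

  expect_error(simulate_tracks(-1, 10, 10), class = "follisim_invalid_input")
})

test_that("estimates are invariant under rotation/translation and unbiased on noise", {
  tr <- simulate_tracks(0.8, 20, 15, seed = 24)
  th <- 1.1
  rot <- tr
  rot$x <- cos(th) * tr$x - sin(th) * tr$y + 12
  rot$y <- sin(th) * tr$x + cos(th) * tr$y - 4
  expect_equal(track_diffusion_table(rot)$D, track_diffusion_table(tr)$D,
               tolerance = 1e-9)

  # stationary molecules: slope estimates are unbiased (noise adds an
  # intercept, not slope), so about half the tracks floor at zero and the
  # median corrected estimate is exactly zero
  noise <- simulate_tracks(0, 10000, 6, sigma_loc = 0.04, seed = 25)
  tab <- track_diffusion_table(noise, correct_noise = TRUE)
  expect_equal(median(tab$D), 0)
  expect_lt(abs(mean(tab$floored) - 0.5), 0.05)
})

test_that("mobility fractions separate the measured soluble/bound conditions", {
  pbs <- track_diffusion_table(simulate_tracks(0.19, 500, 12, seed = 26))$D
  hep <- track_diffusion_table(simulate_tracks(1.6, 500, 12, seed = 27))$D
  rep2 <- mobility_fractions(list(untreated = pbs, heparinase = hep))
  expect_lt(rep2$p_value, 1e-4)
  ratio <- rep2$summary$median_D[2] / rep2$summary$median_D[1]
  expect_lt(abs(ratio - 8.42) / 8.42, 0.2)
  expect_gt(rep2$summary$immobile_fraction[1],
            rep2$summary$immobile_fraction[2])

  allow <- mobility_fractions(list(a = c(0.01, 0.02)), threshold = 0.1)
  expect_equal(allow$summary$immobile_fraction, 1.0)
  expect_true(is.na(allow$p_value))

  # identical distributions: p-values roughly uniform over seeds
  set.seed(28)
  pv <- replicate(200, {
    d <- rnorm(40, 1, 0.2)
    g <- sample(rep(1:2, 20))
    mobility_fractions(split(d, g))$p_value
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.05)
})
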