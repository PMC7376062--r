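# Shared fixtures, built lazily once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small hand-checkable networks ----------------------------------------------

triangle_net <- function() {
  reticular_network(
    data.frame(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1), z = 0,
               subtype = "FDC", secretion_rate = 0),
    rbind(c(1, 2), c(2, 3), c(1, 3)), rbind(c(0, 0, 0), c(1, 1, 1)))
}

star_net <- function() {
  reticular_network(
    data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 0, 0, 1), z = 0,
               subtype = "FDC", secretion_rate = 0),
    rbind(c(1, 2), c(1, 3), c(1, 4)), rbind(c(-1, 0, 0), c(1, 1, 1)))
}

path3_net <- function() {
  reticular_network(
    data.frame(id = 1:3, x = c(0, 1, 2), y = 0, z = 0,
               subtype = "FDC", secretion_rate = 0),
    rbind(c(1, 2), c(2, 3)), rbind(c(0, 0, 0), c(2, 1, 1)))
}

random_net <- function(n, p_edge, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  el <- igraph::as_edgelist(g, names = FALSE)
  reticular_network(
    data.frame(id = seq_len(n), x = runif(n), y = runif(n), z = runif(n),
               subtype = sample(c("FDC", "CD21neg_RC"), n, replace = TRUE),
               secretion_rate = 0),
    el, rbind(c(0, 0, 0), c(1, 1, 1)))
}

# brute-force graph oracles ---------------------------------------------------

adjacency_of <- function(net) {
  n <- nrow(net$nodes)
  A <- matrix(0L, n, n)
  idx <- matrix(match(net$edges, net$nodes$id), ncol = 2)
  A[idx] <- 1L; A[idx[, c(2, 1), drop = FALSE]] <- 1L
  A
}

# transitivity from triangle count (trace of A^3) and connected triples
oracle_global_clustering <- function(net) {
  A <- adjacency_of(net)
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(rowSums(A), 2))
  if (triples == 0) return(0)
  3 * triangles / triples
}

# mean local clustering by direct neighborhood counting
oracle_local_clustering <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    d <- length(nb)
    if (d < 2) return(0)
    t <- sum(A[nb, nb]) / 2
    2 * t / (d * (d - 1))
  }, numeric(1)))
}

# Floyd–Warshall mean shortest path on the largest component
oracle_mean_path <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    lower <- nd < D[i, ]
    D[i, lower] <- nd[lower]
  }
  comp_sizes <- rep(0L, n)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[is.finite(D[i, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  if (length(big) < 2) return(NA_real_)
  vals <- D[big, big][upper.tri(D[big, big])]
  mean(vals)
}

# enumeration oracle for the Vargha–Delaney A statistic
oracle_A <- function(x, y) {
  gt <- 0; eq <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi == yj) eq <- eq + 1
  }
  (gt + 0.5 * eq) / (length(x) * length(y))
}

# dense-matrix textbook formula for Moran's I with binary weights (small
# tolerance so lattice distances on a class edge are classified consistently)
oracle_morans_i <- function(values, coords, d_lo, d_hi) {
  z <- values - mean(values)
  Dm <- as.matrix(stats::dist(coords))
  W <- (Dm > d_lo + 1e-6 & Dm <= d_hi + 1e-6) * 1
  (length(z) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# shared simulation fixtures ---------------------------------------------------

default_net <- function() fixture("default_net", function()
  synthesize_follicle_network(seed = 1))

model_fields <- function() fixture("model_fields", function() {
  net <- default_net()
  lapply(1:2, function(m) {
    fp <- model_parameterization(m, 2000,
                                 n_fdc = sum(net$nodes$subtype == "FDC"),
                                 n_rc = sum(net$nodes$subtype != "FDC"))
    sim <- simulation_config(D = fp$D, lam = fp$lam,
                             secretion_fdc = fp$secretion_fdc,
                             secretion_rc = fp$secretion_rc,
                             k_on_ecm = fp$k_on_ecm, k_off_ecm = fp$k_off_ecm)
    list(sim = sim, grid = follisim:::build_field(sim, net))
  })
})

# one scaled-down emulate-then-optimize campaign, shared by the emulator
# fidelity property and the optimization-direction acceptance check
pipeline_config <- function() experiment_config(
  seed = 101, lhc_samples = 120, lhc_replicates = 6,
  sim = simulation_config(n_cells = 16, duration = 1200))

pipeline_result <- function() fixture("pipeline_result", function()
  suppressMessages(run_emulate_optimize(pipeline_config())))
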