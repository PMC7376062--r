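#' Topology metrics for a reticular network
#'
#' Computes node counts, degree and edge-length tables, the mean local
#' clustering coefficient, transitivity, and the mean shortest path length of
#' a reticular network. Local clustering of degree-0/1 nodes is defined as 0
#' and included in the mean. Shortest path lengths are averaged over all
#' (unordered) reachable node pairs; by default paths are computed within the
#' largest connected component, and the fraction of nodes it covers is
#' reported.
#'
#' @param net a [reticular_network()] (>= 2 nodes).
#' @param paths `"lcc"` (default) restricts the path-length average to pairs
#'   within the largest connected component; `"reachable"` averages over all
#'   reachable pairs of the full graph.
#' @return A list of class `topology_report` with elements `n_nodes`,
#'   `n_edges`, `degree_per_node`, `edge_length_per_edge`, `C_local`,
#'   `C_global`, `L`, and `lcc_fraction`.
#' @export
topology_report <- function(net, paths = c("lcc", "reachable")) {
  paths <- match.arg(paths)
  if (!inherits(net, "reticular_network"))
    fs_stop("net must be a reticular_network", "follisim_invalid_input")
  n <- nrow(net$nodes)
  if (n < 2L)
    fs_stop("topology_report needs at least 2 nodes", "follisim_invalid_input")
  g <- network_igraph(net)
  deg <- igraph::degree(g)
  names(deg) <- net$nodes$id
  c_loc <- igraph::transitivity(g, type = "localundirected")
  c_loc[!is.finite(c_loc)] <- 0       # degree < 2 convention
  c_glob <- igraph::transitivity(g, type = "global")
  if (!is.finite(c_glob)) c_glob <- 0 # no connected triples
  comp <- igraph::components(g)
  lcc_id <- which.max(comp$csize)
  if (paths == "lcc") {
    sub <- igraph::induced_subgraph(g, which(comp$membership == lcc_id))
    L <- if (igraph::vcount(sub) > 1L) igraph::mean_distance(sub) else NA_real_
  } else {
    L <- igraph::mean_distance(g, unconnected = TRUE)
  }
  structure(list(
    n_nodes = n,
    n_edges = nrow(net$edges),
    degree_per_node = deg,
    edge_length_per_edge = edge_lengths(net),
    C_local = mean(c_loc),
    C_global = c_glob,
    L = L,
    lcc_fraction = max(comp$csize) / n
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology report\n")
  cat(sprintf("  nodes: %d  edges: %d  (largest component: %.1f%%)\n",
              x$n_nodes, x$n_edges, 100 * x$lcc_fraction))
  cat(sprintf("  mean degree: %.2f  mean edge length: %.2f um\n",
              mean(x$degree_per_node),
              if (length(x$edge_length_per_edge)) mean(x$edge_length_per_edge) else NA))
  cat(sprintf("  C_local: %.3f  C_global: %.3f  L: %.3f hops\n",
              x$C_local, x$C_global, x$L))
  invisible(x)
}

# Wrap an igraph graph as a geometry-less reticular_network (placeholder
# coordinates at the origin of a unit box).
graph_as_network <- function(g) {
  n <- igraph::vcount(g)
  nodes <- data.frame(id = seq_len(n), x = 0, y = 0, z = 0,
                      subtype = "FDC", secretion_rate = 0)
  el <- igraph::as_edgelist(g, names = FALSE)
  reticular_network(nodes, el, rbind(c(0, 0, 0), c(1, 1, 1)))
}

#' Erdős–Rényi G(n, m) null network
#'
#' Uniformly random simple graph with exactly `n` nodes and `m` edges, the
#' "equivalent random network with the same number of nodes and edges" used as
#' the null model for small-world analysis. Positions are placeholders.
#'
#' @param n node count.
#' @param m edge count, `0 <= m <= n(n-1)/2`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a `reticular_network` without meaningful geometry.
#' @export
erdos_renyi_null <- function(n, m, seed = NULL) {
  if (n < 1 || m < 0 || m > n * (n - 1) / 2)
    fs_stop("require 0 <= m <= n(n-1)/2", "follisim_invalid_input")
  g <- with_seed(seed, igraph::sample_gnm(n, m))
  graph_as_network(g)
}

#' Watts–Strogatz small-world reference network
#'
#' Ring lattice over `n` nodes in which each node connects to its `k` nearest
#' neighbors; each lattice edge is rewired with probability `p` (the far
#' endpoint is redrawn uniformly), keeping the graph simple.
#'
#' @param n node count.
#' @param k even neighbor count, `k < n`.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a `reticular_network` without meaningful geometry.
#' @export
watts_strogatz_reference <- function(n, k, p, seed = NULL) {
  if (k %% 2 != 0 || k >= n || k < 0 || p < 0 || p > 1)
    fs_stop("require even k < n and p in [0, 1]", "follisim_invalid_input")
  with_seed(seed, {
    adj <- matrix(FALSE, n, n)
    for (j in seq_len(k / 2)) {
      tgt <- ((seq_len(n) - 1L + j) %% n) + 1L
      adj[cbind(seq_len(n), tgt)] <- TRUE
      adj[cbind(tgt, seq_len(n))] <- TRUE
    }
    if (p > 0) {
      for (i in seq_len(n)) for (j in seq_len(k / 2)) {
        tgt <- ((i - 1L + j) %% n) + 1L
        if (!adj[i, tgt]) next       # already rewired away
        if (stats::runif(1) < p) {
          free <- which(!adj[i, ] & seq_len(n) != i)
          if (length(free)) {
            new <- free[sample.int(length(free), 1L)]
            adj[i, tgt] <- adj[tgt, i] <- FALSE
            adj[i, new] <- adj[new, i] <- TRUE
          }
        }
      }
    }
    el <- which(adj & upper.tri(adj), arr.ind = TRUE)
    graph_as_network(igraph::graph_from_edgelist(el, directed = FALSE))
  })
}

#' Small-world indices sigma and omega
#'
#' `sigma = (C / C_rand) / (L / L_rand)` and
#' `omega = L_rand / L - C / C_latt`, where `C` is the mean local clustering
#' coefficient, `L` the mean shortest path length (largest component),
#' `C_rand`/`L_rand` are means over `n_null` Erdős–Rényi G(n, m) nulls with
#' matched node and edge counts, and `C_latt` is the clustering of the ring
#' lattice whose even degree matches the network's mean degree (rounded down
#' to even). `sigma > 1` and `omega` near 0 indicate small-world structure.
#'
#' @param net a `reticular_network`.
#' @param n_null number of random nulls (>= 1).
#' @param seed integer seed for the null draws.
#' @return list with `sigma`, `omega`, the ingredient statistics, and
#'   `n_resampled` (disconnected nulls that were redrawn).
#' @export
small_world_indices <- function(net, n_null = 100, seed = NULL) {
  if (n_null < 1) fs_stop("n_null must be >= 1", "follisim_invalid_input")
  rep0 <- topology_report(net)
  n <- rep0$n_nodes; m <- rep0$n_edges
  seeds <- derive_seeds(seed %||% 1L, n_null)
  C_rand <- L_rand <- numeric(n_null)
  n_resampled <- 0L
  for (i in seq_len(n_null)) {
    nul <- erdos_renyi_null(n, m, seeds[i])
    r <- topology_report(nul)
    tries <- 0L
    while (r$lcc_fraction < 1 && tries < 25L) {
      n_resampled <- n_resampled + 1L; tries <- tries + 1L
      nul <- erdos_renyi_null(n, m, seeds[i] + tries * 77003L)
      r <- topology_report(nul)
    }
    C_rand[i] <- r$C_local; L_rand[i] <- r$L
  }
  k_latt <- max(2L, 2L * (floor(mean(rep0$degree_per_node)) %/% 2L))
  latt <- topology_report(watts_strogatz_reference(n, k_latt, 0))
  sigma <- (rep0$C_local / mean(C_rand)) / (rep0$L / mean(L_rand))
  omega <- mean(L_rand) / rep0$L - rep0$C_local / latt$C_local
  list(sigma = sigma, omega = omega,
       C = rep0$C_local, L = rep0$L,
       C_rand = mean(C_rand), L_rand = mean(L_rand),
       C_latt = latt$C_local, k_latt = k_latt, n_resampled = n_resampled)
}

#' Compare topology between FDC and CD21- RC subtypes
#'
#' Per-subtype summaries of node degree and mean incident edge length, with a
#' two-sample Wilcoxon rank-sum comparison per metric (the network-level
#' analogue of the observation that FDCs carry higher degree centralities and
#' edge lengths than CD21- RCs).
#'
#' @param net a `reticular_network` containing both subtypes.
#' @return list with a per-subtype `summary` data.frame and `p_degree`,
#'   `p_edge_length`.
#' @export
subtype_comparison <- function(net) {
  sub <- net$nodes$subtype
  if (length(unique(sub)) < 2L)
    fs_stop("both subtypes must be present for a comparison",
            "follisim_degenerate_comparison")
  rep0 <- topology_report(net)
  deg <- rep0$degree_per_node
  len <- rep0$edge_length_per_edge
  # mean incident edge length per node
  inc <- vapply(seq_len(nrow(net$nodes)), function(i) {
    id <- net$nodes$id[i]
    hit <- net$edges[, 1] == id | net$edges[, 2] == id
    if (any(hit)) mean(len[hit]) else NA_real_
  }, numeric(1))
  fdc <- sub == "FDC"
  smry <- data.frame(
    subtype = c("FDC", "CD21neg_RC"),
    n = c(sum(fdc), sum(!fdc)),
    mean_degree = c(mean(deg[fdc]), mean(deg[!fdc])),
    median_degree = c(stats::median(deg[fdc]), stats::median(deg[!fdc])),
    mean_edge_length = c(mean(inc[fdc], na.rm = TRUE),
                         mean(inc[!fdc], na.rm = TRUE)))
  p_deg <- stats::wilcox.test(deg[fdc], deg[!fdc], exact = FALSE)$p.value
  p_len <- if (sum(!is.na(inc[fdc])) > 0 && sum(!is.na(inc[!fdc])) > 0)
    stats::wilcox.test(inc[fdc], inc[!fdc], exact = FALSE)$p.value else NA_real_
  list(summary = smry, p_degree = p_deg, p_edge_length = p_len)
}
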