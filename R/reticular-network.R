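#' Reticular network container
#'
#' A spatial undirected graph of CXCL13-producing follicular stromal cells.
#' Nodes are follicular dendritic cells (`"FDC"`) or CD21/35-negative
#' reticular cells (`"CD21neg_RC"`) with 3D positions in micrometres and a
#' per-cell chemokine secretion rate; edges are physical connections between
#' neighboring cells.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`, `z`
#'   (µm), `subtype` (`"FDC"` or `"CD21neg_RC"`) and `secretion_rate`
#'   (amount s^-1, >= 0).
#' @param edges two-column integer matrix of node ids (unordered pairs).
#' @param bounds 2 x 3 matrix; row 1 = lower corner, row 2 = upper corner (µm).
#' @return An object of class `reticular_network`.
#' @export
reticular_network <- function(nodes, edges, bounds) {
  nodes <- as.data.frame(nodes)
  required <- c("id", "x", "y", "z", "subtype", "secretion_rate")
  if (!all(required %in% names(nodes)))
    fs_stop(paste("nodes must have columns:", paste(required, collapse = ", ")),
            "follisim_invalid_input")
  if (nrow(nodes) == 0L)
    fs_stop("network must contain at least one node", "follisim_invalid_input")
  if (anyDuplicated(nodes$id))
    fs_stop("duplicate node ids", "follisim_invalid_input")
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(pos)))
    fs_stop("node positions must be finite", "follisim_invalid_input")
  if (!all(nodes$subtype %in% c("FDC", "CD21neg_RC")))
    fs_stop("subtype must be 'FDC' or 'CD21neg_RC'", "follisim_invalid_input")
  if (any(nodes$secretion_rate < 0))
    fs_stop("secretion_rate must be >= 0", "follisim_invalid_input")
  bounds <- matrix(as.numeric(bounds), nrow = 2L)
  eps <- 1e-9
  inb <- pos[, 1] >= bounds[1, 1] - eps & pos[, 1] <= bounds[2, 1] + eps &
         pos[, 2] >= bounds[1, 2] - eps & pos[, 2] <= bounds[2, 2] + eps &
         pos[, 3] >= bounds[1, 3] - eps & pos[, 3] <= bounds[2, 3] + eps
  if (!all(inb))
    fs_stop("all node positions must lie inside bounds", "follisim_invalid_input")

  shortcut <- attr(edges, "shortcut")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2]))
      fs_stop("self-loops are not allowed", "follisim_invalid_input")
    if (!all(edges %in% nodes$id))
      fs_stop("edge endpoint not present among node ids", "follisim_invalid_input")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges))
      fs_stop("duplicate edges are not allowed", "follisim_invalid_input")
  }
  structure(
    list(nodes = nodes, edges = edges, bounds = bounds,
         shortcut = shortcut %||% rep(FALSE, nrow(edges))),
    class = "reticular_network")
}

#' @export
print.reticular_network <- function(x, ...) {
  cat("Reticular network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  FDC:", sum(x$nodes$subtype == "FDC"),
      " CD21neg RC:", sum(x$nodes$subtype == "CD21neg_RC"), "\n")
  cat(sprintf("  bounds: [%g, %g] x [%g, %g] x [%g, %g] um\n",
              x$bounds[1, 1], x$bounds[2, 1], x$bounds[1, 2],
              x$bounds[2, 2], x$bounds[1, 3], x$bounds[2, 3]))
  invisible(x)
}

# igraph view of the network (vertex order = row order of $nodes).
network_igraph <- function(net) {
  el <- matrix(match(net$edges, net$nodes$id), ncol = 2L)
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < nrow(net$nodes))
      igraph::add_vertices(g, nrow(net$nodes) - igraph::vcount(g)) else g)()
}

# Euclidean edge lengths (µm) in edge order.
edge_lengths <- function(net) {
  if (!nrow(net$edges)) return(numeric(0))
  pos <- as.matrix(net$nodes[, c("x", "y", "z")])
  i <- match(net$edges[, 1], net$nodes$id)
  j <- match(net$edges[, 2], net$nodes$id)
  sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
}

#' Read or write reticular networks
#'
#' Networks interchange as GraphML (node attributes `x`, `y`, `z`, `subtype`,
#' `secretion_rate`) or as a JSON dialect
#' `{"nodes": [...], "edges": [[id, id], ...], "bounds": [...]}`.
#'
#' @param net a `reticular_network`.
#' @param path file path; `write_network` dispatches on the `.graphml` /
#'   `.json` extension.
#' @return `read_network` returns a `reticular_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- network_igraph(net)
    igraph::V(g)$x <- net$nodes$x
    igraph::V(g)$y <- net$nodes$y
    igraph::V(g)$z <- net$nodes$z
    igraph::V(g)$subtype <- net$nodes$subtype
    igraph::V(g)$secretion_rate <- net$nodes$secretion_rate
    igraph::V(g)$node_id <- net$nodes$id
    g$bounds <- paste(as.numeric(net$bounds), collapse = " ")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    obj <- list(nodes = net$nodes,
                edges = unname(split(net$edges, row(net$edges))),
                bounds = as.numeric(net$bounds))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
      id = as.integer(igraph::V(g)$node_id),
      x = igraph::V(g)$x, y = igraph::V(g)$y, z = igraph::V(g)$z,
      subtype = igraph::V(g)$subtype,
      secretion_rate = igraph::V(g)$secretion_rate)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(nodes$id[el[, 1]], nodes$id[el[, 2]])
    bounds <- matrix(as.numeric(strsplit(g$bounds, " ")[[1]]), nrow = 2L)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(obj$nodes)
    edges <- if (is.matrix(obj$edges)) obj$edges else
      do.call(rbind, lapply(obj$edges, as.integer))
    bounds <- matrix(as.numeric(obj$bounds), nrow = 2L)
  }
  reticular_network(nodes, edges, bounds)
}
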