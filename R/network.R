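# Road networks: nodes in metres on the analysis plane, undirected edges
# with a length and a speed class. Shortest paths are delegated to igraph.

#' Construct a road network
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`
#'   (metres).
#' @param edges data.frame with columns `from`, `to` (node ids),
#'   `length_m` (> 0) and `speed_kmh` (> 0). Edges are undirected.
#' @return object of class `road_network`. Connected components are
#'   recorded in `nodes$component`.
#' @export
road_network <- function(nodes, edges) {
  need_n <- c("id", "x", "y")
  need_e <- c("from", "to", "length_m", "speed_kmh")
  if (!all(need_n %in% names(nodes)))
    stop_invalid("nodes need columns %s", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop_invalid("edges need columns %s", paste(need_e, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop_invalid("duplicate node ids")
  if (nrow(edges) > 0) {
    if (any(edges$length_m <= 0)) stop_invalid("edge lengths must be > 0")
    if (any(edges$speed_kmh <= 0)) stop_invalid("edge speeds must be > 0")
    if (!all(c(edges$from, edges$to) %in% nodes$id))
      stop_invalid("edge endpoints must be node ids")
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  nodes$component <- as.integer(igraph::components(g)$membership)
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$component)))
  if (nrow(x$edges))
    cat(sprintf("  speeds: %s km/h\n",
                paste(sort(unique(x$edges$speed_kmh)), collapse = ", ")))
  invisible(x)
}

# igraph object with edge weights in minutes at the given speed multiplier.
network_graph_minutes <- function(network, multiplier = 1) {
  e <- network$edges
  w <- (e$length_m / 1000) / (e$speed_kmh * multiplier) * 60
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$id)))
  igraph::E(g)$weight <- w
  g
}

# Nearest network node for each query point (Euclidean), ties broken by the
# lowest node id. Chunked so the point-by-node distance matrix stays small.
nearest_nodes <- function(network, px, py, chunk = 2048L) {
  nx <- network$nodes$x
  ny <- network$nodes$y
  n <- length(px)
  idx <- integer(n)
  dist <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    d2 <- outer(px[s:e], nx, "-")^2 + outer(py[s:e], ny, "-")^2
    # nodes are stored sorted by id, so "first" minimum = lowest id
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1), j)])
  }
  list(node_index = idx, node_id = network$nodes$id[idx], dist_m = dist)
}

#' Regular lattice road network
#'
#' Dense uniform test network: one node per cell of an `n x n` lattice with
#' spacing `spacing_m`, nodes at the lattice cell centres, all edges at one
#' speed. `neighbourhood` controls how well shortest-path distances
#' approximate the Euclidean metric: 4 (axis edges, L1 metric), 8 (plus
#' diagonals) or 16 (plus knight-move edges; the shortest-path unit ball
#' then covers about 97% of the Euclidean disc).
#'
#' @param n nodes per side.
#' @param spacing_m lattice spacing in metres.
#' @param speed_kmh uniform edge speed.
#' @param neighbourhood 4, 8 or 16.
#' @param origin lower-left corner of the covered extent.
#' @return a `road_network` whose nodes sit at the centres of an `n x n`
#'   grid of `spacing_m` cells anchored at `origin`.
#' @export
lattice_network <- function(n, spacing_m, speed_kmh = 60,
                            neighbourhood = c(4, 8, 16), origin = c(0, 0)) {
  neighbourhood <- match.arg(as.character(neighbourhood[1]), c("4", "8", "16"))
  offs <- list(c(1, 0), c(0, 1))
  if (neighbourhood %in% c("8", "16")) offs <- c(offs, list(c(1, 1), c(1, -1)))
  if (neighbourhood == "16")
    offs <- c(offs, list(c(2, 1), c(1, 2), c(2, -1), c(1, -2)))
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))   # i = column, j = row
  nodes <- data.frame(id = seq_len(n * n),
                      x = origin[1] + (ij$i - 0.5) * spacing_m,
                      y = origin[2] + (ij$j - 0.5) * spacing_m)
  node_at <- function(i, j) (j - 1) * n + i
  el <- lapply(offs, function(o) {
    i <- ij$i; j <- ij$j
    ii <- i + o[1]; jj <- j + o[2]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    data.frame(from = node_at(i[ok], j[ok]), to = node_at(ii[ok], jj[ok]),
               length_m = sqrt(sum(o^2)) * spacing_m, speed_kmh = speed_kmh)
  })
  road_network(nodes, do.call(rbind, el))
}

#' Write a road network as GeoJSON LineStrings
#'
#' One feature per edge with `speed_kmh` and `length_m` properties.
#'
#' @param network a `road_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(network, path) {
  nd <- network$nodes
  pos <- function(id) {
    k <- match(id, nd$id)
    c(nd$x[k], nd$y[k])
  }
  feats <- lapply(seq_len(nrow(network$edges)), function(k) {
    e <- network$edges[k, ]
    list(type = "Feature",
         properties = list(speed_kmh = e$speed_kmh, length_m = e$length_m,
                           from = e$from, to = e$to),
         geometry = list(type = "LineString",
                         coordinates = list(pos(e$from), pos(e$to))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
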