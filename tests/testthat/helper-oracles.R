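# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's routing/classification code paths: plain-R Dijkstra,
# exhaustive nearest-node scans, and row-by-row filter loops.

# Single-source shortest-path minutes by plain O(V^2) Dijkstra.
oracle_sssp <- function(network, src_id, multiplier = 1) {
  nodes <- network$nodes
  edges <- network$edges
  n <- nrow(nodes)
  w <- (edges$length_m / 1000) / (edges$speed_kmh * multiplier) * 60
  a <- match(edges$from, nodes$id)
  b <- match(edges$to, nodes$id)
  dist <- rep(Inf, n)
  dist[match(src_id, nodes$id)] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    cand <- ifelse(done, Inf, dist)
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    done[u] <- TRUE
    for (k in which(a == u | b == u)) {
      v <- if (a[k] == u) b[k] else a[k]
      if (dist[u] + w[k] < dist[v]) dist[v] <- dist[u] + w[k]
    }
  }
  dist
}

# Exhaustive travel-time field: per-source Dijkstra runs, nearest node per
# cell by full distance comparison (ties -> lowest node id), straight-line
# access leg.
oracle_field <- function(network, src_ids, grid, multiplier = 1,
                         access_speed_kmh = 30) {
  nodes <- network$nodes
  per_src <- sapply(src_ids, function(s) oracle_sssp(network, s, multiplier))
  node_min <- apply(as.matrix(per_src), 1, min)
  cc <- cell_centres(grid)
  d <- dim(grid$values)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dd <- sqrt((nodes$x - cc$x[i, j])^2 + (nodes$y - cc$y[i, j])^2)
    k <- which(dd == min(dd))
    k <- k[which.min(nodes$id[k])]
    access <- (dd[k] / 1000) / (access_speed_kmh * multiplier) * 60
    out[i, j] <- access + node_min[k]
  }
  out
}

# Random connected road network on [0, extent]^2 with mixed speed classes.
random_network <- function(n_nodes, extent_m, seed) {
  set.seed(seed)
  x <- runif(n_nodes, 0, extent_m)
  y <- runif(n_nodes, 0, extent_m)
  nodes <- data.frame(id = seq_len(n_nodes), x = x, y = y)
  # connect each node to its 3 nearest neighbours, then bridge components
  dmat <- as.matrix(dist(cbind(x, y)))
  diag(dmat) <- Inf
  e <- do.call(rbind, lapply(seq_len(n_nodes), function(i) {
    nb <- order(dmat[i, ])[1:3]
    data.frame(from = i, to = nb)
  }))
  e <- e[e$from < e$to | !paste(e$to, e$from) %in% paste(e$from, e$to), ]
  net <- data.frame(from = pmin(e$from, e$to), to = pmax(e$from, e$to))
  net <- unique(net)
  g <- igraph::graph_from_data_frame(net, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n_nodes)))
  comp <- igraph::components(g)$membership
  while (max(comp) > 1) {
    i <- which(comp == 1)[1]
    j <- which(comp != 1)[which.min(dmat[i, comp != 1])]
    net <- rbind(net, data.frame(from = min(i, j), to = max(i, j)))
    g <- igraph::graph_from_data_frame(net, directed = FALSE,
                                       vertices = data.frame(name = seq_len(n_nodes)))
    comp <- igraph::components(g)$membership
  }
  len <- sqrt((x[net$from] - x[net$to])^2 + (y[net$from] - y[net$to])^2)
  keep <- len > 0
  road_network(nodes, data.frame(from = net$from[keep], to = net$to[keep],
                                 length_m = len[keep],
                                 speed_kmh = sample(c(30, 50, 80, 100),
                                                    sum(keep), replace = TRUE)))
}

# Straight west-east line network: nodes every `step_m`, one speed.
line_network <- function(length_m, step_m, speed_kmh = 60, y = 0) {
  n <- as.integer(length_m / step_m) + 1L
  nodes <- data.frame(id = seq_len(n), x = (seq_len(n) - 1) * step_m, y = y)
  road_network(nodes, data.frame(from = seq_len(n - 1), to = 2:n,
                                 length_m = step_m, speed_kmh = speed_kmh))
}

# Row-by-row reference scan for the registry filters.
oracle_registry_sets <- function(df) {
  keep <- !duplicated(paste(tolower(gsub("\\s+", " ", trimws(df$name))),
                            round(df$x / 100), round(df$y / 100), sep = "|"))
  df <- df[keep, ]
  ct <- c(); ready <- c(); cert <- c()
  for (i in seq_len(nrow(df))) {
    if (df$certified_su[i]) {
      cert <- c(cert, df$id[i])
      ct <- c(ct, df$id[i])          # nesting coercion
      ready <- c(ready, df$id[i])
    } else {
      if (df$ct_procedures[i] >= 3) ct <- c(ct, df$id[i])
      if (df$stroke_ops[i] >= 100) ready <- c(ready, df$id[i])
    }
  }
  list(ct_equipped = sort(unique(ct)), stroke_ready = sort(unique(ready)),
       certified = sort(unique(cert)))
}

# Scalar reference reimplementation of the benefit rule, written from the
# prose definition rather than sharing the package's vectorised code.
oracle_classify <- function(t_ct, t_target, penalty = 0,
                            penalty_affects_reachability = FALSE) {
  eff <- t_ct + penalty
  ct_reach <- if (penalty_affects_reachability) eff <= 60 else t_ct <= 60
  if (t_target > 60) {
    if (ct_reach) return("only_ct_reachable") else return("neither_reachable")
  }
  saving <- t_target - eff
  if (saving >= 30) "high"
  else if (saving >= 20) "medium"
  else if (saving >= 10) "low"
  else "irrelevant"
}

# Small shared synthetic region, built once per test run.
.fixtures <- new.env()
demo_region <- function() {
  if (is.null(.fixtures$region)) {
    spec <- region_spec(extent_m = c(60000, 60000), cell_size_m = 2000,
                        n_urban_centres = 3, total_population = 5e5,
                        n_facilities_by_tier = c(ct_equipped = 20,
                                                 stroke_ready = 8,
                                                 certified = 5),
                        road_grid_spacing_m = 4000, seed = 42)
    .fixtures$region <- generate_region(spec)
    .fixtures$registry <- build_registry(.fixtures$region$facilities)
  }
  list(region = .fixtures$region, registry = .fixtures$registry)
}
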