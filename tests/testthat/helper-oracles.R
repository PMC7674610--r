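# Independent brute-force oracles used to check the package's
# implementations on small cases. These deliberately share no code with R/.

# all permutations of 1..n as a matrix (one per row)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- oracle_perms(n - 1)
  do.call(rbind, lapply(1:n, function(k) cbind(k, p + (p >= k))))
}

# two-sided Spearman permutation p by full enumeration
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  P <- oracle_perms(length(y))
  rhos <- apply(P, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# edge betweenness by explicit enumeration of all shortest paths
oracle_edge_betweenness <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  adj <- lapply(setNames(nodes, nodes), function(v)
    c(edges$to[edges$from == v], edges$from[edges$to == v]))
  ekey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  eb <- setNames(numeric(nrow(edges)),
                 mapply(ekey, edges$from, edges$to))
  all_paths <- function(from, to, maxlen) {
    # all simple paths of length <= maxlen
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == to) { res[[length(res) + 1]] <<- path; return() }
      if (length(path) > maxlen) return()
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(from)
    res
  }
  dist <- function(from, to) {
    # BFS distance
    seen <- from; frontier <- from; d <- 0
    while (length(frontier)) {
      if (to %in% frontier) return(d)
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, frontier); d <- d + 1
    }
    Inf
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    d <- dist(s, t)
    if (!is.finite(d)) next
    paths <- Filter(function(p) length(p) == d + 1, all_paths(s, t, d + 1))
    for (p in paths)
      for (k in seq_len(length(p) - 1)) {
        key <- ekey(p[k], p[k + 1])
        eb[key] <- eb[key] + 1 / length(paths)
      }
  }
  eb
}

# all set partitions of a vector (Bell-number enumeration)
oracle_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  first <- items[1]
  rest <- oracle_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(first, q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(first), p)
  }
  out
}

# Newman modularity of a partition of an unweighted undirected graph
oracle_modularity <- function(edges, partition) {
  m <- nrow(edges)
  memb <- list()
  for (k in seq_along(partition)) for (v in partition[[k]]) memb[[v]] <- k
  q <- 0
  for (k in seq_along(partition)) {
    inside <- sum(mapply(function(a, b)
      memb[[a]] == k && memb[[b]] == k, edges$from, edges$to))
    deg <- sum(edges$from %in% partition[[k]]) +
           sum(edges$to %in% partition[[k]])
    q <- q + inside / m - (deg / (2 * m))^2
  }
  q
}

# best modularity over all partitions (exhaustive)
oracle_best_partition <- function(edges, nodes) {
  parts <- oracle_partitions(nodes)
  qs <- vapply(parts, function(p) oracle_modularity(edges, p), 0)
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick dish constructor for tests
make_dish <- function(times, cum, sown = 50, viable_ung = NULL, dead = 0,
                      stage = "germination", kind = "temperature",
                      value = 20, id = "d1", replicate = 1) {
  if (is.null(viable_ung)) viable_ung <- sown - max(cum) - dead
  dish_time_course(id, "Test sp.", "A1", "reg", stage, kind, value,
                   times, cum, sown, viable_ung, dead, replicate)
}

# exact Boltzmann curve for generating test data
boltz_curve <- function(t, A2, x0, dx, A1 = 0) {
  A2 + (A1 - A2) / (1 + exp((t - x0) / dx))
}
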