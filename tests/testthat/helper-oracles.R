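# Independent oracles, deliberately written with different algorithms and
# data structures than the package implementation.

# Plain queue-based BFS distances from one source over an adjacency list.
oracle_bfs_dist <- function(adj, nodes, from) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Depth-bounded DFS enumeration of all simple paths of exactly `depth` edges.
oracle_paths_exact <- function(adj, from, to, depth) {
  out <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    d <- length(path) - 1L
    if (v == to && d == depth) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    if (d >= depth) return()
    for (w in setdiff(adj[[v]], path)) recurse(c(path, w))
  }
  recurse(from)
  out
}

# All minimum-length simple paths via the two pieces above.
oracle_min_paths <- function(adj, nodes, from, to) {
  d <- oracle_bfs_dist(adj, nodes, from)[to]
  if (is.infinite(d)) return(list())
  oracle_paths_exact(adj, from, to, as.integer(d))
}

adj_from_edges <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1L]]] <- c(adj[[edges[i, 1L]]], edges[i, 2L])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# Straight-line greedy term selection: recompute gains with set operations
# each round, following the documented rule (coverage ceiling, min_new,
# max_overlap, ties by total term size then id).
oracle_greedy <- function(degs, term_genes, coverage_ceiling = 0.5,
                          min_new = 3, max_overlap = 0.5) {
  degs <- unique(degs)
  pool <- names(term_genes)
  pool <- pool[vapply(pool, function(tm) {
    h <- length(intersect(term_genes[[tm]], degs))
    h > 0 && h / length(degs) <= coverage_ceiling
  }, logical(1L))]
  picked <- character()
  have <- character()
  while (length(pool) > 0L) {
    gain <- vapply(pool, function(tm) {
      length(setdiff(intersect(term_genes[[tm]], degs), have))
    }, integer(1L))
    if (max(gain) < min_new) break
    best_pool <- pool[gain == max(gain)]
    sz <- vapply(best_pool, function(tm) length(term_genes[[tm]]),
                 integer(1L))
    best <- best_pool[order(sz, best_pool)][1L]
    hit <- intersect(term_genes[[best]], degs)
    if (length(intersect(hit, have)) / length(hit) > max_overlap) break
    picked <- c(picked, best)
    have <- union(have, hit)
    pool <- setdiff(pool, best)
  }
  picked
}

# Brute-force symmetrized KLD between two Gaussian-mixture densities on a
# dense regular grid, with the published convention (floor 1e-12 before
# normalizing the grid masses). Written point-by-point, independently of the
# package's separable matrix evaluation.
oracle_kld_grid <- function(p1, p2, hx, hy, gx, gy, floor_p = 1e-12) {
  pts <- expand.grid(x = gx, y = gy)
  dens <- function(cloud) {
    v <- vapply(seq_len(nrow(pts)), function(i) {
      mean(stats::dnorm(pts$x[i], cloud[, 1L], hx) *
             stats::dnorm(pts$y[i], cloud[, 2L], hy))
    }, numeric(1L))
    v <- ifelse(v < floor_p, floor_p, v)
    v / sum(v)
  }
  q1 <- dens(p1)
  q2 <- dens(p2)
  (sum(q1 * log(q1 / q2)) + sum(q2 * log(q2 / q1))) / 2
}

# The bandwidth rule restated independently: Silverman's constant on the
# within-group dispersion (root mean variance vs mean IQR/1.349), n = total
# point count.
oracle_bw <- function(x1, x2) {
  n <- length(x1) + length(x2)
  s <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  r <- (stats::IQR(x1) + stats::IQR(x2)) / 2 / 1.349
  0.9 * min(s, if (r > 0) r else s) * n^(-1 / 5)
}
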