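# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so that they share no
# code path with the package implementation.

# P(X >= r) by exhaustive enumeration of all size-n subsets of 1..m, with
# 1..t as the marked elements.
enum_hypergeom_tail <- function(r, m, n, t) {
  if (n == 0) return(as.numeric(r == 0))
  subsets <- utils::combn(m, n)
  overlap <- colSums(subsets <= t)
  mean(overlap >= r)
}

# The textbook complement form 1 - sum_{i=0}^{r-1} C(t,i) C(m-t, n-i) / C(m,n),
# evaluated literally (only numerically safe when the result is not tiny).
complement_hypergeom_tail <- function(r, m, n, t) {
  if (r == 0) return(1)
  i <- 0:(r - 1)
  1 - sum(choose(t, i) * choose(m - t, n - i)) / choose(m, n)
}

# Literal BH step-up: adjusted_(i) = min(1, min_{j >= i} p_(j) * m / j),
# mapped back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  stepup <- ranked * m / seq_len(m)
  adj <- vapply(seq_len(m), function(i) min(1, min(stepup[i:m])), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Unnormalized undirected betweenness by explicit enumeration of every
# shortest path between every unordered node pair (BFS distances + DFS over
# distance-increasing moves).
brute_betweenness <- function(adj) {
  nodes <- names(adj)
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  bfs_dist <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    dist
  }
  for (si in seq_along(nodes)) {
    s <- nodes[si]
    dist <- bfs_dist(s)
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      tt <- nodes[ti]
      if (!is.finite(dist[tt])) next
      paths <- list()
      walk <- function(path) {
        v <- path[length(path)]
        if (v == tt) {
          paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        if (dist[v] >= dist[tt]) return(invisible())
        for (w in adj[[v]]) if (dist[w] == dist[v] + 1) walk(c(path, w))
      }
      walk(s)
      total <- length(paths)
      if (total == 0) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        tab <- table(interior)
        btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / total
      }
    }
  }
  btw
}

# Adjacency list of a cerna_network (undirected).
net_adjacency <- function(net) {
  nodes <- c(net$lnc_nodes, net$mrna_nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(net$edges))) {
    l <- net$edges$lnc[i]; g <- net$edges$mrna[i]
    adj[[l]] <- c(adj[[l]], g)
    adj[[g]] <- c(adj[[g]], l)
  }
  adj
}
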