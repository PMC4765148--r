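# Independent oracles used across the suite. These deliberately share no
# code with the package: coordinate descent (vs the package's LARS),
# plain breadth-first search (vs the DAG distance machinery), and direct
# set arithmetic (vs the metric implementations).

# Cyclic coordinate descent for  min sum((y - X b)^2) + lambda*sum|b| +
# gamma*sum(b^2)  on a raw (unstandardized) design, run to convergence.
oracle_cd <- function(x, y, lambda, gamma = 0, maxit = 100000L, tol = 1e-12) {
  p <- ncol(x)
  beta <- numeric(p)
  d <- colSums(x^2)
  r <- y
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (d[j] < 1e-12) next
      z <- sum(x[, j] * r) + d[j] * beta[j]
      bnew <- sign(z) * max(abs(z) - lambda / 2, 0) / (d[j] + gamma)
      if (bnew != beta[j]) {
        r <- r - x[, j] * (bnew - beta[j])
        delta <- max(delta, abs(bnew - beta[j]))
        beta[j] <- bnew
      }
    }
    if (delta < tol) break
  }
  beta
}

# Solve the standardized-and-centered problem the package fits, then map
# back to the original scale; mirrors the model definition, not the code.
oracle_penalized_fit <- function(x, y, lambda, gamma = 0) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  yc <- y - mean(y)
  bs <- oracle_cd(xs, yc, lambda, gamma)
  beta <- bs / sdv
  list(beta = beta, intercept = mean(y) - sum(beta * mu), beta_std = bs)
}

# Plain level-by-level BFS shortest path on an undirected edge list of
# term ids.
oracle_bfs_distance <- function(edges_from, edges_to, a, b) {
  if (a == b) return(0L)
  nbrs <- function(nodes) {
    unique(c(edges_to[edges_from %in% nodes], edges_from[edges_to %in% nodes]))
  }
  visited <- a
  frontier <- a
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    frontier <- setdiff(nbrs(frontier), visited)
    if (b %in% frontier) return(d)
    visited <- c(visited, frontier)
  }
  Inf
}

# random non-empty label sets
random_label_sets <- function(n, M, max_size = 3L) {
  lapply(seq_len(n), function(i) {
    sort(sample.int(M, sample.int(min(max_size, M), 1L)))
  })
}

# small dense GO-frequency-like matrix with named columns
random_count_matrix <- function(n, t) {
  x <- matrix(rpois(n * t, 1.2) * rbinom(n * t, 1, 0.5), n, t)
  colnames(x) <- sprintf("GO:%07d", seq_len(t))
  x
}

# a tiny OBO document as text, used by the parser tests
toy_obo_lines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: rootA",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: midA",
    "namespace: cellular_component",
    "is_a: GO:0000001 ! rootA",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: leafA",
    "namespace: cellular_component",
    "is_a: GO:0000002 ! midA",
    "relationship: part_of GO:0000001 ! rootA",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: obsolete term",
    "namespace: cellular_component",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: rootB",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000006",
    "name: leafB",
    "namespace: biological_process",
    "is_a: GO:0000005 ! rootB",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of")
}
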