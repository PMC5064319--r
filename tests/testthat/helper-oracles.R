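# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's BFS / predecessor-DAG code
# path: shortest-path counts come from adjacency-matrix powers (a walk of
# length equal to the graph distance is necessarily a simple shortest
# path) and explicit path lists from a depth-bounded DFS.

# random undirected graph with PSN-style node names
random_test_graph <- function(n, density, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < density)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste("A", "LEU", seq_len(n), sep = ":")
  list(graph = g, adj = adj)
}

# shortest-path length and count via matrix powers
oracle_sigma <- function(adj, a, b) {
  n <- nrow(adj)
  P <- diag(n)
  for (l in seq_len(n)) {
    P <- P %*% adj
    if (P[a, b] > 0) return(list(l = l, sigma = P[a, b]))
  }
  list(l = Inf, sigma = 0)
}

# all simple paths a->b of exactly length l, via depth-bounded DFS
oracle_paths <- function(adj, a, b, l) {
  res <- list()
  path <- integer(l + 1)
  visit <- function(u, depth) {
    path[depth] <<- u
    if (depth == l + 1) {
      if (u == b) res[[length(res) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (v in which(adj[u, ] > 0)) {
      if (!(v %in% path[seq_len(depth)])) visit(v, depth + 1L)
    }
    invisible(NULL)
  }
  if (is.finite(l)) visit(a, 1L)
  res
}

# brute-force GROMOS greedy clustering
oracle_gromos <- function(D, cutoff) {
  m <- nrow(D)
  assign <- integer(m)
  cl <- 0L
  while (any(assign == 0L)) {
    cl <- cl + 1L
    left <- which(assign == 0L)
    counts <- sapply(left, function(a) sum(D[a, left] <= cutoff))
    center <- left[which.max(counts)]
    members <- left[D[center, left] <= cutoff]
    assign[members] <- cl
  }
  assign
}

# brute-force single-linkage: repeatedly merge the two closest clusters
# while the minimum inter-cluster distance is <= cutoff
oracle_single_linkage <- function(D, cutoff) {
  m <- nrow(D)
  assign <- seq_len(m)
  repeat {
    labs <- unique(assign)
    if (length(labs) == 1) break
    best <- Inf; pair <- NULL
    for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
      d <- min(D[assign == labs[i], assign == labs[j], drop = FALSE])
      if (d < best) { best <- d; pair <- c(labs[i], labs[j]) }
    }
    if (best > cutoff) break
    assign[assign == pair[2]] <- pair[1]
  }
  match(assign, unique(assign))
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

# two-residue fixtures with groups at exactly controlled positions -----

# Asp (carboxylate collapsed to one point) vs a partner charged group
saltbridge_fixture <- function(distance, partner = "LYS") {
  p2 <- c(distance, 0, 0)
  atoms <- rbind(
    data.frame(name = c("CG", "OD1", "OD2"), resno = 1, resname = "ASP",
               chain = "A", x = 0, y = 0, z = 0),
    if (partner == "LYS")
      data.frame(name = "NZ", resno = 3, resname = "LYS", chain = "A",
                 x = p2[1], y = p2[2], z = p2[3])
    else
      data.frame(name = c("CD", "OE1", "OE2"), resno = 3, resname = "GLU",
                 chain = "A", x = p2[1], y = p2[2], z = p2[3])
  )
  structure_from_atoms(atoms)
}

# Ser donor with hydrogen on +x; acceptor placed at a prescribed
# donor-acceptor distance and donor-hydrogen-acceptor angle (degrees)
hbond_fixture <- function(distance, angle) {
  H <- c(1, 0, 0)
  theta <- angle * pi / 180
  # |A - D| = distance with A = H + rho * (cos(theta)*(-x) + sin(theta)*y):
  # rho^2 - 2 rho cos(theta) + 1 - distance^2 = 0
  rho <- cos(theta) + sqrt(cos(theta)^2 + distance^2 - 1)
  A <- H + rho * c(-cos(theta), sin(theta), 0)
  atoms <- rbind(
    data.frame(name = c("OG", "HG"), resno = 1, resname = "SER", chain = "A",
               x = c(0, H[1]), y = c(0, H[2]), z = c(0, H[3])),
    data.frame(name = c("CD", "OE1", "OE2"), resno = 3, resname = "GLU",
               chain = "A", x = A[1] + c(0, 0, 8), y = A[2] + c(0, 0, 8),
               z = A[3] + c(0, 0, 8))[1:2, ]
  )
  structure_from_atoms(atoms)
}

# two Leu side chains collapsed to points at a prescribed COM distance
hydrophobic_fixture <- function(distance, partner = "LEU") {
  atoms <- rbind(
    data.frame(name = c("CB", "CG", "CD1", "CD2"), resno = 1, resname = "LEU",
               chain = "A", x = 0, y = 0, z = 0),
    if (partner == "LEU")
      data.frame(name = c("CB", "CG", "CD1", "CD2"), resno = 3,
                 resname = "LEU", chain = "A", x = distance, y = 0, z = 0)
    else
      data.frame(name = c("OG", "HG"), resno = 3, resname = "SER",
                 chain = "A", x = distance, y = 0, z = 0)
  )
  structure_from_atoms(atoms)
}

# non-rigid random deformation orthogonal to rigid-body motion is not
# needed exactly: a random direction is almost surely non-rigid
random_conformation <- function(base, magnitude, seed) {
  set.seed(seed)
  base + stats::rnorm(length(base), 0, magnitude)
}
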