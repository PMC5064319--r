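# Shortest-path enumeration between designated residue pairs, the
# communication robustness (CR) index and selective betweenness (SB).
#
# Paths are unweighted (hop count): interaction persistence shapes the
# network only through the p_T filter.  For a pair (A, B):
#   l        — shortest-path length in edges (BFS),
#   sigma_AB — number of distinct shortest paths, counted exactly by the
#              standard BFS path-count recursion,
#   CR       — sigma_AB * p_T / l (formula variant "cr-v1"; see the
#              vignette: the minimal form with the required
#              monotonicities, swappable behind cr_index),
#   SB(v)    — sigma_AB(v) / sigma_AB, the fraction of A-B shortest paths
#              through v, with sigma_AB(v) = sigma_A(v) * sigma_B(v) for
#              nodes on some shortest path (d_A(v) + d_B(v) = l).

.FORMULA_VERSION <- "cr-v1: sigma*pT/l"

# BFS from a source over an adjacency list (list of integer vectors).
# Returns integer distances (Inf as NA -> use large) and path counts.
.bfs_counts <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[src] <- 0
  sigma[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

.graph_adj <- function(graph) {
  adj <- igraph::as_adj_list(graph, mode = "all")
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

.node_index <- function(graph, node) {
  i <- match(node, igraph::V(graph)$name)
  if (is.na(i)) stop("node '", node, "' not in graph")
  i
}

#' All shortest paths between two nodes
#'
#' Breadth-first distance and exact shortest-path count, plus explicit
#' enumeration of the shortest node sequences via the predecessor DAG.
#' The count `sigma_AB` is always exact; only the explicit list is
#' truncated (and flagged) when it would exceed `cap`.
#'
#' @param graph an igraph PSN
#' @param A,B node ids (`"CHAIN:RESNAME:RESID"`)
#' @param cap maximum number of explicit paths to list (default 1e6)
#' @return a `PathSet`: list with `A`, `B`, `l` (edges; `Inf` if
#'   disconnected), `sigma_AB`, `paths` (list of node-id vectors),
#'   `truncated`
#' @export
path_set <- function(graph, A, B, cap = 1e6) {
  stopifnot(!identical(A, B))
  ia <- .node_index(graph, A); ib <- .node_index(graph, B)
  adj <- .graph_adj(graph)
  fa <- .bfs_counts(adj, ia)
  out <- list(A = A, B = B, l = fa$dist[ib], sigma_AB = fa$sigma[ib],
              paths = list(), truncated = FALSE)
  class(out) <- "PathSet"
  if (is.infinite(out$l)) { out$sigma_AB <- 0; return(out) }
  fb <- .bfs_counts(adj, ib)
  l <- out$l
  on_path <- fa$dist + fb$dist == l
  nm <- igraph::V(graph)$name
  # DFS over the shortest-path DAG from A, following edges that stay on
  # some shortest path
  acc <- vector("list", min(out$sigma_AB, cap))
  cnt <- 0L
  stack_path <- integer(l + 1L)
  rec <- function(u, depth) {
    if (cnt >= length(acc)) return(invisible(NULL))
    stack_path[depth] <<- u
    if (u == ib) {
      cnt <<- cnt + 1L
      acc[[cnt]] <<- nm[stack_path[seq_len(depth)]]
      return(invisible(NULL))
    }
    for (v in adj[[u]]) {
      if (on_path[v] && fa$dist[v] == fa$dist[u] + 1) rec(v, depth + 1L)
    }
    invisible(NULL)
  }
  if (out$sigma_AB > 0) rec(ia, 1L)
  out$paths <- acc[seq_len(cnt)]
  out$truncated <- cnt < out$sigma_AB
  out
}

#' @export
print.PathSet <- function(x, ...) {
  cat(sprintf("PathSet %s -> %s: l=%s, sigma_AB=%g%s\n", x$A, x$B,
              format(x$l), x$sigma_AB,
              if (x$truncated) " (path list truncated)" else ""))
  invisible(x)
}

#' Communication robustness index
#'
#' `CR = sigma_AB * p_T / l`: increasing in the number of shortest paths
#' and in the persistence threshold that the path edges survive,
#' decreasing in path length (parsimony).  A disconnected pair has CR 0.
#'
#' @param sigma_AB number of shortest paths (>= 0)
#' @param l shortest-path length in edges (>= 1 when `sigma_AB > 0`)
#' @param p_T persistence threshold, fraction in (0,1)
#' @return non-negative CR value
#' @export
cr_index <- function(sigma_AB, l, p_T) {
  if (any(sigma_AB < 0)) stop("sigma_AB must be non-negative")
  stopifnot(all(p_T > 0), all(p_T < 1))
  if (any(sigma_AB > 0 & (is.na(l) | l < 1)))
    stop("l must be >= 1 when sigma_AB > 0")
  ifelse(sigma_AB == 0, 0, sigma_AB * p_T / l)
}

#' Selective betweenness map for one endpoint pair
#'
#' For each node v, `sigma_AB(v)` is the number of A-B shortest paths
#' through v, computed as the product of one-sided BFS path counts for
#' nodes with `d_A(v) + d_B(v) = l`; `SB(v) = sigma_AB(v)/sigma_AB`.
#' Endpoints carry SB 1 by convention.  The conservation identity
#' `sum over internal v of sigma_AB(v) = sigma_AB * (l - 1)` is asserted
#' on every computed map.
#'
#' @param graph an igraph PSN
#' @param A,B node ids
#' @return an `SBMap` data.frame with `node`, `sigma_v`, `sb`; attributes
#'   `A`, `B`, `l`, `sigma_AB`
#' @export
selective_betweenness <- function(graph, A, B) {
  ia <- .node_index(graph, A); ib <- .node_index(graph, B)
  adj <- .graph_adj(graph)
  fa <- .bfs_counts(adj, ia)
  fb <- .bfs_counts(adj, ib)
  nm <- igraph::V(graph)$name
  l <- fa$dist[ib]
  if (is.infinite(l)) {
    out <- data.frame(node = nm, sigma_v = 0, sb = 0, stringsAsFactors = FALSE)
  } else {
    sigma_AB <- fa$sigma[ib]
    sigma_v <- ifelse(fa$dist + fb$dist == l, fa$sigma * fb$sigma, 0)
    sigma_v[c(ia, ib)] <- sigma_AB
    internal <- setdiff(which(fa$dist + fb$dist == l), c(ia, ib))
    if (abs(sum(sigma_v[internal]) - sigma_AB * (l - 1)) > 1e-6)
      stop("internal error: SB conservation identity violated")
    out <- data.frame(node = nm, sigma_v = sigma_v, sb = sigma_v / sigma_AB,
                      stringsAsFactors = FALSE)
  }
  attr(out, "A") <- A; attr(out, "B") <- B
  attr(out, "l") <- l
  attr(out, "sigma_AB") <- if (is.infinite(l)) 0 else fa$sigma[ib]
  class(out) <- c("SBMap", "data.frame")
  out
}

# lexicographic comparison of two equal-length character vectors:
# negative if a < b
.lex_cmp <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

#' Maximum-selective-betweenness representative path
#'
#' Among all A-B shortest paths, returns the one maximizing the sum of
#' SB over its internal nodes; ties are broken by the lexicographically
#' smallest node-id sequence, making the result deterministic.
#'
#' @param graph an igraph PSN
#' @param A,B node ids
#' @param cap explicit-enumeration cap passed to [path_set()]
#' @return character vector of node ids (empty if disconnected)
#' @export
max_sb_path <- function(graph, A, B, cap = 1e6) {
  ps <- path_set(graph, A, B, cap = cap)
  if (ps$sigma_AB == 0) return(character(0))
  sb <- selective_betweenness(graph, A, B)
  sbv <- stats::setNames(sb$sb, sb$node)
  best <- NULL; best_score <- -Inf
  for (p in ps$paths) {
    internal <- p[-c(1, length(p))]
    score <- if (length(internal)) sum(sbv[internal]) else 0
    take <- is.null(best) || score > best_score + 1e-12 ||
      (abs(score - best_score) <= 1e-12 && .lex_cmp(p, best) < 0)
    if (take) { best <- p; best_score <- score }
  }
  best
}

#' CR matrix over source and sink residue lists
#'
#' One `CRRecord` row per (source, sink) pair: `sigma_AB`, `l`, `p_T` and
#' CR.  Pairs with a node absent from the graph are flagged
#' (`in_graph = FALSE`, CR `NA`); disconnected pairs get CR 0.
#'
#' @param graph an igraph PSN
#' @param sources,sinks character vectors of node ids
#' @param p_T persistence threshold (default: the graph's own)
#' @return data.frame sorted by source then sink, with attribute
#'   `formula`
#' @export
cr_matrix <- function(graph, sources, sinks,
                      p_T = igraph::graph_attr(graph, "p_T")) {
  stopifnot(length(sources) >= 1, length(sinks) >= 1, !is.null(p_T))
  nm <- igraph::V(graph)$name
  rows <- list()
  for (a in sort(sources)) for (b in sort(sinks)) {
    if (identical(a, b)) next
    if (!(a %in% nm) || !(b %in% nm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = a, sink = b, sigma_AB = NA_real_, l = NA_real_,
        p_T = p_T, cr = NA_real_, in_graph = FALSE, stringsAsFactors = FALSE)
      next
    }
    ps <- path_set(graph, a, b, cap = 1L)  # counting only; no list needed
    rows[[length(rows) + 1L]] <- data.frame(
      source = a, sink = b, sigma_AB = ps$sigma_AB,
      l = if (is.infinite(ps$l)) NA_real_ else ps$l, p_T = p_T,
      cr = if (ps$sigma_AB == 0) 0 else cr_index(ps$sigma_AB, ps$l, p_T),
      in_graph = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "formula") <- .FORMULA_VERSION
  out
}

#' Compare CR tables across states
#'
#' Stacks named per-state CR tables (as from [cr_matrix()]) into long
#' format and annotates, per (source, sink) pair, the state with maximal
#' CR (ties flagged `"tie"`).
#'
#' @param tables named list of CR tables sharing source/sink lists
#' @return long-format data.frame with one row per (source, sink, state)
#'   plus a `max_state` annotation
#' @export
compare_states <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  key <- function(t) paste(t$source, t$sink, sep = " -> ")
  ref <- sort(key(tables[[1]]))
  for (nm in names(tables)) {
    k <- sort(key(tables[[nm]]))
    if (!identical(ref, k)) {
      miss <- c(setdiff(ref, k), setdiff(k, ref))
      stop("state '", nm, "' has mismatched (source, sink) pairs: ",
           paste(miss, collapse = "; "))
    }
  }
  long <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    data.frame(source = t$source, sink = t$sink, state = nm, cr = t$cr,
               sigma_AB = t$sigma_AB, l = t$l, stringsAsFactors = FALSE)
  }))
  long <- long[order(long$source, long$sink, long$state), ]
  pk <- paste(long$source, long$sink, sep = " -> ")
  ann <- vapply(unique(pk), function(k) {
    sub <- long[pk == k, ]
    crv <- ifelse(is.na(sub$cr), -Inf, sub$cr)
    mx <- max(crv)
    winners <- sub$state[crv >= mx - 1e-12]
    if (length(winners) > 1) "tie" else winners
  }, character(1))
  long$max_state <- ann[pk]
  rownames(long) <- NULL
  attr(long, "formula") <- .FORMULA_VERSION
  long
}

#' Write an SB map as TSV
#'
#' @param sbmap an `SBMap`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sb_map <- function(sbmap, path) {
  out <- as.data.frame(sbmap)
  out$sb <- round(out$sb, 8)
  write_tsv(out, path)
}
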