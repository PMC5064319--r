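# Persistence-threshold estimation and PSN construction.
#
# The significance threshold p_T is estimated from the size of the largest
# connected component of the hydrophobic-interaction graph as the
# persistence threshold is swept over a grid (default 0-100% in 5% steps).
# That curve falls off sigmoidally between a transient-noise plateau and a
# persistent-core plateau; p_T is taken at the inflection of a fitted
# four-parameter logistic, with the midpoint of the steepest single-step
# drop as fallback.  p_T is estimated on the hydrophobic class only but
# applied to all three interaction classes when the per-class graphs are
# filtered and joined into one PSN.

#' Scan the largest hydrophobic component against a persistence threshold
#'
#' @param table a `PersistenceTable`
#' @param step grid step in percent (must divide 100; default 5)
#' @return a `ThresholdScan`: data.frame with `threshold_percent` and
#'   `largest_component` (node count)
#' @export
threshold_scan <- function(table, step = 5) {
  stopifnot(step > 0, (100 / step) %% 1 == 0)
  hp <- table[table$class == "hydrophobic", , drop = FALSE]
  if (!nrow(hp))
    stop("no hydrophobic interactions in table; p_T is undefined")
  ids <- .table_node_ids(hp)
  grid <- seq(0, 100, by = step)
  size <- vapply(grid, function(t) {
    keep <- hp$persistence * 100 >= t
    if (!any(keep)) return(0)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids$i[keep], to = ids$j[keep]), directed = FALSE)
    as.numeric(max(igraph::components(g)$csize))
  }, numeric(1))
  out <- data.frame(threshold_percent = grid, largest_component = size)
  class(out) <- c("ThresholdScan", "data.frame")
  out
}

#' Estimate the persistence significance threshold p_T
#'
#' Fits a decreasing four-parameter logistic
#' `size(t) = lower + (upper - lower) / (1 + exp((t - m)/s))` to the
#' largest-component curve and returns the inflection abscissa `m` as a
#' fraction.  If the fit does not converge, falls back to the midpoint of
#' the steepest single-step drop.
#'
#' @param scan a `ThresholdScan`
#' @return list with `p_T` (continuous fit value, fraction in (0,1)),
#'   `p_T_grid` (nearest grid value), `method` (`"sigmoid"` or
#'   `"steepest-drop"`)
#' @export
estimate_pt <- function(scan) {
  stopifnot(inherits(scan, "ThresholdScan"))
  t <- scan$threshold_percent
  y <- scan$largest_component
  if (length(y) < 3 || length(unique(y)) < 2)
    stop("largest-component curve has no drop; ",
         "no inflection - supply p_T explicitly")
  drops <- -diff(y)
  k <- which.max(drops)  # earliest steepest drop
  m0 <- (t[k] + t[k + 1]) / 2
  fit <- tryCatch({
    df <- data.frame(t = t, y = y)
    md <- minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + exp((t - m) / s)),
      data = df,
      start = list(lower = min(y), upper = max(y), m = m0, s = max(diff(t)[1] / 2, 1)),
      lower = c(lower = 0, upper = 0, m = min(t), s = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(md)[["m"]]
  }, error = function(e) NA_real_)
  if (is.na(fit) || fit <= 0 || fit >= 100) {
    method <- "steepest-drop"
    m <- m0
  } else {
    method <- "sigmoid"
    m <- fit
  }
  step <- diff(t)[1]
  list(p_T = m / 100,
       p_T_grid = round(m / step) * step / 100,
       method = method)
}

#' Build the union protein structure network
#'
#' Filters each interaction class at `p_T` and joins the surviving edges
#' into one undirected graph.  Each edge keeps the maximum persistence
#' across classes and the set of contributing classes; nodes cover every
#' residue appearing in the table, so a fully filtered table yields a
#' graph with nodes and zero edges.
#'
#' @param table a `PersistenceTable`
#' @param p_T persistence threshold as a fraction in (0,1)
#' @return igraph object with vertex attribute `name`
#'   (`"CHAIN:RESNAME:RESID"`), edge attributes `persistence` (fraction),
#'   `classes` (comma-joined), and graph attributes `p_T`, `formula`
#' @export
build_psn <- function(table, p_T) {
  stopifnot(p_T > 0, p_T < 1)
  ids <- .table_node_ids(table)
  nodes <- unique(c(ids$i, ids$j))
  keep <- table$persistence >= p_T
  if (any(keep)) {
    key <- paste(ids$i, ids$j, sep = "->")[keep]
    pers <- table$persistence[keep]
    cls <- table$class[keep]
    agg_p <- tapply(pers, key, max)
    agg_c <- tapply(cls, key, function(x) paste(sort(unique(x)), collapse = ","))
    uk <- names(agg_p)
    ft <- do.call(rbind, strsplit(uk, "->", fixed = TRUE))
    edges <- data.frame(from = ft[, 1], to = ft[, 2],
                        persistence = as.numeric(agg_p),
                        classes = as.character(agg_c[uk]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        persistence = numeric(0), classes = character(0),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "p_T", p_T)
  igraph::set_graph_attr(g, "formula", "cr-v1: sigma*pT/l")
}

#' Classify PSN hubs by degree
#'
#' A hub is a node with at least `min_degree` neighbours (default 3); the
#' `highest_degree` flag marks degree >= 7.  Records are sorted by degree
#' descending, then residue number ascending.
#'
#' @param graph an igraph PSN
#' @param min_degree minimum neighbour count for hub status (default 3)
#' @param highest_degree_min degree at which the highest-degree flag is
#'   set (default 7)
#' @return data.frame with `node`, `degree`, `highest_degree`
#' @export
find_hubs <- function(graph, min_degree = 3L, highest_degree_min = 7L) {
  stopifnot(min_degree >= 1)
  deg <- igraph::degree(graph)
  keep <- deg >= min_degree
  nodes <- names(deg)[keep]
  d <- unname(deg[keep])
  resno <- suppressWarnings(as.integer(vapply(strsplit(nodes, ":", fixed = TRUE),
                                              function(p) p[length(p)], character(1))))
  o <- order(-d, resno, nodes)
  out <- data.frame(node = nodes[o], degree = d[o],
                    highest_degree = d[o] >= highest_degree_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
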