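# Average structure, pairwise-RMSD matrices and conformational clustering
# (GROMOS greedy neighbour counting and single-linkage agglomeration) at
# the data-driven cutoff: the mean Calpha RMSD of the frames to their
# average structure.

#' Average structure over a trajectory
#'
#' Coordinate-wise mean over frames on the selection.  The trajectory
#' should be superposed first.
#'
#' @param trajectory a superposed `Trajectory`
#' @param selection atom indices (default Calpha)
#' @return numeric xyz vector of the selection's mean coordinates, with
#'   attribute `selection`
#' @export
average_structure <- function(trajectory, selection = NULL) {
  if (!isTRUE(trajectory$superposed))
    warning("trajectory not flagged as superposed; average mixes rigid-body motion",
            call. = FALSE)
  if (is.null(selection)) selection <- select_calpha(trajectory$structure)
  avg <- colMeans(trajectory$xyz[, xyz_index(selection), drop = FALSE])
  attr(avg, "selection") <- selection
  avg
}

#' Data-driven clustering cutoff
#'
#' Mean over frames of the best-fit Calpha RMSD to the average structure;
#' used as the cutoff for both clustering algorithms.
#'
#' @param trajectory a `Trajectory`
#' @param average output of [average_structure()] on the same trajectory
#'   (computed if omitted)
#' @return cutoff in Angstrom
#' @export
derive_cutoff <- function(trajectory, average = NULL) {
  if (is.null(average)) average <- average_structure(trajectory)
  sel <- attr(average, "selection")
  sub <- trajectory$xyz[, xyz_index(sel), drop = FALSE]
  r <- .fit_rmsd(as.numeric(average), sub)
  mean(r)
}

#' Pairwise best-fit RMSD matrix over strided frames
#'
#' @param trajectory a `Trajectory`
#' @param stride keep every `stride`-th frame (default 4)
#' @param selection atom indices (default Calpha)
#' @param max_frames refuse matrices larger than this frame count after
#'   striding (default 2000)
#' @return an `RMSDMatrix`: symmetric matrix (A) with attributes `stride`
#'   and `frames` (1-based indices of the retained frames)
#' @export
rmsd_matrix <- function(trajectory, stride = 4L, selection = NULL,
                        max_frames = 2000L) {
  stopifnot(stride >= 1)
  if (is.null(selection)) selection <- select_calpha(trajectory$structure)
  idx <- seq(1, n_frames(trajectory), by = stride)
  m <- length(idx)
  if (m > max_frames)
    stop(m, " frames after stride exceed max_frames = ", max_frames,
         "; increase the stride or raise max_frames")
  sub <- trajectory$xyz[idx, xyz_index(selection), drop = FALSE]
  D <- matrix(0, m, m)
  for (a in seq_len(m - 1)) {
    D[a, (a + 1):m] <- .fit_rmsd(sub[a, ], sub[(a + 1):m, , drop = FALSE])
  }
  D <- D + t(D)
  attr(D, "stride") <- as.integer(stride)
  attr(D, "frames") <- idx
  class(D) <- c("RMSDMatrix", class(D))
  D
}

.cluster_set <- function(algorithm, cutoff, assignment, centers, frames) {
  sizes <- as.integer(table(assignment))
  o <- order(-sizes, vapply(split(seq_along(assignment), assignment),
                            min, integer(1)))
  relabel <- match(seq_along(sizes), o)
  out <- list(algorithm = algorithm, cutoff = cutoff,
              assignment = relabel[assignment],
              centers = centers[o], sizes = sizes[o], frames = frames)
  class(out) <- "ClusterSet"
  out
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet (%s, cutoff %.3f A): %d clusters over %d frames\n",
              x$algorithm, x$cutoff, length(x$sizes), length(x$assignment)))
  cat("  sizes:", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (length(x$sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' GROMOS clustering of an RMSD matrix
#'
#' Iteratively takes the frame with the most neighbours within the cutoff
#' as a cluster center, removes it and its neighbours, and repeats until
#' no frames remain.  Ties are broken by the lowest frame index.
#'
#' @param matrix an `RMSDMatrix`
#' @param cutoff neighbour cutoff (A)
#' @return a `ClusterSet` (cluster 1 is the most populated; centers are
#'   positions within the strided frame set)
#' @export
gromos_cluster <- function(matrix, cutoff) {
  stopifnot(cutoff > 0)
  m <- nrow(matrix)
  remaining <- rep(TRUE, m)
  assignment <- integer(m)
  centers <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    nb <- vapply(idx, function(a) sum(matrix[a, idx] <= cutoff), integer(1))
    center <- idx[which.max(nb)]  # which.max takes the first (lowest index) on ties
    members <- idx[matrix[center, idx] <= cutoff]
    assignment[members] <- cl
    centers <- c(centers, center)
    remaining[members] <- FALSE
  }
  .cluster_set("gromos", cutoff, assignment, centers, attr(matrix, "frames"))
}

#' Single-linkage clustering of an RMSD matrix
#'
#' Agglomerative single-linkage clustering cut at the cutoff height; each
#' cluster's center is its medoid (the frame minimizing summed RMSD to
#' the other members).
#'
#' @param matrix an `RMSDMatrix`
#' @param cutoff tree-cut height (A)
#' @return a `ClusterSet`
#' @export
linkage_cluster <- function(matrix, cutoff) {
  stopifnot(cutoff > 0)
  m <- nrow(matrix)
  if (m == 1) {
    assignment <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(matrix), method = "single")
    assignment <- stats::cutree(hc, h = cutoff)
  }
  centers <- vapply(sort(unique(assignment)), function(cl) {
    members <- which(assignment == cl)
    members[which.min(rowSums(matrix[members, members, drop = FALSE]))]
  }, integer(1))
  .cluster_set("linkage", cutoff, as.integer(assignment), centers,
               attr(matrix, "frames"))
}

#' Cluster assignments as a data frame
#'
#' @param cluster_set a `ClusterSet`
#' @return data.frame with `frame` (original 1-based index), `cluster`
#' @export
cluster_assignments <- function(cluster_set) {
  data.frame(frame = cluster_set$frames %||% seq_along(cluster_set$assignment),
             cluster = cluster_set$assignment)
}
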