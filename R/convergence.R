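# Sampling-convergence diagnostics: Calpha RMSD traces, covariance / PCA
# of positional fluctuations, essential-subspace projections, cosine
# content and RMSIP across replicas.

#' Per-frame best-fit RMSD trace
#'
#' Best-fit Calpha RMSD of every frame against a reference, with mean and
#' SD attached as attributes.
#'
#' @param trajectory a `Trajectory`
#' @param reference xyz vector (default: frame 0)
#' @param selection atom indices (default Calpha)
#' @return numeric vector of per-frame RMSD (A) with attributes `mean`,
#'   `sd`
#' @export
rmsd_trace <- function(trajectory, reference = NULL, selection = NULL) {
  if (is.null(selection)) selection <- select_calpha(trajectory$structure)
  if (length(selection) == 0) stop("empty atom selection")
  if (is.null(reference)) reference <- trajectory$xyz[1L, ]
  ids <- xyz_index(selection)
  r <- .fit_rmsd(reference, trajectory$xyz, ids)
  attr(r, "mean") <- mean(r)
  attr(r, "sd") <- stats::sd(r)
  r
}

#' Covariance matrix of positional fluctuations
#'
#' Population covariance (divisor n) of the selected coordinates about
#' the trajectory mean, optionally mass-weighted (each coordinate scaled
#' by sqrt(mass); a no-op on an all-Calpha selection).  The trajectory
#' should be superposed first; if it is not, a warning is issued.
#'
#' @param trajectory a `Trajectory`
#' @param selection atom indices (default Calpha)
#' @param mass_weighted logical (default TRUE)
#' @return symmetric PSD matrix (3N x 3N) with attributes `center` (the
#'   coordinate mean) and `selection`
#' @export
covariance_matrix <- function(trajectory, selection = NULL,
                              mass_weighted = TRUE) {
  if (n_frames(trajectory) < 2) stop("need at least 2 frames")
  if (!isTRUE(trajectory$superposed))
    warning("trajectory not flagged as superposed; covariance mixes rigid-body motion",
            call. = FALSE)
  if (is.null(selection)) selection <- select_calpha(trajectory$structure)
  X <- trajectory$xyz[, xyz_index(selection), drop = FALSE]
  if (mass_weighted) {
    w <- sqrt(rep(trajectory$structure$atoms$mass[selection], each = 3))
    X <- sweep(X, 2, w, `*`)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, `-`)
  C <- crossprod(Xc) / nrow(Xc)
  C <- (C + t(C)) / 2
  attr(C, "center") <- mu
  attr(C, "selection") <- selection
  attr(C, "mass_weighted") <- mass_weighted
  C
}

#' Essential subspace from a covariance matrix
#'
#' Diagonalizes the covariance matrix and keeps the top `n_modes`
#' eigenpairs.  Eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive, for reproducible projections.
#' A warning is logged when the subspace captures less than
#' `min_variance` of the total variance.
#'
#' @param C covariance matrix from [covariance_matrix()]
#' @param n_modes subspace dimension S (default 20, capped at 3N)
#' @param source label recorded on the result (replica id or
#'   `"concatenated"`)
#' @param min_variance captured-variance warning threshold (default 0.8)
#' @return an `EssentialSubspace`: list with `vectors` (3N x S,
#'   orthonormal columns), `values` (descending, >= 0), `captured`
#'   (variance fraction), `center`, `source`
#' @export
pca_subspace <- function(C, n_modes = 20L, source = "trajectory",
                         min_variance = 0.8) {
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("covariance matrix must be symmetric")
  n_modes <- min(as.integer(n_modes), ncol(C))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  vec <- e$vectors[, seq_len(n_modes), drop = FALSE]
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  captured <- if (total > 0) sum(vals[seq_len(n_modes)]) / total else NA_real_
  if (!is.na(captured) && captured < min_variance)
    warning(sprintf("essential subspace captures %.1f%% of variance (< %.0f%%)",
                    100 * captured, 100 * min_variance), call. = FALSE)
  out <- list(vectors = vec, values = vals[seq_len(n_modes)],
              all_values = vals, captured = captured,
              center = attr(C, "center"), selection = attr(C, "selection"),
              mass_weighted = attr(C, "mass_weighted") %||% TRUE,
              source = source)
  class(out) <- "EssentialSubspace"
  out
}

#' @export
print.EssentialSubspace <- function(x, ...) {
  cat(sprintf("EssentialSubspace '%s': S=%d, captured variance %.3f\n",
              x$source, ncol(x$vectors),
              if (is.na(x$captured)) NA else x$captured))
  invisible(x)
}

#' Project a trajectory on one principal component
#'
#' `p_i(t) = v_i . (x(t) - center)` using the subspace's own centring and
#' mass-weighting convention.
#'
#' @param trajectory a `Trajectory`
#' @param subspace an `EssentialSubspace`
#' @param i PC index (1-based, <= S)
#' @return a `ProjectionSeries`: numeric per-frame projections with
#'   attribute `T` (total time; frame units when times are absent)
#' @export
project_trajectory <- function(trajectory, subspace, i = 1L) {
  stopifnot(inherits(subspace, "EssentialSubspace"), i >= 1,
            i <= ncol(subspace$vectors))
  X <- trajectory$xyz[, xyz_index(subspace$selection), drop = FALSE]
  if (isTRUE(subspace$mass_weighted)) {
    w <- sqrt(rep(trajectory$structure$atoms$mass[subspace$selection], each = 3))
    X <- sweep(X, 2, w, `*`)
  }
  if (ncol(X) != nrow(subspace$vectors)) stop("dimension mismatch")
  p <- as.numeric(sweep(X, 2, subspace$center, `-`) %*% subspace$vectors[, i])
  tt <- trajectory$time
  attr(p, "T") <- if (!is.null(tt)) max(tt) - min(tt) else nrow(X) - 1
  class(p) <- "ProjectionSeries"
  p
}

#' Cosine content of a projection series
#'
#' Overlap of a PC projection with the half-period cosine
#' `cos(i*pi*t/T)`:
#' `c_i = (2/T) * (int p(t) cos(i pi t / T) dt)^2 / int p(t)^2 dt`,
#' discretized by the trapezoid rule on uniform frame times.  Values near
#' 1 indicate random-diffusion-like, unconverged sampling.
#'
#' @param series a `ProjectionSeries` (or numeric vector)
#' @param i cosine index (default 1)
#' @return `c_i` in \[0,1\]; `NaN` with a warning for an all-zero series
#' @export
cosine_content <- function(series, i = 1L) {
  p <- as.numeric(series)
  n <- length(p)
  stopifnot(n >= 2)
  T_ <- attr(series, "T") %||% (n - 1)
  t <- seq(0, T_, length.out = n)
  den <- pracma::trapz(t, p^2)
  if (den == 0) {
    warning("all-zero projection series; cosine content undefined", call. = FALSE)
    return(NaN)
  }
  num <- pracma::trapz(t, p * cos(i * pi * t / T_))^2
  (2 / T_) * num / den
}

#' Root-mean-square inner product of two essential subspaces
#'
#' `RMSIP = sqrt( (1/S) * sum_i sum_j (v^A_i . v^B_j)^2 )`; 1 for
#' identical spans, 0 for mutually orthogonal subspaces.
#'
#' @param es_A,es_B `EssentialSubspace` objects of equal vector dimension
#'   and equal S
#' @return value in \[0,1\]
#' @export
rmsip <- function(es_A, es_B) {
  stopifnot(inherits(es_A, "EssentialSubspace"),
            inherits(es_B, "EssentialSubspace"))
  if (nrow(es_A$vectors) != nrow(es_B$vectors))
    stop("subspace vector dimensions differ")
  S <- ncol(es_A$vectors)
  if (ncol(es_B$vectors) != S) stop("subspace dimensionalities differ")
  ip <- crossprod(es_A$vectors, es_B$vectors)
  sqrt(sum(ip^2) / S)
}

#' Replica convergence report
#'
#' Computes, for each replica and for the concatenated trajectory: the
#' essential subspace (top `n_modes` PCs), pairwise RMSIP (symmetric
#' matrix including the concatenated trajectory), the cosine content of
#' PC1, and the per-replica mean and SD of the Calpha RMSD trace against
#' the replica's first frame.
#'
#' @param replicas list of superposed `Trajectory` objects (>= 2)
#' @param concatenated superposed concatenated `Trajectory`
#' @param n_modes essential-subspace dimension (default 20)
#' @return list with `rmsip` (matrix), `summary` (data.frame: source,
#'   c1, rmsd_mean, rmsd_sd, captured)
#' @export
replica_report <- function(replicas, concatenated, n_modes = 20L) {
  stopifnot(length(replicas) >= 2)
  labels <- names(replicas) %||% paste0("R", seq_along(replicas))
  if (is.null(names(replicas))) names(replicas) <- labels
  trajs <- c(replicas, list(concatenated = concatenated))
  subspaces <- list(); c1 <- numeric(length(trajs))
  rm_mean <- numeric(length(trajs)); rm_sd <- numeric(length(trajs))
  captured <- numeric(length(trajs))
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    C <- covariance_matrix(tr)
    es <- suppressWarnings(pca_subspace(C, n_modes = n_modes,
                                        source = names(trajs)[k]))
    subspaces[[k]] <- es
    c1[k] <- cosine_content(project_trajectory(tr, es, 1))
    rt <- rmsd_trace(tr)
    rm_mean[k] <- attr(rt, "mean"); rm_sd[k] <- attr(rt, "sd")
    captured[k] <- es$captured
  }
  m <- matrix(NA_real_, length(trajs), length(trajs),
              dimnames = list(names(trajs), names(trajs)))
  for (a in seq_along(trajs)) for (b in seq_len(a)) {
    m[a, b] <- m[b, a] <- rmsip(subspaces[[a]], subspaces[[b]])
  }
  list(rmsip = m,
       summary = data.frame(source = names(trajs), c1 = c1,
                            rmsd_mean = rm_mean, rmsd_sd = rm_sd,
                            captured = captured, stringsAsFactors = FALSE),
       subspaces = subspaces)
}
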