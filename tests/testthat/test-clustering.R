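# Average structure, RMSD matrices, GROMOS and single-linkage clustering.

test_that("average structure: midpoints, single frames, mean-RMSD bound", {
  s <- make_polymer(5)
  base <- structure_xyz(s)
  d <- random_conformation(base, 1, seed = 1) - base
  tr <- new_trajectory(s, rbind(base + d, base - d)); tr$superposed <- TRUE
  avg <- average_structure(tr)
  sel <- xyz_index(attr(avg, "selection"))
  expect_equal(as.numeric(avg), base[sel], tolerance = 1e-10)
  tr1 <- new_trajectory(s, matrix(base, 1)); tr1$superposed <- TRUE
  expect_equal(as.numeric(average_structure(tr1)), base[sel])
  # mean RMSD-to-average <= mean pairwise RMSD
  set.seed(4)
  X <- t(replicate(12, base + stats::rnorm(length(base), 0, 0.5)))
  tr2 <- new_trajectory(s, X); tr2$superposed <- TRUE
  cutoff <- derive_cutoff(tr2)
  M <- rmsd_matrix(tr2, stride = 1)
  expect_lte(cutoff, mean(M[upper.tri(M)]) + 1e-9)
})

test_that("derived cutoff: zero for static input, bounded for two basins", {
  s <- make_polymer(5)
  base <- structure_xyz(s)
  tr <- new_trajectory(s, rbind(base, base)); tr$superposed <- TRUE
  expect_equal(derive_cutoff(tr), 0, tolerance = 1e-8)
  tb <- two_basin_trajectory(sep_mag = 2)
  cutoff <- derive_cutoff(tb$trajectory)
  M <- rmsd_matrix(tb$trajectory, stride = 1)
  inter <- max(M)
  expect_gt(cutoff, 0)
  expect_lt(cutoff, inter)
  # permutation invariance
  perm <- new_trajectory(tb$structure, tb$trajectory$xyz[sample.int(20), ])
  perm$superposed <- TRUE
  expect_equal(derive_cutoff(perm), cutoff, tolerance = 1e-9)
})

test_that("RMSD matrix: stride, zeros for duplicates, per-pair oracle", {
  s <- make_polymer(5)
  base <- structure_xyz(s)
  set.seed(9)
  X <- t(replicate(100, base + stats::rnorm(length(base), 0, 0.4)))
  tr <- new_trajectory(s, X); tr$superposed <- TRUE
  M4 <- rmsd_matrix(tr, stride = 4)
  expect_equal(dim(M4), c(25, 25))
  dup <- new_trajectory(s, X[c(1, 1, 2), ]); dup$superposed <- TRUE
  Md <- rmsd_matrix(dup, stride = 1)
  expect_equal(Md[1, 2], 0, tolerance = 1e-8)
  # direct per-pair recomputation on 10 frames
  tr10 <- new_trajectory(s, X[1:10, ]); tr10$superposed <- TRUE
  M <- rmsd_matrix(tr10, stride = 1)
  ca <- xyz_index(select_calpha(s))
  for (a in 1:9) for (b in (a + 1):10) {
    direct <- as.numeric(bio3d::rmsd(X[a, ], X[b, ], a.inds = ca, b.inds = ca,
                                     fit = TRUE))
    expect_equal(M[a, b], direct, tolerance = 1e-10)
  }
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_error(rmsd_matrix(tr, stride = 1, max_frames = 10), "max_frames")
})

test_that("GROMOS clustering: two basins, giant cutoff, brute-force equality", {
  tb <- two_basin_trajectory()
  M <- rmsd_matrix(tb$trajectory, stride = 1)
  cs <- gromos_cluster(M, cutoff = 0.5)
  expect_equal(length(cs$sizes), 2)
  expect_true(same_partition(cs$assignment, tb$truth))
  expect_true(all(sort(cs$sizes, decreasing = TRUE) == cs$sizes))
  # cutoff above matrix max: one cluster
  cs1 <- gromos_cluster(M, cutoff = max(M) + 1)
  expect_equal(length(cs1$sizes), 1)
  # brute-force equality on random matrices
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(stats::runif(30 * 3), 30)
    D <- as.matrix(stats::dist(P))
    cs <- gromos_cluster(structure(D, class = c("RMSDMatrix", "matrix", "array")),
                         cutoff = 0.4)
    expect_true(same_partition(cs$assignment, oracle_gromos(D, 0.4)))
    # greedy maximality: the largest cluster is as big as the best
    # within-cutoff neighbourhood of any frame
    counts <- rowSums(D <= 0.4)
    expect_equal(max(cs$sizes), max(counts))
    expect_equal(sum(cs$sizes), 30)
  }
})

test_that("single-linkage clustering: chaining, two basins, brute-force equality", {
  # chain of frames 0.5 apart with cutoff 1: chaining gives one cluster
  s <- make_polymer(5)
  base <- structure_xyz(s)
  dirv <- random_conformation(base, 1, seed = 77) - base
  dirv <- dirv / sqrt(mean(dirv^2))
  X <- t(sapply(0:9, function(k) base + 0.5 * k * dirv))
  tr <- new_trajectory(s, X); tr$superposed <- TRUE
  M <- rmsd_matrix(tr, stride = 1)
  cs <- linkage_cluster(M, cutoff = 1)
  expect_equal(length(cs$sizes), 1)
  gr <- gromos_cluster(M, cutoff = 1)
  # chained data reproduce linkage <= gromos cluster counts
  expect_lte(length(cs$sizes), length(gr$sizes))
  # two basins
  tb <- two_basin_trajectory()
  M2 <- rmsd_matrix(tb$trajectory, stride = 1)
  cs2 <- linkage_cluster(M2, cutoff = 0.5)
  expect_equal(length(cs2$sizes), 2)
  expect_true(same_partition(cs2$assignment, tb$truth))
  # centers are medoids inside their clusters
  for (cl in seq_along(cs2$sizes)) {
    members <- which(cs2$assignment == cl)
    expect_true(cs2$centers[cl] %in% members)
  }
  # brute-force equality on random matrices
  for (seed in 1:5) {
    set.seed(seed + 40)
    P <- matrix(stats::runif(25 * 3), 25)
    D <- as.matrix(stats::dist(P))
    cs <- linkage_cluster(structure(D, class = c("RMSDMatrix", "matrix", "array")),
                          cutoff = 0.3)
    expect_true(same_partition(cs$assignment, oracle_single_linkage(D, 0.3)))
  }
})

test_that("cluster assignments partition the strided frame set", {
  tb <- two_basin_trajectory()
  M <- rmsd_matrix(tb$trajectory, stride = 2)
  for (cs in list(gromos_cluster(M, 0.5), linkage_cluster(M, 0.5))) {
    a <- cluster_assignments(cs)
    expect_equal(nrow(a), 10)
    expect_equal(sort(unique(a$frame)), seq(1, 20, by = 2))
    expect_equal(sum(cs$sizes), 10)
    expect_true(all(a$cluster >= 1))
  }
})
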