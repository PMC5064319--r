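# Detector geometry, boundary behaviour and persistence reduction.

test_that("salt-bridge detection respects the 4.5 A COM cutoff and sign rule", {
  frame_of <- function(s) structure_xyz(s)
  s <- saltbridge_fixture(4.4)
  expect_equal(nrow(detect_saltbridges(frame_of(s), s)), 1)
  s <- saltbridge_fixture(4.6)
  expect_equal(nrow(detect_saltbridges(frame_of(s), s)), 0)
  s <- saltbridge_fixture(3.0, partner = "GLU")  # like charges
  expect_equal(nrow(detect_saltbridges(frame_of(s), s)), 0)
})

test_that("ions participate in salt bridges as single-atom groups", {
  atoms <- rbind(
    data.frame(name = c("CG", "OD1", "OD2"), resno = 1, resname = "ASP",
               chain = "A", x = 0, y = 0, z = 0),
    data.frame(name = "CA", resno = 9, resname = "CA", chain = "I",
               x = 3.0, y = 0, z = 0))
  s <- structure_from_atoms(atoms)
  ev <- detect_saltbridges(structure_xyz(s), s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "saltbridge")
})

test_that("H-bond detection requires both 3.5 A distance and 120 deg angle", {
  cases <- list(list(d = 3.4, a = 150, hit = TRUE),
                list(d = 3.4, a = 100, hit = FALSE),
                list(d = 3.6, a = 180, hit = FALSE),
                list(d = 3.4, a = 121, hit = TRUE),
                list(d = 3.4, a = 119, hit = FALSE))
  for (cs in cases) {
    s <- hbond_fixture(cs$d, cs$a)
    n <- nrow(detect_hbonds(structure_xyz(s), s))
    expect_equal(n, as.integer(cs$hit),
                 info = sprintf("d=%.1f angle=%d", cs$d, cs$a))
  }
})

test_that("hydrophobic detection uses 5.5 A COM cutoff and set membership", {
  s <- hydrophobic_fixture(5.0)
  expect_equal(nrow(detect_hydrophobic(structure_xyz(s), s)), 1)
  s <- hydrophobic_fixture(5.6)
  expect_equal(nrow(detect_hydrophobic(structure_xyz(s), s)), 0)
  s <- hydrophobic_fixture(3.0, partner = "SER")  # Ser not hydrophobic
  expect_equal(nrow(detect_hydrophobic(structure_xyz(s), s)), 0)
})

test_that("sequence-adjacent residues are excluded from contacts", {
  atoms <- rbind(
    data.frame(name = c("CB", "CG", "CD1", "CD2"), resno = 1, resname = "LEU",
               chain = "A", x = 0, y = 0, z = 0),
    data.frame(name = c("CB", "CG", "CD1", "CD2"), resno = 2, resname = "LEU",
               chain = "A", x = 3, y = 0, z = 0))
  s <- structure_from_atoms(atoms)
  expect_equal(nrow(detect_hydrophobic(structure_xyz(s), s)), 0)
  # different chains: always allowed
  atoms$chain <- rep(c("A", "B"), each = 4)
  s2 <- structure_from_atoms(atoms)
  expect_equal(nrow(detect_hydrophobic(structure_xyz(s2), s2)), 1)
})

test_that("persistence equals the planted on-fraction exactly", {
  s <- make_polymer(8)
  tr <- make_trajectory(s, contacts = list(
    contact_spec(1, 5, "hydrophobic", 0.25),
    contact_spec(2, 4, "saltbridge", 0.7),  # Glu(-) / Lys(+)
    contact_spec(3, 7, "hbond", 0.4)),
    n_frames = 200, seed = 42)
  gt <- attr(tr, "ground_truth")$contacts
  tab <- persistence_table(tr)
  for (ct in gt) {
    row <- tab[tab$resid_i == ct$resid_i & tab$resid_j == ct$resid_j &
                 tab$class == ct$class, ]
    expect_equal(nrow(row), 1)
    expect_identical(row$count, ct$on_count)
    expect_equal(row$persistence, ct$realized)
  }
  # no contacts other than the planted ones
  expect_equal(nrow(tab), 3)
  # persistence * n_frames is an integer frame count
  expect_true(all(abs(tab$persistence * tab$n_frames -
                        round(tab$persistence * tab$n_frames)) < 1e-9))
})

test_that("persistence is frame-order invariant and duplication invariant", {
  s <- make_polymer(6)
  tr <- make_trajectory(s, contacts = list(
    contact_spec(1, 5, "hydrophobic", 0.5)), n_frames = 60, seed = 9)
  tab <- persistence_table(tr)
  perm <- new_trajectory(s, tr$xyz[sample.int(60), ])
  tab_perm <- persistence_table(perm)
  expect_equal(tab_perm$persistence, tab$persistence)
  dup <- new_trajectory(s, tr$xyz[rep(seq_len(60), each = 2), ])
  tab_dup <- persistence_table(dup)
  expect_equal(tab_dup$persistence, tab$persistence)
  expect_equal(tab_dup$count, 2L * tab$count)
})

test_that("telegraph contacts hit their target persistence within sampling error", {
  s <- make_polymer(6)
  tr <- make_trajectory(s, contacts = list(
    contact_spec(1, 5, "hydrophobic", 0.40, model = "telegraph", dwell = 8)),
    n_frames = 2000, seed = 5)
  gt <- attr(tr, "ground_truth")$contacts[[1]]
  tab <- persistence_table(tr)
  expect_identical(tab$count, gt$on_count)       # realized matches exactly
  expect_lt(abs(tab$persistence - 0.40), 0.06)   # autocorrelated sampling band
})

test_that("structures without polar hydrogens fall back with a warning", {
  atoms <- rbind(
    data.frame(name = "OG", resno = 1, resname = "SER", chain = "A",
               x = 0, y = 0, z = 0),
    data.frame(name = c("CD", "OE1"), resno = 3, resname = "GLU", chain = "A",
               x = 3.0, y = 0, z = 0))
  s <- structure_from_atoms(atoms)
  warn_env <- psnpath:::.warn_env
  rm(list = ls(warn_env), envir = warn_env)
  expect_warning(ev <- detect_hbonds(structure_xyz(s), s), "hydrogen")
  expect_equal(nrow(ev), 0)
})

test_that("persistence tables round-trip through TSV", {
  tab <- make_random_persistence_table(6, density = 0.8, seed = 3,
                                       n_frames = 200)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_persistence_table(tab, f)
  tab2 <- read_persistence_table(f)
  expect_equal(tab2$persistence, tab$persistence, tolerance = 1e-7)
  expect_equal(tab2$resid_i, tab$resid_i)
})
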