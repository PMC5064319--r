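# Per-frame noncovalent interaction detectors and persistence reduction.
#
# Three interaction classes are detected per frame:
#   saltbridge  — oppositely signed charged-group centres of mass within
#                 4.5 A (ions participate as single-atom groups);
#   hbond       — donor-heavy-atom to acceptor distance <= 3.5 A AND
#                 donor-hydrogen-acceptor angle >= 120 deg;
#   hydrophobic — mass-weighted side-chain COM distance <= 5.5 A for
#                 residues in {Ala,Val,Leu,Ile,Met,Phe,Pro,Trp} plus any
#                 configured acyl group.
# Contacts between sequence-adjacent residues (|resno difference| < 2 in
# the same chain) are excluded; the separation is configurable.  A residue
# pair counts at most once per class per frame.

#' Detector configuration
#'
#' @param saltbridge_cutoff charged-group COM distance cutoff (A)
#' @param hbond_distance donor-acceptor heavy-atom distance cutoff (A)
#' @param hbond_angle minimum donor-hydrogen-acceptor angle (degrees)
#' @param hydrophobic_cutoff side-chain COM distance cutoff (A)
#' @param min_seq_sep minimum |resno| difference within one chain
#'   (default 2: nearest neighbours i, i+1 excluded)
#' @param saltbridge_mode `"com"` (group centre of mass, default) or
#'   `"closest"` (closest heavy-atom pair)
#' @return a list of detector parameters
#' @export
interaction_config <- function(saltbridge_cutoff = 4.5,
                               hbond_distance = 3.5,
                               hbond_angle = 120,
                               hydrophobic_cutoff = 5.5,
                               min_seq_sep = 2L,
                               saltbridge_mode = c("com", "closest")) {
  stopifnot(saltbridge_cutoff > 0, hbond_distance > 0,
            hbond_angle >= 0, hbond_angle <= 180, hydrophobic_cutoff > 0)
  list(saltbridge_cutoff = saltbridge_cutoff,
       hbond_distance = hbond_distance,
       hbond_angle = hbond_angle,
       hydrophobic_cutoff = hydrophobic_cutoff,
       min_seq_sep = as.integer(min_seq_sep),
       saltbridge_mode = match.arg(saltbridge_mode))
}

# TRUE where the residue pair passes the sequence-separation rule
.pair_allowed <- function(structure, ri, rj, min_seq_sep) {
  r <- structure$residues
  same_chain <- r$chain[ri] == r$chain[rj]
  sep_ok <- abs(r$resno[ri] - r$resno[rj]) >= min_seq_sep
  (ri != rj) & (!same_chain | sep_ok)
}

# mass-weighted centres of mass for a list of atom-index groups
.group_coms <- function(groups, frame, masses) {
  t(vapply(groups, function(g) {
    idx <- g$atoms
    m <- masses[idx]
    co <- matrix(frame[xyz_index(idx)], ncol = 3, byrow = TRUE)
    colSums(co * m) / sum(m)
  }, numeric(3)))
}

.contact_events <- function(structure, ri, rj, class, frame_index = NA_integer_) {
  n <- length(ri)
  class <- rep_len(as.character(class), n)
  frame_index <- rep_len(frame_index, n)
  swap <- ri > rj
  tmp <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp
  keep <- !duplicated(paste(ri, rj))
  data.frame(ri = ri[keep], rj = rj[keep], class = class[keep],
             frame = frame_index[keep], stringsAsFactors = FALSE)
}

#' Detect salt bridges in one frame
#'
#' An event is recorded for each pair of oppositely signed charged groups
#' whose centres of mass lie within the cutoff.  Ions are single-atom
#' charged groups.
#'
#' @param frame numeric xyz vector
#' @param structure a `Structure`
#' @param cutoff distance cutoff (A), default 4.5
#' @param config an [interaction_config()]
#' @return data.frame of events (`ri`, `rj`, `class`, `frame`)
#' @export
detect_saltbridges <- function(frame, structure, cutoff = config$saltbridge_cutoff,
                               config = interaction_config()) {
  stopifnot(cutoff > 0)
  grp <- structure$groups$charged
  if (length(grp) < 2) return(.contact_events(structure, integer(0), integer(0), character(0)))
  if (config$saltbridge_mode == "com") {
    pos <- .group_coms(grp, frame, structure$atoms$mass)
    d <- as.matrix(stats::dist(pos))
  } else {
    d <- matrix(Inf, length(grp), length(grp))
    for (a in seq_along(grp)) for (b in seq_len(a - 1L)) {
      ca <- matrix(frame[xyz_index(grp[[a]]$atoms)], ncol = 3, byrow = TRUE)
      cb <- matrix(frame[xyz_index(grp[[b]]$atoms)], ncol = 3, byrow = TRUE)
      d[a, b] <- d[b, a] <- min(pracma::distmat(ca, cb))
    }
  }
  sgn <- vapply(grp, `[[`, integer(1), "sign")
  ris <- vapply(grp, `[[`, integer(1), "ri")
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    opp <- sgn[idx[, 1]] * sgn[idx[, 2]] < 0
    ok <- opp & .pair_allowed(structure, ris[idx[, 1]], ris[idx[, 2]],
                              config$min_seq_sep)
    idx <- idx[ok, , drop = FALSE]
  }
  .contact_events(structure, ris[idx[, 1]], ris[idx[, 2]],
                  rep("saltbridge", nrow(idx)))
}

#' Detect hydrogen bonds in one frame
#'
#' Requires explicit polar hydrogens: an event needs donor-to-acceptor
#' heavy-atom distance within `d_cut` and a donor-hydrogen-acceptor angle
#' of at least `angle_cut` degrees.  Donors lacking a hydrogen are skipped
#' with a one-time warning.
#'
#' @param frame numeric xyz vector
#' @param structure a `Structure`
#' @param d_cut distance cutoff (A), default 3.5
#' @param angle_cut angle cutoff (degrees), default 120
#' @param config an [interaction_config()]
#' @return data.frame of events
#' @export
detect_hbonds <- function(frame, structure, d_cut = config$hbond_distance,
                          angle_cut = config$hbond_angle,
                          config = interaction_config()) {
  don <- structure$groups$donors
  acc <- structure$groups$acceptors
  empty <- .contact_events(structure, integer(0), integer(0), character(0))
  if (!length(don) || !length(acc)) return(empty)
  no_h <- vapply(don, function(d) is.na(d$h), logical(1))
  if (any(no_h)) {
    .warn_once("hbond_no_hydrogen",
               "donor(s) without explicit hydrogen skipped; add polar hydrogens for the angle criterion")
    don <- don[!no_h]
    if (!length(don)) return(empty)
  }
  d_idx <- vapply(don, `[[`, integer(1), "d")
  h_idx <- vapply(don, `[[`, integer(1), "h")
  d_ri <- vapply(don, `[[`, integer(1), "ri")
  a_ri <- structure$atoms$ri[acc]
  dpos <- matrix(frame[xyz_index(d_idx)], ncol = 3, byrow = TRUE)
  hpos <- matrix(frame[xyz_index(h_idx)], ncol = 3, byrow = TRUE)
  apos <- matrix(frame[xyz_index(acc)], ncol = 3, byrow = TRUE)
  dd <- pracma::distmat(dpos, apos)  # donors x acceptors
  cand <- which(dd <= d_cut, arr.ind = TRUE)
  if (nrow(cand)) {
    ok <- .pair_allowed(structure, d_ri[cand[, 1]], a_ri[cand[, 2]],
                        config$min_seq_sep)
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand)) {
    hd <- dpos[cand[, 1], , drop = FALSE] - hpos[cand[, 1], , drop = FALSE]
    ha <- apos[cand[, 2], , drop = FALSE] - hpos[cand[, 1], , drop = FALSE]
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    cand <- cand[ang >= angle_cut, , drop = FALSE]
  }
  .contact_events(structure, d_ri[cand[, 1]], a_ri[cand[, 2]],
                  rep("hbond", nrow(cand)))
}

#' Detect hydrophobic contacts in one frame
#'
#' An event is recorded for each pair of hydrophobic side-chain groups
#' (including configured acyl groups) whose mass-weighted centres of mass
#' lie within the cutoff.
#'
#' @param frame numeric xyz vector
#' @param structure a `Structure`
#' @param cutoff COM distance cutoff (A), default 5.5
#' @param config an [interaction_config()]
#' @return data.frame of events
#' @export
detect_hydrophobic <- function(frame, structure, cutoff = config$hydrophobic_cutoff,
                               config = interaction_config()) {
  stopifnot(cutoff > 0)
  grp <- structure$groups$hydrophobic
  if (length(grp) < 2) return(.contact_events(structure, integer(0), integer(0), character(0)))
  pos <- .group_coms(grp, frame, structure$atoms$mass)
  d <- as.matrix(stats::dist(pos))
  ris <- vapply(grp, `[[`, integer(1), "ri")
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    ok <- .pair_allowed(structure, ris[idx[, 1]], ris[idx[, 2]],
                        config$min_seq_sep)
    idx <- idx[ok, , drop = FALSE]
  }
  .contact_events(structure, ris[idx[, 1]], ris[idx[, 2]],
                  rep("hydrophobic", nrow(idx)))
}

.warn_env <- new.env(parent = emptyenv())
.warn_once <- function(key, msg) {
  if (is.null(.warn_env[[key]])) {
    .warn_env[[key]] <- TRUE
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

#' Reduce a trajectory to an interaction-persistence table
#'
#' Runs all three detectors on every frame and reports, per residue pair
#' and interaction class, the fraction of frames in which the contact is
#' present.
#'
#' @param trajectory a `Trajectory`
#' @param config an [interaction_config()]
#' @return a `PersistenceTable` data.frame with columns `chain_i`,
#'   `resid_i`, `resname_i`, `chain_j`, `resid_j`, `resname_j`, `class`,
#'   `count`, `n_frames`, `persistence` (fraction in \[0,1\])
#' @export
persistence_table <- function(trajectory, config = interaction_config()) {
  nf <- n_frames(trajectory)
  if (nf < 1) stop("trajectory has no frames")
  s <- trajectory$structure
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    frame <- trajectory$xyz[f, ]
    ev <- rbind(detect_saltbridges(frame, s, config = config),
                detect_hbonds(frame, s, config = config),
                detect_hydrophobic(frame, s, config = config))
    if (!nrow(ev)) next
    keys <- paste(ev$ri, ev$rj, ev$class, sep = "|")
    for (k in keys) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  keys <- ls(counts)
  if (!length(keys)) {
    tab <- data.frame(chain_i = character(0), resid_i = integer(0),
                      resname_i = character(0), chain_j = character(0),
                      resid_j = integer(0), resname_j = character(0),
                      class = character(0), count = integer(0),
                      n_frames = integer(0), persistence = numeric(0),
                      stringsAsFactors = FALSE)
    class(tab) <- c("PersistenceTable", "data.frame")
    return(tab)
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  ri <- as.integer(parts[, 1]); rj <- as.integer(parts[, 2])
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  r <- s$residues
  tab <- data.frame(
    chain_i = r$chain[ri], resid_i = r$resno[ri], resname_i = r$resname[ri],
    chain_j = r$chain[rj], resid_j = r$resno[rj], resname_j = r$resname[rj],
    class = parts[, 3], count = unname(cnt), n_frames = nf,
    persistence = unname(cnt) / nf, stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$chain_i, tab$resid_i, tab$chain_j, tab$resid_j, tab$class), ]
  rownames(tab) <- NULL
  class(tab) <- c("PersistenceTable", "data.frame")
  tab
}

#' Serialize a persistence table as TSV
#'
#' Persistence is written in percent, matching the network convention.
#'
#' @param table a `PersistenceTable`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_persistence_table <- function(table, path) {
  out <- data.frame(chain_i = table$chain_i, resid_i = table$resid_i,
                    resname_i = table$resname_i,
                    chain_j = table$chain_j, resid_j = table$resid_j,
                    resname_j = table$resname_j, class = table$class,
                    persistence_percent = round(100 * table$persistence, 6),
                    n_frames = table$n_frames, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a persistence table written by [write_persistence_table()]
#' @param path file path
#' @return a `PersistenceTable`
#' @export
read_persistence_table <- function(path) {
  df <- read_tsv(path)
  df$persistence <- df$persistence_percent / 100
  df$count <- as.integer(round(df$persistence * df$n_frames))
  df$persistence_percent <- NULL
  class(df) <- c("PersistenceTable", "data.frame")
  df
}

# node id columns for a persistence table
.table_node_ids <- function(table) {
  list(i = paste(table$chain_i, table$resname_i, table$resid_i, sep = ":"),
       j = paste(table$chain_j, table$resname_j, table$resid_j, sep = ":"))
}
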