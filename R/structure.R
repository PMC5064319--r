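# Residue templates and the Structure / Trajectory containers.
#
# A Structure is a base-R list: an atom table, a residue table and
# precomputed interaction groups (charged groups, hydrophobic side chains,
# polar-hydrogen donor pairs, acceptor atoms) resolved from a built-in
# template table.  Coordinates are in Angstrom throughout; residue
# numbering is 1-based author numbering (PDB style); frame indices are
# 0-based.  Trajectory frames follow the bio3d xyz convention: a matrix
# with one row per frame and columns x1,y1,z1,x2,y2,z2,...

# Atomic masses (Da) by element.  Any consistent mass table is acceptable
# for COM computation; these are standard atomic weights.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, CA = 40.078, MG = 24.305, ZN = 65.38, "NA" = 22.990,
  K = 39.098, CL = 35.45, FE = 55.845
)

.hydrophobic_resnames <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "TRP")

# Side-chain atom-name templates for the 20 standard amino acids plus
# common ions and a myristoyl-like acyl group.  Only atoms actually
# present in a given residue are used; absent atoms are dropped silently
# (e.g. coarse synthetic residues carry a subset).
.residue_templates <- local({
  aa <- function(charged = NULL, sign = 0L, hydrophobic = NULL,
                 donors = NULL, acceptors = NULL) {
    list(category = "standard", charged = charged, sign = sign,
         hydrophobic = hydrophobic, donors = donors, acceptors = acceptors)
  }
  ion <- function(sign) list(category = "ion", charged = "*", sign = sign,
                             hydrophobic = NULL, donors = NULL, acceptors = NULL)
  list(
    ALA = aa(hydrophobic = "CB"),
    ARG = aa(charged = c("NE", "NH1", "NH2"), sign = +1L,
             donors = list(c("NE", "HE"), c("NH1", "HH11"), c("NH2", "HH21"))),
    ASN = aa(donors = list(c("ND2", "HD21")), acceptors = "OD1"),
    ASP = aa(charged = c("CG", "OD1", "OD2"), sign = -1L,
             acceptors = c("OD1", "OD2")),
    CYS = aa(donors = list(c("SG", "HG"))),
    GLN = aa(donors = list(c("NE2", "HE21")), acceptors = "OE1"),
    GLU = aa(charged = c("CD", "OE1", "OE2"), sign = -1L,
             acceptors = c("OE1", "OE2")),
    GLY = aa(),
    HIS = aa(charged = c("ND1", "NE2"), sign = 0L,  # +1 only if config says protonated
             donors = list(c("NE2", "HE2")), acceptors = "ND1"),
    ILE = aa(hydrophobic = c("CB", "CG1", "CG2", "CD1")),
    LEU = aa(hydrophobic = c("CB", "CG", "CD1", "CD2")),
    LYS = aa(charged = "NZ", sign = +1L, donors = list(c("NZ", "HZ1"))),
    MET = aa(hydrophobic = c("CB", "CG", "SD", "CE")),
    PHE = aa(hydrophobic = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    PRO = aa(hydrophobic = c("CB", "CG", "CD")),
    SER = aa(donors = list(c("OG", "HG")), acceptors = "OG"),
    THR = aa(donors = list(c("OG1", "HG1")), acceptors = "OG1"),
    TRP = aa(hydrophobic = c("CB", "CG", "CD1", "CD2", "NE1",
                             "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             donors = list(c("NE1", "HE1"))),
    TYR = aa(donors = list(c("OH", "HH")), acceptors = "OH"),
    VAL = aa(hydrophobic = c("CB", "CG1", "CG2")),
    # divalent / monovalent ions participate as single-atom charged groups
    CA  = ion(+1L), MG = ion(+1L), ZN = ion(+1L),
    "NA" = ion(+1L), K = ion(+1L), CL = ion(-1L),
    # myristoyl-like acyl group: all carbons form one hydrophobic group
    MYR = list(category = "acyl", charged = NULL, sign = 0L,
               hydrophobic = "^C", donors = NULL, acceptors = NULL)
  )
})

.guess_element <- function(name, resname) {
  if (resname %in% c("CA", "MG", "ZN", "NA", "K", "CL", "FE")) return(resname)
  first <- sub("^[0-9]*", "", name)
  two <- toupper(substr(first, 1, 2))
  if (two %in% c("CL", "BR")) return(two)
  toupper(substr(first, 1, 1))
}

#' Build a Structure from an atom table
#'
#' Low-level constructor used by [load_structure()] and the synthetic
#' generators.  Residues are identified by `(chain, resno)`; interaction
#' groups (charged groups, hydrophobic side chains, polar-hydrogen donors,
#' acceptors) are resolved from a built-in template table covering the 20
#' standard amino acids, common ions, and a myristoyl-like acyl group.
#'
#' @param atoms data.frame with columns `name`, `resno`, `resname`,
#'   `chain`, `x`, `y`, `z`; optional `element`, `mass`, `serial`.
#' @param config optional list. `config$residues` maps unknown residue
#'   names to template entries (`list(category=, charged=, sign=,
#'   hydrophobic=, donors=, acceptors=)`); `config$his_protonated = TRUE`
#'   treats His ring nitrogens as a positive charged group.
#' @return object of class `Structure`: `$atoms` (with global residue
#'   ordinal `ri`), `$residues`, `$groups`.
#' @export
structure_from_atoms <- function(atoms, config = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resno", "resname", "chain", "x", "y", "z") %in% names(atoms)))
  atoms$name <- as.character(atoms$name)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element))
    atoms$element <- mapply(.guess_element, atoms$name, atoms$resname)
  if (is.null(atoms$mass)) {
    m <- .element_masses[atoms$element]
    if (anyNA(m)) stop("unknown element(s): ",
                       paste(unique(atoms$element[is.na(m)]), collapse = ", "))
    atoms$mass <- unname(m)
  }
  if (any(atoms$mass <= 0)) stop("atomic masses must be strictly positive")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (anyDuplicated(atoms$serial))
    warning("overlapping atom serial numbers; atoms kept, serials not unique")

  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  ri <- match(key, unique(key))
  atoms$ri <- ri
  first <- !duplicated(ri)
  residues <- data.frame(
    ri = ri[first], resno = atoms$resno[first], resname = atoms$resname[first],
    chain = atoms$chain[first], stringsAsFactors = FALSE
  )
  # residue indices must increase within each chain
  for (ch in unique(residues$chain)) {
    rr <- residues$resno[residues$chain == ch]
    if (any(diff(rr) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }

  templates <- .residue_templates
  extra <- config$residues
  if (!is.null(extra)) templates[names(extra)] <- extra

  charged <- list(); hydrophobic <- list()
  donors <- list(); acceptors <- integer(0)
  category <- character(nrow(residues))
  for (k in seq_len(nrow(residues))) {
    rn <- residues$resname[k]
    tpl <- templates[[rn]]
    if (is.null(tpl))
      stop("no residue template for '", rn,
           "'; supply one via config$residues", call. = FALSE)
    category[k] <- tpl$category
    rows <- which(atoms$ri == residues$ri[k])
    nm <- atoms$name[rows]
    pick <- function(spec) {
      if (is.null(spec)) return(integer(0))
      if (identical(spec, "*")) return(rows)
      if (length(spec) == 1 && startsWith(spec, "^"))
        return(rows[grepl(spec, nm)])
      rows[nm %in% spec]
    }
    sgn <- tpl$sign
    if (rn == "HIS" && isTRUE(config$his_protonated)) sgn <- +1L
    ch_idx <- pick(tpl$charged)
    if (length(ch_idx) && sgn != 0L)
      charged[[length(charged) + 1L]] <- list(ri = k, sign = sgn, atoms = ch_idx)
    hp_idx <- pick(tpl$hydrophobic)
    if (length(hp_idx))
      hydrophobic[[length(hydrophobic) + 1L]] <- list(ri = k, atoms = hp_idx)
    for (d in tpl$donors %||% list()) {
      di <- rows[nm == d[1]]; hi <- rows[nm == d[2]]
      if (length(di) == 1) {
        donors[[length(donors) + 1L]] <-
          list(ri = k, d = di, h = if (length(hi) == 1) hi else NA_integer_)
      }
    }
    acceptors <- c(acceptors, pick(tpl$acceptors))
    # backbone carbonyl oxygen is always an acceptor when present
    acceptors <- c(acceptors, rows[nm == "O"])
  }
  residues$category <- category

  out <- list(
    atoms = atoms, residues = residues,
    groups = list(charged = charged, hydrophobic = hydrophobic,
                  donors = donors, acceptors = sort(unique(acceptors)))
  )
  class(out) <- "Structure"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$residues), "residues,", nrow(x$atoms), "atoms\n")
  cat("  categories:",
      paste(sprintf("%s=%d", names(table(x$residues$category)),
                    table(x$residues$category)), collapse = ", "), "\n")
  cat("  charged groups:", length(x$groups$charged),
      "| hydrophobic groups:", length(x$groups$hydrophobic),
      "| donors:", length(x$groups$donors),
      "| acceptors:", length(x$groups$acceptors), "\n")
  invisible(x)
}

#' Node identifier for a residue
#'
#' PSN node ids are `"CHAIN:RESNAME:RESID"` strings, e.g. `"A:GLU:75"`.
#'
#' @param structure a `Structure`
#' @param ri residue ordinal(s) (row of `structure$residues`)
#' @return character vector of node ids
#' @export
node_id <- function(structure, ri) {
  r <- structure$residues[ri, , drop = FALSE]
  paste(r$chain, r$resname, r$resno, sep = ":")
}

#' Base-coordinate frame of a Structure
#'
#' @param structure a `Structure`
#' @return numeric xyz vector (x1,y1,z1,...) of the stored coordinates
#' @export
structure_xyz <- function(structure) {
  as.numeric(t(as.matrix(structure$atoms[, c("x", "y", "z")])))
}

#' Expand atom indices to xyz column indices
#'
#' @param sel integer atom indices
#' @return integer vector of positions in an xyz row (3 per atom)
#' @export
xyz_index <- function(sel) {
  as.integer(t(outer(3L * (sel - 1L), 1:3, `+`)))
}

#' Select Calpha atoms
#'
#' Returns indices of `CA` atoms of standard residues (calcium ions,
#' which share the name, are excluded via the residue category).
#'
#' @param structure a `Structure`
#' @return integer atom indices
#' @export
select_calpha <- function(structure) {
  std <- structure$residues$ri[structure$residues$category == "standard"]
  which(structure$atoms$name == "CA" & structure$atoms$ri %in% std)
}

#' Assemble a Trajectory
#'
#' @param structure a `Structure`
#' @param xyz numeric matrix, one row per frame, `3 * natoms` columns
#' @param replicas optional data.frame with `label`, `start`, `end`
#'   (1-based inclusive frame ranges); defaults to one replica spanning
#'   all frames.  Ranges must partition the frame list.
#' @param time optional per-frame times (ps)
#' @return object of class `Trajectory`
#' @export
new_trajectory <- function(structure, xyz, replicas = NULL, time = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3L * nrow(structure$atoms))
  n <- nrow(xyz)
  if (is.null(replicas))
    replicas <- data.frame(label = "R1", start = 1L, end = n,
                           stringsAsFactors = FALSE)
  o <- order(replicas$start)
  replicas <- replicas[o, , drop = FALSE]
  covered <- unlist(mapply(seq, replicas$start, replicas$end, SIMPLIFY = FALSE))
  if (length(covered) != n || anyDuplicated(covered) || !all(sort(covered) == seq_len(n)))
    stop("replica ranges must partition the frame list without overlap")
  out <- list(structure = structure, xyz = unname(as.matrix(xyz)),
              replicas = replicas, time = time, superposed = FALSE)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$xyz), "frames,", nrow(x$structure$atoms), "atoms,",
      nrow(x$replicas), "replica(s)",
      if (isTRUE(x$superposed)) "(superposed)" else "", "\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory a `Trajectory`
#' @return integer frame count
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Extract one frame as an xyz vector
#'
#' @param trajectory a `Trajectory`
#' @param i 0-based frame index
#' @return numeric xyz vector
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 0, i < nrow(trajectory$xyz))
  trajectory$xyz[i + 1L, ]
}

#' Extract one replica as a Trajectory
#'
#' @param trajectory a `Trajectory`
#' @param label replica label
#' @return a `Trajectory` holding only that replica's frames
#' @export
get_replica <- function(trajectory, label) {
  r <- trajectory$replicas
  k <- which(r$label == label)
  if (length(k) != 1) stop("no replica labelled '", label, "'")
  idx <- seq(r$start[k], r$end[k])
  out <- new_trajectory(trajectory$structure,
                        trajectory$xyz[idx, , drop = FALSE],
                        time = trajectory$time[idx])
  out$replicas$label <- label
  out$superposed <- trajectory$superposed
  out
}
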