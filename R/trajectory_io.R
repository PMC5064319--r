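# Reading topologies/trajectories, superposition, and graph/table export.

#' Load a topology into a Structure
#'
#' Reads a PDB file (via bio3d) or a GROMACS `.gro` file and resolves
#' interaction groups from the built-in residue templates.
#'
#' @param path file path
#' @param dialect `"pdb"` or `"gro"`; default guessed from the extension
#' @param config passed to [structure_from_atoms()] (templates for
#'   non-standard residues, His protonation)
#' @return a `Structure`
#' @export
load_structure <- function(path, dialect = c("auto", "pdb", "gro"),
                           config = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  atoms <- switch(dialect,
    pdb = {
      pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                      error = function(e) stop("cannot parse PDB file: ",
                                               conditionMessage(e)))
      a <- pdb$atom
      data.frame(serial = a$eleno, name = a$elety, resno = a$resno,
                 resname = a$resid,
                 chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
                 x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    },
    gro = .read_gro(path)
  )
  if (anyDuplicated(atoms$serial))
    warning("duplicate atom serials in ", basename(path))
  structure_from_atoms(atoms, config = config)
}

# GRO fixed-column format; coordinates are nm, converted to Angstrom.
.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("cannot parse GRO file: too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < 2 + n) stop("cannot parse GRO file: bad atom count")
  body <- lines[3:(2 + n)]
  resno <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  serial <- as.integer(substr(body, 16, 20))
  x <- as.numeric(substr(body, 21, 28)) * 10
  y <- as.numeric(substr(body, 29, 36)) * 10
  z <- as.numeric(substr(body, 37, 44)) * 10
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("cannot parse GRO file: malformed atom lines")
  data.frame(serial = serial, name = name, resno = resno, resname = resname,
             chain = "A", x = x, y = y, z = z, stringsAsFactors = FALSE)
}

#' Load trajectory frames
#'
#' Concatenates one or more frame files (multi-model PDB or DCD) against a
#' topology, applying a frame stride.  Provenance records one replica per
#' input path.
#'
#' @param structure the topology `Structure`
#' @param paths ordered character vector of trajectory files
#' @param stride keep every `stride`-th frame (default 1)
#' @param labels optional replica labels (default `R1`, `R2`, ...)
#' @return a `Trajectory`
#' @export
load_trajectory <- function(structure, paths, stride = 1L, labels = NULL) {
  stopifnot(length(paths) >= 1)
  if (!is.numeric(stride) || stride < 1 || stride != round(stride))
    stop("stride must be a positive integer")
  stride <- as.integer(stride)
  nat <- nrow(structure$atoms)
  if (is.null(labels)) labels <- paste0("R", seq_along(paths))
  blocks <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[k]
    if (!file.exists(p)) stop("file not found: ", p)
    xyz <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      unclass(bio3d::read.dcd(p, verbose = FALSE))
    } else {
      m <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz
      unclass(m)
    }
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nat)
      stop("topology mismatch: ", basename(p), " has ", ncol(xyz) / 3,
           " atoms, Structure has ", nat)
    blocks[[k]] <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  }
  nf <- vapply(blocks, nrow, integer(1))
  ends <- cumsum(nf)
  replicas <- data.frame(label = labels, start = c(1L, head(ends, -1) + 1L),
                         end = ends, stringsAsFactors = FALSE)
  new_trajectory(structure, do.call(rbind, blocks), replicas = replicas)
}

#' Superpose every frame onto a reference
#'
#' Rigid-body least-squares fit of each frame to a reference frame on a
#' selection (default Calpha), via bio3d's Kabsch fitting.  Returns a new
#' Trajectory; the input is unmodified.
#'
#' @param trajectory a `Trajectory`
#' @param reference xyz vector of the reference frame (default: frame 0)
#' @param selection integer atom indices to fit on (default Calpha)
#' @return superposed `Trajectory` (flagged `superposed = TRUE`)
#' @export
superpose <- function(trajectory, reference = NULL, selection = NULL) {
  if (is.null(selection)) selection <- select_calpha(trajectory$structure)
  if (length(selection) == 0) stop("empty atom selection")
  if (is.null(reference)) reference <- trajectory$xyz[1L, ]
  if (length(reference) != ncol(trajectory$xyz))
    stop("reference frame incompatible with Structure atom count")
  ids <- xyz_index(selection)
  fitted <- bio3d::fit.xyz(fixed = reference, mobile = trajectory$xyz,
                           fixed.inds = ids, mobile.inds = ids)
  if (is.vector(fitted)) fitted <- matrix(fitted, nrow = 1)
  out <- trajectory
  out$xyz <- unname(as.matrix(fitted))
  out$superposed <- TRUE
  out
}

# best-fit RMSD of frames against one reference (bio3d Kabsch fit);
# the sqrt of a tiny negative residual on (near-)identical frames yields
# NaN, which is clamped to zero
.fit_rmsd <- function(reference, xyz, ids = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  r <- suppressWarnings(as.numeric(
    bio3d::rmsd(a = reference, b = xyz, a.inds = ids, b.inds = ids,
                fit = TRUE)))
  r[is.nan(r)] <- 0
  r
}

#' Write a multi-model PDB
#'
#' Portable plain-text frame format used by the synthetic generators and
#' for cluster-center export.  One MODEL block per frame.
#'
#' @param structure a `Structure`
#' @param xyz matrix of frames (or single xyz vector)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_models_pdb <- function(structure, xyz, path) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     a$serial, nm, a$resname, a$chain, a$resno,
                     co[, 1], co[, 2], co[, 3], a$element)
    writeLines(c(sprintf("MODEL %8d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Export a PSN graph
#'
#' Writes GML (via igraph) or a TSV edge list.  Node ids are
#' `"CHAIN:RESNAME:RESID"`; edges carry persistence (percent) and the
#' contributing interaction classes.  [import_graph()] reproduces the
#' graph exactly.
#'
#' @param graph an igraph PSN (from [build_psn()])
#' @param path output file
#' @param dialect `"gml"` or `"edgelist"`
#' @return `path`, invisibly
#' @export
export_graph <- function(graph, path, dialect = c("gml", "edgelist")) {
  dialect <- match.arg(dialect)
  if (dialect == "gml") {
    igraph::write_graph(graph, path, format = "gml")
    # drop the timestamped Creator line for reproducible output
    lines <- readLines(path)
    writeLines(lines[!startsWith(lines, "Creator")], path)
  } else {
    e <- igraph::as_data_frame(graph, what = "edges")
    iso <- setdiff(igraph::V(graph)$name, unique(c(e$from, e$to)))
    df <- data.frame(node_i = e$from, node_j = e$to,
                     persistence_percent = round(100 * e$persistence, 6),
                     classes = e$classes, stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# p_T=", igraph::graph_attr(graph, "p_T") %||% NA,
                      " formula=", igraph::graph_attr(graph, "formula") %||% ""),
               con)
    writeLines(paste0("# isolated_nodes=", paste(iso, collapse = ",")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import an exported PSN graph
#'
#' @param path file written by [export_graph()]
#' @param dialect `"gml"` or `"edgelist"`
#' @return an igraph PSN
#' @export
import_graph <- function(path, dialect = c("gml", "edgelist")) {
  dialect <- match.arg(dialect)
  if (dialect == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    if (!is.null(igraph::vertex_attr(g, "id")))
      g <- igraph::delete_vertex_attr(g, "id")
    return(g)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  iso <- sub("^# isolated_nodes=", "", hdr[startsWith(hdr, "# isolated_nodes=")])
  iso <- if (nchar(iso)) strsplit(iso, ",")[[1]] else character(0)
  meta <- sub("^# p_T=", "", hdr[startsWith(hdr, "# p_T=")])
  p_T <- suppressWarnings(as.numeric(strsplit(meta, " formula=")[[1]][1]))
  formula <- strsplit(meta, " formula=")[[1]][2]
  edges <- if (nrow(df)) data.frame(from = df$node_i, to = df$node_j,
                                    persistence = df$persistence_percent / 100,
                                    classes = df$classes,
                                    stringsAsFactors = FALSE)
           else data.frame(from = character(0), to = character(0))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = unique(c(df$node_i, df$node_j, iso)))
  if (!is.na(p_T)) g <- igraph::set_graph_attr(g, "p_T", p_T)
  if (!is.na(formula) && nchar(formula))
    g <- igraph::set_graph_attr(g, "formula", formula)
  g
}

#' Write a data frame as TSV
#'
#' Plain deterministic TSV writer used for all tabular outputs.
#'
#' @param df data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
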