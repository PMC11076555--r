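# Structures, trajectories and atom selections.
#
# Coordinates are in Angstrom throughout; residue indices are 1-based PDB
# author numbering. Insertion codes are not supported (reading a record that
# carries one is an error). Hydrogens are kept on input but excluded from all
# distance computations by the heavy-atom selections used downstream.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA1TO3 <- structure(names(AA3), names = unname(AA3))

guess_element <- function(name) {
  s <- gsub("[0-9']", "", name)
  ifelse(substr(s, 1, 1) == "H", "H", substr(s, 1, 1))
}

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `name`, `resid`, `resname`, `chain`,
#'   `x`, `y`, `z` and optionally `element` (guessed from the atom name when
#'   absent).
#' @param model_id Integer model identifier.
#' @param extra_resnames Additional residue names accepted beyond the
#'   standard 20 three-letter codes.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, extra_resnames = character()) {
  need <- c("name", "resid", "resname", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms$resid <- as.integer(atoms$resid)
  bad <- setdiff(unique(atoms$resname), c(names(AA3), extra_resnames))
  if (length(bad))
    stopf("unknown residue name(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate atom(s): %s", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> model %d: %d atoms, %d residues, chain(s) %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

coords_matrix <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

#' Construct a trajectory
#'
#' @param topology A `structure_model` defining the atom order of every frame.
#' @param frames Numeric array of dimension frames x atoms x 3 (Angstrom).
#' @param frame_spacing Spacing between frames, arbitrary units.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_spacing = 1) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stopf("frames must be an F x A x 3 array")
  if (dim(frames)[2] != nrow(topology$atoms))
    stopf("frame atom count (%d) does not match topology (%d)",
          dim(frames)[2], nrow(topology$atoms))
  if (dim(frames)[1] < 1L) stopf("trajectory needs at least one frame")
  structure(list(topology = topology, frames = frames,
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              dim(x$frames)[1], dim(x$frames)[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[1]

parse_pdb_atom_line <- function(line, lineno) {
  f <- function(a, b) substr(line, a, b)
  icode <- f(27, 27)
  if (icode != " " && icode != "")
    stopf("line %d: insertion codes are not supported", lineno)
  xyz <- suppressWarnings(as.numeric(c(f(31, 38), f(39, 46), f(47, 54))))
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  resid <- suppressWarnings(as.integer(f(23, 26)))
  if (any(is.na(xyz)) || is.na(resid))
    stopf("line %d: malformed fixed-width ATOM record", lineno)
  list(name = trimws(f(13, 16)), altloc = f(17, 17),
       resname = trimws(f(18, 20)), chain = f(22, 22), resid = resid,
       x = xyz[1], y = xyz[2], z = xyz[3],
       occ = if (is.na(occ)) 1 else occ,
       element = trimws(f(77, 78)))
}

#' Read a (multi-model) PDB file
#'
#' One `structure_model` is returned per `MODEL` record, or a single model if
#' none is present. For alternate locations, the highest-occupancy conformer
#' is kept, ties broken in favour of altloc `A`.
#'
#' @param path PDB file path.
#' @param extra_resnames Residue names accepted beyond the standard 20.
#' @return List of `structure_model` objects.
#' @export
read_pdb <- function(path, extra_resnames = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  cur_id <- 1L
  seen_model <- FALSE
  flush <- function(models, cur, cur_id) {
    if (!length(cur)) return(models)
    df <- do.call(rbind, lapply(cur, function(a)
      data.frame(name = a$name, altloc = a$altloc, resid = a$resid,
                 resname = a$resname, chain = a$chain,
                 x = a$x, y = a$y, z = a$z, occ = a$occ,
                 element = if (nzchar(a$element)) a$element else guess_element(a$name),
                 stringsAsFactors = FALSE)))
    # altloc resolution: highest occupancy wins, tie -> 'A'
    key <- paste(df$chain, df$resid, df$name)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      sub <- df[idx, ]
      idx[order(-sub$occ, sub$altloc)][1]
    }), use.names = FALSE)
    df <- df[sort(keep), c("name", "element", "resid", "resname", "chain",
                           "x", "y", "z")]
    models[[length(models) + 1L]] <-
      structure_model(df, model_id = cur_id, extra_resnames = extra_resnames)
    models
  }
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      models <- flush(models, cur, cur_id)
      cur <- list()
      seen_model <- TRUE
      cur_id <- suppressWarnings(as.integer(trimws(substr(lines[i], 11, 14))))
      if (is.na(cur_id)) cur_id <- length(models) + 1L
    } else if (rec == "ENDMDL") {
      models <- flush(models, cur, cur_id)
      cur <- list()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      cur[[length(cur) + 1L]] <- parse_pdb_atom_line(lines[i], i)
    }
  }
  models <- flush(models, cur, cur_id)
  if (!length(models)) stopf("no ATOM records found in %s", path)
  if (!seen_model) models[[1]]$model_id <- 1L
  models
}

format_pdb_atom <- function(serial, a) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial,
          if (nchar(a$name) < 4) paste0(" ", a$name) else a$name,
          " ", a$resname, a$chain, a$resid, " ", a$x, a$y, a$z, 1, 0,
          a$element)
}

#' Write one or more structure models as a PDB file
#'
#' Multi-model input is wrapped in `MODEL`/`ENDMDL` records.
#'
#' @param models A `structure_model` or list of them.
#' @param path Output path.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL %8d", m$model_id), con)
    at <- m$atoms
    for (i in seq_len(nrow(at)))
      writeLines(format_pdb_atom(i, at[i, ]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

topology_signature <- function(model)
  paste(model$atoms$name, model$atoms$resid, model$atoms$chain, sep = "|")

#' Read a trajectory from a multi-model PDB or plain-text xyzt file
#'
#' The `xyzt` format is a plain-text frame stack: a header line
#' `"natoms nframes"` followed, per frame, by `natoms` lines
#' `"name resid resname chain x y z"`. The atom order must be identical
#' across frames.
#'
#' @param path Input file path.
#' @param format `"pdb-multimodel"` or `"xyzt"`.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, format = c("pdb-multimodel", "xyzt")) {
  format <- match.arg(format)
  if (format == "pdb-multimodel") {
    models <- read_pdb(path)
    sig <- topology_signature(models[[1]])
    frames <- array(NA_real_, c(length(models), nrow(models[[1]]$atoms), 3))
    for (f in seq_along(models)) {
      if (!identical(topology_signature(models[[f]]), sig))
        stopf("frame %d: atom order/composition differs from frame 1", f)
      frames[f, , ] <- coords_matrix(models[[f]])
    }
    return(trajectory(models[[1]], frames))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || any(is.na(hdr)))
    stopf("xyzt header must be 'natoms nframes'")
  natoms <- hdr[1]; nfr <- hdr[2]
  if (length(lines) < 1L + natoms * nfr)
    stopf("xyzt file truncated: expected %d atom lines", natoms * nfr)
  body <- utils::read.table(text = lines[2:(1 + natoms * nfr)],
                            col.names = c("name", "resid", "resname", "chain",
                                          "x", "y", "z"),
                            colClasses = c("character", "integer", "character",
                                           "character", "numeric", "numeric",
                                           "numeric"))
  frames <- array(NA_real_, c(nfr, natoms, 3))
  sig0 <- NULL
  for (f in seq_len(nfr)) {
    blk <- body[((f - 1L) * natoms + 1L):(f * natoms), ]
    sig <- paste(blk$name, blk$resid, blk$chain, sep = "|")
    if (f == 1L) sig0 <- sig
    else if (!identical(sig, sig0))
      stopf("frame %d: atom order/composition differs from frame 1", f)
    frames[f, , ] <- as.matrix(blk[, c("x", "y", "z")])
  }
  topo <- structure_model(body[seq_len(natoms),
                               c("name", "resid", "resname", "chain",
                                 "x", "y", "z")])
  trajectory(topo, frames)
}

#' Write a trajectory in the plain-text xyzt format
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_xyzt <- function(traj, path) {
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(at), n_frames(traj)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("%s %d %s %s %.6f %.6f %.6f",
                       at$name, at$resid, at$resname, at$chain,
                       traj$frames[f, , 1], traj$frames[f, , 2],
                       traj$frames[f, , 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  models <- lapply(seq_len(n_frames(traj)), function(f) {
    m <- traj$topology
    m$atoms[, c("x", "y", "z")] <- traj$frames[f, , ]
    m$model_id <- f
    m
  })
  write_pdb(models, path)
}

#' Define an atom selection
#'
#' A deterministic predicate over atoms. Side-chain selection keeps heavy
#' atoms excluding the backbone set \{N, CA, C, O, OXT\}; glycine, which has
#' no side-chain heavy atom, is represented by its CA proxy (configurable).
#'
#' @param chain Chain id(s) to keep, or `NULL` for all.
#' @param resid Residue indices to keep, or `NULL` for all.
#' @param atom_names Atom names to keep, or `NULL` for all.
#' @param sidechain If `TRUE`, restrict to side-chain heavy atoms.
#' @param heavy_only If `TRUE` (default), drop hydrogens.
#' @param gly_proxy Atom name standing in for the glycine side chain
#'   (`"CA"`), or `NA` to drop glycines.
#' @return An object of class `atom_selection`.
#' @export
selection <- function(chain = NULL, resid = NULL, atom_names = NULL,
                      sidechain = FALSE, heavy_only = TRUE, gly_proxy = "CA") {
  structure(list(chain = chain, resid = resid, atom_names = atom_names,
                 sidechain = sidechain, heavy_only = heavy_only,
                 gly_proxy = gly_proxy),
            class = "atom_selection")
}

#' Alpha-carbon selection
#' @param chain Chain id(s) to keep, or `NULL` for all.
#' @return An `atom_selection` keeping CA atoms.
#' @export
ca_selection <- function(chain = NULL) selection(chain = chain, atom_names = "CA")

#' Apply an atom selection
#'
#' @param x A `structure_model` or `trajectory`.
#' @param sel An `atom_selection`.
#' @return Sorted integer atom indices (possibly empty).
#' @export
select_atoms <- function(x, sel) {
  if (inherits(x, "trajectory")) x <- x$topology
  stopifnot(inherits(x, "structure_model"), inherits(sel, "atom_selection"))
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resid)) keep <- keep & at$resid %in% sel$resid
  if (!is.null(sel$atom_names)) keep <- keep & at$name %in% sel$atom_names
  if (sel$heavy_only) keep <- keep & at$element != "H"
  if (sel$sidechain) {
    sc <- !(at$name %in% BACKBONE_ATOMS)
    if (!is.na(sel$gly_proxy))
      sc <- sc | (at$resname == "GLY" & at$name == sel$gly_proxy)
    keep <- keep & sc
  }
  sort(which(keep))
}
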