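# Reading and writing molecular structures, coordinate trajectories and the
# ligand node-assignment table.
#
# PDB parsing and DCD reading are delegated to bio3d; the DCD writer is
# implemented here (CHARMM-style, little-endian) because bio3d provides no
# write.dcd. Coordinates are always in Angstrom; no unit auto-detection.

# Residue names treated as standard protein residues (incl. common His/Cys
# force-field variants); waters are never ligand candidates.
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "MSE"
)
.water_res <- c("HOH", "WAT", "TIP3", "TIP", "SOL")

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 columns) into an ordered atom table.
#' HETATM residues whose residue name is not a standard amino acid (and not
#' water) are designated as the hapten; exactly one such residue is required.
#' Hydrogens are retained but flagged, and are excluded from all node geometry
#' downstream. Insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @return An object of class `fq_system`: a list with `atoms` (a tibble with
#'   columns `serial`, `name`, `element`, `chain`, `resseq`, `resname`,
#'   `record`, `is_heavy`, `x`, `y`, `z`) and `ligand_residues` (a one-row
#'   tibble with `chain`, `resseq`, `resname`).
#' @export
read_structure <- function(path) {
  fq_assert(file.exists(path), paste0("file not found: ", path), "io")
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM  |HETATM)", lines)
  if (length(at) == 0L) {
    fq_abort(paste0("no ATOM/HETATM records in ", path), "empty_input")
  }
  for (ln in at) {
    rec <- lines[ln]
    if (nchar(rec) >= 27 && substr(rec, 27, 27) != " ") {
      fq_abort(paste0("insertion code at line ", ln,
                      " is not supported (residues are chain+resseq only)"),
               "parse")
    }
    for (k in 0:2) {
      fld <- substr(rec, 31 + 8 * k, 38 + 8 * k)
      if (is.na(suppressWarnings(as.numeric(fld)))) {
        fq_abort(paste0("malformed coordinate field '", trimws(fld),
                        "' at line ", ln), "parse")
      }
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  if (anyDuplicated(a$eleno)) {
    dup <- a$eleno[duplicated(a$eleno)][1]
    fq_abort(paste0("duplicated atom serial number: ", dup), "parse")
  }
  element <- a$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el)) {
    element[missing_el] <- bio3d::atom2ele(a$elety[missing_el])
  }
  element <- trimws(toupper(element))
  chain <- a$chain
  chain[is.na(chain)] <- ""
  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = element,
    chain = chain,
    resseq = as.integer(a$resno),
    resname = trimws(a$resid),
    record = a$type,
    is_heavy = !(element %in% c("H", "D")),
    x = a$x, y = a$y, z = a$z
  )
  lig <- atoms$record == "HETATM" &
    !(atoms$resname %in% c(.standard_aa, .water_res))
  lig_res <- unique(atoms[lig, c("chain", "resseq", "resname")])
  prot <- atoms$resname %in% .standard_aa
  n_prot_res <- nrow(unique(atoms[prot, c("chain", "resseq")]))
  fq_assert(n_prot_res >= 1,
            "structure contains no standard protein residues", "empty_input")
  if (nrow(lig_res) != 1L) {
    fq_abort(paste0("expected exactly 1 ligand (hetero) residue, found ",
                    nrow(lig_res)), "parse")
  }
  new_fq_system(atoms, lig_res)
}

new_fq_system <- function(atoms, ligand_residues) {
  structure(list(atoms = atoms, ligand_residues = ligand_residues),
            class = "fq_system")
}

#' @export
print.fq_system <- function(x, ...) {
  np <- nrow(unique(x$atoms[x$atoms$resname %in% .standard_aa,
                            c("chain", "resseq")]))
  cat("<fq_system> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_heavy), " heavy), ", np, " protein residues, ligand ",
      x$ligand_residues$resname[1], "\n", sep = "")
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

ligand_atom_idx <- function(system) {
  which(system$atoms$chain == system$ligand_residues$chain[1] &
          system$atoms$resseq == system$ligand_residues$resseq[1] &
          system$atoms$record == "HETATM")
}

#' Read a coordinate trajectory
#'
#' Supports CHARMM-style binary DCD (via [bio3d::read.dcd]) and plain
#' multi-frame XYZ text. Coordinates are interpreted as Angstrom. The atom
#' count of every frame must match the system.
#'
#' @param path Trajectory file.
#' @param system An `fq_system`, used to validate the atom count.
#' @param format `"auto"` (by extension), `"dcd"` or `"xyz"`.
#' @return An `fq_trajectory`: list with `system` and `xyz`, an
#'   `n_frames x (3 * n_atoms)` matrix in x1,y1,z1,x2,... column order.
#' @export
read_trajectory <- function(path, system, format = c("auto", "dcd", "xyz")) {
  format <- match.arg(format)
  fq_assert(file.exists(path), paste0("file not found: ", path), "io")
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  }
  xyz <- if (format == "dcd") read_dcd_frames(path) else read_xyz_frames(path)
  if (ncol(xyz) != 3L * n_atoms(system)) {
    fq_abort(paste0("trajectory has ", ncol(xyz) / 3, " atoms per frame but the",
                    " system has ", n_atoms(system)), "shape")
  }
  new_fq_trajectory(system, xyz, source = path)
}

new_fq_trajectory <- function(system, xyz, source = "memory") {
  dimnames(xyz) <- NULL
  structure(list(system = system, xyz = xyz, source = source),
            class = "fq_trajectory")
}

#' @export
print.fq_trajectory <- function(x, ...) {
  cat("<fq_trajectory> ", nrow(x$xyz), " frames x ", ncol(x$xyz) / 3,
      " atoms (", x$source, ")\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

read_dcd_frames <- function(path) {
  xyz <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) {
      fq_abort(paste0("failed to read DCD (possibly truncated): ",
                      conditionMessage(e)), "truncated")
    }
  )
  matrix(as.numeric(xyz), nrow = nrow(xyz))
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      fq_abort(paste0("expected an atom count at line ", i), "parse")
    }
    if (i + 1L + nat > length(lines)) {
      fq_abort(paste0("truncated final frame: frame starting at line ", i,
                      " declares ", nat, " atoms but the file ends early"),
               "truncated")
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    coords <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      tok <- strsplit(trimws(block[k]), "\\s+")[[1]]
      if (length(tok) < 4L) {
        fq_abort(paste0("malformed XYZ atom line at line ", i + 1L + k), "parse")
      }
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v)) {
        fq_abort(paste0("malformed coordinate at line ", i + 1L + k), "parse")
      }
      coords[k, ] <- v
    }
    frames[[length(frames) + 1L]] <- as.vector(t(coords))
    i <- i + 2L + nat
  }
  fq_assert(length(frames) >= 1L, "no frames in XYZ file", "empty_input")
  nper <- lengths(frames)
  fq_assert(length(unique(nper)) == 1L,
            "inconsistent atom counts across XYZ frames", "shape")
  do.call(rbind, frames)
}

#' Write a trajectory to DCD or XYZ
#'
#' Round-trips with [read_trajectory()]: atom counts are preserved exactly and
#' coordinates to single precision (DCD) or the printed text precision (XYZ).
#'
#' @param traj An `fq_trajectory`.
#' @param path Output file.
#' @param format `"dcd"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("dcd", "xyz")) {
  if (length(format) == 1L && !format %in% c("dcd", "xyz")) {
    fq_abort(paste0("unknown trajectory format '", format, "'"), "usage")
  }
  format <- match.arg(format)
  if (format == "dcd") {
    write_dcd_frames(traj$xyz, path)
  } else {
    write_xyz_frames(traj$xyz, traj$system$atoms$name, path)
  }
  invisible(path)
}

# CHARMM-style DCD: Fortran unformatted records, little-endian, one float32
# x/y/z record triple per frame, no unit-cell records.
write_dcd_frames <- function(xyz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    bytes <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(bytes), con, size = 4L, endian = "little")
    writeBin(bytes, con)
    writeBin(length(bytes), con, size = 4L, endian = "little")
  }
  nf <- nrow(xyz)
  nat <- ncol(xyz) %/% 3L
  rec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    icntrl <- integer(20)
    icntrl[1] <- nf      # frames in file
    icntrl[2] <- 1L      # first step
    icntrl[3] <- 1L      # save interval
    icntrl[4] <- nf
    icntrl[20] <- 24L    # CHARMM version stamp
    writeBin(icntrl[1:9], c2, size = 4L, endian = "little")
    writeBin(1, c2, size = 4L, endian = "little")  # timestep as float32
    writeBin(icntrl[11:20], c2, size = 4L, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L, endian = "little")
    writeBin(charToRaw(formatC("written by fqcross", width = -80)), c2)
  })
  rec(function(c2) writeBin(nat, c2, size = 4L, endian = "little"))
  xi <- seq(1L, 3L * nat, by = 3L)
  for (f in seq_len(nf)) {
    for (ax in 0:2) {
      vals <- xyz[f, xi + ax]
      rec(function(c2) writeBin(vals, c2, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

write_xyz_frames <- function(xyz, atom_names, path) {
  nat <- ncol(xyz) %/% 3L
  con <- file(path, "w")
  on.exit(close(con))
  xi <- seq(1L, 3L * nat, by = 3L)
  for (f in seq_len(nrow(xyz))) {
    writeLines(c(as.character(nat), paste0("frame ", f)), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", atom_names,
                       xyz[f, xi], xyz[f, xi + 1L], xyz[f, xi + 2L]), con)
  }
  invisible(path)
}

#' Read a ligand node-assignment table
#'
#' The table maps every ligand heavy atom to one of 3-4 coarse-grained ligand
#' nodes and flags exactly one node label as the quinolone-ring node (the node
#' holding all non-hydrogen atoms of the quinolone ring, including any
#' ring-attached halogen or amino substituents).
#'
#' @param path Tab-separated file with columns `atom_name`, `node_label`,
#'   `ring_flag` (0/1).
#' @return An `fq_node_map`: list with `map` (tibble) and `ring_label`.
#' @export
read_node_map <- function(path) {
  fq_assert(file.exists(path), paste0("file not found: ", path), "io")
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           atom_name = readr::col_character(),
                           node_label = readr::col_character(),
                           ring_flag = readr::col_integer()
                         ))
  need <- c("atom_name", "node_label", "ring_flag")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    fq_abort(paste0("node map lacks column(s): ", paste(miss, collapse = ", ")),
             "config")
  }
  if (anyDuplicated(map$atom_name)) {
    fq_abort(paste0("duplicate atom_name in node map: ",
                    map$atom_name[duplicated(map$atom_name)][1]), "config")
  }
  fq_assert(all(map$ring_flag %in% c(0L, 1L)),
            "ring_flag must be 0 or 1", "config")
  ring_labels <- unique(map$node_label[map$ring_flag == 1L])
  if (length(ring_labels) != 1L) {
    fq_abort(paste0("expected exactly one ring-flagged node label, found ",
                    length(ring_labels)), "config")
  }
  new_fq_node_map(map[, need], ring_labels)
}

new_fq_node_map <- function(map, ring_label) {
  structure(list(map = map, ring_label = ring_label), class = "fq_node_map")
}

#' @export
print.fq_node_map <- function(x, ...) {
  cat("<fq_node_map> ", nrow(x$map), " atoms -> ",
      length(unique(x$map$node_label)), " ligand nodes (ring: ",
      x$ring_label, ")\n", sep = "")
  invisible(x)
}

#' Write a ligand node-assignment table
#'
#' @param node_map An `fq_node_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_map <- function(node_map, path) {
  readr::write_tsv(node_map$map, path)
  invisible(path)
}
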