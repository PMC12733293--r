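# Coarse-grained node partitioning: one node per amino-acid residue and 3-4
# user-defined nodes per ligand, with a designated quinolone-ring node.
#
# Representative points: residue node = C-alpha position, ligand node =
# unweighted centroid of its member heavy atoms (the `first_atom` convention is
# available as an alternative). Hydrogens never enter node geometry.

#' Partition a protein-ligand system into network nodes
#'
#' Protein nodes come first, in residue order; ligand nodes follow in
#' alphabetical label order. The ligand map must cover every ligand heavy atom
#' (no silent defaults) and define 3-4 nodes, one of them flagged as the
#' quinolone-ring node.
#'
#' @param system An `fq_system`.
#' @param node_map An `fq_node_map` (see [read_node_map()]).
#' @param node_point Representative-point convention: `"calpha_centroid"`
#'   (default; C-alpha for residues, heavy-atom centroid for ligand nodes) or
#'   `"first_atom"` (first heavy atom for every node).
#' @return An `fq_partition`: tibble with columns `node_id`, `kind`
#'   (`"residue"`/`"ligand"`), `label`, `atoms` (list-column of heavy-atom row
#'   indices into `system$atoms`) and `rep_atom` (C-alpha / first-atom index,
#'   `NA` for centroid nodes), with attributes `ring_node_id` and `node_point`.
#' @export
partition_system <- function(system, node_map,
                             node_point = c("calpha_centroid", "first_atom")) {
  node_point <- match.arg(node_point)
  atoms <- system$atoms
  lig_idx <- ligand_atom_idx(system)
  prot <- which(atoms$resname %in% .standard_aa & !(seq_len(nrow(atoms)) %in% lig_idx))

  res_key <- residue_key(atoms$chain[prot], atoms$resseq[prot])
  res_order <- unique(res_key)
  res_rows <- split(prot, factor(res_key, levels = res_order))

  prot_nodes <- imap(res_rows, function(rows, key) {
    heavy <- rows[atoms$is_heavy[rows]]
    if (length(heavy) == 0L) {
      fq_abort(paste0("residue ", key, " has zero heavy atoms"), "partition")
    }
    rep_atom <- if (node_point == "calpha_centroid") {
      ca <- heavy[atoms$name[heavy] == "CA"]
      if (length(ca) == 0L) {
        fq_abort(paste0("residue ", key, " has no C-alpha atom"), "partition")
      }
      ca[1]
    } else {
      heavy[1]
    }
    tibble(kind = "residue", label = key, atoms = list(heavy),
           rep_atom = as.integer(rep_atom))
  })

  lig_heavy <- lig_idx[atoms$is_heavy[lig_idx]]
  map <- node_map$map
  unknown <- setdiff(map$atom_name, atoms$name[lig_heavy])
  if (length(unknown)) {
    fq_abort(paste0("node map lists atom(s) absent from the ligand: ",
                    paste(unknown, collapse = ", ")), "config")
  }
  uncovered <- setdiff(atoms$name[lig_heavy], map$atom_name)
  if (length(uncovered)) {
    fq_abort(paste0("ligand heavy atom(s) not assigned to any node: ",
                    paste(uncovered, collapse = ", ")), "config")
  }
  labels <- sort(unique(map$node_label))
  if (length(labels) < 3L || length(labels) > 4L) {
    fq_abort(paste0("ligand must be partitioned into 3-4 nodes, got ",
                    length(labels)), "partition")
  }
  lig_nodes <- map(labels, function(lb) {
    nms <- map$atom_name[map$node_label == lb]
    rows <- lig_heavy[match(nms, atoms$name[lig_heavy])]
    tibble(kind = "ligand", label = lb, atoms = list(sort(rows)),
           rep_atom = NA_integer_)
  })

  part <- bind_rows(c(prot_nodes, lig_nodes))
  part$node_id <- seq_len(nrow(part))
  part <- part[, c("node_id", "kind", "label", "atoms", "rep_atom")]
  ring_id <- part$node_id[part$kind == "ligand" & part$label == node_map$ring_label]
  structure(part,
            class = c("fq_partition", class(tibble())),
            ring_node_id = ring_id,
            node_point = node_point)
}

ring_node_id <- function(partition) attr(partition, "ring_node_id")

#' @export
print.fq_partition <- function(x, ...) {
  cat("<fq_partition> ", sum(x$kind == "residue"), " residue + ",
      sum(x$kind == "ligand"), " ligand nodes; ring node ",
      ring_node_id(x), " (", x$label[ring_node_id(x)], ")\n", sep = "")
  NextMethod()
}

#' Summarise a partition as a plain table
#'
#' @param partition An `fq_partition`.
#' @return Tibble with `node_id`, `kind`, `label`, `n_atoms`.
#' @export
partition_summary <- function(partition) {
  tibble(node_id = partition$node_id, kind = partition$kind,
         label = partition$label, n_atoms = lengths(partition$atoms))
}

#' Node representative coordinates for a single frame
#'
#' @param partition An `fq_partition`.
#' @param frame Either an `n_atoms x 3` coordinate matrix or a length
#'   `3 * n_atoms` xyz vector.
#' @return An `n_nodes x 3` matrix of node positions (Angstrom).
#' @export
node_coordinates <- function(partition, frame) {
  if (is.matrix(frame) && ncol(frame) == 3L) {
    coords <- frame
  } else {
    coords <- matrix(as.numeric(frame), ncol = 3L, byrow = TRUE)
  }
  out <- matrix(NA_real_, nrow(partition), 3L)
  for (k in seq_len(nrow(partition))) {
    if (!is.na(partition$rep_atom[k])) {
      out[k, ] <- coords[partition$rep_atom[k], ]
    } else {
      members <- partition$atoms[[k]]
      out[k, ] <- colMeans(coords[members, , drop = FALSE])
    }
  }
  out
}

#' Reduce an atom trajectory to a node trajectory
#'
#' Applies the partition's representative-point rule to every frame.
#'
#' @param traj An `fq_trajectory`.
#' @param partition An `fq_partition` built from the same system.
#' @return An `fq_node_trajectory`: list with `partition` and `xyz`
#'   (`n_frames x (3 * n_nodes)` matrix).
#' @export
node_trajectory <- function(traj, partition) {
  nat <- ncol(traj$xyz) %/% 3L
  # averaging weights: atoms x nodes
  w <- matrix(0, nat, nrow(partition))
  for (k in seq_len(nrow(partition))) {
    if (!is.na(partition$rep_atom[k])) {
      w[partition$rep_atom[k], k] <- 1
    } else {
      members <- partition$atoms[[k]]
      w[members, k] <- 1 / length(members)
    }
  }
  nxyz <- matrix(NA_real_, nrow(traj$xyz), 3L * nrow(partition))
  for (ax in 0:2) {
    cols <- seq(1L, 3L * nat, by = 3L) + ax
    nxyz[, seq(1L, ncol(nxyz), by = 3L) + ax] <- traj$xyz[, cols, drop = FALSE] %*% w
  }
  new_fq_node_trajectory(partition, nxyz)
}

new_fq_node_trajectory <- function(partition, xyz) {
  structure(list(partition = partition, xyz = xyz),
            class = "fq_node_trajectory")
}

#' @export
print.fq_node_trajectory <- function(x, ...) {
  cat("<fq_node_trajectory> ", nrow(x$xyz), " frames x ", ncol(x$xyz) / 3,
      " nodes\n", sep = "")
  invisible(x)
}
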