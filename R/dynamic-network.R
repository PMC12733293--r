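# Correlation-weighted dynamical network construction.
#
# Pipeline: superpose frames (least squares on protein nodes), compute the
# normalized cross-correlation of node displacement vectors, restrict edges to
# persistent atom-level contacts, and weight edges w = -ln|C|.

#' Rigid-body superposition of a node trajectory
#'
#' Each frame is least-squares superposed (optimal rotation + translation,
#' computed on protein nodes only) onto a reference; ligand nodes are carried
#' along by the same rigid transform. With `reference = "mean_structure"`
#' frames are first aligned to the initial frame, and then re-aligned onto the
#' mean of that alignment.
#'
#' @param ntraj An `fq_node_trajectory` with at least 2 frames.
#' @param reference `"mean_structure"` (default) or `"first_frame"`.
#' @return The superposed `fq_node_trajectory`.
#' @export
superpose_frames <- function(ntraj, reference = c("mean_structure", "first_frame")) {
  reference <- match.arg(reference)
  fq_assert(nrow(ntraj$xyz) >= 2L, "superposition needs at least 2 frames", "shape")
  prot <- ntraj$partition$node_id[ntraj$partition$kind == "residue"]
  prot_inds <- as.vector(rbind(3L * (prot - 1L) + 1L,
                               3L * (prot - 1L) + 2L,
                               3L * (prot - 1L) + 3L))
  check_not_collinear(ntraj$xyz[1, prot_inds])
  fitted <- fit_to_reference(ntraj$xyz, ntraj$xyz[1, ], prot_inds)
  if (reference == "mean_structure") {
    fitted <- fit_to_reference(fitted, colMeans(fitted), prot_inds)
  }
  new_fq_node_trajectory(ntraj$partition, fitted)
}

fit_to_reference <- function(xyz, ref, prot_inds) {
  bio3d::fit.xyz(fixed = ref, mobile = xyz,
                 fixed.inds = prot_inds, mobile.inds = prot_inds)
}

check_not_collinear <- function(vec) {
  m <- matrix(vec, ncol = 3L, byrow = TRUE)
  m <- sweep(m, 2L, colMeans(m))
  sv <- svd(m, nu = 0, nv = 0)$d
  if (length(sv) < 2L || sv[2] < 1e-6 * max(sv[1], 1e-12)) {
    fq_abort("protein nodes are (near-)collinear; superposition is degenerate",
             "superposition")
  }
  invisible(TRUE)
}

#' Normalized cross-correlation matrix of node motions
#'
#' For displacement vectors about the time mean, `Dr_i(t) = r_i(t) - <r_i>`,
#' computes the scalar (dot-product) correlation
#' `C_ij = <Dr_i . Dr_j> / sqrt(<|Dr_i|^2><|Dr_j|^2>)` with time averages over
#' frames. The input should already be superposed if the trajectory contains
#' global rigid motion.
#'
#' @param ntraj An `fq_node_trajectory` with at least 2 frames.
#' @return An `fq_correlation`: symmetric `n_nodes x n_nodes` matrix with unit
#'   diagonal and entries in `[-1, 1]`; attribute `n_frames`.
#' @export
correlation_matrix <- function(ntraj) {
  fq_assert(nrow(ntraj$xyz) >= 2L, "correlation needs at least 2 frames", "shape")
  nn <- ncol(ntraj$xyz) %/% 3L
  d <- sweep(ntraj$xyz, 2L, colMeans(ntraj$xyz))
  num <- matrix(0, nn, nn)
  for (ax in 0:2) {
    cols <- seq(1L, 3L * nn, by = 3L) + ax
    num <- num + crossprod(d[, cols, drop = FALSE])
  }
  num <- num / nrow(ntraj$xyz)
  v <- diag(num)
  zero <- which(v <= 1e-24)
  if (length(zero)) {
    fq_abort(paste0("node(s) with zero total fluctuation: ",
                    paste(zero, collapse = ", "),
                    "; correlation undefined"), "degenerate")
  }
  cmat <- num / sqrt(outer(v, v))
  cmat <- (cmat + t(cmat)) / 2
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  structure(cmat, class = c("fq_correlation", "matrix"),
            n_frames = nrow(ntraj$xyz))
}

#' @export
print.fq_correlation <- function(x, ...) {
  cat("<fq_correlation> ", nrow(x), " nodes, ", attr(x, "n_frames"),
      " frames\n", sep = "")
  invisible(x)
}

#' Persistent-contact map between nodes
#'
#' Nodes i and j are in contact iff any heavy-atom pair (one atom from each
#' node) lies within `distance_cutoff` in at least `min_frame_fraction` of the
#' analysed frames (both bounds inclusive). Contacts are evaluated at the atom
#' level and lifted to node pairs, because ligand fragment nodes are spatially
#' extended. Covalently adjacent node pairs (sequence-neighbouring residues
#' and ligand fragment nodes of the same molecule) are always edge-eligible,
#' which keeps the graph connected along chains.
#'
#' @param traj An `fq_trajectory` (atom level).
#' @param partition An `fq_partition` for the same system.
#' @param distance_cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_frame_fraction Minimum fraction of frames (default 0.75).
#' @param skip_frames Number of leading frames discarded as equilibration.
#' @param stride Keep every `stride`-th frame after the skip.
#' @return An `fq_contact_map`: list with `in_contact` (logical matrix),
#'   `contact_fraction` (numeric matrix) and `params`.
#' @export
contact_map <- function(traj, partition, distance_cutoff = 4.5,
                        min_frame_fraction = 0.75,
                        skip_frames = 0L, stride = 1L) {
  fq_assert(is_scalar_number(distance_cutoff) && distance_cutoff > 0,
            "distance_cutoff must be a positive number", "config")
  fq_assert(is_scalar_number(min_frame_fraction) &&
              min_frame_fraction > 0 && min_frame_fraction <= 1,
            "min_frame_fraction must lie in (0, 1]", "config")
  fq_assert(is_scalar_number(stride) && stride >= 1,
            "stride must be >= 1", "config")
  fq_assert(is_scalar_number(skip_frames) && skip_frames >= 0,
            "skip_frames must be >= 0", "config")
  sel <- seq.int(skip_frames + 1L, nrow(traj$xyz), by = stride)
  fq_assert(length(sel) >= 1L, "no frames left after skip/stride", "config")

  nn <- nrow(partition)
  heavy <- unlist(partition$atoms)
  node_of <- rep(partition$node_id, lengths(partition$atoms))
  m <- length(heavy)
  # dist() lower-triangle ordering: pair (i, j), i < j, grouped by column i
  ii <- unlist(lapply(seq_len(m - 1L), function(i) rep(i, m - i)))
  jj <- unlist(lapply(seq_len(m - 1L), function(i) seq.int(i + 1L, m)))
  ni <- node_of[ii]
  nj <- node_of[jj]
  inter <- ni != nj
  key <- pmin(ni, nj)[inter] * (nn + 1) + pmax(ni, nj)[inter]
  keyf <- factor(key)
  keys <- as.numeric(levels(keyf))
  hits <- numeric(length(keys))
  cols <- lapply(0:2, function(ax) 3L * (heavy - 1L) + 1L + ax)
  cut2 <- (distance_cutoff * (1 + 1e-12))^2
  for (f in sel) {
    cx <- traj$xyz[f, cols[[1]]]; cy <- traj$xyz[f, cols[[2]]]
    cz <- traj$xyz[f, cols[[3]]]
    d2 <- (cx[ii] - cx[jj])^2 + (cy[ii] - cy[jj])^2 + (cz[ii] - cz[jj])^2
    inc <- rowsum(as.numeric(d2[inter] <= cut2), keyf, reorder = FALSE)
    hits <- hits + as.numeric(inc > 0)
  }
  frac <- matrix(0, nn, nn)
  ki <- floor(keys / (nn + 1))
  kj <- keys - ki * (nn + 1)
  frac[cbind(ki, kj)] <- hits / length(sel)
  frac <- pmax(frac, t(frac))
  in_contact <- frac >= min_frame_fraction - 1e-12
  # covalent adjacency is always edge-eligible
  adj <- covalent_adjacency(partition)
  in_contact <- in_contact | adj
  diag(in_contact) <- FALSE
  structure(list(in_contact = in_contact, contact_fraction = frac,
                 params = list(distance_cutoff = distance_cutoff,
                               min_frame_fraction = min_frame_fraction,
                               skip_frames = skip_frames, stride = stride,
                               n_frames_used = length(sel))),
            class = "fq_contact_map")
}

covalent_adjacency <- function(partition) {
  nn <- nrow(partition)
  adj <- matrix(FALSE, nn, nn)
  res <- which(partition$kind == "residue")
  if (length(res) > 1L) {
    key <- do.call(rbind, strsplit(partition$label[res], ":", fixed = TRUE))
    chain <- key[, 1]
    seqno <- as.integer(key[, 2])
    for (a in seq_len(length(res) - 1L)) {
      b <- a + 1L
      if (chain[a] == chain[b] && abs(seqno[a] - seqno[b]) == 1L) {
        adj[res[a], res[b]] <- adj[res[b], res[a]] <- TRUE
      }
    }
  }
  lig <- which(partition$kind == "ligand")
  if (length(lig) > 1L) {
    adj[lig, lig] <- TRUE
    diag(adj) <- FALSE
  }
  adj
}

#' @export
print.fq_contact_map <- function(x, ...) {
  cat("<fq_contact_map> ", sum(x$in_contact[upper.tri(x$in_contact)]),
      " contact pairs of ", nrow(x$in_contact), " nodes (cutoff ",
      x$params$distance_cutoff, " A, fraction ",
      x$params$min_frame_fraction, ")\n", sep = "")
  invisible(x)
}

#' Build the correlation-weighted network
#'
#' Creates an edge for every contact pair with `|C_ij| > 0`, weighted
#' `w_ij = -ln|C_ij| >= 0` (natural logarithm); short path distances therefore
#' correspond to strongly correlated communication routes. Contact pairs with
#' exactly zero correlation are dropped with a warning (infinite weight).
#'
#' @param cmat An `fq_correlation`.
#' @param contacts An `fq_contact_map` of matching dimension.
#' @return An `fq_network`: list with `n_nodes`, `edges` (tibble `i`, `j`,
#'   `cij`, `weight`, with `i < j`) and `params`.
#' @export
build_network <- function(cmat, contacts) {
  fq_assert(nrow(cmat) == nrow(contacts$in_contact),
            "correlation matrix and contact map have different node counts",
            "shape")
  nn <- nrow(cmat)
  ut <- which(upper.tri(contacts$in_contact) & contacts$in_contact,
              arr.ind = TRUE)
  cij <- cmat[ut]
  zero <- cij == 0
  if (any(zero)) {
    rlang::warn(paste0(sum(zero), " contact pair(s) with exactly zero ",
                       "correlation dropped (infinite weight)"))
  }
  cij_kept <- cij[!zero]
  edges <- tibble(i = ut[!zero, 1], j = ut[!zero, 2], cij = cij_kept,
                  weight = -log(abs(cij_kept)))
  edges <- arrange(edges, .data$i, .data$j)
  structure(list(n_nodes = nn, edges = edges,
                 params = contacts$params),
            class = "fq_network")
}

#' @export
print.fq_network <- function(x, ...) {
  cat("<fq_network> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.fq_network <- function(x, ...) x$edges

#' Write the network as an edge-list TSV
#'
#' @param net An `fq_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}
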