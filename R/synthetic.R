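# Synthetic test-data generation: toy antibody-hapten complexes, seeded
# Gaussian-displacement trajectories with controllable ligand-protein motion
# coupling, and noisy competitive-ELISA panels with exported ground truth.
#
# The generator is statistical, not physical: the network analysis consumes
# only motion correlations and contact persistence, so a multivariate-Gaussian
# displacement field controls exactly the statistics the method measures.

#' Specification for a synthetic trajectory
#'
#' @param n_residues Number of protein residues (>= 20 for a bound ligand).
#' @param ligand_nodes 3 or 4 coarse-grained ligand nodes.
#' @param n_frames Number of trajectory frames.
#' @param coupling_rho Correlation between ligand-node and binding-site
#'   residue displacements, in `[0, 1)`. 0.8 emulates a stably bound
#'   (cross-reactive) hapten, 0 an uncoupled one.
#' @param n_site_residues Number of residues designated as the binding site.
#' @param displacement_sd Per-axis node displacement standard deviation
#'   (Angstrom).
#' @param neighbor_rho Correlation between covalently or spatially adjacent
#'   nodes (keeps the protein graph connected with finite weights).
#' @param geometry `"bound"` (ligand inside the pocket) or `"detached"`
#'   (ligand moved far outside the site, which forces `coupling_rho = 0`).
#' @param seed Integer seed; the full output is deterministic given the seed.
#' @return An `fq_trajectory_spec` (validated list).
#' @export
trajectory_spec <- function(n_residues = 30L, ligand_nodes = 3L,
                            n_frames = 1500L, coupling_rho = 0.8,
                            n_site_residues = 5L, displacement_sd = 0.5,
                            neighbor_rho = 0.3,
                            geometry = c("bound", "detached"), seed = 1L) {
  geometry <- match.arg(geometry)
  fq_assert(is_scalar_number(n_residues) && n_residues >= 3,
            "n_residues must be >= 3", "config")
  fq_assert(ligand_nodes %in% c(3L, 4L), "ligand_nodes must be 3 or 4",
            "config")
  fq_assert(is_scalar_number(n_frames) && n_frames >= 2,
            "n_frames must be >= 2", "config")
  fq_assert(is_scalar_number(coupling_rho) && coupling_rho >= 0 &&
              coupling_rho < 1, "coupling_rho must lie in [0, 1)", "config")
  fq_assert(is_scalar_number(n_site_residues) && n_site_residues >= 1 &&
              n_site_residues <= n_residues,
            "n_site_residues must lie in [1, n_residues]", "config")
  fq_assert(is_scalar_number(displacement_sd) && displacement_sd > 0,
            "displacement_sd must be positive", "config")
  fq_assert(is_scalar_number(neighbor_rho) && neighbor_rho >= 0 &&
              neighbor_rho < 1, "neighbor_rho must lie in [0, 1)", "config")
  if (geometry == "detached") coupling_rho <- 0
  structure(list(n_residues = as.integer(n_residues),
                 ligand_nodes = as.integer(ligand_nodes),
                 n_frames = as.integer(n_frames),
                 coupling_rho = coupling_rho,
                 n_site_residues = as.integer(n_site_residues),
                 displacement_sd = displacement_sd,
                 neighbor_rho = neighbor_rho,
                 geometry = geometry, seed = as.integer(seed)),
            class = "fq_trajectory_spec")
}

# Ligand atom clusters per node label, around the helix axis, stacked in z.
# The ring node is the large central fragment (it holds the bicyclic core
# incl. substituent heavy atoms and dominates the pocket contacts, as in a
# fluoroquinolone); the terminal substituent nodes are small caps near the
# pocket mouth.
ligand_template <- function(ligand_nodes, zc) {
  penta <- function(r, z, phase = 0) {
    ang <- 2 * pi * (0:4) / 5 + phase
    cbind(r * cos(ang), r * sin(ang), z)
  }
  ring <- rbind(penta(1.4, zc - 1.2), penta(1.4, zc + 1.2, phase = pi / 5))
  tri <- cbind(0.7 * cos(2 * pi * (0:2) / 3),
               0.7 * sin(2 * pi * (0:2) / 3), zc - 4.0)
  sqr <- cbind(0.9 * cos(2 * pi * (0:3) / 4 + pi / 4),
               0.9 * sin(2 * pi * (0:3) / 4 + pi / 4), zc + 4.0)
  nodes <- list(ring = ring, cyclopropyl = tri, piperazinyl = sqr)
  if (ligand_nodes == 4L) {
    nodes$methoxy <- cbind(c(0.8, -0.8), c(0.4, -0.4), zc + 5.2)
  }
  nodes
}

#' Build a synthetic antibody-hapten complex
#'
#' Protein residues are coarse backbone beads (one C-alpha plus two side
#' atoms) laid on a folded solenoid (10 residues per turn) whose interior
#' forms the binding pocket; the ligand is an elongated 3-4 fragment molecule
#' placed along the pocket axis (`geometry = "bound"`) or far outside the
#' protein (`"detached"`, minimum ligand-protein atom distance > 10 A). A
#' small seeded coordinate jitter breaks exact symmetry; the output is
#' bit-reproducible for a fixed seed.
#'
#' @param spec An `fq_trajectory_spec`.
#' @return An `fq_complex`: list with `system` (`fq_system`), `node_map`
#'   (`fq_node_map`), `site_residues` (integer residue node indices,
#'   the `n_site_residues` residues closest to the ring fragment in the bound
#'   pose) and `spec`.
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fq_trajectory_spec"))
  n <- spec$n_residues
  if (spec$geometry == "bound" && n < 20L) {
    fq_abort("ligand larger than pocket: a bound geometry needs >= 20 residues",
             "generation")
  }
  turn <- 10L
  rise <- 0.4
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(pi / turn))
  theta <- 2 * pi * (seq_len(n) - 1L) / turn
  zres <- rise * (seq_len(n) - 1L)
  prot <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(c(radius * cos(theta[i]), radius * sin(theta[i]), zres[i]),
          c((radius - 1.4) * cos(theta[i]), (radius - 1.4) * sin(theta[i]), zres[i]),
          c((radius - 2.6) * cos(theta[i]), (radius - 2.6) * sin(theta[i]), zres[i]))
  }))
  zc <- rise * (n - 1L) / 2
  lig_nodes <- ligand_template(spec$ligand_nodes, zc)
  lig <- do.call(rbind, lig_nodes)
  if (spec$geometry == "detached") {
    lig[, 3] <- lig[, 3] + rise * n + 25
  }
  coords <- rbind(prot, lig)
  coords <- withr::with_seed(spec$seed, {
    coords + matrix(runif(length(coords), -0.05, 0.05), nrow(coords))
  })

  n_lig <- nrow(lig)
  atoms <- tibble(
    serial = seq_len(nrow(coords)),
    name = c(rep(c("CA", "CB", "CG"), n),
             sprintf("L%02d", seq_len(n_lig))),
    element = "C",
    chain = c(rep("A", 3L * n), rep("L", n_lig)),
    resseq = c(rep(seq_len(n), each = 3L), rep(1L, n_lig)),
    resname = c(rep("ALA", 3L * n), rep("LIG", n_lig)),
    record = c(rep("ATOM", 3L * n), rep("HETATM", n_lig)),
    is_heavy = TRUE,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  system <- new_fq_system(atoms, tibble(chain = "L", resseq = 1L,
                                        resname = "LIG"))
  map <- tibble(
    atom_name = sprintf("L%02d", seq_len(n_lig)),
    node_label = rep(names(lig_nodes),
                     vapply(lig_nodes, nrow, integer(1))),
    ring_flag = as.integer(rep(names(lig_nodes) == "ring",
                               vapply(lig_nodes, nrow, integer(1))))
  )
  node_map <- new_fq_node_map(map, "ring")

  # site residues: nearest to the ring fragment in the bound pose
  ring_xyz <- ligand_template(spec$ligand_nodes, zc)$ring
  res_min_d <- vapply(seq_len(n), function(i) {
    p <- prot[(3L * i - 2L):(3L * i), , drop = FALSE]
    min(sqrt(outer(rowSums(p^2), rowSums(ring_xyz^2), "+") -
               2 * p %*% t(ring_xyz)))
  }, numeric(1))
  site <- sort(order(res_min_d)[seq_len(spec$n_site_residues)])

  structure(list(system = system, node_map = node_map,
                 site_residues = site, spec = spec),
            class = "fq_complex")
}

#' @export
print.fq_complex <- function(x, ...) {
  cat("<fq_complex> ", x$spec$n_residues, " residues + ",
      x$spec$ligand_nodes, "-node ligand (", x$spec$geometry,
      "), site residues: ", paste(x$site_residues, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Target node-displacement correlation matrix. Coupled block = ligand nodes +
# site residues, equicorrelated at rho (guaranteed PSD for rho >= 0, unlike a
# ligand-site star, which is indefinite at rho = 0.8); covalently or
# spatially adjacent nodes at neighbor_rho; else 0. Projected to the nearest
# PSD matrix by eigenvalue clipping if the combination leaves small negative
# eigenvalues.
target_correlation <- function(cx, partition) {
  spec <- cx$spec
  nn <- nrow(partition)
  sig <- diag(nn)
  adj <- covalent_adjacency(partition)
  sig[adj] <- spec$neighbor_rho
  # spatial residue-residue contacts in the base geometry
  a <- cx$system$atoms
  res_nodes <- which(partition$kind == "residue")
  for (p in res_nodes) {
    for (q in res_nodes[res_nodes > p]) {
      if (sig[p, q] > 0) next
      pa <- partition$atoms[[p]]; qa <- partition$atoms[[q]]
      d2 <- outer(a$x[pa], a$x[qa], "-")^2 +
        outer(a$y[pa], a$y[qa], "-")^2 + outer(a$z[pa], a$z[qa], "-")^2
      if (min(d2) <= 4.5^2) sig[p, q] <- sig[q, p] <- spec$neighbor_rho
    }
  }
  block <- c(cx$site_residues, which(partition$kind == "ligand"))
  if (spec$coupling_rho > 0) {
    sig[block, block] <- pmax(sig[block, block], spec$coupling_rho)
    # nodes dominated by the shared binding-mode factor retain only
    # sqrt(1 - rho^2) residual freedom for local couplings outside the block
    outside <- setdiff(seq_len(nn), block)
    damp <- sqrt(1 - spec$coupling_rho^2)
    sig[block, outside] <- sig[block, outside] * damp
    sig[outside, block] <- sig[outside, block] * damp
    diag(sig) <- 1
  }
  eg <- eigen(sig, symmetric = TRUE)
  adjusted <- 0
  if (min(eg$values) < 1e-10) {
    v <- pmax(eg$values, 1e-10)
    psd <- eg$vectors %*% (v * t(eg$vectors))
    psd <- stats::cov2cor(psd)
    adjusted <- max(abs(psd - sig))
    sig <- (psd + t(psd)) / 2
  }
  list(correlation = sig, psd_adjustment = adjusted)
}

#' Simulate a trajectory with known correlation structure
#'
#' Per-frame node displacements are drawn from a zero-mean multivariate
#' Gaussian (independently per Cartesian axis, so the scalar dot-product node
#' correlation equals the target matrix); all atoms of a node move rigidly
#' with it. The coupled block (ligand nodes + site residues) is
#' equicorrelated at `coupling_rho`; adjacent nodes at `neighbor_rho`. If the
#' combined target is not positive semidefinite it is projected by
#' eigenvalue clipping (at 1e-10) and the applied adjustment recorded.
#'
#' @param cx An `fq_complex` from [make_complex()].
#' @param spec Optional `fq_trajectory_spec` overriding `cx$spec`.
#' @return An `fq_sim`: list with `trajectory` (`fq_trajectory`),
#'   `partition` (`fq_partition`) and `truth` (list: `correlation` --- the
#'   post-projection target node correlation, `label` (`"binder"` /
#'   `"non_binder"`), `site_residues`, `psd_adjustment`).
#' @export
simulate_trajectory <- function(cx, spec = NULL) {
  stopifnot(inherits(cx, "fq_complex"))
  spec <- spec %||% cx$spec
  partition <- partition_system(cx$system, cx$node_map)
  tc <- target_correlation(cx, partition)
  if (min(eigen(tc$correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    fq_abort("target correlation not PSD after projection", "generation")
  }
  nn <- nrow(partition)
  u <- chol(tc$correlation + diag(1e-12, nn))
  disp <- withr::with_seed(spec$seed + 1L, {
    lapply(0:2, function(ax) {
      (matrix(rnorm(spec$n_frames * nn), spec$n_frames, nn) %*% u) *
        spec$displacement_sd
    })
  })
  a <- cx$system$atoms
  nat <- nrow(a)
  node_of_atom <- integer(nat)
  for (k in seq_len(nn)) node_of_atom[partition$atoms[[k]]] <- k
  base <- as.vector(t(cbind(a$x, a$y, a$z)))
  xyz <- matrix(base, spec$n_frames, 3L * nat, byrow = TRUE)
  for (ax in 0:2) {
    cols <- 3L * (seq_len(nat) - 1L) + 1L + ax
    xyz[, cols] <- xyz[, cols] + disp[[ax + 1L]][, node_of_atom, drop = FALSE]
  }
  label <- if (spec$geometry == "bound" && spec$coupling_rho > 0) {
    "binder"
  } else {
    "non_binder"
  }
  structure(list(
    trajectory = new_fq_trajectory(cx$system, xyz, source = "synthetic"),
    partition = partition,
    truth = list(correlation = tc$correlation, label = label,
                 site_residues = cx$site_residues,
                 psd_adjustment = tc$psd_adjustment)
  ), class = "fq_sim")
}

#' @export
print.fq_sim <- function(x, ...) {
  cat("<fq_sim> ", nrow(x$trajectory$xyz), " frames, ",
      nrow(x$partition), " nodes, label ", x$truth$label, "\n", sep = "")
  invisible(x)
}

#' Write an `fq_system` as a PDB file
#'
#' @param system An `fq_system`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path) {
  a <- system$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(cbind(a$x, a$y, a$z))),
                   type = a$record, resno = a$resseq, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Simulate a competitive-ELISA panel
#'
#' OD values are sampled from a decreasing 4PL with multiplicative Gaussian
#' noise, `OD = 4PL(x; a, d, c = true IC50, b) * (1 + eps)`,
#' `eps ~ N(0, noise_cv)`, on a log-serial dilution series. Analytes with a
#' missing (`NA`) true IC50 produce flat, non-inhibited curves at the upper
#' asymptote, emulating compounds the antibody does not bind.
#'
#' @param true_ic50s Named numeric vector of true IC50s (ng/mL); `NA` for
#'   non-inhibiting analytes.
#' @param a,d,b 4PL curve parameters shared by the panel (defaults 2.0, 0.1,
#'   1.2 OD/slope units).
#' @param noise_cv Multiplicative noise coefficient of variation (default
#'   0.03).
#' @param n_replicates Replicates per concentration (default 3).
#' @param n_levels Number of concentration levels (default 8).
#' @param conc_min,conc_max Dilution range in ng/mL (defaults 0.001 and 167).
#' @param seed Integer seed.
#' @return Panel tibble with columns `analyte`, `concentration`,
#'   `replicate`, `od`, suitable for [cr_table()].
#' @export
simulate_elisa_panel <- function(true_ic50s, a = 2.0, d = 0.1, b = 1.2,
                                 noise_cv = 0.03, n_replicates = 3L,
                                 n_levels = 8L, conc_min = 0.001,
                                 conc_max = 167, seed = 1L) {
  fq_assert(length(names(true_ic50s)) == length(true_ic50s),
            "true_ic50s must be named", "config")
  fq_assert(is_scalar_number(noise_cv) || noise_cv == 0, "bad noise_cv",
            "config")
  fq_assert(noise_cv >= 0, "noise_cv must be >= 0", "config")
  conc <- exp(seq(log(conc_min), log(conc_max), length.out = n_levels))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration = conc,
                      analyte = names(true_ic50s),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    mu <- vapply(seq_len(nrow(grid)), function(r) {
      ic <- true_ic50s[[grid$analyte[r]]]
      if (is.na(ic)) a else fourpl(grid$concentration[r], a, d, ic, b)
    }, numeric(1))
    od <- mu * (1 + rnorm(nrow(grid), 0, noise_cv))
    tibble(analyte = grid$analyte, concentration = grid$concentration,
           replicate = grid$replicate, od = pmax(od, 0))
  })
}

#' Regenerate the synthetic test corpus on disk
#'
#' Writes, for a bound (coupled) and a detached system: the PDB structure,
#' an XYZ trajectory, the ligand node map, and a ground-truth table (node
#' correlation matrix and label).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_frames Frames per trajectory (default 100; fixture-sized).
#' @return Tibble manifest of the written files, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1L, n_frames = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (geom in c("bound", "detached")) {
    spec <- trajectory_spec(geometry = geom,
                            coupling_rho = if (geom == "bound") 0.8 else 0,
                            n_frames = n_frames, seed = seed)
    cx <- make_complex(spec)
    sim <- simulate_trajectory(cx)
    stem <- file.path(dir, paste0("synthetic_", geom))
    write_structure(cx$system, paste0(stem, ".pdb"))
    write_trajectory(sim$trajectory, paste0(stem, ".xyz"), format = "xyz")
    write_node_map(cx$node_map, paste0(stem, "_node_map.tsv"))
    tc <- as.data.frame(sim$truth$correlation)
    names(tc) <- paste0("node", seq_len(ncol(tc)))
    readr::write_tsv(tibble(label = sim$truth$label,
                            site_residues = paste(sim$truth$site_residues,
                                                  collapse = ",")),
                     paste0(stem, "_truth.tsv"))
    readr::write_tsv(tc, paste0(stem, "_correlation.tsv"))
    rows[[geom]] <- tibble(geometry = geom,
                           files = paste0(stem, c(".pdb", ".xyz",
                                                  "_node_map.tsv",
                                                  "_truth.tsv",
                                                  "_correlation.tsv")))
  }
  invisible(bind_rows(rows))
}
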