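# Independent oracles and small constructors used across the suite.
# The oracles deliberately share no code with the package implementation.

# ---- graph construction ----------------------------------------------------

make_net <- function(n_nodes, i, j, w) {
  structure(list(n_nodes = n_nodes,
                 edges = tibble::tibble(i = as.integer(i), j = as.integer(j),
                                        cij = exp(-w), weight = w),
                 params = list()),
            class = "fq_network")
}

random_connected_net <- function(n, extra_edges = 2L) {
  # random spanning tree + a few extra edges, random positive weights
  repeat {
    edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L),
                               integer(1)))
    all_pairs <- t(combn(n, 2))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    pool <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, ,
                      drop = FALSE]
    if (nrow(pool) > 0 && extra_edges > 0) {
      take <- pool[sample.int(nrow(pool), min(extra_edges, nrow(pool))), ,
                   drop = FALSE]
      edges <- rbind(edges, take)
    }
    i <- pmin(edges[, 1], edges[, 2])
    j <- pmax(edges[, 1], edges[, 2])
    if (!anyDuplicated(paste(i, j))) break
  }
  make_net(n, i, j, round(runif(length(i), 0.1, 2), 3))
}

# ---- brute-force betweenness oracle ----------------------------------------

# Enumerates every simple path between every unordered pair, keeps the
# minimum-cost paths, and deposits credit on each edge of each such path
# (split across equal-cost paths for "fractional", full unit each for
# "all_paths").
brute_edge_betweenness <- function(net, mode = c("fractional", "all_paths")) {
  mode <- match.arg(mode)
  n <- net$n_nodes
  wmat <- matrix(Inf, n, n)
  wmat[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
  wmat[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
  eb <- matrix(0, n, n)
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(v, path, cost) {
      if (v == t) {
        found[[length(found) + 1L]] <<- list(path = path, cost = cost)
        return()
      }
      for (u in which(is.finite(wmat[v, ]))) {
        if (u %in% path) next
        walk(u, c(path, u), cost + wmat[v, u])
      }
    }
    walk(s, s, 0)
    found
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      costs <- vapply(paths, `[[`, numeric(1), "cost")
      best <- min(costs)
      sel <- which(costs <= best + 1e-9 * max(1, best))
      credit <- if (mode == "fractional") 1 / length(sel) else 1
      for (k in sel) {
        p <- paths[[k]]$path
        for (e in seq_len(length(p) - 1L)) {
          a <- min(p[e], p[e + 1L]); b <- max(p[e], p[e + 1L])
          eb[a, b] <- eb[a, b] + credit
        }
      }
    }
  }
  eb + t(eb)
}

brute_distance <- function(net, s, t) {
  n <- net$n_nodes
  wmat <- matrix(Inf, n, n)
  wmat[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
  wmat[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
  best <- Inf
  walk <- function(v, seen, cost) {
    if (cost >= best) return()
    if (v == t) { best <<- cost; return() }
    for (u in which(is.finite(wmat[v, ]))) {
      if (u %in% seen) next
      walk(u, c(seen, u), cost + wmat[v, u])
    }
  }
  walk(s, s, 0)
  best
}

# ---- quaternion superposition oracle (Horn 1987) ---------------------------

quaternion_align <- function(mobile, fixed, fit_idx = seq_len(nrow(mobile))) {
  p <- mobile[fit_idx, , drop = FALSE]
  q <- fixed[fit_idx, , drop = FALSE]
  cp <- colMeans(p); cq <- colMeans(q)
  s <- t(sweep(p, 2, cp)) %*% sweep(q, 2, cq)
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2], s[3,1]-s[1,3], s[1,2]-s[2,1],
    s[2,3]-s[3,2], s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1], s[3,1]+s[1,3],
    s[3,1]-s[1,3], s[1,2]+s[2,1], -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1], s[3,1]+s[1,3], s[2,3]+s[3,2], -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  qv <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  sweep(sweep(mobile, 2, cp) %*% t(rot), 2, cq, "+")
}

# ---- toy structures --------------------------------------------------------

pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                          x, y, z, element, icode = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, resseq, icode,
          x, y, z, 1, 0, element)
}

# Three alanine-like residues (CA + CB) and a 9-atom hetero ligand.
write_toy_pdb <- function(path, dup_serial = FALSE, bad_coord = FALSE,
                          icode = FALSE, with_hydrogen = FALSE) {
  lines <- character(0)
  serial <- 0L
  for (r in 1:3) {
    for (nm in c("CA", "CB")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, nm, "ALA", "A", r,
                                      r * 3.8, ifelse(nm == "CA", 0, 1.4),
                                      0.5 * r, "C"))
    }
  }
  if (with_hydrogen) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("ATOM", serial, "HA", "ALA", "A", 3,
                                    11.4, 0.9, 1.5, "H"))
  }
  for (k in 1:9) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("HETATM", serial, paste0("L", k), "LIG",
                                    "L", 1, 5 + 0.6 * k, 2.5, 1.0, "C"))
  }
  if (dup_serial) {
    lines[2] <- sub("    2", "    1", lines[2])
  }
  if (bad_coord) {
    substr(lines[3], 31, 38) <- "  xx.yyy"
  }
  if (icode) {
    substr(lines[4], 27, 27) <- "A"
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_node_map <- function(path, ring_atoms = paste0("L", 1:4),
                         pip_atoms = paste0("L", 5:7),
                         cyc_atoms = paste0("L", 8:9),
                         extra_ring_label = FALSE, drop_atom = FALSE,
                         dup_atom = FALSE) {
  map <- data.frame(
    atom_name = c(ring_atoms, pip_atoms, cyc_atoms),
    node_label = c(rep("ring", length(ring_atoms)),
                   rep("piperazinyl", length(pip_atoms)),
                   rep("cyclopropyl", length(cyc_atoms))),
    ring_flag = c(rep(1L, length(ring_atoms)),
                  rep(0L, length(pip_atoms) + length(cyc_atoms)))
  )
  if (extra_ring_label) map$ring_flag[map$node_label == "piperazinyl"] <- 1L
  if (drop_atom) map <- map[map$atom_name != "L9", ]
  if (dup_atom) map <- rbind(map, map[1, ])
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Node trajectory built directly from a frames x (3 * n_nodes) matrix, with a
# minimal residue/ligand partition (single-atom nodes, residue numbers
# controllable so covalent adjacency can be switched off).
fake_partition <- function(kinds, resseq = seq_along(kinds),
                           ring = which(kinds == "ligand")[1]) {
  nn <- length(kinds)
  part <- tibble::tibble(
    node_id = seq_len(nn),
    kind = kinds,
    label = ifelse(kinds == "residue", paste0("A:", resseq),
                   paste0("lig", seq_len(nn))),
    atoms = as.list(seq_len(nn)),
    rep_atom = ifelse(kinds == "residue", seq_len(nn), NA_integer_)
  )
  structure(part, class = c("fq_partition", class(tibble::tibble())),
            ring_node_id = ring, node_point = "calpha_centroid")
}

fake_node_traj <- function(xyz, partition) {
  fqcross:::new_fq_node_trajectory(partition, xyz)
}

fake_traj <- function(xyz, n_atoms) {
  atoms <- tibble::tibble(
    serial = seq_len(n_atoms), name = paste0("X", seq_len(n_atoms)),
    element = "C", chain = "A", resseq = seq_len(n_atoms), resname = "ALA",
    record = "ATOM", is_heavy = TRUE, x = 0, y = 0, z = 0
  )
  sys <- fqcross:::new_fq_system(atoms,
                                 tibble::tibble(chain = "L", resseq = 1L,
                                                resname = "LIG"))
  fqcross:::new_fq_trajectory(sys, xyz)
}

betw_matrix <- function(bet) betweenness_matrix(bet)
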