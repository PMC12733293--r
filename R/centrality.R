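# Shortest paths and edge betweenness on the correlation-weighted network,
# and the quinolone-ring betweenness-sum descriptor.
#
# Brandes' algorithm with an O(n^2) Dijkstra per source; path-cost ties are
# decided with a 1e-12 relative tolerance because -ln|C| weights are floats
# and exact ties arise in symmetric toy systems.

adjacency_lists <- function(net) {
  nn <- net$n_nodes
  nbr <- vector("list", nn)
  wt <- vector("list", nn)
  for (k in seq_len(nn)) { nbr[[k]] <- integer(0); wt[[k]] <- numeric(0) }
  e <- net$edges
  if (any(e$weight < 0)) {
    fq_abort("negative edge weight encountered (internal error)", "internal")
  }
  for (r in seq_len(nrow(e))) {
    i <- e$i[r]; j <- e$j[r]; w <- e$weight[r]
    nbr[[i]] <- c(nbr[[i]], j); wt[[i]] <- c(wt[[i]], w)
    nbr[[j]] <- c(nbr[[j]], i); wt[[j]] <- c(wt[[j]], w)
  }
  list(nbr = nbr, wt = wt)
}

# Single-source Dijkstra with equal-cost predecessor sets and path counts.
dijkstra_source <- function(adj, s, nn, tol = 1e-12) {
  dist <- rep(Inf, nn)
  sigma <- numeric(nn)
  preds <- vector("list", nn)
  visited <- logical(nn)
  dist[s] <- 0
  sigma[s] <- 1
  order <- integer(0)
  repeat {
    u <- NA_integer_
    best <- Inf
    for (k in which(!visited)) {
      if (dist[k] < best) { best <- dist[k]; u <- k }
    }
    if (is.na(u) || !is.finite(best)) break
    visited[u] <- TRUE
    order <- c(order, u)
    nb <- adj$nbr[[u]]
    for (q in seq_along(nb)) {
      v <- nb[q]
      if (visited[v]) next
      nd <- dist[u] + adj$wt[[u]][q]
      tv <- tol * max(1, nd)
      if (nd < dist[v] - tv) {
        dist[v] <- nd
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(nd - dist[v]) <= tv) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order)
}

#' All-pairs shortest paths
#'
#' Dijkstra from every source over the non-negative `-ln|C|` weights.
#' Unreachable pairs get infinite distance and a path count of zero.
#'
#' @param net An `fq_network`.
#' @return An `fq_paths`: list with `distances` and `path_counts`
#'   (`n_nodes x n_nodes` matrices; `path_counts` holds the number of
#'   equal-cost shortest paths, 1 on the diagonal).
#' @export
shortest_path_matrix <- function(net) {
  nn <- net$n_nodes
  adj <- adjacency_lists(net)
  dmat <- matrix(Inf, nn, nn)
  smat <- matrix(0, nn, nn)
  for (s in seq_len(nn)) {
    r <- dijkstra_source(adj, s, nn)
    dmat[s, ] <- r$dist
    smat[s, ] <- r$sigma
  }
  structure(list(distances = dmat, path_counts = smat), class = "fq_paths")
}

#' Edge betweenness centrality
#'
#' For every unordered node pair (s, t) one unit of credit is accumulated on
#' the edges of their shortest path(s). With `count_mode = "fractional"`
#' (default, Brandes accumulation) the unit is split equally among all
#' equal-cost shortest s-t paths; with `"all_paths"` every equal-cost shortest
#' path deposits a full unit on each of its edges. Values are raw
#' (unnormalized) counts over all pairs.
#'
#' @param net An `fq_network`.
#' @param count_mode `"fractional"` or `"all_paths"`.
#' @return An `fq_betweenness`: list with `edges` (tibble `i`, `j`,
#'   `betweenness`), `n_nodes` and `count_mode`.
#' @export
network_betweenness <- function(net, count_mode = c("fractional", "all_paths")) {
  count_mode <- match.arg(count_mode)
  nn <- net$n_nodes
  ne <- nrow(net$edges)
  if (nn == 0L || ne == 0L) {
    return(structure(list(edges = tibble(i = integer(0), j = integer(0),
                                         betweenness = numeric(0)),
                          n_nodes = nn, count_mode = count_mode),
                     class = "fq_betweenness"))
  }
  adj <- adjacency_lists(net)
  eid <- matrix(0L, nn, nn)
  eid[cbind(net$edges$i, net$edges$j)] <- seq_len(ne)
  eid[cbind(net$edges$j, net$edges$i)] <- seq_len(ne)
  eb <- numeric(ne)
  if (count_mode == "fractional") {
    for (s in seq_len(nn)) {
      r <- dijkstra_source(adj, s, nn)
      delta <- numeric(nn)
      for (w in rev(r$order)) {
        for (v in r$preds[[w]]) {
          credit <- r$sigma[v] / r$sigma[w] * (1 + delta[w])
          eb[eid[v, w]] <- eb[eid[v, w]] + credit
          delta[v] <- delta[v] + credit
        }
      }
    }
    eb <- eb / 2
  } else {
    succ_of <- function(preds) {
      succ <- vector("list", nn)
      for (w in seq_len(nn)) for (v in preds[[w]]) succ[[v]] <- c(succ[[v]], w)
      succ
    }
    for (s in seq_len(nn - 1L)) {
      r <- dijkstra_source(adj, s, nn)
      succ <- succ_of(r$preds)
      for (t in seq.int(s + 1L, nn)) {
        if (!is.finite(r$dist[t])) next
        tau <- numeric(nn)
        tau[t] <- 1
        for (v in rev(r$order)) {
          if (v == t) next
          for (w in succ[[v]]) tau[v] <- tau[v] + tau[w]
        }
        for (w in r$order) {
          for (v in r$preds[[w]]) {
            if (tau[w] > 0) {
              eb[eid[v, w]] <- eb[eid[v, w]] + r$sigma[v] * tau[w]
            }
          }
        }
      }
    }
  }
  structure(list(edges = tibble(i = net$edges$i, j = net$edges$j,
                                betweenness = eb),
                 n_nodes = nn, count_mode = count_mode),
            class = "fq_betweenness")
}

#' @export
print.fq_betweenness <- function(x, ...) {
  cat("<fq_betweenness> ", nrow(x$edges), " edges (", x$count_mode,
      " counting)\n", sep = "")
  invisible(x)
}

#' @export
tidy.fq_betweenness <- function(x, ...) x$edges

#' Edge betweenness as a symmetric matrix
#'
#' @param bet An `fq_betweenness`.
#' @return An `n_nodes x n_nodes` matrix (0 where no edge).
#' @export
betweenness_matrix <- function(bet) {
  m <- matrix(0, bet$n_nodes, bet$n_nodes)
  m[cbind(bet$edges$i, bet$edges$j)] <- bet$edges$betweenness
  m[cbind(bet$edges$j, bet$edges$i)] <- bet$edges$betweenness
  m
}

#' Quinolone-ring betweenness profile and sum
#'
#' Per-residue profile of the betweenness carried by the edges joining the
#' quinolone-ring node to protein residue nodes, and their sum `S_q` -- the
#' scalar descriptor of how strongly the ligand is integrated into the
#' antibody's dynamical network. Residues without a ring edge report 0; a
#' ligand that left the binding site has no ring-protein edges and `S_q = 0`.
#' Values are stored at full precision; round for display.
#'
#' @param bet An `fq_betweenness`.
#' @param partition The `fq_partition` the network was built from.
#' @return An `fq_ring_profile`: list with `profile` (tibble `node_id`,
#'   `label`, `betweenness` over protein nodes), `ring_sum` and
#'   `ring_node_id`.
#' @export
ring_betweenness <- function(bet, partition) {
  ring <- ring_node_id(partition)
  if (length(ring) != 1L || is.na(ring) || ring > bet$n_nodes ||
      partition$kind[ring] != "ligand") {
    fq_abort("partition has no valid quinolone-ring node", "config")
  }
  prot <- partition$node_id[partition$kind == "residue"]
  bmat <- betweenness_matrix(bet)
  vals <- bmat[ring, prot]
  profile <- tibble(node_id = prot, label = partition$label[prot],
                    betweenness = vals)
  structure(list(profile = profile, ring_sum = sum(vals),
                 ring_node_id = ring),
            class = "fq_ring_profile")
}

#' @export
print.fq_ring_profile <- function(x, ...) {
  nz <- sum(x$profile$betweenness > 0)
  cat("<fq_ring_profile> ring_sum = ", format(x$ring_sum, digits = 6),
      " over ", nz, " residue(s) with non-zero betweenness\n", sep = "")
  invisible(x)
}

#' @export
tidy.fq_ring_profile <- function(x, ...) x$profile

#' @export
glance.fq_ring_profile <- function(x, ...) {
  tibble(ring_sum = x$ring_sum,
         n_nonzero_residues = sum(x$profile$betweenness > 0),
         ring_node_id = x$ring_node_id)
}
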