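#' @title Residue interaction network and betweenness hubs
#' @description
#' Residues are nodes; two residues are joined when any pair of their heavy
#' atoms lies within a contact cutoff (4.5 Angstrom, closed boundary). The
#' interaction strength is the normalized contact count
#' \deqn{a_{ij} = N_{ij} / (N_i N_j),}
#' with \eqn{N_i} the heavy-atom count of residue i and \eqn{N_{ij}} the
#' number of heavy-atom contact pairs; the edge weight used as shortest-path
#' distance is \eqn{1/a_{ij}}, which relaxes the otherwise dominant bias of
#' covalent (sequence-neighbour) contacts. Residues in the top betweenness
#' quantile are hubs: bottlenecks of intramolecular communication.
#' @name rin
NULL

#' Count heavy-atom contacts between two residues
#'
#' Number of (heavy atom of i, heavy atom of j) pairs within
#' `contact_cutoff`, boundary included.
#'
#' @param coords_i,coords_j heavy-atom coordinate matrices (rows = atoms) of
#'   two distinct residues.
#' @param contact_cutoff contact cutoff in Angstrom (default 4.5).
#' @return integer contact count.
#' @export
count_heavy_contacts <- function(coords_i, coords_j, contact_cutoff = 4.5) {
  stopifnot(contact_cutoff > 0)
  ci <- as.matrix(coords_i); cj <- as.matrix(coords_j)
  if (nrow(ci) == nrow(cj) && isTRUE(all.equal(ci, cj, check.attributes = FALSE))) {
    stop("self-contact is undefined: the two residues are identical",
         call. = FALSE)
  }
  if (nrow(ci) == 0L || nrow(cj) == 0L) return(0L)
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
  sum(d2 <= contact_cutoff^2 + 1e-12)
}

#' Edge strength and length from contact counts
#'
#' @param n_ij heavy-atom contact count (>= 1).
#' @param n_i,n_j heavy-atom counts of the two residues (>= 1).
#' @return list with `strength` (`a_ij = n_ij/(n_i*n_j)`) and `length`
#'   (`1/a_ij`, the shortest-path distance).
#' @export
edge_strength <- function(n_ij, n_i, n_j) {
  stopifnot(n_ij >= 1, n_i >= 1, n_j >= 1)
  a <- n_ij / (n_i * n_j)
  list(strength = a, length = 1 / a)
}

#' Build the residue interaction network
#'
#' One node per residue across all chains; an edge for every residue pair
#' (sequence neighbours and inter-chain pairs included) with at least one
#' heavy-atom contact. Betweenness is computed immediately (see
#' [betweenness_scores()]); hubs are flagged at `quantile`.
#'
#' @param model a curated [allo_structure].
#' @param contact_cutoff heavy-atom contact cutoff in Angstrom (default 4.5).
#' @param quantile hub quantile (default 0.95, i.e. the top 5%).
#' @return an `allo_rin` list: `nodes` data.frame (`key`, `chain`, `resno`,
#'   `icode`, `resname`, `n_heavy`, `betweenness`, `closeness`, `degree`,
#'   `hub`), `edges` data.frame (`key_i`, `key_j`, `n_contacts`, `strength`,
#'   `length`), `graph` (the igraph object), `contact_cutoff`.
#' @export
build_rin <- function(model, contact_cutoff = 4.5, quantile = 0.95) {
  rt <- residue_table(model)
  n <- nrow(rt)
  coords <- lapply(rt$key, residue_heavy_coords, model = model)
  # centroid + radius prefilter: a pair can only touch if centroid distance
  # <= r_i + r_j + cutoff
  cent <- t(vapply(coords, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(i) {
    d <- sweep(coords[[i]], 2, cent[i, ])
    sqrt(max(rowSums(d^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cent))
  lim <- outer(rad, rad, "+") + contact_cutoff
  cand <- which(upper.tri(dc) & dc <= lim, arr.ind = TRUE)
  ei <- integer(0); ej <- integer(0); nij <- integer(0)
  if (nrow(cand)) {
    cnt <- vapply(seq_len(nrow(cand)), function(r) {
      count_heavy_contacts(coords[[cand[r, 1L]]], coords[[cand[r, 2L]]],
                           contact_cutoff)
    }, numeric(1))
    keep <- cnt >= 1
    ei <- cand[keep, 1L]; ej <- cand[keep, 2L]; nij <- as.integer(cnt[keep])
  }
  a_ij <- nij / (rt$n_heavy[ei] * rt$n_heavy[ej])
  edges <- data.frame(key_i = rt$key[ei], key_j = rt$key[ej],
                      n_contacts = nij, strength = a_ij, length = 1 / a_ij,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("key_i", "key_j")], directed = FALSE,
    vertices = data.frame(name = rt$key, stringsAsFactors = FALSE))
  if (nrow(edges)) igraph::E(g)$length <- edges$length
  btw <- betweenness_scores(g)
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(
    g, weights = if (nrow(edges)) igraph::E(g)$length else NULL))
  clo[!is.finite(clo)] <- 0
  nodes <- data.frame(key = rt$key, chain = rt$chain, resno = rt$resno,
                      icode = rt$icode, resname = rt$resname,
                      n_heavy = rt$n_heavy,
                      betweenness = unname(btw[rt$key]),
                      closeness = unname(clo[rt$key]),
                      degree = unname(deg[rt$key]),
                      hub = FALSE, stringsAsFactors = FALSE)
  out <- structure(list(nodes = nodes, edges = edges, graph = g,
                        contact_cutoff = contact_cutoff, quantile = quantile),
                   class = "allo_rin")
  out$nodes$hub <- out$nodes$key %in% select_hubs(out, quantile)
  out
}

#' Weighted betweenness of an interaction network
#'
#' Shortest-path betweenness with edge `length` (= 1/strength) as distance,
#' endpoints excluded, equal fractional credit over tied shortest paths
#' (Brandes, via igraph), normalized by `2/((n-1)(n-2))` so scores are
#' comparable across network sizes. Disconnected networks are allowed:
#' unreachable pairs contribute nothing.
#'
#' @param graph an igraph object with optional `length` edge attribute, or an
#'   `allo_rin`.
#' @return named numeric vector of normalized betweenness scores.
#' @export
betweenness_scores <- function(graph) {
  if (inherits(graph, "allo_rin")) graph <- graph$graph
  n <- igraph::vcount(graph)
  w <- if ("length" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$length else NULL
  if (n < 3L) {
    b <- rep(0, n)
    names(b) <- igraph::V(graph)$name
    return(b)
  }
  b <- igraph::betweenness(graph, directed = FALSE, weights = w)
  b * 2 / ((n - 1) * (n - 2))
}

#' Select hub residues
#'
#' Nodes whose betweenness reaches the `quantile`-th percentile over all
#' nodes (same interpolation and tie conventions as [select_essential()]).
#'
#' @param rin an `allo_rin` (or data.frame with `key` and `betweenness`).
#' @param quantile fraction in (0, 1); default 0.95.
#' @return character vector of hub residue keys.
#' @export
select_hubs <- function(rin, quantile = 0.95) {
  nodes <- if (inherits(rin, "allo_rin")) rin$nodes else rin
  sel <- select_top_quantile(nodes$betweenness, quantile)
  nodes$key[sel]
}

#' Write interaction-network tables as TSV
#'
#' @param rin an `allo_rin`.
#' @param nodes_path,edges_path output paths.
#' @return invisibly, `nodes_path`.
#' @export
write_rin_tsv <- function(rin, nodes_path, edges_path) {
  write_tsv_det(rin$nodes[, c("chain", "resno", "icode", "resname", "n_heavy",
                              "betweenness", "closeness", "degree", "hub")],
                nodes_path)
  write_tsv_det(rin$edges, edges_path)
  invisible(nodes_path)
}
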