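test_that("heavy-atom contact counts match brute force, boundary closed", {
  set.seed(31)
  for (rep in 1:20) {
    ci <- matrix(runif(9, 0, 6), ncol = 3)
    cj <- matrix(runif(9, 0, 6), ncol = 3) + runif(1, 0, 4)
    brute <- sum(as.matrix(dist(rbind(ci, cj)))[1:3, 4:6] <= 4.5)
    expect_equal(count_heavy_contacts(ci, cj), brute)
  }
  # exactly-at-cutoff pair counts as a contact
  expect_equal(count_heavy_contacts(matrix(c(0, 0, 0), 1),
                                    matrix(c(4.5, 0, 0), 1)), 1L)
  # far residues do not touch; identical residues are rejected
  expect_equal(count_heavy_contacts(matrix(0, 1, 3), matrix(50, 1, 3)), 0L)
  expect_error(count_heavy_contacts(matrix(1:3, 1), matrix(1:3, 1)),
               "self-contact")
})

test_that("edge strength implements the normalized contact-count formula", {
  e <- edge_strength(2, 5, 4)
  expect_equal(e$strength, 0.1)
  expect_equal(e$length, 10.0)
  expect_equal(edge_strength(1, 8, 8)$strength, 0.015625)
  expect_equal(edge_strength(1, 8, 8)$length, 64)
  # full contact saturates at strength 1
  expect_equal(edge_strength(20, 4, 5)$strength, 1)
  # random valid triples stay within (0, 1]
  set.seed(12)
  for (rep in 1:200) {
    ni <- sample(1:14, 1); nj <- sample(1:14, 1)
    nij <- sample(1:(ni * nj), 1)
    a <- edge_strength(nij, ni, nj)
    expect_true(a$strength > 0 && a$strength <= 1)
    expect_true(a$length >= 1)
    expect_equal(a$strength, nij / (ni * nj))
  }
})

test_that("the interaction network contains expected edges", {
  # three residues in a row: only sequential pairs are in contact
  lines <- c(pdb_line(serial = 1, resno = 1, x = 0),
             pdb_line(serial = 2, resno = 2, x = 4),
             pdb_line(serial = 3, resno = 3, x = 8))
  m <- load_structure(write_pdb_fixture(lines))
  rin <- build_rin(m)
  expect_equal(nrow(rin$edges), 2L)
  expect_setequal(paste(rin$edges$key_i, rin$edges$key_j),
                  c("A:1 A:2", "A:2 A:3"))
  # inter-chain interface edge
  lines2 <- c(pdb_line(serial = 1, chain = "A", resno = 1, x = 0),
              pdb_line(serial = 2, chain = "B", resno = 1, x = 4))
  rin2 <- build_rin(load_structure(write_pdb_fixture(lines2)))
  expect_equal(nrow(rin2$edges), 1L)
  # isolated residue: present, degree 0, betweenness 0
  lines3 <- c(lines, pdb_line(serial = 4, resno = 9, x = 50))
  rin3 <- build_rin(load_structure(write_pdb_fixture(lines3)))
  expect_equal(nrow(rin3$nodes), 4L)
  iso <- rin3$nodes[rin3$nodes$key == "A:9", ]
  expect_equal(iso$degree, 0)
  expect_equal(iso$betweenness, 0)
})

test_that("betweenness matches brute-force path enumeration on small graphs", {
  # unit path A-B-C: the middle vertex carries the single A-C path
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::E(g)$length <- c(1, 1)
  b <- betweenness_scores(g)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  # star: the hub carries every leaf pair
  s <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(s)$name <- paste0("v", 1:5)
  igraph::E(s)$length <- rep(1, 4)
  bs <- betweenness_scores(s)
  expect_equal(unname(bs["v1"]), 1)
  expect_equal(unname(bs[paste0("v", 2:5)]), rep(0, 4))
  # triangle with one long edge: the opposite vertex intermediates
  tri <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "A"), to = c("B", "C", "C")),
    directed = FALSE)
  igraph::E(tri)$length <- c(1, 1, 10)  # A-B, B-C short; A-C long
  bt <- betweenness_scores(tri)
  expect_equal(unname(bt["B"]), 1)
  expect_equal(unname(bt["A"]), 0)
  # seeded random connected weighted graphs vs the exhaustive oracle
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:7, 1)
    repeat {
      full <- t(combn(n, 2))
      keep <- runif(nrow(full)) < 0.6
      edges <- data.frame(i = full[keep, 1], j = full[keep, 2],
                          w = round(runif(sum(keep), 0.5, 5), 2))
      g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                         vertices = data.frame(name = 1:n))
      if (nrow(edges) > 0 && igraph::components(g)$no == 1) break
    }
    igraph::E(g)$length <- edges$w
    got <- betweenness_scores(g)[as.character(1:n)]
    want <- brute_betweenness(n, edges)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("hub selection honors the top-quantile rule with ties", {
  nodes <- data.frame(key = sprintf("A:%d", 1:100), betweenness = 1:100,
                      stringsAsFactors = FALSE)
  expect_length(select_hubs(nodes, 0.95), 5L)
  all_tied <- data.frame(key = sprintf("A:%d", 1:20), betweenness = rep(3, 20),
                         stringsAsFactors = FALSE)
  expect_length(select_hubs(all_tied, 0.95), 20L)
  # three nodes tied exactly at the interpolated threshold are all included
  b <- c(seq_len(37), 50, 50, 50)
  tied <- data.frame(key = sprintf("A:%d", 1:40), betweenness = b,
                     stringsAsFactors = FALSE)
  expect_equal(brute_percentile(b, 0.95), 50)
  expect_setequal(select_hubs(tied, 0.95), sprintf("A:%d", 38:40))
})

test_that("scores are invariant to residue input order", {
  g <- generate_two_domain(synthetic_spec(seed = 5))
  rin <- build_rin(g$model)
  m2 <- g$model
  perm <- sample(nrow(m2$atoms))
  m2$atoms <- m2$atoms[perm, ]
  rin2 <- build_rin(m2)
  b1 <- rin$nodes$betweenness[order(rin$nodes$key)]
  b2 <- rin2$nodes$betweenness[order(rin2$nodes$key)]
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("bridge residues of the hinge structure are betweenness hubs", {
  g <- generate_two_domain(synthetic_spec(seed = 7))
  rin <- build_rin(g$model)
  hubs <- select_hubs(rin)
  expect_true(any(g$truth$bridge_keys %in% hubs))
  # and the single highest-betweenness residue lies on the bridge
  top1 <- rin$nodes$key[which.max(rin$nodes$betweenness)]
  expect_true(top1 %in% g$truth$bridge_keys)
})
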