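test_that("the grid detector finds the engineered cleft and nothing else", {
  sp <- synthetic_spec(seed = 7, sidechain_mode = "none")
  g <- generate_cleft_structure(sp)
  p <- detect_pockets_grid(g$model)
  expect_gte(nrow(p$table), 1L)
  overlap <- max(vapply(p$residues, function(r)
    length(intersect(r, g$truth$cavity_keys)) / length(g$truth$cavity_keys),
    numeric(1)))
  expect_gte(overlap, 0.6)
})

test_that("convex structures yield no pockets", {
  ball <- load_structure(fixture_convex_ball())
  expect_equal(nrow(detect_pockets_grid(ball)$table), 0L)
  filled <- generate_cleft_structure(synthetic_spec(seed = 7,
                                                    sidechain_mode = "none"),
                                     filled = TRUE)
  expect_equal(nrow(detect_pockets_grid(filled$model)$table), 0L)
})

test_that("two separated clefts are detected as two pockets", {
  sp <- synthetic_spec(seed = 7, sidechain_mode = "none")
  g <- generate_cleft_structure(sp)
  shifted <- g$model$atoms
  shifted$x <- shifted$x + 40
  shifted$resno <- shifted$resno + 1000L
  shifted$key <- residue_key(shifted$chain, shifted$resno, shifted$icode)
  m2 <- g$model
  m2$atoms <- rbind(g$model$atoms, shifted)
  expect_equal(nrow(detect_pockets_grid(m2)$table), 2L)
})

test_that("halving the lattice resolution barely moves the pocket residues", {
  sp <- synthetic_spec(seed = 11, sidechain_mode = "none")
  g <- generate_cleft_structure(sp)
  p10 <- detect_pockets_grid(g$model, spacing = 1.0)
  p15 <- detect_pockets_grid(g$model, spacing = 1.5)
  expect_gte(nrow(p10$table), 1L)
  expect_gte(nrow(p15$table), 1L)
  sym <- length(union(setdiff(p10$residues[[1]], p15$residues[[1]]),
                      setdiff(p15$residues[[1]], p10$residues[[1]])))
  expect_lte(sym, 1L)
})

test_that("the Fpocket layout parses with verbatim scores", {
  pk <- parse_fpocket_output(fpocket_fixture_dir())
  expect_equal(nrow(pk$table), 2L)
  expect_equal(pk$table$druggability, c(0.049, 0.018))
  expect_equal(pk$table$sasa_total, c(718.99, 245.56))
  expect_true("B:702" %in% pk$residues[[1]])
  expect_true("C:41" %in% pk$residues[[2]])
  # the two pockets share their back-to-back residues
  expect_setequal(intersect(pk$residues[[1]], pk$residues[[2]]),
                  c("B:625", "B:973", "C:41"))
})

test_that("Fpocket parsing errors are informative", {
  expect_error(parse_fpocket_output(tempfile()), "no such directory")
  d <- tempfile(); dir.create(d)
  expect_error(parse_fpocket_output(d), "info file")
  writeLines(c("Pocket 1 :", "\tDruggability Score : \tabc"),
             file.path(d, "x_info.txt"))
  expect_error(parse_fpocket_output(d), "line 2")
})

test_that("pocket scoring aggregates member z-scores", {
  prof <- data.frame(key = c("A:1", "A:2", "A:3", "A:4"),
                     z = c(1.0, 2.0, 4.0, 0.5),
                     skipped = FALSE, stringsAsFactors = FALSE)
  pk <- structure(list(
    table = data.frame(pocket_id = 1:2, source = "builtin",
                       n_points = NA_integer_, n_residues = c(3L, 1L),
                       sasa_total = NA_real_, druggability = NA_real_,
                       stringsAsFactors = FALSE),
    residues = list(c("A:1", "A:2", "A:3"), "A:4"),
    source = "builtin"), class = "allo_pockets")
  sc <- score_pockets(pk, prof)
  r1 <- sc$table[sc$table$pocket_id == 1, ]
  expect_equal(r1$essa_median, 2.0)
  expect_equal(r1$essa_max, 4.0)
  r2 <- sc$table[sc$table$pocket_id == 2, ]
  expect_equal(r2$essa_median, 0.5)
  expect_equal(r2$essa_max, 0.5)
  # even-count median uses the midpoint; scoring ignores residue order
  prof2 <- data.frame(key = sprintf("A:%d", 1:4), z = c(-1, -1, 3, 3),
                      skipped = FALSE, stringsAsFactors = FALSE)
  pk2 <- pk; pk2$residues <- list(sprintf("A:%d", 1:4), "A:4")
  pk2$table$n_residues <- c(4L, 1L)
  sc2 <- score_pockets(pk2, prof2)
  expect_equal(sc2$table$essa_median[sc2$table$pocket_id == 1], 1.0)
  pk3 <- pk2; pk3$residues[[1]] <- rev(pk3$residues[[1]])
  sc3 <- score_pockets(pk3, prof2)
  expect_equal(sc2$table$essa_median, sc3$table$essa_median)
  # a pocket with no scored residues ranks last and is flagged
  pk4 <- pk; pk4$residues <- list(c("A:1", "A:2", "A:3"), "Z:9")
  expect_warning(sc4 <- score_pockets(pk4, prof), "missing")
  expect_true(sc4$table$unscored[nrow(sc4$table)])
})

test_that("consensus intersects essential and hub sets under accessibility", {
  pk <- structure(list(
    table = data.frame(pocket_id = 1:2, source = "builtin",
                       n_points = NA_integer_, n_residues = c(3L, 2L),
                       sasa_total = NA_real_, druggability = NA_real_,
                       essa_median = c(1, 0), essa_max = c(2, 0),
                       unscored = FALSE, stringsAsFactors = FALSE),
    residues = list(c("A:2", "A:10", "A:11"), c("A:20", "A:21")),
    source = "builtin", rank_key = "median"), class = "allo_pockets")
  sasa <- data.frame(key = sprintf("A:%d", c(1:3, 10, 11, 20, 21)),
                     sasa = c(50, 50, 50, 50, 50, 50, 50),
                     stringsAsFactors = FALSE)
  cons <- find_consensus_sites(pk, essential = c("A:1", "A:2", "A:3"),
                               hubs = c("A:2", "A:3", "A:4"), sasa = sasa)
  expect_setequal(cons$mutual, c("A:2", "A:3"))
  p1 <- cons$pockets[cons$pockets$pocket_id == 1, ]
  expect_equal(p1$n_mutual, 1L)
  expect_true(p1$consensus)
  expect_false(cons$pockets$consensus[cons$pockets$pocket_id == 2])
  # raising the accessibility floor can only shrink the mutual set
  sasa2 <- sasa; sasa2$sasa[sasa2$key == "A:2"] <- 1
  cons2 <- find_consensus_sites(pk, c("A:1", "A:2", "A:3"),
                                c("A:2", "A:3", "A:4"), sasa2, sasa_min = 5)
  expect_true(all(cons2$mutual %in% cons$mutual))
  expect_setequal(cons2$mutual, "A:3")
  # pockets sharing a residue are reported back-to-back
  pk$residues[[2]] <- c("A:20", "A:11")
  consb <- find_consensus_sites(pk, "A:2", "A:2", sasa)
  expect_equal(nrow(consb$back_to_back), 1L)
  expect_equal(consb$back_to_back$shared, "A:11")
})

test_that("parse-score-consensus on the bundled fixture is byte-stable", {
  run_once <- function() {
    pk <- parse_fpocket_output(fpocket_fixture_dir())
    res <- unique(unlist(pk$residues))
    prof <- data.frame(key = res, z = seq_along(res) / 10,
                       skipped = FALSE, stringsAsFactors = FALSE)
    sasa <- data.frame(key = res, sasa = rep(20, length(res)),
                       stringsAsFactors = FALSE)
    sc <- score_pockets(pk, prof)
    cons <- find_consensus_sites(sc, essential = res[1:5], hubs = res[3:8],
                                 sasa = sasa)
    out <- tempfile(fileext = ".json")
    write_consensus(cons, tempfile(fileext = ".tsv"), out)
    readBin(out, "raw", file.size(out))
  }
  expect_identical(run_once(), run_once())
})
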