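two_cell_table <- function(d) {
  cell_table(data.frame(cell_id = c("a", "b"), x = c(0, d), y = c(0, 0)),
             "two")
}

test_that("the radius boundary is closed and self-edges are excluded", {
  g <- build_proximity_graph(two_cell_table(15), radius = 15)
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$distance, 15)
  g2 <- build_proximity_graph(two_cell_table(15.0001), radius = 15)
  expect_identical(nrow(g2$edges), 0L)
  # coincident distinct cells are connected
  g3 <- build_proximity_graph(two_cell_table(0), radius = 15)
  expect_identical(nrow(g3$edges), 1L)
  one <- cell_table(data.frame(cell_id = "a", x = 0, y = 0), "one")
  expect_identical(nrow(build_proximity_graph(one)$edges), 0L)
  expect_error(build_proximity_graph(one, radius = -1), "positive")
})

test_that("the grid index reproduces brute-force pair enumeration", {
  for (s in 1:4) {
    n <- c(200, 800, 1500, 2000)[s]
    tab <- random_cells(n, 1200, 900, seed = s)
    for (r in c(8, 15, 40)) {
      g <- build_proximity_graph(tab, r)
      ref <- brute_pairs(tab$x, tab$y, r)
      expect_identical(g$edges$i, ref$i)
      expect_identical(g$edges$j, ref$j)
      expect_equal(g$edges$distance, ref$distance)
    }
  }
})

test_that("edge sets are monotone in the radius", {
  tab <- random_cells(600, 800, 800, seed = 9)
  key <- function(g) paste(g$edges$i, g$edges$j)
  e10 <- key(build_proximity_graph(tab, 10))
  e15 <- key(build_proximity_graph(tab, 15))
  e30 <- key(build_proximity_graph(tab, 30))
  expect_true(all(e10 %in% e15))
  expect_true(all(e15 %in% e30))
})

test_that("interaction counts match hand enumeration and conserve edges", {
  df <- data.frame(cell_id = c("u", "v", "w"), x = c(0, 10, 5),
                   y = c(0, 0, 8))
  tab <- cell_table(df, "tri")
  tab$phenotype <- c("CTL", "Th", "Th")
  g <- build_proximity_graph(tab, 15)
  cnt <- interaction_counts(g, tab)
  expect_identical(cnt["CTL", "Th"], 2L)
  expect_identical(cnt["Th", "Th"], 1L)
  expect_identical(sum(cnt[upper.tri(cnt, diag = TRUE)]), 3L)

  tab2 <- random_cells(1000, 1000, 1000, seed = 5,
                       phenotypes = c("CTL", "Th", "B", "Mac"))
  g2 <- build_proximity_graph(tab2, 15)
  cnt2 <- interaction_counts(g2, tab2)
  # conservation: unordered-pair total (diagonal once) equals |edges|
  expect_identical(sum(cnt2[upper.tri(cnt2, diag = TRUE)]),
                   nrow(g2$edges))
  # brute-force recount from the edge list
  lab <- tab2$phenotype
  ref <- table(factor(pmin(lab[g2$edges$i], lab[g2$edges$j])),
               factor(pmax(lab[g2$edges$i], lab[g2$edges$j])))
  for (a in rownames(ref)) {
    for (b in colnames(ref)) {
      if (ref[a, b] > 0) expect_identical(cnt2[a, b], unname(ref[a, b]))
    }
  }

  tab$phenotype[2] <- NA
  expect_error(interaction_counts(g, tab), "lacks a phenotype")
})

test_that("enrichment degenerates gracefully with a single phenotype", {
  tab <- random_cells(50, 100, 100, seed = 1, phenotypes = "CTL")
  g <- build_proximity_graph(tab, 15)
  ir <- interaction_enrichment(g, tab, n_perm = 50, seed = 3)
  expect_identical(dim(ir$z), c(1L, 1L))
  expect_equal(unname(ir$z[1, 1]), 0)   # permutation-invariant statistic
  expect_error(interaction_enrichment(g, tab, n_perm = 0), "n_perm")
})

test_that("a planted attraction pair is strongly enriched", {
  spec <- scene_spec(2000, 2000,
                     region_spec(region_rect(0, 0, 2000, 2000), 1250,
                                 c(Mac = 0.12, CTL = 0.12, Other = 0.76)),
                     attraction = attraction_pair("Mac", "CTL", 15, 0.8),
                     seed = 71)
  tab <- gate_cells(generate_scene(spec))
  g <- build_proximity_graph(tab, 15)
  ir <- interaction_enrichment(g, tab, n_perm = 200, seed = 72)
  expect_gt(ir$z["Mac", "CTL"], 3)
  expect_gt(ir$counts["Mac", "CTL"], ir$null_mean["Mac", "CTL"])
  expect_lte(ir$p_perm["Mac", "CTL"], 1 / 100)
})

test_that("enrichment is deterministic and invariant to cell-id renaming", {
  tab <- random_cells(400, 600, 600, seed = 8,
                      phenotypes = c("CTL", "Th", "Other"))
  g <- build_proximity_graph(tab, 15)
  ir1 <- interaction_enrichment(g, tab, n_perm = 100, seed = 4)
  ir2 <- interaction_enrichment(g, tab, n_perm = 100, seed = 4)
  expect_identical(ir1$z, ir2$z)

  tab2 <- tab
  tab2$cell_id <- paste0("renamed_", tab$cell_id)
  g2 <- build_proximity_graph(tab2, 15)
  ir3 <- interaction_enrichment(g2, tab2, n_perm = 100, seed = 4)
  expect_identical(ir1$counts, ir3$counts)
  expect_identical(ir1$z, ir3$z)
})

test_that("composite labels expose flag-bearing populations", {
  tab <- random_cells(300, 500, 500, seed = 10,
                      phenotypes = c("CTL", "Mac"))
  tab$Ki67_pos <- rep(c(TRUE, FALSE), length.out = 300)
  labs <- composite_labels(tab, "Ki67")
  expect_true("Ki67+ CTL" %in% labs)
  g <- build_proximity_graph(tab, 20)
  ir <- interaction_enrichment(g, tab, n_perm = 50, seed = 2, labels = labs)
  expect_true("Ki67+ CTL" %in% ir$levels)
  expect_identical(sum(ir$counts[upper.tri(ir$counts, diag = TRUE)]),
                   nrow(g$edges))
})
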