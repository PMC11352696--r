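labelled_table <- function(df, phen, case_id = "n") {
  tab <- cell_table(df, case_id)
  tab$phenotype <- phen
  tab
}

test_that("a pure neighborhood yields a one-hot profile row", {
  set.seed(2)
  df <- data.frame(cell_id = sprintf("c%02d", 1:21),
                   x = c(50, stats::runif(20, 0, 100)),
                   y = c(50, stats::runif(20, 0, 100)))
  tab <- labelled_table(df, c("CTL", rep("Th", 20)))
  prof <- neighborhood_profiles(tab, k_nn = 20)
  expect_equal(unname(prof[1, "Th"]), 1)
  expect_equal(sum(prof[1, ]), 1, tolerance = 1e-9)
})

test_that("isolated cells in radius mode give flagged zero rows", {
  df <- data.frame(cell_id = c("a", "b", "c"),
                   x = c(0, 10, 500), y = c(0, 0, 500))
  tab <- labelled_table(df, c("CTL", "Th", "B"))
  prof <- neighborhood_profiles(tab, mode = "radius", radius = 50)
  expect_equal(sum(prof[3, ]), 0)
  expect_identical(attr(prof, "isolated"), 3L)
  expect_equal(unname(prof[1, "Th"]), 1)
})

test_that("knn profiles equal brute-force recomputation", {
  tab <- random_cells(1000, 1000, 1000, seed = 17,
                      phenotypes = c("CTL", "Th", "B", "Mac", "Other"))
  prof <- neighborhood_profiles(tab, k_nn = 20)
  nn <- brute_knn(tab$x, tab$y, 20)
  ref <- t(vapply(seq_len(nrow(tab)), function(i) {
    tabulate(factor(tab$phenotype[nn[i, ]], levels = mif_phenotypes()),
             length(mif_phenotypes())) / 20
  }, numeric(length(mif_phenotypes()))))
  expect_equal(plain(prof), plain(ref), tolerance = 1e-12)
})

test_that("radius profiles equal brute-force recomputation", {
  tab <- random_cells(500, 500, 500, seed = 18,
                      phenotypes = c("CTL", "Th", "Other"))
  prof <- neighborhood_profiles(tab, mode = "radius", radius = 30)
  for (i in c(1, 50, 200, 500)) {
    d <- sqrt((tab$x - tab$x[i])^2 + (tab$y - tab$y[i])^2)
    nb <- which(d <= 30 & seq_along(d) != i)
    ref <- tabulate(factor(tab$phenotype[nb], levels = mif_phenotypes()),
                    length(mif_phenotypes()))
    if (length(nb)) ref <- ref / length(nb)
    expect_equal(unname(prof[i, ]), ref, tolerance = 1e-12)
  }
})

test_that("two distinct profiles separate perfectly at k = 2", {
  prof <- rbind(matrix(rep(c(1, 0), each = 30), 30, 2),
                matrix(rep(c(0, 1), each = 30), 30, 2))
  colnames(prof) <- c("CTL", "Th")
  m <- cluster_niches(prof, k = 2, seed = 1)
  expect_equal(m$tot_withinss, 0, tolerance = 1e-12)
  expect_identical(length(unique(m$labels[1:30])), 1L)
  expect_identical(length(unique(m$labels[31:60])), 1L)
  expect_error(cluster_niches(prof, k = 3), "distinct")
})

test_that("clustering is deterministic and stable under row permutation", {
  tab <- gate_cells(generate_scene(planted_niche_spec(seed = 3,
                                                      n_niches = 3)))
  prof <- neighborhood_profiles(tab)
  m1 <- cluster_niches(prof, k = 3, seed = 5)
  m2 <- cluster_niches(prof, k = 3, seed = 5)
  expect_identical(m1$labels, m2$labels)

  perm <- withr::with_seed(1, sample.int(nrow(prof)))
  profp <- prof[perm, , drop = FALSE]
  attr(profp, "case") <- attr(prof, "case")[perm]
  attr(profp, "mode") <- "knn"; attr(profp, "size") <- 20
  m3 <- cluster_niches(profp, k = 3, seed = 5)
  # canonical re-indexing by size makes summaries order-invariant
  expect_equal(sort(m1$sizes), sort(m3$sizes))
  expect_gt(ari(m1$labels[perm], m3$labels), 0.999)
})

test_that("planted niches are recovered with high agreement", {
  tab <- gate_cells(generate_scene(planted_niche_spec(seed = 21,
                                                      n_niches = 3)))
  prof <- neighborhood_profiles(tab)
  m <- cluster_niches(prof, k = 3, seed = 9)
  expect_gte(ari(m$labels, tab$true_niche), 0.9)
})

test_that("a region holding 60% of cells becomes the predominant niche", {
  spec <- scene_spec(2000, 1000, list(
    region_spec(region_rect(0, 0, 1000, 1000), 3000,
                c(CTL = 0.8, Other = 0.2), niche_id = 1),
    region_spec(region_rect(1000, 0, 1000, 1000), 2000,
                c(Other = 0.9, B = 0.1), niche_id = 2)),
    seed = 31)
  tab <- gate_cells(generate_scene(spec))
  m <- cluster_niches(neighborhood_profiles(tab), k = 2, seed = 2)
  rep_ <- niche_report(m)
  expect_identical(unname(rep_$predominant[1]), 1L)  # largest niche is #1
  expect_lt(abs(rep_$proportions[1, 1] - 0.6), 0.05)
  expect_equal(sum(rep_$proportions[1, ]), 1, tolerance = 1e-9)
})

test_that("multi-case proportions normalise per case", {
  t1 <- gate_cells(generate_scene(one_region_spec(
    1200, c(CTL = 0.7, Other = 0.3), seed = 41, case_id = "case1")))
  t2 <- gate_cells(generate_scene(one_region_spec(
    1200, c(B = 0.7, Other = 0.3), seed = 42, case_id = "case2")))
  pooled <- pool_profiles(list(neighborhood_profiles(t1),
                               neighborhood_profiles(t2)))
  m <- cluster_niches(pooled, k = 2, seed = 3)
  rep_ <- niche_report(m)
  expect_identical(rownames(rep_$proportions), c("case1", "case2"))
  expect_equal(unname(rowSums(rep_$proportions)), c(1, 1),
               tolerance = 1e-9)
  expect_false(rep_$predominant[["case1"]] == rep_$predominant[["case2"]])
})

test_that("fitted assignments are a fixed point of the centroids", {
  tab <- gate_cells(generate_scene(planted_niche_spec(seed = 8,
                                                      n_niches = 3)))
  prof <- neighborhood_profiles(tab)
  m <- cluster_niches(prof, k = 3, seed = 4)
  expect_identical(predict(m, prof), m$labels)
  scan <- niche_k_scan(prof, ks = 2:4, seed = 1, n_init = 3)
  expect_identical(scan$k, 2:4)
  expect_true(all(diff(scan$tot_withinss) <= 1e-9))
})
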