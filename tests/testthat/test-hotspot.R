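test_that("ties resolve to the top-left anchor on a uniform grid", {
  g <- expand.grid(x = seq(5, 995, by = 10), y = seq(5, 995, by = 10))
  tab <- cell_table(data.frame(cell_id = seq_len(nrow(g)),
                               x = g$x, y = g$y), "grid")
  win <- find_hotspot(tab, window_side = 500, stride = 250)
  expect_equal(win$x0, min(tab$x))
  expect_equal(win$y0, min(tab$y))
})

test_that("the chosen window matches an exhaustive anchor scan", {
  for (s in 1:5) {
    tab <- random_cells(1500, 2000, 2000, seed = s)
    win <- find_hotspot(tab, 500, 250)
    ref <- brute_hotspot(tab$x, tab$y, 500, 250)
    expect_equal(win$count, ref$count)
    expect_equal(win$x0, ref$x0)
    expect_equal(win$y0, ref$y0)
  }
})

test_that("a planted dense cluster is found and beats the 1-um scan bound", {
  set.seed(33)
  n_bg <- 1500
  clus <- data.frame(x = stats::runif(500, 800, 1200),
                     y = stats::runif(500, 800, 1200))
  df <- data.frame(
    cell_id = sprintf("c%04d", 1:(n_bg + 500)),
    x = c(stats::runif(n_bg, 0, 2000), clus$x),
    y = c(stats::runif(n_bg, 0, 2000), clus$y))
  tab <- cell_table(df, "clus")
  win <- find_hotspot(tab, 500, 250)
  # the 400-um cluster centroid falls inside the chosen window
  expect_true(win$x0 <= 1000 && 1000 <= win$x0 + win$side)
  expect_true(win$y0 <= 1000 && 1000 <= win$y0 + win$side)
  expect_gte(win$count, 0.9 * grid_max_count(tab$x, tab$y, 500))
})

test_that("window membership is half-open and densities conserve counts", {
  df <- data.frame(cell_id = 1:4, x = c(100, 599.999, 600, 100),
                   y = c(100, 100, 100, 600),
                   CD3 = 100, CD8 = 100)
  for (m in setdiff(mif_markers(), c("CD3", "CD8"))) df[[m]] <- 0
  tab <- gate_cells(cell_table(df, "edge"))
  win <- structure(list(x0 = 100, y0 = 100, side = 500, count = NA),
                   class = "hotspot_window")
  rep_ <- hotspot_densities(tab, win)
  # cells at x = 600 and y = 600 sit on the excluded closing edge
  expect_equal(unname(rep_$densities["CTL"]) * rep_$window_area_mm2, 2)
  expect_equal(sum(rep_$densities) * rep_$window_area_mm2, 2,
               tolerance = 1e-9)

  tab2 <- gate_cells(generate_scene(one_region_spec(
    2000, c(CTL = 0.5, Other = 0.5), seed = 4)))
  win2 <- find_hotspot(tab2)
  rep2 <- hotspot_densities(tab2, win2)
  inside <- sum(tab2$x >= win2$x0 & tab2$x < win2$x0 + 500 &
                tab2$y >= win2$y0 & tab2$y < win2$y0 + 500)
  expect_equal(sum(rep2$densities) * rep2$window_area_mm2, inside,
               tolerance = 1e-9)
})

test_that("a region planted at 782 CTL/mm^2 is estimated within Poisson error", {
  tab <- gate_cells(generate_scene(one_region_spec(
    782, c(CTL = 1), seed = 12, side = 2000)))
  rep_ <- hotspot_densities(tab, find_hotspot(tab))
  a <- rep_$window_area_mm2
  # hotspot selection maximises the count, so allow the Poisson band around
  # the planted density plus the selection bias of the max over ~49 windows
  expect_lt(abs(rep_$densities[["CTL"]] - 782), 4 * sqrt(782 * a) / a)
})

test_that("windows larger than the bounding box fall back with a warning", {
  tab <- random_cells(50, 200, 200, seed = 2)
  expect_warning(win <- find_hotspot(tab, 500), "bounding box")
  expect_equal(win$count, 50)
  expect_error(find_hotspot(tab[0, ]), "empty")
})

test_that("identical group densities give null comparisons", {
  mk_report <- function(id, grp, d) {
    structure(list(case_id = id, group = grp, window = NULL,
                   window_area_mm2 = 0.25,
                   densities = d), class = "density_report")
  }
  d <- stats::setNames(c(10, 20, 30, 40), c("Th", "CTL", "B", "Mac"))
  reports <- c(lapply(1:3, function(i) mk_report(paste0("a", i), "A", d)),
               lapply(1:3, function(i) mk_report(paste0("b", i), "B", d)))
  gs <- group_stats(reports)
  expect_true(all(abs(gs$comparisons$difference) < 1e-9))
  expect_true(all(gs$comparisons$p_adj > 1 - 1e-6))
  # n = 1 median equals the value itself
  one <- group_stats(c(reports[1], reports[4]))
  expect_equal(one$summaries$median, rep(d, each = 2), ignore_attr = TRUE)
  expect_error(group_stats(reports[1]), "2")
})

test_that("well-separated groups are flagged as significant", {
  mk <- function(id, grp, mult, seed) {
    set.seed(seed)
    structure(list(case_id = id, group = grp, window = NULL,
                   window_area_mm2 = 0.25,
                   densities = stats::setNames(
                     mult * c(10, 10, 2, 7) * stats::rlnorm(4, 0, 0.3),
                     c("Th", "CTL", "B", "Mac"))),
              class = "density_report")
  }
  reports <- c(lapply(1:7, function(i) mk(paste0("e", i), "ESS", 1, i)),
               lapply(1:2, function(i) mk(paste0("s", i), "SDUS", 40,
                                          100 + i)))
  gs <- group_stats(reports)
  ctl <- gs$comparisons[gs$comparisons$phenotype == "CTL", ]
  expect_lt(ctl$p_adj, 0.05)
  expect_gt(ctl$difference, 0)
})

test_that("group comparisons hold the familywise error rate under the null", {
  phen <- c("Th", "CTL", "B", "Mac")
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    reports <- lapply(1:9, function(i) {
      structure(list(case_id = paste0("c", i),
                     group = if (i <= 7) "A" else "B",
                     window = NULL, window_area_mm2 = 0.25,
                     densities = stats::setNames(stats::rnorm(4, 50, 15),
                                                 phen)),
                class = "density_report")
    })
    any(group_stats(reports)$comparisons$p_adj < 0.05)
  }, TRUE)
  band <- 2 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), band)
})
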