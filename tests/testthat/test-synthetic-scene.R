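test_that("degenerate scenes behave: zero density, empty ROI, bad regions", {
  empty <- generate_scene(one_region_spec(0, c(CTL = 1), seed = 1))
  expect_s3_class(empty, "cell_table")
  expect_identical(nrow(empty), 0L)

  expect_error(scene_spec(0, 1000, list()), "empty ROI")
  expect_error(
    scene_spec(1000, 1000,
               region_spec(region_rect(0, 0, 2000, 500), 10, c(CTL = 1))),
    "outside the ROI")
  expect_error(
    scene_spec(1000, 1000,
               list(region_spec(region_rect(0, 0, 600, 600), 10,
                                c(CTL = 1), niche_id = 1),
                    region_spec(region_disc(500, 500, 200), 10,
                                c(Th = 1), niche_id = 2))),
    "conflicting niche_ids")
  expect_error(region_spec(region_rect(0, 0, 10, 10), 5,
                           c(CTL = 0.7, Th = 0.2)),
               "sum to 1")
  expect_error(attraction_pair("Mac", "CTL", fraction = 1.2))
})

test_that("single-region counts are Poisson-consistent and labels pure", {
  spec <- one_region_spec(1000, c(CTL = 1), seed = 7)
  tab <- generate_scene(spec)
  expect_lt(abs(nrow(tab) - 1000), 4 * sqrt(1000))
  expect_true(all(tab$true_phenotype == "CTL"))
  expect_true(all(tab$true_niche == 1L))
  expect_true(all(tab$x >= 0 & tab$x <= 1000 & tab$y >= 0 & tab$y <= 1000))
  # CTL-defining markers from the positive log-normal component, the rest
  # from the negative one (log-means 4.61 vs 1.61, sd 0.35)
  for (m in c("CD3", "CD8")) {
    expect_lt(abs(mean(log(tab[[m]])) - log(100)), 0.08)
  }
  expect_lt(abs(mean(log(tab$CD4)) - log(5)), 0.08)
})

test_that("full attraction relocates every target within the radius", {
  spec <- scene_spec(1000, 1000,
                     region_spec(region_rect(0, 0, 1000, 1000), 800,
                                 c(Mac = 0.3, CTL = 0.3, Other = 0.4)),
                     attraction = attraction_pair("Mac", "CTL",
                                                  radius = 15,
                                                  fraction = 1.0),
                     seed = 11)
  tab <- generate_scene(spec)
  ctl <- which(tab$true_phenotype == "CTL")
  mac <- which(tab$true_phenotype == "Mac")
  # brute-force pair scan: every relocated CTL has a Mac within 15 um
  for (i in ctl) {
    dmin <- min(sqrt((tab$x[mac] - tab$x[i])^2 + (tab$y[mac] - tab$y[i])^2))
    expect_lte(dmin, 15 + 1e-9)
  }
})

test_that("identical specs generate byte-identical tables", {
  spec <- case_profile_spec("SDUS-like", seed = 5)
  expect_identical(generate_scene(spec), generate_scene(spec))
  expect_identical(case_profile_spec("ESS-like", seed = 9),
                   case_profile_spec("ESS-like", seed = 9))
})

test_that("planted density is recovered across 100 seeded replicates", {
  d <- 500
  est <- vapply(1:100, function(s) {
    nrow(generate_scene(one_region_spec(d, c(CTL = 1), seed = s)))
  }, 0)
  se <- sqrt(d / 100)                       # Poisson SE of the mean density
  expect_lt(abs(mean(est) - d), 4 * se)
})

test_that("profile specs emulate immune-low vs immune-high cases", {
  for (s in c(1, 2, 3)) {
    ess <- case_profile_spec("ESS-like", seed = s)
    sdus <- case_profile_spec("SDUS-like", seed = s)
    expect_lte(expected_density(ess, "Th"), 64.5)
    expect_gte(expected_density(sdus, "CTL"),
               10 * expected_density(ess, "CTL"))
  }
  expect_error(case_profile_spec("bogus"))

  # margin band holds PD-1+ T cells and PD-L1+ tumor cells
  tab <- generate_scene(case_profile_spec("SDUS-like", seed = 2))
  band <- tab$true_niche == 4L
  expect_gt(sum(band), 0)
  expect_true(all(abs(tab$x[band] - 1900) <= 75))
  expect_true(all(tab$true_phenotype[band] %in% c("T_other", "Other")))
  expect_true(all(tab$PD1_pos[band & tab$true_phenotype == "T_other"]))
  expect_true(all(tab$PDL1_pos[band & tab$true_phenotype == "Other"]))
})

test_that("gating recovers planted phenotypes on a separable scene", {
  mix <- c(CTL = 0.15, Th = 0.15, B = 0.1, Mac = 0.1, Myeloid = 0.05,
           Endothelial = 0.05, Fibroblast = 0.05, SmoothMuscle = 0.05,
           T_other = 0.05, Other = 0.25)
  tab <- generate_scene(one_region_spec(10000, mix, seed = 13))
  expect_gt(nrow(tab), 9000)
  gated <- gate_cells(tab)
  expect_gte(mean(gated$phenotype == gated$true_phenotype), 0.99)
})

test_that("scene specs round-trip through YAML", {
  spec <- case_profile_spec("SDUS-like", seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_spec(spec, path)
  spec2 <- read_scene_spec(path)
  expect_identical(spec2$seed, spec$seed)
  expect_equal(spec2$regions, spec$regions, tolerance = 1e-12)
  expect_equal(spec2$margin, spec$margin, tolerance = 1e-12)
  expect_equal(generate_scene(spec2), generate_scene(spec),
               tolerance = 1e-12)
})
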