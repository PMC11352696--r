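# Markers each lineage phenotype expresses; drives both synthesis and the
# default gating rules.
lineage_positive_markers <- function() {
  list(CTL = c("CD3", "CD8"), Th = c("CD3", "CD4"), T_other = "CD3",
       B = "CD20", Mac = "CD68", Myeloid = "CD14", Endothelial = "CD31",
       Fibroblast = "FAP", SmoothMuscle = "aSMA", Other = character(0))
}

sample_in_geometry <- function(g, n) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (g$type == "rect") {
    cbind(x = stats::runif(n, g$x0, g$x0 + g$width),
          y = stats::runif(n, g$y0, g$y0 + g$height))
  } else {
    r <- g$r * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(x = g$cx + r * cos(th), y = g$cy + r * sin(th))
  }
}

#' Generate a synthetic segmented-cell scene
#'
#' Realises a [scene_spec()] as a [cell_table()] with ground-truth columns.
#' Cell counts per region are Poisson with mean density x area; positions
#' are uniform within the region geometry (homogeneous Poisson process);
#' each cell's true phenotype is drawn from the region mixture and its
#' marker intensities from the two-component log-normal intensity model
#' (positive component for the phenotype's defining markers and any flag
#' markers, negative otherwise). Margin-band PD-1+ T cells and PD-L1+ tumor
#' cells are added on top. Attraction pairs are realised by
#' thinning-and-displacement: the attracted fraction of B-phenotype cells is
#' relocated uniformly into a disc of the attraction radius around a
#' uniformly chosen attractor cell (clamped to the ROI; clamping is a
#' projection onto a convex set, so relocated cells stay within the radius).
#' All draws flow from the single scene seed, so identical specs give
#' byte-identical tables.
#'
#' @param spec A [scene_spec()].
#' @return A [cell_table()] with marker intensities, logical flag columns
#'   and ground-truth `true_phenotype` / `true_niche` columns.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    xs <- ys <- numeric(0)
    phen <- character(0)
    niche <- integer(0)
    pd1 <- pdl1 <- logical(0)

    for (r in spec$regions) {
      n <- stats::rpois(1, r$density * geometry_area_mm2(r$geometry))
      pos <- sample_in_geometry(r$geometry, n)
      xs <- c(xs, pos[, 1]); ys <- c(ys, pos[, 2])
      phen <- c(phen, if (n) sample(names(r$mixture), n, replace = TRUE,
                                    prob = r$mixture) else character(0))
      niche <- c(niche, rep(r$niche_id, n))
      pd1 <- c(pd1, rep(FALSE, n)); pdl1 <- c(pdl1, rep(FALSE, n))
    }

    if (!is.null(spec$margin)) {
      m <- spec$margin
      if (m$band_axis == "x") {
        g <- region_rect(m$band_center - m$band_halfwidth, 0,
                         2 * m$band_halfwidth, spec$roi_height)
      } else {
        g <- region_rect(0, m$band_center - m$band_halfwidth,
                         spec$roi_width, 2 * m$band_halfwidth)
      }
      a <- geometry_area_mm2(g)
      nt <- stats::rpois(1, m$pd1_t_density * a)
      nu <- stats::rpois(1, m$pdl1_tumor_density * a)
      pos <- sample_in_geometry(g, nt + nu)
      xs <- c(xs, pos[, 1]); ys <- c(ys, pos[, 2])
      phen <- c(phen, rep(c("T_other", "Other"), c(nt, nu)))
      niche <- c(niche, rep(m$niche_id, nt + nu))
      pd1 <- c(pd1, rep(c(TRUE, FALSE), c(nt, nu)))
      pdl1 <- c(pdl1, rep(c(FALSE, TRUE), c(nt, nu)))
    }

    n <- length(xs)
    for (ap in spec$attraction) {
      anchors <- which(phen == ap$a)
      targets <- which(phen == ap$b)
      if (!length(anchors) || !length(targets)) next
      nsel <- round(ap$fraction * length(targets))
      sel <- if (nsel) sample(targets, nsel) else integer(0)
      if (length(sel)) {
        host <- anchors[sample.int(length(anchors), length(sel),
                                   replace = TRUE)]
        rr <- ap$radius * sqrt(stats::runif(length(sel)))
        th <- stats::runif(length(sel), 0, 2 * pi)
        xs[sel] <- pmin(pmax(xs[host] + rr * cos(th), 0), spec$roi_width)
        ys[sel] <- pmin(pmax(ys[host] + rr * sin(th), 0), spec$roi_height)
      }
    }

    ki67 <- draw_flag(phen, spec$ki67_rates)
    gzmb <- draw_flag(phen, spec$gzmb_rates)

    lineage <- lineage_positive_markers()
    flagmk <- mif_flags()
    im <- spec$intensity
    intens <- matrix(0, n, length(mif_markers()),
                     dimnames = list(NULL, mif_markers()))
    flag_on <- cbind(PD1 = pd1, PDL1 = pdl1, Ki67 = ki67, GzmB = gzmb)
    for (mk in mif_markers()) {
      posi <- vapply(phen, function(p) mk %in% lineage[[p]], TRUE,
                     USE.NAMES = FALSE)
      fl <- names(flagmk)[flagmk == mk]
      if (length(fl)) posi <- posi | flag_on[, fl]
      meanlog <- ifelse(posi, im$positive_log_mean[mk],
                        im$negative_log_mean[mk])
      sdlog <- ifelse(posi, im$positive_log_sd[mk], im$negative_log_sd[mk])
      intens[, mk] <- if (n) stats::rlnorm(n, meanlog, sdlog) else numeric(0)
    }

    df <- data.frame(cell_id = sprintf("c%06d", seq_len(n)),
                     x = xs, y = ys, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(intens))
    df$PD1_pos <- pd1; df$PDL1_pos <- pdl1
    df$Ki67_pos <- ki67; df$GzmB_pos <- gzmb
    df$true_phenotype <- phen
    df$true_niche <- niche
    cell_table(df, case_id = spec$case_id, group = spec$group)
  })
}

draw_flag <- function(phen, rates) {
  n <- length(phen)
  if (is.null(rates) || n == 0) return(rep(FALSE, n))
  p <- rates[phen]
  p[is.na(p)] <- 0
  stats::runif(n) < p
}

#' Scene spec emulating an immune-low or immune-high case
#'
#' Builds a [scene_spec()] whose planted densities emulate the two study
#' profiles: "ESS-like" (immune-low: T helper, CTL, B and macrophage
#' hotspot densities around medians 10.4, 9.8, 1.2 and 6.6 per mm^2, drawn
#' per case from log-normal spreads truncated to the observed immune-low
#' ranges) and "SDUS-like" (immune-high: a lymphocyte-aggregation region —
#' ground-truth niche 3 — whose hotspot CTL/Th/B/Mac densities land near
#' 780/360/160/145 per mm^2, a vascular-rich region — niche 2 —, Th-B and
#' Th-CTL attraction pairs at 15 um, an invasive-margin band of PD-1+ T
#' cells facing PD-L1+ tumor cells, and Ki67 rates planted so that about
#' 20% of proliferating cells are CTLs and about 14% each are Th and B
#' cells).
#'
#' @param profile "ESS-like" or "SDUS-like".
#' @param seed Integer seed; fixes both the per-case density draw and the
#'   downstream scene realisation.
#' @param case_id,group Labels for the generated case.
#' @return A [scene_spec()].
#' @export
case_profile_spec <- function(profile = c("ESS-like", "SDUS-like"),
                              seed = 1L, case_id = profile, group = NULL) {
  profile <- match.arg(profile)
  case_id <- case_id[1]
  w <- h <- 2000
  if (profile == "ESS-like") {
    if (is.null(group)) group <- "ESS"
    d <- with_seed(derive_seed(seed, "profile", case_id), {
      draw <- function(med, lo, hi, sd = 0.7) {
        min(max(med * stats::rlnorm(1, 0, sd), lo), hi)
      }
      c(Th = draw(10.4, 0, 64.5), CTL = draw(9.8, 2.0, 22.2),
        B = draw(1.2, 0.4, 21.6), Mac = draw(6.6, 2.4, 35.5))
    })
    dens <- 1500
    mixture <- c(CTL = unname(d["CTL"]) / dens, Th = unname(d["Th"]) / dens,
                 B = unname(d["B"]) / dens, Mac = unname(d["Mac"]) / dens,
                 Myeloid = 10 / dens, Endothelial = 20 / dens,
                 Fibroblast = 10 / dens, SmoothMuscle = 20 / dens)
    mixture <- c(mixture, Other = 1 - sum(mixture))
    spec <- scene_spec(w, h,
                       region_spec(region_rect(0, 0, w, h), dens, mixture, 1L),
                       ki67_rates = c(Other = 0.02, CTL = 0.02, Th = 0.02,
                                      B = 0.02, Mac = 0.02),
                       seed = derive_seed(seed, "scene", case_id),
                       case_id = case_id, group = group)
    return(spec)
  }

  if (is.null(group)) group <- "SDUS"
  bg_density <- 2000
  # background CTL density (120/mm^2) keeps the ROI-wide expectation above
  # 10x the top of the emulated immune-low CTL range (22.2/mm^2)
  bg_mix <- c(CTL = 0.06, Th = 0.03, B = 0.005, Mac = 0.02, Myeloid = 0.01,
              Endothelial = 0.015, Fibroblast = 0.005, SmoothMuscle = 0.005,
              Other = 0.85)
  # infiltrates sit on top of the tumor background, so planted patches
  # carry the combined density and mixture; the background tiles around them
  agg_rect <- region_rect(500, 500, 800, 800)
  vas_rect <- region_rect(1350, 1350, 500, 500)
  aggregate <- region_spec(                      # lymphocyte aggregation
    agg_rect,
    bg_density + 1500,
    mix_layers(list(bg_density, bg_mix),
               list(1500, c(CTL = 0.44, Th = 0.20, B = 0.10, Mac = 0.07,
                            Endothelial = 0.05, Other = 0.14))),
    niche_id = 3L)
  vascular <- region_spec(                       # vascular-rich
    vas_rect,
    bg_density + 1200,
    mix_layers(list(bg_density, bg_mix),
               list(1200, c(Endothelial = 0.30, Mac = 0.25, CTL = 0.15,
                            Other = 0.30))),
    niche_id = 2L)
  background <- lapply(rect_complement(w, h, list(agg_rect, vas_rect)),
                       region_spec, density = bg_density, mixture = bg_mix,
                       niche_id = 1L)
  margin <- margin_spec("x", 1900, 75, pd1_t_density = 200,
                        pdl1_tumor_density = 200, niche_id = 4L)
  spec <- scene_spec(w, h, c(background, list(aggregate, vascular)),
                     attraction = list(attraction_pair("Th", "B", 15, 0.5),
                                       attraction_pair("Th", "CTL", 15, 0.5)),
                     margin = margin,
                     seed = derive_seed(seed, "scene", case_id),
                     case_id = case_id, group = group)
  spec$ki67_rates <- planted_ki67_rates(
    spec, targets = c(CTL = 0.20, Th = 0.14, B = 0.14, Mac = 0.07,
                      Endothelial = 0.05, Other = 0.40),
    overall = 0.06)
  spec
}

# Combined phenotype mixture of stacked (density, mixture) layers.
mix_layers <- function(...) {
  layers <- list(...)
  phen <- unique(unlist(lapply(layers, function(l) names(l[[2]]))))
  out <- stats::setNames(numeric(length(phen)), phen)
  total <- 0
  for (l in layers) {
    out[names(l[[2]])] <- out[names(l[[2]])] + l[[1]] * l[[2]]
    total <- total + l[[1]]
  }
  out / total
}

# Rectangles tiling the ROI around pairwise-disjoint axis-aligned holes.
rect_complement <- function(roi_w, roi_h, holes) {
  ys <- sort(unique(c(0, roi_h,
                      unlist(lapply(holes, function(g) {
                        c(g$y0, g$y0 + g$height)
                      })))))
  ys <- ys[ys >= 0 & ys <= roi_h]
  out <- list()
  for (s in seq_len(length(ys) - 1)) {
    y0 <- ys[s]; y1 <- ys[s + 1]
    # holes spanning this slab, as x-intervals
    iv <- Filter(Negate(is.null), lapply(holes, function(g) {
      if (g$y0 <= y0 && g$y0 + g$height >= y1) c(g$x0, g$x0 + g$width)
    }))
    iv <- iv[order(vapply(iv, `[`, 0, 1))]
    x0 <- 0
    for (h in iv) {
      if (h[1] > x0) out[[length(out) + 1]] <- region_rect(x0, y0,
                                                           h[1] - x0,
                                                           y1 - y0)
      x0 <- h[2]
    }
    if (x0 < roi_w) out[[length(out) + 1]] <- region_rect(x0, y0,
                                                          roi_w - x0,
                                                          y1 - y0)
  }
  out
}

# Per-phenotype Ki67 rates that make the expected composition of Ki67+
# cells hit `targets`, with `overall` the expected proliferating fraction.
planted_ki67_rates <- function(spec, targets, overall = 0.06) {
  roi_mm2 <- spec$roi_width * spec$roi_height / 1e6
  e_tot <- sum(vapply(mif_phenotypes(),
                      function(p) expected_density(spec, p), 0)) * roi_mm2
  rates <- vapply(names(targets), function(p) {
    e_p <- expected_density(spec, p) * roi_mm2
    if (e_p <= 0) 0 else targets[[p]] * overall * e_tot / e_p
  }, 0)
  if (any(rates > 1)) stop("planted Ki67 targets unattainable: rate > 1")
  rates
}

#' Scene specs for a study-shaped synthetic suite
#'
#' Builds the cohort shape of the study: 3 LG-ESS + 4 HG-ESS immune-low
#' cases and 2 SDUS immune-high cases, each with an independently derived
#' seed so adding cases never perturbs existing ones.
#'
#' @param seed Global integer seed.
#' @param n_lg,n_hg,n_sdus Cases per group.
#' @return Named list of [scene_spec()]s.
#' @export
case_suite_specs <- function(seed = 1L, n_lg = 3, n_hg = 4, n_sdus = 2) {
  specs <- list()
  for (i in seq_len(n_lg)) {
    id <- sprintf("LG-ESS-%d", i)
    specs[[id]] <- case_profile_spec("ESS-like", derive_seed(seed, id),
                                     case_id = id, group = "LG-ESS")
  }
  for (i in seq_len(n_hg)) {
    id <- sprintf("HG-ESS-%d", i)
    specs[[id]] <- case_profile_spec("ESS-like", derive_seed(seed, id),
                                     case_id = id, group = "HG-ESS")
  }
  for (i in seq_len(n_sdus)) {
    id <- sprintf("SDUS-%d", i)
    specs[[id]] <- case_profile_spec("SDUS-like", derive_seed(seed, id),
                                     case_id = id, group = "SDUS")
  }
  specs
}

#' Planted multi-niche scene spec for clustering benchmarks
#'
#' Tiles the ROI with `n_niches` rectangular regions, each dominated by a
#' distinct phenotype (dominant mixture weight `dominance`, remainder spread
#' evenly over the other dominant phenotypes), giving well-separated
#' neighborhood composition profiles with known ground truth.
#'
#' @param seed Scene seed.
#' @param n_niches Number of planted niches (2..6).
#' @param density Cells per mm^2 in every tile.
#' @param dominance Mixture weight of the tile's dominant phenotype.
#' @param tile Side of each square tile (um).
#' @return A [scene_spec()] with `n_niches` tiles in a 3-column grid.
#' @export
planted_niche_spec <- function(seed = 1L, n_niches = 6, density = 2000,
                               dominance = 0.9, tile = 1000) {
  stopifnot(n_niches >= 2, n_niches <= 6)
  dominants <- c("CTL", "Th", "B", "Mac", "Endothelial", "Other")[1:n_niches]
  ncol_ <- min(3L, n_niches)
  nrow_ <- ceiling(n_niches / ncol_)
  regions <- lapply(seq_len(n_niches), function(i) {
    row <- (i - 1) %/% ncol_
    col <- (i - 1) %% ncol_
    mix <- stats::setNames(rep((1 - dominance) / (n_niches - 1), n_niches),
                           dominants)
    mix[dominants[i]] <- dominance
    region_spec(region_rect(col * tile, row * tile, tile, tile),
                density, mix, niche_id = i)
  })
  scene_spec(ncol_ * tile, nrow_ * tile, regions, seed = seed,
             case_id = sprintf("planted%d", n_niches))
}
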