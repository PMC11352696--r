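#' Rectangular region geometry
#'
#' Axis-aligned rectangle in micrometres (image convention, origin top-left).
#'
#' @param x0,y0 Top-left corner (um).
#' @param width,height Side lengths (um), > 0.
#' @return A region geometry object.
#' @export
region_rect <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0)
  structure(list(type = "rect", x0 = x0, y0 = y0,
                 width = width, height = height),
            class = "mif_geometry")
}

#' Disc region geometry
#'
#' @param cx,cy Centre (um).
#' @param r Radius (um), > 0.
#' @return A region geometry object.
#' @export
region_disc <- function(cx, cy, r) {
  stopifnot(r > 0)
  structure(list(type = "disc", cx = cx, cy = cy, r = r),
            class = "mif_geometry")
}

geometry_area_mm2 <- function(g) {
  switch(g$type,
         rect = g$width * g$height / 1e6,
         disc = pi * g$r^2 / 1e6,
         stop("unknown geometry type ", g$type))
}

geometry_bbox <- function(g) {
  switch(g$type,
         rect = c(g$x0, g$y0, g$x0 + g$width, g$y0 + g$height),
         disc = c(g$cx - g$r, g$cy - g$r, g$cx + g$r, g$cy + g$r))
}

# strict overlap (shared boundary does not count, so tilings are legal)
geometries_overlap <- function(a, b) {
  if (a$type == "rect" && b$type == "rect") {
    return(a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
           a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height)
  }
  if (a$type == "disc" && b$type == "disc") {
    d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
    return(d < a$r + b$r)
  }
  if (a$type == "disc") { tmp <- a; a <- b; b <- tmp }   # a rect, b disc
  px <- min(max(b$cx, a$x0), a$x0 + a$width)
  py <- min(max(b$cy, a$y0), a$y0 + a$height)
  sqrt((px - b$cx)^2 + (py - b$cy)^2) < b$r
}

#' Region of a synthetic scene
#'
#' A homogeneous-Poisson patch of cells: geometry, cell density, a phenotype
#' mixture and a ground-truth niche label.
#'
#' @param geometry [region_rect()] or [region_disc()].
#' @param density Cells per mm^2, >= 0.
#' @param mixture Named probabilities over [mif_phenotypes()], summing to 1.
#' @param niche_id Integer ground-truth niche label.
#' @return A `region_spec`.
#' @export
region_spec <- function(geometry, density, mixture, niche_id = 1L) {
  stopifnot(inherits(geometry, "mif_geometry"), density >= 0)
  mixture <- unlist(mixture)
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop("mixture probabilities must sum to 1 (got ", sum(mixture), ")",
         call. = FALSE)
  }
  bad <- setdiff(names(mixture), mif_phenotypes())
  if (length(bad)) stop("unknown phenotype(s) in mixture: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(geometry = geometry, density = density,
                 mixture = mixture, niche_id = as.integer(niche_id)),
            class = "region_spec")
}

#' Invasive-margin band of a synthetic scene
#'
#' A straight band of PD-1+ T cells interleaved with PD-L1+ tumor cells,
#' emulating checkpoint engagement at the tumor invasive margin.
#'
#' @param band_axis "x" or "y": the coordinate the band is defined on
#'   ("x" gives a vertical strip).
#' @param band_center,band_halfwidth Band position and half width (um).
#' @param pd1_t_density Density of PD-1+ T cells (per mm^2).
#' @param pdl1_tumor_density Density of PD-L1+ tumor cells (per mm^2).
#' @param niche_id Ground-truth niche label given to band cells.
#' @return A `margin_spec`.
#' @export
margin_spec <- function(band_axis = c("x", "y"), band_center, band_halfwidth,
                        pd1_t_density, pdl1_tumor_density, niche_id = 0L) {
  band_axis <- match.arg(band_axis)
  stopifnot(band_halfwidth > 0, pd1_t_density >= 0, pdl1_tumor_density >= 0)
  structure(list(band_axis = band_axis, band_center = band_center,
                 band_halfwidth = band_halfwidth,
                 pd1_t_density = pd1_t_density,
                 pdl1_tumor_density = pdl1_tumor_density,
                 niche_id = as.integer(niche_id)),
            class = "margin_spec")
}

#' Attracted phenotype pair
#'
#' Declares that a fraction of cells of phenotype `b` are relocated to
#' within `radius` of a uniformly chosen cell of phenotype `a`, planting a
#' known positive interaction for the enrichment test to detect.
#'
#' @param a,b Phenotype labels (attractor, attracted).
#' @param radius Attraction radius (um).
#' @param fraction Fraction of `b` cells relocated, in [0, 1].
#' @return An `attraction_pair`.
#' @export
attraction_pair <- function(a, b, radius = 15, fraction = 0.8) {
  stopifnot(a %in% mif_phenotypes(), b %in% mif_phenotypes(),
            radius > 0, fraction >= 0, fraction <= 1)
  structure(list(a = a, b = b, radius = radius, fraction = fraction),
            class = "attraction_pair")
}

#' Two-component log-normal marker intensity model
#'
#' Each marker intensity is log-normal: a "negative" component for cells not
#' expressing the marker and a well-separated "positive" component for cells
#' expressing it. Scalars are recycled over the panel; per-marker named
#' vectors are accepted. The default separation (log-mean gap 3.0, log-sd
#' 0.35, i.e. ~4.3 pooled SDs) keeps marker misclassification per cell well
#' below 1e-4 so gating can recover planted phenotypes essentially exactly.
#'
#' @param positive_log_mean,positive_log_sd Log-scale parameters of the
#'   positive component.
#' @param negative_log_mean,negative_log_sd Log-scale parameters of the
#'   negative component.
#' @return An `intensity_model` with per-marker parameter vectors.
#' @export
intensity_model <- function(positive_log_mean = log(100),
                            positive_log_sd = 0.35,
                            negative_log_mean = log(5),
                            negative_log_sd = 0.35) {
  mk <- mif_markers()
  expand <- function(v) {
    if (length(v) == 1) v <- stats::setNames(rep(v, length(mk)), mk)
    v[mk]
  }
  m <- structure(list(positive_log_mean = expand(positive_log_mean),
                      positive_log_sd = expand(positive_log_sd),
                      negative_log_mean = expand(negative_log_mean),
                      negative_log_sd = expand(negative_log_sd)),
                 class = "intensity_model")
  if (any(m$positive_log_mean <= m$negative_log_mean)) {
    stop("positive_log_mean must exceed negative_log_mean for every marker",
         call. = FALSE)
  }
  m
}

#' Default per-marker gating thresholds from an intensity model
#'
#' Midpoint of the positive and negative components in log space.
#'
#' @param model An [intensity_model()].
#' @return Named numeric vector of intensity thresholds.
#' @export
midpoint_thresholds <- function(model = intensity_model()) {
  exp((model$positive_log_mean + model$negative_log_mean) / 2)
}

#' Full generative description of a synthetic scene
#'
#' @param roi_width,roi_height ROI dimensions (um), > 0.
#' @param regions List of [region_spec()] lying inside the ROI. Regions with
#'   different `niche_id` must not overlap (shared edges are allowed).
#' @param attraction List of [attraction_pair()].
#' @param margin Optional [margin_spec()]; the band must lie inside the ROI.
#' @param intensity An [intensity_model()].
#' @param ki67_rates,gzmb_rates Optional named per-phenotype probabilities of
#'   carrying the Ki67 / Granzyme B functional flag (scene-wide).
#' @param seed Integer seed; a scene spec fully determines its cell table.
#' @param case_id,group Labels carried into the generated table.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(roi_width, roi_height, regions,
                       attraction = list(), margin = NULL,
                       intensity = intensity_model(),
                       ki67_rates = NULL, gzmb_rates = NULL,
                       seed = 1L, case_id = "synthetic", group = NA) {
  if (!(roi_width > 0 && roi_height > 0)) {
    stop("ROI dimensions must be positive (empty ROI)", call. = FALSE)
  }
  if (inherits(regions, "region_spec")) regions <- list(regions)
  if (inherits(attraction, "attraction_pair")) attraction <- list(attraction)
  stopifnot(all(vapply(regions, inherits, TRUE, "region_spec")),
            all(vapply(attraction, inherits, TRUE, "attraction_pair")))
  for (r in regions) {
    bb <- geometry_bbox(r$geometry)
    if (bb[1] < -1e-9 || bb[2] < -1e-9 ||
        bb[3] > roi_width + 1e-9 || bb[4] > roi_height + 1e-9) {
      stop("region extends outside the ROI", call. = FALSE)
    }
  }
  if (length(regions) > 1) {
    for (i in seq_len(length(regions) - 1)) {
      for (j in seq(i + 1, length(regions))) {
        if (regions[[i]]$niche_id != regions[[j]]$niche_id &&
            geometries_overlap(regions[[i]]$geometry,
                               regions[[j]]$geometry)) {
          stop("regions with conflicting niche_ids overlap (",
               regions[[i]]$niche_id, " vs ", regions[[j]]$niche_id, ")",
               call. = FALSE)
        }
      }
    }
  }
  if (!is.null(margin)) {
    stopifnot(inherits(margin, "margin_spec"))
    lim <- if (margin$band_axis == "x") roi_width else roi_height
    if (margin$band_center - margin$band_halfwidth < -1e-9 ||
        margin$band_center + margin$band_halfwidth > lim + 1e-9) {
      stop("margin band lies outside the ROI", call. = FALSE)
    }
  }
  stopifnot(inherits(intensity, "intensity_model"))
  check_rates <- function(r, what) {
    if (is.null(r)) return(invisible())
    if (is.null(names(r)) || !all(names(r) %in% mif_phenotypes()) ||
        any(r < 0) || any(r > 1)) {
      stop(what, " must be named per-phenotype probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  check_rates(ki67_rates, "ki67_rates")
  check_rates(gzmb_rates, "gzmb_rates")
  structure(list(roi_width = roi_width, roi_height = roi_height,
                 regions = regions, attraction = attraction, margin = margin,
                 intensity = intensity, ki67_rates = ki67_rates,
                 gzmb_rates = gzmb_rates, seed = as.integer(seed),
                 case_id = as.character(case_id),
                 group = as.character(group)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> case ", x$case_id,
      sprintf(" | ROI %.0f x %.0f um | %d region(s), %d attraction pair(s)",
              x$roi_width, x$roi_height,
              length(x$regions), length(x$attraction)),
      if (!is.null(x$margin)) " | margin band" else "",
      " | seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Expected ROI-wide phenotype density of a scene spec
#'
#' Closed-form expectation (per mm^2 over the whole ROI) of the density of
#' a phenotype under the spec: sum over regions of density x mixture
#' probability x region area, plus margin-band contributions, divided by
#' ROI area. Attraction pairs relocate cells and do not change counts.
#'
#' @param spec A [scene_spec()].
#' @param phenotype A label from [mif_phenotypes()].
#' @return Expected cells per mm^2.
#' @export
expected_density <- function(spec, phenotype) {
  roi_mm2 <- spec$roi_width * spec$roi_height / 1e6
  n <- 0
  for (r in spec$regions) {
    p <- if (phenotype %in% names(r$mixture)) r$mixture[[phenotype]] else 0
    n <- n + r$density * geometry_area_mm2(r$geometry) * p
  }
  if (!is.null(spec$margin)) {
    other_dim <- if (spec$margin$band_axis == "x") spec$roi_height
                 else spec$roi_width
    band_mm2 <- 2 * spec$margin$band_halfwidth * other_dim / 1e6
    if (phenotype == "T_other") n <- n + spec$margin$pd1_t_density * band_mm2
    if (phenotype == "Other") n <- n + spec$margin$pdl1_tumor_density * band_mm2
  }
  n / roi_mm2
}

#' Write a scene spec as a YAML config
#'
#' @param spec A [scene_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  as_plain <- function(x) {
    if (inherits(x, c("mif_geometry", "region_spec", "margin_spec",
                      "attraction_pair", "intensity_model"))) {
      lapply(unclass(x), as_plain)
    } else if (is.list(x)) {
      lapply(x, as_plain)
    } else x
  }
  lst <- as_plain(unclass(spec))
  lst$intensity <- lapply(spec$intensity, as.list)
  if (!is.null(spec$ki67_rates)) lst$ki67_rates <- as.list(spec$ki67_rates)
  if (!is.null(spec$gzmb_rates)) lst$gzmb_rates <- as.list(spec$gzmb_rates)
  for (k in seq_along(lst$regions)) {
    lst$regions[[k]]$mixture <- as.list(spec$regions[[k]]$mixture)
  }
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' Read a scene spec from a YAML config
#'
#' @param path File written by [write_scene_spec()].
#' @return A [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  geom <- function(g) {
    if (g$type == "rect") region_rect(g$x0, g$y0, g$width, g$height)
    else region_disc(g$cx, g$cy, g$r)
  }
  regions <- lapply(lst$regions, function(r) {
    region_spec(geom(r$geometry), r$density, unlist(r$mixture), r$niche_id)
  })
  attraction <- lapply(lst$attraction, function(a) {
    attraction_pair(a$a, a$b, a$radius, a$fraction)
  })
  margin <- if (!is.null(lst$margin)) {
    margin_spec(lst$margin$band_axis, lst$margin$band_center,
                lst$margin$band_halfwidth, lst$margin$pd1_t_density,
                lst$margin$pdl1_tumor_density, lst$margin$niche_id)
  }
  intensity <- intensity_model(unlist(lst$intensity$positive_log_mean),
                               unlist(lst$intensity$positive_log_sd),
                               unlist(lst$intensity$negative_log_mean),
                               unlist(lst$intensity$negative_log_sd))
  scene_spec(lst$roi_width, lst$roi_height, regions,
             attraction = attraction, margin = margin, intensity = intensity,
             ki67_rates = unlist(lst$ki67_rates),
             gzmb_rates = unlist(lst$gzmb_rates),
             seed = lst$seed, case_id = lst$case_id, group = lst$group)
}
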