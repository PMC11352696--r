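#' Locate the maximum-density window of a case
#'
#' Slides a square window of side `window_side` over the bounding box of
#' the cells on a regular anchor grid of step `stride` and returns the
#' window holding the most reference cells. Window membership is half-open
#' (`[x0, x0+side) x [y0, y0+side)`), so tiling windows never double-count.
#' Ties are broken by the smallest anchor (y first, then x). When the
#' bounding box is smaller than the window the whole bounding box is used,
#' with a warning.
#'
#' @param table A nonempty [cell_table()].
#' @param window_side Window side (um). Default 500 (0.25 mm^2).
#' @param stride Anchor grid step (um).
#' @param reference "all" to rank windows by total cell count, or a
#'   phenotype label to rank by that phenotype only (requires gating).
#' @return List with `x0`, `y0`, `side`, `count` (class `hotspot_window`).
#' @export
find_hotspot <- function(table, window_side = 500, stride = 250,
                         reference = "all") {
  if (!nrow(table)) stop("cannot locate a hotspot in an empty table",
                         call. = FALSE)
  stopifnot(window_side > 0, stride > 0)
  if (reference != "all") {
    if (!"phenotype" %in% names(table)) {
      stop("phenotype reference requires a gated table", call. = FALSE)
    }
    keep <- table$phenotype == reference
  } else {
    keep <- rep(TRUE, nrow(table))
  }
  rx <- table$x[keep]; ry <- table$y[keep]
  xmin <- min(table$x); xmax <- max(table$x)
  ymin <- min(table$y); ymax <- max(table$y)

  if (xmax - xmin < window_side || ymax - ymin < window_side) {
    warning("bounding box smaller than the window; using the whole box")
    win <- structure(list(x0 = xmin, y0 = ymin,
                          side = max(xmax - xmin, ymax - ymin, window_side),
                          count = length(rx)),
                     class = "hotspot_window")
    return(win)
  }
  ax <- seq(xmin, xmax - window_side, by = stride)
  ay <- seq(ymin, ymax - window_side, by = stride)
  best <- c(count = -1, x0 = NA, y0 = NA)
  for (y0 in ay) {          # y outer, ascending: ties keep smallest (y, x)
    iny <- ry >= y0 & ry < y0 + window_side
    for (x0 in ax) {
      cnt <- sum(iny & rx >= x0 & rx < x0 + window_side)
      if (cnt > best["count"]) best <- c(count = cnt, x0 = x0, y0 = y0)
    }
  }
  structure(list(x0 = unname(best["x0"]), y0 = unname(best["y0"]),
                 side = window_side, count = unname(best["count"])),
            class = "hotspot_window")
}

#' @export
print.hotspot_window <- function(x, ...) {
  cat(sprintf("<hotspot_window> [%.1f, %.1f) x [%.1f, %.1f) um, %d cells\n",
              x$x0, x$x0 + x$side, x$y0, x$y0 + x$side, x$count))
  invisible(x)
}

#' Per-phenotype densities within a window
#'
#' Counts each phenotype with centroid inside the half-open window and
#' divides by the window area in mm^2, the per-case quantity used for
#' group comparisons.
#'
#' @param table A gated [cell_table()].
#' @param window A `hotspot_window` from [find_hotspot()].
#' @return A `density_report`: list with `case_id`, `group`, `window`,
#'   `window_area_mm2` and `densities` (named cells per mm^2 over
#'   [mif_phenotypes()]).
#' @export
hotspot_densities <- function(table, window) {
  if (!"phenotype" %in% names(table)) {
    stop("hotspot_densities requires a gated table", call. = FALSE)
  }
  if (window$side <= 0) stop("zero-area window", call. = FALSE)
  inside <- table$x >= window$x0 & table$x < window$x0 + window$side &
            table$y >= window$y0 & table$y < window$y0 + window$side
  area <- window$side^2 / 1e6
  counts <- table(factor(table$phenotype[inside], levels = mif_phenotypes()))
  structure(list(case_id = if (nrow(table)) table$case_id[1] else NA,
                 group = if (nrow(table)) table$group[1] else NA,
                 window = window, window_area_mm2 = area,
                 densities = stats::setNames(as.numeric(counts) / area,
                                             names(counts))),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat("<density_report> case ", x$case_id,
      sprintf(" | window %.2f mm^2\n", x$window_area_mm2), sep = "")
  d <- x$densities[x$densities > 0]
  print(round(d[order(-d)], 1))
  invisible(x)
}

#' Compare hotspot densities between groups
#'
#' Two-factor (group x phenotype) analysis of per-case hotspot densities:
#' an ANOVA linear model `density ~ group * phenotype` supplies the pooled
#' residual variance, and every pairwise group contrast is tested within
#' each phenotype, with Sidak family adjustment across all contrasts.
#' Because case numbers per group are tiny in studies of rare tumors, a
#' rank-based per-phenotype fallback (Wilcoxon rank-sum, same adjustment)
#' is reported alongside, as are per-group medians and ranges.
#'
#' @param reports List of `density_report`s (one per case).
#' @param groups Optional named character vector mapping case_id to group;
#'   defaults to the group labels carried by the reports.
#' @param phenotypes Phenotypes to compare. Defaults to the four headline
#'   immune populations (Th, CTL, B, Mac).
#' @return A `group_stats` object: `comparisons` data.frame (phenotype,
#'   group pair, estimated difference, t, p, p_adj, p_rank, p_rank_adj),
#'   `summaries` data.frame of per-group medians/ranges, `densities` long
#'   data.frame, and the adjustment method name.
#' @export
group_stats <- function(reports, groups = NULL,
                        phenotypes = c("Th", "CTL", "B", "Mac")) {
  stopifnot(length(reports) >= 2)
  cases <- unname(vapply(reports, `[[`, "", "case_id"))
  if (is.null(groups)) {
    groups <- stats::setNames(vapply(reports, `[[`, "", "group"), cases)
  }
  grp <- unname(groups[cases])
  if (anyNA(grp)) stop("every case needs a group label", call. = FALSE)
  glev <- unique(grp)
  if (length(glev) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(grp) < 1)) stop("a group has zero cases", call. = FALSE)

  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(case_id = cases[i], group = grp[i],
               phenotype = phenotypes,
               density = unname(reports[[i]]$densities[phenotypes]),
               stringsAsFactors = FALSE)
  }))
  long$group <- factor(long$group, levels = glev)
  long$phenotype <- factor(long$phenotype, levels = phenotypes)

  fit <- stats::aov(density ~ group * phenotype, data = long)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  dfres <- stats::df.residual(fit)

  pairs <- utils::combn(glev, 2, simplify = FALSE)
  rows <- list()
  for (ph in phenotypes) {
    for (pr in pairs) {
      da <- long$density[long$phenotype == ph & long$group == pr[1]]
      db <- long$density[long$phenotype == ph & long$group == pr[2]]
      diff <- mean(db) - mean(da)
      se <- if (dfres > 0 && is.finite(mse)) {
        sqrt(mse * (1 / length(da) + 1 / length(db)))
      } else NA_real_
      tval <- if (is.na(se)) NA_real_ else if (se > 0) diff / se else 0
      p <- if (dfres > 0 && !is.na(tval)) 2 * stats::pt(-abs(tval), dfres)
           else NA_real_
      prank <- suppressWarnings(
        stats::wilcox.test(da, db, exact = TRUE)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = ph, group_a = pr[1], group_b = pr[2],
        difference = diff, t = tval, p = p, p_rank = prank,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  m <- nrow(comparisons)
  # -expm1(m*log1p(-p)) == 1-(1-p)^m without underflow at tiny p
  sidak <- function(p) pmin(1, -expm1(m * log1p(-p)))
  comparisons$p_adj <- sidak(comparisons$p)
  comparisons$p_rank_adj <- sidak(comparisons$p_rank)

  summaries <- do.call(rbind, lapply(phenotypes, function(ph) {
    do.call(rbind, lapply(glev, function(g) {
      v <- long$density[long$phenotype == ph & long$group == g]
      data.frame(phenotype = ph, group = g, n = length(v),
                 median = stats::median(v), min = min(v), max = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(comparisons = comparisons, summaries = summaries,
                 densities = long, adjustment = "sidak",
                 anova = summary(fit)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, digits = 4, ...) {
  cat("Two-factor (group x phenotype) hotspot-density comparison\n")
  cat("Adjustment:", x$adjustment, "over", nrow(x$comparisons),
      "contrasts\n\n")
  df <- x$comparisons
  df$difference <- signif(df$difference, digits)
  df$t <- signif(df$t, digits)
  for (co in c("p", "p_adj", "p_rank", "p_rank_adj")) {
    df[[co]] <- signif(df[[co]], digits)
  }
  print(df, row.names = FALSE)
  cat("\nPer-group medians (range):\n")
  s <- x$summaries
  s$summary <- sprintf("%.1f (%.1f-%.1f)", s$median, s$min, s$max)
  print(s[, c("phenotype", "group", "n", "summary")], row.names = FALSE)
  invisible(x)
}
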