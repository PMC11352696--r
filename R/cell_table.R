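#' Construct a segmented-cell table
#'
#' The canonical per-cell container used by every stage: one row per
#' segmented cell with its centroid (micrometres, image convention: origin
#' top-left, y increasing downward), mean intensity per panel marker
#' (arbitrary units), and, once gated, an exclusive `phenotype` plus logical
#' functional-flag columns (`PD1_pos`, `PDL1_pos`, `Ki67_pos`, `GzmB_pos`).
#'
#' @param df data.frame with columns `cell_id`, `x`, `y` and one numeric
#'   column per marker in [mif_markers()].
#' @param case_id Case identifier shared by all cells of the table.
#' @param group Group label of the case (e.g. "LG-ESS", "HG-ESS", "SDUS").
#' @return A `cell_table` (data.frame subclass).
#' @export
cell_table <- function(df, case_id = "case1", group = NA_character_) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$case_id <- rep(as.character(case_id), length.out = nrow(df))
  df$group <- rep(as.character(group), length.out = nrow(df))
  class(df) <- c("cell_table", "data.frame")
  validate_cell_table(df)
  df
}

#' Validate a cell table's invariants
#'
#' Checks unique cell ids, finite coordinates, nonnegative intensities and
#' a single case id. Called by constructors and readers; exported so users
#' can re-check after manual edits.
#'
#' @param table A `cell_table`.
#' @return The table, invisibly; errors describe the first violation found.
#' @export
validate_cell_table <- function(table) {
  need <- c("cell_id", "x", "y")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$cell_id)) {
    stop("duplicate cell_id: ",
         table$cell_id[anyDuplicated(table$cell_id)], call. = FALSE)
  }
  if (nrow(table) && (!all(is.finite(table$x)) || !all(is.finite(table$y)))) {
    stop("non-finite cell coordinates", call. = FALSE)
  }
  for (m in intersect(mif_markers(), names(table))) {
    v <- table[[m]]
    if (!is.numeric(v)) stop("marker column ", m, " is not numeric",
                             call. = FALSE)
    if (nrow(table) && (anyNA(v) || any(v < 0))) {
      stop("marker column ", m, " has missing or negative intensities",
           call. = FALSE)
    }
  }
  if (length(unique(table$case_id)) > 1) {
    stop("a cell table must hold a single case_id", call. = FALSE)
  }
  invisible(table)
}

markers_in <- function(table) intersect(mif_markers(), names(table))

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x), " cells, case ",
      if (nrow(x)) x$case_id[1] else "<empty>", sep = "")
  if (nrow(x) && !is.na(x$group[1])) cat(" (", x$group[1], ")", sep = "")
  cat("\n  markers: ", paste(markers_in(x), collapse = ", "), "\n", sep = "")
  if ("phenotype" %in% names(x)) {
    tab <- sort(table(x$phenotype), decreasing = TRUE)
    cat("  phenotypes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cell_table <- function(object, ...) {
  out <- list(
    n = nrow(object),
    case_id = if (nrow(object)) object$case_id[1] else NA_character_,
    group = if (nrow(object)) object$group[1] else NA_character_,
    bbox = if (nrow(object)) {
      c(xmin = min(object$x), xmax = max(object$x),
        ymin = min(object$y), ymax = max(object$y))
    } else NULL,
    phenotypes = if ("phenotype" %in% names(object)) {
      table(factor(object$phenotype, levels = mif_phenotypes()))
    } else NULL
  )
  class(out) <- "summary.cell_table"
  out
}

#' @export
print.summary.cell_table <- function(x, ...) {
  cat("Cell table: ", x$n, " cells, case ", x$case_id, sep = "")
  if (!is.na(x$group)) cat(" (", x$group, ")", sep = "")
  cat("\n")
  if (!is.null(x$bbox)) {
    cat(sprintf("  extent: x [%.1f, %.1f] um, y [%.1f, %.1f] um\n",
                x$bbox["xmin"], x$bbox["xmax"],
                x$bbox["ymin"], x$bbox["ymax"]))
  }
  if (!is.null(x$phenotypes)) {
    cat("  phenotype counts:\n")
    print(x$phenotypes)
  }
  invisible(x)
}

#' Plot cell centroids coloured by phenotype
#'
#' Quick QC scatter in image orientation (y axis flipped).
#'
#' @param x A gated `cell_table`.
#' @param cex Point size.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cell_table <- function(x, cex = 0.3, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    graphics::title(main = "empty cell table")
    return(invisible(x))
  }
  phen <- if ("phenotype" %in% names(x)) x$phenotype else rep("Other", nrow(x))
  lev <- intersect(mif_phenotypes(), unique(phen))
  cols <- grDevices::hcl.colors(max(length(lev), 2L), "Dark 3")[seq_along(lev)]
  graphics::plot(x$x, x$y, col = cols[match(phen, lev)], pch = 16, cex = cex,
                 xlab = "x (um)", ylab = "y (um)", ylim = rev(range(x$y)),
                 asp = 1, ...)
  graphics::legend("topright", legend = lev, col = cols, pch = 16,
                   cex = 0.7, bg = "white")
  invisible(x)
}
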