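#' Read a segmented-cell table
#'
#' Reads CSV/TSV exports of per-cell measurements into the canonical
#' [cell_table()]. Two column dialects are built in: `"generic"`
#' (`cell_id`/`id`, `x`, `y`, one column per marker) and `"qupath"`
#' (QuPath measurement export: `Object ID`, `Centroid X um`,
#' `Centroid Y um`, and `"<marker>: Cell: Mean"` intensity columns).
#' Micro-sign variants in headers are normalised, UTF-8 BOMs tolerated,
#' and the delimiter is sniffed from the header line. Unknown columns are
#' preserved as passthrough metadata and row order is kept.
#'
#' @param path CSV/TSV file.
#' @param dialect "generic" or "qupath".
#' @param marker_map Optional named character vector mapping file column
#'   names to canonical names (`x`, `y`, `cell_id` or a marker from
#'   [mif_markers()]); entries override the dialect defaults. Use this to
#'   state explicitly which QuPath intensity statistic feeds gating.
#' @param case_id,group Used when the file carries no `case_id`/`group`
#'   column; `case_id` defaults to the file name.
#' @param scale Factor applied to coordinates (e.g. pixel size in um for
#'   pixel-based exports); internal units are always micrometres.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, dialect = c("generic", "qupath"),
                            marker_map = NULL, case_id = NULL,
                            group = NA, scale = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- sub("^\ufeff", "", readLines(path, n = 1L, warn = FALSE))
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8-BOM", quote = "\"",
                          comment.char = "")
  names(df) <- gsub("\u00b5", "u", names(df))

  default_map <- if (dialect == "qupath") {
    c("Object ID" = "cell_id", "Centroid X um" = "x", "Centroid Y um" = "y",
      stats::setNames(mif_markers(), paste0(mif_markers(), ": Cell: Mean")))
  } else {
    c(id = "cell_id")
  }
  map <- c(marker_map, default_map)
  map <- map[!duplicated(names(map))]           # user entries win
  hit <- names(map) %in% names(df)
  names(df)[match(names(map)[hit], names(df))] <- map[hit]

  for (co in c("x", "y")) {
    if (!co %in% names(df)) {
      stop("missing coordinate column \"", co, "\" (after dialect mapping)",
           call. = FALSE)
    }
    df[[co]] <- as.numeric(df[[co]]) * scale
  }
  if (!"cell_id" %in% names(df)) {
    df$cell_id <- if (nrow(df)) sprintf("c%06d", seq_len(nrow(df)))
                  else character(0)
  }
  for (m in intersect(mif_markers(), names(df))) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("non-numeric intensity in column ", m, " at row ", bad[1],
             call. = FALSE)
      }
      df[[m]] <- num
    }
  }
  for (fc in intersect(flag_cols(), names(df))) {
    if (!is.logical(df[[fc]])) {
      df[[fc]] <- as.logical(as.numeric(df[[fc]]))
    }
  }
  if (nrow(df) == 0) warning("empty cell table read from ", path)

  cid <- if ("case_id" %in% names(df) && nrow(df)) df$case_id[1]
         else if (!is.null(case_id)) case_id
         else sub("\\.[^.]*$", "", basename(path))
  grp <- if ("group" %in% names(df) && nrow(df)) df$group[1] else group
  cell_table(df, case_id = cid, group = grp)
}

#' Write a segmented-cell table
#'
#' Inverse of [read_cell_table()]: emits CSV (or TSV for a `.tsv` path) in
#' the generic or QuPath column dialect. Functional flags are serialised as
#' 0/1 columns; ground-truth and other passthrough columns are kept, so
#' `read_cell_table(write_cell_table(t))` round-trips.
#'
#' @param table A [cell_table()].
#' @param path Output file.
#' @param dialect "generic" or "qupath".
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, dialect = c("generic", "qupath")) {
  dialect <- match.arg(dialect)
  validate_cell_table(table)
  df <- as.data.frame(table)
  for (fc in intersect(flag_cols(), names(df))) {
    df[[fc]] <- as.integer(df[[fc]])
  }
  if (dialect == "qupath") {
    ren <- c(cell_id = "Object ID", x = "Centroid X \u00b5m",
             y = "Centroid Y \u00b5m",
             stats::setNames(paste0(mif_markers(), ": Cell: Mean"),
                             mif_markers()))
    hit <- names(ren) %in% names(df)
    names(df)[match(names(ren)[hit], names(df))] <- ren[hit]
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}
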