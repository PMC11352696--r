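#' Ordered marker-threshold gating configuration
#'
#' Encodes how marker intensities are turned into cell labels: per-marker
#' intensity thresholds (a cell is positive for marker m iff
#' intensity >= threshold, closed so boundary cells count as positive),
#' an ordered list of exclusive lineage rules (the first rule whose
#' positive/negative marker pattern is satisfied assigns the phenotype;
#' no match gives the fallback "Other"), and independent non-exclusive
#' functional-flag rules.
#'
#' @param thresholds Named nonnegative numeric vector, one per marker
#'   referenced by any rule.
#' @param exclusive_rules Ordered list of
#'   `list(phenotype =, pos = <markers>, neg = <markers>)`.
#' @param functional_rules List of `list(flag =, pos = <markers>)`.
#' @return A `gating_config`.
#' @export
gating_config <- function(thresholds, exclusive_rules, functional_rules) {
  referenced <- unique(unlist(c(
    lapply(exclusive_rules, function(r) c(r$pos, r$neg)),
    lapply(functional_rules, function(r) r$pos))))
  miss <- setdiff(referenced, names(thresholds))
  if (length(miss)) {
    stop("no threshold for rule marker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(thresholds < 0)) stop("thresholds must be nonnegative",
                                call. = FALSE)
  structure(list(thresholds = thresholds,
                 exclusive_rules = exclusive_rules,
                 functional_rules = functional_rules),
            class = "gating_config")
}

#' Default gating configuration
#'
#' Lineage rules in the package's fixed precedence order —
#' CTL (CD3+CD8+) > Th (CD3+CD4+CD8-) > T_other (CD3+) > B (CD20+CD3-) >
#' Mac (CD68+CD3-CD20-) > Myeloid (CD14+CD68-CD3-CD20-) >
#' Endothelial (CD31+) > Fibroblast (FAP+) > SmoothMuscle (aSMA+) > Other —
#' plus the four functional flags (PD-1, PD-L1, Ki67, Granzyme B).
#' Thresholds default to the log-space midpoints of the synthetic
#' [intensity_model()]; real-data use should supply measured per-marker
#' thresholds instead.
#'
#' @param thresholds Named per-marker thresholds; defaults to
#'   [midpoint_thresholds()].
#' @return A [gating_config()].
#' @export
default_gating_config <- function(thresholds = midpoint_thresholds()) {
  rules <- list(
    list(phenotype = "CTL", pos = c("CD3", "CD8"), neg = character(0)),
    list(phenotype = "Th", pos = c("CD3", "CD4"), neg = "CD8"),
    list(phenotype = "T_other", pos = "CD3", neg = character(0)),
    list(phenotype = "B", pos = "CD20", neg = "CD3"),
    list(phenotype = "Mac", pos = "CD68", neg = c("CD3", "CD20")),
    list(phenotype = "Myeloid", pos = "CD14",
         neg = c("CD68", "CD3", "CD20")),
    list(phenotype = "Endothelial", pos = "CD31", neg = character(0)),
    list(phenotype = "Fibroblast", pos = "FAP", neg = character(0)),
    list(phenotype = "SmoothMuscle", pos = "aSMA", neg = character(0)))
  flags <- list(
    list(flag = "PD1", pos = "PD1"),
    list(flag = "PDL1", pos = "PDL1"),
    list(flag = "Ki67", pos = "Ki67"),
    list(flag = "GzmB", pos = "GzmB"))
  gating_config(thresholds, rules, flags)
}

#' @export
print.gating_config <- function(x, ...) {
  cat("<gating_config> precedence:",
      paste(vapply(x$exclusive_rules, `[[`, "", "phenotype"),
            collapse = " > "),
      "> Other\n")
  cat("  flags:", paste(vapply(x$functional_rules, `[[`, "", "flag"),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Assign exclusive phenotypes and functional flags
#'
#' Applies a [gating_config()] to a cell table: marker positivity is
#' intensity >= threshold (closed); the first exclusive rule in precedence
#' order whose pattern matches assigns the phenotype, unmatched cells
#' become "Other"; functional flags are assigned independently and
#' non-exclusively as `<flag>_pos` logical columns.
#'
#' @param table A [cell_table()] carrying all markers referenced by rules.
#' @param config A [gating_config()].
#' @return The table with `phenotype` and flag columns filled.
#' @export
gate_cells <- function(table, config = default_gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  referenced <- unique(unlist(c(
    lapply(config$exclusive_rules, function(r) c(r$pos, r$neg)),
    lapply(config$functional_rules, function(r) r$pos))))
  miss <- setdiff(referenced, names(table))
  if (length(miss)) {
    stop("table lacks marker column(s) required by gating rules: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  noth <- setdiff(referenced, names(config$thresholds))
  if (length(noth)) {
    stop("no threshold for rule marker(s): ",
         paste(noth, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  posmat <- vapply(referenced,
                   function(m) table[[m]] >= config$thresholds[[m]],
                   logical(n))
  if (n == 1) posmat <- matrix(posmat, nrow = 1,
                               dimnames = list(NULL, referenced))
  phenotype <- rep("Other", n)
  unassigned <- rep(TRUE, n)
  for (r in config$exclusive_rules) {
    hit <- unassigned
    for (m in r$pos) hit <- hit & posmat[, m]
    for (m in r$neg) hit <- hit & !posmat[, m]
    phenotype[hit] <- r$phenotype
    unassigned <- unassigned & !hit
  }
  table$phenotype <- phenotype
  for (r in config$functional_rules) {
    on <- rep(TRUE, n)
    for (m in r$pos) on <- on & posmat[, m]
    table[[paste0(r$flag, "_pos")]] <- on
  }
  table
}

#' Phenotype composition of proliferating cells
#'
#' Among Ki67+ cells, the fraction contributed by each exclusive phenotype
#' (fractions sum to 1 across phenotypes including "Other").
#'
#' @param table A gated [cell_table()] with a `Ki67_pos` column.
#' @return Named numeric vector of fractions over [mif_phenotypes()];
#'   empty (with a warning) when no cell is Ki67+.
#' @export
proliferation_composition <- function(table) {
  if (!all(c("phenotype", "Ki67_pos") %in% names(table))) {
    stop("table must be gated (phenotype and Ki67_pos columns) first",
         call. = FALSE)
  }
  prolif <- table$phenotype[table$Ki67_pos]
  if (!length(prolif)) {
    warning("no Ki67+ cells; empty proliferation composition")
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(factor(prolif, levels = mif_phenotypes()))
  out <- as.numeric(tab) / length(prolif)
  stats::setNames(out, names(tab))
}
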