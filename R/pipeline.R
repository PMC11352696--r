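#' Configuration of an end-to-end TiME run
#'
#' Bundles every stage's parameters with the inputs (synthetic scene specs
#' and/or cell-table files) and a single global seed from which all stage
#' seeds are derived ([derive_seed()]), so adding a case never perturbs the
#' results of the others.
#'
#' @param scenes Named list of [scene_spec()]s to simulate.
#' @param inputs Named character vector of cell-table files to read
#'   (names become case ids).
#' @param gating A [gating_config()].
#' @param window_side,stride,reference Hotspot parameters
#'   ([find_hotspot()]).
#' @param radius Interaction radius (um).
#' @param n_perm Permutations for [interaction_enrichment()].
#' @param niche_mode,k_nn,niche_radius,niche_k,n_init Niche parameters
#'   ([neighborhood_profiles()], [cluster_niches()]).
#' @param pool_map Optional named vector collapsing groups for a second,
#'   pooled group comparison (default merges LG-ESS and HG-ESS into "ESS").
#' @param stat_phenotypes Phenotypes entering [group_stats()].
#' @param outdir Output directory (created if missing).
#' @param seed Global integer seed.
#' @return A `run_config`.
#' @export
run_config <- function(scenes = list(), inputs = character(0),
                       gating = default_gating_config(),
                       window_side = 500, stride = 250, reference = "all",
                       radius = 15, n_perm = 500,
                       niche_mode = "knn", k_nn = 20, niche_radius = 50,
                       niche_k = 6, n_init = 10,
                       pool_map = c("LG-ESS" = "ESS", "HG-ESS" = "ESS"),
                       stat_phenotypes = c("Th", "CTL", "B", "Mac"),
                       outdir = tempfile("mifscape_run_"), seed = 1L) {
  stopifnot(all(vapply(scenes, inherits, TRUE, "scene_spec")),
            inherits(gating, "gating_config"))
  if (length(scenes) + length(inputs) == 0) {
    stop("run_config needs at least one scene spec or input file",
         call. = FALSE)
  }
  structure(list(scenes = scenes, inputs = inputs, gating = gating,
                 window_side = window_side, stride = stride,
                 reference = reference, radius = radius, n_perm = n_perm,
                 niche_mode = niche_mode, k_nn = k_nn,
                 niche_radius = niche_radius, niche_k = niche_k,
                 n_init = n_init, pool_map = pool_map,
                 stat_phenotypes = stat_phenotypes,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

stage_try <- function(stage, case, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ", case ", case, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full spatial TiME pipeline
#'
#' simulate/ingest -> gate -> hotspot densities -> proximity-graph
#' interaction enrichment -> pooled niche clustering -> group statistics,
#' writing per-case gated tables, a case x phenotype density matrix,
#' interaction matrices, niche outputs and one JSON summary into the
#' config's output directory. Identical configs produce byte-identical
#' numeric outputs. Any stage error aborts with the stage name and case id.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `mif_bundle` with all stage results, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[mifscape] ", ...)

  tables <- list()
  for (id in names(config$scenes)) {
    say("simulate | ", id)
    tables[[id]] <- stage_try("simulate", id,
                              generate_scene(config$scenes[[id]]))
  }
  for (k in seq_along(config$inputs)) {
    id <- names(config$inputs)[k]
    if (is.null(id) || !nzchar(id)) id <- basename(config$inputs[[k]])
    say("ingest | ", id)
    tables[[id]] <- stage_try("ingest", id,
                              read_cell_table(config$inputs[[k]],
                                              case_id = id))
  }

  reports <- list()
  interactions <- list()
  profiles <- list()
  for (id in names(tables)) {
    say("gate | ", id)
    tables[[id]] <- stage_try("gate", id,
                              gate_cells(tables[[id]], config$gating))
    write_cell_table(tables[[id]],
                     file.path(config$outdir, paste0(id, "_gated.csv")))

    say("density | ", id)
    reports[[id]] <- stage_try("density", id, {
      win <- find_hotspot(tables[[id]], config$window_side, config$stride,
                          config$reference)
      hotspot_densities(tables[[id]], win)
    })

    say("interact | ", id)
    interactions[[id]] <- stage_try("interact", id, {
      g <- build_proximity_graph(tables[[id]], config$radius)
      interaction_enrichment(g, tables[[id]], n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "interact", id))
    })
    utils::write.csv(interactions[[id]]$z,
                     file.path(config$outdir, paste0(id, "_interaction_z.csv")))

    say("niche profiles | ", id)
    profiles[[id]] <- stage_try("niche", id,
      neighborhood_profiles(tables[[id]], mode = config$niche_mode,
                            k_nn = config$k_nn,
                            radius = config$niche_radius))
  }

  dens_mat <- t(vapply(reports, function(r) r$densities,
                       numeric(length(mif_phenotypes()))))
  utils::write.csv(dens_mat, file.path(config$outdir, "densities.csv"))

  stats_subtype <- stats_pooled <- NULL
  groups <- vapply(tables, function(t) t$group[1], "")
  if (length(unique(groups[!is.na(groups)])) >= 2) {
    say("group stats")
    stats_subtype <- stage_try("group_stats", "(all)",
      group_stats(reports, phenotypes = config$stat_phenotypes))
    pooled <- ifelse(groups %in% names(config$pool_map),
                     config$pool_map[groups], groups)
    if (length(unique(pooled)) >= 2 && !identical(pooled, unname(groups))) {
      stats_pooled <- stage_try("group_stats", "(pooled)",
        group_stats(reports,
                    groups = stats::setNames(pooled, names(tables)),
                    phenotypes = config$stat_phenotypes))
    }
  }

  say("niche clustering (pooled, k = ", config$niche_k, ")")
  model <- stage_try("niche", "(pooled)", {
    cluster_niches(pool_profiles(profiles), k = config$niche_k,
                   seed = derive_seed(config$seed, "niche"),
                   n_init = config$n_init)
  })
  nrep <- niche_report(model)
  utils::write.csv(nrep$composition,
                   file.path(config$outdir, "niche_composition.csv"))
  utils::write.csv(nrep$proportions,
                   file.path(config$outdir, "niche_proportions.csv"))

  summary <- list(
    seed = config$seed,
    params = list(window_side = config$window_side, stride = config$stride,
                  reference = config$reference, radius = config$radius,
                  n_perm = config$n_perm, niche_mode = config$niche_mode,
                  k_nn = config$k_nn, niche_k = config$niche_k,
                  adjustment = "sidak"),
    cases = lapply(names(tables), function(id) {
      r <- reports[[id]]
      list(case_id = id, group = groups[[id]], n_cells = nrow(tables[[id]]),
           hotspot = list(x0 = r$window$x0, y0 = r$window$y0,
                          side = r$window$side),
           densities = as.list(r$densities))
    }),
    group_stats = if (!is.null(stats_subtype)) stats_subtype$comparisons,
    group_stats_pooled = if (!is.null(stats_pooled)) stats_pooled$comparisons,
    interaction_z = lapply(interactions, function(ir) {
      list(levels = ir$levels, z = unname(apply(ir$z, 1, as.list)))
    }),
    niches = list(k = model$k, sizes = model$sizes,
                  composition = apply(nrep$composition, 1, as.list),
                  proportions = apply(nrep$proportions, 1, as.list),
                  predominant = as.list(nrep$predominant))
  )
  summary_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  bundle <- structure(list(tables = tables, reports = reports,
                           interactions = interactions,
                           niche_model = model, niche_report = nrep,
                           stats_subtype = stats_subtype,
                           stats_pooled = stats_pooled,
                           summary_path = summary_path,
                           outdir = config$outdir, config = config),
                      class = "mif_bundle")
  say("done | summary at ", summary_path)
  invisible(bundle)
}

#' @export
print.mif_bundle <- function(x, ...) {
  cat("<mif_bundle> ", length(x$tables), " case(s) in ", x$outdir, "\n",
      sep = "")
  for (id in names(x$tables)) {
    cat(sprintf("  %s: %d cells (%s)\n", id, nrow(x$tables[[id]]),
                x$tables[[id]]$group[1]))
  }
  invisible(x)
}

#' QC figures for a pipeline bundle
#'
#' Writes static PNGs — per-case phenotype scatter, interaction z heatmap
#' and niche map — next to the numeric outputs. Each figure is wrapped so
#' that a plotting failure warns and moves on; numeric outputs are never
#' touched.
#'
#' @param bundle A `mif_bundle`.
#' @param outdir Figure directory (defaults to the bundle's).
#' @return Character vector of files written, invisibly.
#' @export
qc_plots <- function(bundle, outdir = bundle$outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  draw <- function(file, expr) {
    tryCatch({
      grDevices::png(file, width = 1200, height = 1000, res = 150)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
      written <<- c(written, file)
    }, error = function(e) warning("qc plot failed (", file, "): ",
                                   conditionMessage(e)))
  }
  for (id in names(bundle$tables)) {
    tab <- bundle$tables[[id]]
    draw(file.path(outdir, paste0(id, "_cells.png")), {
      if (nrow(tab)) plot(tab, main = id) else {
        graphics::plot.new(); graphics::title(main = paste(id, "(empty)"))
      }
    })
    draw(file.path(outdir, paste0(id, "_interactions.png")),
         plot(bundle$interactions[[id]]))
    draw(file.path(outdir, paste0(id, "_niches.png")),
         plot(bundle$niche_model, tab, main = paste(id, "niches")))
  }
  invisible(written)
}
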