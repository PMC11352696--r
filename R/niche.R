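# k nearest neighbors (excluding self) via a uniform-grid index.
# Returns an n x k matrix of row indices ordered by (distance, row index),
# so ties at the k-th distance resolve by cell order. Equals brute force.
knn_grid <- function(x, y, k) {
  n <- length(x)
  if (n < k + 1) stop("need at least k+1 cells for k nearest neighbors",
                      call. = FALSE)
  w <- max(diff(range(x)), 1e-9)
  h <- max(diff(range(y)), 1e-9)
  cs <- max(sqrt(w * h * k / (pi * n)), 1e-9)
  kx <- floor(x / cs); kx <- kx - min(kx)
  ky <- floor(y / cs); ky <- ky - min(ky)
  nx <- max(kx) + 1L; ny <- max(ky) + 1L
  key <- kx + ky * nx
  buckets <- split(seq_len(n), key)
  pos <- stats::setNames(seq_along(buckets), names(buckets))
  nn <- matrix(NA_integer_, n, k)
  for (b in seq_along(buckets)) {
    I <- buckets[[b]]
    bk <- as.numeric(names(buckets)[b])
    bx <- bk %% nx; by <- bk %/% nx
    m <- 1L
    repeat {
      qx <- max(bx - m, 0):min(bx + m, nx - 1)
      qy <- max(by - m, 0):min(by + m, ny - 1)
      cand_keys <- as.character(outer(qx, qy * nx, `+`))
      cand <- unlist(buckets[pos[cand_keys[cand_keys %in% names(pos)]]],
                     use.names = FALSE)
      full_cover <- (bx - m <= 0 && bx + m >= nx - 1 &&
                     by - m <= 0 && by + m >= ny - 1)
      if (length(cand) >= k + 1) {
        ok <- TRUE
        for (ii in I) {
          d2 <- (x[cand] - x[ii])^2 + (y[cand] - y[ii])^2
          o <- cand[order(d2, cand)]
          o <- o[o != ii][seq_len(k)]
          dk <- sqrt((x[o[k]] - x[ii])^2 + (y[o[k]] - y[ii])^2)
          if (dk <= m * cs || full_cover) {
            nn[ii, ] <- o
          } else {
            ok <- FALSE
          }
        }
        if (ok) break
      } else if (full_cover) {
        stop("internal: grid kNN could not find k neighbors")
      }
      m <- m + 1L
    }
  }
  nn
}

#' Neighborhood composition profiles
#'
#' For each reference cell, the fraction of each exclusive phenotype among
#' its spatial neighbors (the reference cell itself excluded). Neighbors
#' are either the `k_nn` nearest cells (default 20, the CODEX-style
#' neighborhood convention) or all cells within a radius; in radius mode
#' isolated cells get an all-zero row and are flagged in the `"isolated"`
#' attribute.
#'
#' @param table A gated [cell_table()].
#' @param mode "knn" (default) or "radius".
#' @param k_nn Neighborhood size in knn mode.
#' @param radius Neighborhood radius (um) in radius mode.
#' @return Numeric matrix cells x phenotypes (rows sum to 1, or 0 for
#'   isolated cells), with the case id in attribute `"case"` and cell ids
#'   as rownames.
#' @export
neighborhood_profiles <- function(table, mode = c("knn", "radius"),
                                  k_nn = 20, radius = 50) {
  mode <- match.arg(mode)
  if (!"phenotype" %in% names(table)) {
    stop("neighborhood profiles require a gated table", call. = FALSE)
  }
  n <- nrow(table)
  lev <- mif_phenotypes()
  f <- as.integer(factor(table$phenotype, levels = lev))
  prof <- matrix(0, n, length(lev), dimnames = list(table$cell_id, lev))
  if (mode == "knn") {
    nn <- knn_grid(table$x, table$y, k_nn)
    for (c_ in seq_len(k_nn)) {
      idx <- cbind(seq_len(n), f[nn[, c_]])
      prof[idx] <- prof[idx] + 1
    }
    prof <- prof / k_nn
  } else {
    pr <- radius_pairs(table$x, table$y, radius)
    if (nrow(pr)) {
      P <- length(lev)
      inc <- tabulate(c((pr$i - 1L) * P + f[pr$j],
                        (pr$j - 1L) * P + f[pr$i]), nbins = n * P)
      prof <- matrix(inc, n, P, byrow = TRUE, dimnames = list(table$cell_id,
                                                              lev))
    }
    deg <- unname(rowSums(prof))
    isolated <- which(deg == 0)
    prof[deg > 0, ] <- prof[deg > 0, , drop = FALSE] / deg[deg > 0]
    attr(prof, "isolated") <- isolated
  }
  attr(prof, "case") <- rep(if (n) table$case_id[1] else character(0), n)
  attr(prof, "mode") <- mode
  attr(prof, "size") <- if (mode == "knn") k_nn else radius
  prof
}

#' Pool neighborhood profiles across cases
#'
#' Niches are compared between cases, so clustering pools cells from all
#' cases into one profile matrix. Neighborhoods themselves are always
#' computed within a case.
#'
#' @param profile_list List of [neighborhood_profiles()] matrices.
#' @return A single profile matrix with the concatenated `"case"` attribute.
#' @export
pool_profiles <- function(profile_list) {
  out <- do.call(rbind, profile_list)
  attr(out, "case") <- unlist(lapply(profile_list, attr, "case"),
                              use.names = FALSE)
  attr(out, "mode") <- attr(profile_list[[1]], "mode")
  attr(out, "size") <- attr(profile_list[[1]], "size")
  out
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  mind2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X),
                               byrow = TRUE))^2)
  for (i in seq_len(k)[-1]) {
    if (sum(mind2) <= 0) {
      stop("fewer than k distinct profile rows", call. = FALSE)
    }
    centers[i] <- sample.int(n, 1, prob = mind2)
    d2 <- rowSums((X - matrix(X[centers[i], ], n, ncol(X), byrow = TRUE))^2)
    mind2 <- pmin(mind2, d2)
  }
  X[centers, , drop = FALSE]
}

#' Cluster neighborhood profiles into cellular niches
#'
#' k-means (Lloyd iterations) on the neighborhood composition profiles with
#' k-means++ initialisation and `n_init` restarts, keeping the run with the
#' lowest within-cluster sum of squares. Niche ids are re-indexed by
#' descending cell count (niche 1 is the largest) so reports are stable
#' under input reordering. Deterministic given `seed`.
#'
#' @param profiles Profile matrix from [neighborhood_profiles()] or
#'   [pool_profiles()].
#' @param k Number of niches (default 6).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of k-means++ restarts.
#' @return A `niche_model`: `centroids`, per-cell `labels`, `sizes`,
#'   `niche_composition` (mean profile per niche), `case` vector,
#'   `tot_withinss`, `k`, `seed`, neighborhood metadata.
#' @export
cluster_niches <- function(profiles, k = 6, seed = 1L, n_init = 10) {
  X <- unname(as.matrix(profiles))
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of cells", call. = FALSE)
  if (k > nrow(unique(X))) {
    stop("k exceeds the number of distinct profile rows", call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      cen <- kmeanspp_centers(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = cen, iter.max = 200,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  ord <- order(-tabulate(best$cluster, k), seq_len(k))
  relab <- match(seq_len(k), ord)          # old id -> new id
  labels <- relab[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]
  colnames(centroids) <- colnames(profiles)
  rownames(centroids) <- paste0("niche", seq_len(k))
  comp <- t(vapply(seq_len(k), function(i) {
    colMeans(as.matrix(profiles)[labels == i, , drop = FALSE])
  }, numeric(ncol(profiles))))
  dimnames(comp) <- dimnames(centroids)
  structure(list(centroids = centroids, labels = labels,
                 sizes = tabulate(labels, k), niche_composition = comp,
                 case = attr(profiles, "case"),
                 cell_id = rownames(profiles),
                 tot_withinss = best$tot.withinss, k = k,
                 seed = as.integer(seed), n_init = n_init,
                 mode = attr(profiles, "mode"),
                 neighborhood_size = attr(profiles, "size")),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat("<niche_model> k = ", x$k, ", ", length(x$labels), " cells (",
      x$mode, " neighborhood, size ", x$neighborhood_size,
      "), total WSS = ", signif(x$tot_withinss, 5), "\n", sep = "")
  for (i in seq_len(x$k)) {
    top <- sort(x$niche_composition[i, ], decreasing = TRUE)[1:3]
    cat(sprintf("  niche %d: %6d cells | %s\n", i, x$sizes[i],
                paste(names(top), sprintf("%.2f", top), collapse = ", ")))
  }
  invisible(x)
}

#' Assign new profiles to fitted niches
#'
#' @param object A `niche_model`.
#' @param newdata Profile matrix with the same phenotype columns.
#' @param ... Unused.
#' @return Integer niche labels (nearest centroid).
#' @export
predict.niche_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, colnames(object$centroids), drop = FALSE]
  d2 <- vapply(seq_len(object$k), function(i) {
    rowSums((X - matrix(object$centroids[i, ], nrow(X), ncol(X),
                        byrow = TRUE))^2)
  }, numeric(nrow(X)))
  if (nrow(X) == 1) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

#' Niche composition and per-case proportions
#'
#' The reporting companion of [cluster_niches()]: the mean composition of
#' each niche, each case's distribution of cells over niches (rows sum
#' to 1), and each case's predominant niche (argmax proportion, ties to
#' the lower niche id).
#'
#' @param model A `niche_model` fitted on pooled per-case profiles.
#' @return List with `composition` (k x phenotypes), `proportions`
#'   (cases x k) and `predominant` (named integer per case), class
#'   `niche_report`.
#' @export
niche_report <- function(model) {
  stopifnot(inherits(model, "niche_model"))
  cases <- model$case
  if (is.null(cases)) cases <- rep("case1", length(model$labels))
  tab <- table(factor(cases, levels = unique(cases)),
               factor(model$labels, levels = seq_len(model$k)))
  prop <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  colnames(prop) <- paste0("niche", seq_len(model$k))
  predominant <- apply(prop, 1, which.max)   # which.max ties -> lowest id
  structure(list(composition = model$niche_composition,
                 proportions = prop,
                 predominant = predominant),
            class = "niche_report")
}

#' @export
print.niche_report <- function(x, digits = 3, ...) {
  cat("Niche composition (mean neighborhood fractions):\n")
  print(round(x$composition, digits))
  cat("\nPer-case niche proportions:\n")
  print(round(x$proportions, digits))
  cat("\nPredominant niche per case:\n")
  print(x$predominant)
  invisible(x)
}

#' Within-cluster sum of squares over a range of k
#'
#' Transparency scan for choosing the niche count: the study's observed
#' count (6) is the default k elsewhere, but the elbow of this curve shows
#' how well other values fit a given dataset.
#'
#' @param profiles Profile matrix.
#' @param ks Candidate cluster counts.
#' @param seed Seed for each fit.
#' @param n_init Restarts per k.
#' @return data.frame with `k` and `tot_withinss`.
#' @export
niche_k_scan <- function(profiles, ks = 2:10, seed = 1L, n_init = 5) {
  data.frame(k = ks, tot_withinss = vapply(ks, function(k) {
    cluster_niches(profiles, k = k, seed = derive_seed(seed, "kscan", k),
                   n_init = n_init)$tot_withinss
  }, 0))
}

#' Map of niche labels in space
#'
#' @param x A `niche_model`.
#' @param table The cell table the profiles came from (one case).
#' @param ... Passed to plot.
#' @export
plot.niche_model <- function(x, table, ...) {
  keep <- if (!is.null(x$case)) x$case == table$case_id[1]
          else rep(TRUE, length(x$labels))
  lab <- x$labels[keep]
  cols <- grDevices::hcl.colors(x$k, "Dark 3")
  graphics::plot(table$x, table$y, col = cols[lab], pch = 16, cex = 0.3,
                 xlab = "x (um)", ylab = "y (um)",
                 ylim = rev(range(table$y)), asp = 1, ...)
  graphics::legend("topright", legend = paste("niche", seq_len(x$k)),
                   col = cols, pch = 16, cex = 0.7, bg = "white")
  invisible(x)
}
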