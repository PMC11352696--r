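# All unordered point pairs within `radius`, found with a uniform-grid
# spatial index (bucket side = radius, so candidates lie in the 3x3 bucket
# neighborhood; each bucket scans itself plus 4 forward neighbors so no
# pair is visited twice). Exact: must equal O(n^2) enumeration.
radius_pairs <- function(x, y, radius) {
  n <- length(x)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (n < 2) return(empty)
  kx <- floor(x / radius); kx <- kx - min(kx)
  ky <- floor(y / radius); ky <- ky - min(ky)
  nx <- max(kx) + 1L
  key <- kx + ky * nx
  buckets <- split(seq_len(n), key)
  keys <- as.numeric(names(buckets))
  pos <- stats::setNames(seq_along(buckets), names(buckets))
  r2 <- radius^2
  acc_i <- vector("list", length(buckets))
  acc_j <- vector("list", length(buckets))
  for (b in seq_along(buckets)) {
    I <- buckets[[b]]
    bk <- keys[b]
    bkx <- bk %% nx; bky <- bk %/% nx
    pi <- pj <- integer(0)
    if (length(I) > 1) {
      m <- length(I)
      pi <- rep(I[-m], times = (m - 1):1)
      pj <- I[unlist(lapply(2:m, function(s) s:m))]
    }
    for (d in list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      qx <- bkx + d[1]; qy <- bky + d[2]
      if (qx < 0 || qx >= nx) next
      q <- pos[as.character(qx + qy * nx)]
      if (is.na(q)) next
      J <- buckets[[q]]
      pi <- c(pi, rep(I, each = length(J)))
      pj <- c(pj, rep(J, times = length(I)))
    }
    if (!length(pi)) next
    d2 <- (x[pi] - x[pj])^2 + (y[pi] - y[pj])^2
    keep <- d2 <= r2
    acc_i[[b]] <- pi[keep]
    acc_j[[b]] <- pj[keep]
  }
  i <- unlist(acc_i); j <- unlist(acc_j)
  if (!length(i)) return(empty)
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  data.frame(i = i, j = j,
             distance = sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
}

#' Build the cell-cell proximity graph
#'
#' Undirected graph connecting every pair of cells whose centroid distance
#' is at most `radius` (closed boundary, so cells exactly at the radius are
#' partners; coincident distinct cells are connected). Built with a
#' uniform-grid spatial index that returns exactly the brute-force edge
#' set. The 15 um default treats touching/adjacent cells as potential
#' interacting partners.
#'
#' @param table A [cell_table()].
#' @param radius Interaction radius in um, > 0.
#' @return A `proximity_graph`: cell ids, an edge data.frame
#'   (`i`, `j` row indices, `id_a`, `id_b`, `distance`), the radius and
#'   node count.
#' @export
build_proximity_graph <- function(table, radius = 15) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("radius must be a positive number of micrometres", call. = FALSE)
  }
  validate_cell_table(table)
  pr <- radius_pairs(table$x, table$y, radius)
  pr$id_a <- table$cell_id[pr$i]
  pr$id_b <- table$cell_id[pr$j]
  structure(list(cell_id = table$cell_id,
                 edges = pr[, c("i", "j", "id_a", "id_b", "distance")],
                 radius = radius, n = nrow(table)),
            class = "proximity_graph")
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf("<proximity_graph> %d cells, %d edges at radius %.1f um\n",
              x$n, nrow(x$edges), x$radius))
  invisible(x)
}

count_pair_matrix <- function(li, lj, levels) {
  P <- length(levels)
  m <- matrix(0L, P, P, dimnames = list(levels, levels))
  if (length(li)) {
    code <- (pmin(li, lj) - 1L) * P + pmax(li, lj)
    tab <- tabulate(code, nbins = P * P)
    for (a in seq_len(P)) {
      for (b in a:P) {
        m[a, b] <- m[b, a] <- tab[(a - 1L) * P + b]
      }
    }
  }
  m
}

graph_labels <- function(graph, table, labels) {
  if (is.null(labels)) {
    if (!"phenotype" %in% names(table)) {
      stop("table must be gated (or supply labels=)", call. = FALSE)
    }
    labels <- table$phenotype
  }
  labels <- labels[match(graph$cell_id, table$cell_id)]
  if (anyNA(labels)) stop("a graph node lacks a phenotype label",
                          call. = FALSE)
  labels
}

#' Observed phenotype-pair interaction counts
#'
#' Symmetric matrix whose (A, B) entry is the number of proximity-graph
#' edges joining an A cell and a B cell; diagonal entries count same-
#' phenotype edges once each, so the matrix total over unordered pairs
#' equals the edge count.
#'
#' @param graph A [build_proximity_graph()] result.
#' @param table The gated [cell_table()] the graph was built from.
#' @param labels Optional label vector overriding `table$phenotype`
#'   (e.g. [composite_labels()]).
#' @return Integer matrix, phenotypes x phenotypes.
#' @export
interaction_counts <- function(graph, table, labels = NULL) {
  labels <- graph_labels(graph, table, labels)
  lev <- intersect(c(mif_phenotypes(), sort(unique(labels))), unique(labels))
  f <- as.integer(factor(labels, levels = lev))
  count_pair_matrix(f[graph$edges$i], f[graph$edges$j], lev)
}

#' Permutation enrichment of cell-cell interactions
#'
#' Tests each phenotype pair's observed edge count against a null in which
#' phenotype labels are permuted uniformly over cells while positions and
#' the graph stay fixed — the standard neighborhood-analysis null that
#' preserves both the spatial architecture and the composition. Reports
#' per-pair z-scores ((observed - null mean) / null sd; 0 when the null sd
#' is 0) and one-sided enrichment p-values
#' (1 + #\{null >= observed\}) / (1 + n_perm). Functional flags ride with
#' their cell; to test composite populations (e.g. Ki67+ CTLs) pass
#' [composite_labels()] as `labels`.
#'
#' @param graph A [build_proximity_graph()] result.
#' @param table The gated [cell_table()].
#' @param n_perm Number of label permutations, >= 1.
#' @param seed Integer seed; results are deterministic given it.
#' @param labels Optional label vector overriding `table$phenotype`.
#' @return An `interaction_result`: `counts`, `z`, `p_perm`, `null_mean`,
#'   `null_sd`, `n_perm`, `seed`, `levels`.
#' @export
interaction_enrichment <- function(graph, table, n_perm = 1000, seed = 1L,
                                   labels = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  labels <- graph_labels(graph, table, labels)
  lev <- intersect(c(mif_phenotypes(), sort(unique(labels))), unique(labels))
  f <- as.integer(factor(labels, levels = lev))
  P <- length(lev)
  ei <- graph$edges$i; ej <- graph$edges$j
  obs <- count_pair_matrix(f[ei], f[ej], lev)
  s1 <- matrix(0, P, P); s2 <- matrix(0, P, P); geq <- matrix(0, P, P)
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      pf <- f[sample.int(graph$n)]
      cnt <- count_pair_matrix(pf[ei], pf[ej], lev)
      s1 <- s1 + cnt
      s2 <- s2 + cnt^2
      geq <- geq + (cnt >= obs)
    }
  })
  null_mean <- s1 / n_perm
  null_var <- if (n_perm > 1) (s2 - n_perm * null_mean^2) / (n_perm - 1)
              else matrix(0, P, P)
  null_sd <- sqrt(pmax(null_var, 0))
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, 0)
  dimnames(z) <- dimnames(null_mean) <- dimnames(null_sd) <- dimnames(obs)
  p <- (1 + geq) / (1 + n_perm)
  dimnames(p) <- dimnames(obs)
  structure(list(counts = obs, z = z, p_perm = p, null_mean = null_mean,
                 null_sd = null_sd, n_perm = n_perm, seed = as.integer(seed),
                 levels = lev),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result> ", nrow(x$counts), " labels, ",
      sum(x$counts[upper.tri(x$counts, diag = TRUE)]), " edges, n_perm = ",
      x$n_perm, ", seed = ", x$seed, "\n", sep = "")
  cat("top enriched pairs (z):\n")
  ut <- which(upper.tri(x$z, diag = TRUE), arr.ind = TRUE)
  o <- order(-x$z[ut])[seq_len(min(5, nrow(ut)))]
  for (k in o) {
    a <- ut[k, 1]; b <- ut[k, 2]
    cat(sprintf("  %s - %s: count %d, z = %.2f, p = %.4g\n",
                x$levels[a], x$levels[b], x$counts[a, b], x$z[a, b],
                x$p_perm[a, b]))
  }
  invisible(x)
}

#' Heatmap of interaction z-scores
#'
#' @param x An `interaction_result`.
#' @param what "z" or "counts".
#' @param ... Unused.
#' @export
plot.interaction_result <- function(x, what = c("z", "counts"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  P <- nrow(m)
  graphics::image(seq_len(P), seq_len(P), t(m[P:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  main = paste("interaction", what))
  graphics::axis(1, seq_len(P), x$levels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(P), rev(x$levels), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Composite lineage-by-flag labels
#'
#' Expands exclusive phenotypes with functional flags, e.g. a CTL with
#' `Ki67_pos` becomes "Ki67+ CTL", so composite populations can enter the
#' interaction analysis as their own labels.
#'
#' @param table A gated [cell_table()].
#' @param flags Flag names (from `names(mif_flags())`) to expand by.
#' @return Character label vector, one per cell.
#' @export
composite_labels <- function(table, flags = "Ki67") {
  stopifnot("phenotype" %in% names(table),
            all(flags %in% names(mif_flags())))
  lab <- table$phenotype
  for (fl in flags) {
    on <- table[[paste0(fl, "_pos")]]
    lab <- ifelse(on, paste0(fl, "+ ", lab), lab)
  }
  lab
}
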