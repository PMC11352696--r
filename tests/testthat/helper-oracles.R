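# Independent brute-force oracles and small fixture builders.

# O(n^2) enumeration of all unordered pairs within `radius`.
brute_pairs <- function(x, y, radius) {
  n <- length(x)
  if (n < 2) {
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0)))
  }
  idx <- utils::combn(n, 2)
  d <- sqrt((x[idx[1, ]] - x[idx[2, ]])^2 + (y[idx[1, ]] - y[idx[2, ]])^2)
  keep <- d <= radius
  out <- data.frame(i = idx[1, keep], j = idx[2, keep], distance = d[keep])
  out[order(out$i, out$j), , drop = FALSE]
}

# Independently written nested-conditional phenotype gate.
gate_oracle <- function(table, th) {
  out <- character(nrow(table))
  for (r in seq_len(nrow(table))) {
    pos <- function(m) table[[m]][r] >= th[[m]]
    out[r] <-
      if (pos("CD3") && pos("CD8")) "CTL"
      else if (pos("CD3") && pos("CD4") && !pos("CD8")) "Th"
      else if (pos("CD3")) "T_other"
      else if (pos("CD20")) "B"
      else if (pos("CD68")) "Mac"
      else if (pos("CD14")) "Myeloid"
      else if (pos("CD31")) "Endothelial"
      else if (pos("FAP")) "Fibroblast"
      else if (pos("aSMA")) "SmoothMuscle"
      else "Other"
  }
  out
}

# Exhaustive window scan on the same anchor grid as find_hotspot.
brute_hotspot <- function(x, y, side, stride) {
  xmin <- min(x); xmax <- max(x); ymin <- min(y); ymax <- max(y)
  best <- list(count = -1, x0 = NA, y0 = NA)
  for (y0 in seq(ymin, ymax - side, by = stride)) {
    for (x0 in seq(xmin, xmax - side, by = stride)) {
      cnt <- sum(x >= x0 & x < x0 + side & y >= y0 & y < y0 + side)
      if (cnt > best$count) best <- list(count = cnt, x0 = x0, y0 = y0)
    }
  }
  best
}

# Exhaustive 1-um-stride window maximum via 2D cumulative sums.
grid_max_count <- function(x, y, side) {
  xmin <- min(x); ymin <- min(y)
  gx <- floor(x - xmin) + 1L
  gy <- floor(y - ymin) + 1L
  nx <- max(gx) + 1L; ny <- max(gy) + 1L
  M <- matrix(0L, ny, nx)
  for (k in seq_along(gx)) M[gy[k], gx[k]] <- M[gy[k], gx[k]] + 1L
  P <- matrix(0, ny + 1, nx + 1)
  P[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  w <- as.integer(side)
  if (w >= ny || w >= nx) return(length(x))
  W <- P[(w + 1):(ny + 1), (w + 1):(nx + 1)] -
       P[1:(ny + 1 - w), (w + 1):(nx + 1)] -
       P[(w + 1):(ny + 1), 1:(nx + 1 - w)] +
       P[1:(ny + 1 - w), 1:(nx + 1 - w)]
  max(W)
}

# Brute-force k nearest neighbors ordered by (distance, row index).
brute_knn <- function(x, y, k) {
  n <- length(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    o <- order(d, seq_len(n))
    o[o != i][seq_len(k)]
  }, integer(k)))
}

ari <- function(a, b) e1071::classAgreement(table(a, b))$crand

# strip dimnames and ancillary attributes for numeric comparison
plain <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

# Uniform random cell table with optional iid phenotype labels.
random_cells <- function(n, w = 1000, h = 1000, seed = 1,
                         phenotypes = NULL, probs = NULL) {
  set.seed(seed)
  df <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                   x = stats::runif(n, 0, w), y = stats::runif(n, 0, h))
  tab <- cell_table(df, case_id = "rand")
  if (!is.null(phenotypes)) {
    tab$phenotype <- sample(phenotypes, n, replace = TRUE, prob = probs)
  }
  tab
}

# One-region scene helper.
one_region_spec <- function(density, mixture, seed, side = 1000, ...) {
  scene_spec(side, side,
             region_spec(region_rect(0, 0, side, side), density, mixture),
             seed = seed, ...)
}
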