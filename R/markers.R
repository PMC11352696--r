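#' The mIF marker panel
#'
#' Thirteen-marker panel used throughout: lineage markers (CD3, CD4, CD8,
#' CD14, CD20, CD68), immune checkpoints (PD-1, PD-L1), vessel/stroma
#' markers (CD31, alpha-SMA, FAP) and functional markers (Ki67, Granzyme B).
#' Column names use plain ASCII tokens ("PD1", "aSMA", "GzmB").
#'
#' @return Character vector of marker names.
#' @export
mif_markers <- function() {
  c("CD3", "CD4", "CD8", "CD14", "CD20", "CD68",
    "PD1", "PDL1", "CD31", "aSMA", "FAP", "Ki67", "GzmB")
}

#' Exclusive phenotype labels
#'
#' The exclusive lineage labels assigned by gating, in precedence order,
#' ending with the fallback "Other" (cells expressing none of the panel's
#' lineage markers, which in tumor tissue are mostly tumor cells).
#'
#' @return Character vector of phenotype labels.
#' @export
mif_phenotypes <- function() {
  c("CTL", "Th", "T_other", "B", "Mac", "Myeloid",
    "Endothelial", "Fibroblast", "SmoothMuscle", "Other")
}

#' Functional flags
#'
#' Non-exclusive functional states layered on top of the lineage label:
#' checkpoint expression (PD-1, PD-L1), proliferation (Ki67) and
#' cytotoxicity (Granzyme B). Stored as logical columns `<flag>_pos`.
#'
#' @return Named character vector mapping flag name to its marker.
#' @export
mif_flags <- function() {
  c(PD1 = "PD1", PDL1 = "PDL1", Ki67 = "Ki67", GzmB = "GzmB")
}

flag_cols <- function() paste0(names(mif_flags()), "_pos")

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministic sub-seed for a pipeline stage and case, so adding a case
#' to a run never perturbs the draws of the others. Polynomial string hash
#' of the context tokens folded into the global seed, reduced mod 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param ... Character/numeric context tokens (stage name, case id, ...).
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(tokens)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}
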