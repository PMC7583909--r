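#' Fuse a feature bundle into a fixed-size histogram tensor
#'
#' Converts the per-phase, per-category vectors of an RNA into a
#' `bins x bins x n_channels` tensor (20 x 20 x 4 with the defaults). For
#' each category the three phase vectors are min-max normalized jointly to
#' `[0, 1]` (a category whose values are all equal maps to 0), then every
#' feature dimension contributes one 2-D point per ordered phase pair
#' (0,1), (0,2), (1,2), and the channel is the 2-D histogram of those
#' `3 * dims` points on a uniform grid over `[0, 1]^2` with the right edge of
#' the last bin inclusive. The graph category has no phase structure: its
#' single embedding is reused for all three phases, so its channel
#' concentrates on the diagonal.
#'
#' This scatter construction is the package's declared reading of
#' "multidimensional histogram fusion": it uses the three phases
#' symmetrically, is deterministic, and produces the fixed CNN input shape
#' regardless of the category dimensions.
#'
#' @param bundle A `feature_bundle` from [encode_rna()].
#' @param bins Grid resolution per axis (default 20, must be >= 2).
#' @param channels Categories to include, in channel order; defaults to all
#'   categories present in the bundle, ordered kmer, ctd, doc2vec, graph.
#' @return A `fused_tensor`: numeric array `bins x bins x length(channels)`
#'   with attribute `rna_id`; channel `c` sums to `3 * dims(c)`.
#' @export
fuse_histogram <- function(bundle, bins = 20L, channels = NULL) {
  if (!inherits(bundle, "feature_bundle")) stop_input("not a feature_bundle")
  bins <- as.integer(bins)
  if (bins < 2L) stop_input("bins must be >= 2, got %d", bins)
  present <- names(bundle$phases[[1]])
  if (!is.null(bundle$graph)) present <- c(present, "graph")
  channels <- channels %||% intersect(c("kmer", "ctd", "doc2vec", "graph"),
                                      present)
  if (length(channels) == 0L) stop_input("no channels to fuse")
  missing <- setdiff(channels, present)
  if (length(missing) > 0L)
    stop_input("bundle for '%s' lacks categor%s: %s", bundle$rna_id,
               if (length(missing) > 1) "ies" else "y",
               paste(missing, collapse = ", "))

  tensor <- array(0, dim = c(bins, bins, length(channels)),
                  dimnames = list(NULL, NULL, channels))
  for (ci in seq_along(channels)) {
    cat <- channels[ci]
    vs <- if (cat == "graph") rep(list(as.numeric(bundle$graph)), 3L)
          else lapply(bundle$phases, function(p) {
            v <- p[[cat]]
            if (is.null(v)) stop_input("phase vector missing for category %s", cat)
            as.numeric(v)
          })
    d <- unique(lengths(vs))
    if (length(d) != 1L)
      stop_input("category %s has unequal phase vector lengths", cat)
    rng <- range(unlist(vs))
    vs <- if (rng[2] > rng[1]) lapply(vs, function(v) (v - rng[1]) / (rng[2] - rng[1]))
          else lapply(vs, function(v) rep(0, length(v)))
    bin_of <- function(v) pmin(floor(v * bins) + 1L, bins)  # last edge inclusive
    H <- matrix(0, bins, bins)
    for (pp in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      ix <- bin_of(vs[[pp[1]]])
      iy <- bin_of(vs[[pp[2]]])
      H <- H + matrix(tabulate(ix + (iy - 1L) * bins, nbins = bins * bins),
                      bins, bins)
    }
    tensor[, , ci] <- H
  }
  structure(tensor, rna_id = bundle$rna_id, class = "fused_tensor")
}

#' Pair two fused tensors for the classifier
#'
#' Validates shapes and returns the ordered (lncRNA, miRNA) pair that is fed
#' unchanged to the twin-tower network.
#'
#' @param lnc,mir `fused_tensor` objects (or plain arrays) of identical shape.
#' @return List with elements `lnc` and `mir`.
#' @export
pair_tensor <- function(lnc, mir) {
  dl <- dim(lnc); dm <- dim(mir)
  if (length(dl) != 3L || length(dm) != 3L || !all(dl == dm))
    stop_input("tensor shape mismatch: %s vs %s",
               paste(dl, collapse = "x"), paste(dm, collapse = "x"))
  list(lnc = lnc, mir = mir)
}
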