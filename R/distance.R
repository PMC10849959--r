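#' Bouton-to-microglia distance analysis
#'
#' Minimal Euclidean distances from axonal bouton points to a 3D microglia
#' mask on an anisotropic voxel grid, computed with an exact separable
#' Euclidean distance transform whose per-axis sampling equals the physical
#' voxel size.
#'
#' @name distance
NULL

bouton_voxel_index <- function(scene) {
  d <- dim(scene$mask)
  vs <- scene$voxel_size_um
  b <- scene$boutons
  coords <- cbind(z = b$z_um, y = b$y_um, x = b$x_um)
  idx <- matrix(0L, nrow(coords), 3L)
  for (a in 1:3) {
    i <- as.integer(round(coords[, a] / vs[a]))
    bad <- coords[, a] < -vs[a] / 2 | coords[, a] > (d[a] - 0.5) * vs[a]
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf(
        "bouton (%g, %g, %g) um lies outside the volume",
        b$x_um[j], b$y_um[j], b$z_um[j]))
    }
    idx[, a] <- pmin(pmax(i, 0L), d[a] - 1L)
  }
  idx  # 0-based (z, y, x)
}

#' Minimal bouton-to-microglia distances
#'
#' An exact Euclidean distance transform of the mask background (per-axis
#' sampling = voxel size) gives each voxel centre's distance to the nearest
#' microglia voxel centre. Each bouton's distance is then measured from its
#' exact physical position to the nearest foreground voxel centre: the EDT
#' value at the containing voxel bounds the search radius, so only a local
#' box of candidate voxels is scanned. Boutons whose containing voxel is
#' foreground (inside microglia) get 0.
#'
#' @param scene a [volume_scene()].
#' @return list of class `distance_result`: `distances_um` (per bouton) and
#'   `edt` (the full voxel-centre distance array, um).
#' @export
min_distances <- function(scene) {
  stopifnot(inherits(scene, "volume_scene"))
  if (!any(scene$mask)) stop("mask contains no microglia voxels")
  d <- dim(scene$mask)
  vs <- scene$voxel_size_um
  edt <- .edt3d_cpp(as.logical(scene$mask), as.integer(d), vs)
  edt <- array(edt, dim = d)
  idx <- bouton_voxel_index(scene)          # 0-based (z, y, x)
  p <- cbind(scene$boutons$z_um, scene$boutons$y_um, scene$boutons$x_um)
  dist <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    vc <- idx[i, ]
    if (scene$mask[vc[1] + 1L, vc[2] + 1L, vc[3] + 1L]) next  # inside: 0
    # triangle inequality: the site achieving the voxel-centre EDT is
    # within this radius of the bouton, so the true minimum is inside it
    ub <- edt[vc[1] + 1L, vc[2] + 1L, vc[3] + 1L] +
      sqrt(sum((p[i, ] - vc * vs)^2))
    lo <- pmax(0, floor((p[i, ] - ub) / vs))
    hi <- pmin(d - 1, ceiling((p[i, ] + ub) / vs))
    sub <- scene$mask[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L,
                      (lo[3]:hi[3]) + 1L, drop = FALSE]
    fg <- which(sub, arr.ind = TRUE)
    cz <- (lo[1] + fg[, 1] - 1) * vs[1]
    cy <- (lo[2] + fg[, 2] - 1) * vs[2]
    cx <- (lo[3] + fg[, 3] - 1) * vs[3]
    dist[i] <- sqrt(min((cz - p[i, 1])^2 + (cy - p[i, 2])^2 +
                          (cx - p[i, 3])^2))
  }
  structure(list(distances_um = dist, edt = edt),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> %d boutons; distances %.2f-%.2f um (median %.2f)\n",
              length(x$distances_um), min(x$distances_um),
              max(x$distances_um), median(x$distances_um)))
  invisible(x)
}

#' Histogram of bouton distances
#'
#' @param distances numeric distances (um) or a `distance_result`.
#' @param bin_um bin width in um (default 1); bins are half-open
#'   `[k*bin, (k+1)*bin)` starting at 0.
#' @return data frame `bin_start_um`, `bin_end_um`, `count`; counts sum to
#'   the number of distances.
#' @export
distance_histogram <- function(distances, bin_um = 1) {
  if (inherits(distances, "distance_result"))
    distances <- distances$distances_um
  if (bin_um <= 0) stop("bin_um must be positive")
  if (any(distances < 0)) stop("distances must be nonnegative")
  k <- floor(distances / bin_um)
  n_bins <- if (length(k)) max(k) + 1L else 0L
  counts <- tabulate(k + 1L, nbins = n_bins)
  data.frame(bin_start_um = (seq_len(n_bins) - 1L) * bin_um,
             bin_end_um = seq_len(n_bins) * bin_um,
             count = counts)
}

#' @importFrom stats median
NULL
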