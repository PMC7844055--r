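#' Simplified 3D brain template for the spiking reservoir
#'
#' Lays spiking neurons on a regular grid inside an ellipsoidal shell and
#' labels each neuron with a coarse anatomical region. The packaged template
#' replaces a full stereotaxic atlas with a deterministic simplification:
#' regions are the eight octants of the head frame (x right, y anterior,
#' z up, millimetres) split into a deep "core" and a superficial "shell"
#' band by normalised radius, giving up to 16 regions. A user-supplied
#' coordinate table with region labels can be used instead for atlas-faithful
#' runs.
#'
#' @param semi_axes ellipsoid semi-axes in mm, `(x, y, z)`.
#' @param resolution grid spacing in mm between neighbouring neurons.
#' @param shell_fraction normalised radius separating core from shell.
#'
#' @return An object of class `brain_template`: a data.frame with columns
#'   `x`, `y`, `z`, `region` (one row per neuron) and attributes recording
#'   the construction parameters. Deterministic given its arguments.
#' @export
#' @examples
#' tpl <- brain_template(resolution = 20)
#' nrow(tpl); table(tpl$region)
brain_template <- function(semi_axes = c(60, 80, 50), resolution = 15,
                           shell_fraction = 0.7) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), resolution > 0,
            shell_fraction > 0, shell_fraction < 1)
  ax <- semi_axes
  gx <- seq(-ax[1], ax[1], by = resolution)
  gy <- seq(-ax[2], ax[2], by = resolution)
  gz <- seq(-ax[3], ax[3], by = resolution)
  # centre the grid on the origin so octants are symmetric
  gx <- gx - mean(gx); gy <- gy - mean(gy); gz <- gz - mean(gz)
  pts <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  rho <- sqrt((pts$x / ax[1])^2 + (pts$y / ax[2])^2 + (pts$z / ax[3])^2)
  pts <- pts[rho <= 1, , drop = FALSE]
  rho <- rho[rho <= 1]
  if (nrow(pts) < 2)
    stop("template resolution too coarse: fewer than 2 neurons", call. = FALSE)
  octant <- 1L + (pts$x >= 0) + 2L * (pts$y >= 0) + 4L * (pts$z >= 0)
  band <- ifelse(rho <= shell_fraction, "core", "shell")
  pts$region <- sprintf("oct%d.%s", octant, band)
  rownames(pts) <- NULL
  structure(pts, class = c("brain_template", "data.frame"),
            semi_axes = ax, resolution = resolution,
            shell_fraction = shell_fraction)
}

#' @param coords data.frame with columns `x`, `y`, `z`, `region` (and an
#'   optional `label` column, ignored): a user-supplied labelled coordinate
#'   table, e.g. exported from an atlas.
#' @rdname brain_template
#' @export
brain_template_from_coords <- function(coords) {
  need <- c("x", "y", "z", "region")
  if (!all(need %in% names(coords)))
    stop("coordinate table needs columns x, y, z, region", call. = FALSE)
  coords <- as.data.frame(coords)[need]
  if (nrow(coords) < 2)
    stop("fewer than 2 neurons", call. = FALSE)
  if (anyDuplicated(coords[c("x", "y", "z")]))
    stop("duplicate neuron coordinates", call. = FALSE)
  structure(coords, class = c("brain_template", "data.frame"))
}

#' @export
print.brain_template <- function(x, ...) {
  cat(sprintf("<brain_template> %d neurons, %d regions\n",
              nrow(x), length(unique(x$region))))
  invisible(as.data.frame(x))
}

#' Approximate 10-20-style montage for 32 channels
#'
#' Electrode positions on the upper half of the default template ellipsoid,
#' derived from nominal inclination/azimuth angles of the extended 10-20
#' layout. Positions are approximate and intended for mapping channels onto
#' the simplified packaged template, not for source localisation.
#'
#' @param semi_axes ellipsoid semi-axes (mm) used to scale the unit-sphere
#'   positions.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
default_montage <- function(semi_axes = c(60, 80, 50)) {
  # label, inclination from vertex (deg), azimuth from anterior midline
  # (deg, positive toward the right ear)
  ang <- matrix(c(
    90, -18,  90, 18,  90, -54,  62, -39,  45, 0,    62, 39,   90, 54,
    73, -67,  32, -45, 32, 45,   73, 67,   90, -90,  45, -90,  0, 0,
    45, 90,   90, 90,  108, -108, 73, -113, 32, -135, 32, 135, 73, 113,
    108, 108, 90, -126, 62, -141, 45, 180,  62, 141,  90, 126, 108, -144,
    90, -162, 90, 180, 90, 162,  108, 144), ncol = 2, byrow = TRUE)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz",
              "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6",
              "TP10", "P7", "P3", "Pz", "P4", "P8", "PO9",
              "O1", "Oz", "O2", "PO10")
  incl <- ang[, 1] * pi / 180
  azim <- ang[, 2] * pi / 180
  data.frame(label = labels,
             x = semi_axes[1] * sin(incl) * sin(azim),
             y = semi_axes[2] * sin(incl) * cos(azim),
             z = semi_axes[3] * cos(incl))
}

#' Map input channels onto template neurons
#'
#' Each channel is assigned the nearest template neuron by Euclidean
#' distance. Channels are processed in lexicographic label order; when two
#' channels contend for one neuron, the later channel takes its next-nearest
#' free neuron, so the mapping is injective and deterministic.
#'
#' @param template a [brain_template()].
#' @param montage data.frame with columns `label`, `x`, `y`, `z` in the same
#'   frame and units as the template.
#' @param warn_distance distance (same units) above which a mapping triggers
#'   a warning, as a guard against unit mismatches.
#' @return Named integer vector: channel label -> neuron row index.
#' @export
map_inputs <- function(template, montage, warn_distance = NULL) {
  stopifnot(inherits(template, "brain_template"))
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(montage)))
    stop("montage needs columns label, x, y, z", call. = FALSE)
  if (nrow(montage) > nrow(template))
    stop("more channels than template neurons", call. = FALSE)
  if (is.null(warn_distance)) {
    res <- attr(template, "resolution")
    warn_distance <- if (is.null(res)) Inf else 3 * res
  }
  ord <- order(montage$label)
  coords <- as.matrix(template[, c("x", "y", "z")])
  taken <- logical(nrow(coords))
  out <- integer(nrow(montage))
  names(out) <- montage$label
  for (i in ord) {
    p <- as.numeric(montage[i, c("x", "y", "z")])
    d2 <- (coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2 +
      (coords[, 3] - p[3])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (sqrt(d2[j]) > warn_distance)
      warning(sprintf("channel %s maps %.1f units away from nearest neuron",
                      montage$label[i], sqrt(d2[j])), call. = FALSE)
    out[montage$label[i]] <- j
    taken[j] <- TRUE
  }
  out
}
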