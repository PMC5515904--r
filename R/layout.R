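# Synthetic spherical electrode layout.
#
# The generator does not ship vendor coordinate files; electrodes are placed
# quasi-uniformly on a sphere (Fibonacci lattice) in a head-centred frame
# (+x right, +y anterior, +z superior; units cm). Numeric labels follow the
# 128-channel convention used by the heartbeat-detection literature, with
# the label groups that the analyses rely on pinned to fixed scalp regions:
# labels 62-69 and 73-77 anterior-right (the connectivity seed, containing
# the right-frontal ERP ROI 67-69), 81-83 anterior-central and 99-101
# anterior-left. `read_layout()` accepts a user-supplied electrode-position
# file to override the synthetic layout.

.roi_directions <- list(
  "anterior-right"   = c(0.55, 0.65, 0.45),
  "anterior-central" = c(0.00, 0.75, 0.66),
  "anterior-left"    = c(-0.55, 0.65, 0.45)
)

.roi_labels <- list(
  "anterior-right"   = as.character(c(62:69, 73:77)),
  "anterior-central" = as.character(81:83),
  "anterior-left"    = as.character(99:101)
)

#' Standard electrode label groups
#'
#' Label sets used by the ERP and connectivity analyses: the right
#' (67-69), central (81-83) and left (99-101) frontal ROIs, and the
#' right-frontal connectivity seed (62-69 and 73-77).
#'
#' @return Named list of character vectors of electrode labels.
#' @export
hep_rois <- function() {
  list(right   = as.character(67:69),
       central = as.character(81:83),
       left    = as.character(99:101),
       seed    = as.character(c(62:69, 73:77)))
}

#' Quasi-uniform spherical electrode layout
#'
#' Places `n_channels` electrodes deterministically on a sphere using a
#' Fibonacci lattice and assigns labels so that the analysis ROIs fall in
#' their conventional scalp regions (see Details). Electrodes with
#' `y <= -radius/2` are designated `"posterior"`; this guarantees that every
#' posterior electrode lies at least 10 cm (chord distance) from the
#' right-frontal seed-ROI centroid on the default 9 cm sphere.
#'
#' @param n_channels Number of electrodes (at least 16; default 128).
#' @param radius Sphere radius in cm (default 9).
#' @return A `channel_layout`: a data frame with columns `label`, `x`, `y`,
#'   `z` (cm) and `region` (`"anterior-right"`, `"anterior-central"`,
#'   `"anterior-left"`, `"posterior"`, `"other"`).
#' @export
make_layout <- function(n_channels = 128, radius = 9) {
  if (!is.numeric(n_channels) || n_channels < 16)
    stop("`n_channels` must be at least 16", call. = FALSE)
  n_channels <- as.integer(n_channels)
  i <- seq_len(n_channels) - 0.5
  z <- 1 - 2 * i / n_channels
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n_channels) - 1L)
  pts <- cbind(x = r * cos(th), y = r * sin(th), z = z) * radius

  labels <- character(n_channels)
  assigned <- rep(FALSE, n_channels)
  # pin ROI label groups to their scalp regions (nearest unassigned points);
  # layouts too small to host the standard labels (toy layouts) skip pinning
  pinned <- character(0)
  for (rg in names(.roi_labels)) {
    want <- .roi_labels[[rg]]
    if (max(as.integer(want)) > n_channels) next
    u <- .roi_directions[[rg]] / sqrt(sum(.roi_directions[[rg]]^2))
    ang <- acos(pmin(1, pmax(-1, (pts %*% u) / radius)))
    ord <- order(ang)
    take <- ord[!assigned[ord]][seq_along(want)]
    labels[take] <- want
    assigned[take] <- TRUE
    pinned <- c(pinned, want)
  }
  rest <- setdiff(as.character(seq_len(n_channels)), pinned)
  labels[!assigned] <- rest
  region <- rep("other", n_channels)
  for (rg in names(.roi_labels)) region[labels %in% .roi_labels[[rg]]] <- rg
  region[pts[, "y"] <= -radius / 2] <- "posterior"
  out <- data.frame(label = labels, x = pts[, "x"], y = pts[, "y"],
                    z = pts[, "z"], region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_layout", "data.frame")
  attr(out, "radius") <- radius
  out
}

#' Euclidean distance between two electrodes
#'
#' Straight-line (chord) distance between two labelled electrodes,
#' `sqrt((x_i-x_j)^2 + (y_i-y_j)^2 + (z_i-z_j)^2)`.
#'
#' @param layout A `channel_layout`.
#' @param i,j Electrode labels (character or coercible).
#' @return Distance in cm.
#' @export
electrode_distance <- function(layout, i, j) {
  ii <- match(as.character(i), layout$label)
  jj <- match(as.character(j), layout$label)
  if (anyNA(c(ii, jj))) stop("unknown electrode label", call. = FALSE)
  a <- as.numeric(layout[ii, c("x", "y", "z")])
  b <- as.numeric(layout[jj, c("x", "y", "z")])
  sqrt(sum((a - b)^2))
}

#' Pairwise electrode distance matrix
#'
#' @param layout A `channel_layout`.
#' @return Symmetric matrix of chord distances in cm, with electrode labels
#'   as dimnames.
#' @export
distance_matrix <- function(layout) {
  m <- as.matrix(stats::dist(as.matrix(layout[, c("x", "y", "z")])))
  dimnames(m) <- list(layout$label, layout$label)
  m
}

#' Write / read electrode positions
#'
#' Tab-separated positions with columns `label`, `x`, `y`, `z` (cm) and
#' optionally `region`. `read_layout()` is the hook for substituting a
#' measured electrode-position file for the synthetic layout.
#'
#' @param layout A `channel_layout`.
#' @param path File path.
#' @return `read_layout()` returns a `channel_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(label = "character"))
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("layout file must have columns label, x, y, z", call. = FALSE)
  if (anyDuplicated(df$label)) stop("duplicate electrode labels", call. = FALSE)
  if (is.null(df$region)) df$region <- "other"
  class(df) <- c("channel_layout", "data.frame")
  df
}
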