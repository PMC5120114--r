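# Electrode geometry. The vendor's true 128-channel geodesic coordinates are
# not redistributable, so the package ships a *synthetic* unit-sphere layout:
# the channels belonging to the standard analysis clusters are pinned near
# their nominal 10-10 scalp sites and the remaining channels fill the head
# surface on a Fibonacci cap. Head frame: +x right ear, +y nasion, +z vertex.

# direction of a point `polar` degrees from the vertex, at azimuth `az`
# degrees measured from the nasion (+y) toward the right ear (+x)
.sph_dir <- function(polar_deg, az_deg) {
  p <- polar_deg * pi / 180
  a <- az_deg * pi / 180
  c(x = sin(p) * sin(a), y = sin(p) * cos(a), z = cos(p))
}

# nominal anchor directions for the named 10-10 sites used by the clusters
.site_anchors <- function() {
  list(
    FP1 = .sph_dir(72, -18),  FP2 = .sph_dir(72, 18),
    FC3 = .sph_dir(46, -55),  FC4 = .sph_dir(46, 55),
    O1  = .sph_dir(72, -162), O2  = .sph_dir(72, 162)
  )
}

#' Electrode clusters used for ERP extraction
#'
#' EGI channel numbers of the occipital (around O1/O2) and frontocentral
#' (around FC3/FC4) analysis clusters, plus prefrontal clusters formed from
#' the channels nearest to the FP1/FP2 scalp positions in the supplied
#' layout. Left-hemisphere clusters are O1, FC3, FP1.
#'
#' @param layout Electrode layout data frame (see [synthetic_egi_layout()]);
#'   required only for the prefrontal clusters.
#' @param fp_size Number of nearest-neighbour channels in each prefrontal
#'   cluster.
#' @return Named list of integer channel vectors with an attribute `side`
#'   giving each cluster's hemisphere (`"left"`/`"right"`).
#' @export
erp_clusters <- function(layout = synthetic_egi_layout(),
                         fp_size = gazerp_defaults("fp_cluster_size")) {
  cl <- list(
    O1  = c(65L, 66L, 70L, 71L, 69L, 74L),
    O2  = c(90L, 84L, 76L, 83L, 82L, 89L),
    FC3 = c(12L, 13L, 19L, 24L, 20L, 28L, 29L),
    FC4 = c(4L, 5L, 111L, 112L, 117L, 118L, 124L)
  )
  anchors <- .site_anchors()
  pos <- as.matrix(layout[, c("x", "y", "z")])
  for (site in c("FP1", "FP2")) {
    d <- drop(pos %*% anchors[[site]])        # cosine similarity to anchor
    ord <- order(d, decreasing = TRUE)
    cl[[site]] <- as.integer(layout$egi_channel[ord[seq_len(fp_size)]])
  }
  structure(cl, side = c(O1 = "left", O2 = "right", FC3 = "left",
                         FC4 = "right", FP1 = "left", FP2 = "right"))
}

#' Synthetic 128-channel unit-sphere electrode layout
#'
#' A stand-in for the geodesic sensor net geometry (the vendor coordinates
#' are not shipped). Channels belonging to the standard analysis clusters
#' are placed on small rings around their nominal 10-10 anchor positions
#' (O1/O2, FC3/FC4) and around the frontal poles; all other channels are
#' distributed over a Fibonacci-spiral cap reaching slightly below the
#' equator, as geodesic nets do. All positions have unit norm.
#'
#' @return Data frame with columns `egi_channel`, `x`, `y`, `z`.
#' @export
synthetic_egi_layout <- function() {
  n <- gazerp_defaults("n_channels")
  pos <- matrix(NA_real_, n, 3)
  anchors <- .site_anchors()
  pinned <- list(
    O1  = c(65L, 66L, 70L, 71L, 69L, 74L),
    O2  = c(90L, 84L, 76L, 83L, 82L, 89L),
    FC3 = c(12L, 13L, 19L, 24L, 20L, 28L, 29L),
    FC4 = c(4L, 5L, 111L, 112L, 117L, 118L, 124L),
    FP1 = c(22L, 26L, 23L, 18L, 15L, 25L),
    FP2 = c(9L, 2L, 3L, 8L, 14L, 1L)
  )
  ring_deg <- 10  # cluster members sit on a 10-degree ring around the anchor
  for (site in names(pinned)) {
    a <- anchors[[site]]
    # local tangent basis at the anchor
    up <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    t1 <- up - sum(up * a) * a; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(a[2] * t1[3] - a[3] * t1[2],
            a[3] * t1[1] - a[1] * t1[3],
            a[1] * t1[2] - a[2] * t1[1])
    ids <- pinned[[site]]
    for (k in seq_along(ids)) {
      ang <- 2 * pi * (k - 1) / length(ids)
      r <- ring_deg * pi / 180
      v <- cos(r) * a + sin(r) * (cos(ang) * t1 + sin(ang) * t2)
      pos[ids[k], ] <- v / sqrt(sum(v^2))
    }
  }
  free <- which(is.na(pos[, 1]))
  m <- length(free)
  golden <- pi * (3 - sqrt(5))
  # cap from the vertex down to 115 degrees polar angle
  cosmax <- cos(115 * pi / 180)
  for (k in seq_len(m)) {
    z <- 1 - (k - 0.5) * (1 - cosmax) / m
    r <- sqrt(max(0, 1 - z^2))
    th <- golden * (k - 1)
    pos[free[k], ] <- c(r * sin(th), r * cos(th), z)
  }
  data.frame(egi_channel = seq_len(n),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Read / write an electrode layout TSV
#'
#' The layout file has columns `egi_channel`, `x`, `y`, `z` with unit-norm
#' positions. Reading validates completeness (all channels 1..n present
#' exactly once) and unit norms.
#'
#' @param path File path.
#' @param n_channels Expected channel count.
#' @return `read_layout()` returns the validated layout data frame.
#' @export
read_layout <- function(path, n_channels = gazerp_defaults("n_channels")) {
  lay <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("egi_channel", "x", "y", "z")
  if (!all(need %in% names(lay)))
    stop("layout file ", path, " lacks columns: ",
         paste(setdiff(need, names(lay)), collapse = ", "), call. = FALSE)
  missing <- setdiff(seq_len(n_channels), lay$egi_channel)
  if (length(missing))
    stop("layout file ", path, " is missing EGI channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lay <- lay[order(lay$egi_channel), ]
  nrm <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop("layout positions must lie on the unit sphere", call. = FALSE)
  lay
}

#' @rdname read_layout
#' @param layout Layout data frame to write.
#' @export
write_layout <- function(layout, path) {
  .write_tsv(layout, path)
  invisible(path)
}
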