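# Spherical spline interpolation of scalp potentials (Perrin-style
# thin-plate splines on the unit sphere): a bad channel's time course is
# reconstructed at every sample from the clean channels, using the kernel
# g(cos t) = sum_n (2n+1) / (n (n+1))^m P_n(cos t) / (4 pi)
# truncated after `n_terms` Legendre terms with stiffness m.

# Legendre polynomials P_1..P_n evaluated at x (vector), via the
# three-term recurrence; returns a length(x) x n matrix
.legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  p0 <- rep(1, length(x))
  p1 <- x
  out[, 1] <- p1
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    out[, k] <- p2
    p0 <- p1
    p1 <- p2
  }
  out
}

# spline kernel matrix between unit-vector rows of A and B
.spline_g <- function(A, B, m, n_terms) {
  cosang <- pmin(1, pmax(-1, tcrossprod(A, B)))
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  P <- .legendre_table(as.vector(cosang), n_terms)
  matrix(P %*% coef, nrow(A), nrow(B))
}

#' Spherical spline interpolation of bad channels
#'
#' Replaces the time courses of `bad_channels` in one epoch by smooth
#' spherical-spline estimates computed from the remaining (clean)
#' channels at every sample. The spline reproduces spatially constant
#' fields exactly and recovers low-order spherical-harmonic fields
#' closely; clean channels are never altered.
#'
#' @param epoch Numeric matrix, time x channel.
#' @param bad_channels Integer indices of channels to reconstruct.
#' @param layout Electrode layout (unit-sphere positions, see
#'   [synthetic_egi_layout()]).
#' @param good_channels Channels used as interpolation support; defaults
#'   to all channels not in `bad_channels`.
#' @param m Spline stiffness (order of the smoothing operator).
#' @param n_terms Legendre series truncation.
#' @return The epoch matrix with bad channels replaced.
#' @export
spline_interpolate <- function(epoch, bad_channels, layout,
    good_channels = setdiff(seq_len(ncol(epoch)), bad_channels),
    m = gazerp_defaults("spline_order_m"),
    n_terms = gazerp_defaults("spline_n_terms")) {
  if (!length(bad_channels)) return(epoch)
  good_channels <- setdiff(good_channels, bad_channels)
  if (length(good_channels) < 4)
    stop("spherical spline interpolation needs at least 4 clean channels",
         call. = FALSE)
  pos <- as.matrix(layout[, c("x", "y", "z")])
  G <- .spline_g(pos[good_channels, , drop = FALSE],
                 pos[good_channels, , drop = FALSE], m, n_terms)
  ng <- length(good_channels)
  # augmented system enforcing the zero-sum constraint on the weights
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  rhs <- rbind(t(epoch[, good_channels, drop = FALSE]), 0)
  sol <- solve(A, rhs)                     # (ng + 1) x time
  Gb <- .spline_g(pos[bad_channels, , drop = FALSE],
                  pos[good_channels, , drop = FALSE], m, n_terms)
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad_channels), ncol(sol), byrow = TRUE)
  epoch[, bad_channels] <- t(est)
  epoch
}

#' Interpolate flagged channels of kept epochs and re-screen them
#'
#' For every kept epoch, channels flagged `needs_interpolation` are
#' reconstructed by [spline_interpolate()] from that epoch's clean
#' channels, then re-checked once against the session's screening
#' thresholds: repaired channels that now pass are flagged
#' `interpolated`, those still failing are flagged `bad` and stay
#' excluded from cluster averages. Epochs with fewer than 4 clean
#' channels are rejected.
#'
#' @param epochs A screened `epoch_set` (see [screen_epochs()]).
#' @param layout Electrode layout.
#' @param m,n_terms Spline parameters, see [spline_interpolate()].
#' @return The `epoch_set` with repaired data and updated flags.
#' @export
interpolate_bad_channels <- function(epochs, layout,
    m = gazerp_defaults("spline_order_m"),
    n_terms = gazerp_defaults("spline_n_terms")) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$screening))
    stop("epochs must be screened before interpolation", call. = FALSE)
  th <- epochs$screening$thresholds
  floor_uv <- epochs$screening$sd_floor_uv
  for (i in seq_along(epochs$status)) {
    if (epochs$status[i] != "kept") next
    bad <- which(epochs$channel_flags[, i] == "needs_interpolation")
    if (!length(bad)) next
    good <- which(epochs$channel_flags[, i] == "clean")
    if (length(good) < 4) {
      epochs$status[i] <- "rejected"
      next
    }
    repaired <- spline_interpolate(epochs$data[, , i], bad, layout,
                                   good_channels = good,
                                   m = m, n_terms = n_terms)
    epochs$data[, , i] <- repaired
    # single recheck pass against the session thresholds
    mets <- epoch_metrics(repaired[, bad, drop = FALSE], epochs$times_ms)
    ok <- !(th$sd$flag(mets$sd) | th$range$flag(mets$range) |
            th$drift$flag(mets$drift) | th$max_step$flag(mets$max_step)) &
      mets$sd > floor_uv
    epochs$channel_flags[bad, i] <- ifelse(ok, "interpolated", "bad")
  }
  epochs
}
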