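# Maximal-overlap discrete wavelet transform (Daubechies extremal-phase
# family), used by the motion-artifact despiker. The MODWT is shift-
# invariant, length-preserving and energy-conserving, so zeroing outlying
# detail coefficients can only remove energy.

# Daubechies-5 scaling filter (10 taps, sum = sqrt(2))
.DB5_H <- c(
  0.160102397974125, 0.603829269797473, 0.724308528438574,
  0.138428145901103, -0.242294887066190, -0.032244869585030,
  0.077571493840065, -0.006241490213012, -0.012580751999016,
  0.003335725285002
)

.wavelet_filters <- function(wavelet = "db5") {
  h <- switch(wavelet,
    db5 = .DB5_H,
    stop("unsupported wavelet: ", wavelet)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror
  list(h = h / sqrt(2), g = g / sqrt(2), L = L)  # MODWT rescaling
}

# circular filter with filter taps spaced 2^(j-1) apart (a trous)
.modwt_filter <- function(v, taps, j) {
  n <- length(v)
  gap <- 2L^(j - 1L)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(taps)) {
    shift <- (l - 1L) * gap
    out <- out + taps[l] * v[((idx0 - shift) %% n) + 1L]
  }
  out
}

# adjoint step used by the inverse transform
.imodwt_filter <- function(v, taps, j) {
  n <- length(v)
  gap <- 2L^(j - 1L)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(taps)) {
    shift <- (l - 1L) * gap
    out <- out + taps[l] * v[((idx0 + shift) %% n) + 1L]
  }
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' @param x Numeric vector.
#' @param n_levels Decomposition depth; the default is the deepest level
#'   supported by the series length for the chosen filter.
#' @param wavelet Filter name (only `"db5"`).
#' @return List with `W` (list of detail coefficient vectors per level),
#'   `V` (final smooth), `n_levels`, `wavelet`.
#' @export
modwt <- function(x, n_levels = NULL, wavelet = "db5") {
  f <- .wavelet_filters(wavelet)
  n <- length(x)
  max_level <- floor(log2((n - 1) / (f$L - 1) + 1))
  if (is.null(n_levels)) n_levels <- max_level
  if (max_level < 1L) stop("series too short for one decomposition level")
  n_levels <- min(n_levels, max_level)
  W <- vector("list", n_levels)
  v <- x
  for (j in seq_len(n_levels)) {
    W[[j]] <- .modwt_filter(v, f$g, j)
    v <- .modwt_filter(v, f$h, j)
  }
  list(W = W, V = v, n_levels = n_levels, wavelet = wavelet)
}

#' Inverse maximal-overlap discrete wavelet transform
#' @param w A decomposition from [modwt()].
#' @return Reconstructed numeric vector.
#' @export
imodwt <- function(w) {
  f <- .wavelet_filters(w$wavelet)
  v <- w$V
  for (j in rev(seq_len(w$n_levels))) {
    v <- .imodwt_filter(v, f$h, j) + .imodwt_filter(w$W[[j]], f$g, j)
  }
  v
}

# despike one vector: zero detail coefficients far from the level median.
# The endpoint-connecting line is removed first so the circular transform
# sees no wrap-around jump that would masquerade as an artifact.
.despike_vector <- function(x, alpha) {
  n <- length(x)
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  w <- modwt(x - line)
  for (j in seq_len(w$n_levels)) {
    d <- w$W[[j]]
    med <- stats::median(d)
    iqr <- stats::IQR(d)
    if (iqr > 0) {
      d[abs(d - med) > alpha * iqr] <- 0
      w$W[[j]] <- d
    }
  }
  imodwt(w) + line
}
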