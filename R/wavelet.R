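#' Discrete wavelet transform (Daubechies, periodized)
#'
#' A compact orthonormal DWT used by the wavelet feature extractor and the
#' transient-suppression cleaner. The decomposition is circular (periodized);
#' odd-length inputs at any level are extended by repeating the final sample,
#' and the recorded per-level lengths make the inverse exact.
#'
#' @param x numeric vector.
#' @param level decomposition depth.
#' @param wavelet wavelet family; `"db4"` (8 taps) or `"haar"`.
#' @return A list of class `nc_dwt` with elements `details` (list of detail
#'   coefficient vectors, finest first), `approx` (approximation coefficients
#'   at the deepest level), `lengths` (original per-level input lengths) and
#'   `wavelet`.
#' @export
nc_dwt <- function(x, level = 4, wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- dwt_filter(wavelet)
  g <- qmf(h)
  if (level < 1) stop("level must be >= 1")
  min_len <- 2^level
  if (length(x) < min_len)
    stop("signal of length ", length(x), " is too short for a depth-",
         level, " decomposition")
  details <- vector("list", level)
  lengths <- integer(level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    lengths[l] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    st <- dwt_step(a, h, g)
    details[[l]] <- st$d
    a <- st$a
  }
  structure(list(details = details, approx = a, lengths = lengths,
                 wavelet = wavelet),
            class = "nc_dwt")
}

#' Inverse of [nc_dwt()]
#'
#' @param dec an `nc_dwt` object (possibly with modified coefficients).
#' @return The reconstructed numeric vector.
#' @export
nc_idwt <- function(dec) {
  h <- dwt_filter(dec$wavelet)
  g <- qmf(h)
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[l]], h, g)
    a <- a[seq_len(dec$lengths[l])]
  }
  a
}

dwt_filter <- function(wavelet) {
  switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    # db4 scaling (low-pass) filter, 4 vanishing moments, 8 taps
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728))
}

qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# one circular analysis step: a[n] = sum_k h[k] x[(2n + k) mod N]
dwt_step <- function(x, h, g) {
  N <- length(x)
  half <- N %/% 2L
  pos0 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (k in seq_along(h)) {
    xi <- x[(pos0 + (k - 1L)) %% N + 1L]
    a <- a + h[k] * xi
    d <- d + g[k] * xi
  }
  list(a = a, d = d)
}

# adjoint (= inverse, by orthonormality) of dwt_step
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  pos0 <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    p <- (pos0 + (k - 1L)) %% N + 1L
    contrib <- h[k] * a + g[k] * d
    # p has no duplicates for filters shorter than N, but accumulate safely
    x[p] <- x[p] + contrib
  }
  x
}
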