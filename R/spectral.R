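#' Discrete Fourier transform of token features
#'
#' Computes the unnormalized DFT `F(k) = sum_n e(n) exp(-2*pi*i*n*k/N)`.
#' With `grid = NULL` the input is a single 1D sequence over the flattened
#' token index (the literal one-dimensional form). With a token grid, the
#' transform is applied separably along the three token-grid axes,
#' independently per channel — the form appropriate for tokens that live on
#' a 3D lattice.
#'
#' The full complex spectrum is stored; for real inputs it is Hermitian
#' symmetric, and [idft()] can enforce that symmetry before returning a real
#' signal.
#'
#' @param signal Numeric/complex vector (1D mode) or `N x C` matrix whose
#'   rows follow the token-grid flattening order (3D mode).
#' @param grid Token-grid shape `(h, w, d)`; `NULL` for the 1D transform.
#' @return An `afno_spectrum`: list with `coeffs` (complex vector in 1D
#'   mode, complex `(h, w, d, C)` array in 3D mode), `source_grid`, `mode`.
#' @export
dft <- function(signal, grid = NULL) {
  if (is.null(grid)) {
    x <- as.vector(signal)
    if (length(x) == 0L) stop("cannot transform an empty signal")
    return(structure(list(coeffs = stats::fft(x),
                          source_grid = length(x), mode = "1d"),
                     class = "afno_spectrum"))
  }
  grid <- as.integer(grid)
  x <- as.matrix(signal)
  if (nrow(x) == 0L) stop("cannot transform an empty signal")
  if (nrow(x) != prod(grid)) {
    stop("signal has ", nrow(x), " rows but grid implies ", prod(grid))
  }
  C <- ncol(x)
  coeffs <- array(complex(real = 0), c(grid, C))
  for (ch in seq_len(C)) {
    coeffs[, , , ch] <- stats::fft(array(x[, ch], grid))
  }
  structure(list(coeffs = coeffs, source_grid = grid, mode = "3d"),
            class = "afno_spectrum")
}

#' Modulate a spectrum with a learned spectral filter
#'
#' Elementwise complex product `F_mod(k) = F(k) * W(k)`: each retained
#' frequency component is scaled by its own learned complex weight, which is
#' how the mixing path emphasizes or suppresses spatial frequencies.
#'
#' @param spec An `afno_spectrum`.
#' @param filt An [spectral_filter()] whose coefficients match `spec` in shape.
#' @return The modulated `afno_spectrum`.
#' @export
modulate <- function(spec, filt) {
  stopifnot(inherits(spec, "afno_spectrum"))
  W <- if (inherits(filt, "afno_spectral_filter")) filt$W else filt
  if (!identical(dim_or_len(W), dim_or_len(spec$coeffs))) {
    stop("filter shape (", paste(dim_or_len(W), collapse = "x"),
         ") does not match spectrum shape (",
         paste(dim_or_len(spec$coeffs), collapse = "x"), ")")
  }
  spec$coeffs <- spec$coeffs * W
  spec
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Inverse discrete Fourier transform
#'
#' Computes `e'(n) = (1/N) sum_k F(k) exp(+2*pi*i*n*k/N)` (separably per
#' axis in 3D mode). With `real = TRUE` the spectrum is first projected onto
#' the Hermitian-symmetric subspace (the symmetry a real signal's spectrum
#' must have), the imaginary residue of the result is checked against
#' `1e-8`, and the real part is returned. With `real = FALSE` the full
#' complex inverse is returned unchanged.
#'
#' @param spec An `afno_spectrum`.
#' @param real Return a real signal after enforcing Hermitian symmetry?
#' @return Numeric/complex vector (1D) or `N x C` matrix (3D).
#' @export
idft <- function(spec, real = TRUE) {
  stopifnot(inherits(spec, "afno_spectrum"))
  if (spec$mode == "1d") {
    co <- spec$coeffs
    if (real) co <- herm_symmetrize_vec(co)
    out <- stats::fft(co, inverse = TRUE) / length(co)
    if (real) {
      res <- max(abs(Im(out)))
      if (res >= 1e-8) stop("imaginary residue ", format(res),
                            " exceeds 1e-8 after Hermitian symmetrization")
      return(Re(out))
    }
    return(out)
  }
  g <- spec$source_grid
  C <- dim(spec$coeffs)[4]
  N <- prod(g)
  out <- if (real) matrix(0, N, C) else
    matrix(complex(real = 0), N, C)
  for (ch in seq_len(C)) {
    co <- spec$coeffs[, , , ch]
    dim(co) <- g
    if (real) co <- herm_symmetrize_arr(co)
    y <- stats::fft(co, inverse = TRUE) / N
    if (real) {
      res <- max(abs(Im(y)))
      if (res >= 1e-8) stop("imaginary residue ", format(res),
                            " exceeds 1e-8 after Hermitian symmetrization")
      y <- Re(y)
    }
    out[, ch] <- as.vector(y)
  }
  out
}

#' Construct / initialize a spectral filter
#'
#' One learnable complex weight per frequency index per channel. The
#' identity initialization `W(k) = 1 + 0i` makes the whole
#' DFT-modulate-IDFT path the identity map at step 0, so freshly
#' initialized models start from a transparent mixing path.
#'
#' @param W Complex array `(h, w, d, C)` (3D mode) or matrix `N x C`
#'   (1D mode).
#' @return An `afno_spectral_filter`.
#' @export
spectral_filter <- function(W) {
  structure(list(W = W), class = "afno_spectral_filter")
}

#' @rdname spectral_filter
#' @param grid Token-grid shape (3D mode) or token count (1D mode).
#' @param channels Number of channels.
#' @param mode `"afno_3d"` or `"afno_1d"`.
#' @export
init_spectral_filter <- function(grid, channels, mode = "afno_3d") {
  if (mode == "afno_1d") {
    W <- matrix(complex(real = 1, imaginary = 0), prod(grid), channels)
  } else {
    W <- array(complex(real = 1, imaginary = 0), c(grid, channels))
  }
  spectral_filter(W)
}

# Hermitian projection: average W with the conjugate of its frequency-mirror
herm_symmetrize_vec <- function(v) {
  n <- length(v)
  mi <- c(1L, rev(seq_len(n)[-1]))
  (v + Conj(v[mi])) / 2
}

herm_symmetrize_arr <- function(a) {
  d <- dim(a)
  mi <- lapply(d, function(n) c(1L, rev(seq_len(n)[-1])))
  (a + Conj(a[mi[[1]], mi[[2]], mi[[3]], drop = FALSE])) / 2
}

herm_project_filter <- function(W) {
  if (is.matrix(W)) {
    n <- nrow(W)
    mi <- c(1L, rev(seq_len(n)[-1]))
    (W + Conj(W[mi, , drop = FALSE])) / 2
  } else {
    d <- dim(W)
    mi <- lapply(d[1:3], function(n) c(1L, rev(seq_len(n)[-1])))
    (W + Conj(W[mi[[1]], mi[[2]], mi[[3]], , drop = FALSE])) / 2
  }
}

#' Adaptive Fourier token mixing
#'
#' The spectral mixing path of the encoder: tokens are laid out on their 3D
#' grid, transformed to the frequency domain per channel, modulated by the
#' learned filter, transformed back, and (by default) added to the input as
#' a residual. In `"afno_1d"` mode the transform runs over the flattened
#' token index instead, the literal sequence form.
#'
#' @param tok A `TokenSequence` (see [embed_patches()]).
#' @param filt An [spectral_filter()] matching the token grid and channels.
#' @param mode `"afno_3d"` (separable 3D transform, default) or `"afno_1d"`.
#' @param residual Add the input back around the transform path?
#' @return A `TokenSequence` of the same shape.
#' @export
afno_mix <- function(tok, filt, mode = c("afno_3d", "afno_1d"),
                     residual = TRUE) {
  mode <- match.arg(mode)
  x <- tok$tokens
  if (mode == "afno_3d") {
    sp <- dft(x, grid = tok$grid)
    sp <- modulate(sp, filt)
    y <- idft(sp, real = TRUE)
  } else {
    W <- if (inherits(filt, "afno_spectral_filter")) filt$W else filt
    y <- x
    for (ch in seq_len(ncol(x))) {
      sp <- dft(x[, ch])
      sp <- modulate(sp, W[, ch])
      y[, ch] <- idft(sp, real = TRUE)
    }
  }
  tok$tokens <- if (residual) x + y else y
  tok
}
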