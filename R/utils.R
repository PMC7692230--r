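## Internal helpers shared across modules.

rq_stop <- function(msg, class = "rq_error", ...) {
  stop(structure(
    class = c(class, "rq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rq_assert <- function(ok, msg, class = "rq_error") {
  if (!isTRUE(ok)) rq_stop(msg, class = class)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Shift a matrix by (dr, dc), padding with `fill`. Used by the thinning and
## Laplacian kernels; dr > 0 moves content down, dc > 0 moves it right.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

## 1-D Gaussian kernel truncated at 4 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur with possibly anisotropic sigmas (in pixels),
## replicate-padded via EBImage FFT convolution on an outer-product kernel.
blur_aniso <- function(x, sigma_row, sigma_col) {
  kr <- gauss_kernel(sigma_row)
  kc <- gauss_kernel(sigma_col)
  k <- outer(kr, kc)
  EBImage::filter2(x, k, boundary = "replicate")
}
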