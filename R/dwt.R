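# Separable 2-D discrete wavelet transform (periodized orthogonal filter
# bank). One analysis level splits an image into the approximation LL and
# the detail subbands LH, HL, HH; deeper levels recurse on LL.

wavelet_filters <- function(wavelet = c("haar", "db2")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

# one periodized analysis step along columns of x (length n, n even):
# returns n/2 approximation and n/2 detail rows
dwt_step_cols <- function(x, h, g) {
  n <- nrow(x); L <- length(h)
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x)); d <- a
  for (m in seq_len(L)) {
    idx <- ((2 * (seq_len(half) - 1) + (m - 1)) %% n) + 1L
    a <- a + h[m] * x[idx, , drop = FALSE]
    d <- d + g[m] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

idwt_step_cols <- function(a, d, h, g) {
  half <- nrow(a); n <- 2L * half; L <- length(h)
  x <- matrix(0, n, ncol(a))
  for (m in seq_len(L)) {
    idx <- ((2 * (seq_len(half) - 1) + (m - 1)) %% n) + 1L
    x[idx, ] <- x[idx, ] + h[m] * a + g[m] * d
  }
  x
}

#' Discrete wavelet decomposition of an image
#'
#' Separable periodized orthogonal DWT: each level filters rows and
#' columns with the low/high-pass pair and decimates by two, producing the
#' approximation LL and details LH (low rows, high columns), HL (high
#' rows, low columns) and HH; the next level recurses on LL. With an
#' orthogonal filter (both built-ins are) the transform conserves energy
#' and [dwt_reconstruct()] inverts it to floating-point accuracy.
#'
#' @param image Numeric matrix; each side must be divisible by
#'   `2^levels`.
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @param levels Number of decomposition levels (>= 1).
#' @return An object of class `dwt_decomposition`: list of levels, each a
#'   list with matrices `LL`, `LH`, `HL`, `HH` (half the previous extent
#'   per axis), plus the wavelet name.
#' @export
dwt_decompose <- function(image, wavelet = "haar", levels = 1) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(dim(image) %% (2^levels) != 0))
    stop("image sides must be divisible by 2^levels", call. = FALSE)
  if (any(dim(image) < 2^levels))
    stop("image too small for the requested levels", call. = FALSE)
  f <- wavelet_filters(wavelet)
  out <- vector("list", levels)
  cur <- image
  for (lv in seq_len(levels)) {
    s <- dwt_step_cols(cur, f$h, f$g)                 # rows direction
    aa <- t(dwt_step_cols(t(s$a), f$h, f$g)$a)        # then columns
    ad <- t(dwt_step_cols(t(s$a), f$h, f$g)$d)
    da <- t(dwt_step_cols(t(s$d), f$h, f$g)$a)
    dd <- t(dwt_step_cols(t(s$d), f$h, f$g)$d)
    out[[lv]] <- list(LL = aa, LH = ad, HL = da, HH = dd)
    cur <- aa
  }
  structure(list(levels = out, wavelet = wavelet),
            class = "dwt_decomposition")
}

#' Reconstruct an image from its wavelet decomposition
#'
#' @param decomposition A [dwt_decompose()] result.
#' @return The reconstructed image matrix.
#' @export
dwt_reconstruct <- function(decomposition) {
  stopifnot(inherits(decomposition, "dwt_decomposition"))
  f <- wavelet_filters(decomposition$wavelet)
  lv <- decomposition$levels
  cur <- lv[[length(lv)]]$LL
  for (k in rev(seq_along(lv))) {
    sb <- lv[[k]]
    a <- t(idwt_step_cols(t(cur), t(sb$LH), f$h, f$g))
    d <- t(idwt_step_cols(t(sb$HL), t(sb$HH), f$h, f$g))
    cur <- idwt_step_cols(a, d, f$h, f$g)
  }
  cur
}
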