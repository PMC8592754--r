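# Colour-space conversion, channel normalization, Otsu thresholding and
# binary morphology producing the candidate-mass mask.

#' RGB to CIE XYZ conversion
#'
#' Per-pixel linear map `(X,Y,Z)' = (1/0.17697) * M %*% (R,G,B)'` with the
#' classic CIE matrix rows (0.49, 0.31, 0.20), (0.17697, 0.8124, 0.01063),
#' (0.00, 0.01, 0.99). Y carries the luminance; X and Z the chromatic
#' information.
#'
#' @param image `h x w x 3` array with RGB values in `[0, 1]`.
#' @return `h x w x 3` array of non-negative X, Y, Z channels.
#' @export
rgb_to_xyz <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("`image` must be an h x w x 3 RGB array", call. = FALSE)
  M <- matrix(c(0.49, 0.31, 0.20,
                0.17697, 0.8124, 0.01063,
                0.00, 0.01, 0.99), 3, 3, byrow = TRUE) / 0.17697
  d <- dim(image)
  flat <- matrix(image, ncol = 3)            # pixels x RGB
  out <- flat %*% t(M)
  array(out, dim = d)
}

#' Per-pixel channel normalization
#'
#' Normalizes the red channel by the RGB vector norm and the X channel by
#' the XYZ vector norm at each pixel: `Rhat = R / sqrt(R^2 + G^2 + B^2)`
#' and `Xhat = X / sqrt(X^2 + Y^2 + Z^2)`. Zero-norm (black) pixels map
#' to 0.
#'
#' @param rgb `h x w x 3` RGB array.
#' @param xyz `h x w x 3` XYZ array (see [rgb_to_xyz()]).
#' @return List of two matrices, `Rhat` and `Xhat`, values in `[0, 1]`.
#' @export
normalize_channels <- function(rgb, xyz) {
  if (!all(dim(rgb) == dim(xyz)))
    stop("`rgb` and `xyz` must have matching shapes", call. = FALSE)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  nr <- sqrt(rgb[, , 1]^2 + rgb[, , 2]^2 + rgb[, , 3]^2)
  nx <- sqrt(xyz[, , 1]^2 + xyz[, , 2]^2 + xyz[, , 3]^2)
  rhat <- matrix(ifelse(nr > 0, rgb[, , 1] / nr, 0), h, w)
  xhat <- matrix(ifelse(nx > 0, xyz[, , 1] / nx, 0), h, w)
  list(Rhat = rhat, Xhat = xhat)
}

#' Otsu threshold of a gray image
#'
#' Builds an `n_bins` histogram over `[0, 1]` and returns the bin edge
#' maximizing the between-class variance
#' `sigma_b^2(t) = w1 w2 (mu1 - mu2)^2` (equivalently minimizing the
#' within-class variance); ties break toward the lower threshold.
#'
#' @param values Numeric matrix (or vector) of intensities in `[0, 1]`
#'   with at least two distinct values.
#' @param n_bins Histogram resolution (default 256, the 8-bit convention).
#' @return The threshold, a value in `(0, 1)`; classify a pixel as
#'   foreground when its intensity is strictly greater.
#' @seealso [otsu_stats()] for the full variance curves.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- as.vector(values)
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("`values` must lie in [0, 1]", call. = FALSE)
  if (length(unique(v)) < 2)
    stop("constant image: Otsu threshold is undefined", call. = FALSE)
  counts <- tabulate(pmin(floor(v * n_bins), n_bins - 1) + 1L, n_bins)
  st <- otsu_stats(counts)
  k <- which.max(st$sigma_b2)  # first max = lower threshold on ties
  k / n_bins
}

#' Between/within-class variance curves of a histogram
#'
#' For every candidate split after bin `k` computes the class weights,
#' class means, between-class variance `w1 w2 (mu1 - mu2)^2` and
#' within-class variance; the two variances sum to the total variance at
#' every split.
#'
#' @param counts Integer histogram counts (bins taken as 0-based codes).
#' @return Tibble with columns `k` (split after bin `k`, 1-based),
#'   `w1`, `w2`, `mu1`, `mu2`, `sigma_b2`, `sigma_w2`.
#' @export
otsu_stats <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("empty histogram", call. = FALSE)
  g <- seq_along(counts) - 1          # 0-based gray codes
  p <- counts / n
  w1 <- cumsum(p)
  m1 <- cumsum(p * g)
  mu_tot <- m1[length(m1)]
  var_tot <- sum(p * (g - mu_tot)^2)
  w2 <- 1 - w1
  mu1 <- ifelse(w1 > 0, m1 / w1, 0)
  mu2 <- ifelse(w2 > 0, (mu_tot - m1) / w2, 0)
  sigma_b2 <- w1 * w2 * (mu1 - mu2)^2
  keep <- seq_len(length(counts) - 1)  # splits after bins 1..n-1
  tibble::tibble(
    k = keep, w1 = w1[keep], w2 = w2[keep],
    mu1 = mu1[keep], mu2 = mu2[keep],
    sigma_b2 = sigma_b2[keep],
    sigma_w2 = var_tot - sigma_b2[keep]
  )
}

# structuring elements ----------------------------------------------------

#' Structuring elements for the morphology steps
#'
#' `"identity"` is the literal 5x5 identity matrix (a diagonal line, the
#' element the segmentation pipeline specifies); `"ones"` is the usual
#' 5x5 square block. A custom 0/1 matrix with odd dimensions is also
#' accepted wherever a structuring element is expected.
#'
#' @param type `"identity"` or `"ones"`.
#' @return A 5x5 binary matrix.
#' @export
structuring_element <- function(type = c("identity", "ones")) {
  type <- match.arg(type)
  if (type == "identity") diag(5) else matrix(1, 5, 5)
}

se_offsets <- function(se) {
  if (!is.matrix(se) || nrow(se) %% 2 == 0 || ncol(se) %% 2 == 0)
    stop("structuring element must be an odd-sized matrix", call. = FALSE)
  ctr <- (dim(se) + 1) / 2
  w <- which(se != 0, arr.ind = TRUE)
  cbind(w[, 1] - ctr[1], w[, 2] - ctr[2])
}

# shift a matrix by (dr, dc), padding vacated cells with `pad`
shift_mat <- function(m, dr, dc, pad) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

#' Binary erosion and dilation
#'
#' Shift-and-combine implementations over the active cells of the
#' structuring element. Outside the image, dilation sees background (0)
#' and erosion sees foreground (1), the convention under which
#' opening/closing are dual through complementation.
#'
#' @param mask Binary 0/1 matrix.
#' @param se Structuring element (matrix, or a [structuring_element()]
#'   type name).
#' @return The eroded / dilated binary matrix.
#' @export
erode <- function(mask, se = structuring_element("identity")) {
  if (is.character(se)) se <- structuring_element(se)
  assert_mask(mask)
  off <- se_offsets(se)
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out * shift_mat(mask, -off[i, 1], -off[i, 2], pad = 1)
  out
}

#' @rdname erode
#' @export
dilate <- function(mask, se = structuring_element("identity")) {
  if (is.character(se)) se <- structuring_element(se)
  assert_mask(mask)
  off <- se_offsets(se)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- pmax(out, shift_mat(mask, off[i, 1], off[i, 2], pad = 0))
  out
}

#' Morphological opening and closing
#'
#' Opening is erosion followed by dilation (removes speckle smaller than
#' the structuring element); closing is dilation followed by erosion
#' (bridges narrow gaps). Both are idempotent; opening is anti-extensive
#' and closing extensive.
#'
#' @inheritParams erode
#' @return The opened / closed binary matrix.
#' @export
opening <- function(mask, se = structuring_element("identity")) {
  if (is.character(se)) se <- structuring_element(se)
  dilate(erode(mask, se), se)
}

#' @rdname opening
#' @export
closing <- function(mask, se = structuring_element("identity")) {
  if (is.character(se)) se <- structuring_element(se)
  erode(dilate(mask, se), se)
}

#' Fill enclosed holes in a binary mask
#'
#' Reconstructs the background reachable from the image border by
#' iterating conditional dilations `X_k = (X_{k-1} (+) B) intersect A^c`
#' from a border seed until a fixed point, then returns the union of the
#' mask with everything the reconstruction could not reach (the enclosed
#' holes). 4-connected background propagation.
#'
#' @param mask Binary 0/1 matrix.
#' @return The mask with all enclosed background regions set to 1;
#'   foreground components are unchanged.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  comp <- 1 - mask
  # border background seed
  x <- matrix(0, h, w)
  x[1, ] <- comp[1, ]; x[h, ] <- comp[h, ]
  x[, 1] <- comp[, 1]; x[, w] <- comp[, w]
  b <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)  # 4-connected cross
  repeat {
    x_new <- dilate(x, b) * comp
    if (all(x_new == x)) break
    x <- x_new
  }
  1 - x  # everything not reached from the border: A plus its holes
}

#' Segment candidate masses in an image
#'
#' Grayscale input is thresholded with [otsu_threshold()] on the intensity
#' channel directly (for R = G = B images the normalized chromatic
#' channels are constant and carry no contrast). Chromatic (3-channel)
#' input follows the colour-space route: RGB to XYZ, per-pixel
#' normalization of the R and X channels, Otsu on each, and intersection
#' of the two masks. Either way the binary mask is post-processed by hole
#' filling, opening and closing with the chosen structuring element.
#'
#' @param image Numeric matrix in `[0, 1]` (grayscale) or `h x w x 3`
#'   array (chromatic).
#' @param se Structuring element (matrix or type name; default the 5x5
#'   identity matrix).
#' @param channels `"auto"` (by input shape), `"gray"`, or `"xyz"`.
#' @return A binary 0/1 matrix of the same height/width as the input.
#' @export
segment_mass <- function(image, se = structuring_element("identity"),
                         channels = c("auto", "gray", "xyz")) {
  channels <- match.arg(channels)
  if (is.character(se)) se <- structuring_element(se)
  chromatic <- length(dim(image)) == 3
  if (channels == "auto") channels <- if (chromatic) "xyz" else "gray"

  if (channels == "xyz") {
    if (!chromatic) stop("`channels = \"xyz\"` needs a 3-channel image",
                         call. = FALSE)
    xyz <- rgb_to_xyz(image)
    nc <- normalize_channels(image, xyz)
    m1 <- (nc$Rhat > otsu_threshold(clamp(nc$Rhat, 0, 1))) * 1
    m2 <- (nc$Xhat > otsu_threshold(clamp(nc$Xhat, 0, 1))) * 1
    mask <- m1 * m2
  } else {
    gray <- if (chromatic) (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
    assert_gray(gray)
    mask <- (gray > otsu_threshold(gray)) * 1
  }
  mask <- fill_holes(mask)
  mask <- opening(mask, se)
  closing(mask, se)
}

#' Dice overlap between two binary masks
#'
#' @param a,b Binary 0/1 matrices of equal shape.
#' @return `2|A & B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
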