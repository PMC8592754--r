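# Gray-level co-occurrence matrices and the five Haralick statistics
# (homogeneity, correlation, energy, contrast, entropy) computed per
# wavelet subband.

#' Quantize a gray image to integer levels
#'
#' Linear floor-rule mapping of `[0, 1]` onto `0 .. levels - 1`, with 1.0
#' included in the top level.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param levels Number of gray levels (default 256).
#' @return Integer matrix of codes in `0 .. levels - 1`.
#' @export
quantize_gray <- function(image, levels = 256) {
  assert_gray(image)
  matrix(as.integer(pmin(floor(image * levels), levels - 1)),
         nrow(image), ncol(image))
}

glcm_offset <- function(d, angle) {
  switch(as.character(angle),
    "0"   = c(0, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0),
    "135" = c(-d, -d),
    stop("unsupported angle (use 0, 45, 90 or 135)", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered gray-level pairs `(i, j)` for pixels separated by the
#' offset defined by distance `d` and angle (0, 45, 90 or 135 degrees;
#' rows grow downward, so angle 0 is the horizontal neighbor). In
#' symmetric mode the transposed counts are added. The matrix is
#' normalized to sum to 1.
#'
#' @param image Integer matrix of gray codes in `0 .. levels - 1`, or a
#'   numeric matrix in `[0, 1]` (then quantized with [quantize_gray()]).
#' @param d Radial pixel distance (default 1).
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels (default 256).
#' @param symmetric Add the transpose before normalizing? Default `FALSE`.
#' @return A `levels x levels` matrix of relative frequencies summing to
#'   1, with attributes `d`, `angle`, `levels`.
#' @export
glcm <- function(image, d = 1, angle = 0, levels = 256, symmetric = FALSE) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  q <- if (is.integer(image)) image else quantize_gray(image, levels)
  if (any(q < 0 | q >= levels)) stop("gray codes out of range", call. = FALSE)
  off <- glcm_offset(d, angle)
  h <- nrow(q); w <- ncol(q)
  rs <- seq_len(h); cs <- seq_len(w)
  r_ok <- rs[rs + off[1] >= 1 & rs + off[1] <= h]
  c_ok <- cs[cs + off[2] >= 1 & cs + off[2] <= w]
  if (length(r_ok) == 0 || length(c_ok) == 0)
    stop("offset larger than the image", call. = FALSE)
  i <- q[r_ok, c_ok, drop = FALSE]
  j <- q[r_ok + off[1], c_ok + off[2], drop = FALSE]
  counts <- tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  attr(P, "d") <- d; attr(P, "angle") <- angle; attr(P, "levels") <- levels
  P
}

#' Haralick statistics of a normalized GLCM
#'
#' Computes, over 0-based gray codes `i, j` with frequencies `f(i, j)`:
#' homogeneity `H = sum f / (1 + (i - j)^2)`, correlation
#' `CR = (sum i j f - mu_i mu_j) / (sigma_i sigma_j)` (0 when either
#' marginal is degenerate), energy `E = sum f^2`, contrast
#' `CN = sum (i - j)^2 f`, and entropy `ER = -sum f log2 f` with
#' `0 log 0 = 0`. `verbatim_formulas = TRUE` instead reproduces the
#' tabulated entropy variant `-sum log2 f` over the nonzero cells (a form
#' without the `f` weight, kept for comparison).
#'
#' @param P Normalized GLCM (square matrix summing to 1).
#' @param verbatim_formulas Use the tabulated (unweighted) entropy sum?
#'   Default `FALSE` (standard Haralick form).
#' @return A one-row tibble with columns `H`, `CR`, `E`, `CN`, `ER`.
#' @export
haralick_features <- function(P, verbatim_formulas = FALSE) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("`P` must be a square matrix", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-8)
    stop("`P` must be normalized (sum to 1)", call. = FALSE)
  G <- nrow(P)
  g <- 0:(G - 1)
  I <- matrix(g, G, G)                  # row code i
  J <- matrix(g, G, G, byrow = TRUE)    # column code j
  D2 <- (I - J)^2

  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(g * pi_m); mu_j <- sum(g * pj_m)
  s_i <- sqrt(sum((g - mu_i)^2 * pi_m))
  s_j <- sqrt(sum((g - mu_j)^2 * pj_m))

  contrast <- sum(D2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + D2))
  nz <- P > 0
  entropy <- if (verbatim_formulas) {
    -sum(log2(P[nz]))
  } else {
    -sum(P[nz] * log2(P[nz]))
  }
  correlation <- if (s_i * s_j > 0) {
    (sum(I * J * P) - mu_i * mu_j) / (s_i * s_j)
  } else 0

  tibble::tibble(H = homogeneity, CR = correlation, E = energy,
                 CN = contrast, ER = entropy)
}

#' Wavelet-subband texture features of a masked region
#'
#' Crops the image to the mask's bounding box, runs a one-level wavelet
#' decomposition, and for each selected subband (default the approximation
#' LL and the vertical-detail HL) rescales the subband to `[0, 1]`,
#' quantizes to `levels` gray codes, averages the GLCM over the four
#' standard angles at distance `d`, and emits the five Haralick statistics
#' in the column order `H, CR, E, CN, ER`.
#'
#' @param image Gray image (numeric matrix in `[0, 1]`).
#' @param mask Binary 0/1 matrix of the same shape (must be nonempty).
#' @param subbands Character vector among `"LL"`, `"LH"`, `"HL"`, `"HH"`.
#' @param wavelet Wavelet name for [dwt_decompose()].
#' @param levels Gray levels for the GLCM (default 256).
#' @param d GLCM pixel distance (default 1).
#' @param angles GLCM angles averaged over (default the four standard
#'   ones).
#' @param verbatim_formulas Passed to [haralick_features()].
#' @return A tibble with one row per subband: columns `subband`, `H`,
#'   `CR`, `E`, `CN`, `ER`.
#' @export
extract_features <- function(image, mask, subbands = c("LL", "HL"),
                             wavelet = "haar", levels = 256, d = 1,
                             angles = c(0, 45, 90, 135),
                             verbatim_formulas = FALSE) {
  assert_gray(image); assert_mask(mask)
  if (!all(dim(image) == dim(mask))) stop("shape mismatch", call. = FALSE)
  if (sum(mask) == 0) stop("empty mask: no region to describe", call. = FALSE)
  subbands <- match.arg(subbands, c("LL", "LH", "HL", "HH"),
                        several.ok = TRUE)

  w <- which(mask == 1, arr.ind = TRUE)
  r <- range(w[, 1]); cc <- range(w[, 2])
  # widen the bounding box to even side lengths (the wavelet level halves)
  widen <- function(lo, hi, n) {
    if ((hi - lo + 1) %% 2 == 1) {
      if (hi < n) hi <- hi + 1 else lo <- max(1, lo - 1)
    }
    c(lo, hi)
  }
  r <- widen(r[1], r[2], nrow(image))
  cc <- widen(cc[1], cc[2], ncol(image))
  crop <- image[r[1]:r[2], cc[1]:cc[2], drop = FALSE]
  if (any(dim(crop) < 2))
    stop("mask region too small for a wavelet level", call. = FALSE)

  dec <- dwt_decompose(crop, wavelet = wavelet, levels = 1)$levels[[1]]

  rows <- purrr::map(subbands, function(sb) {
    band <- dec[[sb]]
    rng <- range(band)
    scaled <- if (diff(rng) > 0) (band - rng[1]) / diff(rng)
              else matrix(0, nrow(band), ncol(band))
    q <- quantize_gray(scaled, levels)
    Ps <- purrr::map(angles, ~ glcm(q, d = d, angle = .x, levels = levels))
    P <- Reduce(`+`, Ps) / length(Ps)
    dplyr::bind_cols(tibble::tibble(subband = sb),
                     haralick_features(P, verbatim_formulas))
  })
  dplyr::bind_rows(rows)
}

#' Flatten a per-subband feature table into one feature vector
#'
#' @param features A tibble from [extract_features()].
#' @return Named numeric vector `<subband>_<stat>` in table order.
#' @export
feature_vector <- function(features) {
  stats_cols <- c("H", "CR", "E", "CN", "ER")
  v <- unlist(lapply(seq_len(nrow(features)), function(i)
    as.numeric(features[i, stats_cols])))
  names(v) <- as.vector(t(outer(features$subband, stats_cols, paste, sep = "_")))
  v
}
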