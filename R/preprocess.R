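# Contrast enhancement and Wang-Mendel fuzzy-rule noise reduction.

#' Lookup-table contrast stretch
#'
#' Linearly rescales intensities so the darkest pixel maps to 0 and the
#' brightest to 1, applied through a 65,536-entry (16-bit) lookup table:
#' every input intensity is quantized to 16 bits and mapped through the
#' precomputed table, the way batch image pipelines store the transform.
#' The LUT path agrees with the exact affine map to within the 16-bit
#' quantization step.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @return The stretched image; its minimum is exactly 0 and maximum
#'   exactly 1. Monotone (order-preserving) and idempotent up to LUT
#'   quantization.
#' @export
contrast_stretch <- function(image) {
  assert_gray(image)
  n_lut <- 65536L
  q <- function(x) as.integer(round(x * (n_lut - 1L)))  # 16-bit code
  lo <- min(image); hi <- max(image)
  if (hi <= lo)
    stop("constant image: contrast stretch is undefined (zero range)",
         call. = FALSE)
  lo_q <- q(lo); hi_q <- q(hi)
  codes <- 0:(n_lut - 1L)
  lut <- clamp((codes - lo_q) / (hi_q - lo_q), 0, 1)
  out <- matrix(lut[q(image) + 1L], nrow(image), ncol(image))
  out
}

# triangular Ruspini partition of [0,1] with k labels: label centers at
# seq(0, 1, length.out = k); any value activates at most two adjacent
# labels with memberships summing to 1
fuzzy_labels <- function(values, k) {
  pos <- clamp(values, 0, 1) * (k - 1)
  lo <- pmin(floor(pos), k - 2)            # 0-based lower label
  frac <- pos - lo
  list(lo = as.integer(lo) + 1L,           # 1-based
       hi = as.integer(lo) + 2L,
       mu_lo = 1 - frac, mu_hi = frac)
}

fuzzy_centers <- function(k) seq(0, 1, length.out = k)

# nearest (max-membership) label and its membership
fuzzy_best <- function(values, k) {
  fl <- fuzzy_labels(values, k)
  use_hi <- fl$mu_hi > fl$mu_lo
  list(label = ifelse(use_hi, fl$hi, fl$lo),
       mu = pmax(fl$mu_lo, fl$mu_hi))
}

# 3x3 neighborhood mean with reflected borders
local_mean3 <- function(image) {
  h <- nrow(image); w <- ncol(image)
  ri <- c(1, seq_len(h), h)  # reflect pad by one
  ci <- c(1, seq_len(w), w)
  p <- image[ri, ci]
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + seq_len(h), dc + seq_len(w)]
  acc / 9
}

#' Learn a Wang-Mendel fuzzy rule base from a noisy/reference image pair
#'
#' Implements the Wang-Mendel procedure on pixels: the antecedent space is
#' the center-pixel intensity and the 3x3 neighborhood mean (reflected
#' borders), each fuzzified over `k_partitions` triangular memberships; the
#' consequent is the fuzzified reference intensity. Every pixel proposes
#' one candidate rule whose degree is the product of the max memberships of
#' its antecedents and consequent; within each antecedent combination only
#' the maximum-degree rule is kept.
#'
#' @param noisy Noisy image (numeric matrix in `[0, 1]`).
#' @param reference Clean/reference image of the same shape (on real data,
#'   a median-filtered copy can serve).
#' @param k_partitions Number of fuzzy labels per variable (>= 2).
#' @return An object of class `wm_rules`: list with `k` and `rules`, a
#'   tibble with columns `a_center`, `a_mean`, `consequent` (label
#'   indices) and `degree`.
#' @export
wm_build_rules <- function(noisy, reference, k_partitions = 7) {
  assert_gray(noisy, "noisy"); assert_gray(reference, "reference")
  if (!all(dim(noisy) == dim(reference)))
    stop("`noisy` and `reference` must have the same shape", call. = FALSE)
  if (k_partitions < 2) stop("`k_partitions` must be >= 2", call. = FALSE)
  k <- as.integer(k_partitions)

  a1 <- fuzzy_best(as.vector(noisy), k)
  a2 <- fuzzy_best(as.vector(local_mean3(noisy)), k)
  co <- fuzzy_best(as.vector(reference), k)
  cand <- tibble::tibble(
    a_center = a1$label, a_mean = a2$label, consequent = co$label,
    degree = a1$mu * a2$mu * co$mu
  )
  rules <- cand |>
    dplyr::group_by(.data$a_center, .data$a_mean) |>
    dplyr::slice_max(.data$degree, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(list(k = k, rules = rules), class = "wm_rules")
}

#' @export
print.wm_rules <- function(x, ...) {
  cat(sprintf("<wm_rules> %d rules over a %d x %d antecedent grid\n",
              nrow(x$rules), x$k, x$k))
  invisible(x)
}

#' Apply a Wang-Mendel rule base to denoise an image
#'
#' Product inference with centroid defuzzification: for every pixel the
#' firing strength of each stored rule is the product of the pixel's
#' antecedent memberships (center value and 3x3 mean), and the output is
#' the firing-weighted mean of the consequent label centers. Pixels firing
#' no rule pass through unchanged.
#'
#' @param image Image to denoise (numeric matrix in `[0, 1]`).
#' @param rules A [wm_build_rules()] result.
#' @return The denoised image, values in `[0, 1]`.
#' @export
wm_denoise <- function(image, rules) {
  assert_gray(image)
  stopifnot(inherits(rules, "wm_rules"))
  if (nrow(rules$rules) == 0) stop("empty rule base", call. = FALSE)
  k <- rules$k
  centers <- fuzzy_centers(k)

  # rule lookup tables over the k x k antecedent grid
  has_rule <- matrix(FALSE, k, k)
  cons <- matrix(0, k, k)
  idx <- cbind(rules$rules$a_center, rules$rules$a_mean)
  has_rule[idx] <- TRUE
  cons[idx] <- centers[rules$rules$consequent]

  f1 <- fuzzy_labels(as.vector(image), k)
  f2 <- fuzzy_labels(as.vector(local_mean3(image)), k)

  num <- 0; den <- 0
  for (s1 in c("lo", "hi")) for (s2 in c("lo", "hi")) {
    l1 <- f1[[s1]]; l2 <- f2[[s2]]
    w <- f1[[paste0("mu_", s1)]] * f2[[paste0("mu_", s2)]]
    ii <- cbind(l1, l2)
    fire <- w * has_rule[ii]
    num <- num + fire * cons[ii]
    den <- den + fire
  }
  out <- as.vector(image)
  hit <- den > 0
  out[hit] <- num[hit] / den[hit]
  matrix(clamp(out, 0, 1), nrow(image), ncol(image))
}
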