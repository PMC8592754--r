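# Synthetic MIAS-like phantom mammograms with ground truth, so every
# pipeline stage is testable without external data.

# separable Gaussian blur used for the correlated texture field
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(outer(seq_len(h), -r:r, `+`), 1), h)
  blur_rows <- matrix(0, h, w)
  for (s in seq_along(k))
    blur_rows <- blur_rows + k[s] * m[ri[, s], , drop = FALSE]
  ci <- pmin(pmax(outer(seq_len(w), -r:r, `+`), 1), w)
  out <- matrix(0, h, w)
  for (s in seq_along(k))
    out <- out + k[s] * blur_rows[, ci[, s], drop = FALSE]
  out
}

#' Specify a phantom mammogram
#'
#' The phantom is a dark frame holding a large elliptical breast field
#' with a smooth intensity gradient, optionally one compact bright mass
#' with a sharp (super-Gaussian) margin, a correlated texture field inside
#' the mass (rough for malignant, smooth for benign), and i.i.d. Gaussian
#' pixel noise. The class signal lives purely in the mass texture
#' statistics, the space the downstream GLCM features measure.
#'
#' @param size Image side in pixels (square; default 128, scalable to
#'   1024 for full MIAS-like frames).
#' @param mass_present Include a mass? Default `TRUE`.
#' @param mass_center Mass center (row, col); `NULL` centers it inside
#'   the breast field.
#' @param mass_radius Half-maximum radius of the mass profile, pixels.
#' @param mass_contrast Peak intensity of the mass above the local breast
#'   field, in `(0, 1]`.
#' @param roughness Correlation length (pixels) of the mass texture;
#'   smaller is rougher.
#' @param texture_amp Standard deviation of the texture field.
#' @param noise_sigma Standard deviation of the i.i.d. Gaussian noise.
#' @param label `"benign"` or `"malignant"` (controls nothing by itself;
#'   class presets live in [generate_dataset()]).
#' @param seed Integer seed making the phantom reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 128, mass_present = TRUE,
                         mass_center = NULL, mass_radius = NULL,
                         mass_contrast = 0.5, roughness = 2,
                         texture_amp = 0.05, noise_sigma = 0.02,
                         label = "benign", seed = 1) {
  if (mass_contrast <= 0 || mass_contrast > 1)
    stop("`mass_contrast` must be in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (is.null(mass_radius)) mass_radius <- round(size * 0.09)
  if (is.null(mass_center)) mass_center <- c(size * 0.45, size * 0.55)
  structure(list(size = as.integer(size), mass_present = mass_present,
                 mass_center = mass_center, mass_radius = mass_radius,
                 mass_contrast = mass_contrast, roughness = roughness,
                 texture_amp = texture_amp, noise_sigma = noise_sigma,
                 label = label, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom mammogram with ground truth
#'
#' Composes background (0.46), breast-field plateau (about 0.52 with a
#' smooth radial gradient), optional mass (super-Gaussian profile of the
#' requested contrast), mass-confined correlated texture, and Gaussian
#' noise, clipped to `[0, 1]`. The truth mask marks pixels where the
#' noise-free mass profile is at least half the contrast.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (matrix in `[0, 1]`), `truth_mask` (binary
#'   matrix), and `label`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  # breast ellipse filling most of the frame
  e_c <- c(n / 2, n / 2)
  e_ax <- c(0.46 * n, 0.42 * n)
  er2 <- ((rr - e_c[1]) / e_ax[1])^2 + ((cc - e_c[2]) / e_ax[2])^2
  breast <- er2 <= 1
  # background sits just below the breast plateau so the image histogram is
  # effectively bimodal (tissue vs mass); see the methods vignette
  field <- 0.46 + breast * (0.06 + 0.06 * (1 - er2) * breast)

  profile <- matrix(0, n, n)
  truth <- matrix(0, n, n)
  if (spec$mass_present) {
    mc <- spec$mass_center
    if (((mc[1] - e_c[1]) / e_ax[1])^2 + ((mc[2] - e_c[2]) / e_ax[2])^2 > 0.8)
      stop("mass center lies outside the breast field", call. = FALSE)
    # super-Gaussian (exponent 6): compact mass with a sharp margin
    sg <- spec$mass_radius / log(2)^(1 / 6)
    r2 <- ((rr - mc[1])^2 + (cc - mc[2])^2) / sg^2
    profile <- spec$mass_contrast * exp(-r2^3)
    truth[profile >= spec$mass_contrast / 2] <- 1

    texture <- matrix(rnorm(n * n), n, n)
    texture <- gaussian_blur(texture, spec$roughness)
    s <- stats::sd(as.vector(texture))
    if (s > 0) texture <- texture / s * spec$texture_amp
    # confine the texture to the mass support
    profile <- profile + texture * (profile > 0.05 * spec$mass_contrast)
  }

  img <- field + profile +
    if (spec$noise_sigma > 0) matrix(rnorm(n * n, sd = spec$noise_sigma), n, n)
    else 0
  list(image = clamp(img, 0, 1), truth_mask = truth, label = spec$label)
}

#' Generate a reproducible phantom cohort
#'
#' Benign phantoms get smooth low-amplitude mass texture (correlation
#' length 3.5 px, amplitude 0.03); malignant phantoms rough high-amplitude
#' texture (1 px, 0.10). Per-sample seeds derive from the master seed,
#' so the whole cohort is reproducible.
#'
#' @param n Number of phantoms (>= 2).
#' @param class_balance Fraction of benign samples (default 0.5).
#' @param seed Master seed.
#' @param size Image side in pixels.
#' @param mass_contrast,noise_sigma Shared mass contrast and noise level.
#' @return List with `images` (list of matrices), `masks`, `labels`
#'   (factor benign/malignant), and `manifest`, a tibble of per-sample
#'   parameters.
#' @export
generate_dataset <- function(n, class_balance = 0.5, seed = 1, size = 128,
                             mass_contrast = 0.5, noise_sigma = 0.02) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  n_benign <- round(n * class_balance)
  labels <- factor(c(rep("benign", n_benign),
                     rep("malignant", n - n_benign)),
                   levels = c("benign", "malignant"))
  presets <- list(
    benign = list(roughness = 3.5, texture_amp = 0.03),
    malignant = list(roughness = 1.0, texture_amp = 0.10)
  )
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  # jitter mass geometry deterministically per sample
  centers_r <- runif(n, 0.40, 0.55) * size
  centers_c <- runif(n, 0.40, 0.60) * size
  radii <- round(runif(n, 0.085, 0.115) * size)

  out <- purrr::map(seq_len(n), function(i) {
    p <- presets[[as.character(labels[i])]]
    sp <- phantom_spec(size = size, mass_center = c(centers_r[i], centers_c[i]),
                       mass_radius = radii[i], mass_contrast = mass_contrast,
                       roughness = p$roughness, texture_amp = p$texture_amp,
                       noise_sigma = noise_sigma,
                       label = as.character(labels[i]),
                       seed = sample_seeds[i])
    list(spec = sp, phantom = generate_phantom(sp))
  })
  manifest <- tibble::tibble(
    id = seq_len(n), label = labels, seed = sample_seeds,
    center_row = centers_r, center_col = centers_c, radius = radii,
    contrast = mass_contrast, noise_sigma = noise_sigma
  )
  list(images = purrr::map(out, ~ .x$phantom$image),
       masks = purrr::map(out, ~ .x$phantom$truth_mask),
       labels = labels, manifest = manifest)
}
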