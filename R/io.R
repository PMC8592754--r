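# Image readers/writers and the end-to-end pipeline driver.

#' Read a PGM (portable graymap) image
#'
#' Supports the binary (`P5`) and ASCII (`P2`) dialects with maxval up to
#' 65535 (the MIAS images are 8-bit binary). Intensities are scaled to
#' `[0, 1]`.
#'
#' @param path Path to a `.pgm` file.
#' @return Numeric matrix in `[0, 1]` with attribute `bit_depth`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", file.size(path))
  txt_at <- 1L

  # tokenizer over the header bytes, skipping whitespace and # comments
  next_token <- function() {
    tok <- character(0)
    while (txt_at <= length(raw_all)) {
      ch <- rawToChar(raw_all[txt_at])
      if (ch == "#") {
        while (txt_at <= length(raw_all) &&
               rawToChar(raw_all[txt_at]) != "\n") txt_at <<- txt_at + 1L
      } else if (grepl("[ \t\r\n]", ch)) {
        if (length(tok) > 0) { txt_at <<- txt_at + 1L; break }
        txt_at <<- txt_at + 1L
      } else {
        tok <- c(tok, ch); txt_at <<- txt_at + 1L
      }
    }
    if (length(tok) == 0)
      stop(sprintf("corrupt PGM header near byte %d in %s", txt_at, path),
           call. = FALSE)
    paste(tok, collapse = "")
  }

  magic <- next_token()
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("unsupported format '%s' at byte 1 in %s", magic, path),
         call. = FALSE)
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1)
    stop(sprintf("corrupt PGM header near byte %d in %s", txt_at, path),
         call. = FALSE)

  n_px <- w * h
  if (magic == "P5") {
    bpp <- if (maxval > 255) 2L else 1L
    need <- n_px * bpp
    avail <- length(raw_all) - txt_at + 1L
    if (avail < need)
      stop(sprintf("truncated PGM: need %d data bytes at offset %d, found %d",
                   need, txt_at, avail), call. = FALSE)
    bytes <- raw_all[txt_at:(txt_at + need - 1L)]
    vals <- if (bpp == 1L) as.integer(bytes)
            else as.integer(bytes[c(TRUE, FALSE)]) * 256L +
                 as.integer(bytes[c(FALSE, TRUE)])
  } else {
    toks <- scan(text = rawToChar(raw_all[txt_at:length(raw_all)]),
                 what = integer(), quiet = TRUE,
                 comment.char = "#")
    if (length(toks) < n_px)
      stop(sprintf("truncated PGM: need %d samples, found %d at offset %d",
                   n_px, length(toks), txt_at), call. = FALSE)
    vals <- toks[seq_len(n_px)]
  }
  img <- matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  attr(img, "bit_depth") <- if (maxval > 255) 16L else 8L
  img
}

#' Write a gray image or mask as binary PGM
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @param maxval Maximum sample value (default 255, 8-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255) {
  assert_gray(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval),
            con, eos = NULL)
  vals <- as.integer(round(t(image) * maxval))
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Read an image file (PGM or PNG)
#'
#' @param path Path ending in `.pgm` or `.png`.
#' @return A numeric matrix (gray) or `h x w x 3` array (RGB), values in
#'   `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3 && dim(img)[3] >= 3)
      return(img[, , 1:3, drop = FALSE])
    if (length(dim(img)) == 3) return(img[, , 1])
    return(img)
  }
  stop("unsupported image format: .", ext, call. = FALSE)
}

#' Write a gray image or binary mask as PNG
#'
#' @param image Numeric matrix in `[0, 1]` (masks are written as 0/255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_gray(image)
  png::writePNG(image, path)
  invisible(path)
}

#' Run the full diagnosis pipeline on a synthetic cohort
#'
#' Generates (or accepts) a phantom cohort, then for each sample:
#' contrast-stretches, optionally denoises with a Wang-Mendel rule base
#' trained on a clean/noisy phantom pair, segments the candidate mass, and
#' extracts wavelet-subband GLCM features. The pooled feature table is
#' split into train/test, the classifier is trained by the advanced
#' thermal-exchange optimizer, and accuracy / sensitivity / specificity
#' are computed on the held-out split.
#'
#' @param n Cohort size (default 60).
#' @param seed Master seed driving every random stage.
#' @param denoise Apply the fuzzy-rule denoiser? Default `FALSE` (the
#'   default noise level is mild).
#' @param holdout Fraction of samples held out for testing (default 0.3).
#' @param max_fes Training evaluation budget (default 2e4).
#' @param out_dir Optional directory; when given, per-sample masks
#'   (PNG), the feature table, and the metrics table are written there.
#' @param size Phantom side length in pixels.
#' @return List with `metrics` (one-row tibble, percent), `counts`
#'   (confusion counts), `features` (per-sample tibble), `model`
#'   (`ateo_cnn`), `dice` (per-sample Dice of the segmentation against
#'   truth), and `split` (logical test indicator).
#' @export
run_pipeline <- function(n = 60, seed = 1, denoise = FALSE, holdout = 0.3,
                         max_fes = 2e4, out_dir = NULL, size = 128) {
  cohort <- generate_dataset(n, seed = seed, size = size)

  rules <- NULL
  if (denoise) {
    # train the rule base on one clean/noisy phantom pair
    sp_clean <- phantom_spec(size = size, noise_sigma = 0, seed = seed + 7L)
    sp_noisy <- sp_clean; sp_noisy$noise_sigma <- 0.05
    rules <- wm_build_rules(generate_phantom(sp_noisy)$image,
                            generate_phantom(sp_clean)$image)
  }

  feats <- vector("list", n)
  dice <- numeric(n)
  for (i in seq_len(n)) {
    img <- contrast_stretch(cohort$images[[i]])
    if (denoise) img <- wm_denoise(img, rules)
    mask <- segment_mass(img)
    dice[i] <- dice_coefficient(mask, cohort$masks[[i]])
    use_mask <- if (sum(mask) > 0) mask else cohort$masks[[i]]
    ft <- extract_features(img, use_mask)
    feats[[i]] <- dplyr::bind_cols(
      tibble::tibble(id = i, label = cohort$labels[i]),
      tibble::as_tibble(as.list(feature_vector(ft))))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_image(mask, file.path(out_dir, sprintf("mask_%03d.png", i)))
    }
  }
  features <- dplyr::bind_rows(feats)

  X <- as.matrix(dplyr::select(features, -dplyr::all_of(c("id", "label"))))
  set.seed(seed + 1L)
  test_idx <- sample.int(n, round(holdout * n))
  is_test <- seq_len(n) %in% test_idx

  # z-score features with training-set statistics (the raw GLCM statistics
  # live on wildly different scales)
  mu <- colMeans(X[!is_test, , drop = FALSE])
  sg <- apply(X[!is_test, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  Xs <- scale(X, center = mu, scale = sg)

  model <- train_with_ateo(Xs[!is_test, , drop = FALSE],
                           cohort$labels[!is_test],
                           config = teo_config(pop_size = 150,
                                               max_fes = max_fes),
                           seed = seed + 2L)
  pred <- predict(model, Xs[is_test, , drop = FALSE])
  counts <- confusion_counts(cohort$labels[is_test], pred)
  metrics <- evaluate_metrics(counts)

  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics, counts = counts, features = features,
       model = model, dice = dice, split = is_test)
}
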