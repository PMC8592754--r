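# Independent oracles used across the suite. These deliberately use slow,
# direct formulations (explicit loops and sums) so they share no code with
# the implementation they check.

# exhaustive Otsu: between/within-class variance for every split, by
# direct per-class summation
oracle_otsu <- function(counts) {
  n <- sum(counts)
  g <- seq_along(counts) - 1
  p <- counts / n
  mu_tot <- sum(p * g)
  var_tot <- sum(p * (g - mu_tot)^2)
  ks <- seq_len(length(counts) - 1)
  sb <- sw <- numeric(length(ks))
  for (k in ks) {
    i1 <- 1:k; i2 <- (k + 1):length(counts)
    w1 <- sum(p[i1]); w2 <- sum(p[i2])
    m1 <- if (w1 > 0) sum(p[i1] * g[i1]) / w1 else 0
    m2 <- if (w2 > 0) sum(p[i2] * g[i2]) / w2 else 0
    v1 <- if (w1 > 0) sum(p[i1] * (g[i1] - m1)^2) / w1 else 0
    v2 <- if (w2 > 0) sum(p[i2] * (g[i2] - m2)^2) / w2 else 0
    sb[k] <- w1 * w2 * (m1 - m2)^2
    sw[k] <- w1 * v1 + w2 * v2
  }
  list(k_best = which.max(sb), sigma_b2 = sb, sigma_w2 = sw,
       var_tot = var_tot)
}

# brute-force co-occurrence counts: visit every pixel pair explicitly
oracle_glcm <- function(q, d, angle, levels) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cl in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cl + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      P[q[r, cl] + 1, q[r2, c2] + 1] <- P[q[r, cl] + 1, q[r2, c2] + 1] + 1
  }
  P / sum(P)
}

# Haralick statistics by explicit double sums
oracle_haralick <- function(P) {
  G <- nrow(P)
  H <- CR <- E <- CN <- ER <- 0
  mu_i <- mu_j <- 0
  for (i in 1:G) for (j in 1:G) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  s_i <- s_j <- 0
  for (i in 1:G) for (j in 1:G) {
    s_i <- s_i + (i - 1 - mu_i)^2 * P[i, j]
    s_j <- s_j + (j - 1 - mu_j)^2 * P[i, j]
  }
  s_i <- sqrt(s_i); s_j <- sqrt(s_j)
  for (i in 1:G) for (j in 1:G) {
    f <- P[i, j]
    H <- H + f / (1 + (i - j)^2)
    E <- E + f^2
    CN <- CN + (i - j)^2 * f
    if (f > 0) ER <- ER - f * log2(f)
    if (s_i > 0 && s_j > 0)
      CR <- CR + ((i - 1 - mu_i) * (j - 1 - mu_j) * f) / (s_i * s_j)
  }
  c(H = H, CR = CR, E = E, CN = CN, ER = ER)
}

# queue-based 4-connected flood fill from the border background
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reached <- matrix(FALSE, h, w)
  queue <- list()
  push <- function(r, c) queue[[length(queue) + 1]] <<- c(r, c)
  for (r in 1:h) for (cl in c(1, w))
    if (mask[r, cl] == 0) push(r, cl)
  for (cl in 1:w) for (r in c(1, h))
    if (mask[r, cl] == 0) push(r, cl)
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    r <- p[1]; cl <- p[2]
    if (reached[r, cl]) next
    reached[r, cl] <- TRUE
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + dd[1]; c2 <- cl + dd[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          mask[r2, c2] == 0 && !reached[r2, c2])
        push(r2, c2)
    }
  }
  out <- mask
  out[!reached & mask == 0] <- 1
  out
}

random_mask <- function(h = 20, w = 20, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# small random blob mask with punched holes
blob_mask <- function(n = 32) {
  m <- matrix(0, n, n)
  for (b in 1:3) {
    ctr <- sample(5:(n - 5), 2)
    r <- sample(3:6, 1)
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    m[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2] <- 1
  }
  holes <- sample(which(m == 1), min(5, sum(m)))
  m[holes] <- 0
  m
}
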