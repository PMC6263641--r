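# Independent oracles and small fixtures shared across the suite.

# Brute-force Haralick descriptors by naive double/triple loops, written
# directly from the textbook definitions and independent of the package's
# vectorised implementation.  Natural logs; zero cells contribute nothing.
haralick_oracle <- function(P) {
  G <- nrow(P)
  px <- numeric(G)
  py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mu_x <- sum((1:G) * px)
  mu_y <- sum((1:G) * py)
  sd_x <- sqrt(sum(((1:G) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:G) - mu_y)^2 * py))

  p_sum <- numeric(2 * G - 1)  # index k-1, k = 2..2G
  p_diff <- numeric(G)         # index d+1, d = 0..G-1
  for (i in 1:G) for (j in 1:G) {
    p_sum[i + j - 1] <- p_sum[i + j - 1] + P[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + P[i, j]
  }

  asm <- 0; contrast <- 0; corr_num <- 0; variance <- 0; idm <- 0; ent <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    corr_num <- corr_num + i * j * p
    variance <- variance + (i - mu_x)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
  }
  for (d in 0:(G - 1)) contrast <- contrast + d^2 * p_diff[d + 1]
  correlation <- if (sd_x * sd_y > 0) (corr_num - mu_x * mu_y) / (sd_x * sd_y) else 0

  sum_average <- 0
  for (k in 2:(2 * G)) sum_average <- sum_average + k * p_sum[k - 1]
  sum_variance <- 0
  for (k in 2:(2 * G)) sum_variance <- sum_variance + (k - sum_average)^2 * p_sum[k - 1]
  sum_entropy <- 0
  for (k in 2:(2 * G)) if (p_sum[k - 1] > 0) {
    sum_entropy <- sum_entropy - p_sum[k - 1] * log(p_sum[k - 1])
  }
  diff_mean <- 0
  for (d in 0:(G - 1)) diff_mean <- diff_mean + d * p_diff[d + 1]
  diff_variance <- 0
  for (d in 0:(G - 1)) diff_variance <- diff_variance + (d - diff_mean)^2 * p_diff[d + 1]
  diff_entropy <- 0
  for (d in 0:(G - 1)) if (p_diff[d + 1] > 0) {
    diff_entropy <- diff_entropy - p_diff[d + 1] * log(p_diff[d + 1])
  }

  hx <- 0; hy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) if (px[i] > 0) hx <- hx - px[i] * log(px[i])
  for (j in 1:G) if (py[j] > 0) hy <- hy - py[j] * log(py[j])
  for (i in 1:G) for (j in 1:G) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(pp)
      hxy2 <- hxy2 - pp * log(pp)
    }
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  sx <- which(px > 0)
  sy <- which(py > 0)
  mcc <- if (length(sx) < 2 || length(sy) < 2) 0 else {
    Q <- matrix(0, length(sx), length(sx))
    for (a in seq_along(sx)) for (b in seq_along(sx)) {
      s <- 0
      for (kk in seq_along(sy)) {
        s <- s + P[sx[a], sy[kk]] * P[sx[b], sy[kk]] / (px[sx[a]] * py[sy[kk]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(max(ev[2], 0), 1))
  }

  c(glcm_asm = asm, glcm_contrast = contrast, glcm_correlation = correlation,
    glcm_variance = variance, glcm_idm = idm, glcm_sum_average = sum_average,
    glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
    glcm_entropy = ent, glcm_diff_variance = diff_variance,
    glcm_diff_entropy = diff_entropy, glcm_imc1 = imc1, glcm_imc2 = imc2,
    glcm_mcc = mcc)
}

# random normalised GLCM of size G
random_glcm <- function(G) {
  M <- matrix(stats::runif(G * G), G, G)
  M / sum(M)
}

# small, fast scene configuration used by most image tests
tiny_config <- function(fruits_per_batch = c(4L, 6L), ...) {
  scene_config(image_width = 160L, image_height = 120L,
               fruits_per_batch = fruits_per_batch,
               fruit_axis_px = c(8, 12), ...)
}

# uniform-colour batch image
flat_image <- function(r, g, b, h = 8L, w = 10L, batch_id = "flat") {
  px <- array(0, dim = c(h, w, 3L))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  batch_image(px, batch_id = batch_id)
}
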