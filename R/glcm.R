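# Grey-level co-occurrence matrices and the 14 Haralick texture
# descriptors.  The GLCM is the joint distribution of quantised grey-level
# pairs at a set of spatial offsets; on masked tray images only pixel pairs
# that fall entirely on fruit are counted, otherwise the zeroed background
# would dominate every statistic.

#' Default GLCM offsets
#'
#' Distance-1 neighbours at 0, 45, 90 and 135 degrees, as `(dy, dx)` pairs
#' with rows increasing downwards.
#'
#' @return list of length-2 integer vectors.
#' @export
glcm_offsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Compute a grey-level co-occurrence matrix
#'
#' Grey levels in `[0, 255]` are quantised into `levels` equal bins over the
#' full 8-bit range (so matrices are comparable across images).  For each
#' offset, every pixel pair whose two members are both inside the mask
#' contributes one count; counts accumulate over offsets, the transpose is
#' added in symmetric mode, and the matrix is normalised to sum to 1.
#'
#' @param grey `H x W` matrix of grey levels in `[0, 255]`.
#' @param mask optional `fruit_mask`; `NULL` counts all pairs.
#' @param levels number of quantisation levels (default 64).
#' @param offsets list of `(dy, dx)` integer pairs; default [glcm_offsets()].
#' @param symmetric add the transposed counts (default `TRUE`).
#' @return a `glcm` object: the `levels x levels` probability matrix with
#'   attributes `levels`, `offsets`, `symmetric`, `n_pairs`.
#' @export
compute_glcm <- function(grey, mask = NULL, levels = 64L,
                         offsets = glcm_offsets(), symmetric = TRUE) {
  if (!is.matrix(grey)) {
    stop_olivescan("grey must be an H x W matrix", "olivescan_image_error")
  }
  levels <- as.integer(levels)
  if (levels < 2L) stop_olivescan("levels must be >= 2", "olivescan_glcm_error")
  if (length(offsets) == 0L) stop_olivescan("offsets must be nonempty", "olivescan_glcm_error")
  H <- nrow(grey)
  W <- ncol(grey)
  m <- if (is.null(mask)) matrix(TRUE, H, W) else mask$mask
  if (!identical(dim(m), dim(grey))) {
    stop_olivescan("grey and mask shapes differ", "olivescan_image_error")
  }
  q <- matrix(pmin(levels, floor(grey * levels / 256) + 1L), H, W)

  counts <- numeric(levels * levels)
  total <- 0L
  for (off in offsets) {
    dy <- off[1]
    dx <- off[2]
    r1 <- max(1L, 1L - dy):min(H, H - dy)
    c1 <- max(1L, 1L - dx):min(W, W - dx)
    if (length(r1) < 1L || length(c1) < 1L) next
    i1 <- q[r1, c1, drop = FALSE]
    i2 <- q[r1 + dy, c1 + dx, drop = FALSE]
    ok <- m[r1, c1, drop = FALSE] & m[r1 + dy, c1 + dx, drop = FALSE]
    if (!any(ok)) next
    idx <- (i1[ok] - 1L) * levels + i2[ok]
    counts <- counts + tabulate(idx, nbins = levels * levels)
    total <- total + sum(ok)
  }
  if (total == 0L) {
    stop_olivescan("no valid pixel pair inside the mask", "olivescan_glcm_error")
  }
  P <- matrix(counts, levels, levels, byrow = TRUE) # row = first pixel level
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  structure(P, class = c("glcm", "matrix"),
            levels = levels, offsets = offsets, symmetric = symmetric,
            n_pairs = total)
}

#' The 14 Haralick texture descriptors of a normalised GLCM
#'
#' Computes, in fixed order: angular second moment, contrast, correlation,
#' variance (of the row marginal), inverse difference moment, sum average,
#' sum variance (about the sum average), sum entropy, entropy, difference
#' variance, difference entropy, the two information measures of
#' correlation, and the maximal correlation coefficient (square root of the
#' second-largest eigenvalue of the Q matrix, clipped to `[0, 1]`).
#'
#' All entropies use natural logarithms; zero-probability cells contribute
#' zero.  Degenerate matrices are handled without exceptions: when a
#' marginal is concentrated on a single level, correlation and the first
#' information measure are defined as 0, and the maximal correlation
#' coefficient is defined as 0 with attribute `mcc_degenerate = TRUE` on
#' the result.
#'
#' @param glcm a `glcm` from [compute_glcm()], or any square nonnegative
#'   matrix summing to 1.
#' @return named numeric vector of length 14 (`glcm_asm` ... `glcm_mcc`).
#' @export
haralick_features <- function(glcm) {
  P <- unclass(glcm)
  attributes(P) <- attributes(P)["dim"]
  G <- nrow(P)
  if (is.null(G) || G != ncol(P)) {
    stop_olivescan("GLCM must be square", "olivescan_glcm_error")
  }
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9) {
    stop_olivescan("GLCM must be nonnegative and sum to 1", "olivescan_glcm_error")
  }
  i <- seq_len(G)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(i * px)
  mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px))
  sd_y <- sqrt(sum((i - mu_y)^2 * py))

  ii <- matrix(i, G, G)
  jj <- t(ii)
  diffs <- abs(ii - jj)

  # p_{x+y}(k), k = 2..2G and p_{x-y}(d), d = 0..G-1
  p_sum <- vapply(2:(2 * G), function(k) sum(P[ii + jj == k]), numeric(1))
  ks <- 2:(2 * G)
  p_diff <- vapply(0:(G - 1), function(d) sum(P[diffs == d]), numeric(1))
  ds <- 0:(G - 1)

  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }

  asm <- sum(P^2)
  contrast <- sum(ds^2 * p_diff)
  correlation <- if (sd_x * sd_y > 0) {
    (sum(ii * jj * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((i - mu_x)^2 * px)
  idm <- sum(P / (1 + (ii - jj)^2))
  sum_average <- sum(ks * p_sum)
  sum_variance <- sum((ks - sum_average)^2 * p_sum)
  sum_entropy <- ent(p_sum)
  entropy <- ent(P)
  diff_mean <- sum(ds * p_diff)
  difference_variance <- sum((ds - diff_mean)^2 * p_diff)
  difference_entropy <- ent(p_diff)

  hx <- ent(px)
  hy <- ent(py)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log(pxpy[pos]))
  hxy2 <- ent(pxpy)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  support <- which(px > 0)
  degenerate <- length(support) < 2L || length(which(py > 0)) < 2L
  mcc <- if (degenerate) {
    0
  } else {
    sx <- support
    sy <- which(py > 0)
    # Q[i,j] = sum_k P[i,k] P[j,k] / (px[i] py[k]) over the support
    A <- P[sx, sy, drop = FALSE] / px[sx]               # rows scaled by px
    B <- t(P[sx, sy, drop = FALSE]) / py[sy]            # cols of P scaled by py
    Q <- A %*% B
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(clamp(ev[2], 0, 1))
  }

  out <- c(glcm_asm = asm, glcm_contrast = contrast,
           glcm_correlation = correlation, glcm_variance = variance,
           glcm_idm = idm, glcm_sum_average = sum_average,
           glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
           glcm_entropy = entropy, glcm_diff_variance = difference_variance,
           glcm_diff_entropy = difference_entropy, glcm_imc1 = imc1,
           glcm_imc2 = imc2, glcm_mcc = mcc)
  if (degenerate) attr(out, "mcc_degenerate") <- TRUE
  out
}
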