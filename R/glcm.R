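# Gray-level co-occurrence matrices (symmetric, distance 1, four
# directions) and the 12 Haralick texture statistics.

GLCM_DIRECTIONS <- list(
  `0` = c(dr = 0L, dc = 1L),
  `45` = c(dr = -1L, dc = 1L),
  `90` = c(dr = -1L, dc = 0L),
  `135` = c(dr = -1L, dc = -1L)
)

HARALICK_NAMES <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "difference_variance", "difference_entropy", "imc")

# Quantize a patch to `levels` gray levels over its own range (additive
# intensity shifts therefore do not change the quantized patch).
quantize_patch <- function(patch, levels = 32L) {
  rng <- range(patch)
  if (diff(rng) <= 0) return(matrix(1L, nrow(patch), ncol(patch)))
  q <- floor((patch - rng[1]) / diff(rng) * levels) + 1L
  q[q > levels] <- levels
  q
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalized co-occurrence matrix of a quantized patch at
#' offset distance 1 in one of the four standard directions.
#'
#' @param patch numeric matrix.
#' @param direction one of `0`, `45`, `90`, `135` (degrees).
#' @param levels number of quantization gray levels (default 32).
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm <- function(patch, direction = 0, levels = 32L) {
  off <- GLCM_DIRECTIONS[[as.character(direction)]]
  if (is.null(off)) stop("direction must be 0, 45, 90 or 135")
  q <- quantize_patch(patch, levels)
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - off["dr"]):min(nr, nr - off["dr"])
  c0 <- max(1L, 1L - off["dc"]):min(nc, nc - off["dc"])
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off["dr"], c0 + off["dc"], drop = FALSE]
  tab <- matrix(0, levels, levels)
  idx <- cbind(as.vector(a), as.vector(b))
  for (i in seq_len(nrow(idx))) tab[idx[i, 1], idx[i, 2]] <- tab[idx[i, 1], idx[i, 2]] + 1
  tab <- tab + t(tab)
  tab / sum(tab)
}

#' The 12 Haralick statistics of a co-occurrence matrix
#'
#' Angular second moment, contrast, correlation, sum-of-squares
#' variance, inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy and the
#' (first) information measure of correlation. Natural logarithms;
#' degenerate matrices (single gray level) yield ASM 1, entropies 0 and
#' correlation 0.
#'
#' @param p normalized symmetric co-occurrence matrix.
#' @return named numeric vector of length 12.
#' @export
haralick_features <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # sum and difference distributions
  psum <- tapply(as.vector(p), as.vector(i + j), sum)
  ks <- as.numeric(names(psum))
  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
  kd <- as.numeric(names(pdiff))
  f6 <- sum(ks * psum)
  mu_d <- sum(kd * pdiff)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 0
  hxy <- -sum(xlogx(p))
  hx <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log(pxpy[pxpy > 0]))
  imc <- if (hx > 0) (hxy - hxy1) / hx else 0
  c(
    asm = sum(p^2),
    contrast = sum(kd^2 * pdiff),
    correlation = corr,
    variance = sum((i - mu)^2 * p),
    idm = sum(p / (1 + (i - j)^2)),
    sum_average = f6,
    sum_variance = sum((ks - f6)^2 * psum),
    sum_entropy = -sum(xlogx(psum)),
    entropy = hxy,
    difference_variance = sum((kd - mu_d)^2 * pdiff),
    difference_entropy = -sum(xlogx(pdiff)),
    imc = imc
  )
}

#' GLCM texture features of a patch (48 values)
#'
#' The 12 Haralick statistics in each of the four directions 0, 45, 90
#' and 135 degrees; names follow `glcm_45deg_contrast`.
#'
#' @param patch numeric matrix.
#' @param levels quantization levels (default 32).
#' @return named numeric vector of length 48.
#' @export
glcm_features <- function(patch, levels = 32L) {
  out <- numeric(0)
  for (dir in names(GLCM_DIRECTIONS)) {
    f <- haralick_features(glcm(patch, as.numeric(dir), levels))
    names(f) <- paste0("glcm_", dir, "deg_", names(f))
    out <- c(out, f)
  }
  out
}
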