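# 2-level stationary wavelet transform (SWT, undecimated / a-trous) and
# wavelet-packet (WP) decompositions with haar, db4, db6 and coif1
# bases, yielding per-subband mean and standard deviation texture
# features. Decomposition low-pass filter coefficients are the standard
# published constants (frozen from PyWavelets 1.9.0).

WAVELET_DEC_LO <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.01059740178506903, 0.0328830116668852, 0.03084138183556076,
          -0.18703481171909309, -0.02798376941685985, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03, 5.5384220116149613e-04,
          -3.1582039317486030e-02, 2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01, 3.1525035170919763e-01,
          7.5113390802109536e-01, 4.9462389039845306e-01, 1.1154074335010947e-01),
  coif1 = c(-0.01565572813579199, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
)

#' Wavelet decomposition filters
#'
#' @param basis one of `"haar"`, `"db4"`, `"db6"`, `"coif1"` (`"coif"`
#'   is accepted as coiflet order 1).
#' @return list with `lo` and `hi` (quadrature mirror) filter vectors.
#' @export
wavelet_filters <- function(basis) {
  if (identical(basis, "coif")) basis <- "coif1"
  lo <- WAVELET_DEC_LO[[basis]]
  if (is.null(lo)) stop("unsupported wavelet basis: ", basis)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1L)
  list(lo = lo, hi = hi)
}

# Periodic 1-D convolution along the rows (y direction) of a matrix.
conv_periodic_rows <- function(m, f) {
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  base <- seq_len(nr)
  for (k in seq_along(f)) {
    idx <- ((base + k - 2L) %% nr) + 1L
    out <- out + f[k] * m[idx, , drop = FALSE]
  }
  out
}

conv_periodic_cols <- function(m, f) t(conv_periodic_rows(t(m), f))

# One undecimated analysis level: filters applied along y (rows) and x
# (columns). Dh = high-pass along y, Dv = high-pass along x.
swt_level <- function(m, lo, hi) {
  ly <- conv_periodic_rows(m, lo); hy <- conv_periodic_rows(m, hi)
  list(
    A = conv_periodic_cols(ly, lo),
    Dh = conv_periodic_cols(hy, lo),
    Dv = conv_periodic_cols(ly, hi),
    Dd = conv_periodic_cols(hy, hi)
  )
}

upsample_filter <- function(f) {
  out <- numeric(2L * length(f) - 1L)
  out[seq(1, length(out), by = 2)] <- f
  out
}

#' 2-level stationary wavelet decomposition
#'
#' Undecimated (a-trous) transform with periodic boundary handling;
#' level-2 subbands decompose the level-1 approximation with zero
#' upsampled filters.
#'
#' @param patch numeric matrix.
#' @param basis wavelet basis name.
#' @return named list of 8 subband matrices: A1, Dh1, Dv1, Dd1, A2A1,
#'   Dh2A1, Dv2A1, Dd2A1.
#' @export
swt2 <- function(patch, basis = "haar") {
  f <- wavelet_filters(basis)
  l1 <- swt_level(patch, f$lo, f$hi)
  l2 <- swt_level(l1$A, upsample_filter(f$lo), upsample_filter(f$hi))
  list(A1 = l1$A, Dh1 = l1$Dh, Dv1 = l1$Dv, Dd1 = l1$Dd,
       A2A1 = l2$A, Dh2A1 = l2$Dh, Dv2A1 = l2$Dv, Dd2A1 = l2$Dd)
}

# One decimated analysis level (periodic convolution, keep every second
# row/column).
dwt_level <- function(m, lo, hi) {
  bands <- swt_level(m, lo, hi)
  dec <- function(x) x[seq(1, nrow(x), by = 2), seq(1, ncol(x), by = 2), drop = FALSE]
  lapply(bands, dec)
}

# Symmetric padding of a patch so both dimensions are multiples of 4
# (two decimation levels).
pad_dyadic <- function(patch, levels = 2L) {
  mult <- 2L^levels
  pr <- (mult - nrow(patch) %% mult) %% mult
  pc <- (mult - ncol(patch) %% mult) %% mult
  if (pr > 0) patch <- rbind(patch, patch[nrow(patch) - seq_len(pr) + 1L, , drop = FALSE])
  if (pc > 0) patch <- cbind(patch, patch[, ncol(patch) - seq_len(pc) + 1L, drop = FALSE])
  patch
}

#' 2-level wavelet-packet decomposition
#'
#' Decimated transform in which every level-1 subband (not only the
#' approximation) is decomposed again. The patch is symmetrically padded
#' to dimensions divisible by 4. Level-2 node names concatenate child
#' and parent, e.g. `Dv2Dv1` is the vertical detail of the level-1
#' vertical detail.
#'
#' @param patch numeric matrix.
#' @param basis wavelet basis name.
#' @return named list of 4 level-1 + 16 level-2 subband matrices.
#' @export
wp2 <- function(patch, basis = "haar") {
  f <- wavelet_filters(basis)
  p <- pad_dyadic(patch)
  l1 <- dwt_level(p, f$lo, f$hi)
  names(l1) <- c("A1", "Dh1", "Dv1", "Dd1")
  out <- l1
  for (parent in names(l1)) {
    l2 <- dwt_level(l1[[parent]], f$lo, f$hi)
    names(l2) <- paste0(c("A2", "Dh2", "Dv2", "Dd2"), parent)
    out <- c(out, l2)
  }
  out
}

#' Wavelet texture features of a patch
#'
#' Mean and standard deviation of every SWT and WP subband for each
#' requested basis; feature names follow the pattern
#' `swt_A2A1_db4_mean`, `wp_Dv2Dv1_haar_std`.
#'
#' @param patch numeric matrix (e.g. the 41 x 21 tendon ROI).
#' @param bases wavelet bases to use.
#' @return named numeric vector.
#' @export
wavelet_features <- function(patch, bases = c("haar", "db4", "db6", "coif1")) {
  out <- numeric(0)
  for (basis in bases) {
    for (tr in c("swt", "wp")) {
      bands <- if (tr == "swt") swt2(patch, basis) else wp2(patch, basis)
      mns <- vapply(bands, mean, 1.0)
      sds <- vapply(bands, stats::sd, 1.0)
      nm <- names(bands)
      v <- c(mns, sds)
      names(v) <- c(paste(tr, nm, basis, "mean", sep = "_"),
                    paste(tr, nm, basis, "std", sep = "_"))
      out <- c(out, v)
    }
  }
  out
}
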