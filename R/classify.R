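# Symptomatic vs asymptomatic pair classification: tendon-centre ROI
# extraction, wavelet + co-occurrence feature vectors, left/right
# feature differencing, divergence-value feature selection and an SVM
# classifier evaluated by repeated leave-one-pair-out cross-validation.

#' Extract the tendon-centre region of interest
#'
#' A `width` x `height` pixel patch centred at the rounded centroid of
#' the segmented tendon contour (defaults 41 x 21). Patches reaching
#' beyond the image are clipped with a warning.
#'
#' @param image numeric matrix.
#' @param contour tendon contour.
#' @param width,height patch size in pixels (odd).
#' @return numeric matrix of the patch.
#' @export
extract_roi <- function(image, contour, width = 41L, height = 21L) {
  ctr <- round(contour_centroid(contour))
  if (ctr[1] < 1 || ctr[1] > ncol(image) || ctr[2] < 1 || ctr[2] > nrow(image))
    stop("tendon centroid outside image")
  hw <- (width - 1L) %/% 2L; hh <- (height - 1L) %/% 2L
  xs <- (ctr[1] - hw):(ctr[1] + hw)
  ys <- (ctr[2] - hh):(ctr[2] + hh)
  if (any(xs < 1) || any(xs > ncol(image)) || any(ys < 1) || any(ys > nrow(image))) {
    warning("ROI clipped at the image border")
    xs <- xs[xs >= 1 & xs <= ncol(image)]
    ys <- ys[ys >= 1 & ys <= nrow(image)]
  }
  image[ys, xs, drop = FALSE]
}

# Area of a closed polygon in px^2 (absolute shoelace area).
polygon_area_px <- function(contour) abs(polygon_signed_area(as.matrix(contour)))

#' Full texture feature vector for one hand
#'
#' Combines the geometric features (tendon area and area inside the
#' sheath, px^2) with the wavelet (SWT/WP) and co-occurrence features of
#' the tendon-centre ROI.
#'
#' @param image numeric matrix.
#' @param tendon tendon contour.
#' @param sheath optional closed sheath contour (its area feature is 0
#'   when absent).
#' @return named numeric vector.
#' @export
hand_features <- function(image, tendon, sheath = NULL) {
  roi <- extract_roi(image, tendon)
  c(
    area_of_tendon = polygon_area_px(tendon),
    area_inside_sheath = if (is.null(sheath)) 0 else polygon_area_px(sheath),
    wavelet_features(roi),
    glcm_features(roi)
  )
}

#' Per-pair feature difference
#'
#' Symptomatic pairs use affected minus contralateral; asymptomatic
#' pairs use right minus left.
#'
#' @param left,right named feature vectors of the two hands.
#' @param label `"symptomatic"` or `"asymptomatic"`.
#' @param affected `"left"` or `"right"` (needed for symptomatic pairs).
#' @return named numeric difference vector.
#' @export
pair_difference <- function(left, right, label, affected = "right") {
  if (identical(label, "symptomatic")) {
    if (identical(affected, "left")) left - right else right - left
  } else {
    right - left
  }
}

#' Divergence value of a feature
#'
#' Class-spread-based univariate importance score
#' `(sn - sa)^2 (1 + sn + sa)^2 / (sn sa)` for the normal and abnormal
#' class standard deviations; zero iff the spreads are equal, symmetric
#' in the classes, and growing with spread disparity. The alternative
#' denominator reading `2 sn sa` is available via `variant`.
#'
#' @param sigma_normal,sigma_abnormal positive class standard deviations.
#' @param variant `"product"` (denominator `sn*sa`) or `"2product"`.
#' @return non-negative scalar.
#' @export
divergence_value <- function(sigma_normal, sigma_abnormal,
                             variant = c("product", "2product")) {
  variant <- match.arg(variant)
  if (any(sigma_normal <= 0) || any(sigma_abnormal <= 0))
    stop("divergence value requires positive standard deviations")
  denom <- sigma_normal * sigma_abnormal
  if (variant == "2product") denom <- 2 * denom
  (sigma_normal - sigma_abnormal)^2 * (1 + sigma_normal + sigma_abnormal)^2 / denom
}

#' Rank features by divergence value and keep the top k
#'
#' Computes each feature's class standard deviations over the pair
#' difference vectors and ranks by [divergence_value()], descending;
#' ties are broken by column order. Features with zero spread in either
#' class are skipped.
#'
#' @param features pairs x features numeric matrix (or data frame) of
#'   difference vectors.
#' @param labels factor/character vector with values `"symptomatic"` /
#'   `"asymptomatic"` per row.
#' @param k number of features to keep (default 20; fewer are returned
#'   if fewer are valid).
#' @param variant divergence denominator variant.
#' @return character vector of selected feature names, ranked.
#' @export
select_features <- function(features, labels, k = 20L,
                            variant = c("product", "2product")) {
  variant <- match.arg(variant)
  x <- as.matrix(features)
  is_abn <- labels == "symptomatic"
  if (sum(is_abn) < 2L || sum(!is_abn) < 2L)
    stop("need at least 2 pairs per class")
  sn <- apply(x[!is_abn, , drop = FALSE], 2, stats::sd)
  sa <- apply(x[is_abn, , drop = FALSE], 2, stats::sd)
  ok <- is.finite(sn) & is.finite(sa) & sn > 0 & sa > 0
  div <- rep(-Inf, ncol(x))
  div[ok] <- divergence_value(sn[ok], sa[ok], variant)
  ord <- order(-div, seq_len(ncol(x)))
  ord <- ord[ok[ord]]
  colnames(x)[utils::head(ord, k)]
}

#' Train the SVM pair classifier
#'
#' RBF-kernel support vector machine on standardized selected features.
#'
#' @param features pairs x features matrix of difference vectors.
#' @param labels class labels per row.
#' @param selected character vector of feature names to use.
#' @param cost,gamma SVM hyperparameters (defaults: cost 1, gamma
#'   1/n_features).
#' @return an `atasm_classifier` wrapping the fitted SVM.
#' @export
train_classifier <- function(features, labels, selected = colnames(features),
                             cost = 1, gamma = NULL) {
  x <- as.matrix(features)[, selected, drop = FALSE]
  y <- factor(labels, levels = c("asymptomatic", "symptomatic"))
  if (nlevels(droplevels(y)) < 2L) stop("training data must contain both classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  # inverse-frequency class weights: leave-one-pair-out folds of a
  # balanced paired design are always off-balance by one, and an
  # unweighted SVM then leans toward the majority class
  cw <- length(y) / (2 * table(y))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = TRUE, class.weights = cw)
  structure(list(fit = fit, selected = selected), class = "atasm_classifier")
}

#' Predict pair labels
#'
#' @param object an `atasm_classifier`.
#' @param features matrix of difference vectors.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.atasm_classifier <- function(object, features, ...) {
  x <- as.matrix(features)[, object$selected, drop = FALSE]
  stats::predict(object$fit, x)
}

#' Evaluate the pair classifier by repeated leave-one-pair-out CV
#'
#' Each repeat holds out one pair at a time, re-runs divergence-based
#' feature selection and SVM training on the remaining pairs, and
#' predicts the held-out pair. Confusion counts are aggregated over all
#' repeats (symptomatic = positive).
#'
#' @param features pairs x features matrix of difference vectors.
#' @param labels class labels per row.
#' @param k features kept per fold.
#' @param repeats number of full leave-one-pair-out passes (default 10).
#' @param cost,gamma SVM hyperparameters.
#' @param seed optional RNG seed for the evaluation.
#' @return list with `confusion` ([confusion_matrix()]), `accuracy`,
#'   `precision` (percent, precision `NA` if undefined) and `decisions`
#'   (total predictions made).
#' @export
evaluate_classifier <- function(features, labels, k = 20L, repeats = 10L,
                                cost = 1, gamma = NULL, seed = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 pairs")
  run <- function() {
    tp <- tn <- fp <- fn <- 0L
    for (rep_i in seq_len(repeats)) {
      for (i in seq_len(n)) {
        sel <- select_features(x[-i, , drop = FALSE], labels[-i], k = k)
        clf <- train_classifier(x[-i, , drop = FALSE], labels[-i], sel,
                                cost = cost, gamma = gamma)
        pred <- as.character(predict(clf, x[i, , drop = FALSE]))
        truth <- labels[i]
        if (truth == "symptomatic" && pred == "symptomatic") tp <- tp + 1L
        else if (truth == "symptomatic") fn <- fn + 1L
        else if (pred == "symptomatic") fp <- fp + 1L
        else tn <- tn + 1L
      }
    }
    cm <- confusion_matrix(tp, tn, fp, fn)
    list(
      confusion = cm,
      accuracy = classification_accuracy(cm),
      precision = if (tp + fp > 0) classification_precision(cm) else NA_real_,
      decisions = tp + tn + fp + fn
    )
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
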