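# Image reading/writing and the versioned model archive (JSON).

#' Read a grayscale ultrasound image
#'
#' Reads PNG or TIFF, converts RGB to luminance (Rec. 601 weights
#' 0.299/0.587/0.114, with a message), rescales to `[0, 255]` by the
#' bit-depth maximum, and attaches the pixel spacing as an attribute.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param pixel_spacing_mm physical pixel size used when the file
#'   carries none (default 0.075).
#' @return numeric matrix in `[0, 255]` with attribute
#'   `pixel_spacing_mm`.
#' @export
read_image <- function(path, pixel_spacing_mm = 0.075) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path, " (PNG/TIFF supported)")
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      message("RGB input converted to luminance: ", path)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  img <- arr * 255
  attr(img, "pixel_spacing_mm") <- pixel_spacing_mm
  img
}

#' Write a grayscale image as PNG
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

ATASM_ARCHIVE_VERSION <- "1.0"

serialize_target <- function(tgt) {
  out <- list(
    shape = list(
      mean_shape = tgt$shape$mean_shape,
      modes = tgt$shape$modes,
      eigenvalues = tgt$shape$eigenvalues,
      n_training = tgt$shape$n_training,
      var_retain = tgt$shape$var_retain,
      scale_hint = tgt$shape$scale_hint
    ),
    texture = tgt$texture[c("gabor", "laws", "n_training", "gabor_sigma",
                            "gabor_phi", "gabor_size")],
    weights = list(values = unclass(tgt$weights)[,], target = attr(tgt$weights, "target"))
  )
  if (!is.null(tgt$template)) {
    out$template <- list(
      pixels = tgt$template$pixels,
      reference_contour = as.matrix(tgt$template$reference_contour),
      origin = tgt$template$origin,
      n_training = tgt$template$n_training
    )
  }
  out
}

deserialize_target <- function(lst) {
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  shape <- structure(list(
    mean_shape = as.numeric(lst$shape$mean_shape),
    modes = matrix(as.numeric(as_mat(lst$shape$modes)),
                   nrow = length(lst$shape$mean_shape)),
    eigenvalues = as.numeric(lst$shape$eigenvalues),
    n_training = lst$shape$n_training,
    var_retain = lst$shape$var_retain,
    scale_hint = lst$shape$scale_hint
  ), class = "atasm_shape_model")
  texture <- structure(list(
    gabor = as.numeric(lst$texture$gabor),
    laws = as.numeric(lst$texture$laws),
    n_training = lst$texture$n_training,
    gabor_sigma = lst$texture$gabor_sigma,
    gabor_phi = lst$texture$gabor_phi,
    gabor_size = lst$texture$gabor_size
  ), class = "atasm_texture_model")
  w <- as_mat(lst$weights$values)
  rownames(w) <- ENERGY_TERMS
  weights <- structure(w, target = lst$weights$target,
                       class = c("atasm_energy_weights", class(w)))
  out <- list(shape = shape, texture = texture, weights = weights)
  if (!is.null(lst$template)) {
    out$template <- structure(list(
      pixels = as_mat(lst$template$pixels),
      reference_contour = as_contour(as_mat(lst$template$reference_contour)),
      origin = unlist(lst$template$origin),
      n_training = lst$template$n_training
    ), class = "atasm_template")
  }
  out
}

#' Save a trained model archive
#'
#' Single versioned JSON archive bundling the shape model, texture
#' profile model, energy weights and intensity template per target.
#'
#' @param model an `atasm_model` from [train_atasm()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_atasm_model <- function(model, path) {
  payload <- list(format = "atasm-model", version = ATASM_ARCHIVE_VERSION,
                  targets = lapply(unclass(model), serialize_target))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model archive written by [save_atasm_model()]
#'
#' @param path archive path.
#' @return an `atasm_model`.
#' @export
load_atasm_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "atasm-model"))
    stop("not an atasm model archive: ", path)
  structure(lapply(payload$targets, deserialize_target), class = "atasm_model")
}
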