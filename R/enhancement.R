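#' Fundus enhancement parameters
#'
#' Parameters of the blur-subtraction contrast enhancement
#' `Ic = alpha * I + beta * G(rho) * I + gamma`, where `G(rho) * I` is the
#' image convolved with a Gaussian of scale `rho`, applied per channel after
#' the image has been cropped and resized to `target_size x target_size`.
#' The defaults `alpha = 3, beta = -3, gamma = 128, rho = 14` and
#' `target_size = 600` are the settings used for screening-scale fundus
#' photographs: with `alpha + beta = 0` the enhancement removes the local
#' illumination field (lighting, camera and exposure variation between
#' images) and recentres every image on the mid-grey value `gamma`.
#'
#' `rho` is interpreted as the Gaussian standard deviation in pixels on the
#' resized image; the kernel is truncated at `4 * rho` and image borders are
#' handled by reflection, which avoids dark vignetting at the fundus edge.
#'
#' @param alpha Dimensionless weight of the raw image.
#' @param beta Dimensionless weight of the blurred image.
#' @param gamma Intensity offset on the 8-bit scale.
#' @param rho Gaussian standard deviation in pixels; must be positive.
#' @param target_size Side of the square output in pixels; at least 32.
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(alpha = 3, beta = -3, gamma = 128, rho = 14,
                           target_size = 600) {
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (target_size < 32) stop("target_size must be at least 32", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, rho = rho,
                 target_size = as.integer(target_size)),
            class = "enhance_params")
}

# Images are numeric arrays H x W x 3 (RGB) with 8-bit values in [0, 255].
assert_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 1 || dim(img)[2] < 1)
    stop("image must be non-empty", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

# round half away from zero; values here are non-negative so this is
# round-half-up, fixed for bit-reproducible outputs
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

# Map out-of-range row indices back into 1..n by symmetric reflection
# (edge row repeated); handles pad widths larger than the image.
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  # period of the reflected sequence is 2n
  i <- (i - 1) %% (2 * n)
  ifelse(i < n, i + 1, 2 * n - i)
}

# Separable Gaussian blur of one channel (matrix), sd = sigma pixels,
# kernel truncated at 4*sigma, reflected boundaries. Real arithmetic.
blur_channel <- function(mat, sigma) {
  r <- as.integer(ceiling(4 * sigma))
  if (r == 0) return(mat)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  one_dim <- function(m) {
    n <- nrow(m)
    pad <- reflect_index(seq(1 - r, n + r), n)
    res <- stats::filter(m[pad, , drop = FALSE], k, sides = 2)
    res[seq_len(n) + r, , drop = FALSE]
  }
  t(one_dim(t(one_dim(mat))))
}

#' Gaussian blur of an 8-bit RGB image
#'
#' Separable Gaussian convolution applied independently per channel, with the
#' kernel truncated at four standard deviations and reflected boundaries.
#' Returned values are real (not rounded); callers that need an 8-bit image
#' should round and clip.
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param sigma Standard deviation in pixels.
#' @return H x W x 3 numeric array.
#' @export
gaussian_blur <- function(img, sigma) {
  assert_image(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- blur_channel(img[, , ch], sigma)
  out
}

#' Crop a fundus photograph to the retinal disc
#'
#' Returns the tight bounding box of pixels whose channel mean exceeds
#' `background_threshold`; fundus photographs have a near-black surround, so
#' this recovers the camera's circular field of view. If no pixel qualifies
#' the input is returned unchanged with a warning and the attribute
#' `cropped = FALSE`.
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param background_threshold Channel-mean intensity separating background
#'   from fundus; default 10 on the 8-bit scale.
#' @return The cropped image with attribute `cropped` (logical).
#' @export
crop_fundus <- function(img, background_threshold = 10) {
  assert_image(img)
  fg <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3 > background_threshold
  if (!any(fg)) {
    warning("no pixel above background threshold; image returned uncropped")
    attr(img, "cropped") <- FALSE
    return(img)
  }
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  out <- img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  attr(out, "cropped") <- TRUE
  out
}

#' Resize an 8-bit RGB image (bilinear)
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param size Output side length in pixels (square output).
#' @return `size x size x 3` array of 8-bit values (rounded half-up).
#' @export
resize_image <- function(img, size) {
  assert_image(img)
  size <- as.integer(size)
  # EBImage stores images width-major; transpose in and out
  e <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  r <- EBImage::resize(e, w = size, h = size, filter = "bilinear")
  out <- aperm(EBImage::imageData(r), c(2, 1, 3)) * 255
  clip8(round_half_up(out))
}

#' Blur-subtraction contrast enhancement
#'
#' Computes `alpha * I + beta * G(rho) * I + gamma` per channel in real
#' arithmetic, then rounds half-up and clips to \[0, 255\]. With the default
#' `alpha = 3, beta = -3, gamma = 128` this amplifies local structure
#' (vessels, lesions) threefold while cancelling the smooth illumination
#' field, so a spatially constant image maps exactly to the constant `gamma`.
#'
#' @param img Square H x W x 3 array, already resized to
#'   `params$target_size`; values in \[0, 255\].
#' @param params An [enhance_params()] object.
#' @return Array of the same dimensions, 8-bit values.
#' @export
enhance_contrast <- function(img, params = enhance_params()) {
  assert_image(img)
  stopifnot(inherits(params, "enhance_params"))
  blurred <- gaussian_blur(img, params$rho)
  out <- params$alpha * img + params$beta * blurred + params$gamma
  clip8(round_half_up(out))
}

#' Full fundus preprocessing pipeline
#'
#' Crop to the retinal disc, resize to `params$target_size` square
#' (bilinear), then apply the blur-subtraction contrast enhancement.
#' Deterministic: the same input and parameters always give a bit-identical
#' output.
#'
#' @inheritParams crop_fundus
#' @inheritParams enhance_contrast
#' @return `target_size x target_size x 3` enhanced 8-bit image.
#' @examples
#' img <- gen_fundus(image_gen_config(size = 64, seed = 1))
#' out <- preprocess_fundus(img, enhance_params(target_size = 64, rho = 4))
#' dim(out)
#' @export
preprocess_fundus <- function(img, params = enhance_params(),
                              background_threshold = 10) {
  cropped <- crop_fundus(img, background_threshold)
  resized <- resize_image(cropped, params$target_size)
  enhance_contrast(resized, params)
}

#' Read / write fundus images
#'
#' Thin wrappers over EBImage's PNG/JPEG codecs converting to and from the
#' package's 8-bit `H x W x 3` array representation.
#'
#' @param path Image file path (`.png`, `.jpg`/`.jpeg`).
#' @return `read_fundus()`: H x W x 3 array of 8-bit values.
#' @export
read_fundus <- function(path) {
  e <- EBImage::readImage(path)
  d <- EBImage::imageData(e)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), dim = c(dim(d), 3))
  if (dim(d)[3] > 3) d <- d[, , 1:3]
  clip8(round_half_up(aperm(d, c(2, 1, 3)) * 255))
}

#' @param img H x W x 3 array of 8-bit values.
#' @rdname read_fundus
#' @export
write_fundus <- function(img, path) {
  assert_image(img)
  e <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(e, path)
  invisible(path)
}

#' Batch preprocessing over a manifest or directory
#'
#' @param input Either a directory of PNG/JPEG images or a CSV manifest with
#'   columns `id, path`.
#' @param output_dir Directory for enhanced images (created if absent),
#'   mirroring input file names.
#' @inheritParams preprocess_fundus
#' @return Invisibly, a data.frame with columns `id`, `input`, `output`.
#' @export
preprocess_batch <- function(input, output_dir, params = enhance_params(),
                             background_threshold = 10) {
  if (dir.exists(input)) {
    paths <- list.files(input, pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
    manifest <- data.frame(id = tools::file_path_sans_ext(basename(paths)),
                           path = paths, stringsAsFactors = FALSE)
  } else {
    manifest <- utils::read.csv(input, colClasses = "character")
    if (!all(c("id", "path") %in% names(manifest)))
      stop("manifest needs columns 'id' and 'path'", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out_paths <- file.path(output_dir, basename(manifest$path))
  for (i in seq_len(nrow(manifest))) {
    img <- read_fundus(manifest$path[i])
    write_fundus(preprocess_fundus(img, params, background_threshold),
                 out_paths[i])
  }
  invisible(data.frame(id = manifest$id, input = manifest$path,
                       output = out_paths, stringsAsFactors = FALSE))
}
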