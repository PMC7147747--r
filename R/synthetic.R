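#' Configuration for the synthetic probability-record generator
#'
#' The generator emulates the softmax output of a fundus classifier of
#' controllable quality: a true class is drawn from `prevalence`, then the
#' probability vector is drawn from a Dirichlet distribution whose parameters
#' depend on the true class. The Dirichlet is the simplest class-conditional
#' model on the simplex with controllable confusability: concentration mass
#' on the true class's coordinate sets the classifier's discriminability, and
#' the overall concentration magnitude its decisiveness.
#'
#' @param scheme A [grade_scheme()].
#' @param n Number of records.
#' @param prevalence Named numeric vector over the scheme classes summing
#'   to 1 (tolerance 1e-9).
#' @param concentration Named list: for each class, a strictly positive
#'   numeric vector of Dirichlet parameters aligned with `scheme$classes`.
#' @param seed Integer seed; the output is a pure function of the config.
#' @return An object of class `prob_gen_config`.
#' @seealso [paperlike_prob_config()] for the shipped screening-like preset.
#' @export
prob_gen_config <- function(scheme, n, prevalence, concentration, seed = 1L) {
  stopifnot(inherits(scheme, "grade_scheme"))
  k <- length(scheme$classes)
  if (!setequal(names(prevalence), scheme$classes))
    stop("prevalence must be named by the scheme classes", call. = FALSE)
  prevalence <- prevalence[scheme$classes]
  if (any(prevalence < 0) || abs(sum(prevalence) - 1) > 1e-9)
    stop("prevalence must be non-negative and sum to 1", call. = FALSE)
  if (!setequal(names(concentration), scheme$classes))
    stop("concentration must be named by the scheme classes", call. = FALSE)
  concentration <- concentration[scheme$classes]
  ok <- vapply(concentration, function(v)
    length(v) == k && all(v > 0), logical(1))
  if (!all(ok))
    stop("each concentration vector must be strictly positive and of ",
         "length ", k, call. = FALSE)
  structure(list(scheme = scheme, n = as.integer(n),
                 prevalence = prevalence, concentration = concentration,
                 seed = as.integer(seed)),
            class = "prob_gen_config")
}

#' Screening-like generator preset
#'
#' Three-class configuration with prevalence proportional to the
#' 65,300 : 19,400 : 4,000 healthy / non-referable / referable composition
#' of a large public fundus screening set, and concentrations chosen once so
#' that unboosted argmax decisions show the qualitative pattern of a
#' screening classifier: high healthy sensitivity, moderate sensitivity for
#' the disease grades.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A [prob_gen_config()].
#' @export
paperlike_prob_config <- function(n = 13305, seed = 1L) {
  sch <- grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
  prev <- stats::setNames(c(65300, 19400, 4000) / 88700, sch$classes)
  conc <- list("Healthy" = c(9.0, 2.2, 0.5),
               "Non-referable DR" = c(4.0, 5.0, 1.8),
               "Referable DR" = c(2.2, 3.6, 4.2))
  prob_gen_config(sch, n, prev, conc, seed)
}

#' Generate labelled synthetic probability records
#'
#' @param cfg A [prob_gen_config()].
#' @return Data frame with columns `id`, one `p_<class>` column per scheme
#'   class, and `true_label`; `cfg$n` rows. Probability rows sum to 1 by
#'   construction. Identical configs give bit-identical output.
#' @examples
#' rec <- gen_prob_records(paperlike_prob_config(n = 100, seed = 7))
#' head(rec)
#' @export
gen_prob_records <- function(cfg) {
  stopifnot(inherits(cfg, "prob_gen_config"))
  sch <- cfg$scheme
  k <- length(sch$classes)
  with_seed(cfg$seed, {
    lab_idx <- sample.int(k, cfg$n, replace = TRUE, prob = cfg$prevalence)
    g <- matrix(0, cfg$n, k)
    for (ci in seq_len(k)) {
      rows <- which(lab_idx == ci)
      if (!length(rows)) next
      shape <- cfg$concentration[[ci]]
      g[rows, ] <- matrix(stats::rgamma(length(rows) * k,
                                        shape = rep(shape, each = length(rows))),
                          nrow = length(rows))
    }
    pm <- g / rowSums(g)
    df <- data.frame(id = sprintf("s%06d", seq_len(cfg$n)),
                     stringsAsFactors = FALSE)
    df[prob_cols(sch)] <- as.data.frame(pm)
    df$true_label <- sch$classes[lab_idx]
    df
  })
}

#' Configuration for the synthetic fundus-image generator
#'
#' @param size Image side in pixels (square).
#' @param disc_radius_fraction Disc radius as a fraction of `size / 2`,
#'   in (0, 1).
#' @param vessel_count Number of vessel-like dark curves.
#' @param blur_sigma Gaussian defocus applied after drawing, in pixels
#'   (0 = sharp).
#' @param exposure_scale Multiplicative exposure factor (> 0; < 1
#'   under-exposes, 0 would be all-black and is allowed as the degenerate
#'   lower limit).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise on
#'   the 8-bit scale.
#' @param seed Integer seed.
#' @return An object of class `image_gen_config`.
#' @export
image_gen_config <- function(size = 128, disc_radius_fraction = 0.8,
                             vessel_count = 6, blur_sigma = 0,
                             exposure_scale = 1, noise_sd = 0, seed = 1L) {
  if (size < 8) stop("size must be at least 8", call. = FALSE)
  if (disc_radius_fraction <= 0 || disc_radius_fraction >= 1)
    stop("disc_radius_fraction must lie in (0, 1)", call. = FALSE)
  if (blur_sigma < 0 || noise_sd < 0 || exposure_scale < 0)
    stop("blur_sigma, noise_sd must be >= 0 and exposure_scale >= 0",
         call. = FALSE)
  structure(list(size = as.integer(size),
                 disc_radius_fraction = disc_radius_fraction,
                 vessel_count = as.integer(vessel_count),
                 blur_sigma = blur_sigma, exposure_scale = exposure_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_gen_config")
}

#' Generate a synthetic fundus-like test image
#'
#' Draws a centred bright disc with radial shading on a dark background,
#' adds vessel-like dark meandering curves, then degrades the image by
#' exposure scaling, Gaussian defocus and additive noise. The output is a
#' pure function of the config and is intended as a test fixture for the
#' preprocessing and quality modules — it emulates the geometry and
#' low-level statistics a gradability heuristic responds to, not retinal
#' pathology.
#'
#' @param cfg An [image_gen_config()].
#' @return `size x size x 3` array of 8-bit values.
#' @examples
#' img <- gen_fundus(image_gen_config(size = 64, seed = 1))
#' range(img)
#' @export
gen_fundus <- function(cfg) {
  stopifnot(inherits(cfg, "image_gen_config"))
  n <- cfg$size
  with_seed(cfg$seed, {
    ctr <- (n + 1) / 2
    r <- cfg$disc_radius_fraction * n / 2
    xy <- expand.grid(row = seq_len(n), col = seq_len(n))
    d <- sqrt((xy$row - ctr)^2 + (xy$col - ctr)^2)
    shade <- matrix(pmax(1 - 0.45 * (d / r)^2, 0) * (d <= r), n, n)
    base <- c(230, 150, 70)  # fundus-like orange
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) img[, , ch] <- base[ch] * shade

    # vessel-like curves: jittered radial walks from near the disc centre
    if (cfg$vessel_count > 0 && r > 3) {
      for (v in seq_len(cfg$vessel_count)) {
        ang <- stats::runif(1, 0, 2 * pi)
        pos <- c(ctr, ctr) + 0.1 * r * c(cos(ang), sin(ang))
        dir <- ang + stats::runif(1, -0.5, 0.5)
        for (step in seq_len(as.integer(2.5 * r))) {
          dir <- dir + stats::rnorm(1, 0, 0.15)
          pos <- pos + c(cos(dir), sin(dir)) * 0.45
          i <- round(pos[1]); j <- round(pos[2])
          if (i < 1 || i > n || j < 1 || j > n) break
          if (sqrt((i - ctr)^2 + (j - ctr)^2) > 0.95 * r) break
          ii <- max(1, i - 1):min(n, i)
          img[ii, j, 1] <- pmin(img[ii, j, 1], 90)
          img[ii, j, 2] <- pmin(img[ii, j, 2], 35)
          img[ii, j, 3] <- pmin(img[ii, j, 3], 25)
        }
      }
    }

    img <- img * cfg$exposure_scale
    if (cfg$blur_sigma > 0) img <- gaussian_blur(clip8(img), cfg$blur_sigma)
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(n * n * 3, 0, cfg$noise_sd),
                         dim = dim(img))
    clip8(round_half_up(img))
  })
}
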