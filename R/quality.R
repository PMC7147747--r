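# Registry of image-adequacy scorers. A scorer is a function
# (img, parameters) -> score in [0, 1]; higher = more adequate for grading.
.scorer_registry <- new.env(parent = emptyenv())

#' Register or look up image-adequacy scorers
#'
#' The quality module fixes the curation *workflow* (score every image,
#' threshold, split into curated/rejected subsets, re-evaluate metrics on
#' both) while leaving the scorer itself pluggable, so a learned gradability
#' model can be dropped in later. A `"baseline"` heuristic scorer is
#' registered at load time.
#'
#' @param name Scorer identifier.
#' @param fn Function `(img, parameters)` returning a score in \[0, 1\].
#' @return `register_scorer()` returns `name` invisibly; `list_scorers()`
#'   the registered names.
#' @export
register_scorer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .scorer_registry)
  invisible(name)
}

#' @rdname register_scorer
#' @export
list_scorers <- function() sort(ls(.scorer_registry))

#' Scorer specification
#'
#' @param name Name of a registered scorer (see [list_scorers()]).
#' @param threshold Curation threshold in \[0, 1\]: images scoring at or
#'   above it are labelled `adequate`, below it `inadequate`.
#' @param parameters Named list of scorer parameters.
#' @return An object of class `scorer_spec`.
#' @export
scorer_spec <- function(name = "baseline", threshold = 0.5,
                        parameters = list()) {
  if (!exists(name, envir = .scorer_registry))
    stop("unregistered scorer: ", name, call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, threshold = threshold, parameters = parameters),
            class = "scorer_spec")
}

# Baseline heuristic scorer: weighted mean of
#   area     — fraction of pixels whose channel mean exceeds the background
#              threshold (a gradable fundus fills most of the frame),
#   sharpness — variance of a discrete 4-neighbour Laplacian on the green
#              channel, normalized by a saturation constant and capped at 1
#              (the green channel carries most vessel contrast),
#   contrast — interquartile range of the channel-mean intensities / 255.
# Defaults: weights (0.4, 0.3, 0.3), background threshold 10,
# sharpness saturation 500 (Laplacian variance on the 8-bit scale at which
# an image counts as fully sharp). All artifact-chosen, configurable.
baseline_scorer <- function(img, parameters = list()) {
  p <- utils::modifyList(list(weights = c(area = 0.4, sharpness = 0.3,
                                          contrast = 0.3),
                              background_threshold = 10,
                              sharpness_saturation = 500),
                         parameters)
  chan_mean <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  area <- mean(chan_mean > p$background_threshold)
  g <- img[, , 2]
  n <- nrow(g); m <- ncol(g)
  if (n >= 3 && m >= 3) {
    core <- g[2:(n - 1), 2:(m - 1)]
    lap <- g[1:(n - 2), 2:(m - 1)] + g[3:n, 2:(m - 1)] +
      g[2:(n - 1), 1:(m - 2)] + g[2:(n - 1), 3:m] - 4 * core
    sharp <- min(stats::var(as.vector(lap)) / p$sharpness_saturation, 1)
  } else sharp <- 0
  contrast <- unname(diff(stats::quantile(chan_mean, c(0.25, 0.75)))) / 255
  w <- p$weights / sum(p$weights)
  unname(w["area"] * area + w["sharpness"] * sharp + w["contrast"] * contrast)
}

#' Score the gradability of a fundus image
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param spec A [scorer_spec()].
#' @param id Optional sample identifier carried into the result.
#' @return An object of class `quality_score`: list with `id`, `score` in
#'   \[0, 1\] and `label` (`"adequate"` iff `score >= spec$threshold`).
#' @examples
#' img <- gen_fundus(image_gen_config(size = 64, seed = 1))
#' score_quality(img, scorer_spec("baseline", threshold = 0.5))
#' @export
score_quality <- function(img, spec = scorer_spec(), id = NA_character_) {
  assert_image(img)
  stopifnot(inherits(spec, "scorer_spec"))
  fn <- get(spec$name, envir = .scorer_registry)
  s <- fn(img, spec$parameters)
  s <- min(max(s, 0), 1)
  structure(list(id = id, score = s,
                 label = if (s >= spec$threshold) "adequate" else "inadequate"),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("quality score %.4f (%s)%s\n", x$score, x$label,
              if (is.na(x$id)) "" else paste0(" id=", x$id)))
  invisible(x)
}

#' Score a batch of images
#'
#' @param imgs Named list of images (names used as ids) or a manifest
#'   data.frame with columns `id, path`.
#' @param spec A [scorer_spec()].
#' @return Data frame with columns `id, score, label`.
#' @export
score_quality_batch <- function(imgs, spec = scorer_spec()) {
  if (is.data.frame(imgs)) {
    ids <- as.character(imgs$id)
    get_img <- function(i) read_fundus(imgs$path[i])
  } else {
    ids <- names(imgs)
    if (is.null(ids)) ids <- as.character(seq_along(imgs))
    get_img <- function(i) imgs[[i]]
  }
  rows <- lapply(seq_along(ids), function(i)
    score_quality(get_img(i), spec, id = ids[i]))
  data.frame(id = ids,
             score = vapply(rows, `[[`, numeric(1), "score"),
             label = vapply(rows, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}

#' Curate a sample set by quality threshold
#'
#' Splits `ids` into a curated subset (score at or above `threshold`) and a
#' rejected subset, reporting the exact rejection rate
#' `|rejected| / |ids|`. An empty id list yields rate 0 with a warning.
#'
#' @param ids Sample identifiers.
#' @param scores Either a data.frame `(id, score)` as from
#'   [score_quality_batch()] or a numeric vector of scores named by (or
#'   aligned with) `ids`; every id must have exactly one score.
#' @param threshold Curation threshold in \[0, 1\].
#' @return An object of class `curation`: list with `curated`, `rejected`
#'   (character vectors, preserving input order) and `rejection_rate`.
#' @export
curate <- function(ids, scores, threshold) {
  ids <- as.character(ids)
  if (length(ids) == 0) {
    warning("curating an empty id list; rejection rate reported as 0")
    return(structure(list(curated = character(0), rejected = character(0),
                          rejection_rate = 0), class = "curation"))
  }
  if (is.data.frame(scores)) {
    idx <- match(ids, as.character(scores$id))
    if (anyNA(idx))
      stop("missing score for id(s): ",
           paste(ids[is.na(idx)][seq_len(min(3, sum(is.na(idx))))],
                 collapse = ", "), call. = FALSE)
    s <- scores$score[idx]
  } else {
    if (!is.null(names(scores))) {
      idx <- match(ids, names(scores))
      if (anyNA(idx))
        stop("missing score for id(s): ", ids[is.na(idx)][1], call. = FALSE)
      s <- unname(scores[idx])
    } else {
      if (length(scores) != length(ids))
        stop("unnamed scores must align with ids", call. = FALSE)
      s <- scores
    }
  }
  keep <- s >= threshold
  structure(list(curated = ids[keep], rejected = ids[!keep],
                 rejection_rate = sum(!keep) / length(ids)),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  n <- length(x$curated) + length(x$rejected)
  cat(sprintf("curated %d / %d images (rejection rate %.4f)\n",
              length(x$curated), n, x$rejection_rate))
  invisible(x)
}

#' Write quality scores as CSV
#'
#' @param scores Data frame `(id, score, label)`.
#' @param path Output path.
#' @export
write_quality_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
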