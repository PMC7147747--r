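#' Define an ordered disease-grade scheme
#'
#' A grade scheme is an ordered set of class names, least severe first, with a
#' designated fallback class. The fallback is the class assigned by decision
#' rules when no other rule fires (conventionally written `~` in a cascading
#' threshold specification such as `(~, 0.3, 0.3)`).
#'
#' @param classes Character vector of unique class names, ordered from least
#'   to most severe. At least two classes are required.
#' @param fallback Name of the fallback class; must be one of `classes`.
#'   Defaults to the least severe class.
#' @return An object of class `grade_scheme`: a list with elements `classes`
#'   and `fallback`.
#' @examples
#' grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
#' grade_scheme(c("Healthy", "Diseased"))
#' @export
grade_scheme <- function(classes, fallback = classes[1]) {
  classes <- as.character(classes)
  if (length(classes) < 2)
    stop("a grade scheme needs at least 2 classes", call. = FALSE)
  if (anyDuplicated(classes))
    stop("class names must be unique", call. = FALSE)
  fallback <- as.character(fallback)
  if (length(fallback) != 1 || !fallback %in% classes)
    stop("fallback class must be one of the scheme classes", call. = FALSE)
  structure(list(classes = classes, fallback = fallback),
            class = "grade_scheme")
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat("Grade scheme (least -> most severe):",
      paste(x$classes, collapse = " < "), "\n")
  cat("Fallback class:", x$fallback, "\n")
  invisible(x)
}

#' The five Kaggle EyePACS source grades
#'
#' Grade names as used in the public EyePACS fundus dataset, least severe
#' first. The integers 0-4 are the dataset's numeric encoding of the same
#' grades and are accepted wherever grade names are read.
#'
#' @return Character vector of the five grade names.
#' @export
kaggle_grades <- function() {
  c("No DR", "Mild DR", "Moderate DR", "Severe DR", "Proliferative DR")
}

#' Define a severity-preserving label map between grade schemes
#'
#' @param entries Named character vector: names are source grades, values are
#'   target class names. Every source grade must map to exactly one target
#'   class, every target class must receive at least one source grade, and the
#'   map must preserve severity order (a more severe source grade never maps
#'   to a less severe target class).
#' @param source_scheme Character vector of source grade names in severity
#'   order.
#' @param target_scheme A [grade_scheme()].
#' @return An object of class `label_map`.
#' @seealso [preset_label_map()] for the shipped screening schemes.
#' @export
label_map <- function(entries, source_scheme, target_scheme) {
  stopifnot(inherits(target_scheme, "grade_scheme"))
  source_scheme <- as.character(source_scheme)
  if (!setequal(names(entries), source_scheme) ||
      length(entries) != length(source_scheme))
    stop("entries must cover every source grade exactly once", call. = FALSE)
  entries <- entries[source_scheme]  # severity order
  if (!all(entries %in% target_scheme$classes))
    stop("entries map outside the target scheme", call. = FALSE)
  if (!all(target_scheme$classes %in% entries))
    stop("every target class must receive at least one source grade",
         call. = FALSE)
  sev <- match(entries, target_scheme$classes)
  if (is.unsorted(sev))
    stop("map is not severity-preserving: a more severe source grade maps ",
         "to a less severe target class", call. = FALSE)
  structure(list(entries = entries, source_scheme = source_scheme,
                 target_scheme = target_scheme),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("Label map:", length(x$source_scheme), "source grades ->",
      length(x$target_scheme$classes), "target classes\n")
  for (g in x$source_scheme)
    cat("  ", format(g, width = 18), "->", x$entries[[g]], "\n")
  invisible(x)
}

#' Shipped screening label maps
#'
#' Two named remappings of the five EyePACS grades used for screening:
#' `"kaggle5to3"` collapses them to Healthy / Non-referable DR / Referable DR
#' (mild and moderate disease are detectable but do not yet warrant specialist
#' referral; severe and proliferative disease do), and `"kaggle5to2"` to
#' Healthy / Diseased.
#'
#' @param name `"kaggle5to3"` or `"kaggle5to2"`.
#' @return A [label_map()].
#' @examples
#' remap_labels(c("No DR", "Moderate DR"), preset_label_map("kaggle5to3"))
#' @export
preset_label_map <- function(name = c("kaggle5to3", "kaggle5to2")) {
  name <- match.arg(name)
  src <- kaggle_grades()
  if (name == "kaggle5to3") {
    tgt <- grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
    entries <- c("No DR" = "Healthy",
                 "Mild DR" = "Non-referable DR",
                 "Moderate DR" = "Non-referable DR",
                 "Severe DR" = "Referable DR",
                 "Proliferative DR" = "Referable DR")
  } else {
    tgt <- grade_scheme(c("Healthy", "Diseased"))
    entries <- c("No DR" = "Healthy",
                 "Mild DR" = "Diseased",
                 "Moderate DR" = "Diseased",
                 "Severe DR" = "Diseased",
                 "Proliferative DR" = "Diseased")
  }
  label_map(entries, src, tgt)
}

#' Read grade schemes and label maps from a YAML config file
#'
#' The config format holds one or more named maps, each with `source`,
#' `target` (ordered class lists, least severe first), optional
#' `fallback` (default: first target class) and `entries` (source -> target).
#' The two shipped presets live in
#' `system.file("extdata", "schemes.yaml", package = "drscreen")`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [label_map()] objects.
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(m) {
    tgt <- grade_scheme(m$target,
                        fallback = if (!is.null(m$fallback)) m$fallback
                                   else m$target[[1]])
    label_map(unlist(m$entries), m$source, tgt)
  })
  out
}

# Normalize a grade vector: integers 0-4 (Kaggle encoding) become names.
normalize_grades <- function(labels, source_scheme = kaggle_grades()) {
  labels <- as.character(labels)
  num <- suppressWarnings(as.integer(labels))
  is_num <- !is.na(num) & labels == as.character(num)
  bad <- is_num & (num < 0 | num >= length(source_scheme))
  if (any(bad))
    stop("numeric grade out of range 0-", length(source_scheme) - 1, ": ",
         labels[bad][1], call. = FALSE)
  labels[is_num] <- source_scheme[num[is_num] + 1]
  labels
}

#' Remap source grade labels to a target scheme
#'
#' @param labels Character vector of source grade names (integer aliases 0-4
#'   are accepted for the Kaggle encoding).
#' @param map A [label_map()].
#' @return Character vector of target class names, same length as `labels`.
#' @export
remap_labels <- function(labels, map) {
  stopifnot(inherits(map, "label_map"))
  if (length(labels) == 0) return(character(0))
  labels <- normalize_grades(labels, map$source_scheme)
  unknown <- setdiff(unique(labels), map$source_scheme)
  if (length(unknown))
    stop("unknown source grade(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(map$entries[labels])
}

#' Per-class counts of a labelled dataset
#'
#' @param labels Character vector of class names drawn from `scheme`.
#' @param scheme A [grade_scheme()].
#' @return An object of class `dataset_summary`: list with `counts` (named
#'   integer vector over all scheme classes, zeros included) and `total`.
#' @export
summarize_labels <- function(labels, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), scheme$classes)
  if (length(unknown))
    stop("label(s) outside the scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(labels, levels = scheme$classes))
  counts <- stats::setNames(as.integer(counts), scheme$classes)
  structure(list(counts = counts, total = length(labels)),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  for (cl in names(x$counts))
    cat(format(cl, width = 20), format(x$counts[[cl]], big.mark = ","), "\n")
  cat(format("Total", width = 20), format(x$total, big.mark = ","), "\n")
  invisible(x)
}

# Largest-remainder apportionment of n into parts proportional to ratios;
# ties in the remainder are broken by position order.
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    rem <- exact - sizes
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' Deterministic train/validation/test split
#'
#' Partitions sample identifiers into train, validation and test sets at the
#' given ratios (default 70/15/15). Set sizes follow largest-remainder
#' rounding; with `stratified = TRUE` (the default) the allocation is done
#' independently within each class so per-class proportions also match the
#' ratios within rounding. The split is a pure function of its arguments:
#' the same ids, labels, ratios and seed always give the identical partition.
#'
#' @param ids Character or integer vector of unique sample identifiers.
#' @param labels Class labels aligned with `ids`; required when
#'   `stratified = TRUE`.
#' @param ratios Numeric vector of three non-negative fractions
#'   (train, validation, test) summing to 1.
#' @param seed Integer seed controlling the random shuffle.
#' @param stratified Stratify the split by `labels`? Default `TRUE`:
#'   screening datasets are heavily imbalanced (referable disease is rare),
#'   and unstratified small test fractions would carry noisy class mixes.
#' @return List with character-vector elements `train`, `validation`, `test`;
#'   pairwise disjoint, union equal to `ids`.
#' @examples
#' sp <- make_split(sprintf("img%04d", 1:100),
#'                  labels = rep(c("Healthy", "Diseased"), c(80, 20)),
#'                  seed = 1)
#' lengths(sp)
#' @export
make_split <- function(ids, labels = NULL, ratios = c(0.70, 0.15, 0.15),
                       seed = 1L, stratified = TRUE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("sample ids must be unique", call. = FALSE)
  if (length(ratios) != 3 || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three non-negative fractions summing to 1",
         call. = FALSE)
  if (stratified && is.null(labels))
    stop("labels are required for a stratified split", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(ids))
    stop("labels must align with ids", call. = FALSE)

  assign_one <- function(grp_ids) {
    sizes <- largest_remainder(length(grp_ids), ratios)
    perm <- sample.int(length(grp_ids))
    shuffled <- grp_ids[perm]
    list(train = shuffled[seq_len(sizes[1])],
         validation = shuffled[seq_len(sizes[2]) + sizes[1]],
         test = shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]])
  }

  with_seed(seed, {
    if (stratified) {
      # class order fixed by first appearance for reproducibility
      labels <- as.character(labels)
      parts <- lapply(split(ids, factor(labels, levels = unique(labels))),
                      assign_one)
      out <- list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
                  validation = unlist(lapply(parts, `[[`, "validation"), use.names = FALSE),
                  test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
    } else {
      out <- assign_one(ids)
    }
    out
  })
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Read / write sample label tables
#'
#' Label tables are CSV/TSV with a header and columns `id`, `grade` and
#' optionally `split`; the grade column accepts grade names or the Kaggle
#' 0-4 integer encoding.
#'
#' @param path File path; tab-separated when the extension is `.tsv`.
#' @return `read_labels()`: data.frame with character columns `id`, `grade`
#'   (names, never integers) and `split` when present.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("id", "grade") %in% names(df)))
    stop("label table needs columns 'id' and 'grade'", call. = FALSE)
  df$grade <- normalize_grades(df$grade)
  df
}

#' @param df Data frame with columns `id`, `grade` and optionally `split`.
#' @rdname read_labels
#' @export
write_labels <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
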