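#' Validate and normalize a probability vector
#'
#' Classifier softmax outputs must be non-negative and sum to 1. Sums within
#' `1e-6` of 1 are accepted as-is; sums off by up to `1e-3` are renormalized
#' with a warning (rounding in CSV round-trips); anything further off is
#' rejected.
#'
#' @param probs Numeric vector aligned with the scheme classes.
#' @param n_classes Expected length.
#' @return The (possibly renormalized) probability vector.
#' @keywords internal
validate_probs <- function(probs, n_classes) {
  if (length(probs) != n_classes)
    stop("probability vector has length ", length(probs),
         ", expected ", n_classes, call. = FALSE)
  if (any(probs < 0) || anyNA(probs))
    stop("probabilities must be non-negative", call. = FALSE)
  s <- sum(probs)
  if (abs(s - 1) > 1e-3)
    stop("probabilities sum to ", format(s), ", outside tolerance 1e-3",
         call. = FALSE)
  if (abs(s - 1) > 1e-6) {
    warning("probabilities sum to ", format(s), "; renormalizing")
    probs <- probs / s
  }
  probs
}

#' Decision policies over classifier probability vectors
#'
#' A decision policy maps a class-probability vector to a predicted class.
#' Three rules are provided:
#'
#' * `policy_argmax()` — the usual classification-output rule: the class of
#'   maximum probability, exact ties broken toward the more severe class
#'   (conservative for screening).
#' * `policy_cascade()` — cascading thresholds: classes are scanned from most
#'   to least severe, skipping the fallback class, and the first class whose
#'   probability reaches its threshold is returned regardless of the less
#'   severe probabilities; if none fires the fallback class is returned.
#'   A specification such as `(~, 0.3, 0.3)` on
#'   (Healthy, Non-referable, Referable) means: Referable wins at
#'   probability >= 0.3, else Non-referable at >= 0.3, else Healthy.
#' * `policy_margin_max()` — margin max: let `m*` be the maximum probability;
#'   the most-preferred class whose probability lies within `margin` of `m*`
#'   is returned. The argmax always satisfies the condition, so a result
#'   always exists. Boosting a class means putting it first in the
#'   preference order; with `margin = 0.2` and boosting Healthy, the vector
#'   (0.3, 0.45, 0.25) yields Healthy even though it is not the maximum.
#'
#' By default the preference order places the boosted class first and the
#' remaining classes by increasing severity distance from it (ties toward the
#' more severe class), so boosting the least severe class gives
#' severity-ascending preference and boosting the most severe class gives
#' severity-descending preference.
#'
#' @param scheme A [grade_scheme()].
#' @param thresholds Named numeric vector of thresholds in \[0, 1\], one per
#'   class except the fallback class.
#' @param margin Real in \[0, 1\].
#' @param boost Class whose sensitivity is boosted (put first in the
#'   preference order). Ignored when `preference` is given.
#' @param preference Optional explicit preference order: a permutation of
#'   `scheme$classes`, most preferred first.
#' @return A policy object (class `dr_policy` plus a rule-specific subclass)
#'   usable with [decide()] and [apply_policy()].
#' @examples
#' sch <- grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
#' decide(c(0.3, 0.45, 0.25), policy_argmax(sch))
#' decide(c(0.3, 0.45, 0.25), policy_margin_max(0.2, "Healthy", sch))
#' decide(c(0.5, 0.2, 0.3),
#'        policy_cascade(c("Non-referable DR" = 0.3, "Referable DR" = 0.3), sch))
#' @name policies
NULL

#' @rdname policies
#' @export
policy_argmax <- function(scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  structure(list(scheme = scheme, label = "Original"),
            class = c("argmax_policy", "dr_policy"))
}

#' @rdname policies
#' @export
policy_cascade <- function(thresholds, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  need <- setdiff(scheme$classes, scheme$fallback)
  if (!setequal(names(thresholds), need))
    stop("thresholds must cover exactly the non-fallback classes: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  thresholds <- thresholds[need]
  lab <- sprintf("Cascading Thresholds (%s)", paste(
    vapply(scheme$classes, function(cl)
      if (cl == scheme$fallback) "~" else format(thresholds[[cl]]),
      character(1)), collapse = ", "))
  structure(list(thresholds = thresholds, scheme = scheme, label = lab),
            class = c("cascade_policy", "dr_policy"))
}

#' @rdname policies
#' @export
policy_margin_max <- function(margin, boost = NULL, scheme,
                              preference = NULL) {
  stopifnot(inherits(scheme, "grade_scheme"))
  if (margin < 0 || margin > 1)
    stop("margin must lie in [0, 1]", call. = FALSE)
  if (is.null(preference)) {
    if (is.null(boost) || !boost %in% scheme$classes)
      stop("boost must name a scheme class (or give an explicit preference)",
           call. = FALSE)
    sev <- seq_along(scheme$classes)
    b <- match(boost, scheme$classes)
    # increasing severity distance from the boosted class, ties -> more severe
    preference <- scheme$classes[order(abs(sev - b), -sev)]
  } else {
    if (!setequal(preference, scheme$classes) ||
        length(preference) != length(scheme$classes))
      stop("preference must be a permutation of the scheme classes",
           call. = FALSE)
    boost <- preference[1]
  }
  structure(list(margin = margin, preference = preference, boost = boost,
                 scheme = scheme,
                 label = sprintf("Margin Max (%s) Boosting %s",
                                 format(margin), boost)),
            class = c("margin_max_policy", "dr_policy"))
}

#' @export
print.dr_policy <- function(x, ...) {
  cat(x$label, "on scheme:", paste(x$scheme$classes, collapse = " < "), "\n")
  invisible(x)
}

#' Apply a decision policy to one probability vector
#'
#' @param probs Numeric probability vector aligned with the policy's scheme
#'   classes (validated and renormalized as for softmax outputs).
#' @param policy A policy from [policy_argmax()], [policy_cascade()] or
#'   [policy_margin_max()].
#' @return A single class name.
#' @export
decide <- function(probs, policy) UseMethod("decide", policy)

#' @export
decide.argmax_policy <- function(probs, policy) {
  p <- validate_probs(probs, length(policy$scheme$classes))
  m <- max(p)
  # ties broken toward the more severe class
  policy$scheme$classes[max(which(p == m))]
}

#' @export
decide.cascade_policy <- function(probs, policy) {
  sch <- policy$scheme
  p <- stats::setNames(validate_probs(probs, length(sch$classes)),
                       sch$classes)
  for (cl in rev(sch$classes)) {
    if (cl == sch$fallback) next
    if (p[[cl]] >= policy$thresholds[[cl]]) return(cl)
  }
  sch$fallback
}

#' @export
decide.margin_max_policy <- function(probs, policy) {
  sch <- policy$scheme
  p <- stats::setNames(validate_probs(probs, length(sch$classes)),
                       sch$classes)
  m <- max(p)
  for (cl in policy$preference)
    if (m - p[[cl]] <= policy$margin) return(cl)
  stop("unreachable: the argmax class is always within the margin")
}

#' Apply a decision policy to a batch of probability records
#'
#' @param records Data frame of probability records as produced by
#'   [gen_prob_records()] or [read_prob_records()]: a column `id`, one
#'   `p_<class>` column per scheme class (in scheme order), and optionally
#'   `true_label`.
#' @param policy A `dr_policy`.
#' @return Data frame with columns `id` and `predicted`, one row per record,
#'   in input order.
#' @export
apply_policy <- function(records, policy) {
  stopifnot(inherits(policy, "dr_policy"))
  pm <- prob_matrix(records, policy$scheme)
  predicted <- vapply(seq_len(nrow(pm)), function(i) decide(pm[i, ], policy),
                      character(1))
  data.frame(id = as.character(records$id), predicted = predicted,
             stringsAsFactors = FALSE)
}

# Extract and validate the K probability columns of a record table.
prob_matrix <- function(records, scheme) {
  cols <- prob_cols(scheme)
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records lack probability column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pm <- as.matrix(records[cols])
  if (nrow(pm)) {
    s <- rowSums(pm)
    if (any(pm < 0) || anyNA(pm))
      stop("probabilities must be non-negative", call. = FALSE)
    bad <- abs(s - 1) > 1e-3
    if (any(bad))
      stop("record ", records$id[which(bad)[1]], " probabilities sum to ",
           format(s[which(bad)[1]]), ", outside tolerance 1e-3",
           call. = FALSE)
    fix <- abs(s - 1) > 1e-6
    if (any(fix)) {
      warning(sum(fix), " record(s) renormalized (sum off by <= 1e-3)")
      pm[fix, ] <- pm[fix, ] / s[fix]
    }
  }
  pm
}

prob_cols <- function(scheme) paste0("p_", gsub("[^A-Za-z0-9]+", "_",
                                                scheme$classes))

#' Read / write probability record tables
#'
#' Probability tables are CSV with a header `id, p_<class>..., true_label`
#' (the `p_` column names use underscores for non-alphanumeric characters in
#' the class name, e.g. `p_Non_referable_DR`); `true_label` is optional.
#'
#' @param path CSV file path.
#' @param scheme A [grade_scheme()] the columns are checked against.
#' @return `read_prob_records()`: data.frame of records.
#' @export
read_prob_records <- function(path, scheme) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$id <- as.character(df$id)
  pm <- prob_matrix(df, scheme)  # validates
  df[prob_cols(scheme)] <- pm
  df
}

#' @param records Record data frame.
#' @rdname read_prob_records
#' @export
write_prob_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param predictions Data frame `(id, predicted)` from [apply_policy()].
#' @rdname read_prob_records
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
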