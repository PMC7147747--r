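#' Evaluate one decision policy on labelled records
#'
#' Applies the policy, builds the confusion matrix against `true_label` and
#' computes the screening metrics.
#'
#' @param records Probability records with a `true_label` column.
#' @param policy A `dr_policy`.
#' @param scheme A [grade_scheme()]; defaults to the policy's scheme.
#' @return A `metrics_report`.
#' @export
evaluate_policy <- function(records, policy, scheme = policy$scheme) {
  if (is.null(records$true_label))
    stop("records need a 'true_label' column for evaluation", call. = FALSE)
  pred <- apply_policy(records, policy)
  compute_metrics(confusion(records$true_label, pred$predicted, scheme))
}

#' Compare decision policies on a common record set
#'
#' Evaluates each supplied policy plus the plain argmax baseline (the
#' `"Original"` column) on the same records, producing one metrics column
#' per policy — the structure of a boosted-vs-original screening report.
#'
#' @param records Probability records with `true_label`.
#' @param policies List of `dr_policy` objects (at least one).
#' @param scheme A [grade_scheme()].
#' @return An object of class `comparison_report`: list with `reports`
#'   (named list of `metrics_report`, `"Original"` included), `scheme` and
#'   `header` (reproducibility lines).
#' @examples
#' rec <- gen_prob_records(paperlike_prob_config(n = 500, seed = 2))
#' sch <- grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
#' cmp <- run_comparison(rec, list(policy_margin_max(0.4, "Healthy", sch)), sch)
#' print(cmp)
#' @export
run_comparison <- function(records, policies, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  if (length(policies) == 0)
    stop("at least one policy is required", call. = FALSE)
  if (inherits(policies, "dr_policy")) policies <- list(policies)
  all_pol <- c(list(policy_argmax(scheme)), policies)
  labels <- vapply(all_pol, `[[`, character(1), "label")
  labels <- make.unique(labels, sep = " #")
  reports <- stats::setNames(
    lapply(all_pol, function(p) evaluate_policy(records, p, scheme)), labels)
  # Original column placed in the middle, mirroring boosted/original layout
  structure(list(reports = reports, scheme = scheme,
                 header = run_header(list(n = nrow(records),
                                          policies = labels))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(x$header, sep = "\n")
  cat(format_metrics(x$reports), sep = "\n")
  invisible(x)
}

# Reproducibility header: config hash (FNV-1a over the deparsed config),
# package version, R version.
run_header <- function(config) {
  h <- fnv1a(paste(deparse(config), collapse = ""))
  c(sprintf("# drscreen %s | R %s.%s | config %s",
            as.character(utils::packageVersion("drscreen")),
            R.version$major, R.version$minor, h))
}

# 32-bit FNV-1a in double arithmetic; the multiply is split 16/16 so no
# intermediate exceeds 2^53.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (((h %/% 65536) * m %% 65536) * 65536 + (h %% 65536) * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Operating-point sweep for a boosting policy
#'
#' Evaluates a grid of policy parameters (margins for margin max, uniform
#' threshold values for cascading thresholds) and selects the operating
#' point that meets a screening objective — e.g. sensitivity of the
#' referable class at least 0.85 — while maximizing the complementary
#' metric, the specificity of the same class. Among parameters tied on the
#' complement the least aggressive (first in grid order) is chosen. If no
#' parameter meets the objective the best-achieving one is returned with
#' `met = FALSE`.
#'
#' @param records Probability records with `true_label`.
#' @param policy_kind `"marginmax"` or `"cascade"`.
#' @param grid Ordered numeric vector of parameter values (margins, or a
#'   common threshold applied to every non-fallback class).
#' @param objective List with elements `metric` (a `metrics_report` column,
#'   e.g. `"sensitivity"`), `class`, `direction` (`">="` or `"<="`) and
#'   `target`.
#' @param scheme A [grade_scheme()].
#' @param boost Boosted class for margin max; defaults to the scheme's most
#'   severe class.
#' @return List with `chosen` (parameter value), `met` (logical),
#'   `objective_values` (per grid point), and `report` (a
#'   `comparison_report` over the grid).
#' @export
sweep_policy <- function(records, policy_kind = c("marginmax", "cascade"),
                         grid, objective, scheme,
                         boost = scheme$classes[length(scheme$classes)]) {
  policy_kind <- match.arg(policy_kind)
  if (length(grid) == 0) stop("empty parameter grid", call. = FALSE)
  stopifnot(all(c("metric", "class", "target") %in% names(objective)))
  direction <- if (is.null(objective$direction)) ">=" else objective$direction
  make_pol <- function(v) {
    if (policy_kind == "marginmax") policy_margin_max(v, boost, scheme)
    else {
      th <- stats::setNames(rep(v, length(scheme$classes) - 1),
                            setdiff(scheme$classes, scheme$fallback))
      policy_cascade(th, scheme)
    }
  }
  policies <- lapply(grid, make_pol)
  cmp <- run_comparison(records, policies, scheme)
  grid_reports <- cmp$reports[-1]  # drop the Original column
  pick <- function(rep, metric) {
    v <- rep[[metric]][match(objective$class, rep$class)]
    if (is.null(v)) NA_real_ else v
  }
  obj_vals <- vapply(grid_reports, pick, numeric(1), objective$metric)
  comp_vals <- vapply(grid_reports, pick, numeric(1), "specificity")
  ok <- !is.na(obj_vals) &
    (if (direction == ">=") obj_vals >= objective$target
     else obj_vals <= objective$target)
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[order(-comp_vals[cand], cand)][1]
    met <- TRUE
  } else {
    best <- if (direction == ">=") which.max(obj_vals) else which.min(obj_vals)
    met <- FALSE
  }
  list(chosen = grid[best], met = met,
       objective_values = stats::setNames(obj_vals, grid), report = cmp)
}

#' Curated-versus-uncurated evaluation
#'
#' The screening robustness experiment: score (or take precomputed scores
#' for) every record's image, curate at a threshold, then evaluate the same
#' policies on the full (un-curated) set and on the curated subset.
#'
#' @param records Probability records with `true_label`.
#' @param quality_scores Data frame `(id, score)` covering every record id
#'   (e.g. from [score_quality_batch()]).
#' @param policies List of `dr_policy` objects.
#' @param threshold Curation threshold in \[0, 1\].
#' @param scheme A [grade_scheme()].
#' @return List with `uncurated` and `curated` (`comparison_report`s;
#'   `curated` is `NULL` with `curated_empty = TRUE` when everything is
#'   rejected), `rejection_rate` and the `curation` object.
#' @export
run_curation_experiment <- function(records, quality_scores, policies,
                                    threshold, scheme) {
  cur <- curate(records$id, quality_scores, threshold)
  uncurated <- run_comparison(records, policies, scheme)
  curated_records <- records[records$id %in% cur$curated, , drop = FALSE]
  if (nrow(curated_records) == 0) {
    curated <- NULL
    empty <- TRUE
  } else {
    curated <- run_comparison(curated_records, policies, scheme)
    empty <- FALSE
  }
  list(uncurated = uncurated, curated = curated, curated_empty = empty,
       rejection_rate = cur$rejection_rate, curation = cur)
}
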