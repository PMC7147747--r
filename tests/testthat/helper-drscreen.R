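# Shared fixtures for the drscreen suite; everything is built in code.

sch3 <- function() grade_scheme(c("Healthy", "Non-referable DR", "Referable DR"))
sch2 <- function() grade_scheme(c("Healthy", "Diseased"))

# All probability vectors over k classes on a step-grid of the simplex.
simplex_grid <- function(k, step = 0.05) {
  m <- round(1 / step)
  if (k == 2) {
    a <- 0:m
    cbind(a, m - a) / m
  } else if (k == 3) {
    out <- list()
    for (a in 0:m) for (b in 0:(m - a)) out[[length(out) + 1]] <- c(a, b, m - a - b)
    do.call(rbind, out) / m
  } else stop("unsupported k")
}

# Random confusion matrix with positive grand total.
random_cm <- function(k, scheme = NULL, max_count = 40) {
  if (is.null(scheme))
    scheme <- grade_scheme(paste0("class", seq_len(k)))
  m <- matrix(sample.int(max_count + 1, k * k, replace = TRUE) - 1L, k, k)
  if (sum(m) == 0) m[1, 1] <- 1L
  labs <- rep(rep(scheme$classes, k), as.vector(t(m)))
  pred <- rep(rep(scheme$classes, each = k), as.vector(m))
  # rebuild through the public constructor from expanded samples
  true <- rep(scheme$classes, rowSums(m))
  pred2 <- unlist(lapply(seq_len(k), function(i)
    rep(scheme$classes, m[i, ])), use.names = FALSE)
  confusion(true, pred2, scheme)
}

# Records table from explicit probability rows.
records_from_matrix <- function(pm, scheme, true_label = NULL) {
  df <- data.frame(id = sprintf("r%04d", seq_len(nrow(pm))),
                   stringsAsFactors = FALSE)
  df[paste0("p_", gsub("[^A-Za-z0-9]+", "_", scheme$classes))] <-
    as.data.frame(pm)
  if (!is.null(true_label)) df$true_label <- true_label
  df
}
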