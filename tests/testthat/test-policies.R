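test_that("argmax picks the maximum and breaks ties toward severity", {
  expect_identical(decide(c(1, 0, 0), policy_argmax(sch3())), "Healthy")
  expect_identical(decide(c(0.3, 0.45, 0.25), policy_argmax(sch3())),
                   "Non-referable DR")
  expect_identical(decide(c(0.5, 0.5), policy_argmax(sch2())), "Diseased")
})

test_that("cascading thresholds fire from most severe downward", {
  pol <- policy_cascade(c("Non-referable DR" = 0.3, "Referable DR" = 0.3),
                        sch3())
  # the severe class meets its threshold regardless of larger probabilities
  expect_identical(decide(c(0.50, 0.20, 0.30), pol), "Referable DR")
  expect_identical(decide(c(0.90, 0.05, 0.05), pol), "Healthy")
  expect_identical(decide(c(0.55, 0.35, 0.10), pol), "Non-referable DR")
})

test_that("margin max reproduces the boosting example and its fallback", {
  pol <- policy_margin_max(0.2, "Healthy", sch3())
  expect_identical(decide(c(0.3, 0.45, 0.25), pol), "Healthy")
  # margin not met: falls back to the argmax class
  expect_identical(decide(c(0.2, 0.45, 0.35), pol), "Non-referable DR")
  # margin 1 always selects the boosted class
  pol1 <- policy_margin_max(1, "Healthy", sch3())
  set.seed(31)
  for (i in 1:20) {
    p <- rgamma(3, 1); p <- p / sum(p)
    expect_identical(decide(p, pol1), "Healthy")
  }
})

test_that("every policy is total on the simplex", {
  grid <- simplex_grid(3, 0.05)
  pols <- list(policy_argmax(sch3()),
               policy_cascade(c("Non-referable DR" = 0.3,
                                "Referable DR" = 0.3), sch3()),
               policy_margin_max(0.4, "Healthy", sch3()),
               policy_margin_max(0.4, "Referable DR", sch3()))
  for (pol in pols) {
    out <- apply(grid, 1, decide, policy = pol)
    expect_true(all(out %in% sch3()$classes))
  }
})

test_that("margin 0 reproduces argmax away from exact ties", {
  set.seed(32)
  pol0 <- policy_margin_max(0, "Healthy", sch3())
  am <- policy_argmax(sch3())
  for (i in 1:50) {
    p <- rgamma(3, 1); p <- p / sum(p)
    if (anyDuplicated(p)) next
    expect_identical(decide(p, pol0), decide(p, am))
  }
})

test_that("degenerate cascading thresholds collapse to constants", {
  hi <- policy_cascade(c("Non-referable DR" = 1, "Referable DR" = 1), sch3())
  lo <- policy_cascade(c("Non-referable DR" = 0, "Referable DR" = 0), sch3())
  set.seed(33)
  for (i in 1:20) {
    p <- rgamma(3, 1); p <- p / sum(p)
    if (max(p) < 1) expect_identical(decide(p, hi), "Healthy")
    expect_identical(decide(p, lo), "Referable DR")
  }
})

test_that("apply_policy matches record-by-record application", {
  set.seed(34)
  cfg <- paperlike_prob_config(n = 300, seed = 5)
  rec <- gen_prob_records(cfg)
  pol <- policy_margin_max(0.3, "Healthy", sch3())
  batch <- apply_policy(rec, pol)
  expect_identical(batch$id, rec$id)
  pm <- as.matrix(rec[paste0("p_", c("Healthy", "Non_referable_DR",
                                     "Referable_DR"))])
  loop <- vapply(seq_len(nrow(pm)), function(i) decide(pm[i, ], pol),
                 character(1))
  expect_identical(batch$predicted, loop)
  # empty input
  empty <- apply_policy(rec[0, ], pol)
  expect_identical(nrow(empty), 0L)
})

test_that("boosted-class predictions grow with the margin", {
  rec <- gen_prob_records(paperlike_prob_config(n = 2000, seed = 6))
  counts <- vapply(c(0, 0.1, 0.2, 0.4, 0.7, 1), function(m) {
    pred <- apply_policy(rec, policy_margin_max(m, "Healthy", sch3()))
    sum(pred$predicted == "Healthy")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("severe-class predictions shrink as its cascade threshold rises", {
  rec <- gen_prob_records(paperlike_prob_config(n = 2000, seed = 7))
  counts <- vapply(c(0, 0.2, 0.3, 0.5, 0.8), function(t) {
    pol <- policy_cascade(c("Non-referable DR" = 0.3, "Referable DR" = t),
                          sch3())
    sum(apply_policy(rec, pol)$predicted == "Referable DR")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("boosting Healthy raises its sensitivity and Diseased specificity", {
  sch <- sch2()
  cfg <- prob_gen_config(sch, 3000,
                         c(Healthy = 0.7, Diseased = 0.3),
                         list(Healthy = c(5, 2), Diseased = c(2, 4)),
                         seed = 8)
  rec <- gen_prob_records(cfg)
  base <- evaluate_policy(rec, policy_argmax(sch))
  boost <- evaluate_policy(rec, policy_margin_max(0.3, "Healthy", sch))
  sens_h <- function(r) r$sensitivity[r$class == "Healthy"]
  spec_d <- function(r) r$specificity[r$class == "Diseased"]
  expect_gte(sens_h(boost), sens_h(base))
  expect_gte(spec_d(boost), spec_d(base))
  # one-vs-rest identity: the two quantities coincide in a binary scheme
  expect_equal(sens_h(boost), spec_d(boost))
})

test_that("probability validation renormalizes small drift and rejects large", {
  pol <- policy_argmax(sch2())
  expect_warning(out <- decide(c(0.6, 0.4005), pol), "renormaliz")
  expect_identical(out, "Healthy")
  expect_error(decide(c(0.6, 0.5), pol), "outside tolerance")
  expect_error(decide(c(-0.1, 1.1), pol), "non-negative")
  expect_error(decide(c(0.5, 0.3, 0.2), pol), "length")
})

test_that("policy constructors validate their parameters", {
  expect_error(policy_cascade(c("Non-referable DR" = 0.3), sch3()),
               "cover exactly")
  expect_error(policy_cascade(c("Healthy" = 0.3, "Non-referable DR" = 0.3,
                                "Referable DR" = 0.3), sch3()),
               "cover exactly")
  expect_error(policy_margin_max(1.2, "Healthy", sch3()), "margin")
  expect_error(policy_margin_max(0.2, "Cataract", sch3()), "boost")
  # explicit preference must be a permutation
  expect_error(policy_margin_max(0.2, scheme = sch3(),
                                 preference = c("Healthy", "Healthy",
                                                "Referable DR")),
               "permutation")
})

test_that("probability records round-trip through CSV", {
  rec <- gen_prob_records(paperlike_prob_config(n = 50, seed = 9))
  p <- withr::local_tempfile(fileext = ".csv")
  write_prob_records(rec, p)
  back <- read_prob_records(p, sch3())
  expect_identical(back$id, rec$id)
  expect_identical(back$true_label, rec$true_label)
  pm_cols <- grep("^p_", names(rec), value = TRUE)
  expect_equal(as.matrix(back[pm_cols]), as.matrix(rec[pm_cols]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
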