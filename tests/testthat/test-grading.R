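test_that("preset maps reproduce the screening remapping", {
  m3 <- preset_label_map("kaggle5to3")
  expect_identical(remap_labels("Moderate DR", m3), "Non-referable DR")
  expect_identical(remap_labels(c("Severe DR", "Proliferative DR"), m3),
                   rep("Referable DR", 2))
  m2 <- preset_label_map("kaggle5to2")
  expect_identical(remap_labels(c("No DR", "No DR"), m2),
                   c("Healthy", "Healthy"))
  expect_identical(remap_labels(c("Mild DR", "Severe DR"), m2),
                   rep("Diseased", 2))
  # Kaggle integer aliases
  expect_identical(remap_labels(c("0", "2", "4"), m3),
                   c("Healthy", "Non-referable DR", "Referable DR"))
})

test_that("remapping matches a brute-force tally on random compositions", {
  m3 <- preset_label_map("kaggle5to3")
  lookup <- c("No DR" = "Healthy", "Mild DR" = "Non-referable DR",
              "Moderate DR" = "Non-referable DR", "Severe DR" = "Referable DR",
              "Proliferative DR" = "Referable DR")
  set.seed(11)
  for (i in 1:5) {
    labels <- sample(kaggle_grades(), 100, replace = TRUE)
    out <- remap_labels(labels, m3)
    expect_length(out, 100)
    oracle <- vapply(labels, function(l) lookup[[l]], character(1))
    expect_identical(c(table(out)), c(table(unname(oracle))))
    # conservation: target counts sum to input length
    expect_identical(sum(table(out)), 100L)
  }
})

test_that("unknown source grades are rejected by name", {
  m <- preset_label_map("kaggle5to3")
  expect_error(remap_labels(c("No DR", "Glaucoma"), m), "Glaucoma")
  expect_error(remap_labels("7", m), "out of range")
})

test_that("label_map enforces coverage and severity order", {
  tgt <- grade_scheme(c("low", "high"))
  expect_error(label_map(c(a = "low", b = "low"), c("a", "b"), tgt),
               "at least one source grade")
  # severity inversion: more severe source maps to less severe target
  expect_error(label_map(c(a = "high", b = "low"), c("a", "b"), tgt),
               "severity")
  ok <- label_map(c(a = "low", b = "high"), c("a", "b"), tgt)
  expect_s3_class(ok, "label_map")
})

test_that("summarize_labels reproduces the screening composition counts", {
  labels <- rep(c("Healthy", "Non-referable DR", "Referable DR"),
                c(65300, 19400, 4000))
  s <- summarize_labels(labels, sch3())
  expect_identical(s$counts, c("Healthy" = 65300L,
                               "Non-referable DR" = 19400L,
                               "Referable DR" = 4000L))
  expect_identical(s$total, 88700L)
  s2 <- summarize_labels(rep(c("Healthy", "Diseased"), c(65300, 23400)),
                         sch2())
  expect_identical(s2$total, 88700L)
})

test_that("summarize_labels handles empty input and tallies randomly", {
  s <- summarize_labels(character(0), sch2())
  expect_identical(unname(s$counts), c(0L, 0L))
  expect_identical(s$total, 0L)
  set.seed(4)
  labels <- sample(sch3()$classes, 500, replace = TRUE,
                   prob = c(0.7, 0.25, 0.05))
  s3 <- summarize_labels(labels, sch3())
  for (cl in sch3()$classes)
    expect_identical(s3$counts[[cl]], sum(labels == cl))
  expect_error(summarize_labels("Cataract", sch3()), "Cataract")
})

test_that("splits are disjoint, exhaustive and reproducible", {
  set.seed(9)
  for (n in c(10, 101, 1234)) {
    ids <- sprintf("id%05d", seq_len(n))
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    sp <- make_split(ids, labels, seed = 7)
    expect_setequal(c(sp$train, sp$validation, sp$test), ids)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$validation, sp$test), 0)
    sp2 <- make_split(ids, labels, seed = 7)
    expect_identical(sp, sp2)
    expect_false(identical(sp, make_split(ids, labels, seed = 8)))
  }
})

test_that("a 70/15/15 split of 88,700 ids yields a 13,305 test set", {
  ids <- as.character(seq_len(88700))
  labels <- rep(c("Healthy", "Non-referable DR", "Referable DR"),
                c(65300, 19400, 4000))
  sp <- make_split(ids, labels, seed = 1)
  expect_length(sp$test, 13305)
  expect_length(sp$validation, 13305)
  expect_length(sp$train, 62090)
})

test_that("degenerate ratios put everything in one set", {
  sp <- make_split(as.character(1:10), ratios = c(1, 0, 0), seed = 1,
                   stratified = FALSE)
  expect_length(sp$train, 10)
  expect_length(sp$validation, 0)
  expect_length(sp$test, 0)
})

test_that("stratified allocation matches a largest-remainder oracle", {
  lr_oracle <- function(n, ratios) {
    exact <- n * ratios
    sz <- floor(exact)
    rem <- exact - sz
    for (extra in seq_len(n - sum(sz)))
      sz[order(-rem, seq_along(rem))[extra]] <-
        sz[order(-rem, seq_along(rem))[extra]] + 1
    sz
  }
  set.seed(2)
  ids <- sprintf("x%04d", 1:1000)
  labels <- sample(c("a", "b", "c"), 1000, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
  sp <- make_split(ids, labels, seed = 3)
  for (cl in c("a", "b", "c")) {
    n_cl <- sum(labels == cl)
    want <- lr_oracle(n_cl, c(0.7, 0.15, 0.15))
    got <- c(sum(ids[labels == cl] %in% sp$train),
             sum(ids[labels == cl] %in% sp$validation),
             sum(ids[labels == cl] %in% sp$test))
    expect_identical(got, as.integer(want))
  }
})

test_that("split input validation rejects bad specs", {
  expect_error(make_split(c("a", "a"), seed = 1, stratified = FALSE),
               "unique")
  expect_error(make_split(c("a", "b"), ratios = c(0.5, 0.2, 0.2), seed = 1,
                          stratified = FALSE), "summing to 1")
  expect_error(make_split(c("a", "b"), seed = 1), "labels")
})

test_that("label tables round-trip through CSV and TSV with aliases", {
  df <- data.frame(id = c("i1", "i2", "i3"),
                   grade = c("No DR", "2", "Proliferative DR"),
                   stringsAsFactors = FALSE)
  for (ext in c("csv", "tsv")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_labels(df, p)
    back <- read_labels(p)
    expect_identical(back$grade,
                     c("No DR", "Moderate DR", "Proliferative DR"))
    expect_identical(back$id, df$id)
  }
})

test_that("scheme config file reproduces the shipped presets", {
  cfg <- read_scheme_config(system.file("extdata", "schemes.yaml",
                                        package = "drscreen"))
  expect_setequal(names(cfg), c("kaggle5to3", "kaggle5to2"))
  for (nm in names(cfg)) {
    want <- preset_label_map(nm)
    expect_identical(cfg[[nm]]$entries, want$entries)
    expect_identical(cfg[[nm]]$target_scheme$classes,
                     want$target_scheme$classes)
  }
})
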