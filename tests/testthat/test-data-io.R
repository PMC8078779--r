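test_that("matrix TSV round-trips exactly and normalises orientation", {
  set.seed(1)
  m <- matrix(rnorm(6), 3, 2,
              dimnames = list(c("S1", "S2", "S3"), c("gA", "gB")))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  back <- read_matrix_tsv(f)
  expect_identical(back, m)

  # genes-in-rows file of 5 genes x 4 samples comes back as 4 x 5
  g <- matrix(seq_len(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("S", 1:4)))
  f2 <- tempfile(fileext = ".tsv")
  write_matrix_tsv(t(g), f2, orientation = "genes_in_rows")
  back2 <- read_matrix_tsv(f2, orientation = "genes_in_rows")
  expect_equal(dim(back2), c(4, 5))
  expect_identical(back2, t(g))
})

test_that("readers reject duplicate identifiers and non-numeric cells", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "TP53\t1\t2", "KRAS\t0\t1", "TP53\t1\t1"), f)
  expect_error(read_matrix_tsv(f, "genes_in_rows"), "TP53")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tgA\tgB", "S1\t1.5\t2", "S2\toops\t3"), f2)
  expect_error(read_matrix_tsv(f2), "oops.*S2.*gA|S2.*gA.*oops")
})

test_that("match_and_filter keeps the staged sample intersection", {
  ex <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("g1", "g2")))
  mu <- matrix(0, 3, 2, dimnames = list(c("B", "C", "D"), c("g1", "g2")))
  stages <- c(B = 2, C = 4, D = 1)
  cohort <- match_and_filter(ex, mu, stages)
  expect_identical(cohort$sample_ids, c("B", "C"))
  expect_identical(cohort$stages, c(2L, 4L))

  # identical id sets, all staged -> all retained
  stages2 <- c(A = 1, B = 2, C = 3)
  mu2 <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("g1", "g2")))
  expect_length(match_and_filter(ex, mu2, stages2)$sample_ids, 3)

  # disjoint id sets -> error
  mu3 <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("g1", "g2")))
  expect_error(match_and_filter(ex, mu3, stages2), "no samples")
})

test_that("stage labels map from Roman, Arabic and 'Stage X' forms", {
  expect_identical(map_stage_labels(c("I", "II", "III", "IV")), 1:4)
  expect_identical(map_stage_labels(c("Stage I", "stage iv", "2", " 3 ")),
                   c(1L, 4L, 2L, 3L))
  expect_warning(out <- map_stage_labels(c("I", "Stage X", "NA")),
                 "unmappable")
  expect_identical(out, c(1L, NA_integer_, NA_integer_))
})

test_that("stratified split hits the per-stage round rule", {
  cohort <- tiny_cohort(counts = c(10, 10, 10, 10))
  sp <- stratified_split(cohort, 0.7, seed = 1)
  expect_equal(unname(c(table(sp$train$stages))), rep(7L, 4))
  expect_equal(unname(c(table(sp$test$stages))), rep(3L, 4))

  # severely imbalanced counts: round(0.7 * n_s) per stage
  cohort2 <- tiny_cohort(counts = c(110, 383, 152, 12), n_genes = 4,
                         n_informative = 2)
  sp2 <- stratified_split(cohort2, 0.7, seed = 3)
  expect_equal(unname(c(table(sp2$train$stages))), c(77L, 268L, 106L, 8L))
  expect_equal(length(sp2$train$sample_ids), 459L)

  # determinism
  sp3 <- stratified_split(cohort2, 0.7, seed = 3)
  expect_identical(sp2$train$sample_ids, sp3$train$sample_ids)

  # a stage with < 2 samples cannot be split
  bad <- cohort2
  keep <- bad$sample_ids[bad$stages != 4 |
                           bad$sample_ids == bad$sample_ids[bad$stages == 4][1]]
  bad <- omixaug:::subset_cohort(bad, keep)
  expect_error(stratified_split(bad, 0.7, seed = 1), "4")
})

test_that("split partitions are disjoint, exhaustive and correctly sized (fuzz)", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- sample(2:9, 4, replace = TRUE)
    n <- sum(counts)
    stages <- rep(1:4, counts)
    ids <- sprintf("S%03d", seq_len(n))
    expr <- matrix(0, n, 1, dimnames = list(ids, "g1"))
    cohort <- cohort_dataset(expr, expr, stages, ids)
    frac <- runif(1, 0.3, 0.9)
    sp <- stratified_split(cohort, frac, seed = i)
    expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
    expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), ids)
    want <- pmin(pmax(round(frac * counts), 1), counts - 1)
    expect_equal(unname(c(table(sp$train$stages))), as.integer(want))
  }
})

test_that("cohort invariants are enforced", {
  ex <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("g1", "g2")))
  expect_error(cohort_dataset(ex, ex, stages = c(1, 5)), "1..4")
  expect_error(cohort_dataset(ex, ex, stages = c(1, 2),
                              sample_ids = c("A", "A")), "duplicate")
  exdup <- ex; colnames(exdup) <- c("g1", "g1")
  expect_error(cohort_dataset(exdup, ex, stages = c(1, 2)), "duplicate")
  exbad <- ex; exbad[1, 1] <- 0.5
  expect_error(cohort_dataset(ex, exbad, stages = c(1, 2)), "binary")
})

test_that("cohort directories round-trip through write_cohort/read_cohort", {
  cohort <- tiny_cohort(counts = c(3, 3, 3, 3), n_genes = 5, n_informative = 2)
  d <- tempfile()
  write_cohort(cohort, d)
  back <- read_cohort(d)
  expect_identical(back$sample_ids, cohort$sample_ids)
  expect_equal(back$expression, cohort$expression)
  expect_identical(back$stages, cohort$stages)
})
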