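test_that("per-class ratios match their definitions", {
  expect_equal(round(sensitivity(45, 1), 2), 0.98)
  expect_equal(sensitivity(12, 0), 1)
  expect_equal(sensitivity(0, 5), 0)
  expect_true(is.na(sensitivity(0, 0)))

  expect_equal(round(specificity_paper(12, 1), 2), 0.92)
  expect_equal(specificity_paper(7, 0), 1)
  expect_equal(specificity_paper(0, 3), 0)
  expect_true(is.na(specificity_paper(0, 0)))

  expect_equal(specificity_standard(90, 10), 0.9)
})

test_that("mean predictability averages class sensitivities, excluding empty classes", {
  expect_equal(round(mean_predictability(c(45, 45), c(46, 46)), 2), 97.83)
  # empty class dropped from the mean
  expect_equal(round(mean_predictability(c(33, 9, 7, 2, 0), c(38, 13, 16, 2, 0)), 2),
               74.96)
  expect_equal(mean_predictability(10, 10), 100)
  expect_error(mean_predictability(numeric(0), numeric(0)),
               class = "glyco_validation_error")
  expect_error(mean_predictability(0, 0), class = "glyco_validation_error")
  expect_error(mean_predictability(5, 4), class = "glyco_validation_error")
})

test_that("a constant-prediction dummy scores the 100/k chance level on balanced data", {
  truth <- rep(c("A", "B", "C", "D"), each = 10)
  pred <- rep("A", 40)
  rep1 <- task_report(truth, pred, task = "s_link")
  expect_equal(glance(rep1)$mean_predictability, 100 / 4)
})

test_that("task reports carry confusion counts, ratios and NA markers", {
  truth <- c("A", "A", "B", "B", "B")
  pred <- c("A", "B", "B", "B", "A")
  rep1 <- task_report(truth, pred, task = "ano_r")
  s <- tidy(rep1)
  expect_equal(s$size, c(2L, 3L))
  expect_equal(s$correct, c(1L, 2L))
  expect_equal(s$sensitivity, c(1 / 2, 2 / 3))
  expect_equal(s$specificity, c(1 / 2, 2 / 3))
  # row sums of the confusion equal class sizes
  expect_equal(unname(rowSums(rep1$confusions$ano_r)), c(2, 3))

  # empty classes show undefined, not zero
  rep2 <- task_report(c("A", "A"), c("A", "A"), task = "red_end")
  s2 <- tidy(rep2)
  expect_true(all(is.na(s2$sensitivity[s2$class != "A"])))
})

test_that("a ground-truth predictor scores perfect reports", {
  recs <- small_records(10, 10)
  rep1 <- task_report(recs[task_names()], recs[task_names()])
  expect_true(all(glance(rep1)$mean_predictability == 100))
  s <- tidy(rep1)
  expect_true(all(s$sensitivity[s$size > 0] == 1))
})

test_that("reports round-trip through TSV", {
  recs <- small_records(8, 8)
  rep1 <- task_report(recs[task_names()], recs[task_names()])
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tidy(rep1), path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tidy(rep1)))
})

test_that("compare_reports lays out one mean-predictability column per report", {
  recs <- small_records(10, 10)
  perfect <- task_report(recs[task_names()], recs[task_names()])
  dummy <- task_report(recs$ano_r, rep("A", nrow(recs)), task = "ano_r")
  cmp <- compare_reports(all_tasks = perfect, dummy_ano_r = dummy)
  expect_equal(names(cmp), c("task", "all_tasks", "dummy_ano_r"))
  expect_equal(nrow(cmp), 9)
  expect_true(all(cmp$all_tasks == 100))
  expect_equal(sum(!is.na(cmp$dummy_ano_r)), 1)
})

# Printed per-class (size, correct, sensitivity) rows of the published
# trisaccharide table (random-forest columns) and the combined di- and
# trisaccharide table, as train/test pairs. Two rows of the combined table
# whose printed sensitivities are inconsistent with their own printed
# counts (reducing-end Man and Fuc training entries) are excluded.
published_rows <- function() {
  tri <- tibble::tribble(
    ~task, ~class, ~size_tr, ~cor_tr, ~sens_tr, ~size_te, ~cor_te, ~sens_te,
    "ano_f", "A", 46, 33, 0.71, 12, 6, 0.50,
    "ano_f", "B", 46, 35, 0.76, 15, 12, 0.80,
    "ano_s", "A", 46, 45, 0.98, 12, 12, 1.00,
    "ano_s", "B", 46, 45, 0.98, 15, 14, 0.93,
    "ano_r", "A", 46, 34, 0.74, 16, 12, 0.75,
    "ano_r", "B", 46, 36, 0.78, 11, 10, 0.91,
    "f_link", "A", 33, 30, 0.91, 13, 10, 0.77,
    "f_link", "B", 27, 22, 0.81, 7, 7, 1.00,
    "f_link", "C", 16, 11, 0.69, 4, 2, 0.50,
    "f_link", "D", 16, 15, 0.94, 3, 3, 1.00,
    "s_link", "A", 8, 1, 0.12, 1, 0, 0.00,
    "s_link", "B", 17, 9, 0.53, 12, 7, 0.58,
    "s_link", "C", 51, 50, 0.98, 13, 13, 1.00,
    "s_link", "D", 16, 13, 0.81, 1, 1, 1.00,
    "red_end", "A", 26, 21, 0.81, 17, 14, 0.82,
    "red_end", "B", 18, 8, 0.44, 5, 5, 1.00,
    "red_end", "C", 18, 9, 0.50, 3, 2, 0.67,
    "red_end", "D", 17, 12, 0.70, 2, 2, 1.00,
    "red_end", "E", 13, 10, 0.77, 0, 0, NA,
    "m_residue", "A", 26, 19, 0.73, 6, 5, 0.83,
    "m_residue", "B", 19, 9, 0.47, 5, 4, 0.80,
    "m_residue", "C", 19, 9, 0.47, 5, 4, 0.80,
    "m_residue", "D", 12, 6, 0.50, 4, 3, 0.75,
    "m_residue", "E", 16, 9, 0.56, 7, 4, 0.57,
    "f_residue", "A", 22, 18, 0.82, 9, 6, 0.67,
    "f_residue", "B", 18, 14, 0.78, 3, 2, 0.67,
    "f_residue", "C", 16, 9, 0.56, 6, 2, 0.33,
    "f_residue", "D", 19, 14, 0.74, 4, 3, 0.75,
    "f_residue", "E", 17, 15, 0.88, 5, 3, 0.60,
    "chain_type", "A", 39, 29, 0.74, 8, 7, 0.88,
    "chain_type", "B", 53, 47, 0.89, 19, 18, 0.95
  )
  combined <- tibble::tribble(
    ~task, ~class, ~size_tr, ~cor_tr, ~sens_tr, ~size_te, ~cor_te, ~sens_te,
    "ano_f", "A", 105, 89, 0.85, 30, 25, 0.83,
    "ano_f", "B", 99, 87, 0.88, 39, 32, 0.82,
    "ano_s", "A", 46, 38, 0.83, 12, 10, 0.83,
    "ano_s", "B", 46, 33, 0.72, 15, 13, 0.87,
    "ano_s", "X", 112, 112, 1.00, 42, 42, 1.00,
    "ano_r", "A", 102, 84, 0.82, 39, 31, 0.79,
    "ano_r", "B", 102, 91, 0.89, 30, 28, 0.93,
    "f_link", "A", 33, 30, 0.91, 13, 10, 0.77,
    "f_link", "B", 27, 21, 0.78, 7, 7, 1.00,
    "f_link", "C", 16, 11, 0.69, 4, 2, 0.50,
    "f_link", "D", 16, 14, 0.88, 3, 3, 1.00,
    "f_link", "X", 112, 112, 1.00, 42, 42, 1.00,
    "s_link", "A", 36, 22, 0.61, 13, 10, 0.77,
    "s_link", "B", 48, 38, 0.79, 21, 15, 0.71,
    "s_link", "C", 71, 69, 0.97, 26, 24, 0.92,
    "s_link", "D", 49, 45, 0.92, 9, 9, 1.00,
    "red_end", "A", 72, 60, 0.83, 38, 33, 0.87,
    "red_end", "B", 58, 39, 0.67, 13, 9, 0.69,
    "red_end", "D", 17, 12, 0.70, 2, 2, 1.00,
    "m_residue", "A", 26, 20, 0.77, 6, 5, 0.83,
    "m_residue", "B", 19, 9, 0.47, 5, 4, 0.80,
    "m_residue", "C", 19, 7, 0.37, 5, 4, 0.80,
    "m_residue", "D", 12, 6, 0.50, 4, 3, 0.75,
    "m_residue", "E", 16, 10, 0.62, 7, 4, 0.57,
    "m_residue", "X", 112, 112, 1.00, 42, 42, 1.00,
    "f_residue", "A", 74, 65, 0.88, 33, 31, 0.94,
    "f_residue", "B", 44, 31, 0.70, 7, 2, 0.28,
    "f_residue", "C", 50, 39, 0.78, 20, 12, 0.60,
    "f_residue", "D", 19, 14, 0.74, 4, 3, 0.75,
    "f_residue", "E", 17, 15, 0.88, 5, 4, 0.80,
    "chain_type", "A", 39, 28, 0.72, 8, 7, 0.88,
    "chain_type", "B", 53, 47, 0.89, 19, 18, 0.95,
    "chain_type", "X", 112, 112, 1.00, 42, 42, 1.00
  )
  dplyr::bind_rows(tri, combined)
}

test_that("published (correct, size) pairs reproduce the printed sensitivities", {
  rows <- published_rows()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    expect_lt(abs(sensitivity(r$cor_tr, r$size_tr - r$cor_tr) - r$sens_tr), 0.011)
    if (r$size_te > 0) {
      expect_lt(abs(sensitivity(r$cor_te, r$size_te - r$cor_te) - r$sens_te), 0.011)
    }
  }
})
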