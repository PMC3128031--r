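test_that("stratified folds preserve class structure deterministically", {
  labels <- rep(paste0("L", 1:10), each = 25)
  f1 <- stratified_kfold(labels, k = 10, seed = 4)
  f2 <- stratified_kfold(labels, k = 10, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, stratified_kfold(labels, k = 10, seed = 5)))
  expect_identical(sort(unique(f1)), 1:10)
  # 250 samples, 10 balanced classes: folds of 25 with 2-3 per class
  expect_true(all(table(f1) == 25))
  per_fold_class <- table(f1, labels)
  expect_true(all(per_fold_class >= 2 & per_fold_class <= 3))
  # every class appears in every fold's *training* split
  for (f in 1:10) {
    expect_identical(sort(unique(labels[f1 != f])), sort(unique(labels)))
  }
})

test_that("fold-count edge cases are handled", {
  labels <- rep(c("a", "b"), each = 6)
  expect_error(stratified_kfold(labels, k = 1), "at least 2")
  expect_error(stratified_kfold(labels, k = 20), "more folds than samples")
  y <- c(rep("a", 8), rep("b", 3), "c")
  expect_warning(f <- stratified_kfold(y, k = 3, seed = 1),
                 "single member")
  expect_true(is.na(f[12]))
  expect_true(all(!is.na(f[1:11])))
})

test_that("separable data cross-validates to zero error", {
  tab <- generate_genotypes(separable_spec(n_groups = 3, per_group = 8,
                                           seed = 61))
  cv <- cross_validate(tab, selector = NULL,
                       classifier = classifier_config("klda"),
                       k = 4, seed = 2)
  expect_equal(cv$mean_error, 0)
  expect_equal(cv$se, 0)
  # mean equals the sample-weighted fold average, recomputable
  ok <- !is.na(cv$fold_errors)
  expect_equal(cv$mean_error,
               stats::weighted.mean(cv$fold_errors[ok], cv$fold_sizes[ok]))
})

test_that("shuffled labels drive the error to chance level", {
  tab <- generate_genotypes(synth_spec(3, 12, 8, informative_markers = 6,
                                       seed = 67))
  set.seed(8)
  errs <- replicate(5, {
    shuffled <- sample(as.character(tab$labels))
    cross_validate(tab, labels = shuffled, selector = NULL,
                   classifier = classifier_config("klda"),
                   k = 4, seed = 3)$mean_error
  })
  chance <- 1 - max(table(tab$labels)) / length(tab$labels)  # 2/3
  expect_gt(mean(errs), chance - 0.25)
})

test_that("selection runs inside the loop; the leaky flag is optimistic", {
  # pure-noise world: no marker carries signal, so honest CV ~ chance while
  # full-data selection leaks label information into the folds
  deltas <- vapply(1:3, function(r) {
    tab <- generate_genotypes(synth_spec(
      n_groups = 2, samples_per_group = 12, n_markers = 12,
      informative_markers = 0, seed = 500 + r))
    sel <- selection_config(2, alpha = 0)
    cls <- classifier_config("klda")
    honest <- cross_validate(tab, selector = sel, classifier = cls,
                             k = 4, seed = r)
    leaky <- cross_validate(tab, selector = sel, classifier = cls,
                            k = 4, seed = r, leaky = TRUE)
    # leaky mode reuses one full-data kit in every fold
    expect_identical(length(unique(leaky$selected_kits[
      !vapply(leaky$selected_kits, is.null, TRUE)])), 1L)
    honest$mean_error - leaky$mean_error
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

test_that("per-fold kits are recorded and reflect training-split selection", {
  tab <- generate_genotypes(synth_spec(3, 10, 6, informative_markers = 2,
                                       seed = 71))
  cv <- cross_validate(tab, selector = selection_config(2, alpha = 0),
                       classifier = classifier_config("kpclda"),
                       k = 3, seed = 11)
  kits <- cv$selected_kits[!vapply(cv$selected_kits, is.null, TRUE)]
  expect_true(all(lengths(kits) == 2))
})

test_that("grid search returns the best parameter with small-value ties", {
  tab <- generate_genotypes(separable_spec(n_groups = 3, per_group = 8,
                                           seed = 73))
  sel <- selection_config(2, method = "FS")
  cls <- classifier_config("klda")
  single <- grid_search(tab, selector = sel, classifier = cls,
                        grid = 1, k = 4, seed = 2)
  direct <- cross_validate(tab, selector = sel, classifier = cls,
                           k = 4, seed = 2)
  expect_equal(single$mean_error, direct$mean_error)
  # separable world: every alpha ties at error 0 -> smallest wins
  best <- grid_search(tab, selector = sel, classifier = cls,
                      grid = c(0, 0.75, 1), k = 4, seed = 2)
  expect_equal(best$best_parameter, 0)
  expect_length(best$grid_reports, 3L)
})

test_that("redundant-marker world makes alpha > 0 beat alpha = 0", {
  tab <- complementary_table(per_group = 8)
  best <- grid_search(tab, selector = selection_config(2, method = "FS"),
                      classifier = classifier_config("klda"),
                      grid = c(0, 1), k = 4, seed = 6)
  expect_gt(best$best_parameter, 0)
  e0 <- best$grid_reports[["0"]]$mean_error
  e1 <- best$grid_reports[["1"]]$mean_error
  expect_lt(e1, e0)
})

test_that("exhaustive search enumerates, summarizes and ranks subsets", {
  expect_length(enumerate_subsets(paste0("M", 1:6), 2), 15L)
  expect_error(enumerate_subsets(paste0("M", 1:30), 15, cap = 1000),
               "exceeds cap")

  tab <- generate_genotypes(synth_spec(3, 6, 5, informative_markers = 2,
                                       seed = 79))
  search <- exhaustive_subset_search(tab, subset_size = 2,
                                     classifier =
                                       classifier_config("kpclda"),
                                     k = 3, seed = 4)
  expect_equal(search$n_subsets, choose(5, 2))
  expect_true(all(diff(search$quantiles) >= 0))  # nondecreasing quantiles

  # subset_size = m: single subset, equal to the full-set CV
  full <- exhaustive_subset_search(tab, subset_size = 5,
                                   classifier = classifier_config("kpclda"),
                                   k = 3, seed = 4)
  expect_equal(full$n_subsets, 1)
  direct <- cross_validate(tab, selector = NULL,
                           classifier = classifier_config("kpclda"),
                           k = 3, seed = 4)
  expect_equal(unname(full$errors), direct$mean_error)

  expect_equal(rank_selected_kit(min(search$errors), search$errors), 0)
  expect_equal(rank_selected_kit(max(search$errors) + 0.1, search$errors),
               1)
})

test_that("the whole pipeline is reproducible for a fixed seed", {
  tab <- generate_genotypes(synth_spec(3, 10, 8, informative_markers = 4,
                                       seed = 89))
  run <- function() {
    # small kits can rank-limit KPCA below n_classes - 1; the fallback
    # warning is expected and not under test here
    suppressWarnings(
      cross_validate(tab, selector = selection_config(3),
                     classifier = classifier_config("kpclda"),
                     k = 4, seed = 21))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$fold_errors, r2$fold_errors)
  expect_identical(r1$selected_kits, r2$selected_kits)
})
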