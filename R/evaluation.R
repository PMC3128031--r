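#' @title Cross-validated benchmarking with in-loop marker selection
#' @name evaluation
#'
#' @description
#' Stratified k-fold cross-validation of (selector x classifier x kit size)
#' combinations.  Marker selection runs *inside* each fold, on the training
#' split only, so that the reported error is free of selection bias; a
#' deliberately `leaky = TRUE` mode (selection once on the full data) exists
#' solely to demonstrate that bias.  Reported dispersion (`se`) is the
#' standard error of the per-fold error rates; the per-fold errors are kept
#' so users can recompute alternatives.
NULL

with_local_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds, keeping class proportions
#' approximately equal across folds.  Deterministic given `seed`.  Classes
#' with fewer members than folds still spread over distinct folds; a class
#' with a single member is kept in training splits only (fold `NA`) with a
#' warning.
#'
#' @param labels Class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k` (or `NA` for
#'   training-only singletons).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  y <- factor(as.character(labels))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2 (no held-out data otherwise)",
                   call. = FALSE)
  if (k > length(y)) stop("more folds than samples", call. = FALSE)
  counts <- table(y)
  if (any(counts < k)) {
    small <- names(counts)[counts < k & counts > 1L]
    if (length(small) > 0L) {
      warning("class(es) with fewer members than folds: ",
              paste(small, collapse = ", "),
              "; they will be absent from some test splits")
    }
  }
  folds <- integer(length(y))
  with_local_seed(seed, {
    offset <- 0L
    for (lv in levels(y)) {
      idx <- which(y == lv)
      if (length(idx) == 1L) {
        warning("class '", lv, "' has a single member; kept in training ",
                "splits only")
        folds[idx] <- NA_integer_
        next
      }
      idx <- idx[sample.int(length(idx))]
      # rotate the fold cycle between classes so small classes do not all
      # land in the low-numbered folds
      folds[idx] <- as.integer(((seq_along(idx) - 1L + offset) %% k) + 1L)
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Classifier configuration
#'
#' @param method `"klda"` or `"kpclda"`.
#' @param regularization KLDA ridge coefficient.
#' @param n_components Optional KPCLDA component cap.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(method = c("klda", "kpclda"),
                              regularization = 1e-3, n_components = NULL) {
  method <- match.arg(method)
  structure(list(method = method, regularization = regularization,
                 n_components = n_components),
            class = "classifier_config")
}

fit_classifier <- function(gram, labels, config) {
  if (config$method == "klda") {
    fit_klda(gram, labels, regularization = config$regularization)
  } else {
    fit_kpclda(gram, labels, n_components = config$n_components)
  }
}

#' Cross-validated error of a selector/classifier pipeline
#'
#' For each fold: (optionally) select a marker kit on the training split,
#' build the training Gram matrix over that kit, fit the classifier, score
#' the held-out samples through their similarity vectors, and record the
#' misclassification rate.
#'
#' @param table A labelled [genotype_table()].
#' @param labels Class labels (default: the table's own).
#' @param selector A [selection_config()], or `NULL` to use the full marker
#'   set.
#' @param classifier A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Fold seed.
#' @param leaky If `TRUE`, selection runs once on the full data before
#'   cross-validation (the statistically wrong protocol); only for
#'   demonstrating selection bias.
#' @return A list of class `cv_report`: `mean_error` (sample-weighted),
#'   `se` (standard error across folds), `fold_errors`, `fold_sizes`,
#'   `selected_kits` (list of marker-id vectors per fold), `failed_folds`,
#'   `k`, `seed`, config echoes.
#' @export
cross_validate <- function(table, labels = table$labels, selector = NULL,
                           classifier = classifier_config("klda"),
                           k = 10L, seed = 1L, leaky = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  labels <- factor(as.character(labels))
  folds <- stratified_kfold(labels, k, seed)
  full_kit <- NULL
  if (leaky && !is.null(selector)) {
    full_kit <- select_kit(table, labels, selector)$selected$marker
  }
  fold_errors <- rep(NA_real_, k)
  fold_sizes <- integer(k)
  kits <- vector("list", k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f | is.na(folds))
    if (length(test_idx) == 0L) next
    res <- tryCatch({
      train <- subset_table(table, samples = train_idx)
      test <- subset_table(table, samples = test_idx)
      train$labels <- labels[train_idx]
      kit <- if (is.null(selector)) train$marker_ids
             else if (leaky) full_kit
             else select_kit(train, train$labels, selector)$selected$marker
      gram <- gram_matrix(train, kit)
      model <- fit_classifier(gram, labels[train_idx], classifier)
      cross <- cross_gram(train, test, kit)
      pred <- predict(model, cross)
      list(err = mean(as.character(pred) != as.character(labels[test_idx])),
           kit = kit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, f)
      next
    }
    fold_errors[f] <- res$err
    fold_sizes[f] <- length(test_idx)
    kits[[f]] <- res$kit
  }
  ok <- !is.na(fold_errors)
  if (!any(ok)) stop("all folds failed", call. = FALSE)
  if (length(failed) > 0L) {
    warning("fold(s) failed: ", paste(failed, collapse = ", "),
            "; report is partial")
  }
  structure(list(
    mean_error = stats::weighted.mean(fold_errors[ok], fold_sizes[ok]),
    se = stats::sd(fold_errors[ok]) / sqrt(sum(ok)),
    fold_errors = fold_errors, fold_sizes = fold_sizes,
    selected_kits = kits, failed_folds = failed,
    k = k, seed = seed, selector = selector, classifier = classifier,
    leaky = leaky), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  sel <- if (is.null(x$selector)) "full marker set"
         else paste0(x$selector$method, " N=", x$selector$kit_size)
  cat(sprintf("%d-fold CV [%s, %s]: error %.3f +/- %.3f\n", x$k, sel,
              x$classifier$method, x$mean_error, x$se))
  invisible(x)
}

#' Cross-validated grid search over a selector parameter
#'
#' Runs [cross_validate()] for each value of the tuned parameter (`alpha`
#' for FS, `beta` for MIFS; mRMR has none) and returns the report with the
#' smallest mean error, breaking ties toward the smaller parameter value.
#' The conventional grid is `c(0, 0.75, 1, 1.25)`.
#'
#' @inheritParams cross_validate
#' @param grid Numeric vector of parameter values.
#' @return The best `cv_report`, with `best_parameter` and `grid_reports`
#'   (all evaluated reports, named by parameter value) attached.
#' @export
grid_search <- function(table, labels = table$labels, selector, classifier,
                        grid = c(0, 0.75, 1, 1.25), k = 10L, seed = 1L) {
  stopifnot(length(grid) > 0L)
  grid <- sort(grid)
  reports <- lapply(grid, function(val) {
    cfg <- selector
    if (selector$method == "FS") cfg$alpha <- val
    else if (selector$method == "MIFS") cfg$beta <- val
    cross_validate(table, labels, cfg, classifier, k = k, seed = seed)
  })
  names(reports) <- as.character(grid)
  errs <- vapply(reports, `[[`, numeric(1L), "mean_error")
  best <- which.min(errs)       # ties: first = smallest parameter
  out <- reports[[best]]
  out$best_parameter <- grid[best]
  out$grid_reports <- reports
  out
}

#' Enumerate all marker subsets of a given size
#'
#' @param marker_ids Character vector of marker ids.
#' @param subset_size Subset cardinality.
#' @param cap Error out if the number of subsets exceeds this.
#' @return A list of character vectors (deterministic lexicographic
#'   order over input positions).
#' @export
enumerate_subsets <- function(marker_ids, subset_size, cap = 1e6) {
  m <- length(marker_ids)
  stopifnot(subset_size >= 1, subset_size <= m)
  n_sub <- choose(m, subset_size)
  if (n_sub > cap) {
    stop("subset count ", format(n_sub, big.mark = ","), " exceeds cap (",
         format(cap, big.mark = ","), "); use a random-sample survey instead",
         call. = FALSE)
  }
  cmb <- utils::combn(m, subset_size)
  lapply(seq_len(ncol(cmb)), function(j) marker_ids[cmb[, j]])
}

#' Exhaustive cross-validated search over marker subsets
#'
#' Evaluates the cross-validated error of *every* marker subset of the
#' given size and summarizes the error distribution by quantiles at
#' 0, 0.5, 1, 5, 25, 50, 75 and 100 percent.  Quadratic-plus work: the
#' count is `choose(m, subset_size)` and each subset costs a k-fold CV —
#' a 19-choose-5 search (11,628 subsets) is desk-scale only for small
#' sample counts.
#'
#' @inheritParams cross_validate
#' @param subset_size Kit cardinality to enumerate.
#' @param cap Maximum allowed number of subsets (default `1e6`).
#' @return A list of class `subset_search`: `errors` (named by
#'   comma-joined subset), `subsets`, `quantiles`, `n_subsets`, plus
#'   config echoes.
#' @export
exhaustive_subset_search <- function(table, labels = table$labels,
                                     subset_size,
                                     classifier = classifier_config("klda"),
                                     k = 10L, seed = 1L, cap = 1e6) {
  stopifnot(inherits(table, "genotype_table"))
  subsets <- enumerate_subsets(table$marker_ids, subset_size, cap)
  errors <- vapply(subsets, function(kit) {
    cross_validate(subset_table(table, markers = kit), labels,
                   selector = NULL, classifier = classifier,
                   k = k, seed = seed)$mean_error
  }, numeric(1L))
  names(errors) <- vapply(subsets, paste, character(1L), collapse = ",")
  probs <- c(0, 0.005, 0.01, 0.05, 0.25, 0.5, 0.75, 1)
  structure(list(errors = errors, subsets = subsets,
                 quantiles = stats::quantile(errors, probs = probs),
                 n_subsets = length(subsets), subset_size = subset_size,
                 classifier = classifier, k = k, seed = seed),
            class = "subset_search")
}

#' Percentile rank of a selected kit within an error distribution
#'
#' The fraction of subsets whose error is strictly below the kit's error:
#' 0 means the kit ties the best subset, 1 means every subset beats it.
#'
#' @param selected_kit_error Scalar CV error of the chosen kit.
#' @param error_distribution Numeric vector of subset errors (e.g.
#'   `subset_search$errors`).
#' @return A fraction in `[0, 1]`.
#' @export
rank_selected_kit <- function(selected_kit_error, error_distribution) {
  stopifnot(length(error_distribution) > 0L)
  mean(error_distribution < selected_kit_error)
}
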