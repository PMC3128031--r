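#' @title Kernel discriminant classifiers on precomputed Gram matrices
#' @name kernel_classifiers
#'
#' @description
#' Two classifiers operating purely on a precomputed similarity (Gram)
#' matrix, so any positive definite kernel — here the Nei-Li similarity —
#' can drive them:
#'
#' * **KLDA** (kernel Fisher discriminant analysis): maximizes the Fisher
#'   between/within scatter ratio in the kernel-induced feature space.  In
#'   dual form, with Gram matrix `K`, class-mean projector `P` and overall
#'   mean projector `J/n`, the between scatter is `M = K (P - J/n) K` and
#'   the within scatter `N = K (I - P) K`; discriminant directions are
#'   dual-coefficient vectors solving the regularized generalized
#'   eigenproblem `M a = lambda (N + mu * tr(N)/n * I) a`.
#' * **KPCLDA**: kernel PCA (double-centered Gram, leading eigenvectors)
#'   followed by ordinary multi-class LDA on the component scores.
#'
#' Both predict by projecting test samples through their similarity vectors
#' to the training samples and assigning the nearest class centroid
#' (Euclidean metric) in discriminant space.
NULL

validate_gram_labels <- function(gram, labels) {
  gram <- unclass(gram)
  stopifnot(is.matrix(gram), nrow(gram) == ncol(gram))
  if (length(labels) != nrow(gram)) {
    stop("labels length must match the Gram matrix", call. = FALSE)
  }
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) {
    stop("at least two classes are required", call. = FALSE)
  }
  if (any(table(y) < 2L)) {
    stop("every class needs at least two training samples", call. = FALSE)
  }
  list(gram = gram, y = y)
}

class_mean_projector <- function(y) {
  n <- length(y)
  P <- matrix(0, n, n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    P[idx, idx] <- 1 / length(idx)
  }
  P
}

# Generalized symmetric eigenproblem M a = lambda W a via Cholesky whitening.
gen_eigen <- function(M, W, n_dirs) {
  R <- tryCatch(chol(W), error = function(e) {
    stop("within-class scatter is singular; increase 'regularization'",
         call. = FALSE)
  })
  Ri <- backsolve(R, diag(nrow(W)))
  A <- crossprod(Ri, M %*% Ri)
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  keep <- seq_len(n_dirs)
  list(vectors = Ri %*% eg$vectors[, keep, drop = FALSE],
       values = eg$values[keep])
}

#' Fit a kernel Fisher discriminant (KLDA) classifier
#'
#' @param gram Training Gram matrix (e.g. from [gram_matrix()]).
#' @param labels Class labels, one per training sample.
#' @param regularization Nonnegative ridge coefficient `mu`; the within
#'   scatter receives `mu * tr(N)/n` on its diagonal.  Gram matrices from
#'   few samples are rank-deficient, so the default `1e-3` is rarely worth
#'   lowering.  `0` is allowed and errors if the scatter is singular.
#' @return A `kernel_classifier` model (method `"klda"`) holding dual
#'   coefficients, class centroids in discriminant space, and training
#'   sample ids.
#' @seealso [fit_kpclda()], [predict.kernel_classifier()]
#' @export
fit_klda <- function(gram, labels, regularization = 1e-3) {
  stopifnot(is.numeric(regularization), regularization >= 0)
  v <- validate_gram_labels(gram, labels)
  K <- v$gram; y <- v$y
  n <- nrow(K); C <- nlevels(y)
  P <- class_mean_projector(y)
  J <- matrix(1 / n, n, n)
  M <- K %*% (P - J) %*% K
  N <- K %*% (diag(n) - P) %*% K
  M <- (M + t(M)) / 2; N <- (N + t(N)) / 2
  scale <- sum(diag(N)) / n
  if (scale <= 0) scale <- 1     # perfectly separated blocks: N == 0
  W <- N + diag(regularization * scale, n)
  n_dirs <- C - 1L
  eg <- gen_eigen(M, W, n_dirs)
  alpha <- eg$vectors
  Z <- K %*% alpha
  centroids <- rowsum(Z, y) / as.vector(table(y))
  structure(list(method = "klda",
                 training_sample_ids = rownames(K),
                 dual_coefficients = alpha,
                 class_centroids = centroids,
                 class_labels = levels(y),
                 eigenvalues = eg$values,
                 hyperparameters = list(regularization = regularization)),
            class = c("klda", "kernel_classifier"))
}

# Double-center a Gram matrix; returns centered matrix plus the train
# statistics needed to center out-of-sample similarity vectors consistently.
center_kernel <- function(K) {
  col_means <- colMeans(K)
  total_mean <- mean(K)
  Kc <- K - matrix(col_means, nrow(K), ncol(K), byrow = TRUE) -
    matrix(rowMeans(K), nrow(K), ncol(K)) + total_mean
  list(Kc = (Kc + t(Kc)) / 2, col_means = col_means,
       total_mean = total_mean)
}

center_cross <- function(K_test, col_means, total_mean) {
  row_means <- rowMeans(K_test)
  K_test - matrix(col_means, nrow(K_test), ncol(K_test), byrow = TRUE) -
    matrix(row_means, nrow(K_test), ncol(K_test)) + total_mean
}

# Minimal multi-class LDA on score matrices: pooled within-class covariance
# (tiny ridge for numerical safety), between-class scatter of centroids,
# nearest-centroid rule in the discriminant subspace.
lda_fit <- function(X, y, ridge = 1e-9) {
  n <- nrow(X); C <- nlevels(y)
  mu <- colMeans(X)
  Sw <- matrix(0, ncol(X), ncol(X))
  Sb <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    Xc <- X[idx, , drop = FALSE]
    m_c <- colMeans(Xc)
    dev <- sweep(Xc, 2L, m_c)
    Sw <- Sw + crossprod(dev)
    Sb <- Sb + length(idx) * tcrossprod(m_c - mu)
  }
  Sw <- Sw / max(n - C, 1L)
  scale <- mean(diag(Sw)); if (scale <= 0) scale <- 1
  eg <- gen_eigen(Sb, Sw + diag(ridge * scale + 1e-12, ncol(X)),
                  min(C - 1L, ncol(X)))
  W <- eg$vectors
  Z <- X %*% W
  centroids <- rowsum(Z, y) / as.vector(table(y))
  list(weights = W, centroids = centroids)
}

#' Fit a kernel-PCA + LDA (KPCLDA) classifier
#'
#' Double-centers the training Gram matrix, extracts leading kernel
#' principal components, then fits ordinary multi-class LDA on the scores.
#'
#' @inheritParams fit_klda
#' @param eig_tol Components with eigenvalue below `eig_tol` times the
#'   largest are dropped.
#' @param n_components Optional explicit number of retained components,
#'   overriding the variance rule.
#' @param variance_cutoff Default retention rule: keep the leading
#'   components explaining this share of the centered-kernel variance
#'   (0.95), never more than `n - n_classes`.  Retaining every
#'   above-tolerance component up to `n - n_classes` makes the downstream
#'   LDA fit noise directions and collapse under cross-validation, so the
#'   cutoff matters.  If fewer than `n_classes - 1` components survive, a
#'   warning is issued and all above-tolerance components are used.
#' @return A `kernel_classifier` model (method `"kpclda"`).
#' @export
fit_kpclda <- function(gram, labels, n_components = NULL, eig_tol = 1e-9,
                       variance_cutoff = 0.95) {
  v <- validate_gram_labels(gram, labels)
  K <- v$gram; y <- v$y
  n <- nrow(K); C <- nlevels(y)
  ck <- center_kernel(K)
  eg <- eigen(ck$Kc, symmetric = TRUE)
  lambda <- eg$values
  pos <- which(lambda > eig_tol * max(lambda, .Machine$double.eps))
  if (length(pos) == 0L) {
    stop("degenerate kernel: no positive principal components ",
         "(all samples identical?)", call. = FALSE)
  }
  if (is.null(n_components)) {
    shares <- cumsum(lambda[pos]) / sum(lambda[pos])
    cap <- min(max(which(shares >= variance_cutoff)[1], C - 1L),
               max(n - C, C - 1L))
  } else {
    cap <- n_components
  }
  keep <- pos[seq_len(min(length(pos), cap))]
  if (length(keep) < C - 1L) {
    if (length(pos) > length(keep)) {
      warning("fewer retained components than classes - 1; ",
              "falling back to all positive-eigenvalue components")
      keep <- pos
    } else {
      warning("kernel rank supports only ", length(keep),
              " component(s) for ", C, " classes")
    }
  }
  V <- eg$vectors[, keep, drop = FALSE]
  lam <- lambda[keep]
  scores <- V %*% diag(sqrt(lam), length(lam))
  lda <- lda_fit(scores, y)
  structure(list(method = "kpclda",
                 training_sample_ids = rownames(K),
                 dual_coefficients = V %*% diag(1 / sqrt(lam), length(lam)),
                 kpca_eigenvalues = lam,
                 centering = ck[c("col_means", "total_mean")],
                 lda_weights = lda$weights,
                 class_centroids = lda$centroids,
                 class_labels = levels(y),
                 hyperparameters = list(n_components = length(lam),
                                        eig_tol = eig_tol)),
            class = c("kpclda", "kernel_classifier"))
}

#' KPCA component scores of the training samples
#'
#' @param model A fitted `kpclda` model.
#' @return The training score matrix (samples x retained components); its
#'   cross-product reconstructs the centered Gram matrix when all positive
#'   components are retained.
#' @export
kpca_scores <- function(model) {
  stopifnot(inherits(model, "kpclda"))
  # dual_coefficients = V Lambda^-1/2, so scores = (dual) Lambda.
  model$dual_coefficients %*% diag(model$kpca_eigenvalues,
                                   length(model$kpca_eigenvalues))
}

check_cross_alignment <- function(model, cross) {
  cross <- as.matrix(cross)
  if (ncol(cross) != length(model$training_sample_ids)) {
    stop("similarity matrix has ", ncol(cross), " columns but the model ",
         "was trained on ", length(model$training_sample_ids), " samples",
         call. = FALSE)
  }
  ids <- colnames(cross)
  if (!is.null(ids) && !identical(ids, model$training_sample_ids)) {
    stop("similarity matrix columns are not aligned with the model's ",
         "training samples", call. = FALSE)
  }
  cross
}

#' Project samples into a model's discriminant space
#'
#' @param model A fitted `kernel_classifier`.
#' @param cross Test-by-train similarity matrix (see [cross_gram()]); for
#'   training-set projections pass the training Gram matrix.
#' @return A numeric matrix of discriminant coordinates.
#' @export
discriminant_projection <- function(model, cross) {
  cross <- check_cross_alignment(model, cross)
  if (model$method == "klda") {
    cross %*% model$dual_coefficients
  } else {
    kc <- center_cross(cross, model$centering$col_means,
                       model$centering$total_mean)
    scores <- kc %*% model$dual_coefficients
    scores %*% model$lda_weights
  }
}

#' Predict class labels from a similarity matrix
#'
#' @param object A fitted `kernel_classifier`.
#' @param cross Test-by-train similarity matrix with columns in training
#'   sample order ([cross_gram()] output).
#' @param ... Unused.
#' @return Factor of predicted labels, one per test row.
#' @export
predict.kernel_classifier <- function(object, cross, ...) {
  Z <- discriminant_projection(object, cross)
  cents <- object$class_centroids
  d2 <- outer(rowSums(Z^2), rowSums(cents^2), `+`) - 2 * Z %*% t(cents)
  idx <- max.col(-d2, ties.method = "first")
  factor(object$class_labels[idx], levels = object$class_labels)
}

#' @export
print.kernel_classifier <- function(x, ...) {
  cat(toupper(x$method), "model:", length(x$training_sample_ids),
      "training samples,", length(x$class_labels), "classes\n")
  invisible(x)
}

#' Serialize a fitted kernel classifier to JSON
#'
#' Stores ids, dual coefficients, centroids and hyperparameters in a single
#' self-describing file so a fitted kit model can score new genotype tables
#' later.
#'
#' @param model A `kernel_classifier`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kernel_classifier"))
  payload <- lapply(unclass(model), function(f) {
    if (is.matrix(f)) list(.matrix = TRUE, data = as.vector(f),
                           nrow = nrow(f), ncol = ncol(f),
                           rownames = rownames(f)) else f
  })
  payload$.class <- class(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized kernel classifier
#'
#' @param path Path written by [write_model()].
#' @return The restored `kernel_classifier`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- unlist(payload$.class)
  payload$.class <- NULL
  model <- lapply(payload, function(f) {
    if (is.list(f) && isTRUE(f$.matrix)) {
      m <- matrix(unlist(f$data), f$nrow, f$ncol)
      if (!is.null(f$rownames) && length(f$rownames) == f$nrow) {
        rownames(m) <- unlist(f$rownames)
      }
      m
    } else f
  })
  model$training_sample_ids <- as.character(unlist(model$training_sample_ids))
  model$class_labels <- as.character(unlist(model$class_labels))
  structure(model, class = cls)
}
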