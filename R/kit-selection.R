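#' @title Marker kit selection by uncertainty-coefficient Z-scores
#' @name kit_selection
#'
#' @description
#' Filter feature selection for SSR markers.  Each marker's genotype calls
#' are treated as one nominal variable (each distinct allele set is one
#' category).  With plug-in entropies `H`:
#'
#' * discrimination power of marker i:
#'   `p_i = U(Group | SSR_i) = [H(Group) + H(SSR_i) - H(Group, SSR_i)] / H(Group)`
#'   (asymmetric uncertainty coefficient — the fraction of group entropy
#'   explained by the marker);
#' * redundancy of markers i, j:
#'   `U_ij = 2 [H(i) + H(j) - H(i, j)] / [H(i) + H(j)]`
#'   (symmetric uncertainty coefficient).
#'
#' Both coefficients carry delta-method asymptotic variances (below), giving
#' Z-scores `U / sqrt(var)` that measure the statistical evidence for
#' non-zero association.  The greedy kit selector visits markers in
#' decreasing power order and keeps marker i iff
#' `power_z(i) >= alpha * max_j redundancy_z(i, j)` over the already
#' selected j — the evidence for its discrimination power must exceed
#' `alpha` times the evidence of its redundancy with the current kit.  The
#' right-hand side is a pairwise surrogate for the multivariate redundancy
#' Z-score, which cannot be estimated reliably at realistic sample sizes.
#' `alpha = 0` disables skipping (plain top-N by power); `alpha = 1` is the
#' default.
#'
#' With p_ij the joint cell proportions, p_i./p_.j the margins, and
#' `H_R, H_C, H_RC` the marginal/joint entropies, the variances are
#' \deqn{var\,U(C|R) = \frac{1}{n H_C^4} \sum_{ij} p_{ij}
#'   \left[ H_C \log(p_{ij}/p_{i.}) + (H_R - H_{RC}) \log p_{.j} \right]^2}
#' \deqn{var\,U_{sym} = \frac{4}{n (H_R + H_C)^4} \sum_{ij} p_{ij}
#'   \left[ H_{RC} \log(p_{i.} p_{.j}) - (H_R + H_C) \log p_{ij} \right]^2}
NULL

#' Plug-in (empirical) entropy of a count vector
#'
#' Natural-log entropy of the empirical distribution; zero counts contribute
#' nothing.  All reported uncertainty coefficients are base-free ratios, so
#' the internal base never shows downstream.
#'
#' @param counts Nonnegative numeric vector of category counts.
#' @return Entropy in nats.
#' @examples
#' empirical_entropy(c(3, 3))     # log(2)
#' empirical_entropy(c(1, 1, 2))  # 1.0397
#' @export
empirical_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("counts sum to zero", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Contingency table of two categorical vectors after pairwise NA deletion.
joint_counts <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) {
    stop("fewer than two complete observations after missing-data removal",
         call. = FALSE)
  }
  table(x, y)
}

entropy_triple <- function(tab) {
  list(h_r = empirical_entropy(rowSums(tab)),
       h_c = empirical_entropy(colSums(tab)),
       h_rc = empirical_entropy(as.vector(tab)),
       n = sum(tab))
}

z_from <- function(value, variance) {
  if (variance > 0) value / sqrt(variance)
  else if (value > 0) Inf
  else 0
}

#' Asymmetric uncertainty coefficient U(group | marker)
#'
#' The discrimination power of a marker: the fraction of group entropy
#' explained by the marker's genotype categories, with its delta-method
#' asymptotic variance and Z-score.  Pairs with a missing value in either
#' vector are dropped.
#'
#' @param group Categorical vector of class labels (the variable being
#'   predicted).
#' @param marker_genotypes Categorical vector of genotype categories (e.g.
#'   [genotype_categories()] output); `NA` = missing call.
#' @return A list of class `marker_score`: `power`, `power_variance`,
#'   `power_z`, `n`.
#' @export
asymmetric_uncertainty <- function(group, marker_genotypes) {
  if (length(group) != length(marker_genotypes)) {
    stop("length mismatch between group and marker vectors", call. = FALSE)
  }
  tab <- joint_counts(marker_genotypes, group)   # rows = marker, cols = group
  et <- entropy_triple(tab)
  if (et$h_c <= 0) {
    stop("group variable is constant (zero entropy)", call. = FALSE)
  }
  u <- (et$h_r + et$h_c - et$h_rc) / et$h_c
  u <- min(max(u, 0), 1)
  p <- tab / et$n
  p_r <- rowSums(p); p_c <- colSums(p)
  lp_r <- log(ifelse(p_r > 0, p_r, 1))
  lp_c <- log(ifelse(p_c > 0, p_c, 1))
  lp <- log(ifelse(p > 0, p, 1))
  term <- et$h_c * (lp - matrix(lp_r, nrow(p), ncol(p))) +
    (et$h_r - et$h_rc) * matrix(lp_c, nrow(p), ncol(p), byrow = TRUE)
  variance <- sum(p * term^2) / (et$n * et$h_c^4)
  variance <- max(variance, 0)
  structure(list(power = u, power_variance = variance,
                 power_z = z_from(u, variance), n = et$n),
            class = "marker_score")
}

#' Symmetric uncertainty coefficient U(marker_i, marker_j)
#'
#' The redundancy between two markers' genotype categories: twice the mutual
#' information normalized by the sum of marginal entropies, with asymptotic
#' variance and Z-score.  Symmetric in its arguments.
#'
#' @param marker_i,marker_j Categorical vectors; `NA` = missing.
#' @return A list of class `redundancy_score`: `value`, `variance`, `z`,
#'   `n`.
#' @export
symmetric_uncertainty <- function(marker_i, marker_j) {
  if (length(marker_i) != length(marker_j)) {
    stop("length mismatch between marker vectors", call. = FALSE)
  }
  tab <- joint_counts(marker_i, marker_j)
  et <- entropy_triple(tab)
  denom <- et$h_r + et$h_c
  if (denom <= 0) {
    stop("both markers are constant (zero total entropy)", call. = FALSE)
  }
  u <- 2 * (et$h_r + et$h_c - et$h_rc) / denom
  u <- min(max(u, 0), 1)
  p <- tab / et$n
  p_r <- rowSums(p); p_c <- colSums(p)
  lmarg <- log(ifelse(p_r > 0, p_r, 1)) %o% rep(1, ncol(p)) +
    rep(1, nrow(p)) %o% log(ifelse(p_c > 0, p_c, 1))
  lp <- log(ifelse(p > 0, p, 1))
  term <- et$h_rc * lmarg - denom * lp
  variance <- 4 * sum(p * term^2) / (et$n * denom^4)
  variance <- max(variance, 0)
  structure(list(value = u, variance = variance, z = z_from(u, variance),
                 n = et$n),
            class = "redundancy_score")
}

# Plug-in mutual information in nats (pairwise NA deletion).
mutual_information <- function(x, y) {
  tab <- joint_counts(x, y)
  et <- entropy_triple(tab)
  max(et$h_r + et$h_c - et$h_rc, 0)
}

#' Score every marker's discrimination power
#'
#' @param table A [genotype_table()].
#' @param labels Class labels (default: the table's own labels).
#' @return A data.frame with columns `marker`, `power`, `power_variance`,
#'   `power_z`, `n`, in the table's marker order.  Markers whose genotype is
#'   constant (after missing-data removal) get power 0.
#' @export
marker_scores <- function(table, labels = table$labels) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  group <- as.character(labels)
  rows <- lapply(table$marker_ids, function(mk) {
    geno <- genotype_categories(table, mk)
    sc <- tryCatch(asymmetric_uncertainty(group, geno), error = function(e) {
      # constant marker or no complete pairs: no discriminating information
      list(power = 0, power_variance = 0, power_z = 0, n = 0L)
    })
    data.frame(marker = mk, power = sc$power,
               power_variance = sc$power_variance,
               power_z = sc$power_z, n = sc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Selection configuration
#'
#' @param kit_size Maximum number of markers `N` to retain.
#' @param alpha Power/redundancy trade-off for the FS method (default 1:
#'   keep a marker when the evidence for its power is at least the evidence
#'   for its redundancy).  `0` never skips.
#' @param method `"FS"` (uncertainty Z-score greedy), `"MIFS"` or `"mRMR"`.
#' @param beta MIFS redundancy weight (ignored by the other methods).
#' @param redundancy_aggregate How FS aggregates pairwise redundancy
#'   Z-scores over the selected kit: `"max"` (default, most conservative
#'   pairwise surrogate for the multivariate redundancy) or `"sum"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(kit_size, alpha = 1, method = c("FS", "MIFS",
                                                             "mRMR"),
                             beta = 1, redundancy_aggregate = c("max",
                                                                "sum")) {
  method <- match.arg(method)
  stopifnot(kit_size >= 1, alpha >= 0, beta >= 0)
  structure(list(kit_size = as.integer(kit_size), alpha = alpha,
                 method = method, beta = beta,
                 redundancy_aggregate = match.arg(redundancy_aggregate)),
            class = "selection_config")
}

empty_skip_frame <- function() {
  data.frame(marker = character(0), power = numeric(0),
             power_z = numeric(0), blocked_by = character(0),
             redundancy = numeric(0), redundancy_z = numeric(0),
             stringsAsFactors = FALSE)
}

#' Greedy uncertainty-coefficient kit selection (FS)
#'
#' Visits markers in decreasing discrimination power (stable tie-break by
#' input marker order).  A visited marker enters the kit iff its power
#' Z-score is at least `alpha` times the aggregated redundancy Z-score
#' against the markers already selected; otherwise it is skipped and the
#' blocking marker recorded.  Stops once `kit_size` markers are selected.
#'
#' @param table A [genotype_table()].
#' @param labels Class labels (default: the table's own).
#' @param config A [selection_config()] with `method = "FS"`.
#' @return A list of class `selection_result`: `selected` (data.frame of
#'   markers with scores, in selection order), `skipped` (data.frame with
#'   the blocking redundancy evidence), `config`, `method`.
#' @examples
#' spec <- synth_spec(n_groups = 3, samples_per_group = 10, n_markers = 6,
#'                    informative_markers = 3, seed = 7)
#' tab <- generate_genotypes(spec)
#' greedy_select(tab, config = selection_config(kit_size = 3))
#' @export
greedy_select <- function(table, labels = table$labels, config) {
  stopifnot(inherits(config, "selection_config"), config$method == "FS")
  scores <- marker_scores(table, labels)
  m <- nrow(scores)
  N <- config$kit_size
  if (N > m) {
    warning("kit_size exceeds the number of markers; selecting all ", m)
    N <- m
  }
  ord <- order(-scores$power)          # stable: ties keep input order
  genos <- lapply(table$marker_ids, function(mk) genotype_categories(table,
                                                                     mk))
  names(genos) <- table$marker_ids
  selected <- integer(0)
  skipped <- empty_skip_frame()
  agg <- if (config$redundancy_aggregate == "max") max else sum
  for (i in ord) {
    if (length(selected) >= N) break
    if (length(selected) == 0L) { selected <- i; next }
    reds <- lapply(selected, function(j) {
      tryCatch(symmetric_uncertainty(genos[[scores$marker[i]]],
                                     genos[[scores$marker[j]]]),
               error = function(e) list(value = 0, variance = 0, z = 0))
    })
    red_z <- vapply(reds, `[[`, numeric(1L), "z")
    rhs <- config$alpha * agg(red_z)
    if (config$alpha == 0) rhs <- 0    # 0 * Inf guard: alpha = 0 never skips
    if (scores$power_z[i] >= rhs) {
      selected <- c(selected, i)
    } else {
      worst <- which.max(red_z)
      skipped <- rbind(skipped, data.frame(
        marker = scores$marker[i], power = scores$power[i],
        power_z = scores$power_z[i],
        blocked_by = scores$marker[selected[worst]],
        redundancy = reds[[worst]]$value,
        redundancy_z = red_z[worst], stringsAsFactors = FALSE))
    }
  }
  structure(list(selected = scores[selected, , drop = FALSE],
                 skipped = skipped, config = config, method = "FS"),
            class = "selection_result")
}

# Shared greedy loop for the mutual-information baselines; `penalty` maps
# the vector of I(candidate; selected_j) to a scalar redundancy charge.
mi_greedy <- function(table, labels, N, penalty) {
  group <- as.character(labels)
  markers <- table$marker_ids
  m <- length(markers)
  if (N > m) {
    warning("kit_size exceeds the number of markers; selecting all ", m)
    N <- m
  }
  genos <- lapply(markers, function(mk) genotype_categories(table, mk))
  relevance <- vapply(genos, function(g) {
    tryCatch(mutual_information(group, g), error = function(e) 0)
  }, numeric(1L))
  selected <- integer(0)
  obj <- numeric(0)
  remaining <- seq_len(m)
  while (length(selected) < N && length(remaining) > 0L) {
    crit <- vapply(remaining, function(i) {
      if (length(selected) == 0L) return(relevance[i])
      red <- vapply(selected, function(j) {
        tryCatch(mutual_information(genos[[i]], genos[[j]]),
                 error = function(e) 0)
      }, numeric(1L))
      relevance[i] - penalty(red)
    }, numeric(1L))
    best <- remaining[which.max(crit)]
    obj <- c(obj, max(crit))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  data.frame(marker = markers[selected], relevance = relevance[selected],
             objective = obj, stringsAsFactors = FALSE)
}

#' MIFS marker selection baseline
#'
#' Greedy maximization of
#' `I(Group; SSR_i) - beta * sum_j I(SSR_i; SSR_j)` over the already
#' selected markers j, on genotype-category variables with plug-in mutual
#' information.
#'
#' @inheritParams greedy_select
#' @return A `selection_result` (skipped is empty: MIFS reranks rather than
#'   skips).
#' @export
mifs_select <- function(table, labels = table$labels, config) {
  stopifnot(inherits(config, "selection_config"), config$method == "MIFS")
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  beta <- config$beta
  sel <- mi_greedy(table, labels, config$kit_size,
                   function(red) beta * sum(red))
  structure(list(selected = sel, skipped = empty_skip_frame(),
                 config = config, method = "MIFS"),
            class = "selection_result")
}

#' mRMR marker selection baseline
#'
#' Greedy maximization of
#' `I(Group; SSR_i) - mean_j I(SSR_i; SSR_j)` (the MID difference form) on
#' genotype-category variables.
#'
#' @inheritParams greedy_select
#' @return A `selection_result`.
#' @export
mrmr_select <- function(table, labels = table$labels, config) {
  stopifnot(inherits(config, "selection_config"), config$method == "mRMR")
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  sel <- mi_greedy(table, labels, config$kit_size, mean)
  structure(list(selected = sel, skipped = empty_skip_frame(),
                 config = config, method = "mRMR"),
            class = "selection_result")
}

#' Run the selector named in a configuration
#'
#' @param table,labels As in [greedy_select()].
#' @param config A [selection_config()]; its `method` field picks the
#'   selector.
#' @return A `selection_result`.
#' @export
select_kit <- function(table, labels = table$labels, config) {
  switch(config$method,
         FS = greedy_select(table, labels, config),
         MIFS = mifs_select(table, labels, config),
         mRMR = mrmr_select(table, labels, config))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, "kit of", nrow(x$selected), "markers:",
      paste(x$selected$marker, collapse = ", "), "\n")
  if (nrow(x$skipped) > 0L) {
    cat("skipped:", paste0(x$skipped$marker, " (redundant with ",
                           x$skipped$blocked_by, ")", collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Write a selection report as TSV
#'
#' One row per visited marker with power, variance, Z, selection status and
#' (for skipped markers) the blocking marker and redundancy evidence.
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(result, path) {
  sel <- result$selected
  sel$status <- "selected"
  sel$blocked_by <- NA_character_
  sel$redundancy <- NA_real_
  sel$redundancy_z <- NA_real_
  keep <- c("marker", "status", "blocked_by", "redundancy", "redundancy_z")
  num <- intersect(c("power", "power_variance", "power_z", "relevance",
                     "objective"), names(sel))
  sel <- sel[, c(keep[1:2], num, keep[3:5])]
  if (nrow(result$skipped) > 0L) {
    sk <- result$skipped
    sk$status <- "skipped"
    for (col in setdiff(names(sel), names(sk))) sk[[col]] <- NA
    sel <- rbind(sel, sk[, names(sel)])
  }
  utils::write.table(sel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
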