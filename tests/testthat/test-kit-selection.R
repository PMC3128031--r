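test_that("empirical entropy matches hand computations", {
  expect_equal(empirical_entropy(5), 0)
  expect_equal(empirical_entropy(c(3, 3)), log(2))
  expect_equal(empirical_entropy(c(1, 1, 2)),
               -2 * 0.25 * log(0.25) - 0.5 * log(0.5))
  expect_equal(empirical_entropy(c(2, 0, 2)), log(2))  # zero category
  expect_error(empirical_entropy(c(0, 0)), "sum to zero")
  expect_error(empirical_entropy(c(-1, 2)), "nonnegative")
})

test_that("asymmetric uncertainty hits its boundary cases", {
  # bijective mapping: marker determines the group exactly
  grp <- rep(c("a", "b", "c"), each = 4)
  expect_equal(asymmetric_uncertainty(grp, grp)$power, 1)
  relabel <- c(a = "x", b = "y", c = "z")[grp]
  expect_equal(asymmetric_uncertainty(grp, relabel)$power, 1)
  # exact empirical independence (outer-product 2x2 counts [[2,2],[2,2]])
  g <- rep(c("a", "b"), each = 4)
  m <- rep(c("x", "y"), 4)
  expect_equal(asymmetric_uncertainty(g, m)$power, 0)

  expect_error(asymmetric_uncertainty(rep("a", 6), m[1:6]), "constant")
  expect_error(asymmetric_uncertainty(g, m[-1]), "length mismatch")
})

test_that("asymmetric uncertainty equals the entropy-decomposition oracle", {
  # counts [[2,0],[1,1]]: marker rows {x,x,y,y}, groups {a,a,a,b}
  grp <- c("a", "a", "a", "b")
  mkr <- c("x", "x", "y", "y")
  oracle <- (empirical_entropy(c(2, 2)) + empirical_entropy(c(3, 1)) -
               empirical_entropy(c(2, 0, 1, 1))) /
    empirical_entropy(c(3, 1))
  sc <- asymmetric_uncertainty(grp, mkr)
  expect_equal(sc$power, oracle)
  expect_gt(sc$power_variance, 0)
  expect_equal(sc$power_z, sc$power / sqrt(sc$power_variance))
})

test_that("asymptotic variances agree with a bootstrap oracle", {
  set.seed(101)
  n <- 2000
  px <- c(0.2, 0.5, 0.3)
  py_given <- rbind(c(0.6, 0.2, 0.1, 0.1),
                    c(0.1, 0.5, 0.3, 0.1),
                    c(0.2, 0.2, 0.2, 0.4))
  x_idx <- sample.int(3, n, TRUE, px)
  y_idx <- vapply(x_idx, function(i) sample.int(4, 1, prob = py_given[i, ]),
                  integer(1))
  x <- letters[x_idx]; y <- LETTERS[y_idx]
  asym <- asymmetric_uncertainty(x, y)
  sym <- symmetric_uncertainty(x, y)
  boot <- replicate(300, {
    i <- sample.int(n, replace = TRUE)
    c(asymmetric_uncertainty(x[i], y[i])$power,
      symmetric_uncertainty(x[i], y[i])$value)
  })
  expect_equal(asym$power_variance, stats::var(boot[1, ]),
               tolerance = 0.15)
  expect_equal(sym$variance, stats::var(boot[2, ]), tolerance = 0.15)
})

test_that("variances shrink as O(1/n) under resampling", {
  set.seed(55)
  pop_x <- sample(letters[1:4], 5000, TRUE, c(0.4, 0.3, 0.2, 0.1))
  noise <- sample(letters[1:4], 5000, TRUE)
  pop_y <- ifelse(stats::runif(5000) < 0.5, pop_x, noise)
  scaled <- vapply(c(100, 400, 1600), function(n) {
    i <- sample.int(5000, n)
    n * asymmetric_uncertainty(pop_x[i], pop_y[i])$power_variance
  }, numeric(1))
  # n * var stays bounded within a factor while var itself drops ~16x
  expect_lt(max(scaled) / min(scaled), 3)
})

test_that("symmetric uncertainty boundary cases and symmetry", {
  v <- c("A", "A", "B", "B", "A", "B")
  self <- symmetric_uncertainty(v, v)
  expect_equal(self$value, 1)
  relabeled <- c(A = "C", B = "D")[v]
  expect_equal(symmetric_uncertainty(v, relabeled)$value, 1)
  indep <- symmetric_uncertainty(c("A", "A", "B", "B"),
                                 c("A", "B", "A", "B"))
  expect_equal(indep$value, 0)
  a <- c("A", "A", "B", "C"); b <- c("x", "y", "x", "x")
  s1 <- symmetric_uncertainty(a, b); s2 <- symmetric_uncertainty(b, a)
  expect_equal(s1$value, s2$value)
  expect_equal(s1$variance, s2$variance)
  expect_error(symmetric_uncertainty(rep("A", 4), rep("B", 4)),
               "zero total entropy")
})

test_that("uncertainty coefficients are relabeling-invariant and in [0,1]", {
  set.seed(77)
  for (i in 1:20) {
    g <- sample(letters[1:3], 40, TRUE)
    m <- sample(LETTERS[1:5], 40, TRUE)
    u <- asymmetric_uncertainty(g, m)$power
    s <- symmetric_uncertainty(g, m)$value
    expect_true(u >= 0 && u <= 1)
    expect_true(s >= 0 && s <= 1)
    perm <- setNames(sample(LETTERS[1:5]), LETTERS[1:5])
    expect_equal(asymmetric_uncertainty(g, perm[m])$power, u)
    expect_equal(symmetric_uncertainty(g, perm[m])$value, s)
  }
})

test_that("marker_scores ranks constant markers last with zero power", {
  tab <- generate_genotypes(synth_spec(3, 8, 5, informative_markers = 3,
                                       seed = 41))
  tab$cells[, 5] <- rep(list(42L), nrow(tab$cells))
  sc <- marker_scores(tab)
  expect_equal(sc$power[5], 0)
  expect_equal(sc$power_z[5], 0)
  ord <- order(-sc$power)
  expect_equal(ord[length(ord)], 5L)
})

test_that("alpha = 0 greedy selection equals top-N by power", {
  set.seed(19)
  for (i in 1:10) {
    tab <- generate_genotypes(synth_spec(
      n_groups = 3, samples_per_group = 10,
      n_markers = 8, informative_markers = sample(2:6, 1), seed = 300 + i))
    sc <- marker_scores(tab)
    top3 <- sc$marker[order(-sc$power)][1:3]   # stable-tie oracle
    res <- greedy_select(tab, config = selection_config(3, alpha = 0))
    expect_identical(res$selected$marker, top3)
    expect_identical(nrow(res$skipped), 0L)
  }
})

test_that("an exact duplicate of the top marker is skipped at alpha = 1", {
  tab <- complementary_table()
  res1 <- greedy_select(tab, config = selection_config(2, alpha = 1))
  expect_identical(res1$selected$marker, c("M1", "M3"))
  expect_true("M2" %in% res1$skipped$marker)
  skip_row <- res1$skipped[res1$skipped$marker == "M2", ]
  expect_identical(skip_row$blocked_by, "M1")
  expect_equal(skip_row$redundancy, 1)
  res0 <- greedy_select(tab, config = selection_config(2, alpha = 0))
  expect_identical(res0$selected$marker, c("M1", "M2"))
})

test_that("independent complementary markers pass the redundancy gate", {
  tab <- complementary_table()
  res <- greedy_select(tab, config = selection_config(3, alpha = 1))
  # M3 is empirically independent of M1 (balanced complementary split)
  expect_true(all(c("M1", "M3") %in% res$selected$marker))
})

test_that("raising alpha only ever increases skipping", {
  tab <- generate_genotypes(synth_spec(
    n_groups = 5, samples_per_group = 15, n_markers = 10,
    informative_markers = 6, seed = 83))
  n_skipped <- max_red <- numeric(0)
  for (alpha in c(0, 0.5, 1, 2, 4)) {
    res <- greedy_select(tab, config = selection_config(4, alpha = alpha))
    n_skipped <- c(n_skipped, nrow(res$skipped))
    kit <- res$selected$marker
    reds <- 0
    if (length(kit) > 1) {
      pairs <- utils::combn(kit, 2)
      reds <- max(apply(pairs, 2, function(p) {
        symmetric_uncertainty(genotype_categories(tab, p[1]),
                              genotype_categories(tab, p[2]))$z
      }))
    }
    max_red <- c(max_red, reds)
  }
  expect_true(all(diff(n_skipped) >= 0))
  expect_true(all(diff(max_red) <= 1e-9))
})

test_that("kit_size larger than the marker count selects all with warning", {
  tab <- complementary_table()
  expect_warning(res <- greedy_select(tab,
                                      config = selection_config(10,
                                                                alpha = 0)),
                 "exceeds")
  expect_identical(nrow(res$selected), 4L)
})

test_that("MIFS baseline honors its beta penalty", {
  tab <- complementary_table()
  # beta = 0: plain mutual-information ranking, duplicate chosen second
  res0 <- mifs_select(tab, config = selection_config(2, method = "MIFS",
                                                     beta = 0))
  expect_identical(res0$selected$marker, c("M1", "M2"))
  # beta = 1: I(dup; top) = H(top) dominates, duplicate deferred
  res1 <- mifs_select(tab, config = selection_config(2, method = "MIFS",
                                                     beta = 1))
  expect_identical(res1$selected$marker, c("M1", "M3"))
  one <- subset_table(tab, markers = "M1")
  one$labels <- tab$labels
  resx <- mifs_select(one, config = selection_config(1, method = "MIFS"))
  expect_identical(resx$selected$marker, "M1")
})

test_that("mRMR baseline defers duplicates and starts at max relevance", {
  tab <- complementary_table()
  res <- mrmr_select(tab, config = selection_config(3, method = "mRMR"))
  expect_identical(res$selected$marker[1], "M1")  # argmax MI with group
  expect_identical(res$selected$marker[2], "M3")  # duplicate deferred
  # independent markers: ordering equals pure relevance
  set.seed(9)
  g <- sample(letters[1:3], 60, TRUE)
  cells <- cbind(A = as.character(ifelse(g == "a", 100, 102)),
                 B = sample(as.character(c(200, 202)), 60, TRUE),
                 C = sample(as.character(c(300, 302, 304)), 60, TRUE))
  tab2 <- genotype_table(cells, sample_ids = paste0("s", 1:60),
                         marker_ids = c("A", "B", "C"), labels = g)
  res2 <- mrmr_select(tab2, config = selection_config(3, method = "mRMR"))
  expect_identical(res2$selected$marker[1], "A")
})

test_that("selection reports serialize to TSV", {
  tab <- complementary_table()
  res <- greedy_select(tab, config = selection_config(2, alpha = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(res, path)
  rep <- utils::read.delim(path)
  expect_true(all(c("marker", "status", "power", "blocked_by") %in%
                    names(rep)))
  expect_identical(rep$status[rep$marker == "M2"], "skipped")
})
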