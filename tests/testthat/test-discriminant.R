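test_that("Wilks' lambda equals the determinant-ratio oracle on random designs", {
  # independent oracle: explicit loops over groups, no shared code
  oracle <- function(X, labels) {
    labels <- as.factor(labels)
    Tm <- matrix(0, ncol(X), ncol(X)); W <- Tm
    gm <- colMeans(X)
    for (i in seq_len(nrow(X))) {
      d <- X[i, ] - gm
      Tm <- Tm + outer(d, d)
    }
    for (g in levels(labels)) {
      Xg <- X[labels == g, , drop = FALSE]
      mg <- colMeans(Xg)
      for (i in seq_len(nrow(Xg))) {
        d <- Xg[i, ] - mg
        W <- W + outer(d, d)
      }
    }
    det(W) / det(Tm)
  }
  set.seed(101)
  for (rep in 1:100) {
    g <- sample(2:4, 1); p <- sample(1:5, 1)
    d <- random_design(rep(sample(4:8, 1), g), p, g,
                       shift = matrix(rnorm(g * p), g), seed = 1000 + rep)
    expect_equal(wilks_lambda(d$X, d$labels), oracle(d$X, d$labels),
                 tolerance = 1e-10)
  }
})

test_that("lambda hits its analytic limits", {
  # identical group means: W = T
  X <- cbind(rep(c(1, 2, 3, 4), 2), rep(c(0, 1, 0, 1), 2))
  lab <- rep(c("a", "b"), each = 4)
  expect_equal(wilks_lambda(X, lab), 1)
  # separated groups with near-zero within-group variance
  set.seed(2)
  X2 <- rbind(matrix(rnorm(20, 0, 1e-4), 10), matrix(rnorm(20, 5, 1e-4), 10))
  expect_lt(wilks_lambda(X2, rep(c("a", "b"), each = 10)), 1e-6)
  # singular total matrix names the variables
  X3 <- cbind(V1 = rnorm(10), V2 = 0)
  X3[, 2] <- X3[, 1]
  expect_error(wilks_lambda(X3, rep(c("a", "b"), 5)), "multicollinearity")
})

test_that("two-group single-variable lambda matches the t-statistic identity", {
  set.seed(5)
  for (rep in 1:25) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    x <- c(rnorm(n1, 0), rnorm(n2, runif(1, 0, 2)))
    lab <- rep(c("a", "b"), c(n1, n2))
    t2 <- unname(stats::t.test(x ~ lab, var.equal = TRUE)$statistic)^2
    n <- n1 + n2
    expect_equal(wilks_lambda(matrix(x), lab), 1 / (1 + t2 / (n - 2)),
                 tolerance = 1e-10)
  }
})

test_that("stepwise selection admits informative variables and drops redundancy", {
  # a strong variable among noise enters first
  set.seed(9)
  d <- random_design(c(10, 10), 10, 2, seed = 77)
  X <- d$X
  X[d$labels == "G2", 1] <- X[d$labels == "G2", 1] + 3
  sel <- stepwise_select(X, d$labels)
  expect_equal(sel$selected[1], "V1")
  expect_lt(sel$lambda, 1)
  expect_equal(sel$trace$action[1], "enter")

  # a duplicated copy of the informative variable cannot enter twice
  X2 <- cbind(X[, 1, drop = FALSE], V1copy = X[, 1])
  sel2 <- stepwise_select(X2, d$labels)
  expect_equal(sel2$selected, "V1")

  expect_error(stepwise_select(X, d$labels, f_in = 2, f_out = 3), "config error")
})

test_that("classifier coefficients, VIF and predictions are consistent", {
  set.seed(21)
  d <- random_design(c(12, 12, 12), 3, 3,
                     shift = rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)), seed = 3)
  fit <- fit_classifier(d$X, d$labels)
  expect_equal(sum(fit$priors), 1)
  expect_equal(ncol(fit$raw_coefficients), 2)  # min(g-1, p)
  expect_true(all(fit$vif >= 1))
  expect_gte(fit$wilks_lambda, 0); expect_lte(fit$wilks_lambda, 1)

  # orthogonal predictors carry unit VIF
  Xo <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  fo <- fit_classifier(Xo + rnorm(20, 0, 1e-8), rep(c("g1", "g2"), each = 10))
  expect_equal(unname(fo$vif), c(1, 1), tolerance = 1e-3)

  # duplicated predictor: singular pooled covariance is refused with names
  Xd <- cbind(v = rnorm(20), w = 0); Xd[, 2] <- Xd[, 1]
  expect_error(fit_classifier(Xd, rep(c("g1", "g2"), each = 10)), "aliased")

  # cross-check predictions against an independent LDA implementation
  skip_if_not_installed("MASS")
  m <- MASS::lda(d$X, grouping = d$labels, prior = rep(1 / 3, 3))
  expect_equal(as.character(predict(fit, d$X)),
               as.character(predict(m, d$X)$class))
})

test_that("classification is invariant under affine rescaling of a variable", {
  set.seed(31)
  d <- random_design(c(10, 10), 3, 2, shift = rbind(c(0, 0, 0), c(2, 1, 0)),
                     seed = 13)
  fit <- fit_classifier(d$X, d$labels)
  X2 <- d$X
  X2[, 1] <- 100 * X2[, 1] - 7
  fit2 <- fit_classifier(X2, d$labels)
  expect_equal(as.character(predict(fit, d$X)),
               as.character(predict(fit2, X2)))
  # standardized coefficients are unchanged by the rescaling
  expect_equal(abs(fit$standardized_coefficients),
               abs(fit2$standardized_coefficients), tolerance = 1e-8)
})

test_that("leave-one-out separates well-separated groups and only those", {
  set.seed(41)
  d <- random_design(c(10, 10), 3, 2, shift = rbind(c(0, 0, 0), c(6, 0, 0)),
                     seed = 19)
  cv <- loo_cv(d$X, d$labels, colnames(d$X))
  expect_equal(cv$overall_accuracy, 100)
  expect_equal(unname(rowSums(cv$confusion)), c(10, 10))

  # permutation null: accuracy near chance over repeated shuffles
  accs <- vapply(1:25, function(s) {
    set.seed(500 + s)
    lab <- sample(d$labels)
    loo_cv(d$X, lab, colnames(d$X))$overall_accuracy
  }, 0)
  expect_gt(mean(accs), 20); expect_lt(mean(accs), 70)

  # minimal n = 3 per group still runs with full confusion rows
  d3 <- random_design(c(3, 3), 2, 2, shift = rbind(c(0, 0), c(5, 0)), seed = 7)
  cv3 <- loo_cv(d3$X, d3$labels, colnames(d3$X))
  expect_equal(unname(rowSums(cv3$confusion)), c(3, 3))

  # nested mode re-runs selection inside the folds
  cvn <- loo_cv(d$X, d$labels, nested = TRUE)
  expect_gte(cvn$overall_accuracy, 90)
})

test_that("holdout evaluation honours the train/test contract", {
  set.seed(51)
  d <- random_design(c(12, 12), 2, 2, shift = rbind(c(0, 0), c(6, 0)), seed = 23)
  test_ids <- c(1:3, 13:15); train_ids <- setdiff(1:24, test_ids)
  hv <- holdout_eval(d$X, d$labels, train_ids, test_ids, colnames(d$X))
  expect_equal(hv$overall_accuracy, 100)

  # a row equal to a training centroid lands in that group
  fit <- fit_classifier(d$X[train_ids, ], d$labels[train_ids], colnames(d$X))
  centroid <- fit$group_means["G2", , drop = FALSE]
  expect_equal(as.character(predict(fit, centroid)), "G2")

  expect_error(holdout_eval(d$X, d$labels, 1:20, 20:24, colnames(d$X)),
               "disjoint")
  expect_warning(hv0 <- holdout_eval(d$X, d$labels, train_ids, integer(0),
                                     colnames(d$X)), "empty test set")
  expect_equal(sum(hv0$confusion), 0)

  # unseen group label in the test rows is refused
  lab3 <- as.character(d$labels); lab3[24] <- "G3"
  expect_warning(hv3 <- holdout_eval(d$X, lab3, train_ids[train_ids < 24],
                                     c(1:2, 24), colnames(d$X)), "unseen")
  expect_true(is.na(hv3$predicted[3]))
})

test_that("missing values are imputed as zero with a note before modelling", {
  set.seed(61)
  d <- random_design(c(8, 8), 3, 2, shift = rbind(c(0, 0, 0), c(4, 0, 0)),
                     seed = 29)
  X <- d$X; X[3, 2] <- NA
  expect_message(fit <- fit_classifier(X, d$labels), "imputed 1")
  expect_s3_class(fit, "discriminant_model")
})
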