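#' Wilks' lambda of a grouped design
#'
#' The ratio of within-group to total variability,
#' \code{lambda = det(W) / det(T)}, where \code{W} is the pooled
#' within-group and \code{T} the total cross-product (SSCP) matrix of the
#' given variables. Values near 0 indicate strong group separation; 1 means
#' the group means coincide.
#'
#' @param X Numeric matrix or data.frame, observations x variables.
#' @param labels Group labels, one per row.
#' @return Wilks' lambda in [0, 1].
#' @export
wilks_lambda <- function(X, labels) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need >= 2 groups", call. = FALSE)
  mats <- .sscp(X, labels)
  dT <- det(mats$T)
  if (!is.finite(dT) || abs(dT) < 1e-300) {
    stop("multicollinearity error: total SSCP is singular for variables ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  lam <- det(mats$W) / dT
  min(max(lam, 0), 1)
}

.sscp <- function(X, labels) {
  labels <- droplevels(as.factor(labels))
  Tc <- sweep(X, 2, colMeans(X))
  Tm <- crossprod(Tc)
  W <- matrix(0, ncol(X), ncol(X))
  for (g in levels(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    Wc <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Wc)
  }
  dimnames(Tm) <- dimnames(W) <- list(colnames(X), colnames(X))
  list(W = W, T = Tm)
}

# lambda, or NA when the design is numerically singular
.safe_lambda <- function(X, labels) {
  tryCatch(wilks_lambda(X, labels), error = function(e) NA_real_)
}

# impute missing descriptor values as 0 (empty-bin convention) with a note
impute_missing <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n_na <- sum(!is.finite(X))
  if (n_na > 0) {
    X[!is.finite(X)] <- 0
    message(sprintf("imputed %d missing/non-finite value(s) as 0", n_na))
  }
  X
}

#' Stepwise variable selection by Wilks' lambda
#'
#' SPSS-style stepwise discriminant selection. At each step the candidate
#' variable minimizing the new overall Wilks' lambda enters if its partial
#' F-to-enter reaches \code{f_in}; after every entry, included variables
#' whose partial F-to-remove falls below \code{f_out} leave. The partial F
#' for moving between a model with \code{q} and \code{q + 1} variables is
#' \deqn{F = \frac{n - g - q}{g - 1}\left(\frac{\Lambda_q}{\Lambda_{q+1}} - 1\right)}
#' with \code{n} observations and \code{g} groups. Ties in the entry
#' criterion are broken by column order; missing values are imputed as 0
#' beforehand.
#'
#' @param X Observations x candidate variables.
#' @param labels Group labels.
#' @param f_in F-to-enter threshold (default 3.84).
#' @param f_out F-to-remove threshold (default 2.71; must be below
#'   \code{f_in} to prevent cycling).
#' @param tolerance Minimum tolerance (1 minus the within-group squared
#'   multiple correlation of a candidate with the already-entered
#'   variables); candidates below it cannot enter. Keeps the selected set
#'   numerically well conditioned (default 0.001).
#' @param max_steps Safety bound on entry/removal steps.
#' @return A list of class \code{stepwise_selection}: \code{selected}
#'   (ordered variable names), \code{lambda} (final Wilks' lambda, 1 when
#'   nothing entered) and \code{trace} (one row per step: action, variable,
#'   lambda, partial F).
#' @export
stepwise_select <- function(X, labels, f_in = 3.84, f_out = 2.71,
                            tolerance = 0.001, max_steps = 100) {
  if (f_out >= f_in)
    stop("config error: f_out must be below f_in to prevent cycling",
         call. = FALSE)
  X <- impute_missing(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  labels <- droplevels(as.factor(labels))
  n <- nrow(X); g <- nlevels(labels)
  # exclude degenerate candidates up front
  variable_ok <- apply(X, 2, function(col) stats::sd(col) > 0)
  candidates_all <- colnames(X)[variable_ok]
  Wfull <- .sscp(X, labels)$W

  # tolerance of candidate v given the entered set (within-group R^2)
  tol_of <- function(v, sel) {
    if (Wfull[v, v] <= 0) return(0)
    if (!length(sel)) return(1)
    r2 <- tryCatch(
      drop(Wfull[v, sel, drop = FALSE] %*%
             solve(Wfull[sel, sel, drop = FALSE],
                   Wfull[sel, v, drop = FALSE])) / Wfull[v, v],
      error = function(e) 1)
    max(0, 1 - r2)
  }

  selected <- character(0)
  lambda_cur <- 1
  trace <- list()
  seen_states <- character(0)
  for (step in seq_len(max_steps)) {
    q <- length(selected)
    # ---- entry
    cands <- setdiff(candidates_all, selected)
    cands <- cands[vapply(cands, tol_of, 0, sel = selected) >= tolerance]
    best <- NULL
    if (length(cands) && (n - g - q) > 0) {
      lams <- vapply(cands, function(v)
        .safe_lambda(X[, c(selected, v), drop = FALSE], labels), 0)
      ok <- is.finite(lams)
      if (any(ok)) {
        i <- which(ok)[which.min(lams[ok])]  # first minimum: column order
        F_enter <- (n - g - q) / (g - 1) * (lambda_cur / lams[i] - 1)
        if (is.finite(F_enter) && F_enter >= f_in)
          best <- list(var = cands[i], lambda = lams[i], F = F_enter)
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best$var)
    lambda_cur <- best$lambda
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, action = "enter", variable = best$var,
      lambda = best$lambda, partial_F = best$F)
    # ---- removal sweep
    repeat {
      q <- length(selected)
      if (q < 2) break
      lams_wo <- vapply(selected, function(v)
        .safe_lambda(X[, setdiff(selected, v), drop = FALSE], labels), 0)
      F_rm <- (n - g - (q - 1)) / (g - 1) * (lams_wo / lambda_cur - 1)
      worst <- which.min(F_rm)
      if (!is.finite(F_rm[worst]) || F_rm[worst] >= f_out) break
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, action = "remove", variable = selected[worst],
        lambda = lams_wo[worst], partial_F = F_rm[worst])
      lambda_cur <- lams_wo[worst]
      selected <- selected[-worst]
    }
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen_states) {
      warning("stepwise selection cycled; halting", call. = FALSE)
      break
    }
    seen_states <- c(seen_states, state)
  }
  structure(list(selected = selected, lambda = lambda_cur,
                 trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(step = integer(0), action = character(0),
                                 variable = character(0), lambda = numeric(0),
                                 partial_F = numeric(0))),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("<stepwise_selection> %d variable(s), Wilks lambda %.3f\n",
              length(x$selected), x$lambda))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a linear discriminant classifier on a fixed variable list
#'
#' Computes the canonical discriminant functions from the eigenstructure of
#' \code{solve(W) \%*\% B} (within- and between-group SSCP), scaled so that
#' canonical scores have unit pooled within-group variance; standardized
#' coefficients multiply the raw coefficients by the pooled within-group
#' standard deviations. Fisher linear classification functions (one linear
#' score per group, including the log-prior) are derived from the pooled
#' covariance, and a variance inflation factor is reported per variable.
#'
#' @param X Observations x variables (superset allowed).
#' @param labels Group labels.
#' @param variables Character vector of columns to use (default: all).
#' @param priors Named or unnamed per-group prior probabilities; default
#'   equal.
#' @return An object of class \code{discriminant_model}: selected
#'   variables, Wilks' lambda, raw/standardized canonical coefficients,
#'   Fisher classification functions, priors, VIFs, group means and pooled
#'   covariance.
#' @export
fit_classifier <- function(X, labels, variables = colnames(as.data.frame(X)),
                           priors = NULL) {
  X <- impute_missing(as.data.frame(X)[, variables, drop = FALSE])
  labels <- droplevels(as.factor(labels))
  g <- nlevels(labels); n <- nrow(X); p <- ncol(X)
  if (any(table(labels) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / g, g)
  if (is.null(names(priors))) names(priors) <- levels(labels)
  priors <- priors[levels(labels)] / sum(priors)

  mats <- .sscp(X, labels)
  Sw <- mats$W / (n - g)
  # variables live on wildly different scales (ratios vs range products);
  # rank checks and solves are done on the within-group correlation scale
  sd_w <- sqrt(diag(Sw))
  if (any(sd_w <= 0))
    stop("singular pooled covariance; aliased variables: ",
         paste(colnames(X)[sd_w <= 0], collapse = ", "), call. = FALSE)
  Rw <- Sw / outer(sd_w, sd_w)
  qrRw <- qr(Rw)
  if (qrRw$rank < p) {
    aliased <- colnames(X)[qrRw$pivot[-seq_len(qrRw$rank)]]
    stop("singular pooled covariance; aliased variables: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  B <- mats$T - mats$W
  Bs <- B / outer(sd_w, sd_w)
  m <- min(g - 1, p)
  eig <- eigen(solve(Rw * (n - g), Bs))
  ord <- order(Re(eig$values), decreasing = TRUE)[seq_len(m)]
  raw <- Re(eig$vectors[, ord, drop = FALSE]) / sd_w
  # unit pooled within-group variance of each canonical score
  for (j in seq_len(m)) {
    s <- sqrt(drop(t(raw[, j]) %*% Sw %*% raw[, j]))
    raw[, j] <- raw[, j] / s
    # sign convention: largest-magnitude coefficient positive
    k <- which.max(abs(raw[, j]))
    if (raw[k, j] < 0) raw[, j] <- -raw[, j]
  }
  rownames(raw) <- colnames(X)
  std <- raw * sqrt(diag(Sw))

  means <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(X[labels == l, , drop = FALSE])))
  rownames(means) <- levels(labels)
  Swi <- t(solve(Rw) / outer(sd_w, sd_w))
  coef_k <- means %*% Swi                     # g x p
  const_k <- -0.5 * rowSums(coef_k * means) + log(priors)

  vif <- vapply(seq_len(p), function(j) {
    if (p == 1) return(1)
    r2 <- tryCatch({
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    }, error = function(e) 1)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)

  structure(list(variables = colnames(X),
                 wilks_lambda = .safe_lambda(X, labels),
                 raw_coefficients = raw,
                 standardized_coefficients = std,
                 classification_coefficients = coef_k,
                 classification_constants = const_k,
                 priors = priors, vif = vif,
                 group_means = means, pooled_covariance = Sw,
                 levels = levels(labels), n = n),
            class = "discriminant_model")
}

#' Classify observations with a fitted discriminant model
#'
#' @param object A \code{\link{fit_classifier}} model.
#' @param newdata Data.frame or matrix containing the model's variables.
#' @param ... Unused.
#' @return Factor of predicted group labels.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  Xn <- impute_missing(as.data.frame(newdata)[, object$variables, drop = FALSE])
  scores <- Xn %*% t(object$classification_coefficients)
  scores <- sweep(scores, 2, object$classification_constants, `+`)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d groups, %d variable(s), Wilks lambda %.3f\n",
              length(x$levels), length(x$variables), x$wilks_lambda))
  std <- round(x$standardized_coefficients, 3)
  colnames(std) <- paste0("F", seq_len(ncol(std)))
  tab <- data.frame(variable = x$variables, std,
                    VIF = round(x$vif, 3), row.names = NULL)
  print(tab)
  invisible(x)
}

.cv_result <- function(truth, pred, levels) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  keep <- !is.na(pred)
  cm <- table(truth = truth[keep], predicted = pred[keep])
  per_class <- vapply(levels, function(l) {
    nl <- sum(truth == l & keep)
    if (nl == 0) NA_real_ else 100 * sum(truth == l & pred == l, na.rm = TRUE) / nl
  }, 0)
  overall <- 100 * sum(diag(cm)) / max(1, sum(cm))
  structure(list(confusion = cm, per_class_accuracy = per_class,
                 overall_accuracy = overall, predicted = pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> overall accuracy %.1f%%\n", x$overall_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out cross-validation with a fixed variable list
#'
#' Each observation is classified by a model refitted on all remaining
#' observations using the same (fixed) variable list; the variable
#' selection itself is \emph{not} repeated inside the folds, mirroring the
#' usual SPSS cross-validation. For an optimism-free protocol that re-runs
#' selection within every fold, set \code{nested = TRUE} and pass the
#' stepwise thresholds.
#'
#' @param X Observations x variables.
#' @param labels Group labels (each group >= 3 observations recommended).
#' @param variables Fixed variable list (ignored when \code{nested}).
#' @param priors Per-group priors; default equal.
#' @param nested Re-run stepwise selection inside each fold.
#' @param f_in,f_out Thresholds for nested selection.
#' @return A \code{cv_result}: confusion matrix, per-class and overall
#'   accuracy (percent), per-observation predictions.
#' @export
loo_cv <- function(X, labels, variables, priors = NULL, nested = FALSE,
                   f_in = 3.84, f_out = 2.71) {
  X <- as.data.frame(X)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  pred <- rep(NA_character_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    lab_tr <- droplevels(labels[-i])
    if (nlevels(lab_tr) < nlevels(labels) || any(table(lab_tr) < 2)) {
      skipped <- skipped + 1L
      next
    }
    vars_i <- if (nested) {
      sel <- stepwise_select(X[-i, , drop = FALSE], labels[-i],
                             f_in = f_in, f_out = f_out)
      if (!length(sel$selected)) next
      sel$selected
    } else variables
    pred[i] <- tryCatch({
      fit <- fit_classifier(X[-i, , drop = FALSE], labels[-i], vars_i, priors)
      as.character(predict(fit, X[i, , drop = FALSE]))
    }, error = function(e) {
      skipped <<- skipped + 1L
      NA_character_
    })
  }
  if (skipped > 0)
    warning(sprintf("%d fold(s) skipped (group emptied or fit failed)", skipped),
            call. = FALSE)
  .cv_result(labels, pred, levels(labels))
}

#' Train/test split evaluation
#'
#' Fits the classifier on the training rows only and reports accuracy on
#' the held-out test rows. Test rows whose group label was not present in
#' training are refused (predicted \code{NA}) with a warning.
#'
#' @param X Observations x variables.
#' @param labels Group labels.
#' @param train_ids,test_ids Disjoint row indices.
#' @param variables Variable list for the model.
#' @param priors Per-group priors.
#' @return A \code{cv_result} over the test rows.
#' @export
holdout_eval <- function(X, labels, train_ids, test_ids, variables,
                         priors = NULL) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test sets must be disjoint", call. = FALSE)
  X <- as.data.frame(X)
  labels <- as.factor(labels)
  if (!length(test_ids)) {
    warning("empty test set", call. = FALSE)
    return(.cv_result(factor(character(0), levels = levels(labels)),
                      character(0), levels(labels)))
  }
  fit <- fit_classifier(X[train_ids, , drop = FALSE],
                        droplevels(labels[train_ids]), variables, priors)
  pred <- rep(NA_character_, length(test_ids))
  known <- as.character(labels[test_ids]) %in% fit$levels
  if (any(!known))
    warning(sprintf("%d test row(s) with unseen group label refused",
                    sum(!known)), call. = FALSE)
  if (any(known))
    pred[known] <- as.character(predict(fit, X[test_ids[known], , drop = FALSE]))
  .cv_result(labels[test_ids], pred, levels(droplevels(labels[test_ids])))
}
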