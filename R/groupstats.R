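#' One-way ANOVA with Tukey HSD post hoc, per variable
#'
#' For each named variable the observations are compared across groups by
#' classic one-way ANOVA; pairwise differences are then assessed with
#' Tukey's honestly significant difference test on the studentized range
#' (harmonic-mean group sizes for unbalanced cells). Missing values are
#' dropped per variable; a variable with an empty group is skipped with a
#' warning.
#'
#' @param table Cohort data.frame (one row per individual x condition).
#' @param variables Character vector of numeric columns to test.
#' @param group_col Column holding the group labels (default builds a
#'   6-level label from \code{group} and \code{tnf} when both exist,
#'   otherwise uses \code{group}).
#' @param groups Optional subset of group labels to compare.
#' @return A list of class \code{anova_tukey_result}: \code{anova}
#'   (data.frame: variable, F, p) and \code{tukey} (data.frame: variable,
#'   comparison, difference, adjusted p).
#' @export
anova_tukey <- function(table, variables, group_col = NULL, groups = NULL) {
  lab <- .group_labels(table, group_col)
  if (!is.null(groups)) {
    keep <- lab %in% groups
    table <- table[keep, , drop = FALSE]
    lab <- factor(lab[keep], levels = groups)
  }
  an_rows <- list(); tk_rows <- list()
  for (v in variables) {
    y <- table[[v]]
    ok <- is.finite(y)
    gl <- droplevels(as.factor(lab[ok]))
    if (nlevels(gl) < 2 || any(table(gl) < 2)) {
      warning("skipping variable with empty/short group: ", v, call. = FALSE)
      next
    }
    fit <- stats::aov(y[ok] ~ gl)
    ft <- summary(fit)[[1]]
    an_rows[[v]] <- data.frame(variable = v, F = ft$`F value`[1],
                               p = ft$`Pr(>F)`[1])
    tk <- stats::TukeyHSD(fit)$gl
    tk_rows[[v]] <- data.frame(variable = v, comparison = rownames(tk),
                               difference = tk[, "diff"],
                               p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(anova = do.call(rbind, c(an_rows, list(make.row.names = FALSE))),
                 tukey = do.call(rbind, c(tk_rows, list(make.row.names = FALSE)))),
            class = "anova_tukey_result")
}

.group_labels <- function(table, group_col) {
  if (!is.null(group_col)) return(as.factor(table[[group_col]]))
  if (!is.null(table$tnf) && !is.null(table$group))
    return(factor(paste0(table$group, ifelse(table$tnf, "+TNF", ""))))
  as.factor(table$group)
}

#' Pairwise correlation matrices between two variable sets
#'
#' Pairwise-complete Pearson or Spearman correlations between every
#' variable of \code{set_a} and every variable of \code{set_b}, with the
#' usual t-transform (Pearson) or rank-based (Spearman, average ranks for
#' ties) p-values. Pairs with a constant column or fewer than 4 complete
#' observations yield \code{NA}. No multiplicity correction is applied by
#' default; set \code{adjust = "BH"} for Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param table Cohort data.frame.
#' @param set_a,set_b Character vectors of numeric column names.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param adjust P-value adjustment method (\code{"none"} default; any
#'   \code{\link[stats]{p.adjust}} method).
#' @return A list of class \code{correlation_result} with matrices
#'   \code{r} and \code{p} (rows \code{set_a}, columns \code{set_b}) and a
#'   tidy data.frame \code{tidy}.
#' @export
correlations <- function(table, set_a, set_b,
                         method = c("pearson", "spearman"),
                         adjust = "none") {
  method <- match.arg(method)
  r <- p <- matrix(NA_real_, length(set_a), length(set_b),
                   dimnames = list(set_a, set_b))
  for (a in set_a) for (b in set_b) {
    xa <- table[[a]]; xb <- table[[b]]
    ok <- is.finite(xa) & is.finite(xb)
    if (sum(ok) < 4) next
    if (stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(xa[ok], xb[ok], method = method,
                                           exact = FALSE))
    r[a, b] <- unname(ct$estimate)
    p[a, b] <- ct$p.value
  }
  tidy <- data.frame(var_a = rep(set_a, times = length(set_b)),
                     var_b = rep(set_b, each = length(set_a)),
                     r = as.vector(r), p = as.vector(p))
  tidy$p_adj <- stats::p.adjust(tidy$p, method = adjust)
  structure(list(r = r, p = p, tidy = tidy, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s, %d x %d pairs (%d defined)\n",
              x$method, nrow(x$r), ncol(x$r), sum(is.finite(x$r))))
  invisible(x)
}
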