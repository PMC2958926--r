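# ---------------------------------------------------------------------------
# Validation statistics comparing algorithmic results with expert ratings:
# diagnostic (Bayesian predictive) metrics on a 2x2 confusion table, Cohen's
# kappa for k-class agreement, and the two-way consistency intraclass
# correlation for score vectors.
# ---------------------------------------------------------------------------

#' Build a confusion table from label vectors
#'
#' Rows are the reference (expert, gold standard), columns the test (model).
#'
#' @param reference,test equal-length label vectors; for the binary
#'   efficient/inefficient comparison the positive level is
#'   `"efficient-group"`.
#' @param levels optional common level ordering.
#' @return A k x k integer matrix of class `ebca_confusion`.
#' @export
confusion_table <- function(reference, test, levels = NULL) {
  if (length(reference) != length(test))
    stop("confusion_table: length mismatch", call. = FALSE)
  lv <- levels %||% sort(union(unique(as.character(reference)),
                               unique(as.character(test))))
  tab <- base::table(factor(reference, lv), factor(test, lv))
  m <- matrix(as.integer(tab), nrow(tab), dimnames = dimnames(tab))
  structure(m, class = c("ebca_confusion", class(m)))
}

.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

.lr_ci <- function(lr, a, b, c_, d, conf = 0.95) {
  # log method: Var(log LR) ~ 1/a - 1/(a+b) + 1/c - 1/(c+d)
  if (!is.finite(lr) || lr <= 0 || a == 0 || c_ == 0)
    return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' With the convention rows = reference, columns = test and the first
#' level positive: `TP = tab[1,1]`, `FN = tab[1,2]`, `FP = tab[2,1]`,
#' `TN = tab[2,2]`.  Proportion confidence intervals use the Wilson score
#' method; likelihood-ratio intervals use the log method.  Division by zero
#' returns documented sentinels: `LR+ = Inf` when specificity is 1 and
#' sensitivity positive, `NaN` when both are degenerate.
#'
#' @param tab 2x2 matrix/table of nonnegative integer counts, or an
#'   `ebca_confusion`.
#' @param conf confidence level (default 0.95).
#' @return An `ebca_diag` list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `lr_pos`, `lr_neg`, each with a `ci` attribute, plus `counts` and
#'   `ci_method`.
#' @export
diagnostic_metrics <- function(tab, conf = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    stop("diagnostic_metrics: a 2x2 table is required", call. = FALSE)
  if (any(tab < 0))
    stop("diagnostic_metrics: negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0))
    stop("diagnostic_metrics: empty reference class", call. = FALSE)
  TP <- tab[1, 1]; FN <- tab[1, 2]; FP <- tab[2, 1]; TN <- tab[2, 2]
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NaN
  npv <- if (TN + FN > 0) TN / (TN + FN) else NaN
  lr_pos <- if (spec < 1) sens / (1 - spec) else if (sens > 0) Inf else NaN
  lr_neg <- if (spec > 0) (1 - sens) / spec else if (sens < 1) Inf else NaN
  wrap <- function(v, x, n) structure(v, ci = .wilson_ci(x, n, conf))
  structure(list(
    sensitivity = wrap(sens, TP, TP + FN),
    specificity = wrap(spec, TN, TN + FP),
    ppv = structure(ppv, ci = .wilson_ci(TP, TP + FP, conf)),
    npv = structure(npv, ci = .wilson_ci(TN, TN + FN, conf)),
    lr_pos = structure(lr_pos, ci = .lr_ci(lr_pos, TP, FN, FP, TN, conf)),
    lr_neg = structure(lr_neg, ci = .lr_ci(lr_neg, FN, TP, TN, FP, conf)),
    counts = c(TP = TP, FN = FN, FP = FP, TN = TN),
    ci_method = c(proportions = "wilson", likelihood_ratios = "log"),
    conf = conf), class = "ebca_diag")
}

#' @export
print.ebca_diag <- function(x, ...) {
  fmt <- function(v) {
    ci <- attr(v, "ci")
    sprintf("%.4g [%s, %s]", as.numeric(v),
            format(ci[1], digits = 3), format(ci[2], digits = 3))
  }
  cat("Diagnostic metrics (positive = first level; CI:",
      paste(x$ci_method, collapse = "/"), ")\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat("  LR+:        ", fmt(x$lr_pos), "\n")
  cat("  LR-:        ", fmt(x$lr_neg), "\n")
  invisible(x)
}

#' Cohen's unweighted kappa
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed diagonal
#' agreement and `p_e` the chance agreement from the marginals.  A table
#' with `p_e = 1` (all mass in one row and column) returns the sentinel
#' `kappa = 1` when agreement is perfect, `NaN` otherwise, with a note.
#'
#' @param tab square k x k count matrix (rows reference, columns test).
#' @return An `ebca_kappa` list: `kappa`, `p_o`, `p_e`, `note`.
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab))
    stop("cohen_kappa: square table required", call. = FALSE)
  n <- sum(tab)
  if (n == 0) stop("cohen_kappa: empty table", call. = FALSE)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-14) {
    k <- if (p_o >= 1 - 1e-14) 1 else NaN
    return(structure(list(kappa = k, p_o = p_o, p_e = p_e,
                          note = "degenerate marginals"),
                     class = "ebca_kappa"))
  }
  structure(list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e,
                 note = ""), class = "ebca_kappa")
}

#' @export
print.ebca_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.4f (p_o = %.4f, p_e = %.4f)%s\n",
              x$kappa, x$p_o, x$p_e,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Two-way consistency intraclass correlation (single measure)
#'
#' ICC(C,1) from the two-way ANOVA without interaction (rows = units,
#' columns = raters): `(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)`.
#' The consistency model ignores fixed rater shifts: adding a constant to
#' one rater's column leaves the ICC at 1.  The confidence interval comes
#' from the F ratio `MS_rows / MS_error` with `(n-1, (n-1)(k-1))` degrees
#' of freedom.
#'
#' @param ratings numeric matrix, units x raters, no missing cells.
#' @param conf confidence level (default 0.95).
#' @return An `ebca_icc` list: `icc`, `ci`, `ms_rows`, `ms_error`, `df`.
#' @export
icc_consistency <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m))
    stop("icc_consistency: missing cells; drop incomplete units first",
         call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("icc_consistency: need >= 2 units and >= 2 raters", call. = FALSE)
  row_m <- rowMeans(m); col_m <- colMeans(m); g <- mean(m)
  ss_rows <- k * sum((row_m - g)^2)
  ss_cols <- n * sum((col_m - g)^2)
  ss_tot <- sum((m - g)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  df_rows <- n - 1; df_err <- (n - 1) * (k - 1)
  ms_rows <- ss_rows / df_rows
  ms_err <- ss_err / df_err
  icc <- if (ms_rows + (k - 1) * ms_err == 0) 1
         else (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  ci <- if (ms_err <= 0) c(icc, icc) else {
    fv <- ms_rows / ms_err
    alpha <- 1 - conf
    fl <- fv / stats::qf(1 - alpha / 2, df_rows, df_err)
    fu <- fv * stats::qf(1 - alpha / 2, df_err, df_rows)
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci = ci, ms_rows = ms_rows, ms_error = ms_err,
                 df = c(rows = df_rows, error = df_err), conf = conf),
            class = "ebca_icc")
}

#' @export
print.ebca_icc <- function(x, ...) {
  cat(sprintf("ICC (two-way consistency, single measure): %.4f  %g%% CI [%.4f, %.4f]\n",
              x$icc, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}
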