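# ---------------------------------------------------------------------------
# Support-interpretation tools: per-variable significance across classes,
# class panel graphs (class x variable conditional distributions),
# characteristic-cell marking, and inconsistency detection.  These drive the
# elicitation of implicit knowledge: an anomalous class prompts a new rule.
# ---------------------------------------------------------------------------

#' Per-variable significance of a partition
#'
#' Numeric variables get a one-way location test: classical ANOVA when every
#' class sample passes a Shapiro-Wilk normality screen (at 0.05, requiring
#' n >= 8 per class), otherwise the rank-based Kruskal-Wallis test.
#' Categorical variables get a chi-squared independence test on the class x
#' category contingency table; when any expected count falls below 5 the
#' rarest categories are pooled first.  P-values are Benjamini-Hochberg
#' adjusted across variables and the result is sorted by adjusted p.
#'
#' @param table an `ebca_table`.
#' @param partition factor over the records (k >= 2 non-empty classes).
#' @return Data frame: `variable`, `test`, `statistic`, `p`, `p_adj`,
#'   `note`.
#' @export
test_variables <- function(table, partition) {
  partition <- factor(partition)
  if (nlevels(droplevels(partition)) < 2)
    stop("test_variables: need at least 2 non-empty classes", call. = FALSE)
  partition <- droplevels(partition)
  rows <- list()
  for (v in numeric_vars(table)) {
    x <- table[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) <= 1) {
      rows[[v]] <- data.frame(variable = v, test = "skipped",
                              statistic = NA_real_, p = NA_real_,
                              note = "constant or empty variable")
      next
    }
    g <- partition[ok]; xx <- x[ok]
    normal <- all(vapply(levels(g), function(cl) {
      xs <- xx[g == cl]
      if (length(xs) < 8) return(FALSE)
      if (length(unique(xs)) == 1) return(FALSE)
      if (length(xs) > 4999) xs <- sample(xs, 4999)
      stats::shapiro.test(xs)$p.value >= 0.05
    }, logical(1)))
    if (normal) {
      ft <- stats::oneway.test(xx ~ g, var.equal = TRUE)
      rows[[v]] <- data.frame(variable = v, test = "anova",
                              statistic = unname(ft$statistic),
                              p = ft$p.value, note = "")
    } else {
      kt <- stats::kruskal.test(xx, g)
      rows[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                              statistic = unname(kt$statistic),
                              p = kt$p.value, note = "")
    }
  }
  for (v in categorical_vars(table)) {
    x <- table[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) <= 1) {
      rows[[v]] <- data.frame(variable = v, test = "skipped",
                              statistic = NA_real_, p = NA_real_,
                              note = "constant or empty variable")
      next
    }
    tab <- base::table(partition[ok], x[ok])
    note <- ""
    # pool rarest categories while any expected count < 5 and > 2 remain
    repeat {
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (all(expd >= 5) || ncol(tab) <= 2) break
      o <- order(colSums(tab))
      pooled <- tab[, o[1]] + tab[, o[2]]
      keep <- tab[, -o[1:2], drop = FALSE]
      tab <- cbind(keep, other = pooled)
      note <- "rare categories pooled"
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- data.frame(variable = v, test = "chi-squared",
                            statistic = unname(ct$statistic),
                            p = ct$p.value, note = note)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("variable", "test", "statistic", "p", "p_adj", "note")]
  out[order(out$p_adj, out$variable), ]
}

#' Build a class panel graph
#'
#' A class x variable grid of conditional distributions: per numeric
#' variable, shared equal-width bins over the pooled sample (bin count by
#' Sturges' rule unless given); per categorical variable, the declared
#' categories.  Within each occupied cell the frequencies sum to 1.
#'
#' @param table an `ebca_table`.
#' @param partition factor over the records.
#' @param bins optional named integer vector of bin counts per numeric
#'   variable.
#' @return An `ebca_cpg`: long-format data frame `class`, `variable`, `bin`,
#'   `count`, `freq`, `marked`, with a `breaks` attribute per numeric
#'   variable.
#' @export
build_cpg <- function(table, partition, bins = NULL) {
  partition <- factor(partition)
  classes <- levels(partition)
  long <- list()
  breaks_list <- list()
  for (v in numeric_vars(table)) {
    x <- table[[v]]
    ok <- !is.na(x)
    nb <- bins[[v]] %||% grDevices::nclass.Sturges(x[ok])
    rng <- range(x[ok])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = nb + 1)
    breaks_list[[v]] <- brk
    binlab <- paste0("[", signif(brk[-length(brk)], 4), ",",
                     signif(brk[-1], 4), ")")
    for (cl in classes) {
      xs <- x[ok & partition == cl]
      cnt <- if (length(xs) == 0) rep(0L, nb) else
        as.integer(base::table(cut(xs, brk, include.lowest = TRUE,
                                   labels = FALSE)) |>
                     (\(t) {out <- rep(0L, nb); out[as.integer(names(t))] <- t; out})())
      long[[length(long) + 1]] <- data.frame(
        class = cl, variable = v, bin = binlab, count = cnt,
        freq = if (sum(cnt) > 0) cnt / sum(cnt) else 0,
        empty_class = length(xs) == 0)
    }
  }
  for (v in categorical_vars(table)) {
    sp <- table_specs(table)[[v]]
    cats <- sp$categories %||% sort(unique(stats::na.omit(table[[v]])))
    x <- table[[v]]
    ok <- !is.na(x)
    for (cl in classes) {
      xs <- x[ok & partition == cl]
      cnt <- vapply(cats, function(cc) sum(xs == cc), integer(1))
      long[[length(long) + 1]] <- data.frame(
        class = cl, variable = v, bin = cats, count = cnt,
        freq = if (sum(cnt) > 0) cnt / sum(cnt) else 0,
        empty_class = length(xs) == 0)
    }
  }
  out <- do.call(rbind, long)
  out$marked <- FALSE
  rownames(out) <- NULL
  structure(out, breaks = breaks_list, classes = classes,
            class = c("ebca_cpg", "data.frame"))
}

#' Mark the characteristic cells of a class panel graph
#'
#' A (class, variable, bin) cell is characteristic when its adjusted
#' standardised residual
#' `(O - E) / sqrt(E (1 - row_total/n) (1 - col_total/n))` under class/bin
#' independence exceeds the threshold in absolute value.  Marked cells show
#' *why* a variable separates the classes.
#'
#' @param cpg an `ebca_cpg` from [build_cpg()].
#' @param threshold absolute adjusted-residual threshold (default 2.0).
#' @return The `ebca_cpg` with its `marked` column filled.
#' @export
mark_cells <- function(cpg, threshold = 2.0) {
  stopifnot(inherits(cpg, "ebca_cpg"))
  cpg$marked <- FALSE
  for (v in unique(cpg$variable)) {
    sub <- cpg$variable == v
    tab <- stats::xtabs(count ~ class + bin, data = cpg[sub, ])
    n <- sum(tab)
    if (n == 0) next
    rs <- rowSums(tab); cs <- colSums(tab)
    E <- outer(rs, cs) / n
    denom <- sqrt(E * outer(1 - rs / n, 1 - cs / n))
    R <- (tab - E) / denom
    R[!is.finite(R)] <- 0
    idx <- which(abs(R) > threshold, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      key <- paste(rownames(tab)[idx[, 1]], colnames(tab)[idx[, 2]])
      cellkey <- paste(cpg$class[sub], cpg$bin[sub])
      cpg$marked[sub][cellkey %in% key] <- TRUE
    }
  }
  cpg
}

#' Detect within-class inconsistencies that prompt new rules
#'
#' Two anomaly heuristics per (class, numeric variable):
#' \itemize{
#' \item \strong{bimodality}: the kernel density of the class sample shows
#'   two substantial modes (second peak at least 25% of the first) separated
#'   by a trough no deeper than `trough_ratio` times the smaller peak - the
#'   signature of a class silently merging two populations;
#' \item \strong{variance inflation}: the class variance exceeds
#'   `var_ratio` times the pooled within-class variance of the variable.
#' }
#'
#' @param table an `ebca_table`.
#' @param partition factor over the records.
#' @param trough_ratio bimodality trough threshold (default 0.3).
#' @param var_ratio variance-inflation threshold (default 1.5).
#' @param min_n smallest class sample evaluated (default 10).
#' @return Data frame `class`, `variable`, `anomaly`, `evidence`, sorted by
#'   decreasing evidence; zero rows when nothing is flagged.
#' @export
detect_inconsistencies <- function(table, partition, trough_ratio = 0.3,
                                   var_ratio = 1.5, min_n = 10) {
  partition <- factor(partition)
  out <- list()
  nv <- numeric_vars(table)
  # pooled within-class variance per variable
  pooled <- vapply(nv, function(v) {
    x <- table[[v]]
    num <- 0; den <- 0
    for (cl in levels(partition)) {
      xs <- x[!is.na(x) & partition == cl]
      if (length(xs) >= 2) {
        num <- num + (length(xs) - 1) * stats::var(xs)
        den <- den + (length(xs) - 1)
      }
    }
    if (den > 0) num / den else NA_real_
  }, numeric(1))
  for (v in nv) {
    x <- table[[v]]
    for (cl in levels(partition)) {
      xs <- x[!is.na(x) & partition == cl]
      if (length(xs) < min_n || length(unique(xs)) < 3) next
      # bimodality via kernel density troughs; Sheather-Jones bandwidth
      # (Silverman's rule oversmooths bimodal samples)
      bw <- tryCatch(stats::bw.SJ(xs), error = function(e) stats::bw.nrd0(xs))
      de <- stats::density(xs, bw = bw, n = 256)
      y <- de$y
      loc_max <- which(diff(sign(diff(y))) == -2) + 1
      if (length(loc_max) >= 2) {
        pk <- loc_max[order(y[loc_max], decreasing = TRUE)[1:2]]
        p1 <- min(pk); p2 <- max(pk)
        trough <- min(y[p1:p2])
        small <- min(y[p1], y[p2])
        if (y[p2] >= 0.25 * max(y[p1], y[p2]) && y[p1] >= 0.25 * max(y[p1], y[p2]) &&
            small > 0 && trough / small <= trough_ratio) {
          out[[length(out) + 1]] <- data.frame(
            class = cl, variable = v, anomaly = "bimodality",
            evidence = 1 - trough / small)
        }
      }
      # variance inflation
      if (is.finite(pooled[[v]]) && pooled[[v]] > 0 && length(xs) >= 2) {
        ratio <- stats::var(xs) / pooled[[v]]
        if (ratio > var_ratio)
          out[[length(out) + 1]] <- data.frame(
            class = cl, variable = v, anomaly = "variance inflation",
            evidence = ratio)
      }
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(class = character(), variable = character(),
               anomaly = character(), evidence = numeric())
  res[order(-res$evidence), , drop = FALSE]
}

#' Plot a class panel graph
#'
#' One row per class, one column per variable; each panel shows the
#' class-conditional distribution as a barplot, with characteristic
#' (marked) cells filled dark.
#'
#' @param x an `ebca_cpg`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.ebca_cpg <- function(x, ...) {
  classes <- attr(x, "classes")
  vars <- unique(x$variable)
  op <- graphics::par(mfrow = c(length(classes), length(vars)),
                      mar = c(2.5, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (cl in classes) {
    for (v in vars) {
      cell <- x[x$class == cl & x$variable == v, ]
      graphics::barplot(cell$freq, names.arg = cell$bin, las = 2,
                        cex.names = 0.5, ylim = c(0, 1),
                        col = ifelse(cell$marked, "grey25", "grey80"),
                        main = paste(cl, "/", v), cex.main = 0.8)
    }
  }
  invisible(x)
}

#' Write a class panel graph to CSV (long format)
#'
#' @param cpg an `ebca_cpg`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cpg <- function(cpg, path) {
  utils::write.csv(as.data.frame(cpg), path, row.names = FALSE)
  invisible(path)
}
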