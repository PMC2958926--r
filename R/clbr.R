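# ---------------------------------------------------------------------------
# Clustering Based on Rules: records satisfying a knowledge-base rule are
# condensed into a mass-weighted prototype; prototypes and residual records
# are agglomerated by reciprocal-nearest-neighbour Ward clustering under a
# mixed numeric/categorical dissimilarity; the Calinski-Harabasz index picks
# the cut.  Rule classes therefore land intact in the final partition.
# ---------------------------------------------------------------------------

#' Parameters of the mixed dissimilarity
#'
#' The squared dissimilarity between two entities (records or prototypes) is
#' \deqn{d^2(a,b) = \alpha \frac{1}{n_Q}\sum_k \left(\frac{a_k-b_k}{s_k}\right)^2
#'   + \beta \frac{1}{n_C}\sum_k \delta_k(a,b)}
#' where the numeric sum runs over the quantitative variables (scaled by
#' `s_k`) and `delta_k` is the 0/1 category mismatch for records, or half
#' the L1 distance between category frequency distributions for prototypes.
#' Defaults: `alpha = n_Q/(n_Q+n_C)`, `beta = n_C/(n_Q+n_C)`, `s_k` = the
#' per-variable standard deviation over the table.  Missing cells are
#' handled pairwise-complete: each block averages over the comparable
#' variables only, and if a whole block is incomparable the remaining block
#' is renormalised.
#'
#' @param table an `ebca_table` used to fill defaults.
#' @param alpha,beta nonnegative block weights, `alpha + beta > 0`.
#' @param scale named vector of positive scalings for the numeric variables.
#' @return An `ebca_mixed_params`.
#' @export
mixed_params <- function(table = NULL, alpha = NULL, beta = NULL,
                         scale = NULL) {
  nQ <- nC <- NULL
  if (!is.null(table)) {
    nv <- numeric_vars(table); cv <- categorical_vars(table)
    nQ <- length(nv); nC <- length(cv)
    if (is.null(scale) && nQ > 0) {
      scale <- vapply(nv, function(v)
        stats::sd(table[[v]], na.rm = TRUE), numeric(1))
      scale[!is.finite(scale) | scale == 0] <- 1
    }
    if (is.null(alpha)) alpha <- if (nQ + nC > 0) nQ / (nQ + nC) else 0
    if (is.null(beta)) beta <- if (nQ + nC > 0) nC / (nQ + nC) else 0
  }
  alpha <- alpha %||% 0.5
  beta <- beta %||% 0.5
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("mixed_params: need alpha, beta >= 0 and alpha + beta > 0",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, scale = scale),
            class = "ebca_mixed_params")
}

# --- leaf sets --------------------------------------------------------------
# A leafset holds the entities to cluster in matrix form:
#   num:  L x n_Q matrix of (mean) values, NA = missing
#   cat:  per categorical variable an L x n_categories frequency matrix
#         (records are one-hot rows; a missing cell is an all-NA row)
#   mass: numeric L; ids: character L; members: list of record-id vectors

.leafset_from_table <- function(table) {
  nv <- numeric_vars(table); cv <- categorical_vars(table)
  sp <- table_specs(table)
  L <- nrow(table)
  num <- if (length(nv) > 0)
    as.matrix(.plain_df(table)[nv]) else matrix(0, L, 0)
  cat_m <- lapply(cv, function(v) {
    cats <- sp[[v]]$categories %||% sort(unique(stats::na.omit(table[[v]])))
    m <- matrix(0, L, length(cats), dimnames = list(NULL, cats))
    x <- table[[v]]
    for (j in seq_along(cats)) m[, j] <- as.numeric(x == cats[j])
    m[is.na(x), ] <- NA_real_
    m
  })
  names(cat_m) <- cv
  ids <- table_ids(table)
  list(num = num, cat = cat_m, mass = rep(1, L), ids = ids,
       members = as.list(ids))
}

#' Induce a prototype from a subset of records
#'
#' The prototype carries the missing-aware mean of every numeric variable,
#' the category frequency distribution of every categorical variable, and
#' the subset size as its mass, so that during clustering a rule class of m
#' patients attracts merges like m records would.
#'
#' @param table an `ebca_table`.
#' @param rows logical/integer/character subset of rows (non-empty).
#' @return An `ebca_prototype`: list with `num` (named means), `cat` (named
#'   list of frequency vectors summing to 1), `mass`, `members`.
#' @export
build_prototype <- function(table, rows) {
  df <- .plain_df(table)
  if (is.character(rows)) rows <- match(rows, table_ids(table))
  sub <- df[rows, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("build_prototype: empty record subset", call. = FALSE)
  nv <- numeric_vars(table); cv <- categorical_vars(table)
  sp <- table_specs(table)
  num <- vapply(nv, function(v) {
    x <- sub[[v]]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  cat_f <- lapply(cv, function(v) {
    cats <- sp[[v]]$categories %||% sort(unique(stats::na.omit(table[[v]])))
    x <- stats::na.omit(sub[[v]])
    if (length(x) == 0) return(stats::setNames(rep(NA_real_, length(cats)),
                                               cats))
    f <- vapply(cats, function(cc) mean(x == cc), numeric(1))
    f
  })
  names(cat_f) <- cv
  structure(list(num = num, cat = cat_f, mass = nrow(sub),
                 members = table_ids(table)[rows]),
            class = "ebca_prototype")
}

.leafset_add_prototype <- function(ls, proto, id) {
  num <- if (ncol(ls$num) > 0)
    rbind(ls$num, proto$num[colnames(ls$num)]) else
    rbind(ls$num, matrix(0, 1, 0))
  cat_m <- ls$cat
  for (v in names(cat_m)) {
    f <- proto$cat[[v]]
    cat_m[[v]] <- rbind(cat_m[[v]], f[colnames(cat_m[[v]])])
  }
  list(num = num, cat = cat_m, mass = c(ls$mass, proto$mass),
       ids = c(ls$ids, id), members = c(ls$members, list(proto$members)))
}

# --- mixed dissimilarity ----------------------------------------------------

# squared mixed dissimilarity matrix between the rows of leafset `ls`
# (and optionally a second leafset `ls2`, giving a rectangular matrix)
.mixed_d2 <- function(ls, params, ls2 = NULL) {
  sym <- is.null(ls2)
  if (sym) ls2 <- ls
  L1 <- length(ls$mass); L2 <- length(ls2$mass)
  snum <- matrix(0, L1, L2); cnum <- matrix(0, L1, L2)
  if (ncol(ls$num) > 0) {
    for (k in seq_len(ncol(ls$num))) {
      s <- params$scale[[colnames(ls$num)[k]]] %||% 1
      x <- ls$num[, k] / s; y <- ls2$num[, k] / s
      d <- outer(x, y, `-`)^2
      ok <- !is.na(d)
      d[!ok] <- 0
      snum <- snum + d; cnum <- cnum + ok
    }
  }
  scat <- matrix(0, L1, L2); ccat <- matrix(0, L1, L2)
  for (v in names(ls$cat)) {
    A <- ls$cat[[v]]; B <- ls2$cat[[v]]
    # half-L1 distance between frequency rows
    d <- matrix(0, L1, L2)
    for (j in seq_len(ncol(A)))
      d <- d + abs(outer(A[, j], B[, j], `-`))
    d <- d / 2
    ok <- !is.na(d)
    d[!ok] <- 0
    scat <- scat + d; ccat <- ccat + ok
  }
  wn <- ifelse(cnum > 0, params$alpha, 0)
  wc <- ifelse(ccat > 0, params$beta, 0)
  tot <- wn + wc
  if (any(tot == 0))
    stop("mixed dissimilarity: some pair has no comparable variable",
         call. = FALSE)
  d2 <- (wn * ifelse(cnum > 0, snum / pmax(cnum, 1), 0) +
         wc * ifelse(ccat > 0, scat / pmax(ccat, 1), 0)) *
        (params$alpha + params$beta) / tot
  if (sym) { d2[cbind(seq_len(L1), seq_len(L1))] <- 0 }
  d2
}

#' Mixed dissimilarity between two entities
#'
#' @param a,b one-row data frames / named lists (records) or
#'   `ebca_prototype` objects sharing the variable schema of `table`.
#' @param params an `ebca_mixed_params`.
#' @param table the `ebca_table` declaring the schema.
#' @param squared return the squared dissimilarity (default `TRUE`, the
#'   quantity the Ward cost uses).
#' @return Nonnegative scalar.
#' @export
mixed_distance <- function(a, b, params, table, squared = TRUE) {
  as_leaf <- function(x) {
    if (inherits(x, "ebca_prototype")) {
      ls <- .leafset_from_table(table[0, , drop = FALSE])
      .leafset_add_prototype(ls, x, "p")
    } else {
      df <- .plain_df(as.data.frame(x))[, names(table_specs(table)), drop = FALSE]
      .leafset_from_table(mixed_table(df, table_specs(table), ids = "r"))
    }
  }
  d2 <- .mixed_d2(as_leaf(a), params, as_leaf(b))[1, 1]
  if (squared) d2 else sqrt(d2)
}

# --- reciprocal-nearest-neighbour Ward agglomeration ------------------------

# Ward merge cost between clusters represented in a dissimilarity matrix D
# (entries are already Delta-W costs); Lance-Williams update keeps them so.
.lw_update <- function(D, mass, a, b, active) {
  ma <- mass[a]; mb <- mass[b]
  idx <- active[active != a & active != b]
  if (length(idx) > 0) {
    mc <- mass[idx]
    D[a, idx] <- D[idx, a] <-
      ((ma + mc) * D[a, idx] + (mb + mc) * D[b, idx] - mc * D[a, b]) /
      (ma + mb + mc)
  }
  D
}

#' Reciprocal-nearest-neighbour Ward clustering
#'
#' Leaves (records and/or mass-weighted prototypes) are agglomerated under
#' the mass-weighted Ward cost
#' `DeltaW(A,B) = m_A m_B / (m_A + m_B) * d2(A, B)`, maintained across
#' merges by the Lance-Williams update.  Reciprocal nearest neighbours are
#' merged first; ties break on the lowest leaf index, so the procedure is
#' fully deterministic.  Heights are the Ward merge costs and are
#' nondecreasing after the final height sort (Ward costs are reducible).
#'
#' @param x an `ebca_table` (each record a unit-mass leaf) or a leafset as
#'   built internally by [clbr_cluster()].
#' @param params an `ebca_mixed_params`; defaults to `mixed_params(x)` when
#'   `x` is a table.
#' @return An `ebca_dendrogram`: list with `merge` (hclust convention:
#'   negative entries index leaves), `height`, `labels`, `masses`,
#'   `members`, and the `leafset` used.
#' @export
rnn_ward_cluster <- function(x, params = NULL) {
  ls <- if (inherits(x, "ebca_table")) {
    if (is.null(params)) params <- mixed_params(x)
    .leafset_from_table(x)
  } else x
  if (is.null(params))
    stop("rnn_ward_cluster: params required for a raw leafset", call. = FALSE)
  n <- length(ls$mass)
  if (n < 2)
    stop("rnn_ward_cluster: need at least 2 leaves", call. = FALSE)
  d2 <- .mixed_d2(ls, params)
  mass <- ls$mass
  D <- d2 * outer(mass, mass) / outer(mass, mass, `+`)
  diag(D) <- Inf
  # cluster bookkeeping: index i holds either a leaf or a merged cluster;
  # merged clusters reuse the smaller index slot
  active <- seq_len(n)
  node_of <- -seq_len(n)           # hclust code of the cluster in each slot
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  nn_of <- function(i) {
    cand <- active[active != i]
    cand[which.min(D[i, cand])]
  }
  chain <- integer(0)
  for (step in seq_len(n - 1)) {
    if (length(chain) == 0) chain <- min(active)
    repeat {
      cur <- chain[length(chain)]
      nn <- nn_of(cur)
      if (length(chain) >= 2 && nn == chain[length(chain) - 1]) {
        a <- min(cur, nn); b <- max(cur, nn)
        break
      }
      chain <- c(chain, nn)
    }
    heights[step] <- D[a, b]
    merges[step, ] <- c(node_of[a], node_of[b])
    D <- .lw_update(D, mass, a, b, active)
    mass[a] <- mass[a] + mass[b]
    node_of[a] <- step
    active <- active[active != b]
    D[b, ] <- D[, b] <- Inf
    chain <- chain[seq_len(max(length(chain) - 2, 0))]
    chain <- chain[chain != b]
  }
  # sort merges by height (stable), relabel internal nodes; with reducible
  # Ward costs a child's height never exceeds its parent's, so a stable
  # sort preserves the child-before-parent ordering
  ord <- order(heights)
  relabel <- integer(n - 1)
  relabel[ord] <- seq_len(n - 1)
  merge_sorted <- merges[ord, , drop = FALSE]
  merge_sorted[] <- ifelse(merge_sorted > 0, relabel[pmax(merge_sorted, 1)],
                           merge_sorted)
  structure(list(merge = merge_sorted, height = heights[ord],
                 labels = ls$ids, masses = ls$mass, members = ls$members,
                 leafset = ls, params = params),
            class = "ebca_dendrogram")
}

#' @export
print.ebca_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves (total mass %g), %d merges, height range [%g, %g]\n",
              length(x$labels), sum(x$masses), nrow(x$merge),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a dendrogram into k classes
#'
#' Cutting removes the `k - 1` highest merges.
#'
#' @param dend an `ebca_dendrogram`.
#' @param k number of classes, `1 <= k <=` number of leaves.
#' @return Integer vector of class labels (1..k, numbered by first
#'   appearance in leaf order), named by leaf label.
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n)
    stop("cut_dendrogram: k out of range", call. = FALSE)
  comp <- seq_len(n)             # leaf -> component id
  node_comp <- integer(n - 1)
  find <- function(i) i
  for (s in seq_len(n - k)) {
    l <- dend$merge[s, 1]; r <- dend$merge[s, 2]
    cl <- if (l < 0) comp[-l] else node_comp[l]
    cr <- if (r < 0) comp[-r] else node_comp[r]
    comp[comp == cr] <- cl
    node_comp[node_comp == cr] <- cl
    node_comp[s] <- cl
  }
  # unmerged higher nodes keep their own ids for completeness
  if (n - k + 1 <= n - 1)
    for (s in seq(n - k + 1, n - 1)) {
      l <- dend$merge[s, 1]
      node_comp[s] <- if (l < 0) comp[-l] else node_comp[l]
    }
  stats::setNames(match(comp, unique(comp)), dend$labels)
}

#' Convert to a base-R hclust object
#'
#' @param x an `ebca_dendrogram`.
#' @param ... unused.
#' @return An `hclust` object (heights are Ward merge costs).
#' @export
as.hclust.ebca_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  # leaf order by left-to-right traversal
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) { ord <<- c(ord, -node); return(invisible()) }
    walk(x$merge[node, 1]); walk(x$merge[node, 2])
  }
  walk(n - 1)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "ward-mixed",
                 call = match.call(), dist.method = "mixed"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string
#'
#' Requires the `ape` package; branch lengths derive from merge heights.
#'
#' @param dend an `ebca_dendrogram`.
#' @return Newick character scalar.
#' @export
dendrogram_newick <- function(dend) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("dendrogram_newick requires the 'ape' package", call. = FALSE)
  ph <- ape::as.phylo(as.hclust(dend))
  ape::write.tree(ph)
}

# --- Calinski-Harabasz cut selection ---------------------------------------

# mass-weighted centroid of a set of leaf rows
.centroid_of <- function(ls, rows) {
  w <- ls$mass[rows]
  num <- if (ncol(ls$num) > 0) {
    vapply(seq_len(ncol(ls$num)), function(k) {
      x <- ls$num[rows, k]
      ok <- !is.na(x)
      if (!any(ok)) NA_real_ else sum(w[ok] * x[ok]) / sum(w[ok])
    }, numeric(1))
  } else numeric(0)
  cat_f <- lapply(ls$cat, function(A) {
    M <- A[rows, , drop = FALSE]
    ok <- !is.na(M[, 1])
    if (!any(ok)) rep(NA_real_, ncol(A))
    else colSums(M[ok, , drop = FALSE] * w[ok]) / sum(w[ok])
  })
  list(num = num, cat = cat_f)
}

.centroid_leafset <- function(ls, centroids) {
  num <- do.call(rbind, lapply(centroids, `[[`, "num"))
  if (is.null(num)) num <- matrix(0, length(centroids), 0)
  colnames(num) <- colnames(ls$num)
  cat_m <- lapply(names(ls$cat) %||% character(), function(v)
    do.call(rbind, lapply(centroids, function(cc) cc$cat[[v]]))) |>
    stats::setNames(names(ls$cat))
  for (v in names(cat_m)) colnames(cat_m[[v]]) <- colnames(ls$cat[[v]])
  list(num = num, cat = cat_m, mass = rep(1, length(centroids)),
       ids = paste0("c", seq_along(centroids)),
       members = vector("list", length(centroids)))
}

#' Calinski-Harabasz curve over dendrogram cuts
#'
#' For each `k` the dendrogram is cut into `k` classes and
#' `CH(k) = (B/(k-1)) / (W/(n-k))` is computed, where `B` and `W` are the
#' mass-weighted between/within sums of squared mixed dissimilarities to the
#' class and global centroids and `n` is the total mass.  `W = 0` yields an
#' `Inf` sentinel (that `k` wins).
#'
#' @param dend an `ebca_dendrogram` from [rnn_ward_cluster()].
#' @param kmax largest `k` to score, `2 <= kmax <=` leaves - 1; default
#'   `min(10, leaves - 1)`.
#' @return An `ebca_chcurve`: data frame `k`, `ch` with attribute `k_star`
#'   (smallest maximiser).
#' @export
calinski_cut <- function(dend, kmax = NULL) {
  stopifnot(inherits(dend, "ebca_dendrogram"))
  ls <- dend$leafset
  params <- dend$params
  L <- length(ls$mass)
  kmax <- kmax %||% min(10, L - 1)
  if (kmax < 2 || kmax > L - 1)
    stop("calinski_cut: kmax out of range [2, leaves-1]", call. = FALSE)
  n <- sum(ls$mass)
  glob <- .centroid_of(ls, seq_len(L))
  ch <- vapply(2:kmax, function(k) {
    lab <- cut_dendrogram(dend, k)
    Wk <- 0; Bk <- 0
    cents <- list()
    for (cl in seq_len(k)) {
      rows <- which(lab == cl)
      cents[[cl]] <- .centroid_of(ls, rows)
    }
    cls <- .centroid_leafset(ls, c(cents, list(glob)))
    # distances of each leaf to its class centroid, and of class centroids
    # to the global centroid
    d2 <- .mixed_d2(ls, params, cls)
    dcents <- .mixed_d2(cls, params)
    for (cl in seq_len(k)) {
      rows <- which(lab == cl)
      Wk <- Wk + sum(ls$mass[rows] * d2[rows, cl])
      Mc <- sum(ls$mass[rows])
      Bk <- Bk + Mc * dcents[cl, k + 1]
    }
    if (Wk <= 1e-12) return(Inf)
    (Bk / (k - 1)) / (Wk / (n - k))
  }, numeric(1))
  curve <- data.frame(k = 2:kmax, ch = ch)
  k_star <- curve$k[which.max(curve$ch)]
  structure(curve, k_star = k_star, class = c("ebca_chcurve", "data.frame"))
}

#' @export
print.ebca_chcurve <- function(x, ...) {
  cat("Calinski-Harabasz curve (k* =", attr(x, "k_star"), "):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

# --- the full rule-guided pipeline -----------------------------------------

#' Rule-guided clustering of a mixed table
#'
#' Pipeline: evaluate the knowledge base over the table
#' ([kb_partition()]); condense each non-empty rule class into a
#' mass-weighted prototype ([build_prototype()]); agglomerate the residual
#' records together with the prototypes ([rnn_ward_cluster()]); choose the
#' number of classes by [calinski_cut()] (unless `k` is forced); expand
#' prototypes back to their member records.  Every rule class therefore
#' shares one final class label, so the semantic constraints of the
#' knowledge base survive in the partition.  With an empty knowledge base
#' the result is identical to plain mixed-metric Ward clustering.
#'
#' @param table an `ebca_table`.
#' @param kb an `ebca_kb` in clbr mode (possibly empty).
#' @param params an `ebca_mixed_params`; default `mixed_params(table)`.
#' @param kmax passed to [calinski_cut()].
#' @param k force the number of classes (skips the Calinski selection).
#' @return An `ebca_clbr` list: `partition` (factor over records, with a
#'   `provenance` attribute per class: `"rule-seeded"` or `"data-driven"`),
#'   `dendrogram`, `ch` (the CH curve, `NULL` when `k` forced), `k`,
#'   `rule_groups` (the rule partition).
#' @export
clbr_cluster <- function(table, kb = NULL, params = NULL, kmax = NULL,
                         k = NULL) {
  stopifnot(inherits(table, "ebca_table"))
  if (is.null(kb)) kb <- kb_empty("clbr")
  if (is.null(params)) params <- mixed_params(table)
  rg <- kb_partition(kb, table)
  ids <- table_ids(table)
  rule_ids <- setdiff(levels(rg), "residual")
  resid_rows <- which(rg == "residual")

  ls <- .leafset_from_table(table[resid_rows, , drop = FALSE])
  ls$ids <- ids[resid_rows]
  ls$members <- as.list(ids[resid_rows])
  proto_leaf <- character(0)
  for (rid in rule_ids) {
    rows <- which(rg == rid)
    if (length(rows) == 0) {
      warning("rule '", rid, "' captured no records; skipped", call. = FALSE)
      next
    }
    proto <- build_prototype(table, rows)
    pid <- paste0("<", rid, ">")
    ls <- .leafset_add_prototype(ls, proto, pid)
    proto_leaf <- c(proto_leaf, pid)
  }
  if (length(ls$mass) == 1) {
    # everything condensed into a single leaf (e.g. one rule captured the
    # whole sample): the partition is the single class
    part <- factor(rep(1L, length(ids)), levels = 1L)
    names(part) <- ids
    attr(part, "provenance") <-
      if (length(proto_leaf) > 0) "rule-seeded" else "data-driven"
    return(structure(list(partition = part, dendrogram = NULL, ch = NULL,
                          k = 1L, rule_groups = rg),
                     class = "ebca_clbr"))
  }
  dend <- rnn_ward_cluster(ls, params)
  chc <- NULL
  if (is.null(k)) {
    L <- length(ls$mass)
    km <- min(kmax %||% min(10, L - 1), L - 1)
    if (km < 2) {
      # too few leaves to score cuts (e.g. rules condensed almost
      # everything); keep the leaves as classes
      k <- L
    } else {
      chc <- calinski_cut(dend, km)
      k <- attr(chc, "k_star")
    }
  }
  leaf_lab <- cut_dendrogram(dend, k)
  # expand leaves back to records
  rec_class <- integer(length(ids))
  names(rec_class) <- ids
  for (i in seq_along(dend$labels))
    rec_class[dend$members[[i]]] <- leaf_lab[i]
  provenance <- vapply(seq_len(k), function(cl) {
    if (any(leaf_lab[dend$labels %in% proto_leaf] == cl))
      "rule-seeded" else "data-driven"
  }, character(1))
  part <- factor(rec_class, levels = seq_len(k))
  names(part) <- ids
  attr(part, "provenance") <- provenance
  structure(list(partition = part, dendrogram = dend, ch = chc, k = k,
                 rule_groups = rg),
            class = "ebca_clbr")
}

#' @export
print.ebca_clbr <- function(x, ...) {
  cat(sprintf("Rule-guided clustering: %d classes over %d records\n",
              x$k, length(x$partition)))
  tab <- base::table(x$partition)
  prov <- attr(x$partition, "provenance")
  for (cl in seq_len(x$k))
    cat(sprintf("  class %d: %d record(s) [%s]\n", cl, tab[cl], prov[cl]))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b vectors of equal length (factors or atomic labels).
#' @return The Hubert-Arabie adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- base::table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}
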