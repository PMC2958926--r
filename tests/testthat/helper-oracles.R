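# Independent oracle implementations used to cross-check the engines.
# These deliberately share no code with the package internals.

# --- DEA: brute-force multiplier-form (ratio/dual) solution ----------------
# Input-oriented CCR efficiency of unit k:
#   max u'y_k  s.t.  v'x_k = 1,  u'y_j - v'x_j <= 0  (all j),  u, v >= 0
# solved by enumerating candidate vertices (sets of d active constraints).
oracle_ccr_input <- function(X, Y, k, tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); mi <- ncol(X); mo <- ncol(Y)
  d <- mi + mo
  # constraint rows a'w <= b (the first is an equality)
  A <- rbind(c(X[k, ], rep(0, mo)))                 # v'x_k  = 1
  b <- 1
  for (j in seq_len(n)) { A <- rbind(A, c(-X[j, ], Y[j, ])); b <- c(b, 0) }
  for (i in seq_len(d)) { e <- rep(0, d); e[i] <- -1; A <- rbind(A, e); b <- c(b, 0) }
  nr <- nrow(A)
  best <- -Inf
  combos <- utils::combn(2:nr, d - 1, simplify = FALSE)
  for (cc in combos) {
    act <- c(1, cc)
    M <- A[act, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    w <- tryCatch(solve(M, b[act]), error = function(e) NULL)
    if (is.null(w)) next
    if (any(A %*% w > b + tol)) next                # infeasible vertex
    obj <- sum(w[(mi + 1):d] * Y[k, ])
    if (obj > best) best <- obj
  }
  best
}

# --- Ward: exhaustive greedy agglomeration ---------------------------------
# Plain squared mixed dissimilarity between two records (independent of the
# package's vectorised implementation); pairwise-complete with block
# renormalisation.
oracle_mixed_d2 <- function(ra, rb, kinds, scale, alpha, beta) {
  sq <- 0; nq <- 0; sc <- 0; nc <- 0
  for (v in names(kinds)) {
    a <- ra[[v]]; b <- rb[[v]]
    if (is.na(a) || is.na(b)) next
    if (kinds[[v]] == "numeric") {
      sq <- sq + ((a - b) / scale[[v]])^2; nq <- nq + 1
    } else {
      sc <- sc + as.numeric(a != b); nc <- nc + 1
    }
  }
  wn <- if (nq > 0) alpha else 0
  wc <- if (nc > 0) beta else 0
  stopifnot(wn + wc > 0)
  (wn * (if (nq > 0) sq / nq else 0) + wc * (if (nc > 0) sc / nc else 0)) *
    (alpha + beta) / (wn + wc)
}

# Greedy Ward on an initial squared-dissimilarity matrix with masses:
# always merge the globally cheapest pair (lexicographic tie-break),
# Lance-Williams update.  Returns heights and the member set of each merge.
oracle_greedy_ward <- function(d2, mass, ids) {
  n <- nrow(d2)
  D <- d2 * outer(mass, mass) / outer(mass, mass, `+`)
  diag(D) <- Inf
  members <- as.list(ids)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < bestv - 1e-12) { bestv <- D[i, j]; best <- c(i, j) }
      }
    }
    a <- best[1]; b2 <- best[2]
    heights[s] <- bestv
    others <- setdiff(active, c(a, b2))
    for (o in others) {
      D[a, o] <- D[o, a] <-
        ((mass[a] + mass[o]) * D[a, o] + (mass[b2] + mass[o]) * D[b2, o] -
         mass[o] * D[a, b2]) / (mass[a] + mass[b2] + mass[o])
    }
    mass[a] <- mass[a] + mass[b2]
    members[[a]] <- sort(c(members[[a]], members[[b2]]))
    merged_sets[[s]] <- members[[a]]
    active <- setdiff(active, b2)
    D[b2, ] <- D[, b2] <- Inf
  }
  list(heights = heights, sets = merged_sets)
}

# member sets of each merge of an ebca_dendrogram, in merge order
dendro_merge_sets <- function(dend) {
  n <- length(dend$labels)
  node_members <- vector("list", n - 1)
  get_m <- function(code) {
    if (code < 0) dend$members[[-code]] else node_members[[code]]
  }
  for (s in seq_len(n - 1)) {
    node_members[[s]] <- sort(unlist(c(get_m(dend$merge[s, 1]),
                                       get_m(dend$merge[s, 2]))))
  }
  node_members
}

# --- random fixtures --------------------------------------------------------

random_mixed_table <- function(n, nQ = 2, nC = 1, seed = 1, missing_rate = 0,
                               n_cats = 3) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(stats::rnorm(n * nQ), n, nQ))
    names(df) <- paste0("q", seq_len(nQ))
    specs <- lapply(names(df), function(v) variable_spec(v, "numeric"))
    if (nC > 0) {
      for (ci in seq_len(nC)) {
        cats <- paste0("lv", seq_len(n_cats))
        df[[paste0("c", ci)]] <- sample(cats, n, replace = TRUE)
        specs[[length(specs) + 1]] <-
          variable_spec(paste0("c", ci), "categorical", categories = cats)
      }
    }
    if (missing_rate > 0) {
      for (j in seq_along(df))
        df[stats::runif(n) < missing_rate, j] <- NA
    }
    mixed_table(df, specs, ids = sprintf("r%03d", seq_len(n)))
  })
}

# a random knowledge base whose rules reference the table's variables
random_kb <- function(table, n_rules = 2, seed = 1) {
  sp <- table_specs(table)
  withr::with_seed(seed, {
    lines <- character()
    for (r in seq_len(n_rules)) {
      conds <- character()
      for (ci in seq_len(sample(1:2, 1))) {
        v <- sample(names(sp), 1)
        if (sp[[v]]$kind == "numeric") {
          thr <- round(stats::quantile(table[[v]],
                                       stats::runif(1, 0.2, 0.8),
                                       na.rm = TRUE, names = FALSE), 3)
          op <- sample(c("<", "<=", ">", ">="), 1)
          conds <- c(conds, sprintf("(%s %s %s)", v, op, thr))
        } else {
          cats <- sp[[v]]$categories
          conds <- c(conds, sprintf("(%s = %s)", v, sample(cats, 1)))
        }
      }
      conn <- sample(c(" and ", " or "), 1)
      lines <- c(lines, sprintf("k%d: if (%s) then class-%d", r,
                                paste(conds, collapse = conn), r))
    }
    kb_parse(lines, sp, mode = "clbr")
  })
}

# label-permutation equality of two partitions
same_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  length(unique(a)) == length(unique(b)) &&
    all(stats::ave(b, a, FUN = function(x) length(unique(x))) == 1) &&
    all(stats::ave(a, b, FUN = function(x) length(unique(x))) == 1)
}
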