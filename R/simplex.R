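# ---------------------------------------------------------------------------
# Small dense two-phase simplex with Bland's anti-cycling rule.  The DEA
# envelopment programmes are tiny (tens of variables) but heavily
# degenerate (zero right-hand sides), which makes textbook pivoting rules
# cycle; Bland's rule guarantees termination.
# ---------------------------------------------------------------------------

# Solve: min c'x  s.t.  A x {<=,>=,=} b, x >= 0.
# `ctype` is a character vector of "<=", ">=", "=" per row.
# Returns list(value, x, status) with status "optimal", "infeasible" or
# "unbounded".
.lp_solve <- function(cvec, A, b, ctype, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(ctype) == m, length(cvec) == n)
  if (maximize) cvec <- -cvec
  # normalise to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    ctype[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[ctype[neg]]
  }
  # row equilibration: badly scaled rows make Bland pivots chase numerical
  # dust; scaling each row to unit max-abs keeps reduced costs O(1)
  rs <- pmax(apply(abs(A), 1, max), b, 1e-12)
  A <- A / rs
  b <- b / rs
  n_slack <- sum(ctype != "=")
  n_art <- sum(ctype != "<=")
  N <- n + n_slack + n_art
  T_ <- matrix(0, m, N + 1)
  T_[, seq_len(n)] <- A
  T_[, N + 1] <- b
  basis <- integer(m)
  js <- n; ja <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (ctype[i] == "<=") {
      js <- js + 1; T_[i, js] <- 1; basis[i] <- js
    } else if (ctype[i] == ">=") {
      js <- js + 1; T_[i, js] <- -1
      ja <- ja + 1; T_[i, ja] <- 1; basis[i] <- ja
      art_cols <- c(art_cols, ja)
    } else {
      ja <- ja + 1; T_[i, ja] <- 1; basis[i] <- ja
      art_cols <- c(art_cols, ja)
    }
  }
  is_art <- rep(FALSE, N); is_art[art_cols] <- TRUE

  # reduced-cost rows for both phases, updated through the same pivots
  c1 <- c(rep(0, N), 0); c1[art_cols] <- 1
  c2 <- c(cvec, rep(0, N - n), 0)
  for (i in seq_len(m)) {
    if (c1[basis[i]] != 0) c1 <- c1 - c1[basis[i]] * c(T_[i, ])
    if (c2[basis[i]] != 0) c2 <- c2 - c2[basis[i]] * c(T_[i, ])
  }

  pivot <- function(r, j) {
    T_[r, ] <<- T_[r, ] / T_[r, j]
    for (i in seq_len(m)) if (i != r && abs(T_[i, j]) > 0)
      T_[i, ] <<- T_[i, ] - T_[i, j] * T_[r, ]
    if (abs(c1[j]) > 0) c1 <<- c1 - c1[j] * T_[r, ]
    if (abs(c2[j]) > 0) c2 <<- c2 - c2[j] * T_[r, ]
    basis[r] <<- j
  }

  run_phase <- function(crow_get, allowed) {
    repeat {
      crow <- crow_get()
      enter <- which(allowed & crow[seq_len(N)] < -tol)
      if (length(enter) == 0) return("optimal")
      j <- enter[1]                              # Bland: smallest index
      col <- T_[, j]
      rows <- which(col > tol)
      if (length(rows) == 0) return("unbounded")
      ratio <- T_[rows, N + 1] / col[rows]
      rmin <- min(ratio)
      cand <- rows[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]          # Bland: smallest basic index
      pivot(r, j)
    }
  }

  # phase 1
  if (n_art > 0) {
    st <- run_phase(function() c1, allowed = rep(TRUE, N))
    if (st == "unbounded" || -c1[N + 1] > 1e-7 * (1 + max(abs(b))))
      return(list(value = NA_real_, x = NULL, status = "infeasible"))
    # drive remaining artificials out of the basis where possible
    for (i in seq_len(m)) {
      if (is_art[basis[i]]) {
        j <- which(!is_art[seq_len(N)] & abs(T_[i, seq_len(N)]) > tol)
        if (length(j) > 0) pivot(i, j[1])
      }
    }
  }
  # phase 2 (artificial columns barred from entering)
  st <- run_phase(function() c2, allowed = !is_art)
  if (st == "unbounded")
    return(list(value = if (maximize) Inf else -Inf, x = NULL,
                status = "unbounded"))
  x <- numeric(n)
  for (i in seq_len(m)) if (basis[i] <= n) x[basis[i]] <- T_[i, N + 1]
  value <- sum(cvec * x)
  list(value = if (maximize) -value else value, x = x, status = "optimal")
}
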