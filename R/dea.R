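# ---------------------------------------------------------------------------
# Monte-Carlo, knowledge-guided Data Envelopment Analysis.  Each simulation
# run draws input/output values from expert-elicited distributions, applies
# the monotone-decreasing transform to non-standard variables, and solves
# one envelopment-form linear programme per decision-making unit (DMU).
# Scores are pooled across runs until the block means stabilise.
# ---------------------------------------------------------------------------

#' Construct and validate a DEA instance
#'
#' @param inputs numeric matrix (units x input variables), strictly positive.
#' @param outputs numeric matrix (units x output variables), strictly
#'   positive.
#' @return An `ebca_dea_instance`.
#' @export
dea_instance <- function(inputs, outputs) {
  inputs <- as.matrix(inputs); outputs <- as.matrix(outputs)
  if (nrow(inputs) != nrow(outputs))
    stop("dea_instance: inputs and outputs must cover the same units",
         call. = FALSE)
  if (nrow(inputs) < 2)
    stop("dea_instance: at least 2 units required", call. = FALSE)
  if (ncol(inputs) < 1 || ncol(outputs) < 1)
    stop("dea_instance: at least one input and one output required",
         call. = FALSE)
  if (any(!is.finite(inputs)) || any(!is.finite(outputs)) ||
      any(inputs <= 0) || any(outputs <= 0))
    stop("dea_instance: all cells must be finite and strictly positive",
         call. = FALSE)
  if (is.null(rownames(inputs)))
    rownames(inputs) <- rownames(outputs) <- paste0("u", seq_len(nrow(inputs)))
  structure(list(inputs = inputs, outputs = outputs,
                 units = rownames(inputs)),
            class = "ebca_dea_instance")
}

#' DEA model configuration
#'
#' @param orientation `"input"` (contract inputs at given outputs) or
#'   `"output"` (expand outputs at given inputs; scores are reported as
#'   `1/phi` so both orientations live on the same `(0, 1]` scale).
#' @param rts returns to scale: `"constant"` or `"variable"` (adds the
#'   convexity constraint `sum(lambda) = 1`).
#' @param epsilon efficiency tolerance in `(0, 0.05]`: a score `>= 1 -
#'   epsilon` counts as efficient in pooling and tier classification.
#' @return An `ebca_dea_config`.
#' @export
dea_config <- function(orientation = c("input", "output"),
                       rts = c("constant", "variable"),
                       epsilon = 0.01) {
  orientation <- match.arg(orientation)
  rts <- match.arg(rts)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 0.05)
    stop("dea_config: epsilon must lie in (0, 0.05]", call. = FALSE)
  structure(list(orientation = orientation, rts = rts, epsilon = epsilon),
            class = "ebca_dea_config")
}

#' Linear monotone-decreasing transform for non-standard variables
#'
#' A non-standard input/output is reflected as `x' = (max(x) + margin) - x`
#' with `margin = margin_frac * range(x)`, so the transformed column stays
#' strictly positive and its rank order is exactly reversed.  A constant
#' column (zero range) maps to the positive floor constant.
#'
#' @param x strictly positive numeric vector (one column, one simulation
#'   run).
#' @param margin_frac margin as a fraction of the column range (default
#'   0.1).
#' @param floor positive constant used when the column range is zero.
#' @return Transformed vector, strictly positive.
#' @export
transform_nonstandard <- function(x, margin_frac = 0.1, floor = 1e-3) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("transform_nonstandard: column must be strictly positive",
         call. = FALSE)
  rg <- max(x) - min(x)
  margin <- if (rg > 0) margin_frac * rg else floor
  max(x) + margin - x
}

# envelopment LP for one target unit; returns the raw optimum
.dea_lp <- function(X, Y, k, orientation, rts) {
  n <- nrow(X); mi <- ncol(X); mo <- ncol(Y)
  if (orientation == "input") {
    # min theta  s.t.  X'lambda <= theta x_k ; Y'lambda >= y_k ; lambda >= 0
    a <- c(1, rep(0, n))
    A1 <- cbind(-X[k, ], t(X))
    b1 <- rep(0, mi)
    A2 <- cbind(0, t(Y))
    b2 <- Y[k, ]
    maxi <- FALSE
  } else {
    # max phi  s.t.  X'lambda <= x_k ; Y'lambda >= phi y_k ; lambda >= 0
    a <- c(1, rep(0, n))
    A1 <- cbind(0, t(X))
    b1 <- X[k, ]
    A2 <- cbind(-Y[k, ], t(Y))
    b2 <- rep(0, mo)
    maxi <- TRUE
  }
  A <- rbind(A1, A2)
  b <- c(b1, b2)
  ctype <- c(rep("<=", length(b1)), rep(">=", length(b2)))
  if (rts == "variable") {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    ctype <- c(ctype, "=")
  }
  # the envelopment programme is always feasible (lambda = e_k), so an
  # "infeasible" verdict is numerical; escalate the pivot tolerance
  for (tol in c(1e-9, 1e-8, 1e-7)) {
    s <- .lp_solve(a, A, b, ctype, maximize = maxi, tol = tol)
    if (s$status == "optimal") break
  }
  if (s$status != "optimal")
    stop("solve_dea: internal error, LP ", s$status, " for unit ", k,
         call. = FALSE)
  s$value
}

#' Solve the DEA envelopment programme for one unit
#'
#' Input orientation minimises the radial input contraction `theta`; output
#' orientation maximises the radial output expansion `phi` and reports
#' `1/phi`.  Either way the score lies in `(0, 1]` (clamped against solver
#' round-off at tolerance 1e-7).
#'
#' @param instance an `ebca_dea_instance`.
#' @param config an `ebca_dea_config`.
#' @param target unit id or index.
#' @return Efficiency score in `(0, 1]`.
#' @export
solve_dea <- function(instance, config = dea_config(), target) {
  stopifnot(inherits(instance, "ebca_dea_instance"))
  k <- if (is.character(target)) match(target, instance$units) else target
  if (is.na(k) || k < 1 || k > length(instance$units))
    stop("solve_dea: unknown target unit", call. = FALSE)
  v <- .dea_lp(instance$inputs, instance$outputs, k,
               config$orientation, config$rts)
  score <- if (config$orientation == "input") v else 1 / v
  min(max(score, .Machine$double.eps), 1)
}

#' Solve the DEA programme for every unit
#'
#' @inheritParams solve_dea
#' @return Named numeric vector of scores.
#' @export
solve_dea_all <- function(instance, config = dea_config()) {
  stats::setNames(
    vapply(seq_along(instance$units),
           function(k) solve_dea(instance, config, k), numeric(1)),
    instance$units)
}

#' Define an input/output scenario
#'
#' @param id scenario identifier.
#' @param inputs,outputs disjoint, non-empty character vectors of variable
#'   names.
#' @param provenance `"expert"` or `"automatic"`.
#' @return An `ebca_scenario`.
#' @export
scenario <- function(id, inputs, outputs,
                     provenance = c("expert", "automatic")) {
  provenance <- match.arg(provenance)
  if (length(inputs) < 1 || length(outputs) < 1)
    stop("scenario: inputs and outputs must be non-empty", call. = FALSE)
  if (length(intersect(inputs, outputs)) > 0)
    stop("scenario: inputs and outputs must be disjoint", call. = FALSE)
  structure(list(id = id, inputs = inputs, outputs = outputs,
                 provenance = provenance),
            class = "ebca_scenario")
}

#' Monte-Carlo control parameters
#'
#' Convergence is declared when the maximum over DMUs of the change in the
#' cumulative mean score between consecutive blocks drops below `tolerance`
#' (at least two blocks are always run).
#'
#' @param block_size runs per convergence block (default 500).
#' @param tolerance block-mean stability tolerance (default 0.005).
#' @param max_runs hard cap on total runs (default 20000).
#' @param max_resample cap on rejection-resampling of runs that produce a
#'   non-positive cell (only possible with user-supplied distributions).
#' @return A list of control parameters.
#' @export
mc_control <- function(block_size = 500, tolerance = 0.005,
                       max_runs = 20000, max_resample = 100) {
  stopifnot(block_size >= 1, tolerance > 0, max_runs >= 2 * block_size)
  list(block_size = as.integer(block_size), tolerance = tolerance,
       max_runs = as.integer(max_runs),
       max_resample = as.integer(max_resample))
}

#' Run the Monte-Carlo DEA engine
#'
#' Per run: draw every cell from the stochastic spec, apply the
#' monotone-decreasing transform to variables annotated non-standard, solve
#' the envelopment programme for every DMU, and append the scores to the
#' pool.  The engine stops when the cumulative per-DMU means stabilise
#' across blocks or at the run cap.  Fully reproducible given `seed`.
#'
#' @param spec an `ebca_stospec` covering the scenario's variables for every
#'   unit.
#' @param annotations named list from [read_io_annotations()]; variables
#'   absent from it default to standard orientation with the role implied by
#'   the scenario.
#' @param config an `ebca_dea_config`.
#' @param scen an `ebca_scenario`.
#' @param seed integer RNG seed.
#' @param control see [mc_control()].
#' @return An `ebca_pool`: list with `scores` (runs x units), `runs`,
#'   `converged`, `trace` (per-block cumulative means), `n_resampled`,
#'   `seed`, `config`, `scenario`.
#' @export
run_monte_carlo <- function(spec, annotations = list(), config = dea_config(),
                            scen, seed, control = mc_control()) {
  stopifnot(inherits(spec, "ebca_stospec"), inherits(scen, "ebca_scenario"))
  units <- attr(spec, "units")
  vars <- c(scen$inputs, scen$outputs)
  missing_vars <- setdiff(vars, attr(spec, "variables"))
  if (length(missing_vars) > 0)
    stop("run_monte_carlo: stochastic spec does not cover variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  nonstd <- vars[vapply(vars, function(v) {
    a <- annotations[[v]]
    !is.null(a) && a$orientation == "non-standard"
  }, logical(1))]

  withr::with_seed(seed, {
    nmax <- control$max_runs
    scores <- matrix(NA_real_, nmax, length(units),
                     dimnames = list(NULL, units))
    trace <- NULL
    prev_mean <- NULL
    n_resampled <- 0L
    run <- 0L
    converged <- FALSE
    repeat {
      for (b in seq_len(control$block_size)) {
        run <- run + 1L
        # rejection-resample runs with non-positive sampled cells
        tries <- 0L
        repeat {
          m <- sample_spec(spec)[, vars, drop = FALSE]
          if (all(m > 0)) break
          tries <- tries + 1L; n_resampled <- n_resampled + 1L
          if (tries > control$max_resample)
            stop("run_monte_carlo: persistent non-positive samples; ",
                 "check the stochastic spec", call. = FALSE)
        }
        for (v in nonstd) {
          a <- annotations[[v]]
          m[, v] <- transform_nonstandard(m[, v], a$margin %||% 0.1)
        }
        inst <- dea_instance(m[, scen$inputs, drop = FALSE],
                             m[, scen$outputs, drop = FALSE])
        scores[run, ] <- solve_dea_all(inst, config)
        if (run >= nmax) break
      }
      cur_mean <- colMeans(scores[seq_len(run), , drop = FALSE])
      trace <- rbind(trace, c(runs = run, cur_mean))
      if (!is.null(prev_mean) &&
          max(abs(cur_mean - prev_mean)) < control$tolerance) {
        converged <- TRUE
        break
      }
      if (run >= nmax) break
      prev_mean <- cur_mean
    }
    if (n_resampled > 0)
      warning("run_monte_carlo: ", n_resampled,
              " non-positive sample(s) rejected and redrawn", call. = FALSE)
    structure(list(scores = scores[seq_len(run), , drop = FALSE],
                   runs = run, converged = converged, trace = trace,
                   n_resampled = n_resampled, seed = seed, config = config,
                   scenario = scen, control = control),
              class = "ebca_pool")
  })
}

#' Summarise an efficiency pool
#'
#' @param pool an `ebca_pool`.
#' @return Data frame per DMU: `unit`, `mean`, `sd`, `frac_efficient`
#'   (fraction of runs with score `>= 1 - epsilon`).
#' @export
pool_summary <- function(pool) {
  stopifnot(inherits(pool, "ebca_pool"))
  eps <- pool$config$epsilon
  data.frame(unit = colnames(pool$scores),
             mean = colMeans(pool$scores),
             sd = apply(pool$scores, 2, stats::sd),
             frac_efficient = colMeans(pool$scores >= 1 - eps),
             row.names = NULL)
}

#' @export
print.ebca_pool <- function(x, ...) {
  cat(sprintf("Monte-Carlo DEA pool: %d run(s), %d DMU(s), %s (seed %s)\n",
              x$runs, ncol(x$scores),
              if (x$converged) "converged" else "run cap reached",
              format(x$seed)))
  print(pool_summary(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tier thresholds for classifying pooled efficiency scores
#'
#' Defaults: a DMU is `efficient` when its pooled mean score is at least
#' `efficient_mean` *and* it attains the frontier (score `>= 1 - epsilon`)
#' in at least `efficient_frac` of the runs; `nearly-efficient` when the
#' mean is at least `nearly_mean`; `uncertain` at `uncertain_mean`; else
#' `inefficient`.  The binary collapse groups efficient + nearly-efficient
#' against the rest.
#'
#' @param efficient_mean,efficient_frac,nearly_mean,uncertain_mean numeric
#'   thresholds.
#' @return A list of thresholds.
#' @export
tier_thresholds <- function(efficient_mean = 0.95, efficient_frac = 0.5,
                            nearly_mean = 0.90, uncertain_mean = 0.75) {
  list(efficient_mean = efficient_mean, efficient_frac = efficient_frac,
       nearly_mean = nearly_mean, uncertain_mean = uncertain_mean)
}

#' Classify pooled DMU scores into efficiency tiers
#'
#' @param pool an `ebca_pool` (a pool that hit the run cap without
#'   converging is still classified, with a warning).
#' @param thresholds see [tier_thresholds()].
#' @return An `ebca_tiers` data frame: `unit`, `mean`, `frac_efficient`,
#'   `tier` (`efficient`, `nearly-efficient`, `uncertain`, `inefficient`)
#'   and `group` (`efficient-group` iff tier is efficient or
#'   nearly-efficient).
#' @export
classify_tiers <- function(pool, thresholds = tier_thresholds()) {
  stopifnot(inherits(pool, "ebca_pool"))
  if (nrow(pool$scores) == 0)
    stop("classify_tiers: empty pool", call. = FALSE)
  if (!pool$converged)
    warning("classify_tiers: pool did not converge (run cap reached)",
            call. = FALSE)
  s <- pool_summary(pool)
  tier <- with(thresholds, ifelse(
    s$mean >= efficient_mean & s$frac_efficient >= efficient_frac,
    "efficient",
    ifelse(s$mean >= nearly_mean, "nearly-efficient",
           ifelse(s$mean >= uncertain_mean, "uncertain", "inefficient"))))
  group <- ifelse(tier %in% c("efficient", "nearly-efficient"),
                  "efficient-group", "inefficient-group")
  structure(data.frame(unit = s$unit, mean = s$mean,
                       frac_efficient = s$frac_efficient,
                       tier = tier, group = group, row.names = NULL),
            thresholds = thresholds, class = c("ebca_tiers", "data.frame"))
}

#' Enumerate input/output scenarios
#'
#' Expert mode returns the supplied combinations verbatim.  Automatic mode
#' enumerates all non-empty input and output subsets up to the size limits
#' (in deterministic lexicographic order) and prunes any scenario whose
#' variable set contains a pair flagged by the redundancy report.
#'
#' @param specs list of [variable_spec()] with DEA roles assigned.
#' @param mode `"expert"` or `"automatic"`.
#' @param expert list of `list(inputs =, outputs =)` combinations (expert
#'   mode).
#' @param correlation data frame with columns `var1`, `var2` (e.g. from
#'   [redundancy_report()]); pairs listed there never co-occur in a
#'   scenario.
#' @param max_inputs,max_outputs subset size limits (automatic mode).
#' @return List of `ebca_scenario` objects.
#' @export
enumerate_scenarios <- function(specs, mode = c("expert", "automatic"),
                                expert = list(), correlation = NULL,
                                max_inputs = 2, max_outputs = 2) {
  mode <- match.arg(mode)
  roles <- vapply(specs, `[[`, character(1), "role")
  nms <- vapply(specs, `[[`, character(1), "name")
  in_vars <- nms[roles == "dea-input"]
  out_vars <- nms[roles == "dea-output"]
  if (length(in_vars) < 1 || length(out_vars) < 1)
    stop("enumerate_scenarios: need at least one dea-input and one ",
         "dea-output variable", call. = FALSE)
  if (mode == "expert") {
    return(lapply(seq_along(expert), function(i)
      scenario(paste0("S", i), expert[[i]]$inputs, expert[[i]]$outputs,
               provenance = "expert")))
  }
  subsets <- function(v, kmax) {
    out <- list()
    for (k in seq_len(min(kmax, length(v))))
      out <- c(out, utils::combn(v, k, simplify = FALSE))
    out
  }
  bad_pair <- function(vars) {
    if (is.null(correlation) || nrow(correlation) == 0) return(FALSE)
    any(correlation$var1 %in% vars & correlation$var2 %in% vars)
  }
  res <- list(); i <- 0
  for (ins in subsets(in_vars, max_inputs))
    for (outs in subsets(out_vars, max_outputs)) {
      if (bad_pair(c(ins, outs))) next
      i <- i + 1
      res[[i]] <- scenario(paste0("A", i), ins, outs,
                           provenance = "automatic")
    }
  if (length(res) == 0)
    stop("enumerate_scenarios: every combination was pruned; consider ",
         "raising the redundancy threshold", call. = FALSE)
  res
}
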