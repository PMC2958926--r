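# ---------------------------------------------------------------------------
# Synthetic-data generators emulating the two application settings: (a)
# small-health-area input/output tables with uniform-bounded stochastic
# structure seeded from the expert-driven community-care model, and (b)
# patient tables with planted mixed-type cluster structure on which the
# shipped example rules fire verbatim.  All generators are pure functions
# of (config, seed).
# ---------------------------------------------------------------------------

#' Expert-driven community-care model bounds
#'
#' Reads the shipped fixture encoding the expected ranges (rates per
#' 100,000 population) of the twelve service availability/utilisation
#' variables of the basic community mental-health-care model: types (T),
#' places (P) and utilisation (U) of acute care (R2), non-acute hospital
#' care (R4-R7), residential community care (R8-R13) and day care (D1+D4).
#' Availability variables carry the DEA input role, utilisation variables
#' the output role.  Utilisation weights are stored as metadata and unused
#' by the engines.
#'
#' @return Data frame: `variable`, `kind`, `role`, `lower`, `upper`,
#'   `weight_lo`, `weight_hi`, `group`, `description`.
#' @export
bmhcc_bounds <- function() {
  path <- system.file("extdata", "bmhcc_table1.csv", package = "ebca")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Small-health-area generator configuration
#'
#' @param n_units number of areas (default 12, the benchmark-study size).
#' @param bounds data frame like [bmhcc_bounds()] giving per-variable
#'   uniform bounds and roles.
#' @param inefficient_units character/integer subset of units whose inputs
#'   are inflated (default: the last third of the units).
#' @param input_scale input-scaling factor `>= 1` applied to inefficient
#'   units (default 1.5).
#' @param halfwidth_frac relative half-width of the uniform distribution
#'   attached to each sampled central value (default 0.1; 0 gives
#'   point-mass specs).
#' @return A list of class `ebca_sha_config`.
#' @export
sha_config <- function(n_units = 12, bounds = bmhcc_bounds(),
                       inefficient_units = NULL, input_scale = 1.5,
                       halfwidth_frac = 0.1) {
  stopifnot(n_units >= 2, input_scale >= 1, halfwidth_frac >= 0,
            halfwidth_frac < 1)
  if (any(bounds$upper < bounds$lower))
    stop("sha_config: bounds out of order", call. = FALSE)
  if (is.null(inefficient_units))
    inefficient_units <- seq_len(n_units) > ceiling(2 * n_units / 3)
  structure(list(n_units = n_units, bounds = bounds,
                 inefficient_units = inefficient_units,
                 input_scale = input_scale,
                 halfwidth_frac = halfwidth_frac),
            class = "ebca_sha_config")
}

#' Generate a synthetic small-health-area benchmarking problem
#'
#' Each unit's central value for each variable is drawn uniformly within
#' the expert bounds; units on the inefficiency plan then have all their
#' input variables multiplied by `input_scale`, making them radially
#' dominated.  The emitted stochastic spec attaches a uniform distribution
#' of relative half-width `halfwidth_frac` around each central value
#' (degenerating to point masses at width zero).
#'
#' @param config an `ebca_sha_config`.
#' @param seed integer RNG seed.
#' @return List: `table` (an `ebca_table` of central values), `spec` (an
#'   `ebca_stospec`), `truth` (logical vector, `TRUE` = inefficient by
#'   construction).
#' @export
generate_sha <- function(config = sha_config(), seed = 1) {
  stopifnot(inherits(config, "ebca_sha_config"))
  b <- config$bounds
  n <- config$n_units
  units <- sprintf("area%02d", seq_len(n))
  ineff <- rep(FALSE, n)
  iu <- config$inefficient_units
  if (is.logical(iu)) ineff[iu[seq_len(n)]] <- TRUE
  else if (is.numeric(iu)) ineff[iu] <- TRUE
  else ineff[match(iu, units)] <- TRUE
  withr::with_seed(seed, {
    m <- sapply(seq_len(nrow(b)), function(j)
      stats::runif(n, b$lower[j], b$upper[j]))
    colnames(m) <- b$variable
    is_input <- b$role == "dea-input"
    m[ineff, is_input] <- m[ineff, is_input] * config$input_scale
    if (any(m <= 0))
      stop("generate_sha: non-positive cell generated; check bounds/scale",
           call. = FALSE)
    specs <- lapply(seq_len(nrow(b)), function(j)
      variable_spec(b$variable[j], "numeric", b$role[j],
                    units = "rate per 100k",
                    weight = if (is.na(b$weight_lo[j])) 1
                             else mean(c(b$weight_lo[j], b$weight_hi[j]))))
    tab <- mixed_table(as.data.frame(m), specs, ids = units)
    hw <- config$halfwidth_frac
    entries <- lapply(seq_len(n), function(i) {
      row <- lapply(seq_len(nrow(b)), function(j) {
        v <- m[i, j]
        if (hw == 0) list(dist = "point-mass", v = v)
        else list(dist = "uniform", a = v * (1 - hw), b = v * (1 + hw))
      })
      stats::setNames(row, b$variable)
    })
    names(entries) <- units
    spec <- stochastic_spec(entries = entries, units = units,
                            variables = b$variable)
    list(table = tab, spec = spec, truth = stats::setNames(ineff, units))
  })
}

#' Patient generator configuration
#'
#' Defaults emulate a case-mix study of about three hundred patients with
#' schizophrenia described by global functioning (GAF clinical and social
#' scores), objective family burden (hours of support in daily activities,
#' frequency of behavioural problems) and employment status, with three
#' planted severity profiles: severely ill, intermediate, autonomous.
#' The numeric cluster means of adjacent profiles are `separation` pooled
#' standard deviations apart, and the per-cluster category distributions
#' are pairwise at least 0.6 apart in total variation, so the example
#' rules (low functioning + daily behavioural burden -> severely ill;
#' working + high functioning -> good condition) fire on the intended
#' profiles.
#'
#' @param n number of patients (default 306).
#' @param k number of planted profiles (default 3; must divide the default
#'   mean/probability layouts, i.e. `k <= 3` unless all layouts are
#'   supplied).
#' @param separation adjacent-cluster numeric separation in within-cluster
#'   standard deviations (default 6).
#' @param mixing mixing proportions (default equal).
#' @param missing_rate completely-at-random per-cell missingness in
#'   `[0, 1)` (default 0).
#' @param num_means,num_sds optional k x 3 matrices (columns GAFCLA,
#'   GAFSOCIAL, MAXECFOS_A) overriding the built-in layout.
#' @param cat_probs optional list of k-row probability matrices for
#'   MAXECFOS_B (Never, Some_Days, Every_Day) and INGRESE (WORK, PENSION,
#'   UNEMPLOYED).
#' @param seed integer RNG seed.
#' @return A list of class `ebca_patient_config`.
#' @export
patient_config <- function(n = 306, k = 3, separation = 6, mixing = NULL,
                           missing_rate = 0, num_means = NULL,
                           num_sds = NULL, cat_probs = NULL, seed = 1) {
  stopifnot(n >= 2, k >= 1, missing_rate >= 0, missing_rate < 1)
  mixing <- mixing %||% rep(1 / k, k)
  if (length(mixing) != k || abs(sum(mixing) - 1) > 1e-8)
    stop("patient_config: mixing proportions must sum to 1", call. = FALSE)
  if (k * 2 > n)
    stop("patient_config: n too small for k clusters", call. = FALSE)
  if (is.null(num_sds)) num_sds <- matrix(c(5, 5, 2), k, 3, byrow = TRUE)
  if (is.null(num_means)) {
    if (k > 3) stop("patient_config: supply num_means for k > 3",
                    call. = FALSE)
    i <- seq_len(k)
    num_means <- cbind(GAFCLA = 25 + (i - 1) * separation * 5,
                       GAFSOCIAL = 25 + (i - 1) * separation * 5,
                       MAXECFOS_A = 10 + (k - i) * separation * 2)
  }
  colnames(num_means) <- colnames(num_sds) <-
    c("GAFCLA", "GAFSOCIAL", "MAXECFOS_A")
  if (is.null(cat_probs)) {
    if (k > 3) stop("patient_config: supply cat_probs for k > 3",
                    call. = FALSE)
    full_b <- matrix(c(0.02, 0.08, 0.90,
                       0.10, 0.80, 0.10,
                       0.90, 0.08, 0.02), 3, 3, byrow = TRUE)
    full_i <- matrix(c(0.02, 0.93, 0.05,
                       0.10, 0.10, 0.80,
                       0.93, 0.02, 0.05), 3, 3, byrow = TRUE)
    cat_probs <- list(MAXECFOS_B = full_b[seq_len(k), , drop = FALSE],
                      INGRESE = full_i[seq_len(k), , drop = FALSE])
  }
  colnames(cat_probs$MAXECFOS_B) <- c("Never", "Some_Days", "Every_Day")
  colnames(cat_probs$INGRESE) <- c("WORK", "PENSION", "UNEMPLOYED")
  structure(list(n = n, k = k, separation = separation, mixing = mixing,
                 missing_rate = missing_rate, num_means = num_means,
                 num_sds = num_sds, cat_probs = cat_probs, seed = seed),
            class = "ebca_patient_config")
}

#' Generate a synthetic patient table with planted mixed-type clusters
#'
#' Records are drawn from a finite mixture: independent normals per cluster
#' for the numeric variables, per-cluster multinomials for the categorical
#' ones; cells are then masked completely at random at the configured
#' missing rate.  The variables are named so the shipped example rules run
#' verbatim.
#'
#' @param config an `ebca_patient_config` (carries its own seed).
#' @return List: `table` (an `ebca_table`), `truth` (integer planted
#'   cluster labels).
#' @export
generate_patients <- function(config = patient_config()) {
  stopifnot(inherits(config, "ebca_patient_config"))
  withr::with_seed(config$seed, {
    n <- config$n; k <- config$k
    z <- sample.int(k, n, replace = TRUE, prob = config$mixing)
    num <- sapply(colnames(config$num_means), function(v)
      stats::rnorm(n, config$num_means[z, v], config$num_sds[z, v]))
    cat_cols <- lapply(names(config$cat_probs), function(v) {
      P <- config$cat_probs[[v]]
      cats <- colnames(P)
      vapply(z, function(zi) sample(cats, 1, prob = P[zi, ]), character(1))
    })
    names(cat_cols) <- names(config$cat_probs)
    df <- data.frame(num, cat_cols, stringsAsFactors = FALSE)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * ncol(df)) < config$missing_rate,
                     n, ncol(df))
      for (j in seq_len(ncol(df))) df[mask[, j], j] <- NA
    }
    specs <- c(
      lapply(colnames(config$num_means), function(v)
        variable_spec(v, "numeric")),
      lapply(names(config$cat_probs), function(v)
        variable_spec(v, "categorical",
                      categories = colnames(config$cat_probs[[v]]))))
    tab <- mixed_table(df, specs, ids = sprintf("p%04d", seq_len(n)))
    list(table = tab, truth = stats::setNames(z, table_ids(tab)))
  })
}

#' Example prior-knowledge rules for the patient fixture
#'
#' Two extreme-antagonism rules: severe illness (low functioning with high
#' daily family burden) and good condition (working with high
#' functioning).  The second rule's antecedent is fully parenthesised as
#' `(INGRESE = WORK) and ((GAFCLA > 70) or (GAFSOCIAL > 70))`.
#'
#' @param table an `ebca_table` from [generate_patients()] supplying the
#'   variable declarations.
#' @return An `ebca_kb` with rules `r1`, `r2`.
#' @export
example_patient_kb <- function(table) {
  kb_parse(c(
    "r1: if ((GAFCLA < 40) or (GAFSOCIAL < 40)) and ((MAXECFOS_A > 15) and (MAXECFOS_B = Every_Day)) then severely-ill",
    "r2: if (INGRESE = WORK) and ((GAFCLA > 70) or (GAFSOCIAL > 70)) then good-condition"),
    table_specs(table), mode = "clbr")
}

#' Generate a synthetic expert rating matrix
#'
#' Each rater reports the true unit scores plus independent Gaussian
#' noise; used to exercise the agreement statistics.
#'
#' @param true_scores named numeric vector of per-unit true scores.
#' @param noise_sd rater noise standard deviation.
#' @param n_raters number of raters (default 2).
#' @param seed integer RNG seed.
#' @return Numeric matrix units x raters.
#' @export
generate_expert_ratings <- function(true_scores, noise_sd, n_raters = 2,
                                    seed = 1) {
  n <- length(true_scores)
  if (n < 2) stop("generate_expert_ratings: need >= 2 units", call. = FALSE)
  withr::with_seed(seed, {
    m <- sapply(seq_len(n_raters), function(r)
      true_scores + stats::rnorm(n, 0, noise_sd))
    rownames(m) <- names(true_scores)
    colnames(m) <- paste0("rater", seq_len(n_raters))
    m
  })
}
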