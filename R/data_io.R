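# ---------------------------------------------------------------------------
# Mixed-type tabular data model: variable declarations, typed tables with
# explicit missing markers, readers/writers and descriptive statistics
# (step 1 of the cooperative-analysis loop).
# ---------------------------------------------------------------------------

#' Declare a variable of a mixed-type table
#'
#' @param name identifier (must match the CSV column header).
#' @param kind `"numeric"` or `"categorical"`.
#' @param role `"descriptive"` (default), `"dea-input"` or `"dea-output"`.
#' @param units free-text measurement units.
#' @param weight nonnegative importance/utilisation weight (metadata only;
#'   unused by the engines by default).
#' @param categories ordered character vector of admissible categories
#'   (categorical variables only).
#' @return An `ebca_varspec` object.
#' @export
variable_spec <- function(name, kind = c("numeric", "categorical"),
                          role = c("descriptive", "dea-input", "dea-output"),
                          units = "", weight = 1, categories = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(weight) || length(weight) != 1 || is.na(weight) || weight < 0)
    stop("variable '", name, "': weight must be a nonnegative number",
         call. = FALSE)
  if (kind == "numeric" && !is.null(categories))
    stop("variable '", name, "': categories only apply to categorical kind",
         call. = FALSE)
  structure(list(name = name, kind = kind, role = role, units = units,
                 weight = weight, categories = categories),
            class = "ebca_varspec")
}

#' Construct a typed mixed table
#'
#' A thin, validated wrapper around a data frame: the first structure both
#' engines consume.  Cells are numeric or character; `NA` is the explicit
#' missing marker.  Categorical cells must belong to the declared category
#' set (when one is declared).
#'
#' @param data data frame; row content must match `specs` column for column.
#'   An `id` column (or the row names) provides unit identifiers.
#' @param specs list of [variable_spec()], one per data column (excluding the
#'   id column).
#' @param ids optional character vector of unit ids (unique).
#' @return An `ebca_table`: the data frame with attributes `specs` and `ids`.
#' @export
mixed_table <- function(data, specs, ids = NULL) {
  data <- as.data.frame(data)
  if (is.null(ids)) {
    if ("id" %in% names(data)) {
      ids <- as.character(data[["id"]])
      data[["id"]] <- NULL
    } else {
      ids <- rownames(data)
    }
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("mixed_table: unit ids must be unique", call. = FALSE)
  if (length(ids) != nrow(data))
    stop("mixed_table: ", length(ids), " ids for ", nrow(data), " rows",
         call. = FALSE)
  nm <- unname(vapply(specs, `[[`, character(1), "name"))
  if (!identical(sort(nm), sort(names(data))))
    stop("mixed_table: declared variables {",
         paste(setdiff(nm, names(data)), collapse = ","),
         "} missing and/or undeclared columns {",
         paste(setdiff(names(data), nm), collapse = ","), "} present",
         call. = FALSE)
  data <- data[, nm, drop = FALSE]
  names(specs) <- nm
  for (v in nm) {
    s <- specs[[v]]
    if (s$kind == "numeric") {
      if (!is.numeric(data[[v]]))
        stop("mixed_table: column '", v, "' declared numeric but is not",
             call. = FALSE)
      if (any(!is.finite(data[[v]]) & !is.na(data[[v]])))
        stop("mixed_table: non-finite value in numeric column '", v, "'",
             call. = FALSE)
    } else {
      data[[v]] <- as.character(data[[v]])
      if (!is.null(s$categories)) {
        bad <- setdiff(stats::na.omit(unique(data[[v]])), s$categories)
        if (length(bad) > 0)
          stop("mixed_table: value(s) ", paste0("'", bad, "'", collapse = ", "),
               " in column '", v, "' outside the declared category set",
               call. = FALSE)
      }
    }
  }
  rownames(data) <- ids
  structure(data, specs = specs, ids = ids,
            class = c("ebca_table", "data.frame"))
}

#' @export
`[.ebca_table` <- function(x, i, j, ..., drop = FALSE) {
  sp <- table_specs(x)
  ids <- table_ids(x)
  df <- x
  class(df) <- "data.frame"
  if (missing(j) && (nargs() - (!missing(drop))) <= 2) {
    sub <- df[i]                       # single-index form: columns
    return(mixed_table(sub, sp[names(sub)], ids = ids))
  }
  if (missing(i)) i <- seq_len(nrow(df))
  if (missing(j)) j <- seq_len(ncol(df))
  sub <- df[i, j, drop = FALSE]
  mixed_table(sub, sp[names(sub)], ids = ids[i])
}

# internal: the underlying plain data frame (no ebca_table dispatch)
.plain_df <- function(x) {
  class(x) <- "data.frame"
  x
}

#' @export
print.ebca_table <- function(x, ...) {
  sp <- attr(x, "specs")
  cat(sprintf("Mixed table: %d unit(s) x %d variable(s) (%d numeric, %d categorical)\n",
              nrow(x), length(sp),
              sum(vapply(sp, `[[`, character(1), "kind") == "numeric"),
              sum(vapply(sp, `[[`, character(1), "kind") == "categorical")))
  print.data.frame(utils::head(.plain_df(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' Accessors for mixed tables
#'
#' @param table an `ebca_table`.
#' @return `table_specs`: the list of [variable_spec()]s; `table_ids`: the
#'   unit ids; `numeric_vars` / `categorical_vars`: variable names by kind;
#'   `dea_vars`: names of the variables with a DEA role.
#' @export
table_specs <- function(table) attr(table, "specs")

#' @rdname table_specs
#' @export
table_ids <- function(table) attr(table, "ids")

#' @rdname table_specs
#' @export
numeric_vars <- function(table) {
  sp <- table_specs(table)
  names(sp)[vapply(sp, `[[`, character(1), "kind") == "numeric"]
}

#' @rdname table_specs
#' @export
categorical_vars <- function(table) {
  sp <- table_specs(table)
  names(sp)[vapply(sp, `[[`, character(1), "kind") == "categorical"]
}

#' @rdname table_specs
#' @export
dea_vars <- function(table) {
  sp <- table_specs(table)
  names(sp)[vapply(sp, `[[`, character(1), "role") != "descriptive"]
}

# --- metadata sidecar -------------------------------------------------------

#' Read a variable-metadata sidecar (YAML or JSON)
#'
#' The sidecar declares each variable's kind, role, units, weight and
#' category set, e.g.
#' \preformatted{
#' variables:
#'   - {name: TR2, kind: numeric, role: dea-input, units: "per 100k"}
#'   - {name: MAXECFOS_B, kind: categorical,
#'      categories: [Never, Some_Days, Every_Day]}
#' }
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list of [variable_spec()] objects.
#' @export
read_meta <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  vars <- obj$variables %||% obj
  lapply(vars, function(v)
    variable_spec(v$name, v$kind %||% "numeric",
                  v$role %||% "descriptive",
                  units = v$units %||% "",
                  weight = v$weight %||% 1,
                  categories = if (!is.null(v$categories))
                    unlist(v$categories)))
}

#' Write variable metadata to a sidecar file
#'
#' @param specs list of [variable_spec()].
#' @param path output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_meta <- function(specs, path) {
  obj <- list(variables = lapply(specs, function(s)
    Filter(Negate(is.null),
           list(name = s$name, kind = s$kind, role = s$role, units = s$units,
                weight = s$weight, categories = s$categories))))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

# --- CSV reader / writer ----------------------------------------------------

#' Read a mixed-type CSV into a typed table
#'
#' Comma-separated, UTF-8, `.` decimal separator; empty cells and `NA` are
#' missing.  The first column holds unit ids.  Every other column must be
#' declared in `metadata`; numeric cells that fail to parse raise an error
#' naming the row and column.
#'
#' @param path CSV file.
#' @param metadata list of [variable_spec()] (e.g. from [read_meta()]).
#' @return An `ebca_table`.
#' @export
read_mixed_table <- function(path, metadata) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  if (ncol(raw) < 2)
    stop("read_mixed_table: expected an id column plus data columns",
         call. = FALSE)
  ids <- raw[[1]]
  dat <- raw[, -1, drop = FALSE]
  nm <- vapply(metadata, `[[`, character(1), "name")
  undecl <- setdiff(names(dat), nm)
  if (length(undecl) > 0)
    stop("read_mixed_table: undeclared column(s): ",
         paste(undecl, collapse = ", "), call. = FALSE)
  names(metadata) <- nm
  for (v in names(dat)) {
    if (metadata[[v]]$kind == "numeric") {
      num <- suppressWarnings(as.numeric(dat[[v]]))
      bad <- which(is.na(num) & !is.na(dat[[v]]))
      if (length(bad) > 0)
        stop("read_mixed_table: unparseable numeric cell '", dat[[v]][bad[1]],
             "' at row ", bad[1], ", column '", v, "'", call. = FALSE)
      dat[[v]] <- num
    }
  }
  mixed_table(dat, metadata[names(dat)], ids = ids)
}

#' Write a mixed table (and optionally its metadata) to CSV
#'
#' @param table an `ebca_table`.
#' @param path output CSV path.
#' @param meta_path optional sidecar path for [write_meta()].
#' @return `path`, invisibly.
#' @export
write_mixed_table <- function(table, path, meta_path = NULL) {
  df <- cbind(id = table_ids(table), .plain_df(table))
  # full precision so the CSV round trip is bit-exact
  for (v in numeric_vars(table)) {
    x <- sprintf("%.17g", df[[v]])
    x[is.na(df[[v]])] <- NA
    df[[v]] <- x
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  if (!is.null(meta_path)) write_meta(table_specs(table), meta_path)
  invisible(path)
}

# --- descriptive statistics -------------------------------------------------

#' Descriptive summary of a mixed table
#'
#' Per numeric variable: n, missing count, mean, sd, min, quartiles, max and
#' Tukey-fence outlier flags (beyond 1.5 x IQR from the quartiles; values are
#' flagged, never removed).  Per categorical variable: a frequency table.
#'
#' @param table an `ebca_table`.
#' @return An `ebca_summary`: list with `numeric` (data frame), `categorical`
#'   (named list of frequency tables) and `outliers` (named list of flagged
#'   unit ids per numeric variable).
#' @export
summarize_table <- function(table) {
  nv <- numeric_vars(table)
  cv <- categorical_vars(table)
  num <- NULL; outliers <- list()
  if (length(nv) > 0) {
    rows <- lapply(nv, function(v) {
      x <- table[[v]]
      ok <- !is.na(x)
      if (!any(ok)) {
        warning("variable '", v, "' is entirely missing", call. = FALSE)
        return(data.frame(variable = v, n = 0L, missing = sum(!ok),
                          mean = NA_real_, sd = NA_real_, min = NA_real_,
                          q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                          max = NA_real_, n_outliers = 0L))
      }
      q <- stats::quantile(x[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      fence <- c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
      fl <- ok & (x < fence[1] | x > fence[2])
      outliers[[v]] <<- table_ids(table)[which(fl)]
      data.frame(variable = v, n = sum(ok), missing = sum(!ok),
                 mean = mean(x[ok]), sd = stats::sd(x[ok]),
                 min = min(x[ok]), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(x[ok]), n_outliers = sum(fl))
    })
    num <- do.call(rbind, rows)
  }
  cat_tabs <- lapply(cv, function(v) base::table(table[[v]], useNA = "ifany"))
  names(cat_tabs) <- cv
  structure(list(numeric = num, categorical = cat_tabs, outliers = outliers),
            class = "ebca_summary")
}

#' @export
print.ebca_summary <- function(x, ...) {
  if (!is.null(x$numeric)) {
    cat("Numeric variables:\n")
    print(x$numeric, row.names = FALSE, digits = 4)
  }
  if (length(x$categorical) > 0) {
    cat("Categorical variables:\n")
    for (v in names(x$categorical)) {
      cat(" ", v, ":\n"); print(x$categorical[[v]])
    }
  }
  invisible(x)
}

#' Pairwise-correlation redundancy report
#'
#' Supports scenario design: pairs of numeric variables whose absolute
#' Pearson correlation exceeds the threshold are reported (never removed).
#'
#' @param table an `ebca_table`.
#' @param threshold absolute-correlation threshold (default 0.9).
#' @return Data frame with columns `var1`, `var2`, `correlation`.
#' @export
redundancy_report <- function(table, threshold = 0.9) {
  nv <- numeric_vars(table)
  out <- data.frame(var1 = character(), var2 = character(),
                    correlation = numeric())
  if (length(nv) < 2) return(out)
  cm <- stats::cor(.plain_df(table)[nv], use = "pairwise.complete.obs")
  for (i in seq_len(length(nv) - 1))
    for (j in seq((i + 1), length(nv))) {
      r <- cm[i, j]
      if (!is.na(r) && abs(r) > threshold)
        out <- rbind(out, data.frame(var1 = nv[i], var2 = nv[j],
                                     correlation = r))
    }
  out
}

# --- stochastic specification ----------------------------------------------

.check_dist <- function(d, where) {
  fam <- d$dist %||% d$family
  if (is.null(fam)) stop("stochastic spec ", where, ": missing distribution ",
                         "family", call. = FALSE)
  fam <- match.arg(fam, c("uniform", "triangular", "point-mass"))
  if (fam == "uniform") {
    a <- as.numeric(d$a); b <- as.numeric(d$b)
    if (is.na(a) || is.na(b) || b < a)
      stop("stochastic spec ", where, ": uniform requires a <= b", call. = FALSE)
    list(dist = "uniform", a = a, b = b)
  } else if (fam == "triangular") {
    a <- as.numeric(d$a); m <- as.numeric(d$m); b <- as.numeric(d$b)
    if (anyNA(c(a, m, b)) || a > m || m > b)
      stop("stochastic spec ", where, ": triangular requires a <= m <= b",
           call. = FALSE)
    list(dist = "triangular", a = a, m = m, b = b)
  } else {
    v <- as.numeric(d$v %||% d$value)
    if (is.na(v)) stop("stochastic spec ", where, ": point-mass requires v",
                       call. = FALSE)
    list(dist = "point-mass", v = v)
  }
}

#' Build a per-unit, per-variable stochastic specification
#'
#' The stochastic spec carries, for every DEA-role variable of every unit,
#' the expert-elicited probability model of its value (uniform bounds,
#' triangular, or a degenerate point mass).
#'
#' @param entries nested named list `unit -> variable -> distribution`, where
#'   a distribution is `list(dist = "uniform", a =, b =)`,
#'   `list(dist = "triangular", a =, m =, b =)` or
#'   `list(dist = "point-mass", v =)`.
#' @param defaults optional named list `variable -> distribution` expanded to
#'   every unit not explicitly covered.
#' @param units character vector of all unit ids to cover.
#' @param variables character vector of all DEA variables to cover.
#' @return An `ebca_stospec`: nested list `unit -> variable -> distribution`.
#' @export
stochastic_spec <- function(entries = list(), defaults = list(),
                            units, variables) {
  out <- list()
  for (u in units) {
    row <- list()
    for (v in variables) {
      d <- entries[[u]][[v]] %||% defaults[[v]]
      if (is.null(d))
        stop("stochastic spec: no distribution for unit '", u,
             "', variable '", v, "'", call. = FALSE)
      row[[v]] <- .check_dist(d, paste0("(", u, ",", v, ")"))
    }
    out[[u]] <- row
  }
  structure(out, units = units, variables = variables,
            class = "ebca_stospec")
}

#' Read a stochastic specification from YAML or JSON
#'
#' The file may give per-variable `defaults` and/or per-unit overrides under
#' `units`:
#' \preformatted{
#' defaults:
#'   TR2: {dist: uniform, a: 2, b: 3.5}
#' units:
#'   area03:
#'     TR2: {dist: point-mass, v: 3}
#' }
#'
#' @param path YAML/JSON file.
#' @param table the `ebca_table` whose DEA variables and units must be
#'   covered.
#' @return An `ebca_stospec`.
#' @export
read_stochastic_spec <- function(path, table) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  stochastic_spec(entries = obj$units %||% list(),
                  defaults = obj$defaults %||% list(),
                  units = table_ids(table), variables = dea_vars(table))
}

#' Draw one Monte-Carlo realisation from a stochastic spec
#'
#' @param spec an `ebca_stospec`.
#' @return Numeric matrix units x variables.
#' @export
sample_spec <- function(spec) {
  units <- attr(spec, "units"); vars <- attr(spec, "variables")
  m <- matrix(NA_real_, length(units), length(vars),
              dimnames = list(units, vars))
  for (u in units) for (v in vars) {
    d <- spec[[u]][[v]]
    m[u, v] <- switch(d$dist,
      "uniform" = stats::runif(1, d$a, d$b),
      "point-mass" = d$v,
      "triangular" = {
        # inverse-CDF sampling of the triangular distribution
        p <- stats::runif(1)
        fc <- if (d$b > d$a) (d$m - d$a) / (d$b - d$a) else 0
        if (p < fc) d$a + sqrt(p * (d$b - d$a) * (d$m - d$a))
        else d$b - sqrt((1 - p) * (d$b - d$a) * (d$b - d$m))
      })
  }
  m
}
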