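# ---------------------------------------------------------------------------
# The six-step cooperative-analysis loop as a config-driven pipeline:
# (1) data preparation, (2) prior knowledge base, (3) knowledge-guided
# analysis, (4) support interpretation / inconsistency detection, (5) KB
# update and repeat, (6) post-processing.  The human-in-the-loop step is
# realised as a file-based knowledge-base hand-off.
# ---------------------------------------------------------------------------

#' Assemble a pipeline configuration
#'
#' @param engine `"clbr"` or `"dea"`.
#' @param table an `ebca_table` (or CSV path, with `metadata` the sidecar
#'   path).
#' @param metadata metadata sidecar path when `table` is a path.
#' @param spec an `ebca_stospec` (or YAML/JSON path) - DEA engine only.
#' @param scen an `ebca_scenario` - DEA engine only.
#' @param annotations named list from [read_io_annotations()] (or a path).
#' @param dea `ebca_dea_config` - DEA engine only.
#' @param params `ebca_mixed_params` - clbr engine only.
#' @param kmax Calinski cut limit - clbr engine only.
#' @param control [mc_control()] - DEA engine only.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed, set explicitly.
#' @return An `ebca_config`.
#' @export
ebca_config <- function(engine = c("clbr", "dea"), table, metadata = NULL,
                        spec = NULL, scen = NULL, annotations = list(),
                        dea = dea_config(), params = NULL, kmax = NULL,
                        control = mc_control(), out_dir = tempfile("ebca_"),
                        seed) {
  engine <- match.arg(engine)
  if (missing(seed))
    stop("ebca_config: set the seed explicitly for reproducibility",
         call. = FALSE)
  if (is.character(table)) {
    if (is.null(metadata))
      stop("ebca_config: a table path needs a metadata sidecar", call. = FALSE)
    table <- read_mixed_table(table, read_meta(metadata))
  }
  if (is.character(spec)) spec <- read_stochastic_spec(spec, table)
  if (is.character(annotations)) annotations <- read_io_annotations(annotations)
  if (engine == "dea" && is.null(spec))
    stop("ebca_config: the dea engine needs a stochastic spec", call. = FALSE)
  if (engine == "dea" && is.null(scen)) {
    sp <- table_specs(table)
    roles <- vapply(sp, `[[`, character(1), "role")
    scen <- scenario("all", names(sp)[roles == "dea-input"],
                     names(sp)[roles == "dea-output"])
  }
  structure(list(engine = engine, table = table, spec = spec, scen = scen,
                 annotations = annotations, dea = dea, params = params,
                 kmax = kmax, control = control, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "ebca_config")
}

.digest <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run one iteration of the cooperative-analysis loop
#'
#' Executes the configured engine under the supplied knowledge base, then
#' the interpretation step (clbr: significance tests, marked class panel
#' graph, inconsistency report; dea: pool summary, tier classification,
#' convergence trace), writes every artifact plus a JSON manifest of all
#' decided parameters to the output directory, and returns the iteration
#' record.
#'
#' @param config an `ebca_config`.
#' @param kb an `ebca_kb` (clbr mode for the clustering engine; its DEA
#'   counterpart contributes orientation annotations via
#'   `config$annotations`).
#' @param iteration iteration index (default 1).
#' @return An `ebca_iteration` record: `iteration`, `kb_version`,
#'   `digest`, `n_inconsistencies`, `result`, `files`, `timestamp`.
#' @export
run_iteration <- function(config, kb, iteration = 1L) {
  stopifnot(inherits(config, "ebca_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wf <- function(df, name) {
    p <- file.path(out, sprintf("iter%02d_%s", iteration, name))
    utils::write.csv(df, p, row.names = FALSE)
    files[[length(files) + 1]] <<- p
    p
  }
  if (config$engine == "clbr") {
    res <- withr::with_seed(config$seed,
      clbr_cluster(config$table, kb, params = config$params,
                   kmax = config$kmax))
    part_df <- data.frame(id = names(res$partition),
                          class = as.integer(res$partition),
                          provenance = attr(res$partition,
                                            "provenance")[res$partition])
    wf(part_df, "partition.csv")
    if (!is.null(res$ch)) wf(as.data.frame(res$ch), "ch_curve.csv")
    sig <- test_variables(config$table, res$partition)
    wf(sig, "significance.csv")
    cpg <- mark_cells(build_cpg(config$table, res$partition))
    wf(as.data.frame(cpg), "cpg.csv")
    inc <- detect_inconsistencies(config$table, res$partition)
    pinc <- file.path(out, sprintf("iter%02d_inconsistencies.json", iteration))
    jsonlite::write_json(inc, pinc, dataframe = "rows", digits = NA)
    files <- c(files, pinc)
    digest <- .digest(as.integer(res$partition))
    n_inc <- nrow(inc)
  } else {
    pool <- run_monte_carlo(config$spec, config$annotations, config$dea,
                            config$scen, seed = config$seed,
                            control = config$control)
    res <- list(pool = pool, tiers = classify_tiers(pool))
    wf(pool_summary(pool), "pool_summary.csv")
    wf(as.data.frame(pool$trace), "convergence.csv")
    wf(as.data.frame(res$tiers), "tiers.csv")
    digest <- .digest(pool$scores)
    n_inc <- 0L
  }
  manifest <- list(iteration = iteration, engine = config$engine,
                   seed = config$seed, kb_version = kb$version,
                   kb_rules = kb_format(kb),
                   n_inconsistencies = n_inc, digest = digest,
                   package_version = as.character(utils::packageVersion("ebca")),
                   parameters = if (config$engine == "dea")
                     c(config$dea, config$control)
                   else list(kmax = config$kmax),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  pman <- file.path(out, sprintf("iter%02d_manifest.json", iteration))
  jsonlite::write_json(manifest, pman, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(files, pman)
  structure(list(iteration = iteration, kb_version = kb$version,
                 digest = digest, n_inconsistencies = n_inc, result = res,
                 files = files, timestamp = manifest$timestamp),
            class = "ebca_iteration")
}

#' Run the iterative loop over a sequence of knowledge bases
#'
#' Non-interactive stand-in for the expert meetings of the methodology:
#' each iteration consumes the next knowledge base of `kb_sequence` (the
#' last is reused when the sequence is exhausted).  The loop stops early
#' when the knowledge base did not change and no inconsistencies are
#' flagged; a knowledge base whose version regresses is an error.
#'
#' @param config an `ebca_config`.
#' @param kb_sequence list of `ebca_kb` objects or rule-file paths (parsed
#'   against the table's metadata).
#' @param max_iterations iteration cap (default 5).
#' @return List of `ebca_iteration` records.
#' @export
run_loop <- function(config, kb_sequence, max_iterations = 5) {
  stopifnot(max_iterations >= 1)
  if (!is.list(kb_sequence)) kb_sequence <- list(kb_sequence)
  get_kb <- function(i) {
    k <- kb_sequence[[min(i, length(kb_sequence))]]
    if (is.character(k))
      k <- kb_parse(readLines(k), table_specs(config$table))
    k
  }
  records <- list()
  prev_kb <- NULL
  for (i in seq_len(max_iterations)) {
    kb <- get_kb(i)
    if (!is.null(prev_kb)) {
      if (kb$version < prev_kb$version)
        stop("run_loop: knowledge base version regressed (",
             kb$version, " < ", prev_kb$version, ")", call. = FALSE)
      changed <- length(unlist(kb_diff(prev_kb, kb)[c("added", "removed",
                                                      "modified")])) > 0
      if (!changed && records[[i - 1]]$n_inconsistencies == 0) break
    }
    records[[i]] <- run_iteration(config, kb, iteration = i)
    prev_kb <- kb
  }
  records
}

# optimal one-to-one class matching maximizing the confusion diagonal
.match_classes <- function(tab) {
  k <- max(dim(tab))
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (requireNamespace("clue", quietly = TRUE)) {
    as.integer(clue::solve_LSAP(m, maximum = TRUE))
  } else {
    if (k > 8) stop("class matching for k > 8 requires the 'clue' package",
                    call. = FALSE)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- NULL; bestv <- -Inf
    for (p in perms(seq_len(k))) {
      v <- sum(m[cbind(seq_len(k), p)])
      if (v > bestv) { bestv <- v; best <- p }
    }
    best
  }
}

#' Compare an algorithmic result with expert labels
#'
#' Dispatch on the result type: binary tier classifications get diagnostic
#' metrics (positive = efficient-group, reference = the expert rating)
#' plus Cohen's kappa; multi-class partitions get kappa after optimal
#' one-to-one class matching on the confusion matrix; numeric score
#' vectors get the consistency ICC against the expert rating columns.
#'
#' @param result an `ebca_tiers` data frame, a factor/named partition, or
#'   a named numeric score vector.
#' @param expert named expert labels (binary or multi-class) or a rating
#'   matrix for the ICC route.
#' @return A list with the relevant `ebca_diag` / `ebca_kappa` /
#'   `ebca_icc` components and the aligned `confusion` table.
#' @export
compare_with_expert <- function(result, expert) {
  if (inherits(result, "ebca_tiers")) {
    ref <- expert
    if (is.data.frame(ref)) ref <- stats::setNames(ref[[2]], ref[[1]])
    ids <- result$unit
    missing_ids <- setdiff(ids, names(ref))
    if (length(missing_ids) > 0)
      stop("compare_with_expert: expert labels missing for: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    lv <- c("efficient-group", "inefficient-group")
    tab <- confusion_table(factor(ref[ids], lv), factor(result$group, lv),
                           levels = lv)
    return(list(confusion = tab, diagnostics = diagnostic_metrics(tab),
                kappa = cohen_kappa(tab)))
  }
  if (is.numeric(result) && !is.matrix(result)) {
    m <- cbind(model = result,
               as.matrix(expert)[names(result), , drop = FALSE])
    return(list(icc = icc_consistency(m)))
  }
  # multi-class partition
  part <- result
  if (inherits(part, "ebca_clbr")) part <- part$partition
  ref <- expert
  if (is.data.frame(ref)) ref <- stats::setNames(ref[[2]], ref[[1]])
  ids <- names(part)
  if (is.null(ids))
    stop("compare_with_expert: partition must be named by unit id",
         call. = FALSE)
  missing_ids <- setdiff(ids, names(ref))
  if (length(missing_ids) > 0)
    stop("compare_with_expert: expert labels missing for: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  tab <- base::table(factor(ref[ids]), factor(part))
  perm <- .match_classes(tab)
  k <- max(dim(tab))
  sq <- matrix(0L, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  aligned <- sq[, perm, drop = FALSE]
  list(confusion = tab, matching = perm, kappa = cohen_kappa(aligned),
       ari = adjusted_rand_index(ref[ids], part))
}

# --- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `synth sha|patients|ratings`, `dea`, `clbr`, `validate`.
#' Invoked by the `inst/cli/ebca.R` script:
#' \preformatted{Rscript -e 'ebca::ebca_cli()' -- dea --table T.csv ...}
#'
#' @param args character vector of command-line arguments (default: the
#'   trailing `commandArgs`).
#' @return Exit status 0 invisibly; artifacts are written to `--out`.
#' @export
ebca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: ebca <synth|dea|clbr|validate> [options]", call. = FALSE)
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i) == 0) return(default)
    rest[i + 1]
  }
  out_dir <- opt("out", ".")
  seed <- as.integer(opt("seed", "1"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "synth") {
    what <- rest[1]
    if (what == "sha") {
      g <- generate_sha(sha_config(), seed = seed)
      write_mixed_table(g$table, file.path(out_dir, "sha_table.csv"),
                        file.path(out_dir, "sha_meta.yaml"))
      utils::write.csv(data.frame(id = names(g$truth),
                                  inefficient = g$truth),
                       file.path(out_dir, "sha_truth.csv"),
                       row.names = FALSE)
    } else if (what == "patients") {
      g <- generate_patients(patient_config(seed = seed))
      write_mixed_table(g$table, file.path(out_dir, "patients.csv"),
                        file.path(out_dir, "patients_meta.yaml"))
      utils::write.csv(data.frame(id = names(g$truth), cluster = g$truth),
                       file.path(out_dir, "patients_truth.csv"),
                       row.names = FALSE)
    } else stop("unknown synth target '", what, "'", call. = FALSE)
  } else if (cmd %in% c("dea", "clbr")) {
    tab <- read_mixed_table(opt("table"), read_meta(opt("meta")))
    kb <- if (!is.null(opt("kb")))
      kb_parse(readLines(opt("kb")), table_specs(tab)) else kb_empty()
    if (cmd == "dea") {
      cfg <- ebca_config("dea", tab,
                         spec = read_stochastic_spec(opt("spec"), tab),
                         annotations = if (!is.null(opt("ann")))
                           read_io_annotations(opt("ann")) else list(),
                         dea = dea_config(opt("orientation", "input"),
                                          opt("rts", "constant")),
                         out_dir = out_dir, seed = seed)
    } else {
      cfg <- ebca_config("clbr", tab,
                         kmax = if (!is.null(opt("kmax")))
                           as.integer(opt("kmax")),
                         out_dir = out_dir, seed = seed)
    }
    rec <- run_iteration(cfg, kb)
    message("iteration written: ", paste(basename(rec$files), collapse = ", "))
  } else if (cmd == "validate") {
    pred <- utils::read.csv(opt("pred"))
    ref <- utils::read.csv(opt("ref"))
    cmpr <- compare_with_expert(stats::setNames(factor(pred[[2]]), pred[[1]]),
                                ref)
    jsonlite::write_json(list(kappa = cmpr$kappa$kappa, ari = cmpr$ari),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  } else stop("unknown command '", cmd, "'", call. = FALSE)
  invisible(0L)
}
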