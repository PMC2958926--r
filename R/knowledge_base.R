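# ---------------------------------------------------------------------------
# Prior Knowledge Base: an ordered set of if-then rules over the variables of
# a mixed-type table.  Rules guide either the clustering engine (conclusions
# are class labels) or the DEA engine (conclusions annotate variables as
# standard / non-standard inputs and outputs).
# ---------------------------------------------------------------------------

#' Create an empty knowledge base
#'
#' An empty knowledge base is valid and corresponds to blind (rule-free)
#' analysis: the clustering engine degenerates to plain hierarchical
#' clustering, the DEA engine treats every variable as standard.
#'
#' @param mode `"clbr"` (conclusions are class labels) or `"dea"`
#'   (conclusions are input/output orientation annotations).
#' @param metadata optional list of [variable_spec()] objects declaring the
#'   variables rules may reference.
#' @return An object of class `ebca_kb`.
#' @export
kb_empty <- function(mode = c("clbr", "dea"), metadata = list()) {
  mode <- match.arg(mode)
  structure(
    list(rules = list(), mode = mode, version = 1L,
         changelog = character(), metadata = .kb_meta(metadata)),
    class = "ebca_kb")
}

# normalize metadata to a named list name -> list(kind, categories)
.kb_meta <- function(metadata) {
  if (length(metadata) == 0) return(list())
  out <- lapply(metadata, function(v) {
    if (inherits(v, "ebca_varspec"))
      list(kind = v$kind, categories = v$categories)
    else
      list(kind = v$kind, categories = v$categories)
  })
  names(out) <- vapply(metadata, function(v) v$name, character(1))
  out
}

# --- tokenizer --------------------------------------------------------------

.tok_patterns <- list(
  c("ws",     "^\\s+"),
  c("num",    "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"),
  c("op",     "^(<=|>=|!=|<|>|=)"),
  c("lparen", "^\\("),
  c("rparen", "^\\)"),
  c("lbrack", "^\\["),
  c("rbrack", "^\\]"),
  c("lbrace", "^\\{"),
  c("rbrace", "^\\}"),
  c("comma",  "^,"),
  c("colon",  "^:"),
  c("str",    "^\"[^\"]*\""),
  c("ident",  "^[A-Za-z_][A-Za-z0-9_.-]*")
)

.kb_tokenize <- function(line) {
  toks <- list()
  rest <- line
  while (nzchar(rest)) {
    matched <- FALSE
    for (p in .tok_patterns) {
      m <- regmatches(rest, regexpr(p[2], rest))
      if (length(m) == 1 && nzchar(m)) {
        if (p[1] != "ws") {
          type <- p[1]
          val <- m
          if (type == "ident" && tolower(val) %in%
              c("if", "then", "and", "or", "not", "in")) {
            type <- "kw"; val <- tolower(val)
          }
          if (type == "str") val <- substr(val, 2, nchar(val) - 1)
          toks[[length(toks) + 1]] <- list(type = type, value = val)
        }
        rest <- substr(rest, nchar(m) + 1, nchar(rest))
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop("rule parse error: unrecognised input near '",
           substr(rest, 1, 20), "'", call. = FALSE)
  }
  toks
}

# --- recursive-descent parser ----------------------------------------------

# parser state: environment with tokens, position, metadata
.ps_new <- function(tokens, metadata) {
  e <- new.env(parent = emptyenv())
  e$toks <- tokens; e$pos <- 1L; e$meta <- metadata
  e
}
.ps_peek <- function(ps) if (ps$pos <= length(ps$toks)) ps$toks[[ps$pos]] else NULL
.ps_next <- function(ps) { t <- .ps_peek(ps); ps$pos <- ps$pos + 1L; t }
.ps_expect <- function(ps, type, value = NULL) {
  t <- .ps_next(ps)
  ok <- !is.null(t) && t$type == type && (is.null(value) || t$value == value)
  if (!ok)
    stop("rule parse error: expected ",
         if (is.null(value)) type else paste0("'", value, "'"),
         " but found ",
         if (is.null(t)) "end of rule" else paste0("'", t$value, "'"),
         call. = FALSE)
  t
}

.parse_expr <- function(ps) {
  args <- list(.parse_unary(ps))
  conn <- NULL
  repeat {
    t <- .ps_peek(ps)
    if (is.null(t) || t$type != "kw" || !(t$value %in% c("and", "or"))) break
    if (is.null(conn)) {
      conn <- t$value
    } else if (conn != t$value) {
      stop("rule parse error: 'and' and 'or' mixed at the same level; ",
           "add explicit parentheses", call. = FALSE)
    }
    .ps_next(ps)
    args[[length(args) + 1]] <- .parse_unary(ps)
  }
  if (is.null(conn)) args[[1]] else list(node = conn, args = args)
}

.parse_unary <- function(ps) {
  t <- .ps_peek(ps)
  if (is.null(t)) stop("rule parse error: unexpected end of rule", call. = FALSE)
  if (t$type == "kw" && t$value == "not") {
    .ps_next(ps)
    return(list(node = "not", arg = .parse_unary(ps)))
  }
  if (t$type == "lparen") {
    .ps_next(ps)
    e <- .parse_expr(ps)
    .ps_expect(ps, "rparen")
    return(e)
  }
  .parse_atom(ps)
}

.parse_atom <- function(ps) {
  vt <- .ps_expect(ps, "ident")
  var <- vt$value
  meta <- ps$meta
  if (length(meta) > 0 && !(var %in% names(meta)))
    stop("rule parse error: undeclared variable '", var, "'", call. = FALSE)
  kind <- if (length(meta) > 0) meta[[var]]$kind else NA_character_
  t <- .ps_next(ps)
  if (is.null(t)) stop("rule parse error: unexpected end after '", var, "'",
                       call. = FALSE)
  if (t$type == "op") {
    op <- t$value
    lit <- .ps_next(ps)
    if (is.null(lit)) stop("rule parse error: missing literal for '", var, "'",
                           call. = FALSE)
    if (lit$type == "num") {
      if (!is.na(kind) && kind != "numeric") {
        if (op %in% c("<", "<=", ">", ">="))
          stop("rule parse error: ordering operator '", op,
               "' on categorical variable '", var, "'", call. = FALSE)
        stop("rule parse error: numeric literal for categorical variable '",
             var, "'", call. = FALSE)
      }
      return(list(node = "cond", variable = var, op = op,
                  value = as.numeric(lit$value), kind = "numeric"))
    }
    if (lit$type %in% c("ident", "str")) {
      if (op %in% c("<", "<=", ">", ">="))
        stop("rule parse error: ordering operator '", op,
             "' requires a numeric variable ('", var, "')", call. = FALSE)
      if (!is.na(kind) && kind != "categorical")
        stop("rule parse error: category literal for numeric variable '",
             var, "'", call. = FALSE)
      if (!is.na(kind) && length(meta[[var]]$categories) > 0 &&
          !(lit$value %in% meta[[var]]$categories))
        stop("rule parse error: category '", lit$value,
             "' not declared for variable '", var, "'", call. = FALSE)
      return(list(node = "cond", variable = var, op = op,
                  value = lit$value, kind = "categorical"))
    }
    stop("rule parse error: bad literal '", lit$value, "'", call. = FALSE)
  }
  if (t$type == "kw" && t$value == "in") {
    t2 <- .ps_peek(ps)
    if (!is.null(t2) && t2$type == "lbrace") {      # category set
      .ps_next(ps)
      set <- character()
      repeat {
        el <- .ps_next(ps)
        if (is.null(el) || !(el$type %in% c("ident", "str", "num")))
          stop("rule parse error: bad set element", call. = FALSE)
        set <- c(set, el$value)
        sep <- .ps_next(ps)
        if (is.null(sep)) stop("rule parse error: unterminated set", call. = FALSE)
        if (sep$type == "rbrace") break
        if (sep$type != "comma")
          stop("rule parse error: expected ',' in set", call. = FALSE)
      }
      if (!is.na(kind) && kind != "categorical")
        stop("rule parse error: set membership requires a categorical ",
             "variable ('", var, "')", call. = FALSE)
      return(list(node = "cond", variable = var, op = "in-set",
                  value = set, kind = "categorical"))
    }
    # interval
    lt <- .ps_next(ps)
    if (is.null(lt) || !(lt$type %in% c("lbrack", "lparen")))
      stop("rule parse error: expected interval after 'in'", call. = FALSE)
    lo <- as.numeric(.ps_expect(ps, "num")$value)
    .ps_expect(ps, "comma")
    hi <- as.numeric(.ps_expect(ps, "num")$value)
    rt <- .ps_next(ps)
    if (is.null(rt) || !(rt$type %in% c("rbrack", "rparen")))
      stop("rule parse error: unterminated interval", call. = FALSE)
    if (lo > hi)
      stop("rule parse error: interval bounds out of order [", lo, ",", hi, "]",
           call. = FALSE)
    if (!is.na(kind) && kind != "numeric")
      stop("rule parse error: interval requires a numeric variable ('",
           var, "')", call. = FALSE)
    return(list(node = "cond", variable = var, op = "in-interval",
                lo = lo, hi = hi,
                lo_closed = lt$type == "lbrack",
                hi_closed = rt$type == "rbrack",
                kind = "numeric"))
  }
  stop("rule parse error: expected operator or 'in' after '", var, "'",
       call. = FALSE)
}

#' Parse a rule file into a knowledge base
#'
#' One rule per line, `#` starts a comment.  Grammar:
#' \preformatted{
#' rule     := ID ':' 'if' expr 'then' LABEL
#' expr     := '(' expr ')' | expr ('and'|'or') expr | 'not' expr | atom
#' atom     := VAR OP literal | VAR 'in' interval | VAR 'in' set
#' OP       := '<' '<=' '>' '>=' '=' '!='
#' interval := ('['|'(') number ',' number (']'|')')
#' set      := '{' element (',' element)* '}'
#' }
#' Mixing `and` and `or` at the same parenthesis level is rejected: the
#' parser demands explicit parentheses rather than imposing a silent
#' precedence.
#'
#' @param text character scalar or vector of lines with rule definitions.
#' @param metadata list of [variable_spec()] declarations; when supplied,
#'   rules may only reference declared variables and operators compatible
#'   with the variable kind.
#' @param mode `"clbr"` or `"dea"`.
#' @return An `ebca_kb` object.
#' @examples
#' meta <- list(variable_spec("GAFCLA", "numeric"),
#'              variable_spec("GAFSOCIAL", "numeric"))
#' kb <- kb_parse("r0: if (GAFCLA < 40) or (GAFSOCIAL < 40) then severe",
#'                meta)
#' @export
kb_parse <- function(text, metadata = list(), mode = c("clbr", "dea")) {
  mode <- match.arg(mode)
  kb <- kb_empty(mode, metadata)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ids <- character()
  for (line in lines) {
    m <- regexec("^([A-Za-z_][A-Za-z0-9_.-]*)\\s*:\\s*(.*)$", line)
    parts <- regmatches(line, m)[[1]]
    if (length(parts) != 3)
      stop("rule parse error: expected 'ID : if ... then ...' in '",
           line, "'", call. = FALSE)
    id <- parts[2]
    if (id %in% ids)
      stop("rule parse error: duplicate rule id '", id, "'", call. = FALSE)
    body <- parts[3]
    # split off the conclusion: LABEL = free text after the last 'then'
    tm <- regexec("^[Ii][Ff]\\s+(.*)\\s+[Tt][Hh][Ee][Nn]\\s+(.+)$", body)
    bp <- regmatches(body, tm)[[1]]
    if (length(bp) != 3)
      stop("rule parse error: expected 'if <expr> then <label>' in rule '",
           id, "'", call. = FALSE)
    toks <- .kb_tokenize(bp[2])
    ps <- .ps_new(toks, kb$metadata)
    ant <- .parse_expr(ps)
    if (!is.null(.ps_peek(ps)))
      stop("rule parse error: trailing tokens in rule '", id, "'",
           call. = FALSE)
    kb$rules[[length(kb$rules) + 1]] <-
      structure(list(id = id, antecedent = ant,
                     conclusion = trimws(bp[3])),
                class = "ebca_rule")
    ids <- c(ids, id)
  }
  kb
}

# --- serialization ----------------------------------------------------------

.format_expr <- function(node) {
  switch(node$node,
    cond = {
      v <- node$variable
      if (node$op == "in-interval") {
        paste0("(", v, " in ",
               if (node$lo_closed) "[" else "(", node$lo, ",", node$hi,
               if (node$hi_closed) "]" else ")", ")")
      } else if (node$op == "in-set") {
        paste0("(", v, " in {", paste(.format_lit(node$value), collapse = ","),
               "})")
      } else {
        paste0("(", v, " ", node$op, " ", .format_lit(node$value), ")")
      }
    },
    not = paste0("(not ", .format_expr(node$arg), ")"),
    paste0("(", paste(vapply(node$args, .format_expr, character(1)),
                      collapse = paste0(" ", node$node, " ")), ")")
  )
}

.format_lit <- function(x) {
  if (is.numeric(x)) format(x, digits = 15)
  else ifelse(grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x), x, paste0("\"", x, "\""))
}

#' Serialize a knowledge base back to rule-file text
#'
#' The emitted text is fully parenthesised; `kb_parse(kb_format(kb))` yields
#' an identical expression tree (round-trip identity).
#'
#' @param kb an `ebca_kb`.
#' @return character vector, one rule per element.
#' @export
kb_format <- function(kb) {
  stopifnot(inherits(kb, "ebca_kb"))
  vapply(kb$rules, function(r)
    paste0(r$id, ": if ", .format_expr(r$antecedent), " then ", r$conclusion),
    character(1))
}

#' @export
format.ebca_kb <- function(x, ...) {
  c(sprintf("Knowledge base (%s mode), version %d, %d rule(s)",
            x$mode, x$version, length(x$rules)),
    paste0("  ", kb_format(x)))
}

#' @export
print.ebca_kb <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Serialize / restore a knowledge base as JSON
#'
#' @param kb an `ebca_kb` object.
#' @param path file path; when `NULL`, `kb_to_json` returns the JSON string.
#' @return `kb_to_json`: JSON string or (invisibly) `path`;
#'   `kb_from_json`: an `ebca_kb`.
#' @export
kb_to_json <- function(kb, path = NULL) {
  stopifnot(inherits(kb, "ebca_kb"))
  obj <- list(mode = kb$mode, version = kb$version,
              changelog = as.list(kb$changelog),
              rules = kb_format(kb),
              metadata = kb$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname kb_to_json
#' @param json JSON string (ignored when `path` given).
#' @export
kb_from_json <- function(path = NULL, json = NULL) {
  obj <- jsonlite::fromJSON(if (!is.null(path)) path else json,
                            simplifyVector = FALSE)
  meta <- lapply(obj$metadata, function(m)
    list(kind = m$kind, categories = unlist(m$categories)))
  specs <- lapply(names(meta), function(nm)
    variable_spec(nm, meta[[nm]]$kind, categories = meta[[nm]]$categories))
  kb <- kb_parse(unlist(obj$rules), specs, mode = obj$mode)
  kb$version <- as.integer(obj$version)
  kb$changelog <- unlist(obj$changelog) %||% character()
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- evaluation (Kleene three-valued logic) ---------------------------------

.eval_expr <- function(node, record) {
  switch(node$node,
    cond = .eval_cond(node, record),
    not = { v <- .eval_expr(node$arg, record); !v },
    and = Reduce(`&`, lapply(node$args, .eval_expr, record = record)),
    or  = Reduce(`|`, lapply(node$args, .eval_expr, record = record))
  )
}

.eval_cond <- function(node, record) {
  if (!(node$variable %in% names(record)))
    stop("evaluation error: variable '", node$variable,
         "' absent from record", call. = FALSE)
  v <- record[[node$variable]]
  if (length(v) != 1) v <- v[[1]]
  if (is.na(v)) return(NA)
  if (node$kind == "numeric") {
    if (!is.numeric(v))
      stop("evaluation error: operator on variable '", node$variable,
           "' requires a numeric cell", call. = FALSE)
  } else if (is.numeric(v)) {
    stop("evaluation error: categorical comparison on numeric cell for '",
         node$variable, "'", call. = FALSE)
  } else {
    v <- as.character(v)
  }
  switch(node$op,
    "<"  = v <  node$value,
    "<=" = v <= node$value,
    ">"  = v >  node$value,
    ">=" = v >= node$value,
    "="  = v == node$value,
    "!=" = v != node$value,
    "in-set" = v %in% node$value,
    "in-interval" = {
      lo_ok <- if (node$lo_closed) v >= node$lo else v > node$lo
      hi_ok <- if (node$hi_closed) v <= node$hi else v < node$hi
      lo_ok & hi_ok
    })
}

#' Evaluate one rule on one record
#'
#' Missing cells propagate through the antecedent under Kleene three-valued
#' logic: the result is `"unknown"` exactly when the truth value depends on a
#' missing cell (e.g. `FALSE and NA` is still `FALSE`, `TRUE or NA` is still
#' `TRUE`).
#'
#' @param rule an `ebca_rule` (element of `kb$rules`).
#' @param record a one-row data frame or named list of cell values.
#' @return `"fires"`, `"no-fire"` or `"unknown"`.
#' @export
evaluate_rule <- function(rule, record) {
  stopifnot(inherits(rule, "ebca_rule"))
  v <- .eval_expr(rule$antecedent, record)
  if (is.na(v)) "unknown" else if (v) "fires" else "no-fire"
}

#' Partition the records of a table by the rules of a knowledge base
#'
#' Each record is assigned to the first rule (in knowledge-base order) whose
#' antecedent fires, or to the residual group.  Records whose rule status is
#' unknown because of missing cells fall to the residual group and are
#' counted in the `n_unknown` attribute; records captured by more than one
#' rule are counted in `n_overlap` and trigger a warning.
#'
#' @param kb an `ebca_kb` in clbr mode.
#' @param table an `ebca_table` (see [mixed_table()]) or data frame.
#' @return A factor of length `nrow(table)` with levels
#'   `c(<rule ids>, "residual")` and attributes `counts`, `n_unknown`,
#'   `n_overlap`.
#' @export
kb_partition <- function(kb, table) {
  stopifnot(inherits(kb, "ebca_kb"))
  if (kb$mode != "clbr")
    stop("kb_partition requires a clbr-mode knowledge base", call. = FALSE)
  df <- if (inherits(table, "ebca_table")) .plain_df(table) else as.data.frame(table)
  n <- nrow(df)
  ids <- vapply(kb$rules, `[[`, character(1), "id")
  lev <- c(ids, "residual")
  assign <- rep("residual", n)
  n_unknown <- 0L; n_overlap <- 0L
  if (length(kb$rules) > 0 && n > 0) {
    status <- matrix("no-fire", n, length(kb$rules))
    for (j in seq_along(kb$rules))
      for (i in seq_len(n))
        status[i, j] <- evaluate_rule(kb$rules[[j]], df[i, , drop = FALSE])
    for (i in seq_len(n)) {
      fired <- which(status[i, ] == "fires")
      if (length(fired) > 1) n_overlap <- n_overlap + 1L
      if (length(fired) >= 1) {
        assign[i] <- ids[fired[1]]
      } else if (any(status[i, ] == "unknown")) {
        n_unknown <- n_unknown + 1L
      }
    }
  }
  if (n_overlap > 0)
    warning(n_overlap, " record(s) satisfied more than one rule; ",
            "first match kept", call. = FALSE)
  if (n_unknown > 0)
    warning(n_unknown, " record(s) with unknown rule status (missing cells) ",
            "assigned to residual", call. = FALSE)
  f <- factor(assign, levels = lev)
  structure(f, counts = base::table(f), n_unknown = n_unknown,
            n_overlap = n_overlap)
}

# --- versioning -------------------------------------------------------------

#' Difference between two knowledge-base versions
#'
#' @param old,new `ebca_kb` objects sharing the same mode.
#' @return A list with elements `added`, `removed`, `modified` (rule ids) and
#'   `new_kb`: `new` with its version bumped past `old` and the changeset
#'   appended to the changelog.
#' @export
kb_diff <- function(old, new) {
  stopifnot(inherits(old, "ebca_kb"), inherits(new, "ebca_kb"))
  if (old$mode != new$mode)
    stop("kb_diff: knowledge bases have different modes", call. = FALSE)
  oid <- vapply(old$rules, `[[`, character(1), "id")
  nid <- vapply(new$rules, `[[`, character(1), "id")
  added <- setdiff(nid, oid)
  removed <- setdiff(oid, nid)
  common <- intersect(oid, nid)
  otxt <- stats::setNames(kb_format(old), oid)
  ntxt <- stats::setNames(kb_format(new), nid)
  modified <- common[otxt[common] != ntxt[common]]
  entry <- sprintf("v%d -> v%d: added{%s} removed{%s} modified{%s}",
                   old$version, old$version + 1L,
                   paste(added, collapse = ","),
                   paste(removed, collapse = ","),
                   paste(modified, collapse = ","))
  new$version <- max(old$version + 1L, new$version)
  new$changelog <- c(new$changelog, entry)
  list(added = added, removed = removed, modified = modified, new_kb = new)
}

# --- DEA orientation annotations -------------------------------------------

#' Input/output orientation annotations for the DEA engine
#'
#' A non-standard input (or output) is one whose conventional direction is
#' reversed: larger values signal *better* use of resources (for inputs) or
#' *worse* performance (for outputs).  Such variables are passed through a
#' linear monotone-decreasing transformation ([transform_nonstandard()])
#' before entering the DEA linear programme.
#'
#' @param path YAML or JSON file mapping variable name to
#'   `{role: input|output, orientation: standard|non-standard}` with an
#'   optional `margin` (fraction of the column range, default 0.1) for
#'   non-standard variables.
#' @param annotations alternatively, a named list with the same structure.
#' @return A named list of `ebca_ioann` records.
#' @export
read_io_annotations <- function(path = NULL, annotations = NULL) {
  if (!is.null(path)) {
    annotations <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
  }
  out <- lapply(names(annotations), function(nm) {
    a <- annotations[[nm]]
    role <- match.arg(a$role, c("input", "output"))
    orientation <- match.arg(a$orientation %||% "standard",
                             c("standard", "non-standard"))
    margin <- a$margin %||% (if (orientation == "non-standard") 0.1 else NULL)
    if (orientation == "standard" && !is.null(a$margin))
      stop("annotation for '", nm, "': margin is only meaningful for ",
           "non-standard orientation", call. = FALSE)
    structure(list(variable = nm, role = role, orientation = orientation,
                   margin = margin),
              class = "ebca_ioann")
  })
  stats::setNames(out, names(annotations))
}
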