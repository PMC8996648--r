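#' Parse an Ovid-dialect search strategy
#'
#' Understands the numbered-line subset of Ovid MEDLINE syntax used by
#' study-type filters:
#'
#' * `exp Heading/` — exploded MeSH heading (the heading and all tree
#'   descendants);
#' * `Heading/` — non-exploded MeSH heading;
#' * `term.tw` — textword search over title and abstract; the term may be
#'   quoted, may span several words (matched as adjacent tokens) and may
#'   carry a single trailing `*` truncation wildcard;
#' * `or/1-13`, `and/2-4`, `1 or 2 or 3`, `1 not 2` — Boolean combinations
#'   of earlier lines (en-dash ranges are accepted and normalized).
#'
#' Line numbers must be consecutive starting at 1 and combinations may only
#' reference earlier lines.
#'
#' @param text Strategy text, one numbered line per strategy row (a file
#'   path is also accepted).
#' @param name Name stored on the strategy.
#' @return An object of class `ovid_strategy`: a list with `name` and
#'   `lines`, where `lines[[i]]` is the AST node of line `i`. Nodes are
#'   lists with a `type` of `"mesh"` (fields `heading`, `explode`),
#'   `"textword"` (fields `term`, `truncated`, `fields`) or `"combo"`
#'   (fields `op`, `refs`).
#' @examples
#' s <- parse_strategy("1 risk.tw\n2 exp Prognosis/\n3 or/1-2")
#' length(s$lines)
#' @export
parse_strategy <- function(text, name = "strategy") {
  lines <- read_input_lines(text, must_exist = FALSE)
  lines <- gsub("–|—", "-", lines)  # en/em dash -> hyphen
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty strategy", call. = FALSE)
  nodes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([0-9]+)[.)]?\\s+(.*)$", lines[i]))[[1]]
    if (!length(m)) {
      stop("strategy line ", i, " is not of the form 'N expression': ",
           lines[i], call. = FALSE)
    }
    num <- as.integer(m[2])
    if (num != i) {
      stop("strategy line numbers must be consecutive from 1; line ", i,
           " is numbered ", num, call. = FALSE)
    }
    nodes[[i]] <- parse_expression(m[3], line = i)
    if (nodes[[i]]$type == "combo") {
      refs <- nodes[[i]]$refs
      if (any(refs >= i) || any(refs < 1)) {
        stop("line ", i, " references line(s) ",
             paste(refs[refs >= i | refs < 1], collapse = ", "),
             " outside 1..", i - 1, call. = FALSE)
      }
    }
  }
  structure(list(name = name, lines = nodes), class = "ovid_strategy")
}

parse_expression <- function(expr, line) {
  expr <- trimws(expr)
  # op/N1-N2 range combos
  m <- regmatches(expr,
    regexec("^(and|or|not)\\s*/\\s*([0-9]+)\\s*-\\s*([0-9]+)$", expr,
            ignore.case = TRUE))[[1]]
  if (length(m)) {
    lo <- as.integer(m[3]); hi <- as.integer(m[4])
    if (lo > hi) stop("line ", line, ": empty range ", expr, call. = FALSE)
    return(combo_node(tolower(m[2]), seq.int(lo, hi)))
  }
  # N1 op N2 (op N3 ...) combos, single operator
  if (grepl("^[0-9]+(\\s+(and|or|not)\\s+[0-9]+)+$", expr, ignore.case = TRUE)) {
    toks <- strsplit(expr, "\\s+")[[1]]
    ops <- unique(tolower(toks[seq(2, length(toks), by = 2)]))
    if (length(ops) != 1) {
      stop("line ", line, ": mixed Boolean operators need explicit grouping: ",
           expr, call. = FALSE)
    }
    return(combo_node(ops, as.integer(toks[seq(1, length(toks), by = 2)])))
  }
  # exploded / plain MeSH heading
  m <- regmatches(expr, regexec("^exp\\s+(.+)/$", expr, ignore.case = TRUE))[[1]]
  if (length(m)) return(mesh_node(m[2], explode = TRUE))
  m <- regmatches(expr, regexec("^([^/.]+)/$", expr))[[1]]
  if (length(m)) return(mesh_node(m[2], explode = FALSE))
  # textword with a field suffix
  m <- regmatches(expr, regexec("^(.*)\\.([a-z]+)\\.?$", expr))[[1]]
  if (length(m)) {
    if (tolower(m[3]) != "tw") {
      stop("line ", line, ": unsupported field suffix '.", m[3], "'",
           call. = FALSE)
    }
    term <- gsub('^"|"$', "", trimws(m[2]))
    truncated <- grepl("\\*$", term)
    term <- sub("\\*+$", "", term)
    if (grepl("\\*", term)) {
      stop("line ", line, ": only trailing truncation is supported: ", expr,
           call. = FALSE)
    }
    if (!nzchar(trimws(term))) stop("line ", line, ": empty term", call. = FALSE)
    return(textword_node(term, truncated))
  }
  stop("line ", line, ": cannot parse expression: ", expr, call. = FALSE)
}

mesh_node <- function(heading, explode) {
  list(type = "mesh", heading = trimws(heading), explode = isTRUE(explode))
}

textword_node <- function(term, truncated = FALSE,
                          fields = c("title", "abstract")) {
  stopifnot(nzchar(term), all(fields %in% c("title", "abstract")))
  list(type = "textword", term = trimws(term), truncated = isTRUE(truncated),
       fields = fields)
}

combo_node <- function(op, refs) {
  stopifnot(op %in% c("and", "or", "not"), length(refs) >= 1)
  list(type = "combo", op = op, refs = as.integer(refs))
}

#' @export
print.ovid_strategy <- function(x, ...) {
  cat("<ovid_strategy> ", x$name, " (", length(x$lines), " lines)\n", sep = "")
  cat(format_strategy(x), sep = "\n")
  invisible(x)
}

#' Serialize a strategy back to numbered-line text
#'
#' The output reparses to an equal AST via [parse_strategy()].
#'
#' @param strategy An `ovid_strategy`.
#' @return Character vector of lines.
#' @export
format_strategy <- function(strategy) {
  stopifnot(inherits(strategy, "ovid_strategy"))
  vapply(seq_along(strategy$lines), function(i) {
    node <- strategy$lines[[i]]
    expr <- switch(node$type,
      mesh = paste0(if (node$explode) "exp " else "", node$heading, "/"),
      textword = {
        term <- paste0(node$term, if (node$truncated) "*")
        quoted <- if (grepl("\\s|\\*", term)) paste0('"', term, '"') else term
        paste0(quoted, ".tw")
      },
      combo = {
        r <- node$refs
        if (length(r) > 1 && all(diff(r) == 1)) {
          paste0(node$op, "/", r[1], "-", r[length(r)])
        } else {
          paste(r, collapse = paste0(" ", node$op, " "))
        }
      }
    )
    paste(i, expr)
  }, character(1))
}

#' Convert a strategy AST to JSON
#'
#' @param strategy An `ovid_strategy`.
#' @return A JSON string.
#' @export
strategy_to_json <- function(strategy) {
  stopifnot(inherits(strategy, "ovid_strategy"))
  jsonlite::toJSON(list(name = strategy$name, lines = strategy$lines),
                   auto_unbox = TRUE, pretty = TRUE)
}

# ---- Evaluation -------------------------------------------------------------

match_tokens <- function(tokens, term_tokens, truncated) {
  k <- length(term_tokens)
  n <- length(tokens)
  if (k == 0 || n < k) return(FALSE)
  last <- term_tokens[k]
  if (k == 1) {
    if (truncated) return(any(startsWith(tokens, last)))
    return(any(tokens == last))
  }
  starts <- which(tokens[seq_len(n - k + 1)] == term_tokens[1])
  for (s in starts) {
    seg <- tokens[s:(s + k - 1)]
    head_ok <- all(seg[-k] == term_tokens[-k])
    tail_ok <- if (truncated) startsWith(seg[k], last) else seg[k] == last
    if (head_ok && tail_ok) return(TRUE)
  }
  FALSE
}

#' Evaluate one strategy line against one record
#'
#' Textword terms match case-insensitively on whole tokens (text is
#' lowercased and split on non-alphanumerics); multi-word terms must occur
#' as adjacent tokens within a single field; trailing truncation turns the
#' final word into a token-prefix match. Non-exploded MeSH lines match the
#' heading itself (case- and punctuation-insensitive); exploded lines also
#' match any tree descendant.
#'
#' @param node A leaf AST node from [parse_strategy()].
#' @param record One-row records tibble (or a list with `title`,
#'   `abstract`, `mesh`).
#' @param mesh_tree A [mesh_tree()]; an empty tree makes explosion behave
#'   as exact match.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_line <- function(node, record, mesh_tree = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- list(title = record$title, abstract = record$abstract,
                   mesh = record$mesh[[1]])
  }
  if (is.null(mesh_tree)) mesh_tree <- mesh_tree()
  switch(node$type,
    textword = {
      tt <- tokenize1(node$term)
      any(vapply(node$fields, function(f) {
        match_tokens(tokenize1(record[[f]] %||% ""), tt, node$truncated)
      }, logical(1)))
    },
    mesh = {
      have <- normalize_heading(record$mesh %||% character())
      want <- if (node$explode) {
        normalize_heading(mesh_descendants(mesh_tree, node$heading))
      } else {
        normalize_heading(node$heading)
      }
      any(want %in% have)
    },
    combo = stop("evaluate_line() is for leaf nodes; use apply_strategy()",
                 call. = FALSE)
  )
}

#' Run a strategy against a corpus
#'
#' Evaluates every line of the strategy over the whole corpus and returns
#' the ids matching the final line. Per-line match sets are attached for
#' inspection.
#'
#' @param strategy An `ovid_strategy` (or strategy text, which is parsed).
#' @param records A records tibble.
#' @param mesh_tree A [mesh_tree()] used for explosion; `NULL` or an empty
#'   tree degrades `exp` to exact match (with one warning per call if the
#'   strategy uses explosion).
#' @return Character vector of retrieved record ids, with attribute
#'   `line_matches`: a list (one element per line) of the ids matching that
#'   line.
#' @export
apply_strategy <- function(strategy, records, mesh_tree = NULL) {
  if (is.character(strategy)) strategy <- parse_strategy(strategy)
  stopifnot(inherits(strategy, "ovid_strategy"))
  records <- validate_records(records)
  empty_tree <- is.null(mesh_tree) ||
    length(mesh_tree$heading_to_treenums) == 0
  uses_exp <- any(vapply(strategy$lines, function(nd) {
    nd$type == "mesh" && nd$explode
  }, logical(1)))
  if (empty_tree && uses_exp) {
    warning("no MeSH tree supplied; exploded headings match exactly",
            call. = FALSE)
    mesh_tree <- mesh_tree()
  }
  if (is.null(mesh_tree)) mesh_tree <- mesh_tree()

  n <- nrow(records)
  title_tok <- tokenize(records$title)
  abs_tok <- tokenize(records$abstract)
  mesh_norm <- lapply(records$mesh, normalize_heading)

  hits <- matrix(FALSE, nrow = max(n, 0), ncol = length(strategy$lines))
  for (j in seq_along(strategy$lines)) {
    node <- strategy$lines[[j]]
    hits[, j] <- switch(node$type,
      textword = {
        tt <- tokenize1(node$term)
        res <- logical(n)
        if ("title" %in% node$fields) {
          res <- vapply(title_tok, match_tokens, logical(1),
                        term_tokens = tt, truncated = node$truncated)
        }
        if ("abstract" %in% node$fields) {
          res <- res | vapply(abs_tok, match_tokens, logical(1),
                              term_tokens = tt, truncated = node$truncated)
        }
        res
      },
      mesh = {
        want <- if (node$explode) {
          normalize_heading(mesh_descendants(mesh_tree, node$heading))
        } else {
          normalize_heading(node$heading)
        }
        vapply(mesh_norm, function(h) any(want %in% h), logical(1))
      },
      combo = {
        cols <- hits[, node$refs, drop = FALSE]
        switch(node$op,
          or = rowSums(cols) > 0,
          and = rowSums(cols) == length(node$refs),
          # "A not B [not C ...]": first operand minus the union of the rest
          not = if (length(node$refs) == 1) cols[, 1] else {
            cols[, 1] & rowSums(cols[, -1, drop = FALSE]) == 0
          }
        )
      }
    )
  }
  final <- if (n) hits[, ncol(hits)] else logical(0)
  out <- records$id[final]
  attr(out, "line_matches") <-
    lapply(seq_len(ncol(hits)), function(j) records$id[hits[, j]])
  out
}

# ---- Built-in strategies ----------------------------------------------------

pf_filter_text <- paste(
  "1 exp Risk/",
  "2 risk.tw",
  "3 exp Cohort Studies/",
  "4 cohort.tw",
  "5 exp Prognosis/",
  '6 "prognos*".tw',
  '7 "predict*".tw',
  "8 exp Incidence/",
  "9 incidence.tw",
  "10 exp Survival Analysis/",
  "11 survival.tw",
  '12 "causal factor".tw',
  "13 course.tw",
  "14 or/1–13",  # en-dash, as the strategy is published
  sep = "\n")

#' Built-in search strategies
#'
#' Returns the two strategies the package ships ready to run:
#'
#' * `pf_filter` — the 14-line prognostic factor filter for Ovid MEDLINE
#'   (five exploded MeSH headings, eight textword terms with `prognos*`
#'   and `predict*` truncated, OR-combined on the final line);
#' * `haynes_broad` — the Haynes broad prognosis filter, hand-translated
#'   from its PubMed form (`[MeSH:noexp]` as non-exploded heading,
#'   `[MeSH Terms]` as exploded heading, `[Text Word]` as `.tw`).
#'
#' @return Named list of `ovid_strategy` objects.
#' @examples
#' length(builtin_strategies()$pf_filter$lines)
#' @export
builtin_strategies <- function() {
  pf <- parse_strategy(pf_filter_text, name = "pf_filter")
  haynes <- structure(list(
    name = "haynes_broad",
    lines = list(
      mesh_node("Incidence", explode = FALSE),
      mesh_node("Mortality", explode = TRUE),
      mesh_node("Follow-Up Studies", explode = FALSE),
      textword_node("prognos", truncated = TRUE),
      textword_node("predict", truncated = TRUE),
      textword_node("course", truncated = TRUE),
      combo_node("or", 1:6)
    )
  ), class = "ovid_strategy")
  list(pf_filter = pf, haynes_broad = haynes)
}
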