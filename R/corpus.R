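#' Construct a tibble of bibliographic records
#'
#' A record corpus is a tibble with one row per bibliographic record and
#' columns `id` (character, unique, non-empty), `title` (character,
#' non-empty), `abstract` (character, possibly empty), `mesh` (list of
#' character vectors of MeSH headings, no duplicates within a record) and
#' `year` (integer, possibly `NA`). All corpus-consuming functions in the
#' package accept this shape.
#'
#' @param id Character vector of record identifiers (PMID-like, but treated
#'   as opaque text).
#' @param title Character vector of titles.
#' @param abstract Character vector of abstracts; `""` for records without
#'   one.
#' @param mesh List of character vectors of MeSH headings (subheadings and
#'   major-topic markers already stripped), or a single character vector
#'   recycled per record.
#' @param year Optional integer publication years.
#' @return A validated records tibble.
#' @examples
#' bib_records(id = c("1", "2"),
#'             title = c("Risk factors for X", "A cohort study of Y"),
#'             abstract = c("", "Survival was predicted."),
#'             mesh = list("Risk Factors", c("Cohort Studies", "Incidence")))
#' @export
bib_records <- function(id, title, abstract = "", mesh = list(character()),
                        year = NA_integer_) {
  n <- length(id)
  if (!is.list(mesh)) mesh <- list(as.character(mesh))
  records <- tibble::tibble(
    id = as.character(id),
    title = as.character(title),
    abstract = rep_len(as.character(abstract), n),
    mesh = rep_len(mesh, n),
    year = rep_len(suppressWarnings(as.integer(year)), n)
  )
  validate_records(records)
}

validate_records <- function(records, where = "records") {
  stopifnot(is.data.frame(records))
  need <- c("id", "title", "abstract", "mesh")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(where, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"year" %in% names(records)) records$year <- NA_integer_
  if (anyNA(records$id) || any(!nzchar(records$id))) {
    stop("every record needs a non-empty id", call. = FALSE)
  }
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup)) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(records$title) | !nzchar(records$title))
  if (length(bad)) {
    stop("record(s) with empty title: ",
         paste(records$id[bad], collapse = ", "), call. = FALSE)
  }
  records$abstract[is.na(records$abstract)] <- ""
  records$mesh <- lapply(records$mesh, function(m) unique(as.character(m)))
  tibble::as_tibble(records)
}

# ---- MEDLINE flat file (nbib-style) -----------------------------------------

#' Read bibliographic records from MEDLINE flat-file or RIS text
#'
#' The MEDLINE reader understands the PubMed "nbib" tag layout (`PMID- `,
#' `TI  - `, `AB  - `, `MH  - `, `DP  - `; continuation lines indented with
#' spaces; records separated by blank lines or a new `PMID`). MeSH values
#' are normalized: subheadings (anything after `/`) and major-topic `*`
#' markers are stripped, and duplicates removed. The RIS reader understands
#' the usual `TY`/`TI`/`T1`/`AB`/`N2`/`KW`/`ID`/`AN`/`PY`/`Y1`/`ER` tags,
#' with `KW` mapped to MeSH-like headings.
#'
#' @param path Path to a file, or a character vector of lines (anything
#'   containing a newline is treated as literal text).
#' @param format `"medline"` (default) or `"ris"`.
#' @return A records tibble (see [bib_records()]); records appear in file
#'   order.
#' @seealso [write_records()] for the inverse operation.
#' @export
read_records <- function(path, format = c("medline", "ris")) {
  format <- match.arg(format)
  lines <- read_input_lines(path)
  switch(format,
    medline = parse_medline(lines),
    ris = parse_ris(lines)
  )
}

read_input_lines <- function(path, must_exist = TRUE) {
  if (length(path) == 1 && !grepl("\n", path) && (must_exist ||
      file.exists(path))) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
}

strip_mesh_heading <- function(x) {
  x <- sub("/.*$", "", x)      # drop subheadings
  x <- gsub("\\*", "", x)      # drop major-topic markers
  trimws(x)
}

parse_medline <- function(lines) {
  entries <- list()
  cur <- NULL
  tag <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) entries[[length(entries) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      this_tag <- trimws(sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln))
      value <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      if (this_tag == "PMID" && !is.null(cur) && "PMID" %in% names(cur)) flush()
      if (is.null(cur)) cur <- list()
      tag <- this_tag
      cur[[tag]] <- c(cur[[tag]], value)
    } else if (grepl("^\\s+", ln) && !is.null(cur) && !is.null(tag)) {
      # continuation line: append to the last value of the open tag
      i <- length(cur[[tag]])
      cur[[tag]][i] <- paste(cur[[tag]][i], trimws(ln))
    }
    # anything else (stray text outside an entry) is ignored
  }
  flush()
  if (!length(entries)) return(bib_records(character(), character())[0, ])
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    id <- trimws(e[["PMID"]][1] %||% "")
    title <- trimws(paste(e[["TI"]] %||% "", collapse = " "))
    if (!nzchar(id)) stop("MEDLINE entry ", i, " has no PMID", call. = FALSE)
    if (!nzchar(title)) stop("MEDLINE entry ", i, " has no TI", call. = FALSE)
    year <- NA_integer_
    if (!is.null(e[["DP"]])) {
      y <- regmatches(e[["DP"]][1], regexpr("[0-9]{4}", e[["DP"]][1]))
      if (length(y)) year <- as.integer(y)
    }
    tibble::tibble(
      id = id, title = title,
      abstract = trimws(paste(e[["AB"]] %||% "", collapse = " ")),
      mesh = list(unique(strip_mesh_heading(e[["MH"]] %||% character()))),
      year = year
    )
  })
  validate_records(dplyr::bind_rows(rows))
}

parse_ris <- function(lines) {
  entries <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^[A-Z][A-Z0-9]\\s{2}-", ln)) {
      tag <- substr(ln, 1, 2)
      value <- trimws(sub("^[A-Z][A-Z0-9]\\s{2}-\\s?", "", ln))
      if (tag == "TY") cur <- list()
      if (is.null(cur)) next
      if (tag == "ER") {
        entries[[length(entries) + 1L]] <- cur
        cur <- NULL
      } else {
        cur[[tag]] <- c(cur[[tag]], value)
      }
    }
  }
  if (!length(entries)) return(bib_records(character(), character())[0, ])
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    id <- trimws((e[["ID"]] %||% e[["AN"]] %||% "")[1])
    title <- trimws(paste(e[["TI"]] %||% e[["T1"]] %||% "", collapse = " "))
    if (!nzchar(id)) stop("RIS entry ", i, " has no ID/AN", call. = FALSE)
    if (!nzchar(title)) stop("RIS entry ", i, " has no TI/T1", call. = FALSE)
    year <- NA_integer_
    py <- (e[["PY"]] %||% e[["Y1"]] %||% character())[1]
    if (length(py) && grepl("[0-9]{4}", py %||% "")) {
      year <- as.integer(regmatches(py, regexpr("[0-9]{4}", py)))
    }
    tibble::tibble(
      id = id, title = title,
      abstract = trimws(paste(e[["AB"]] %||% e[["N2"]] %||% "", collapse = " ")),
      mesh = list(unique(strip_mesh_heading(e[["KW"]] %||% character()))),
      year = year
    )
  })
  validate_records(dplyr::bind_rows(rows))
}

#' Write bibliographic records
#'
#' Serializes a records tibble back to MEDLINE flat-file or RIS text such
#' that [read_records()] round-trips to an equal corpus.
#'
#' @param records A records tibble.
#' @param path Output file path, or `NULL` to return the text invisibly.
#' @inheritParams read_records
#' @return The lines, invisibly.
#' @export
write_records <- function(records, path = NULL, format = c("medline", "ris")) {
  format <- match.arg(format)
  records <- validate_records(records)
  fmt_one <- function(i) {
    r <- records[i, ]
    mesh <- r$mesh[[1]]
    if (format == "medline") {
      out <- c(paste0("PMID- ", r$id), paste0("TI  - ", r$title))
      if (nzchar(r$abstract)) out <- c(out, paste0("AB  - ", r$abstract))
      out <- c(out, if (length(mesh)) paste0("MH  - ", mesh))
      if (!is.na(r$year)) out <- c(out, paste0("DP  - ", r$year))
      c(out, "")
    } else {
      c("TY  - JOUR",
        paste0("ID  - ", r$id),
        paste0("TI  - ", r$title),
        if (nzchar(r$abstract)) paste0("AB  - ", r$abstract),
        if (length(mesh)) paste0("KW  - ", mesh),
        if (!is.na(r$year)) paste0("PY  - ", r$year),
        "ER  - ", "")
    }
  }
  lines <- unlist(lapply(seq_len(nrow(records)), fmt_one), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---- Reference sets ---------------------------------------------------------

#' Reference set of known-relevant record ids
#'
#' A reference set (the "gold standard" in relative-recall evaluation) is
#' the set of records included in a systematic review, against which a
#' filtered search is scored.
#'
#' @param label Review label.
#' @param ids Character vector of record ids; de-duplicated.
#' @return An object of class `reference_set` with elements `label` and
#'   `ids`.
#' @export
reference_set <- function(label, ids) {
  ids <- as.character(ids)
  ids <- ids[nzchar(ids) & !is.na(ids)]
  if (!length(ids)) stop("reference set '", label, "' is empty", call. = FALSE)
  if (anyDuplicated(ids)) {
    warning("reference set '", label, "' has duplicate ids; de-duplicated",
            call. = FALSE)
    ids <- unique(ids)
  }
  structure(list(label = as.character(label), ids = ids),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", x$label, ": ", length(x$ids), " ids\n", sep = "")
  invisible(x)
}

#' Read a reference set from an id list
#'
#' One id per line; blank lines are ignored and repeated ids de-duplicated
#' (with a warning).
#'
#' @param path File path or literal text (see [read_records()]).
#' @param label Review label attached to the set.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path, label = "reference") {
  lines <- trimws(read_input_lines(path))
  reference_set(label, lines[nzchar(lines)])
}
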