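#' MeSH tree for query explosion
#'
#' A minimal representation of the MeSH hierarchy sufficient to interpret
#' exploded headings (`exp Heading/`): each heading owns one or more
#' dot-separated tree numbers, and X is a descendant of Y exactly when some
#' tree number of X extends a tree number of Y by one or more `.suffix`
#' components. Heading lookup is case-insensitive and ignores punctuation,
#' so `"Follow up studies"` and `"Follow-Up Studies"` name the same
#' heading.
#'
#' @param headings Character vector of headings (repeated when a heading
#'   has several tree numbers).
#' @param treenums Character vector of tree numbers, parallel to
#'   `headings`.
#' @return An object of class `mesh_tree` with elements
#'   `heading_to_treenums` (named list) and `treenum_to_heading` (named
#'   character vector).
#' @examples
#' tr <- mesh_tree(c("Risk", "Risk Factors"), c("N06.850", "N06.850.505"))
#' mesh_descendants(tr, "Risk")
#' @export
mesh_tree <- function(headings = character(), treenums = character()) {
  stopifnot(length(headings) == length(treenums))
  headings <- trimws(as.character(headings))
  treenums <- trimws(as.character(treenums))
  if (any(!nzchar(headings)) || any(!nzchar(treenums))) {
    stop("headings and tree numbers must be non-empty", call. = FALSE)
  }
  h2t <- split(treenums, headings)
  h2t <- lapply(h2t, unique)
  t2h <- setNames(rep(names(h2t), lengths(h2t)), unlist(h2t, use.names = FALSE))
  structure(
    list(heading_to_treenums = h2t, treenum_to_heading = t2h,
         key_to_heading = setNames(names(h2t), normalize_heading(names(h2t)))),
    class = "mesh_tree"
  )
}

normalize_heading <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' @export
print.mesh_tree <- function(x, ...) {
  cat("<mesh_tree> ", length(x$heading_to_treenums), " headings, ",
      length(x$treenum_to_heading), " tree numbers\n", sep = "")
  invisible(x)
}

#' Read a MeSH tree from two-column delimited text
#'
#' Each line holds `heading<TAB>tree.number` (tab, comma or semicolon
#' delimited); a heading may appear on several lines, one per tree number.
#' An empty file yields an empty tree, under which explosion degenerates to
#' exact heading match.
#'
#' @param path File path or literal text (see [read_records()]).
#' @return A [mesh_tree()].
#' @export
read_mesh_tree <- function(path) {
  lines <- read_input_lines(path, must_exist = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(mesh_tree())
  parts <- strsplit(lines, "[\t,;]")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("malformed MeSH tree line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  mesh_tree(trimws(m[, 1]), trimws(m[, 2]))
}

#' Look up a heading and its tree descendants
#'
#' @param tree A [mesh_tree()].
#' @param heading Heading to explode (case/punctuation-insensitive).
#' @return Character vector of headings: the heading itself (in the tree's
#'   canonical casing if known, otherwise as given) plus every strict
#'   descendant by the tree-number prefix rule.
#' @export
mesh_descendants <- function(tree, heading) {
  stopifnot(inherits(tree, "mesh_tree"))
  key <- normalize_heading(heading)
  canon <- tree$key_to_heading[key]
  if (is.na(canon)) return(as.character(heading))
  nums <- tree$heading_to_treenums[[canon]]
  all_nums <- names(tree$treenum_to_heading)
  hit <- unique(unlist(lapply(nums, function(n) {
    all_nums[startsWith(all_nums, paste0(n, "."))]
  }), use.names = FALSE))
  unique(c(canon, unname(tree$treenum_to_heading[hit])))
}

mesh_is_descendant <- function(tree, child, parent) {
  kids <- setdiff(normalize_heading(mesh_descendants(tree, parent)),
                  normalize_heading(parent))
  normalize_heading(child) %in% kids
}

#' A small synthetic MeSH tree for offline use
#'
#' Roughly twenty headings covering the hierarchy the built-in strategies
#' rely on (Risk and its factors, the cohort-study family including
#' Follow-Up Studies, Prognosis with Disease-Free Survival, Survival
#' Analysis, Incidence, Mortality) plus a few clinical fillers. Tree
#' numbers mimic MeSH style but are synthetic; the full MeSH vocabulary is
#' not shipped.
#'
#' @return A [mesh_tree()].
#' @export
toy_mesh_tree <- function() {
  tab <- c(
    "Risk",                  "N06.850",
    "Risk Factors",          "N06.850.505",
    "Risk Assessment",       "N06.850.520",
    "Cohort Studies",        "E05.318.760",
    "Longitudinal Studies",  "E05.318.760.500",
    "Follow-Up Studies",     "E05.318.760.500.400",
    "Prospective Studies",   "E05.318.760.500.750",
    "Retrospective Studies", "E05.318.760.600",
    "Prognosis",             "E01.789",
    "Disease-Free Survival", "E01.789.200",
    "Disease-Free Survival", "E05.318.740.600.200",
    "Survival Analysis",     "E05.318.740.600",
    "Survival Rate",         "E05.318.740.600.800",
    "Incidence",             "E05.318.308.985.525",
    "Prevalence",            "E05.318.308.985.525.750",
    "Mortality",             "E05.318.308.985.550",
    "Hospital Mortality",    "E05.318.308.985.550.300",
    "Depression",            "F03.600.300",
    "Neoplasms",             "C04",
    "Lung Neoplasms",        "C04.588.894",
    "Wound Healing",         "G16.100.856"
  )
  m <- matrix(tab, ncol = 2, byrow = TRUE)
  mesh_tree(m[, 1], m[, 2])
}
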