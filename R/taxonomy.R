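#' Structure-class taxonomy
#'
#' A taxonomy defines the set of canonical structure classes the classifier can
#' emit, plus the text prefixes that identify dose-optimization helper
#' structures. The default covers a prostate radiotherapy nomenclature with 22
#' trainable classes (9 organs at risk, 2 support structures, 1 GTV, and CTV +
#' PTV for five target scenarios) and one analysis-only `"Other"` class that
#' may appear as a ground-truth label but is never a model output.
#'
#' @param classes A data frame with columns `class_id` (contiguous integers
#'   from 0), `canonical_name`, `category` (one of `"OAR"`, `"support"`,
#'   `"GTV"`, `"CTV"`, `"PTV"`, `"other"`) and `dose_suffix_expected`.
#' @param optimization_prefixes Character vector of name prefixes (matched
#'   case-insensitively at the start of a structure name) that mark
#'   optimization structures.
#' @return An object of class `rtn_taxonomy`: a list with a `classes` tibble
#'   and the `optimization_prefixes`.
#' @examples
#' tax <- default_taxonomy()
#' nrow(trainable_classes(tax))  # 22
#' @export
taxonomy <- function(classes, optimization_prefixes) {
  classes <- tibble::as_tibble(classes)
  required <- c("class_id", "canonical_name", "category", "dose_suffix_expected")
  missing_cols <- setdiff(required, names(classes))
  if (length(missing_cols) > 0) {
    stop("taxonomy classes table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  classes$class_id <- as.integer(classes$class_id)
  if (anyDuplicated(classes$class_id) ||
      !identical(sort(classes$class_id), seq_len(nrow(classes)) - 1L)) {
    stop("class_id values must be unique and contiguous from 0", call. = FALSE)
  }
  if (anyDuplicated(classes$canonical_name) || any(!nzchar(classes$canonical_name))) {
    stop("canonical_name values must be unique and non-empty", call. = FALSE)
  }
  ok_cat <- c("OAR", "support", "GTV", "CTV", "PTV", "other")
  if (!all(classes$category %in% ok_cat)) {
    stop("category must be one of ", paste(ok_cat, collapse = ", "), call. = FALSE)
  }
  if (!is.character(optimization_prefixes) || any(!nzchar(optimization_prefixes))) {
    stop("optimization_prefixes must be non-empty strings", call. = FALSE)
  }
  structure(
    list(
      classes = classes[order(classes$class_id), , drop = FALSE],
      optimization_prefixes = optimization_prefixes
    ),
    class = "rtn_taxonomy"
  )
}

#' @export
print.rtn_taxonomy <- function(x, ...) {
  n_train <- nrow(trainable_classes(x))
  cat(sprintf("<rtn_taxonomy: %d trainable classes + %d analysis-only; %d optimization prefixes>\n",
              n_train, nrow(x$classes) - n_train, length(x$optimization_prefixes)))
  invisible(x)
}

#' @rdname taxonomy
#' @export
default_taxonomy <- function() {
  cls <- tibble::tribble(
    ~canonical_name,      ~category,  ~dose_suffix_expected,
    "Body",               "OAR",      FALSE,
    "Bladder",            "OAR",      FALSE,
    "Rectum",             "OAR",      FALSE,
    "FemoralHead_L",      "OAR",      FALSE,
    "FemoralHead_R",      "OAR",      FALSE,
    "PenileBulb",         "OAR",      FALSE,
    "BowelBag",           "OAR",      FALSE,
    "Genitalia",          "OAR",      FALSE,
    "AnalCanal",          "OAR",      FALSE,
    "CouchSurface",       "support",  FALSE,
    "CouchInterior",      "support",  FALSE,
    "GTV",                "GTV",      TRUE,
    "GlandCTV",           "CTV",      TRUE,
    "GlandPTV",           "PTV",      TRUE,
    "GlandVesiclesCTV",   "CTV",      TRUE,
    "GlandVesiclesPTV",   "PTV",      TRUE,
    "VesicleCTV",         "CTV",      TRUE,
    "VesiclePTV",         "PTV",      TRUE,
    "LymphNodesCTV",      "CTV",      TRUE,
    "LymphNodesPTV",      "PTV",      TRUE,
    "ProstateBedCTV",     "CTV",      TRUE,
    "ProstateBedPTV",     "PTV",      TRUE,
    "Other",              "other",    FALSE
  )
  cls$class_id <- seq_len(nrow(cls)) - 1L
  taxonomy(cls, optimization_prefixes = c("Tuning", "Help", "X", "Y", "Z", "Dose", "Match"))
}

#' Trainable classes of a taxonomy
#'
#' Classes with category `"other"` are analysis-only: they can occur as ground
#' truth (e.g. structures outside the training nomenclature) but are excluded
#' from the model's output layer.
#'
#' @param tax An `rtn_taxonomy`.
#' @return Tibble of the trainable class rows, ordered by `class_id`.
#' @export
trainable_classes <- function(tax) {
  stopifnot(inherits(tax, "rtn_taxonomy"))
  tax$classes[tax$classes$category != "other", , drop = FALSE]
}

#' Look up a class row by canonical name or id
#' @param tax An `rtn_taxonomy`.
#' @param name Canonical class name.
#' @param id Integer class id.
#' @return A one-row tibble.
#' @keywords internal
#' @export
class_by <- function(tax, name = NULL, id = NULL) {
  stopifnot(inherits(tax, "rtn_taxonomy"))
  if (!is.null(name)) {
    row <- tax$classes[tax$classes$canonical_name == name, , drop = FALSE]
  } else {
    row <- tax$classes[tax$classes$class_id == as.integer(id), , drop = FALSE]
  }
  if (nrow(row) != 1) stop("unknown class: ", if (is.null(name)) id else name, call. = FALSE)
  row
}

#' Is a structure name an optimization structure?
#'
#' Optimization ("tuning"/helper) structures shape the optimizer's dose
#' distribution and are excluded from classification and from all context
#' channels. They are recognized purely by name: the name must begin,
#' case-insensitively, with one of the taxonomy's configured prefixes
#' (default `Tuning, Help, X, Y, Z, Dose, Match`). No whitespace stripping is
#' performed beyond what the caller provides; matching is a plain
#' lower-cased `startsWith`.
#'
#' @param name Character vector of structure names (non-empty).
#' @param tax An `rtn_taxonomy` (default [default_taxonomy()]).
#' @return Logical vector.
#' @examples
#' is_optimization_structure(c("Tuning_rectum", "PTV 78Gy", "xBase"))
#' @export
is_optimization_structure <- function(name, tax = default_taxonomy()) {
  stopifnot(inherits(tax, "rtn_taxonomy"))
  if (length(name) == 0 || !is.character(name) || any(is.na(name)) || any(!nzchar(name))) {
    stop("structure names must be non-empty strings", call. = FALSE)
  }
  lowered <- tolower(name)
  prefixes <- tolower(tax$optimization_prefixes)
  vapply(lowered, function(nm) any(startsWith(nm, prefixes)), logical(1), USE.NAMES = FALSE)
}

#' Balanced class weights from label counts
#'
#' Computes inverse-frequency ("balanced") weights used in the weighted
#' categorical cross-entropy loss: `w_c = N_total / (K * n_c)` for `K` classes
#' with counts `n_c`. Equal counts give unit weights for every class.
#'
#' @param label_counts Named numeric vector of per-class counts (names are
#'   class ids or canonical names); every count must be >= 1.
#' @return Named numeric vector of strictly positive weights.
#' @examples
#' compute_class_weights(c(A = 10, B = 10, C = 20))
#' @export
compute_class_weights <- function(label_counts) {
  if (length(label_counts) == 0) stop("no classes given", call. = FALSE)
  counts <- as.numeric(label_counts)
  zero <- counts < 1 | is.na(counts)
  if (any(zero)) {
    stop("class(es) with zero training count: ",
         paste(names(label_counts)[zero], collapse = ", "), call. = FALSE)
  }
  w <- sum(counts) / (length(counts) * counts)
  names(w) <- names(label_counts)
  w
}

#' Extract a prescription-dose token from a structure name
#'
#' Clinical target names often embed the prescribed dose (e.g. `"PTV 78Gy"`,
#' `"ctv prost 42,7 gy"`). The first token of the form *number* (optional
#' decimal part with `.` or `,`) followed by an optional space and a
#' case-insensitive `Gy` unit is extracted and normalized to `"<number>Gy"`
#' with a decimal point. Absence of a token is a valid result (`NA`).
#'
#' @param name Character vector of structure names.
#' @return Character vector of normalized dose tokens, `NA` where none found.
#' @examples
#' extract_dose_token(c("PTV 78Gy", "Bladder", "CTV1 42.7 gy"))
#' @export
extract_dose_token <- function(name) {
  stopifnot(is.character(name))
  pattern <- "([0-9]+([.,][0-9]+)?)\\s*[Gg][Yy]"
  m <- regexpr(pattern, name, perl = TRUE)
  out <- rep(NA_character_, length(name))
  hit <- m > 0
  if (any(hit)) {
    token <- regmatches(name, m)
    num <- sub("\\s*[Gg][Yy]$", "", token)
    num <- gsub(",", ".", num, fixed = TRUE)
    out[hit] <- paste0(num, "Gy")
  }
  out
}

#' Read / write a taxonomy configuration
#'
#' The taxonomy is serialized as a small versioned JSON document so clinics can
#' override class definitions without touching code.
#'
#' @param tax An `rtn_taxonomy`.
#' @param path File path of the JSON config.
#' @return `write_taxonomy` returns `path` invisibly; `read_taxonomy` returns
#'   an `rtn_taxonomy`.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "rtn_taxonomy"))
  doc <- list(
    format = "rtnamer-taxonomy",
    version = 1L,
    optimization_prefixes = tax$optimization_prefixes,
    classes = tax$classes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "rtnamer-taxonomy")) {
    stop("not a taxonomy config: ", path, call. = FALSE)
  }
  taxonomy(doc$classes, doc$optimization_prefixes)
}

#' Read a class-label correction table
#'
#' Mirrors a clinical "class label correction file": a CSV with columns
#' `subject_id`, `original_name`, `corrected_class_id` that overrides the
#' name-derived ground-truth label for specific structures when building a
#' training feature store.
#'
#' @param path CSV path.
#' @return Tibble with the three columns, `corrected_class_id` integer.
#' @export
read_corrections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "original_name", "corrected_class_id")
  if (!all(required %in% names(df))) {
    stop("correction file must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df$corrected_class_id <- as.integer(df$corrected_class_id)
  tibble::as_tibble(df[required])
}
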