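#' Define a multimethod multi-situation measurement design
#'
#' An MM-LST-RF design crosses `indicators` (i) within `methods` (m),
#' measured on `occasions` (t) in each fixed `situations` (s). The number of
#' manifest variables is the product of the four dimensions; the indicator
#' count is assumed equal across methods.
#'
#' The full MM-LST-RF model needs at least two indicators per method and at
#' least two occasions. `methods = 1` and/or `situations = 1` are accepted and
#' yield the reduced LST-RF / MM-LST model families when a model is built from
#' the design.
#'
#' @param indicators number of indicators per method (I >= 1).
#' @param methods number of methods (M >= 1).
#' @param occasions number of measurement occasions (T >= 1).
#' @param situations number of fixed situations (S >= 1).
#' @param indicator_names,method_names,occasion_names,situation_names optional
#'   label vectors, recycled into default labels when `NULL`.
#' @param max_dim upper bound per dimension (mirrors the interactive
#'   interface's limit of 25).
#' @return an object of class `mmDesign`.
#' @examples
#' d <- mmDesign(indicators = 3, methods = 2, occasions = 2, situations = 2)
#' d$n_manifest  # 24
#' @export
mmDesign <- function(indicators, methods = 1L, occasions = 2L, situations = 1L,
                     indicator_names = NULL, method_names = NULL,
                     occasion_names = NULL, situation_names = NULL,
                     max_dim = 25L) {
  dims <- c(indicators = indicators, methods = methods,
            occasions = occasions, situations = situations)
  for (nm in names(dims)) {
    v <- dims[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("invalid design: `", nm, "` must be a positive integer, got ",
           deparse(v), call. = FALSE)
    if (v > max_dim)
      stop("invalid design: `", nm, "` exceeds the supported maximum of ",
           max_dim, call. = FALSE)
  }
  dims <- as.integer(dims)
  names(dims) <- c("I", "M", "T", "S")

  chk_labels <- function(x, n, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != n)
      stop("`", what, "` must have length ", n, call. = FALSE)
    as.character(x)
  }
  des <- structure(list(
    I = dims[["I"]], M = dims[["M"]], `T` = dims[["T"]], S = dims[["S"]],
    n_manifest = prod(dims),
    indicator_names = chk_labels(indicator_names, dims[["I"]], "indicator_names"),
    method_names    = chk_labels(method_names, dims[["M"]], "method_names"),
    occasion_names  = chk_labels(occasion_names, dims[["T"]], "occasion_names"),
    situation_names = chk_labels(situation_names, dims[["S"]], "situation_names")
  ), class = "mmDesign")
  des
}

#' @export
print.mmDesign <- function(x, ...) {
  cat("MM-LST-RF measurement design\n")
  cat(sprintf("  indicators per method (I): %d\n", x$I))
  cat(sprintf("  methods (M):               %d\n", x$M))
  cat(sprintf("  occasions (T):             %d\n", x$`T`))
  cat(sprintf("  fixed situations (S):      %d\n", x$S))
  cat(sprintf("  manifest variables:        %d\n", x$n_manifest))
  invisible(x)
}

is_mmDesign <- function(x) inherits(x, "mmDesign")

stopifnot_design <- function(design) {
  if (!is_mmDesign(design)) stop("`design` must be an mmDesign object", call. = FALSE)
  invisible(design)
}

#' Ordered manifest-variable layout of a design
#'
#' Returns the (i, m, t, s) index tuple for every manifest variable, in column
#' order: grouped first by fixed situation, then occasion, then method, with
#' the indicator index varying fastest.
#'
#' @param design an [mmDesign()] object.
#' @return a data.frame with integer columns `i`, `m`, `t`, `s` and a `name`
#'   column holding the default variable name `S{s}T{t}M{m}I{i}`.
#' @export
manifestLayout <- function(design) {
  stopifnot_design(design)
  g <- expand.grid(i = seq_len(design$I), m = seq_len(design$M),
                   t = seq_len(design$`T`), s = seq_len(design$S),
                   KEEP.OUT.ATTRS = FALSE)
  g$name <- sprintf("S%dT%dM%dI%d", g$s, g$t, g$m, g$i)
  g
}

#' Default manifest-variable names for a design
#'
#' @param design an [mmDesign()] object.
#' @return character vector of length `design$n_manifest`.
#' @export
manifestNames <- function(design) manifestLayout(design)$name

# ---- wide data container ----------------------------------------------------

#' Construct a wide-format dataset bound to a design
#'
#' One row per subject, one column per manifest variable, columns in the
#' design's layout order ([manifestLayout()]). Column names of `x` are kept
#' but mapped positionally; the design imposes the order, not the names.
#'
#' @param x matrix or data.frame of numeric values (`NA` = missing).
#' @param design an [mmDesign()] object.
#' @return object of class `mmData` with elements `values` (numeric matrix),
#'   `missing` (logical matrix), `design`, `n_subjects`.
#' @export
asWideData <- function(x, design) {
  stopifnot_design(design)
  if (is.data.frame(x)) {
    non_num <- !vapply(x, is.numeric, logical(1))
    if (any(non_num))
      stop("non-numeric column(s): ", paste(names(x)[non_num], collapse = ", "),
           call. = FALSE)
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix or data.frame", call. = FALSE)
  if (ncol(x) != design$n_manifest)
    stop(sprintf("layout error: expected %d columns (I*M*T*S) but found %d",
                 design$n_manifest, ncol(x)), call. = FALSE)
  cn <- colnames(x)
  if (is.null(cn)) cn <- manifestNames(design)
  colnames(x) <- cn
  structure(list(values = x, missing = is.na(x), design = design,
                 n_subjects = nrow(x)),
            class = "mmData")
}

#' @export
print.mmData <- function(x, ...) {
  cat(sprintf("mmData: %d subjects x %d manifest variables (%.1f%% missing)\n",
              x$n_subjects, ncol(x$values), 100 * mean(x$missing)))
  invisible(x)
}

#' Read a wide-format CSV file against a design
#'
#' The file must have a header row and one row per subject; columns must be in
#' the design's layout order (situation slowest, indicator fastest). Cells
#' matching one of `na_tokens` become missing values.
#'
#' @param path path to a CSV file.
#' @param design an [mmDesign()] object.
#' @param na_tokens strings treated as missing.
#' @return an `mmData` object.
#' @export
readWideData <- function(path, design, na_tokens = c("NA", "", "NaN")) {
  stopifnot_design(design)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  if (ncol(raw) != design$n_manifest)
    stop(sprintf("layout error: expected %d columns (I*M*T*S) but found %d in %s",
                 design$n_manifest, ncol(raw), path), call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    is_na <- cell %in% na_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value %s at row %d, column %d (%s)",
                   dQuote(cell[bad[1]]), bad[1], j, names(raw)[j]), call. = FALSE)
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  asWideData(vals, design)
}

#' Write an `mmData` object to CSV
#'
#' Round-trips with [readWideData()]: observed cells are reproduced exactly,
#' missing cells are written as `"NA"`.
#'
#' @param data an `mmData` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWideData <- function(data, path) {
  stopifnot(inherits(data, "mmData"))
  utils::write.csv(as.data.frame(data$values), path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' Screen a dataset for structural problems
#'
#' Report-only check of a wide dataset against its design: per-column missing
#' rates, all-missing columns, zero-variance columns, and subjects with no
#' observed values.
#'
#' @param data an `mmData` object.
#' @param design optional design (defaults to the one attached to `data`).
#' @return a list of class `mmValidation` with a per-column summary table and
#'   an `issues` character vector (empty when the data look clean).
#' @export
validateData <- function(data, design = data$design) {
  stopifnot(inherits(data, "mmData"))
  stopifnot_design(design)
  v <- data$values
  miss_rate <- colMeans(data$missing)
  obs_var <- apply(v, 2, function(col) stats::var(col[!is.na(col)]))
  all_missing <- miss_rate >= 1
  zero_var <- !all_missing & !is.na(obs_var) & obs_var == 0
  empty_subjects <- which(rowSums(!data$missing) == 0)

  issues <- character(0)
  if (any(all_missing))
    issues <- c(issues, paste0("all-missing column(s): ",
                               paste(colnames(v)[all_missing], collapse = ", ")))
  if (any(zero_var))
    issues <- c(issues, paste0("zero-variance column(s): ",
                               paste(colnames(v)[zero_var], collapse = ", ")))
  if (length(empty_subjects))
    issues <- c(issues, paste0("subject(s) with no observed values: ",
                               paste(empty_subjects, collapse = ", ")))
  structure(list(
    columns = data.frame(name = colnames(v), missing_rate = miss_rate,
                         variance = obs_var, row.names = NULL),
    all_missing = colnames(v)[all_missing],
    zero_variance = colnames(v)[zero_var],
    empty_subjects = empty_subjects,
    issues = issues
  ), class = "mmValidation")
}

#' @export
print.mmValidation <- function(x, ...) {
  if (!length(x$issues)) {
    cat("No structural issues found.\n")
  } else {
    cat("Issues:\n")
    for (i in x$issues) cat(" -", i, "\n")
  }
  cat(sprintf("Mean per-column missing rate: %.3f\n",
              mean(x$columns$missing_rate)))
  invisible(x)
}
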