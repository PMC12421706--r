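#' Export a model as SEM model-description text
#'
#' Writes the model graph in the lavaan dialect: `=~` measurement lines,
#' `~` regressions, `~~` (co)variances, `~ 1` intercept/mean lines. Fixed
#' values appear as numeric pre-multipliers (`1*y`), equality constraints as
#' shared label pre-multipliers (`lab*y`). Re-parsing the exported text with
#' [parseSyntax()] recovers the same free-parameter count and degrees of
#' freedom.
#'
#' @param model an `mmModel` object.
#' @param file optional path; when given the text is also written to it.
#' @return the model syntax as a single character string.
#' @export
exportSyntax <- function(model, file = NULL) {
  stopifnot_model(model)
  pt <- model$partable
  term <- function(r, target) {
    if (!pt$free[r]) paste0(format(pt$value[r], digits = 12), "*", target)
    else if (nzchar(pt$label[r])) paste0(pt$label[r], "*", target)
    else target
  }
  lines <- character(0)
  meas <- which(pt$op == "=~")
  for (lv in unique(pt$lhs[meas])) {
    rows <- meas[pt$lhs[meas] == lv]
    lines <- c(lines, paste(lv, "=~",
                            paste(vapply(rows, function(r) term(r, pt$rhs[r]),
                                         character(1)), collapse = " + ")))
  }
  regs <- which(pt$op == "~")
  for (lhs in unique(pt$lhs[regs])) {
    rows <- regs[pt$lhs[regs] == lhs]
    lines <- c(lines, paste(lhs, "~",
                            paste(vapply(rows, function(r) term(r, pt$rhs[r]),
                                         character(1)), collapse = " + ")))
  }
  for (r in which(pt$op == "~~"))
    lines <- c(lines, paste(pt$lhs[r], "~~", term(r, pt$rhs[r])))
  for (r in which(pt$op == "~1"))
    lines <- c(lines, paste(pt$lhs[r], "~", term(r, "1")))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  txt
}

# Parse one term like "0.5*y", "lab*y", "NA*y", "y", "1", "0*1".
parse_term <- function(tok, line) {
  tok <- trimws(tok)
  if (!nzchar(tok)) stop("malformed line (empty term): ", line, call. = FALSE)
  parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
  if (length(parts) == 1L)
    return(list(target = parts[1], free = TRUE, value = NA_real_, label = ""))
  if (length(parts) != 2L)
    stop("malformed term '", tok, "' in line: ", line, call. = FALSE)
  modif <- trimws(parts[1]); target <- trimws(parts[2])
  if (identical(modif, "NA"))
    return(list(target = target, free = TRUE, value = NA_real_, label = ""))
  num <- suppressWarnings(as.numeric(modif))
  if (!is.na(num))
    return(list(target = target, free = FALSE, value = num, label = ""))
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", modif))
    stop("malformed modifier '", modif, "' in line: ", line, call. = FALSE)
  list(target = target, free = TRUE, value = NA_real_, label = modif)
}

#' Parse model-description text
#'
#' Accepts the restricted lavaan-dialect grammar used by [exportSyntax()]:
#' one specification per line, operators `=~`, `~~`, `~`, intercepts as
#' `~ <modifier>*1`, fixed values as numeric pre-multipliers, equality labels
#' as name pre-multipliers, `NA*` for an explicitly free parameter, and `#`
#' comments. Anything else is rejected.
#'
#' @param text character scalar or vector of syntax lines.
#' @return a minimal `mmModel`-compatible object (parameter table, manifests,
#'   latents) suitable for [degreesOfFreedom()] and free-parameter counting.
#' @export
parseSyntax <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- pt_empty()
  for (line in lines) {
    op <- if (grepl("=~", line, fixed = TRUE)) "=~"
    else if (grepl("~~", line, fixed = TRUE)) "~~"
    else if (grepl("~", line, fixed = TRUE)) "~"
    else stop("malformed line (no operator): ", line, call. = FALSE)
    halves <- strsplit(line, op, fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      stop("malformed line: ", line, call. = FALSE)
    lhs <- trimws(halves[1])
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", lhs))
      stop("malformed left-hand side '", lhs, "' in line: ", line, call. = FALSE)
    for (tok in strsplit(halves[2], "+", fixed = TRUE)[[1]]) {
      tm <- parse_term(tok, line)
      if (op == "~" && tm$target == "1") {
        rows <- pt_bind(rows, pt_row(lhs, "~1", "", free = tm$free,
                                     value = ifelse(is.na(tm$value), 0, tm$value),
                                     label = tm$label, family = "custom"))
      } else {
        if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", tm$target))
          stop("malformed variable name '", tm$target, "' in line: ", line,
               call. = FALSE)
        default_start <- if (op != "~~") 1
        else if (lhs == tm$target) 0.5 else 0
        rows <- pt_bind(rows, pt_row(lhs, op, tm$target, free = tm$free,
                                     value = ifelse(is.na(tm$value),
                                                    default_start, tm$value),
                                     label = tm$label, family = "custom"))
      }
    }
  }
  # Manifest variables are the indicators (right-hand side of "=~"); every
  # other variable is latent, including phantom latents that only appear in
  # regressions or covariances. With no measurement lines at all, every
  # variable is manifest.
  all_names <- unique(c(rows$lhs, rows$rhs[nzchar(rows$rhs)]))
  if (any(rows$op == "=~")) {
    manifests <- unique(rows$rhs[rows$op == "=~"])
    lat_names <- setdiff(all_names, manifests)
  } else {
    manifests <- all_names
    lat_names <- character(0)
  }
  structure(list(
    design = NULL,
    options = list(mean_structure = any(rows$op == "~1")),
    partable = rows,
    latents = data.frame(name = lat_names,
                         kind = rep("parsed", length(lat_names)),
                         i = rep(NA_integer_, length(lat_names)),
                         m = rep(NA_integer_, length(lat_names)),
                         t = rep(NA_integer_, length(lat_names)),
                         s = rep(NA_integer_, length(lat_names))),
    manifests = manifests,
    skipped_constraints = character(0),
    log = character(0)
  ), class = "mmModel")
}

#' Apply custom model-syntax lines to a model
#'
#' Each line uses the restricted grammar of [parseSyntax()] and must refer to
#' variables that already exist in the model (manifest or latent). Lines that
#' target an existing parameter override it (the conflict is logged in
#' `model$log`); otherwise a new entry is added.
#'
#' @param model an `mmModel` object.
#' @param lines character vector of syntax lines.
#' @return the modified `mmModel`.
#' @export
addCustomLines <- function(model, lines) {
  stopifnot_model(model)
  if (!length(lines)) return(model)
  parsed <- parseSyntax(lines)
  known <- c(model$manifests, model$latents$name)
  pt <- model$partable
  pp <- parsed$partable
  for (r in seq_len(nrow(pp))) {
    vars <- c(pp$lhs[r], if (nzchar(pp$rhs[r])) pp$rhs[r])
    unknown <- setdiff(vars, known)
    if (length(unknown))
      stop("parse error: unknown model variable '", unknown[1],
           "' in custom line", call. = FALSE)
    hit <- pt_match(pt, pp$lhs[r], pp$op[r], pp$rhs[r])
    if (length(hit)) {
      hit <- hit[1]
      changed <- pt$free[hit] != pp$free[r] ||
        (!pp$free[r] && pt$value[hit] != pp$value[r]) ||
        (nzchar(pp$label[r]) && pt$label[hit] != pp$label[r])
      if (changed)
        model$log <- c(model$log,
                       sprintf("custom line overrides %s %s %s", pp$lhs[r],
                               pp$op[r], pp$rhs[r]))
      pt$free[hit] <- pp$free[r]
      pt$value[hit] <- pp$value[r]
      if (nzchar(pp$label[r])) pt <- pt_equate(pt, hit, pp$label[r])
      else if (!pp$free[r]) pt$label[hit] <- ""
    } else {
      newrow <- pp[r, , drop = FALSE]
      if (newrow$free && newrow$op == "~~") newrow$value <- 0
      pt <- pt_bind(pt, newrow)
      if (nzchar(newrow$label)) pt <- pt_equate(pt, nrow(pt), newrow$label)
    }
  }
  model$partable <- pt
  model
}
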