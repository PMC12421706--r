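#' Assemble the report artifacts for a fitted model
#'
#' Writes four files into `out`: the model syntax (`model.lav`), a JSON dump
#' of the fit (`fit.json`), the coefficient table (`coefficients.csv`), and a
#' plain-text report (`report.txt`) with three sections mirroring the usual
#' output panels: model summary (estimator, free parameters, sample size,
#' chi-square p-value) with coefficients, fit indices with benchmark
#' annotations and the parameter table, and the generated model syntax.
#'
#' @param fit an `mmFit` object.
#' @param coeffs an `mmCoefficients` object (or `NULL` to recompute).
#' @param model the `mmModel`; defaults to the fitted one.
#' @param out output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeReport <- function(fit, coeffs = NULL, model = fit$model, out = ".") {
  stopifnot(inherits(fit, "mmFit"))
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory ", out,
                  call. = FALSE)
  }
  if (is.null(coeffs) && !is.null(model$design))
    coeffs <- tryCatch(lstCoefficients(fit), error = function(e) NULL)

  syntax_file <- file.path(out, "model.lav")
  exportSyntax(model, file = syntax_file)

  fit_file <- file.path(out, "fit.json")
  writeFitJson(fit, fit_file)

  coef_file <- file.path(out, "coefficients.csv")
  if (!is.null(coeffs)) writeCoefficients(coeffs, coef_file)

  report_file <- file.path(out, "report.txt")
  con <- file(report_file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("== Model Summary & Coefficients ==")
  w(sprintf("Estimator:        %s", fit$estimator))
  w(sprintf("Free parameters:  %d", fit$n_free))
  w(sprintf("Sample size:      %d", fit$n))
  w(sprintf("Chi-square:       %.3f (df = %d, p = %.4g)", fit$chisq, fit$df,
            fit$pvalue))
  if (!fit$converged) w("WARNING: convergence not certain")
  if (length(fit$negative_variances))
    w("WARNING: negative variance estimate(s): ",
      paste(fit$negative_variances, collapse = ", "))
  if (!is.null(coeffs)) {
    w("")
    w("Indicator coefficients (Con = consistency, Spe = occasion specificity,")
    w("Rel = reliability):")
    tab <- coeffs$indicators
    for (r in seq_len(nrow(tab)))
      w(sprintf("  %-14s Con=%.3f Spe=%.3f Method=%.3f Rel=%.3f",
                tab$name[r], tab$con[r], tab$spe[r], tab$method_share[r],
                tab$rel[r]))
    if (!is.null(coeffs$trait)) {
      w("")
      w("Trait commonality / situation specificity:")
      for (r in seq_len(nrow(coeffs$trait)))
        w(sprintf("  %-16s Corr=%.3f Comm=%.3f SitSpe=%.3f",
                  coeffs$trait$pair[r], coeffs$trait$corr[r],
                  coeffs$trait$comm[r], coeffs$trait$sitspe[r]))
    }
  }
  w("")
  w("== Model Fit & Parameters ==")
  ix <- fit$indices
  mark <- function(ok) if (isTRUE(ok)) "acceptable" else "poor"
  w(sprintf("chisq/df = %.3f (%s; benchmark <= 3)", ix$chisq_df_ratio,
            mark(ix$benchmarks$chisq_df_ok)))
  w(sprintf("CFI   = %.3f (%s; benchmark >= 0.90)", ix$cfi,
            mark(ix$benchmarks$cfi_ok)))
  w(sprintf("TLI   = %.3f (%s; benchmark >= 0.90)", ix$tli,
            mark(ix$benchmarks$tli_ok)))
  w(sprintf("RMSEA = %.3f [%.3f, %.3f] (%s; benchmark <= 0.08)", ix$rmsea,
            ix$rmsea_ci[1], ix$rmsea_ci[2], mark(ix$benchmarks$rmsea_ok)))
  w(sprintf("SRMR  = %.3f (%s; benchmark <= 0.10)", ix$srmr,
            mark(ix$benchmarks$srmr_ok)))
  w(sprintf("AIC = %.2f, BIC = %.2f", ix$aic, ix$bic))
  w("")
  w("Parameter estimates:")
  pe <- standardErrors(fit)
  for (r in seq_len(nrow(pe)))
    w(sprintf("  %-24s est=%9.4f se=%8.4f z=%8.3f", pe$parameter[r],
              pe$estimate[r], pe$se[r], pe$z[r]))
  w("")
  w("== Model Syntax ==")
  w(exportSyntax(model))

  files <- c(syntax = syntax_file, fit = fit_file,
             coefficients = coef_file, report = report_file)
  invisible(files)
}

writeFitJson <- function(fit, path) {
  obj <- list(
    estimator = fit$estimator,
    n = fit$n, n_free = fit$n_free,
    loglik = fit$loglik, loglik_sat = fit$loglik_sat,
    loglik_base = fit$loglik_base,
    chisq = fit$chisq, df = fit$df, pvalue = fit$pvalue,
    indices = fit$indices[c("cfi", "tli", "rmsea", "srmr", "aic", "bic")],
    converged = fit$converged,
    admissible = fit$admissible,
    negative_variances = as.list(fit$negative_variances),
    estimates = as.list(fit$estimates),
    se = as.list(fit$se)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

cli_log <- function(con, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

cli_take <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args))
    stop("flag ", flag, " expects a value", call. = FALSE)
  args[i[1] + 1]
}

cli_has <- function(args, flag) flag %in% args

#' Command-line entry point
#'
#' Runs the full pipeline -- load or simulate data, build the model, fit it,
#' compute coefficients, optionally run an invariance sequence -- and writes
#' the artifacts (model syntax, fit JSON, coefficient CSV, text report, log)
#' into the output directory. Designed to be called from a thin Rscript
#' wrapper (see `inst/cli/lstmm.R`).
#'
#' Flags: `--data FILE` or `--simulate simulated_like|real_like`;
#' `--indicators/--methods/--occasions/--situations N` (indicators are
#' derived from the column count when omitted); `--structural
#' none|traits|tm|both`; `--cov-trait --cov-trait-method --cov-occasion
#' --cov-occasion-method`; `--no-om-factors`; `--mean-structure`;
#' `--invariance-methods LEVEL`, `--invariance-situations LEVEL`;
#' `--equivalence-trait/--equivalence-occasion/--equivalence-om LEVEL`;
#' `--missing listwise|fiml`; `--extra-syntax FILE`; `--fit`;
#' `--invariance-sequence methods|situations`; `--seed N`; `--out DIR`;
#' `--config FILE` (JSON or YAML; explicit flags win).
#'
#' @param args character vector of command-line arguments.
#' @return exit status, 0 on success (invisibly).
#' @export
runCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- 0L
  logcon <- NULL
  stage <- "setup"
  tryCatch({
    cfg <- list()
    cfg_file <- cli_take(args, "--config")
    if (!is.null(cfg_file)) {
      if (grepl("\\.ya?ml$", cfg_file)) {
        if (!requireNamespace("yaml", quietly = TRUE))
          stop("YAML config requires the 'yaml' package; use JSON instead",
               call. = FALSE)
        cfg <- yaml::read_yaml(cfg_file)
      } else cfg <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    }
    getopt <- function(flag, key, default = NULL) {
      v <- cli_take(args, flag)
      if (!is.null(v)) return(v)
      if (!is.null(cfg[[key]])) return(cfg[[key]])
      default
    }
    getflag <- function(flag, key) {
      cli_has(args, flag) || isTRUE(cfg[[key]])
    }

    out <- getopt("--out", "out", "lstmm-output")
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    logcon <- file(file.path(out, "run.log"), "w")
    on.exit(if (!is.null(logcon)) close(logcon), add = TRUE)
    seed <- as.integer(getopt("--seed", "seed", 1))

    stage <- "load"
    sim <- getopt("--simulate", "simulate")
    data_path <- getopt("--data", "data")
    M <- as.integer(getopt("--methods", "methods", 1))
    TT <- as.integer(getopt("--occasions", "occasions", 2))
    S <- as.integer(getopt("--situations", "situations", 1))
    if (!is.null(sim)) {
      dat <- exampleData(sim, seed = seed)
      design <- dat$design
      cli_log(logcon, stage, sprintf("simulated '%s' dataset: %d x %d", sim,
                                     dat$n_subjects, ncol(dat$values)))
    } else if (!is.null(data_path)) {
      if (!file.exists(data_path))
        stop("file not found: ", data_path, call. = FALSE)
      I <- getopt("--indicators", "indicators")
      if (is.null(I)) {
        ncols <- length(utils::read.csv(data_path, header = TRUE, nrows = 1,
                                        check.names = FALSE))
        I <- ncols / (M * TT * S)
        if (I != round(I))
          stop(sprintf("cannot derive indicator count: %d columns not divisible by M*T*S = %d",
                       ncols, M * TT * S), call. = FALSE)
      }
      design <- mmDesign(as.integer(I), M, TT, S)
      dat <- readWideData(data_path, design)
      cli_log(logcon, stage, sprintf("loaded %s: %d x %d", data_path,
                                     dat$n_subjects, ncol(dat$values)))
    } else stop("either --data or --simulate is required", call. = FALSE)

    val <- validateData(dat)
    for (issue in val$issues) cli_log(logcon, stage, paste("data issue:", issue))

    stage <- "build"
    structural <- switch(getopt("--structural", "structural", "none"),
                         none = "measurement_only",
                         traits = "trait_interactions",
                         tm = "trait_method_interactions",
                         both = "both",
                         stop("unknown --structural value", call. = FALSE))
    extra_file <- getopt("--extra-syntax", "extra_syntax")
    extra <- if (!is.null(extra_file)) readLines(extra_file) else character(0)
    options <- mmOptions(
      structural = structural,
      cov_trait = getflag("--cov-trait", "cov_trait"),
      cov_trait_method = getflag("--cov-trait-method", "cov_trait_method"),
      cov_occasion = getflag("--cov-occasion", "cov_occasion"),
      cov_occasion_method = getflag("--cov-occasion-method", "cov_occasion_method"),
      include_om_factors = !getflag("--no-om-factors", "no_om_factors"),
      mean_structure = getflag("--mean-structure", "mean_structure"),
      invariance_methods = getopt("--invariance-methods", "invariance_methods",
                                  "configural"),
      invariance_situations = getopt("--invariance-situations",
                                     "invariance_situations", "configural"),
      equivalence_trait = getopt("--equivalence-trait", "equivalence_trait",
                                 "parallelity"),
      equivalence_occasion = getopt("--equivalence-occasion",
                                    "equivalence_occasion",
                                    "essential_equivalence"),
      equivalence_om = getopt("--equivalence-om", "equivalence_om",
                              "essential_equivalence"),
      extra_lines = extra,
      missing = getopt("--missing", "missing", "listwise"))
    model <- buildModel(design, options)
    cli_log(logcon, stage,
            sprintf("model built: %d free parameters, df = %d",
                    pt_n_free(model$partable), degreesOfFreedom(model)))

    stage <- "fit"
    do_fit <- getflag("--fit", "fit") || is.null(getopt("--invariance-sequence",
                                                        "invariance_sequence"))
    if (do_fit) {
      warns <- character(0)
      fit <- withCallingHandlers(
        fitModel(dat, model, seed = seed),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      for (wmsg in warns) cli_log(logcon, stage, paste("WARNING:", wmsg))
      cli_log(logcon, stage,
              sprintf("fit complete: loglik = %.3f, chisq = %.3f, df = %d",
                      fit$loglik, fit$chisq, fit$df))
      stage <- "report"
      coeffs <- tryCatch(lstCoefficients(fit), error = function(e) {
        cli_log(logcon, stage, paste("coefficients unavailable:",
                                     conditionMessage(e)))
        NULL
      })
      files <- writeReport(fit, coeffs, model, out)
      for (f in files) cli_log(logcon, stage, paste("wrote", f))
    }

    inv_facet <- getopt("--invariance-sequence", "invariance_sequence")
    if (!is.null(inv_facet)) {
      stage <- "invariance"
      inv <- invarianceSequence(dat, design, options, facet = inv_facet,
                                seed = seed)
      levels_tab <- do.call(rbind, lapply(names(inv$fits), function(nm) {
        f <- inv$fits[[nm]]
        data.frame(level = nm, chisq = f$chisq, df = f$df,
                   cfi = f$indices$cfi, rmsea = f$indices$rmsea,
                   srmr = f$indices$srmr)
      }))
      dtab <- inv$comparisons
      names(dtab)[names(dtab) == "step"] <- "level"
      levels_tab <- merge(levels_tab, dtab, by = "level", all.x = TRUE,
                          sort = FALSE)
      inv_file <- file.path(out, "invariance.csv")
      utils::write.csv(levels_tab, inv_file, row.names = FALSE)
      cli_log(logcon, stage, paste("wrote", inv_file))
      for (tr in inv$traces) cli_log(logcon, stage, tr)
    }
    cli_log(logcon, "done", "all stages complete")
  }, error = function(e) {
    msg <- sprintf("error in stage '%s': %s", stage, conditionMessage(e))
    if (!is.null(logcon)) try(writeLines(msg, logcon), silent = TRUE)
    message(msg)
    status <<- 1L
  })
  invisible(status)
}
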