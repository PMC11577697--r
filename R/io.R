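# delimited-text I/O and command-line entry points

#' Read an ordinal dataset from delimited text
#'
#' Reads a header-ed delimited file and validates it into an [ord_data()].
#' The outcome may be integer-coded `1..K` or use ordered labels supplied
#' through `levels`.
#'
#' @param path file path.
#' @param outcome_col name of the outcome column.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @param weight_col optional name of a positive weight column.
#' @param levels optional character vector giving the outcome levels in
#'   ascending order (required when the outcome is not integer coded).
#' @param sep field separator (default comma).
#' @param K optional number of categories (inferred otherwise).
#' @return an [ord_data()].
#' @export
read_ordinal_table <- function(path, outcome_col, covariate_cols = character(0),
                               weight_col = NULL, levels = NULL, sep = ",",
                               K = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  used <- c(outcome_col, covariate_cols, weight_col)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  na_rows <- which(rowSums(is.na(df[, used, drop = FALSE])) > 0)
  if (length(na_rows))
    stop(sprintf("missing values in used columns at rows: %s",
                 paste(utils::head(na_rows, 20L), collapse = ", ")),
         call. = FALSE)
  yraw <- df[[outcome_col]]
  if (!is.null(levels)) {
    y <- match(as.character(yraw), levels)
    if (any(is.na(y)))
      stop("outcome values outside the supplied level order", call. = FALSE)
    K <- K %||% length(levels)
  } else {
    y <- suppressWarnings(as.integer(yraw))
    if (any(is.na(y)) || any(y != as.numeric(yraw)))
      stop("outcome must be integer coded 1..K, or supply `levels`",
           call. = FALSE)
  }
  X <- if (length(covariate_cols)) {
    as.matrix(df[, covariate_cols, drop = FALSE])
  } else NULL
  w <- if (!is.null(weight_col)) {
    wv <- as.numeric(df[[weight_col]])
    if (any(wv <= 0)) stop("weights must be strictly positive", call. = FALSE)
    wv
  } else NULL
  ord_data(y, X, w = w, K = K)
}

#' Serialize a fit (and covariances) to JSON
#'
#' Numbers are written at full double precision; the seed and configuration
#' used to produce the fit are embedded for reproducibility.
#'
#' @param fit an [ord_fit()].
#' @param cov optional [design_cov()] result.
#' @param path output path.
#' @param seed,config optional provenance to embed.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, cov = NULL, path, seed = NULL, config = list()) {
  obj <- list(
    family = fit$family$name, K = fit$family$K, p = fit$family$p,
    n = fit$n, weighted = fit$weighted, converged = fit$converged,
    loglik = fit$loglik, par_names = fit$family$par_names,
    estimates = as.list(fit$theta),
    se_model = if (!is.null(fit$vcov_model))
      as.list(stats::setNames(sqrt(diag(fit$vcov_model)), fit$family$par_names)),
    vcov_model = fit$vcov_model,
    seed = seed, config = config,
    package_version = as.character(utils::packageVersion("svyord")))
  if (!is.null(cov)) {
    obj$se_design <- as.list(stats::setNames(cov$se_design, fit$family$par_names))
    obj$vcov_design <- cov$design_based
    obj$design <- cov$design
  }
  if (fit$family$name == "sm" && fit$family$p > 0L) {
    use <- if (!is.null(cov)) cov else fit$vcov_model
    which <- if (!is.null(cov)) "design" else "model"
    obj$phi_beta <- tryCatch(delta_phi_beta(fit, use, which = which),
                             error = function(e) NULL)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor",
                       null = "null")
  invisible(path)
}

cli_parse <- function(parser, argv) {
  tryCatch(optparse::parse_args(parser, args = argv),
           error = function(e) {
             message("usage error: ", conditionMessage(e))
             NULL
           })
}

cli_log <- function(out_dir, name, config) {
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  config$package_version <- as.character(utils::packageVersion("svyord"))
  jsonlite::write_json(config, file.path(out_dir, name), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Command-line interface: fit a model to a delimited dataset
#'
#' Flags: `--data PATH --outcome COL --covariates C1,C2 [--weights COL]
#' [--family sm|ac|cr|cm] [--design wr|stratified] [--out DIR] [--seed S]`.
#' Writes `fit_<family>.json` into the output directory and returns the
#' exit status (0 on success) invisibly.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status, invisibly (0 = success, 1 = usage/run error).
#' @export
cli_fit <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--data", type = "character"),
    optparse::make_option("--outcome", type = "character", default = "y"),
    optparse::make_option("--covariates", type = "character", default = ""),
    optparse::make_option("--weights", type = "character", default = NULL),
    optparse::make_option("--family", type = "character", default = "cm"),
    optparse::make_option("--design", type = "character", default = "wr"),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--seed", type = "integer", default = NULL)))
  opt <- cli_parse(parser, argv)
  if (is.null(opt)) return(invisible(1L))
  status <- tryCatch({
    if (is.null(opt$data)) stop("--data is required")
    if (!opt$family %in% c("sm", "ac", "cr", "cm"))
      stop(sprintf("unknown family '%s'", opt$family))
    if (!opt$design %in% c("wr", "stratified"))
      stop(sprintf("unknown design '%s'", opt$design))
    covs <- if (nzchar(opt$covariates))
      strsplit(opt$covariates, ",")[[1]] else character(0)
    dat <- read_ordinal_table(opt$data, opt$outcome, covs,
                              weight_col = opt$weights)
    fam <- ord_family(opt$family, K = dat$K, p = dat$p)
    fit <- ord_fit(fam, dat)
    cov <- design_cov(fit, dat, design = opt$design)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_fit_json(fit, cov, file.path(opt$out, paste0("fit_", opt$family, ".json")),
                   seed = opt$seed, config = opt[setdiff(names(opt), "help")])
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

#' Command-line interface: calibrate true parameters for a scenario
#'
#' Flags: `--scenario L1..H5 --K 3|5 [--M 1e6] [--seed S] [--out DIR]
#' [--families sm,ac,cr,cm]`.  Writes `truth_<scenario>_K<K>.json`.
#'
#' @inheritParams cli_fit
#' @return exit status, invisibly.
#' @export
cli_calibrate <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--scenario", type = "character"),
    optparse::make_option("--K", type = "integer", default = 5L),
    optparse::make_option("--M", type = "double", default = 1e6),
    optparse::make_option("--seed", type = "integer", default = 20240901L),
    optparse::make_option("--families", type = "character", default = "sm,ac,cr,cm"),
    optparse::make_option("--out", type = "character", default = ".")))
  opt <- cli_parse(parser, argv)
  if (is.null(opt)) return(invisible(1L))
  status <- tryCatch({
    if (is.null(opt$scenario)) stop("--scenario is required")
    sc <- ods_scenario(opt$scenario, opt$K)
    fams <- strsplit(opt$families, ",")[[1]]
    truth <- calibrate_truth(sc, families = fams, M = opt$M, seed = opt$seed)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    obj <- list(scenario = sc$label, K = sc$K, proportions = sc$proportions,
                alpha_star = sc$alpha_star, M = opt$M, seed = opt$seed,
                truth = lapply(truth$params, function(p)
                  list(alpha = p$alpha, phi = p$phi, beta = p$beta)))
    path <- file.path(opt$out, sprintf("truth_%s_K%d.json", sc$label, sc$K))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    cli_log(opt$out, sprintf("truth_%s_K%d_log.json", sc$label, sc$K),
            opt[setdiff(names(opt), "help")])
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

#' Command-line interface: run a replicated ODS simulation cell
#'
#' Flags: `--scenario L1..H5 --K 3|5 --family sm|ac|cr|cm --reps R
#' [--seed S] [--N 10000] [--nk 80] [--M 1e6] [--out DIR]`.  Calibrates the
#' truth, runs the study, and writes a summary CSV (one row per parameter)
#' plus a replicate-level CSV and a JSON log.
#'
#' @inheritParams cli_fit
#' @return exit status, invisibly.
#' @export
cli_simulate <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--scenario", type = "character"),
    optparse::make_option("--K", type = "integer", default = 5L),
    optparse::make_option("--family", type = "character", default = "cm"),
    optparse::make_option("--reps", type = "integer", default = 100L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--N", type = "integer", default = 10000L),
    optparse::make_option("--nk", type = "integer", default = NULL),
    optparse::make_option("--M", type = "double", default = 1e6),
    optparse::make_option("--out", type = "character", default = ".")))
  opt <- cli_parse(parser, argv)
  if (is.null(opt)) return(invisible(1L))
  status <- tryCatch({
    if (is.null(opt$scenario)) stop("--scenario is required")
    if (!opt$family %in% c("sm", "ac", "cr", "cm"))
      stop(sprintf("unknown family '%s'", opt$family))
    sc <- ods_scenario(opt$scenario, opt$K, N = opt$N, n_k = opt$nk)
    truth <- calibrate_truth(sc, families = opt$family, M = opt$M,
                             seed = opt$seed + 500000L)
    fam <- ord_family(opt$family, K = sc$K, p = 2L)
    study <- run_study(sc, fam, truth$params[[opt$family]], R = opt$reps,
                       seed = opt$seed)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    stem <- sprintf("study_%s_K%d_%s", sc$label, sc$K, opt$family)
    utils::write.csv(summary(study),
                     file.path(opt$out, paste0(stem, "_summary.csv")),
                     row.names = FALSE)
    reps <- data.frame(replicate = rep(seq_len(study$R), each = fam$npar),
                       param = rep(fam$par_names, study$R),
                       est_u = as.vector(t(study$est_u)),
                       se_u = as.vector(t(study$se_u)),
                       est_w = as.vector(t(study$est_w)),
                       se_w = as.vector(t(study$se_w)))
    utils::write.csv(reps, file.path(opt$out, paste0(stem, "_replicates.csv")),
                     row.names = FALSE)
    cli_log(opt$out, paste0(stem, "_log.json"), opt[setdiff(names(opt), "help")])
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
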