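#' Build a pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"study"` (read
#'   time-course tables from disk).
#' @param network path to a network spec file, or `NULL` for the
#'   packaged default network.
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_per_group,noise_sd cohort settings (synthetic mode).
#' @param conditions conditions to generate/fit.
#' @param subregions `"signal"` (use the generator's known signal-bearing
#'   sub-region; synthetic mode only), `"select"` (greedy data-driven
#'   selection) or `"first"`.
#' @param fit_opts see [sapm_fit_opts()].
#' @param alpha_family familywise alpha for the group table.
#' @param covariate covariate name for regression/ANCOVA
#'   (default `"first_pain"`).
#' @param n_null surrogate fits for the null reference.
#' @param timecourses,covariates_file input CSV paths (study mode).
#' @return list of class `sapm_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "study"), network = NULL,
                            out_dir = tempfile("sapm_run_"), seed = 1L,
                            n_per_group = 15L, noise_sd = 0.2,
                            conditions = c("Pain", "No-Pain"),
                            subregions = c("signal", "select", "first"),
                            fit_opts = sapm_fit_opts(),
                            alpha_family = 0.05, covariate = "first_pain",
                            n_null = 10L, timecourses = NULL,
                            covariates_file = NULL) {
  cfg <- list(mode = match.arg(mode), network = network, out_dir = out_dir,
              seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              noise_sd = noise_sd, conditions = conditions,
              subregions = match.arg(subregions), fit_opts = fit_opts,
              alpha_family = alpha_family, covariate = covariate,
              n_null = as.integer(n_null), timecourses = timecourses,
              covariates_file = covariates_file)
  class(cfg) <- "sapm_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments
#'   (fit options under `fit_opts:`).
#' @return a `sapm_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  fo <- do.call(sapm_fit_opts, if (is.null(raw$fit_opts)) list() else
    raw$fit_opts)
  raw$fit_opts <- fo
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  args$fit_opts <- fo
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' @param cfg a `sapm_pipeline_config`.
#' @return character vector of issues; empty iff runnable.
#' @export
validate_config <- function(cfg) {
  issues <- character()
  chk <- function(cond, msg) if (cond) issues <<- c(issues, msg)
  chk(!cfg$mode %in% c("synthetic", "study"), "mode: must be synthetic|study")
  chk(!is.numeric(cfg$alpha_family) || cfg$alpha_family <= 0 ||
        cfg$alpha_family > 1, "alpha_family: must be in (0, 1]")
  chk(cfg$n_per_group < 3,
      "n_per_group: group statistics need n >= 3 per group")
  chk(cfg$noise_sd < 0, "noise_sd: must be >= 0")
  chk(cfg$n_null < 2, "n_null: must be >= 2")
  if (!is.null(cfg$network))
    chk(!file.exists(cfg$network),
        paste0("network: file not found: ", cfg$network))
  if (cfg$mode == "study") {
    chk(is.null(cfg$timecourses),
        "timecourses: required in study mode")
    if (!is.null(cfg$timecourses))
      chk(!file.exists(cfg$timecourses),
          paste0("timecourses: file not found: ", cfg$timecourses))
    chk(cfg$subregions == "signal",
        "subregions: 'signal' is only available in synthetic mode")
  }
  issues
}

# internal: pick the observation matrix for one participant/condition
.pick_observed <- function(tc_array, net, cfg, signal_idx = NULL) {
  ab <- net$regions$abbrev
  if (cfg$subregions == "signal") {
    if (is.null(signal_idx)) stop("signal sub-regions unknown", call. = FALSE)
    obs <- t(vapply(seq_along(ab), function(i)
      tc_array[ab[i], signal_idx[ab[i]], ], numeric(dim(tc_array)[3])))
    rownames(obs) <- ab
    return(list(observed = obs, choice = signal_idx))
  }
  if (cfg$subregions == "first") {
    obs <- tc_array[ab, 1, ]
    return(list(observed = obs,
                choice = stats::setNames(rep(1L, length(ab)), ab)))
  }
  fit <- select_subregions(tc_array[ab, , , drop = FALSE], net, cfg$fit_opts)
  list(observed = NULL, fit = fit, choice = fit$subregion_choice)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: generate a two-group cohort (FM and HC ground truths
#' from the published connectivity table), fit every participant and
#' condition, compute the null reference, group statistics table,
#' covariate regression per connection, and group-by-covariate ANCOVA;
#' write fits, tables, a run log and a hashed output manifest under
#' `cfg$out_dir`.  Study mode reads time-course/covariate CSVs instead
#' of generating them.  Re-running with the same config reproduces all
#' numeric outputs bit-for-bit in synthetic mode.
#'
#' @param cfg a `sapm_pipeline_config`.
#' @return the run manifest (named list), invisibly: output files with
#'   MD5 hashes, stage timings, seeds.
#' @export
run_pipeline <- function(cfg) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid pipeline config:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    logf("stage ", name, " done in ", timings[[name]], " s")
    res
  }

  net <- if (is.null(cfg$network)) default_network() else
    load_network(cfg$network)
  logf("network: ", nrow(net$regions), " regions, ",
       connection_count(net, FALSE), " connections (+",
       connection_count(net, TRUE) - connection_count(net, FALSE),
       " latent links)")

  # --- stage: data -----------------------------------------------------
  if (cfg$mode == "synthetic") {
    cohort <- stage("simulate", {
      gt_fm <- lapply(cfg$conditions, function(cn)
        ground_truth(net, "FM", cn))
      names(gt_fm) <- cfg$conditions
      gt_hc <- lapply(cfg$conditions, function(cn)
        ground_truth(net, "HC", cn))
      names(gt_hc) <- cfg$conditions
      generate_cohort(net, gt_fm, gt_hc,
                      cohort_config(n_per_group = cfg$n_per_group,
                                    noise_sd = cfg$noise_sd,
                                    seed = derive_seed(cfg$seed, "simulate"),
                                    conditions = cfg$conditions))
    })
    covariates <- cohort$covariates
    tc_path <- file.path(cfg$out_dir, "timecourses.csv")
    write_timecourses(cohort, tc_path)
    utils::write.csv(covariates, file.path(cfg$out_dir, "covariates.csv"),
                     row.names = FALSE)
    datasets <- list()
    for (p in cohort$participants) for (cond in names(p$conditions)) {
      d <- p$conditions[[cond]]
      datasets[[paste(p$id, cond, sep = "_")]] <- list(
        id = p$id, group = p$group, condition = cond,
        tc = d$timecourses, signal = d$signal_subregion)
    }
  } else {
    tc <- read_timecourses(cfg$timecourses)
    covariates <- if (!is.null(cfg$covariates_file))
      utils::read.csv(cfg$covariates_file, stringsAsFactors = FALSE) else NULL
    datasets <- list()
    for (pid in unique(tc$participant)) for (cond in unique(tc$condition)) {
      sel <- tc$participant == pid & tc$condition == cond
      if (!any(sel)) next
      datasets[[paste(pid, cond, sep = "_")]] <- list(
        id = pid, group = tc$group[sel][1], condition = cond,
        tc = timecourse_array(tc, pid, cond), signal = NULL)
    }
  }

  # --- stage: fit ------------------------------------------------------
  fit_dir <- file.path(cfg$out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  fits <- stage("fit", {
    out <- list()
    for (key in names(datasets)) {
      d <- datasets[[key]]
      opts <- cfg$fit_opts
      opts$seed <- derive_seed(cfg$seed, paste("fit", key))
      picked <- .pick_observed(d$tc, net, cfg, d$signal)
      f <- if (!is.null(picked$fit)) picked$fit else
        fit_sapm(picked$observed, net, opts)
      f$subregion_choice <- picked$choice
      write_fit(f, file.path(fit_dir, paste0(key, ".json")))
      out[[key]] <- f
    }
    out
  })

  # --- stage: null reference ------------------------------------------
  null_ref <- stage("null_reference", {
    first <- fits[[1]]
    fit_null_reference(first$observed, net, n_null = cfg$n_null,
                       seed = derive_seed(cfg$seed, "null"),
                       opts = cfg$fit_opts)
  })

  # --- stage: stats ----------------------------------------------------
  stats_out <- stage("stats", {
    meta <- do.call(rbind, lapply(names(datasets), function(k)
      data.frame(key = k, id = datasets[[k]]$id,
                 group = datasets[[k]]$group,
                 condition = datasets[[k]]$condition,
                 stringsAsFactors = FALSE)))
    cells <- split(meta$key, paste(meta$group, meta$condition, sep = "_"))
    fits_by_cell <- lapply(cells, function(keys) {
      fl <- fits[keys]
      names(fl) <- meta$id[match(keys, meta$key)]
      fl
    })
    gs <- summarize_table(fits_by_cell, null_ref, cfg$alpha_family)
    utils::write.csv(gs$rows, file.path(cfg$out_dir, "group_stats.csv"),
                     row.names = FALSE)
    writeLines(format_group_stats(gs),
               file.path(cfg$out_dir, "report.md"))

    reg_df <- anc_df <- NULL
    if (!is.null(covariates) && cfg$covariate %in% names(covariates)) {
      pain_cells <- grep("_Pain$", names(fits_by_cell), value = TRUE)
      reg_rows <- list(); anc_rows <- list()
      labs <- colnames(db_matrix(fits[1]))
      for (cell in pain_cells) {
        mat <- db_matrix(fits_by_cell[[cell]])
        cv <- covariates[[cfg$covariate]][
          match(rownames(mat), covariates$participant)]
        for (cn in labs) {
          rr <- regress_db(cv, mat[, cn])
          reg_rows[[paste(cell, cn)]] <- data.frame(
            cell = cell, connection = cn, slope = rr$slope, r = rr$r,
            p_value = rr$p_value, n = rr$n, stringsAsFactors = FALSE)
        }
      }
      if (length(pain_cells) == 2) {
        m1 <- db_matrix(fits_by_cell[[pain_cells[1]]])
        m2 <- db_matrix(fits_by_cell[[pain_cells[2]]])
        gl <- c(rep(sub("_Pain$", "", pain_cells[1]), nrow(m1)),
                rep(sub("_Pain$", "", pain_cells[2]), nrow(m2)))
        cv <- covariates[[cfg$covariate]][
          match(c(rownames(m1), rownames(m2)), covariates$participant)]
        for (cn in labs) {
          ar <- ancova(gl, cv, c(m1[, cn], m2[, cn]))
          ar$connection <- cn
          anc_rows[[cn]] <- ar
        }
      }
      reg_df <- do.call(rbind, reg_rows)
      if (length(anc_rows)) anc_df <- do.call(rbind, anc_rows)
      if (!is.null(reg_df))
        utils::write.csv(reg_df, file.path(cfg$out_dir, "regression.csv"),
                         row.names = FALSE)
      if (!is.null(anc_df))
        utils::write.csv(anc_df, file.path(cfg$out_dir, "ancova.csv"),
                         row.names = FALSE)
    }
    list(group = gs, regression = reg_df, ancova = anc_df)
  })

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(cfg$out_dir, "manifest.json"))
  manifest <- list(
    mode = cfg$mode, seed = cfg$seed, timings = timings,
    n_fits = length(fits),
    outputs = lapply(files, function(f) list(
      path = sub(paste0("^", cfg$out_dir, "/?"), "", f),
      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete: ", length(files), " output files")
  invisible(c(manifest, list(stats = stats_out, fits = fits,
                             null_reference = null_ref)))
}

#' Command-line entry point
#'
#' Verbs: `run` (all stages), `simulate`, `validate`; flags `--config`
#' (YAML), `--seed`, `--out`, `--mode`.  Exit codes: 0 success, 1 config
#' error, 2 stage failure.  Installed as `inst/cli/sapm.R`:
#' `Rscript -e 'sapmnet::sapm_cli()' run --out out/`.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
sapm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verb <- if (length(args)) args[1] else "run"
  opts <- list(config = NULL, seed = NULL, out = NULL, mode = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (key %in% names(opts)) { opts[[key]] <- rest[i + 1]; i <- i + 2 }
    else { message("unknown flag: ", rest[i]); return(invisible(1L)) }
  }
  cfg <- tryCatch({
    base <- if (!is.null(opts$config)) load_pipeline_config(opts$config)
            else pipeline_config()
    if (!is.null(opts$seed)) base$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) base$out_dir <- opts$out
    if (!is.null(opts$mode)) base$mode <- opts$mode
    base
  }, error = function(e) { message("config error: ", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(invisible(1L))
  issues <- validate_config(cfg)
  if (verb == "validate") {
    if (length(issues)) { message(paste(issues, collapse = "\n")); return(invisible(1L)) }
    message("config OK"); return(invisible(0L))
  }
  if (length(issues)) {
    message("config error:\n  ", paste(issues, collapse = "\n  "))
    return(invisible(1L))
  }
  status <- tryCatch({
    if (verb == "simulate") {
      net <- if (is.null(cfg$network)) default_network() else
        load_network(cfg$network)
      gt_fm <- lapply(cfg$conditions, function(cn) ground_truth(net, "FM", cn))
      gt_hc <- lapply(cfg$conditions, function(cn) ground_truth(net, "HC", cn))
      names(gt_fm) <- names(gt_hc) <- cfg$conditions
      cohort <- generate_cohort(net, gt_fm, gt_hc,
        cohort_config(n_per_group = cfg$n_per_group, noise_sd = cfg$noise_sd,
                      seed = derive_seed(cfg$seed, "simulate"),
                      conditions = cfg$conditions))
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_timecourses(cohort, file.path(cfg$out_dir, "timecourses.csv"))
      utils::write.csv(cohort$covariates,
                       file.path(cfg$out_dir, "covariates.csv"),
                       row.names = FALSE)
      0L
    } else if (verb == "run") {
      run_pipeline(cfg)
      0L
    } else {
      message("unknown verb: ", verb); 1L
    }
  }, error = function(e) {
    message("stage failure: ", conditionMessage(e))
    writeLines(conditionMessage(e), file.path(cfg$out_dir, "FAILED"))
    2L
  })
  invisible(status)
}
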