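#' Configuration for an end-to-end surveillance run
#'
#' Collects everything [run_surveillance()] needs: input table,
#' model/sampler settings, optional standardization and inequality
#' comparisons, and the output directory. A plain-text `key = value`
#' file can be read with [read_run_config()]; explicit arguments win
#' over file values.
#'
#' @param input Path to the surveillance table.
#' @param dialect `"plain"` or `"wonder"`.
#' @param column_map Named vector for [read_surveillance()].
#' @param family,joint,chains,draws,warmup,seed Passed to
#'   [model_spec()].
#' @param std_pop Path to a standard-population CSV, or `NULL`.
#' @param group_d,group_a Group pair for inequality output, or `NULL`.
#' @param aapc_window AAPC window length in periods (default 4).
#' @param out Output directory (created if missing).
#' @param per Reporting scale for rates (default 1e5).
#' @return A `run_config` list.
#' @export
run_config <- function(input, dialect = "plain",
                       column_map = c(time = "Year", count = "Count",
                                      population = "Population",
                                      group = "Group", age = "Age"),
                       family = "poisson", joint = FALSE,
                       chains = 4L, draws = 6000L, warmup = 3000L,
                       seed = 1L, std_pop = NULL, group_d = NULL,
                       group_a = NULL, aapc_window = 4L, out = "ratetrends-out",
                       per = 1e5) {
  cfg <- list(input = input, dialect = dialect, column_map = column_map,
              family = family, joint = isTRUE(joint) || identical(joint, "true"),
              chains = as.integer(chains), draws = as.integer(draws),
              warmup = as.integer(warmup), seed = as.integer(seed),
              std_pop = std_pop, group_d = group_d, group_a = group_a,
              aapc_window = as.integer(aapc_window), out = out,
              per = as.numeric(per))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$warmup >= cfg$draws)
    stop("config error: warmup must be smaller than draws", call. = FALSE)
  if (cfg$aapc_window < 2L)
    stop("config error: aapc_window must be >= 2", call. = FALSE)
  if (!file.exists(cfg$input))
    stop("config error: input file not found: ", cfg$input, call. = FALSE)
  if (!is.null(cfg$std_pop) && !file.exists(cfg$std_pop))
    stop("config error: standard-population file not found: ", cfg$std_pop,
         call. = FALSE)
  if (xor(is.null(cfg$group_d), is.null(cfg$group_a)))
    stop("config error: group_d and group_a must be given together",
         call. = FALSE)
  invisible(cfg)
}

#' Read a key = value run-configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys match
#' the arguments of [run_config()]; `column_map` entries are given as
#' `column.time`, `column.count`, etc. Overrides passed as `...` win.
#'
#' @param path Config file path.
#' @param ... Overrides forwarded to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  args <- as.list(vals[!startsWith(names(vals), "column.")])
  cm <- vals[startsWith(names(vals), "column.")]
  if (length(cm)) {
    names(cm) <- sub("^column\\.", "", names(cm))
    args$column_map <- cm
  }
  for (nm in c("joint")) if (nm %in% names(args))
    args[[nm]] <- tolower(args[[nm]]) %in% c("true", "1", "yes")
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' Run the full surveillance workflow
#'
#' Reads the input table, fits the random-walk model, and writes tidy
#' CSV outputs to the configured directory: `rates.csv` (posterior
#' rate summaries per group/stratum), `change.csv` (annual and
#' cumulative percent change plus AAPC windows), `diagnostics.csv`
#' (split R-hat, ESS, MCSE per parameter), and, when configured,
#' `standardized.csv` (directly age-standardized rates) and
#' `inequality.csv` (pairwise measures for the declared group pair,
#' age-standardized when a standard population is given). A
#' `manifest.txt` logs the configuration, seed and package version.
#' Partial outputs are removed if any step fails.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 iff all diagnostic gates
#'   passed), `fit`, and the output file paths.
#' @export
run_surveillance <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  say("reading ", cfg$input, " [", cfg$dialect, "]")
  series <- read_surveillance(cfg$input, cfg$dialect, cfg$column_map)
  spec <- model_spec(family = cfg$family, joint = cfg$joint,
                     chains = cfg$chains, draws_per_chain = cfg$draws,
                     warmup = cfg$warmup, seed = cfg$seed)
  say("fitting ", spec$family, " random-walk model (",
      spec$chains, " chains x ", spec$draws_per_chain, " draws)")
  gates_ok <- TRUE
  fit <- withCallingHandlers(
    fit_rw(series, spec),
    ratetrends_convergence_warning = function(w) {
      gates_ok <<- FALSE
      say("convergence warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  path <- function(f) file.path(cfg$out, f)
  keep <- function(p) { written <<- c(written, p); p }

  rates <- do.call(rbind, lapply(series$strata, function(s)
    do.call(rbind, lapply(series$groups, function(g)
      summarize_draws(rate_draws(fit, g, s, per = cfg$per),
                      quantity = paste0("rate_per_", format(cfg$per, scientific = FALSE)),
                      group = g, stratum = s)))))
  write_summary(rates, keep(path("rates.csv")))

  change <- do.call(rbind, lapply(series$strata, function(s)
    do.call(rbind, lapply(series$groups, function(g) {
      rd <- rate_draws(fit, g, s, per = cfg$per)
      apc <- summarize_draws(apc_series(rd), quantity = "annual_percent_change",
                             group = g, stratum = s)
      cpc <- cumulative_percent_change(rd, group = g, stratum = s)
      n <- length(series$time)
      starts <- seq(1L, n - cfg$aapc_window + 1L, by = cfg$aapc_window)
      aapcs <- do.call(rbind, lapply(starts, function(i)
        aapc(rd, window = i:min(i + cfg$aapc_window - 1L, n),
             group = g, stratum = s)))
      rbind(apc, cpc, aapcs)
    }))))
  write_summary(change, keep(path("change.csv")))

  write.csv(fit$diagnostics, keep(path("diagnostics.csv")), row.names = FALSE)

  if (!is.null(cfg$std_pop)) {
    std <- read_standard_population(cfg$std_pop)
    stdz <- do.call(rbind, lapply(series$groups, function(g)
      summarize_draws(direct_standardize(fit, std, g, per = cfg$per),
                      quantity = paste0("std_rate_per_",
                                        format(cfg$per, scientific = FALSE)),
                      group = g, stratum = "age-standardized")))
    write_summary(stdz, keep(path("standardized.csv")))
  }

  if (!is.null(cfg$group_d)) {
    ineq <- if (!is.null(cfg$std_pop))
      standardized_pairwise(fit, read_standard_population(cfg$std_pop),
                            cfg$group_d, cfg$group_a, per = cfg$per)
    else pairwise_inequality(fit, cfg$group_d, cfg$group_a, per = cfg$per)
    write_summary(summary(ineq), keep(path("inequality.csv")))
  }

  manifest <- c(
    paste0("ratetrends version: ", as.character(packageVersion("ratetrends"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("R version: ", R.version.string),
    "",
    "configuration:",
    paste0("  ", names(cfg), " = ",
           vapply(cfg, function(v) paste(format(unlist(v)), collapse = ","), "")),
    "",
    paste0("diagnostic gates passed: ", gates_ok),
    paste0("max divergence count: ", max(fit$sampler_info$divergent)))
  writeLines(manifest, keep(path("manifest.txt")))

  ok <- TRUE
  say("wrote ", length(written), " file(s) to ", cfg$out,
      "; status ", if (gates_ok) 0L else 1L)
  invisible(list(status = if (gates_ok) 0L else 1L, fit = fit,
                 files = written))
}
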