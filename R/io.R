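#' Read a 1-D scattering curve from a text file
#'
#' Whitespace- or comma-delimited columns (abscissa, intensity, optional
#' error); `#` starts a comment. Rows are sorted by abscissa with a warning
#' when out of order; duplicate abscissa values are averaged with a warning.
#'
#' @param path File path.
#' @param scale Observation scale of the data.
#' @return A [scattering_data()].
#' @export
read_curve <- function(path, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(gsub(",", " ", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no data rows in ", path)
  m <- tryCatch(
    do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric)),
    warning = function(w) stop("non-numeric rows in ", path))
  if (any(!is.finite(m[, 1:2]))) stop("non-numeric rows in ", path)
  scattering_data(m[, 1], m[, 2],
                  error = if (ncol(m) >= 3) m[, 3] else NULL,
                  scale = scale)
}

#' Write / read a chain as a columnar text file
#'
#' One row per iteration: the physical-scale parameters, acceptance flag,
#' step size and energy error; metadata (kernel, seed, burn-in) in `#`
#' header comments. `write_chain()` with `format = "rds"` stores the full
#' chain object (including the transform and configuration) as a binary
#' container instead.
#'
#' @param chain An `hmc_chain`.
#' @param path Output path.
#' @param format `"text"` or `"rds"`.
#' @export
write_chain <- function(chain, path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(chain, path)
    return(invisible(path))
  }
  d <- chain_draws(chain, scale = "physical", include_burn_in = TRUE)
  d$.iteration <- NULL
  tab <- cbind(iteration = seq_len(nrow(d)), as.data.frame(d),
               accepted = as.integer(chain$accepted),
               step_size = chain$step_size, dH = chain$dH,
               divergent = as.integer(chain$divergent))
  hdr <- c(paste("# kernel:", chain$kernel),
           paste("# seed:", chain$seed),
           paste("# burn_in:", chain$burn_in),
           paste("# params:", paste(chain$param_names, collapse = " ")),
           paste("#", paste(colnames(tab), collapse = "\t")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(tab, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) return(readRDS(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    trimws(sub(paste0("# ", key, ":"), "", ln[1]))
  }
  params <- strsplit(get_meta("params"), " ")[[1]]
  tab <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  colnames(tab) <- c("iteration", params, "accepted", "step_size", "dH",
                     "divergent")
  draws <- as.matrix(tab[, params, drop = FALSE])
  structure(list(draws = draws, accepted = tab$accepted == 1, dH = tab$dH,
                 step_size = tab$step_size, divergent = tab$divergent == 1,
                 accept_stat = rep(NA_real_, nrow(tab)),
                 burn_in = as.integer(get_meta("burn_in")),
                 kernel = get_meta("kernel"), param_names = params,
                 transform = NULL, seed = as.integer(get_meta("seed")),
                 final_step_size = tab$step_size[nrow(tab)], mass = NULL,
                 config = NULL),
            class = "hmc_chain")
}

#' Read a run configuration file
#'
#' YAML with fields `model` (preset name or model spec), `data` (curve
#' path), `parameters` (named list: `init`, optional `fixed`), `sampler`
#' (passed to [sampler_config()]), `seed`, `output_dir`. Validated before
#' use.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("model", "parameters")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0)
    stop("config missing fields: ", paste(miss, collapse = ", "))
  inits <- vapply(cfg$parameters, function(p) !is.null(p$init), logical(1))
  fixed <- vapply(cfg$parameters, function(p) !is.null(p$fixed), logical(1))
  if (!all(inits | fixed))
    stop("every parameter needs an init (or a fixed value)")
  cfg
}

cli_usage <- function() {
  paste(
    "usage: hmcscatter <subcommand> [--key value ...]",
    "subcommands:",
    "  simulate --preset NAME --seed N --out FILE",
    "  fit      --preset NAME [--data FILE] --seed N --out-dir DIR",
    "           [--kernel nuts|hmc|random_walk] [--iters N] [--burn-in N]",
    "  diagnose --chain FILE --out-dir DIR",
    "  compare  --preset NAME --seed N --iters N [--out FILE]",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    out[[substring(key, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Starting values for the preset regimes
#'
#' Sensible initial values of the kind a practitioner would supply from
#' prior knowledge of the sample, not the generating truth: a deliberately
#' poor sphere-size guess for the SAXS regime, nominal literature-style
#' layer values for the bilayer regimes, and a flat spline profile for the
#' hologram. The residual variance starts at its conditional maximum
#' likelihood value given those guesses when the dataset is supplied.
#'
#' @param spec A [synthetic_spec()] from one of the preset generators.
#' @param data Optional dataset used to initialise `sigma2`.
#' @export
preset_init <- function(spec, data = NULL) {
  nm <- spec$model$name
  init <- if (nm == "saxs_spheres") {
    c(I0 = 1, Ib = 1e-5, R = 500, sigR = 20, sigq = 1e-5, sigma2 = 1e-2)
  } else if (nm == "refl_bilayer_3layer") {
    c(I0 = 1, sigma_Si = 3, h_o = 12, h_t = 24, h_i = 12,
      delta_o = 7e-7, delta_t = 4e-7, delta_i = 9e-7,
      sigma_o = 5, sigma_t = 5, sigma_i = 5, sigma2 = 1e-3)
  } else if (nm == "refl_bilayer_4layer") {
    c(I0 = 1, sigma_Si = 3, h_o = 12, h_t = 24, h_i = 12, h_w = 5,
      delta_o = 7e-7, delta_t = 4e-7, delta_i = 9e-7, delta_w = 5.8e-7,
      sigma_o = 5, sigma_t = 5, sigma_i = 5, sigma_w = 5, sigma2 = 1e-3)
  } else if (nm == "xwfh_gold_monolayer") {
    nb <- spec$model$n_basis
    c(I0 = 0.1, z_offset = 15.5, sigma_air_ps = 30, d_ps = 240,
      sigma_ps_ptba = 20, d_ptba = 580, d_au = 5, f_elastic = 0.01,
      setNames(rep(1 / nb, nb), paste0("a_", seq_len(nb))), sigma2 = 1e-2)
  } else {
    init <- spec$truth * 1.1
    init
  }
  if (!is.null(data)) {
    f <- spec$model$predict(init, data$abscissa)
    r <- if (obs_scale(data) == "log") log(data$observed) - log(f)
         else data$observed - f
    init["sigma2"] <- max(mean(r^2), 1e-8)
  }
  init
}

#' Command-line interface
#'
#' Subcommands: `simulate` (preset to dataset file), `fit` (dataset to
#' chain + summary table + credible band files), `diagnose` (chain file to
#' ACF/ESS/correlation tables), `compare` (HMC versus random-walk ESS
#' report at matched draw count). Returns the process exit code; invalid
#' input prints the usage text and returns nonzero. A thin launcher script
#' is installed under `exec/`.
#'
#' @param argv Character vector of command-line arguments.
#' @export
cli_main <- function(argv) {
  if (length(argv) == 0) {
    message(cli_usage())
    return(1L)
  }
  sub <- argv[1]
  opts <- tryCatch(cli_args(argv[-1]), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(opts)) {
    message(cli_usage())
    return(1L)
  }
  seed <- as.integer(opts$seed %||% 1L)
  ok <- tryCatch({
    switch(sub,
      simulate = {
        spec <- synthetic_preset(opts$preset, seed)
        ds <- simulate_dataset(spec)
        out <- opts$out %||% paste0(opts$preset, ".tsv")
        con <- file(out, "w")
        writeLines(c(paste("# preset:", opts$preset),
                     paste("# seed:", seed),
                     paste("# truth:", jsonlite::toJSON(
                       as.list(attr(ds, "truth")), auto_unbox = TRUE,
                       digits = NA))), con)
        write.table(data.frame(ds$abscissa, ds$observed), con, sep = "\t",
                    row.names = FALSE, col.names = FALSE, quote = FALSE)
        close(con)
        message("wrote ", out)
        TRUE
      },
      fit = {
        spec <- synthetic_preset(opts$preset, seed)
        ds <- if (!is.null(opts$data)) read_curve(opts$data)
              else simulate_dataset(spec)
        out_dir <- opts[["out-dir"]] %||% "."
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        iters <- as.integer(opts$iters %||% 2000L)
        burn <- as.integer(opts[["burn-in"]] %||% max(1L, iters %/% 4))
        cfg <- sampler_config(n_iterations = iters, n_burn_in = burn,
                              seed = seed)
        fit <- fit_hmc(ds, spec$model, preset_init(spec, ds),
                       kernel = opts$kernel %||% "nuts", config = cfg)
        write_chain(fit$chain, file.path(out_dir, "chain.tsv"))
        s <- tidy(fit)
        write.table(as.data.frame(s), file.path(out_dir, "summary.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        band <- credible_band(fit)
        write.table(as.data.frame(band), file.path(out_dir, "band.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        message("wrote chain.tsv, summary.tsv, band.tsv in ", out_dir)
        TRUE
      },
      diagnose = {
        chain <- read_chain(opts$chain)
        out_dir <- opts[["out-dir"]] %||% "."
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        s <- summarize_chain(chain)
        write.table(as.data.frame(s), file.path(out_dir, "diagnostics.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        cm <- correlation_matrix(chain)
        write.table(round(cm, 4), file.path(out_dir, "correlations.tsv"),
                    sep = "\t", quote = FALSE)
        message("wrote diagnostics.tsv, correlations.tsv in ", out_dir)
        TRUE
      },
      compare = {
        spec <- synthetic_preset(opts$preset, seed)
        ds <- simulate_dataset(spec)
        iters <- as.integer(opts$iters %||% 1000L)
        burn <- min(iters - 10L, max(60L, iters %/% 4))
        cfg <- sampler_config(n_iterations = iters, n_burn_in = burn,
                              seed = seed)
        fit_h <- fit_hmc(ds, spec$model, preset_init(spec, ds), kernel = "nuts",
                         config = cfg)
        cfg_rw <- cfg
        fit_r <- fit_hmc(ds, spec$model, preset_init(spec, ds),
                         kernel = "random_walk", config = cfg_rw)
        rep <- dplyr::left_join(
          dplyr::select(tidy(fit_h), "term", hmc_ess_fraction =
                        "ess_fraction"),
          dplyr::select(tidy(fit_r), "term", rw_ess_fraction =
                        "ess_fraction"),
          by = "term")
        if (!is.null(opts$out))
          write.table(as.data.frame(rep), opts$out, sep = "\t",
                      row.names = FALSE, quote = FALSE)
        print(as.data.frame(rep), digits = 3)
        TRUE
      },
      {
        message("unknown subcommand: ", sub)
        message(cli_usage())
        FALSE
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    FALSE
  })
  if (isTRUE(ok)) 0L else 1L
}
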