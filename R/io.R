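# Configuration, CSV serialization, run manifests and the command-line
# surface.  Config files are structured key-value YAML with sections
# `params` (Table-style model constants), `init`, `run` and `geometry`;
# unknown keys are errors, missing keys take the documented defaults.

#' Load a simulation configuration
#'
#' @param path YAML file with optional sections `params`, `init`, `run`,
#'   `geometry` (`"flat"` or `"round"`), `N`, `L`.
#' @return list with `params` (`model_params`), `init` (`init_spec`), `run`
#'   (`run_config`), `geometry`, `N`, `L`, and `resolved` (the full resolved
#'   key-value set echoed into manifests).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # YAML 1.1 parses a bare `N:` key as boolean false; map it back
  names(raw)[names(raw) == "FALSE"] <- "N"
  known_top <- c("params", "init", "run", "geometry", "N", "L")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_sec <- function(sec, fn) {
    sec <- if (is.null(sec)) list() else sec
    allowed <- names(formals(fn))
    bad <- setdiff(names(sec), allowed)
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    sec
  }
  pars <- check_sec(raw$params, model_params)
  p <- do.call(model_params, pars)
  ini <- check_sec(raw$init, init_spec)
  spec <- do.call(init_spec, ini)
  rn <- check_sec(raw$run, run_config)
  cfg <- do.call(run_config, rn)
  geometry <- if (is.null(raw$geometry)) "flat" else
    match.arg(raw$geometry, c("flat", "round"))
  N <- if (is.null(raw$N)) 256L else as.integer(raw$N)
  L <- if (is.null(raw$L)) 20 else as.numeric(raw$L)
  list(params = p, init = spec, run = cfg, geometry = geometry, N = N, L = L,
       resolved = list(params = unclass(p), init = unclass(spec),
                       run = unclass(cfg), geometry = geometry, N = N, L = L))
}

#' Write/read a state snapshot as CSV
#'
#' Snapshots are strict CSV with one row per node; constant fields (`t`,
#' `L_init`, and `dx` or `A_pref`/`M_total`) are repeated per row so the
#' file reconstructs the state exactly.
#'
#' @param state `flat_state` or `contour_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  g <- state_geometry(state)
  if (inherits(state, "flat_state")) {
    df <- data.frame(index = seq_along(state$h), x = state$x, h = state$h,
                     phi = state$phi, H = g$H, t = state$t,
                     L_init = state$L_init, dx = state$dx)
  } else {
    df <- data.frame(index = seq_along(state$x), x = state$x, y = state$y,
                     phi = state$phi, H = g$H, t = state$t,
                     L_init = state$L_init, A_pref = state$A_pref,
                     M_total = state$M_total)
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  df <- utils::read.csv(path)
  if ("h" %in% names(df)) {
    st <- list(x = df$x, h = df$h, phi = df$phi, t = df$t[1],
               L_init = df$L_init[1], dx = df$dx[1])
    class(st) <- "flat_state"
  } else {
    st <- list(x = df$x, y = df$y, phi = df$phi, t = df$t[1],
               A_pref = df$A_pref[1], L_init = df$L_init[1],
               M_total = df$M_total[1])
    class(st) <- "contour_state"
  }
  st
}

#' Write a trajectory summary as CSV
#'
#' @param summary a trajectory summary data.frame (or `trajectory`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(summary, path) {
  if (inherits(summary, "trajectory")) summary <- summary$summary
  utils::write.csv(format(summary, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the fully resolved configuration, seed, geometry, package
#' version, timing, termination reason and an inventory (with MD5 checksums)
#' of the files the run produced; sufficient to reproduce the run
#' bit-identically on one platform.
#'
#' @param path output JSON file.
#' @param resolved resolved configuration list.
#' @param seed RNG seed.
#' @param geometry `"flat"` or `"round"`.
#' @param reason termination reason.
#' @param files character vector of produced files.
#' @param t_start,t_end POSIXct wall-clock times.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, resolved, seed, geometry, reason, files,
                           t_start = Sys.time(), t_end = Sys.time()) {
  inv <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(f))))
  man <- list(package = "cellcontour",
              version = as.character(utils::packageVersion("cellcontour")),
              seed = seed, geometry = geometry, config = resolved,
              started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(t_end, "%Y-%m-%dT%H:%M:%S%z"),
              termination = reason, outputs = inv)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

cli_log <- function(...) message("[cellcontour] ", ...)

parse_args <- function(argv, spec) {
  # spec: named list of defaults; --key value pairs
  out <- spec
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (!key %in% names(spec)) stop("unknown option --", key)
    if (i == length(argv)) stop("missing value for --", key)
    val <- argv[i + 1]
    out[[key]] <- if (is.numeric(spec[[key]])) as.numeric(val) else val
    i <- i + 2
  }
  out
}

build_state <- function(conf, seed) {
  spec <- conf$init
  spec$rng_seed <- as.integer(seed)
  if (conf$geometry == "flat")
    init_flat(conf$params, N = conf$N, L = conf$L, spec = spec)
  else init_round(conf$params, N = conf$N, spec = spec)
}

#' Command-line dispatcher
#'
#' Entry point behind `inst/cli/cellcontour.R`.  Subcommands: `simulate`,
#' `stability`, `phase-diagram`, `scan-coalescence`, `scan-counts`,
#' `scan-crescent`, `analyze`.  Data go to files under `--out`; logs to
#' stderr.  Every artifact-producing command writes a JSON run manifest.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit code (0 on success).
#' @export
cli_dispatch <- function(argv) {
  t0 <- Sys.time()
  res <- try({
    if (length(argv) < 1) stop(
      "usage: cellcontour <simulate|stability|phase-diagram|scan-coalescence|",
      "scan-counts|scan-crescent|analyze> [--config F] [--seed N] [--out DIR]")
    cmd <- argv[1]
    opts <- parse_args(argv[-1],
                       list(config = "", seed = 1, out = ".",
                            geometry = "", t_end = 0))
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    conf <- if (nzchar(opts$config)) load_config(opts$config) else
      load_config_defaults()
    if (nzchar(opts$geometry)) conf$geometry <- opts$geometry
    if (opts$t_end > 0) conf$run$t_end <- run_config(t_end = opts$t_end)$t_end
    cli_log("command: ", cmd, "; seed: ", opts$seed)
    files <- character()
    reason <- "completed"
    switch(cmd,
      simulate = {
        st <- build_state(conf, opts$seed)
        tr <- run(st, conf$params, conf$run)
        reason <- tr$reason
        f1 <- file.path(opts$out, "snapshot_final.csv")
        f2 <- file.path(opts$out, "timeseries.csv")
        write_snapshot(tr$state, f1)
        write_timeseries(tr, f2)
        files <- c(f1, f2)
      },
      stability = {
        qg <- default_q_grid(conf$L, conf$L / conf$N)
        d <- dispersion_flat(qg, conf$params)
        f1 <- file.path(opts$out, "dispersion.csv")
        utils::write.csv(d, f1, row.names = FALSE)
        files <- f1
      },
      `phase-diagram` = {
        p <- conf$params
        ac <- critical_boundary(p, "alpha")$value
        Ac <- critical_boundary(p, "A")$value
        grid <- expand.grid(A = seq(0, 2 * Ac, length.out = 7),
                            alpha = seq(0, 2 * ac, length.out = 7))
        rows <- apply(grid, 1, function(g) {
          p2 <- p; p2$A_actin <- g[["A"]]; p2$alpha_adh <- g[["alpha"]]
          cl <- classify_regime(p2)
          data.frame(A = g[["A"]], alpha = g[["alpha"]], regime = cl$regime,
                     q_max = cl$q_max, omega_max = cl$omega_max)
        })
        f1 <- file.path(opts$out, "phase_diagram.csv")
        utils::write.csv(do.call(rbind, rows), f1, row.names = FALSE)
        files <- f1
      },
      `scan-coalescence` = {
        p <- conf$params
        ac <- critical_boundary(p, "alpha")$value
        sc <- coalescence_scan(p, "alpha", ac * c(1.3, 1.6, 2, 2.6, 3.4),
                               seeds = opts$seed + 0:2)
        f1 <- file.path(opts$out, "coalescence_scan.csv")
        utils::write.csv(sc$table, f1, row.names = FALSE)
        files <- f1
        cli_log("log-log slope: ", signif(sc$slope, 4))
      },
      `scan-counts` = {
        p <- conf$params
        ac <- critical_boundary(p, "alpha")$value
        tab <- protrusion_count_vs_driver(
          p, "alpha", ac * c(0.9, 1.1, 1.5, 2.5, 4), T_cell = conf$run$t_end,
          seed = opts$seed)
        f1 <- file.path(opts$out, "counts_vs_driver.csv")
        utils::write.csv(tab, f1, row.names = FALSE)
        files <- f1
      },
      `scan-crescent` = {
        p <- conf$params
        Ac <- critical_boundary(p, "A")$value
        tab <- crescent_scan(p, A_values = Ac * c(1.05, 1.15, 1.6, 2.4, 3.2),
                             seed = opts$seed)
        f1 <- file.path(opts$out, "crescent_scan.csv")
        utils::write.csv(tab, f1, row.names = FALSE)
        files <- f1
      },
      analyze = {
        st <- build_state(conf, opts$seed)
        tr <- run(st, conf$params, conf$run)
        chk <- steady_state_density_curvature_check(tr$state, conf$params)
        out <- data.frame(tau_c = as.numeric(coalescence_time(tr)),
                          n_final = tr$summary$n_protrusions[nrow(tr$summary)],
                          residual = chk$residual,
                          rank_correlation = chk$rank_correlation)
        f1 <- file.path(opts$out, "analysis.csv")
        utils::write.csv(out, f1, row.names = FALSE)
        files <- f1
      },
      stop("unknown subcommand: ", cmd))
    write_manifest(file.path(opts$out, paste0(cmd, "_manifest.json")),
                   conf$resolved, opts$seed, conf$geometry, reason, files,
                   t0, Sys.time())
    0L
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    message("error: ", attr(res, "condition")$message)
    return(1L)
  }
  res
}

load_config_defaults <- function() {
  list(params = model_params(), init = init_spec(), run = run_config(),
       geometry = "flat", N = 256L, L = 20,
       resolved = list(params = unclass(model_params()),
                       init = unclass(init_spec()),
                       run = unclass(run_config()),
                       geometry = "flat", N = 256L, L = 20))
}
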