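CONFIG_KEYS <- c(
  # model parameters
  "Z", "N", "n_pg", "n_I", "b", "c", "r", "delta", "pi_t", "mu", "beta",
  "variant",
  # run directives
  "command", "preset", "r_grid", "seed", "steps", "stride", "n_traj",
  "target", "bracket", "tol", "out", "verbose"
)

#' Load and validate a run configuration
#'
#' Reads a flat YAML or JSON configuration (recognised by file extension,
#' with YAML as the fallback dialect) and/or an overrides list (e.g. parsed
#' CLI flags, which take precedence over file values), validates every model
#' parameter bound through [crd_params], and rejects unknown keys by name.
#' A `preset` key seeds the model parameters from [crd_preset] before other
#' keys are applied.
#'
#' @param path Optional path to a YAML or JSON config file.
#' @param overrides Named list of config keys overriding the file values.
#' @return Object of class `crd_config`: list with `params` (a validated
#'   `crd_params`) and `run` (the run directives, with defaults filled in).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      # keep the single-letter YAML 1.1 boolean tokens (notably the key "N")
      # as literal strings; spelled-out booleans still parse as logical
      keep_short_bools <- function(x) {
        if (tolower(x) %in% c("true", "yes", "on")) return(TRUE)
        if (tolower(x) %in% c("false", "no", "off")) return(FALSE)
        x
      }
      yaml::read_yaml(path, handlers = list("bool#yes" = keep_short_bools,
                                            "bool#no" = keep_short_bools))
    }
    if (!is.list(cfg)) stop("config file must contain a key: value mapping")
  }
  stopifnot(is.list(overrides))
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  par_keys <- intersect(names(cfg), names(formals(crd_params)))
  params <- if (!is.null(cfg$preset)) {
    do.call(crd_preset, c(list(name = cfg$preset), cfg[par_keys]))
  } else {
    if (is.null(cfg$Z)) stop("missing config key: Z (or use a preset)")
    do.call(crd_params, cfg[par_keys])
  }
  run <- cfg[setdiff(names(cfg), c(par_keys, "preset"))]
  defaults <- list(command = "stationary", seed = 1L, stride = 50L,
                   n_traj = 50L, target = 0.5, tol = 1e-3, out = NULL,
                   verbose = FALSE)
  run <- utils::modifyList(defaults, run)
  if (!is.null(run$r_grid)) {
    if (is.character(run$r_grid)) {
      # "lo:hi:step"
      v <- as.numeric(strsplit(run$r_grid, ":", fixed = TRUE)[[1]])
      if (length(v) != 3L || anyNA(v)) {
        stop("r_grid must be numeric or 'lo:hi:step'")
      }
      run$r_grid <- seq(v[1], v[2], by = v[3])
    }
    stopifnot(is.numeric(run$r_grid))
  }
  structure(list(params = params, run = run), class = "crd_config")
}

#' Serialise the effective configuration
#'
#' Returns the fully resolved configuration as a flat named list that
#' [load_config] accepts again (round-trip identity), and is embedded in
#' every artifact.
#'
#' @param cfg A `crd_config` object.
#' @return Named list of config keys.
#' @export
effective_config <- function(cfg) {
  stopifnot(inherits(cfg, "crd_config"))
  p <- cfg$params
  c(p[c("Z", "N", "n_pg", "n_I", "b", "c", "r", "delta", "pi_t", "mu",
        "beta", "variant")],
    cfg$run[!vapply(cfg$run, is.null, logical(1))])
}

fmt_num <- function(x) {
  # canonical 12-significant-digit text for reproducible, diffable artifacts
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

#' Write a result table as annotated CSV
#'
#' Writes a header of `#`-prefixed metadata lines (tool version, parameter
#' hash and string, seed when applicable) followed by a standard CSV table
#' with floats at fixed 12-significant-digit precision, so identical runs
#' produce byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params A `crd_params` object for the metadata block.
#' @param meta Optional named list of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, params, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("crdelect"))
  writeLines(c(
    sprintf("# crdelect %s", ver),
    sprintf("# params_hash: %s", params_hash(params)),
    sprintf("# params: %s", params_string(params)),
    vapply(names(meta), function(nm) sprintf("# %s: %s", nm,
                                             format(meta[[nm]])),
           character(1))
  ), con)
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an annotated CSV written by [write_result_csv]
#'
#' @param path File path.
#' @return Data frame with the metadata lines in attribute `meta`.
#' @export
read_result_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = ",",
                          header = TRUE)
  attr(df, "meta") <- sub("^# ?", "", meta)
  df
}

states_df <- function(states, value, value_name = "value") {
  out <- data.frame(i_C = states[, "C"], i_P = states[, "P"],
                    i_R = states[, "R"], i_D = states[, "D"])
  if (is.matrix(value)) {
    out <- cbind(out, as.data.frame(value))
  } else {
    out[[value_name]] <- value
  }
  out
}

#' Execute a configured run
#'
#' Dispatches on `cfg$run$command` and writes the artifact to
#' `cfg$run$out` (when set) as annotated CSV or JSON:
#' \describe{
#'   \item{`stationary`}{Stationary distribution over states (CSV).}
#'   \item{`risk-curve`}{[risk_curve] over `r_grid` (CSV).}
#'   \item{`critical-risk`}{[critical_risk] report (JSON).}
#'   \item{`gradient`}{[gradient_field] per state (CSV).}
#'   \item{`attractors`}{[find_attractors] report (JSON).}
#'   \item{`simulate`}{[simulate_ensemble] summary (JSON) or a single
#'     trajectory (CSV) when `n_traj = 1`.}
#'   \item{`incidence`}{[incidence_of_incentives] report (JSON).}
#' }
#'
#' @param cfg A `crd_config` object from [load_config].
#' @return The computed result object, invisibly.
#' @export
run_command <- function(cfg) {
  stopifnot(inherits(cfg, "crd_config"))
  p <- cfg$params
  run <- cfg$run
  if (isTRUE(run$verbose)) {
    message("effective config: ",
            paste(sprintf("%s=%s", names(effective_config(cfg)),
                          vapply(effective_config(cfg), format, character(1))),
                  collapse = " "))
  }
  jmeta <- function(extra = list()) {
    c(list(tool = paste("crdelect",
                        as.character(utils::packageVersion("crdelect"))),
           params_hash = params_hash(p), params = params_string(p)),
      extra)
  }
  wjson <- function(obj, extra = list()) {
    if (!is.null(run$out)) {
      jsonlite::write_json(c(jmeta(extra), obj), run$out, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
  res <- switch(run$command,
    "stationary" = {
      st <- stationary_distribution(p)
      if (!is.null(run$out)) {
        write_result_csv(states_df(st$states, st$p, "probability"),
                         run$out, p, list(residual = fmt_num(st$residual)))
      }
      st
    },
    "risk-curve" = {
      grid <- if (is.null(run$r_grid)) seq(0, 1, by = 0.05) else run$r_grid
      rc <- risk_curve(p, r = grid, verbose = isTRUE(run$verbose))
      if (!is.null(run$out)) write_result_csv(rc, run$out, p)
      rc
    },
    "critical-risk" = {
      cr <- critical_risk(p, target = run$target,
                          bracket = if (is.null(run$bracket)) c(0, 1)
                                    else run$bracket,
                          tol = run$tol, verbose = isTRUE(run$verbose))
      wjson(list(r_star = cr$r_star, converged = cr$converged,
                 no_crossing = cr$no_crossing, target = cr$target,
                 bracket = cr$bracket, eta_bracket = cr$eta_bracket))
      cr
    },
    "gradient" = {
      chain <- build_transition_matrix(p)
      g <- gradient_field(chain)
      colnames(g) <- paste0("grad_", colnames(g))
      if (!is.null(run$out)) {
        write_result_csv(states_df(chain$states, g), run$out, p)
      }
      g
    },
    "attractors" = {
      at <- find_attractors(p)
      wjson(list(attractors = at))
      at
    },
    "simulate" = {
      if (run$n_traj == 1L) {
        tr <- simulate_trajectory(p, steps = run$steps, seed = run$seed,
                                  stride = run$stride)
        if (!is.null(run$out)) {
          df <- cbind(step = tr$step,
                      states_df(tr$states, NULL)[, 1:4])
          write_result_csv(df, run$out, p, list(seed = run$seed))
        }
        tr
      } else {
        en <- simulate_ensemble(p, n = run$n_traj, steps = run$steps,
                                seed = run$seed, stride = run$stride)
        wjson(list(seed = en$seed, counts = as.list(en$counts),
                   p_led_fraction = en$p_led_fraction,
                   attractor = as.list(en$attractor)))
        en
      }
    },
    "incidence" = {
      inc <- incidence_of_incentives(p)
      wjson(inc)
      inc
    },
    stop("unknown command: ", run$command)
  )
  invisible(res)
}
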