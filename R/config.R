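## Run-configuration parsing (flat key=value text with per-component
## sections), protocol/time planning, and report writing.

CONFIG_KEY_TYPES <- list(
  scheme = "character", temperature = "numeric", blocks = "integer",
  dlambda = "numeric", lambda_mode = "character", lambda_n = "integer",
  windows = "integer", window_production_ns = "numeric",
  window_equil_ns = "numeric",
  search_center = "numeric3", search_radius = "numeric",
  l1l2_range = "numeric2", l2l3_range = "numeric2",
  k_r = "numeric", k_angle = "numeric", k_dihedral = "numeric",
  k_conf = "numeric", k_com = "numeric",
  protein_anchors = "integer3",
  ligand_resname = "character", water_model = "character",
  ion_concentration = "numeric"
)

CONFIG_KEY_UNITS <- c(
  temperature = "K", dlambda = "dimensionless lambda", blocks = "count",
  lambda_n = "count", windows = "count",
  window_production_ns = "ns", window_equil_ns = "ns",
  search_center = "Angstrom (3 values)", search_radius = "Angstrom",
  l1l2_range = "Angstrom (min max)", l2l3_range = "Angstrom (min max)",
  k_r = "kcal/mol/A^2", k_angle = "kcal/mol/rad^2",
  k_dihedral = "kcal/mol/rad^2", k_conf = "kcal/mol/rad^2",
  k_com = "kcal/mol/A^2", protein_anchors = "atom serials (3 values)",
  ion_concentration = "M"
)

CONFIG_DEFAULTS <- list(
  temperature = 298.15, blocks = 5L, dlambda = 0.001,
  lambda_mode = "gauss_quadrature", lambda_n = 12L,
  windows = 12L, window_production_ns = 2.1, window_equil_ns = 0,
  l1l2_range = c(2.5, 5.0), l2l3_range = c(2.5, 5.0),
  k_r = 10, k_angle = 100, k_dihedral = 100, k_conf = 10, k_com = 10
)

coerce_config_value <- function(key, raw) {
  type <- CONFIG_KEY_TYPES[[key]]
  unit <- CONFIG_KEY_UNITS[key]
  unit <- if (is.na(unit)) "text" else unit
  fail <- function() {
    abort(sprintf("config key '%s' expects %s (%s), got '%s'",
                  key, type, unit, raw))
  }
  parts <- strsplit(trimws(raw), "\\s+")[[1]]
  want_n <- as.integer(sub("^[a-z]+", "", type))
  base <- sub("[0-9]+$", "", type)
  if (base == "character") return(paste(parts, collapse = " "))
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) fail()
  if (!is.na(want_n) && length(vals) != want_n) fail()
  if (base == "integer") {
    if (any(vals != round(vals))) fail()
    vals <- as.integer(vals)
  }
  vals
}

#' Parse a run-configuration file
#'
#' Flat `key = value` text with `#` comments and optional
#' `[component <letter>]` sections holding per-component overrides of the
#' window counts and lengths. Unknown keys warn and are preserved; missing
#' required keys error with the full missing list; defaults are filled for
#' the rest (temperature 298.15 K, finite-difference dlambda 0.001,
#' 5 data blocks, ...).
#'
#' @param path Path to the configuration file.
#' @return An `abfe_config` list with a `components` element of
#'   per-component overrides and an `extra` element of preserved unknown
#'   keys.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list(components = list(), extra = list())
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[component\\s+\\S+\\]$", ln)) {
      section <- sub("^\\[component\\s+(\\S+)\\]$", "\\1", ln)
      next
    }
    if (grepl("^\\[", ln)) abort(paste0("unrecognised section header: ", ln))
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("not a key = value line: ", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    raw <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(CONFIG_KEY_TYPES)) {
      warn(paste0("unknown config key '", key, "' preserved verbatim"))
      if (is.null(section)) {
        cfg$extra[[key]] <- raw
      } else {
        cfg$components[[section]]$extra[[key]] <- raw
      }
      next
    }
    val <- coerce_config_value(key, raw)
    if (is.null(section)) {
      cfg[[key]] <- val
    } else {
      cfg$components[[section]][[key]] <- val
    }
  }
  required <- "scheme"
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("config is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!cfg$scheme %in% names(SCHEME_LETTERS)) {
    abort(paste0("unknown scheme: ", cfg$scheme, " (valid: ",
                 paste(names(SCHEME_LETTERS), collapse = ", "), ")"))
  }
  for (key in names(CONFIG_DEFAULTS)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- CONFIG_DEFAULTS[[key]]
  }
  if (!cfg$lambda_mode %in% c("explicit", "gauss_quadrature")) {
    abort("lambda_mode must be 'explicit' or 'gauss_quadrature'")
  }
  if (cfg$windows < 1 || cfg$window_production_ns < 0 ||
      cfg$window_equil_ns < 0) {
    abort("window counts must be positive and lengths nonnegative")
  }
  structure(cfg, class = "abfe_config")
}

#' Serialize a run configuration back to text
#'
#' @param cfg An `abfe_config`.
#' @param path Output path.
#' @return `path`, invisibly; `parse_config(serialize_config(cfg))`
#'   round-trips.
#' @export
serialize_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "abfe_config"))
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  keys <- setdiff(names(cfg), c("components", "extra"))
  lines <- vapply(keys, function(k) paste(k, "=", fmt(cfg[[k]])),
                  character(1))
  for (k in names(cfg$extra)) {
    lines <- c(lines, paste(k, "=", cfg$extra[[k]]))
  }
  for (comp in names(cfg$components)) {
    lines <- c(lines, paste0("[component ", comp, "]"))
    ov <- cfg$components[[comp]]
    for (k in setdiff(names(ov), "extra")) {
      lines <- c(lines, paste(k, "=", fmt(ov[[k]])))
    }
    for (k in names(ov$extra)) lines <- c(lines, paste(k, "=", ov$extra[[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.abfe_config <- function(x, ...) {
  cat("ABFE run configuration: scheme", x$scheme, "at", x$temperature, "K\n")
  invisible(x)
}

#' Plan the simulation protocol of a scheme
#'
#' Enumerates every window of every simulated component in the scheme
#' (analytic components need no windows) with its planned equilibration +
#' production length, and totals the simulation time.
#'
#' @param cfg An `abfe_config` from [parse_config()].
#' @return An `abfe_plan`: tibble with one row per component (`component`,
#'   `windows`, `ns_per_window`, `time_ns`) and the total in attribute
#'   `total_ns` (also via [plan_total_ns()]).
#' @export
plan_protocol <- function(cfg) {
  stopifnot(inherits(cfg, "abfe_config"))
  letters <- setdiff(SCHEME_LETTERS[[cfg$scheme]], "b")
  rows <- lapply(letters, function(letter) {
    ov <- cfg$components[[letter]]
    windows <- (ov$windows %||% cfg$windows)
    per <- (ov$window_production_ns %||% cfg$window_production_ns) +
      (ov$window_equil_ns %||% cfg$window_equil_ns)
    if (windows < 1) {
      abort(paste0("component '", letter, "' has zero windows"))
    }
    tibble::tibble(component = letter, windows = as.integer(windows),
                   ns_per_window = per, time_ns = windows * per)
  })
  plan <- dplyr::bind_rows(rows)
  attr(plan, "total_ns") <- sum(plan$time_ns)
  class(plan) <- c("abfe_plan", class(plan))
  plan
}

#' @rdname plan_protocol
#' @param plan An `abfe_plan`.
#' @export
plan_total_ns <- function(plan) {
  stopifnot(inherits(plan, "abfe_plan"))
  attr(plan, "total_ns")
}

#' Write a human-readable + JSON result report
#'
#' One line per component letter with its value and uncertainty (one
#' decimal, half away from zero, as workflow outputs print them), the
#' assembled binding free energy, the dissociation constant, and the total
#' planned simulation time; a machine-readable JSON twin is written next to
#' it. Stored values are never rounded.
#'
#' @param result An `abfe_cycle` from [assemble()].
#' @param path Output text path; the JSON twin is `paste0(path, ".json")`.
#' @param plan Optional `abfe_plan` whose total time is reported.
#' @return Invisibly, a list with both paths.
#' @export
write_report <- function(result, path, plan = NULL) {
  stopifnot(inherits(result, "abfe_cycle"))
  total_ns <- if (!is.null(plan)) plan_total_ns(plan) else
    result$total_planned_time_ns
  comp <- result$components
  fmt1 <- function(x) sprintf("%.1f", round_half_away(x, 1))
  lines <- c(
    sprintf("ABFE result (%s scheme, %.2f K)", result$scheme,
            result$temperature),
    "",
    sprintf("  %-3s %8s %-55s", "cmp", "kcal/mol", "description"),
    sprintf("  %-3s %8s %-55s", comp$letter,
            sprintf("%s (%s)", fmt1(comp$value), fmt1(comp$uncertainty)),
            comp$description),
    "",
    sprintf("  dG_bind = %s (%s) kcal/mol", fmt1(result$dg_bind),
            fmt1(result$uncertainty)),
    sprintf("  Kd      = %.3e M", result$kd),
    if (is.finite(total_ns %||% NA_real_)) {
      sprintf("  total simulation time = %.1f ns", total_ns)
    } else {
      "  total simulation time = (no plan supplied)"
    }
  )
  writeLines(lines, path)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(scheme = result$scheme, temperature = result$temperature,
         components = comp[, c("letter", "value", "uncertainty", "method")],
         dg_bind = result$dg_bind, uncertainty = result$uncertainty,
         kd = result$kd, total_simulation_time_ns = total_ns),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(text = path, json = json_path))
}

#' Read back the JSON twin of a report
#'
#' @param json_path Path written by [write_report()].
#' @return A list mirroring the in-memory result.
#' @export
read_report_json <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
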