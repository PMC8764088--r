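#' Table schema for validated delimited input
#'
#' A schema names the required columns, their types, and optional per-value
#' checks. Files are comma-delimited UTF-8 with dot decimals and ISO-8601
#' dates; mole fractions are always nmol mol^-1 (ppb).
#'
#' @param columns Named list: each element is a list with `type`
#'   (`"numeric"`, `"character"`, `"logical"`, `"date"`), optional
#'   `required` (default `TRUE`) and optional `check`, a predicate applied
#'   to each non-missing value.
#' @return A list of class `table_schema`.
#' @export
table_schema <- function(columns) {
  stopifnot(is.list(columns), length(names(columns)) == length(columns))
  structure(list(columns = columns), class = "table_schema")
}

#' Read and validate a delimited table against a schema
#'
#' Columns may appear in any order; missing required columns are a
#' file-level error. Rows whose values fail a schema check are collected
#' (with line numbers) into an error report attached as the `"row_errors"`
#' attribute rather than aborting the read, so a single bad record never
#' hides the rest of a file.
#'
#' @param path Path to a comma-delimited text file with a header.
#' @param schema A [table_schema()].
#' @return Data frame of the valid rows, with attributes `row_errors`
#'   (data frame of `line`, `column`, `message`) and `n_read`.
#' @export
read_table <- function(path, schema) {
  stopifnot(inherits(schema, "table_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- names(schema$columns)[vapply(schema$columns, function(c)
    isTRUE(c$required %||% TRUE), logical(1))]
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  errors <- list()
  bad_rows <- logical(nrow(raw))
  for (nm in intersect(names(schema$columns), names(raw))) {
    col <- schema$columns[[nm]]
    vals <- raw[[nm]]
    if (col$type == "numeric") {
      conv <- suppressWarnings(as.numeric(vals))
      bad <- !is.na(vals) & is.na(conv)
      if (any(bad)) errors[[length(errors) + 1L]] <- data.frame(
        line = which(bad) + 1L, column = nm, message = "not numeric")
      raw[[nm]] <- conv
      bad_rows <- bad_rows | bad
    } else if (col$type == "date") {
      conv <- as.Date(vals, format = "%Y-%m-%d")
      bad <- !is.na(vals) & is.na(conv)
      if (any(bad)) errors[[length(errors) + 1L]] <- data.frame(
        line = which(bad) + 1L, column = nm, message = "not an ISO-8601 date")
      raw[[nm]] <- conv
      bad_rows <- bad_rows | bad
    } else if (col$type == "logical") {
      raw[[nm]] <- as.logical(vals)
    }
    if (!is.null(col$check)) {
      ok <- is.na(raw[[nm]]) | vapply(raw[[nm]], col$check, logical(1))
      if (any(!ok)) {
        errors[[length(errors) + 1L]] <- data.frame(
          line = which(!ok) + 1L, column = nm, message = "failed value check")
        bad_rows <- bad_rows | !ok
      }
    }
  }
  out <- raw[!bad_rows, , drop = FALSE]
  attr(out, "row_errors") <- if (length(errors)) do.call(rbind, errors)
    else data.frame(line = integer(), column = character(),
                    message = character())
  attr(out, "n_read") <- nrow(raw)
  out
}

numeric_col <- function(check = NULL, required = TRUE) {
  list(type = "numeric", check = check, required = required)
}

#' Built-in schemas for the pipeline's input tables
#'
#' @return A [table_schema()] for, respectively, chamber headspace series
#'   (`chamber_id`, `species`, `time_min`, `mole_fraction_ppb`, `temp_C`,
#'   optional `pressure_atm`), flux panels, stream vials and isotope pairs.
#' @name schemas
NULL

#' @rdname schemas
#' @export
chamber_table_schema <- function() table_schema(list(
  chamber_id = list(type = "character"),
  species = list(type = "character",
                 check = function(x) x %in% c("CH4", "N2O")),
  time_min = numeric_col(function(x) x >= 0),
  mole_fraction_ppb = numeric_col(function(x) x >= 0),
  temp_C = numeric_col(),
  pressure_atm = numeric_col(function(x) x > 0, required = FALSE)))

#' @rdname schemas
#' @export
flux_panel_schema <- function() table_schema(list(
  site = list(type = "character"),
  forest_type = list(type = "character",
                     check = function(x) x %in% c("montane", "lowland",
                                                  "swamp")),
  plot = list(type = "character", required = FALSE),
  chamber_id = list(type = "character"),
  date = list(type = "date"),
  flux = numeric_col(),
  soil_temperature = numeric_col(required = FALSE),
  wfps = numeric_col(function(x) x >= 0 && x <= 150, required = FALSE),
  inundated = list(type = "logical", required = FALSE)))

#' @rdname schemas
#' @export
vial_table_schema <- function() table_schema(list(
  species = list(type = "character",
                 check = function(x) x %in% c("CH4", "N2O")),
  water_ml = numeric_col(function(x) x > 0),
  headspace_ml = numeric_col(function(x) x > 0),
  temp_C = numeric_col(),
  pressure_atm = numeric_col(function(x) x > 0, required = FALSE),
  x_hs_ppb = numeric_col(function(x) x >= 0)))

#' @rdname schemas
#' @export
isotope_pairs_schema <- function() table_schema(list(
  chamber_id = list(type = "character"),
  c_start = numeric_col(function(x) x > 0),
  c_end = numeric_col(function(x) x > 0),
  d15n_start = numeric_col(required = FALSE),
  d15n_end = numeric_col(required = FALSE),
  d18o_start = numeric_col(required = FALSE),
  d18o_end = numeric_col(required = FALSE)))

#' Read a chamber headspace series table
#'
#' @param path Path to the delimited file.
#' @return Validated data frame (see [read_table()]).
#' @export
read_chamber_table <- function(path) read_table(path, chamber_table_schema())

#' Read a flux panel table
#'
#' @inheritParams read_chamber_table
#' @export
read_flux_panel <- function(path) read_table(path, flux_panel_schema())

#' Write a delimited output table
#'
#' Comma-delimited UTF-8, dot decimals, no row names, full precision.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(tab, path) {
  # doubles serialised at 17 significant digits so a write-read cycle is
  # value-exact (default as.character drops to 15)
  for (nm in names(tab)) {
    if (is.double(tab[[nm]])) tab[[nm]] <- sprintf("%.17g", tab[[nm]])
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the defaults every stage needs so a whole run is reproducible
#' from one object: chamber geometry, solubility parameters, atmospheric
#' mixing ratios, per-gas transforms, coverage weights and the seed.
#'
#' @param geometry A [chamber_geometry()].
#' @param solubility Named list of [solubility_params()] keyed by species.
#' @param atm_mixing_ratios Named numeric (ppb) keyed by species.
#' @param transforms Named list of [transform_spec()] keyed by summary
#'   group (see [summarize_by_forest_type()]); `NULL` defers to per-group
#'   sign-based defaults.
#' @param weights A [coverage_weights()].
#' @param units Reporting units label.
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = chamber_geometry_from_dimensions(0.3, 0.3),
                            solubility = list(CH4 = solubility_params("CH4"),
                                              N2O = solubility_params("N2O")),
                            atm_mixing_ratios = c(CH4 = 1870, N2O = 332),
                            transforms = NULL,
                            weights = coverage_weights(),
                            units = "kg_element_ha_yr",
                            seed = 1) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(weights, "coverage_weights"))
  structure(
    list(geometry = geometry, solubility = solubility,
         atm_mixing_ratios = atm_mixing_ratios, transforms = transforms,
         weights = weights, units = units, seed = seed),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 4294967296)
}

#' Run the full analysis pipeline
#'
#' Chains the stages over whatever inputs are present: chamber series ->
#' fluxes; flux panel -> per-forest-type geometric means -> basin
#' upscaling; stream vials -> dissolved concentrations; isotope pairs ->
#' source signatures. Absent optional inputs skip their stage with a log
#' note. Each output table is written alongside a provenance JSON
#' (config hash, seed, package and R versions).
#'
#' @param config A [pipeline_config()].
#' @param inputs List with any of `series`, `panel`, `vials`, `pairs`
#'   (data frames, e.g. from the readers or generators).
#' @param out_dir Output directory, created if needed; `NULL` to skip
#'   writing.
#' @param quiet Suppress stage log messages.
#' @return List of class `pipeline_result` with the per-stage outputs
#'   (`fluxes`, `summary`, `basin`, `dissolved`, `signatures`) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list(),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[soilghg] ", ...)
  out <- list()

  if (!is.null(inputs$series)) {
    say("flux-compute: ", nrow(inputs$series), " headspace rows")
    out$fluxes <- compute_flux_table(inputs$series, config$geometry)
  } else say("flux-compute skipped: no chamber series input")

  if (!is.null(inputs$panel)) {
    say("summarize: ", nrow(inputs$panel), " panel rows")
    out$summary <- summarize_by_forest_type(inputs$panel, config$transforms)
    have <- out$summary$forest_type
    if (all(c("lowland", "montane") %in% have) &&
        any(grepl("swamp", have))) {
      ests <- build_type_estimates(out$summary, config$weights)
      basin <- basin_weighted_mean(ests, config$weights)
      out$basin <- data.frame(forest_type = "basin", point = basin$point,
                              ci_low = basin$ci_low, ci_high = basin$ci_high)
      say("upscale: basin mean ", signif(basin$point, 4), " ", config$units)
    } else say("upscale skipped: need lowland, montane and swamp summaries")
  } else say("summarize skipped: no flux panel input")

  if (!is.null(inputs$vials)) {
    say("dissolved: ", nrow(inputs$vials), " vials")
    out$dissolved <- do.call(rbind, lapply(seq_len(nrow(inputs$vials)),
      function(i) {
        v <- inputs$vials[i, ]
        vs <- vial_sample(v$species, v$water_ml, v$headspace_ml,
                          v$temp_C + 273.15, v$x_hs_ppb,
                          lab_pressure = v$pressure_atm %||% 1)
        r <- headspace_to_dissolved(vs, config$solubility[[v$species]])
        data.frame(species = v$species,
                   concentration_molar = r$concentration_molar,
                   concentration_mass = r$concentration_mass,
                   saturation_ratio = saturation_ratio(
                     r, stream_temperature = v$temp_C + 273.15,
                     atm_mixing_ratio = config$atm_mixing_ratios[[v$species]],
                     params = config$solubility[[v$species]]))
      }))
  } else say("dissolved skipped: no vial input")

  if (!is.null(inputs$pairs)) {
    say("isotopes: ", nrow(inputs$pairs), " pairs")
    out$signatures <- two_source_mixing_table(inputs$pairs)
  } else say("isotopes skipped: no isotope-pair input")

  out$provenance <- list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("soilghg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "provenance")) {
      write_output_table(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(out$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  structure(out, class = "pipeline_result")
}

build_type_estimates <- function(summary_tab, weights) {
  pick <- function(type) {
    row <- summary_tab[summary_tab$forest_type == type, ]
    if (!nrow(row)) return(NULL)
    type_estimate(type, row$point[[1L]], row$ci_low[[1L]], row$ci_high[[1L]])
  }
  swamp <- pick("swamp")
  if (is.null(swamp)) {
    inund <- pick("swamp_inundated")
    non <- pick("swamp_non_inundated")
    if (is.null(inund) || is.null(non)) {
      stop("swamp summary needs either a combined `swamp` group or both ",
           "inundated states", call. = FALSE)
    }
    swamp <- swamp_composite(inund, non, weights$inundated_fraction)
  }
  list(pick("lowland"), pick("montane"), swamp)
}
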