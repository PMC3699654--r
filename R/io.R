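# Delimited-text readers/writers with schema validation, measurement
# pairing, and run manifests. All tables are plain CSV; fluid densities are
# carried at full precision (no rounding on write).

measurement_schema <- c("cell_id", "fluid_label", "buoyant_mass_fg",
                        "exposure_time_s")
fluid_schema <- c("label", "density_g_per_cm3", "permeable",
                  "intracellular_water_density_g_per_cm3")

check_schema <- function(df, expected, path, allow_missing = character()) {
  unknown <- setdiff(names(df), expected)
  if (length(unknown))
    stop("schema error in ", path, ": unknown column(s) ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(setdiff(expected, allow_missing), names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a per-cell buoyant-mass measurement table
#'
#' Expects the header `cell_id,fluid_label,buoyant_mass_fg,exposure_time_s`
#' (exposure time optional). Buoyant masses must be finite; they may be
#' negative (cells float in a dense impermeable fluid).
#'
#' @param path CSV file path.
#' @return Validated data frame in the measurement schema.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, measurement_schema, path,
               allow_missing = "exposure_time_s")
  if (!"exposure_time_s" %in% names(df)) df$exposure_time_s <- NA_real_
  bad <- which(!is.finite(df$buoyant_mass_fg))
  if (length(bad))
    stop("validation error in ", path, ": non-finite buoyant_mass_fg at row ",
         bad[1L])
  df
}

#' Read a fluid-specification table
#'
#' Expects the header
#' `label,density_g_per_cm3,permeable,intracellular_water_density_g_per_cm3`.
#'
#' @param path CSV file path.
#' @return Named list of [fluid_spec] objects.
#' @export
read_fluids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, fluid_schema, path)
  bad <- which(!is.finite(df$density_g_per_cm3) | df$density_g_per_cm3 <= 0)
  if (length(bad))
    stop("validation error in ", path,
         ": density_g_per_cm3 must be positive (row ", bad[1L], ")")
  fluids <- lapply(seq_len(nrow(df)), function(i)
    fluid_spec(df$label[i], df$density_g_per_cm3[i],
               as.logical(df$permeable[i]),
               df$intracellular_water_density_g_per_cm3[i]))
  names(fluids) <- df$label
  fluids
}

#' Write a results table as CSV
#'
#' Plain CSV, no row names, full numeric precision.
#'
#' @param path Output path.
#' @param table Data frame to write.
#' @export
write_results <- function(path, table) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Pair per-fluid records into dual-fluid measurement pairs
#'
#' Matches, per cell, one record in `fluid1` with one record in `fluid2`.
#' Cells lacking either record are excluded and counted. Cells with
#' duplicate records in a fluid are an error under the `"strict"` policy;
#' under `"first"` the first record in table order is used deterministically.
#'
#' @param records Measurement table ([read_measurements()] schema).
#' @param fluid1,fluid2 [fluid_spec] objects whose labels select the records;
#'   attached to the result so the `solve_*` functions need no repeating.
#' @param policy Duplicate-record policy: `"strict"` (default) or `"first"`.
#' @return Data frame with `cell_id`, `mb1`, `mb2`, `exposure_time` (from the
#'   second-fluid record), fluid specs as attributes `fluid1`/`fluid2`, and
#'   an `exclusions` attribute counting cells dropped per reason.
#' @export
pair_measurements <- function(records, fluid1, fluid2,
                              policy = c("strict", "first")) {
  policy <- match.arg(policy)
  stopifnot(inherits(fluid1, "fluid_spec"), inherits(fluid2, "fluid_spec"))
  check_schema(records, measurement_schema, "records",
               allow_missing = "exposure_time_s")
  take <- function(label) {
    sub <- records[records$fluid_label == label, , drop = FALSE]
    dup <- duplicated(sub$cell_id)
    if (any(dup)) {
      if (policy == "strict")
        stop("ambiguous duplicates: cell(s) ",
             paste(unique(sub$cell_id[dup]), collapse = ", "),
             " have multiple records in fluid '", label,
             "' (policy = \"strict\")")
      sub <- sub[!dup, , drop = FALSE]
    }
    sub
  }
  r1 <- take(fluid1$label)
  r2 <- take(fluid2$label)
  common <- intersect(r1$cell_id, r2$cell_id)
  excl <- c(missing_fluid1 = length(setdiff(r2$cell_id, r1$cell_id)),
            missing_fluid2 = length(setdiff(r1$cell_id, r2$cell_id)))
  i1 <- match(common, r1$cell_id)
  i2 <- match(common, r2$cell_id)
  et <- if ("exposure_time_s" %in% names(r2)) r2$exposure_time_s[i2]
        else rep(NA_real_, length(common))
  out <- data.frame(cell_id = common,
                    mb1 = r1$buoyant_mass_fg[i1],
                    mb2 = r2$buoyant_mass_fg[i2],
                    exposure_time = et,
                    stringsAsFactors = FALSE)
  attr(out, "fluid1") <- fluid1
  attr(out, "fluid2") <- fluid2
  attr(out, "exclusions") <- excl
  out
}

#' Record a reproducible run manifest
#'
#' Snapshot of everything needed to reproduce a pipeline run: the scenario or
#' analysis configuration, every seed used, md5 digests of input/output
#' files, the package version and a timestamp.
#'
#' @param config Configuration object or list (stored as-is).
#' @param seeds Named list/vector of the seeds used.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return Object of class `"run_manifest"`.
#' @export
run_manifest <- function(config = NULL, seeds = list(),
                         inputs = character(), outputs = character()) {
  digest <- function(paths) {
    if (!length(paths)) return(character())
    existing <- paths[file.exists(paths)]
    tools::md5sum(existing)
  }
  structure(list(config = config,
                 seeds = seeds,
                 input_digests = digest(inputs),
                 output_digests = digest(outputs),
                 package_version = as.character(
                   utils::packageVersion("drycell")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ")),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> drycell", x$package_version, "at", x$timestamp, "\n")
  if (length(x$seeds))
    cat("  seeds:", paste(names(x$seeds), unlist(x$seeds), sep = "=",
                          collapse = ", "), "\n")
  if (length(x$input_digests))
    cat("  inputs:", length(x$input_digests), "file(s) digested\n")
  if (length(x$output_digests))
    cat("  outputs:", length(x$output_digests), "file(s) digested\n")
  invisible(x)
}
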