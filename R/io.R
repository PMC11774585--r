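# Canonical CSV formats:
#   timeseries:       strain,condition,plate,well,time_s,od
#   elements:         element,isotope,group,replicate,concentration_ugL,below_lod
#   characteristics:  strain,condition,plate,well,yield,growth_rate_per_h,
#                     fit_type,r2,excluded,exclusion_reason

.ts_columns <- c("strain", "condition", "plate", "well", "time_s", "od")

#' Read a long-format plate-reader time-series table
#'
#' The canonical input is one long CSV with one row per well per time point
#' and header `strain,condition,plate,well,time_s,od`. Rows are grouped into
#' one [growth_experiment()] per (strain, condition); within each well the
#' rows are sorted by time, so the reader is independent of row order.
#'
#' @param path Path to a CSV file.
#' @return A list of [growth_experiment()] objects.
#' @seealso [wide_to_long()] for converting wide plate-reader exports.
#' @export
read_timeseries_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("format error: time-series table is empty: ", path, call. = FALSE)
  missing <- setdiff(.ts_columns, names(df))
  if (length(missing))
    stop("format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$condition), c("with_TE", "without_TE"))
  if (length(bad))
    stop("format error: unknown condition value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  experiments_from_long(df)
}

#' Assemble experiments from a long-format data frame
#'
#' @param df Data frame with columns
#'   `strain,condition,plate,well,time_s,od`.
#' @return A list of [growth_experiment()] objects, one per
#'   (strain, condition), each curve sorted by time.
#' @export
experiments_from_long <- function(df) {
  missing <- setdiff(.ts_columns, names(df))
  if (length(missing))
    stop("format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$time_s) || !is.numeric(df$od))
    stop("format error: time_s and od must be numeric", call. = FALSE)
  if (anyNA(df$od) || anyNA(df$time_s))
    stop("data error: missing time or OD values are not allowed", call. = FALSE)
  key <- interaction(df$strain, df$condition, drop = TRUE, sep = "\r")
  lapply(split(df, key), function(sub) {
    wkey <- interaction(sub$plate, sub$well, drop = TRUE, sep = "\r")
    curves <- lapply(split(sub, wkey), function(w) {
      o <- order(w$time_s)
      w <- w[o, ]
      if (anyDuplicated(w$time_s))
        stop("data error: duplicate or non-monotone times in well ",
             w$well[1], " (plate ", w$plate[1], ")", call. = FALSE)
      growth_curve(well_id = as.character(w$well[1]),
                   plate_id = as.character(w$plate[1]),
                   times = w$time_s, ods = w$od)
    })
    names(curves) <- NULL
    # deterministic curve order regardless of input row order
    ord <- order(vapply(curves, `[[`, character(1), "plate_id"),
                 vapply(curves, `[[`, character(1), "well_id"))
    growth_experiment(strain = as.character(sub$strain[1]),
                      condition = as.character(sub$condition[1]),
                      curves = curves[ord])
  })
}

#' Write experiments to the canonical long-format CSV
#'
#' @param experiments A [growth_experiment()] or list thereof.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(experiments, path) {
  if (inherits(experiments, "growth_experiment"))
    experiments <- list(experiments)
  df <- do.call(rbind, lapply(experiments, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a wide plate-reader export to the canonical long format
#'
#' Wide exports have one time column plus one column per well. The long form
#' is authoritative; this is a convenience converter.
#'
#' @param df Data frame whose first column (or `time_col`) holds times in
#'   seconds and whose remaining columns hold one well each.
#' @param strain,condition,plate Metadata to attach to every row.
#' @param time_col Name of the time column (default: first column).
#' @return A long-format data frame with the canonical columns.
#' @export
wide_to_long <- function(df, strain, condition, plate = "P1",
                         time_col = names(df)[1]) {
  stopifnot(time_col %in% names(df))
  wells <- setdiff(names(df), time_col)
  if (!length(wells)) stop("no well columns found", call. = FALSE)
  out <- do.call(rbind, lapply(wells, function(w) {
    data.frame(strain = strain, condition = condition, plate = plate,
               well = w, time_s = df[[time_col]], od = df[[w]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.el_columns <- c("element", "isotope", "group", "replicate",
                 "concentration_ugL", "below_lod")

#' Read an element-concentration table (ICP-MS style)
#'
#' Expects header
#' `element,isotope,group,replicate,concentration_ugL,below_lod` with
#' `group` in `{sample, control}`. Concentrations of below-LOD records may
#' be empty; they are kept as `NA` with the censoring flag preserved.
#'
#' @param path Path to a CSV file.
#' @return A data frame of measurements, ordered by element.
#' @export
read_element_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(concentration_ugL = "numeric"))
  missing <- setdiff(.el_columns, names(df))
  if (length(missing))
    stop("format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$group), c("sample", "control"))
  if (length(bad))
    stop("format error: group must be 'sample' or 'control', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df$below_lod <- as.logical(df$below_lod)
  if (anyNA(df$below_lod))
    stop("format error: below_lod must be TRUE/FALSE", call. = FALSE)
  if (any(!df$below_lod & (is.na(df$concentration_ugL) |
                           df$concentration_ugL < 0)))
    stop("data error: quantified records need a non-negative concentration",
         call. = FALSE)
  df$isotope <- as.character(df$isotope)
  df$isotope[is.na(df$isotope)] <- ""
  df[order(df$element, df$isotope), , drop = FALSE]
}

#' Write an element-concentration table
#'
#' @param measurements Data frame as returned by [read_element_table()] or
#'   [generate_element_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_element_table <- function(measurements, path) {
  stopifnot(all(.el_columns %in% names(measurements)))
  write.csv(measurements[, .el_columns], path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

.chr_columns <- c("strain", "condition", "plate", "well", "yield",
                  "growth_rate_per_h", "fit_type", "r2", "excluded",
                  "exclusion_reason")

#' Write a per-well growth-characteristics table
#'
#' One row per well with yield, growth rate, fit diagnostics and exclusion
#' status. Excluded wells keep empty yield/rate fields with the reason
#' filled. Numeric fields are written with full precision so the table
#' round-trips losslessly through [read_characteristics_table()].
#'
#' @param results Data frame with columns
#'   `strain,condition,plate,well,yield,growth_rate_per_h,fit_type,r2,excluded,exclusion_reason`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_characteristics_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("`results` must be a non-empty data frame", call. = FALSE)
  missing <- setdiff(.chr_columns, names(results))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- results[, .chr_columns]
  for (cc in c("yield", "growth_rate_per_h", "r2"))
    out[[cc]] <- ifelse(is.na(out[[cc]]), "",
                        formatC(out[[cc]], digits = 15, format = "g"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-well growth-characteristics table
#'
#' @param path CSV written by [write_characteristics_table()].
#' @return Data frame with the canonical characteristics columns.
#' @export
read_characteristics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(yield = "numeric",
                                growth_rate_per_h = "numeric",
                                r2 = "numeric"))
  missing <- setdiff(.chr_columns, names(df))
  if (length(missing))
    stop("format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$excluded <- as.logical(df$excluded)
  df$fit_type <- as.character(df$fit_type)
  df$fit_type[is.na(df$fit_type)] <- ""
  df
}
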