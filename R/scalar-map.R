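#' Per-pixel scalar map with units and a validity mask
#'
#' A `scalar_map` is the package's container for quantitative images: T1
#' maps (s), R1 maps (1/s), TOLD enhancement maps (%), volume-fraction
#' maps, or oxygen-shift maps. It carries the pixel values, a unit tag,
#' and a logical validity mask. Pixels that could not be fitted (or fell
#' outside an ROI) are flagged invalid rather than silently zeroed, and
#' every summary in the package uses valid pixels only.
#'
#' @param values numeric matrix (or array) of pixel values.
#' @param unit unit tag, one of `"s"`, `"1/s"`, `"%"`, `"mM"`, `"mmHg"`,
#'   `"fraction"`, `"intensity"`.
#' @param valid logical mask of the same shape; defaults to
#'   `is.finite(values)`.
#' @return An object of class `scalar_map`.
#' @examples
#' m <- scalar_map(matrix(1.85, 4, 4), unit = "s")
#' r <- t1_to_r1(m)
#' round(values(r)[1, 1], 2)
#' @export
scalar_map <- function(values, unit, valid = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  unit <- match.arg(unit, c("s", "1/s", "%", "mM", "mmHg", "fraction",
                            "intensity"))
  values <- as.array(values)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- array(as.logical(valid), dim(values))
  if (!identical(dim(valid), dim(values)))
    stop("`valid` mask shape does not match `values`")
  values[!valid] <- NA_real_
  structure(list(values = values, unit = unit, valid = valid),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> %s pixels, unit '%s', %d valid\n",
              paste(dim(x$values), collapse = " x "), x$unit,
              sum(x$valid)))
  v <- x$values[x$valid]
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Extract the value array of a scalar map
#' @param x a `scalar_map`.
#' @return The numeric array of pixel values (`NA` where invalid).
#' @export
values <- function(x) UseMethod("values")

#' @export
values.scalar_map <- function(x) x$values

#' Convert between T1 and R1 maps
#'
#' Takes reciprocals pixelwise: a T1 map in seconds becomes an R1
#' relaxation-rate map in 1/s and vice versa, so the operation is its own
#' inverse on valid pixels. Zero-valued pixels are flagged invalid.
#'
#' @param map a `scalar_map` with unit `"s"` or `"1/s"`, or a bare
#'   numeric vector of T1 values in seconds.
#' @return A `scalar_map` with the reciprocal unit (or a numeric vector).
#' @export
t1_to_r1 <- function(map) {
  if (is.numeric(map)) return(1 / map)
  if (!inherits(map, "scalar_map")) stop("`map` must be a scalar_map")
  if (!map$unit %in% c("s", "1/s"))
    stop(sprintf("cannot invert a map with unit '%s'", map$unit))
  ok <- map$valid & is.finite(map$values) & map$values != 0
  out <- 1 / map$values
  scalar_map(out, unit = if (map$unit == "s") "1/s" else "s", valid = ok)
}

#' Difference of two R1 maps or ROI means
#'
#' Forms the gas-challenge relaxation-rate shift, e.g. R1 under carbogen
#' minus R1 under air. Pixels are valid only where both inputs are.
#'
#' @param r1_after,r1_before `scalar_map`s with matching unit and
#'   geometry, or plain numerics.
#' @return A `scalar_map` (or numeric) of the difference.
#' @export
delta_r1 <- function(r1_after, r1_before) {
  if (is.numeric(r1_after) && is.numeric(r1_before))
    return(r1_after - r1_before)
  if (!inherits(r1_after, "scalar_map") || !inherits(r1_before, "scalar_map"))
    stop("inputs must both be scalar_maps or both numeric")
  if (!identical(r1_after$unit, r1_before$unit))
    stop(sprintf("unit mismatch: '%s' vs '%s'",
                 r1_after$unit, r1_before$unit))
  if (!identical(dim(r1_after$values), dim(r1_before$values)))
    stop("geometry mismatch between the two maps")
  scalar_map(r1_after$values - r1_before$values, unit = r1_after$unit,
             valid = r1_after$valid & r1_before$valid)
}

#' Summarise a scalar map over labelled ROIs
#'
#' @param map a `scalar_map`.
#' @param labels integer label image of the same shape (0 = background),
#'   or a single logical mask.
#' @param roi_names optional character names for the integer labels.
#' @return A data.frame with columns `roi`, `n_pixels`, `mean`, `sd`
#'   computed over valid pixels only.
#' @export
roi_summary <- function(map, labels, roi_names = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  labels <- as.array(labels)
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  if (!identical(dim(labels), dim(map$values)))
    stop("label image shape does not match the map")
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(i) {
    sel <- labels == i & map$valid
    v <- map$values[sel]
    data.frame(
      roi = if (!is.null(roi_names) && i <= length(roi_names))
        roi_names[i] else as.character(i),
      n_pixels = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
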