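#' Upper-quartile intensity of a set of pixel values
#'
#' The robust per-object intensity score: the 75th percentile of the
#' object's pixel values under linear interpolation between order
#' statistics (rank position `0.75 * (n - 1)`, 0-based). The same
#' percentile convention is used for all quartiles reported by the
#' package.
#'
#' @param pixel_values non-empty numeric vector of non-negative values.
#' @return the upper-quartile intensity.
#' @export
upper_quartile_intensity <- function(pixel_values) {
  percentile_linear(pixel_values, 0.75)
}

# shared percentile convention: linear interpolation between order
# statistics at 0-based rank position p * (n - 1)
percentile_linear <- function(x, p) {
  if (length(x) == 0) stop("pixel_values must be non-empty")
  if (anyNA(x)) stop("pixel_values must not contain NA")
  s <- sort(x)
  n <- length(s)
  h <- p * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  if (lo + 2 > n) return(s[n])
  s[lo + 1] * (1 - frac) + s[lo + 2] * frac
}

#' Score retained fragments on one image
#'
#' Computes the upper-quartile signal intensity of every retained
#' fragment and joins it with the fragment's shape measures.
#'
#' @param signal an [image_channel()] with role `"signal"`.
#' @param fragments a `label_map` of retained fragments.
#' @param shape_table data.frame from [measure_shapes()] on `fragments`.
#' @param image_id image identifier recorded with each fragment.
#' @param condition optional condition label (filled by pooling when
#'   `NA`).
#' @return data.frame of fragment records with columns `image_id`,
#'   `condition`, `label`, `area_px`, `perimeter_px`, `circularity`,
#'   `upq_intensity`, `upq_normalized` (NA until normalization).
#' @export
quantify_fragments <- function(signal, fragments, shape_table, image_id,
                               condition = NA_character_) {
  stopifnot(inherits(signal, "image_channel"),
            inherits(fragments, "label_map"))
  n <- fragments$n_objects
  if (n == 0L)
    return(data.frame(image_id = character(0), condition = character(0),
                      label = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      upq_intensity = numeric(0), upq_normalized = numeric(0)))
  lab <- fragments$labels
  pos <- lab > 0L
  upq <- vapply(split(as.numeric(signal$pixels[pos]), lab[pos]),
                upper_quartile_intensity, numeric(1))
  st <- shape_table[match(seq_len(n), shape_table$label), ]
  data.frame(image_id = image_id, condition = condition,
             label = seq_len(n), area_px = st$area_px,
             perimeter_px = st$perimeter_px, circularity = st$circularity,
             upq_intensity = as.numeric(upq),
             upq_normalized = NA_real_, row.names = NULL)
}

#' Pool per-image fragment records across conditions
#'
#' Joins fragment records with a manifest mapping `image_id` to
#' condition and returns a condition table. Conditions present in the
#' manifest but without any fragment records are kept with n = 0 (with a
#' warning).
#'
#' @param per_image_records data.frame of fragment records (rows from
#'   [quantify_fragments()], possibly several images).
#' @param manifest data.frame with columns `file` (the image id) and
#'   `condition`.
#' @param control_label the control condition.
#' @return an object of class `condition_table`: `records`,
#'   `control_label`, `conditions`, `n_per_condition`, `n_per_image`.
#' @export
pool_measurements <- function(per_image_records, manifest,
                              control_label = "CTRL") {
  stopifnot(is.data.frame(per_image_records), is.data.frame(manifest),
            all(c("file", "condition") %in% names(manifest)))
  rec <- per_image_records
  unknown <- setdiff(unique(rec$image_id), manifest$file)
  if (length(unknown))
    stop("fragment records reference image ids absent from the manifest: ",
         paste(unknown, collapse = ", "))
  rec$condition <- manifest$condition[match(rec$image_id, manifest$file)]
  conditions <- unique(manifest$condition)
  if (!control_label %in% conditions)
    stop("control condition '", control_label, "' absent from the manifest")
  n_per_condition <- vapply(conditions,
                            function(cc) sum(rec$condition == cc), integer(1))
  names(n_per_condition) <- conditions
  empty <- conditions[n_per_condition == 0]
  if (length(empty))
    warning("conditions with no fragment records: ",
            paste(empty, collapse = ", "))
  n_per_image <- vapply(manifest$file,
                        function(f) sum(rec$image_id == f), integer(1))
  names(n_per_image) <- manifest$file
  structure(list(records = rec[order(match(rec$condition, conditions)), ,
                               drop = FALSE],
                 control_label = control_label,
                 conditions = conditions,
                 n_per_condition = n_per_condition,
                 n_per_image = n_per_image),
            class = "condition_table")
}

#' Normalize pooled intensities to the control-condition median
#'
#' Divides every fragment's raw upper-quartile intensity by the median
#' raw intensity of the control condition, so the control's normalized
#' median is exactly 1 (the unit of all reported medians). Idempotent on
#' already-normalized values.
#'
#' @param table a `condition_table` from [pool_measurements()].
#' @return the table with `upq_normalized` populated.
#' @export
normalize_to_control <- function(table) {
  stopifnot(inherits(table, "condition_table"))
  ctrl <- table$records$upq_intensity[
    table$records$condition == table$control_label]
  if (length(ctrl) == 0)
    stop("control condition '", table$control_label, "' has no records")
  med <- median(ctrl)
  if (!is.finite(med) || med == 0)
    stop("control median is zero or undefined; cannot normalize")
  table$records$upq_normalized <- table$records$upq_intensity / med
  table$control_median_raw <- med
  table
}

#' Per-condition summary statistics (violin-plot numbers)
#'
#' Median and interquartile range (25th-75th percentile, same linear
#' interpolation convention as [upper_quartile_intensity()]) of the
#' normalized scores, plus the pooled fragment count per condition.
#'
#' @param table a normalized `condition_table`.
#' @param value `"upq_normalized"` (default) or `"upq_intensity"`.
#' @return data.frame: `condition`, `median`, `q25`, `q75`, `n`.
#' @export
summarize_conditions <- function(table, value = "upq_normalized") {
  stopifnot(inherits(table, "condition_table"))
  rows <- lapply(table$conditions, function(cc) {
    v <- table$records[[value]][table$records$condition == cc]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(data.frame(condition = cc, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, n = 0L))
    data.frame(condition = cc,
               median = percentile_linear(v, 0.5),
               q25 = percentile_linear(v, 0.25),
               q75 = percentile_linear(v, 0.75),
               n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.condition_table <- function(x, ...) {
  cat("condition_table:", nrow(x$records), "fragments across",
      length(x$conditions), "conditions (control:", x$control_label, ")\n")
  print(x$n_per_condition)
  invisible(x)
}
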