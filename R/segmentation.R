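# Segmentation primitives: thresholding, connected components, nuclear
# exclusion mask, shape measurement and shape-based object selection.
# All labeling uses 8-connectivity (configured once here) for both the
# nuclei and the signal channel.

FRAGMENT_CONNECTIVITY <- 8L

new_label_map <- function(labels, n_objects) {
  structure(list(labels = labels, n_objects = as.integer(n_objects)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map:", x$n_objects, "objects on a",
      nrow(x$labels), "x", ncol(x$labels), "grid\n")
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' Deterministic two-pass union-find labeling; labels are consecutive
#' integers 1..n in row-major order of first occurrence.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return a `label_map`: `labels` (integer matrix, 0 = background) and
#'   `n_objects`.
#' @export
label_components <- function(mask, connectivity = FRAGMENT_CONNECTIVITY) {
  stopifnot(is.matrix(mask))
  lab <- label_components_cpp(mask, as.integer(connectivity))
  new_label_map(lab, attr(lab, "n_objects"))
}

# relabel retained objects consecutively, preserving original order;
# returns list(map = label_map, mapping = data.frame(old, new))
relabel_consecutive <- function(labels, keep) {
  keep <- sort(unique(keep))
  lut <- integer(max(labels, 1L))
  lut[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos]]
  list(map = new_label_map(out, length(keep)),
       mapping = data.frame(old = keep, new = seq_along(keep)))
}

#' Otsu threshold (two-class)
#'
#' Maximizes between-class variance on a 256-bin histogram; returns the
#' threshold value (pixels strictly above it are foreground).
#'
#' @param values numeric vector of pixel values.
#' @param bins number of histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[2])  # degenerate: nothing above
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- pmin(findInterval(values, edges, rightmost.closed = TRUE), bins)
  h <- tabulate(idx, bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- cumsum(p)
  m <- cumsum(p * mids)
  mt <- m[bins]
  valid <- w > 0 & w < 1
  sb2 <- rep(-Inf, bins)
  sb2[valid] <- (mt * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  t_idx <- which.max(sb2)
  edges[t_idx + 1L]
}

# Three-class Otsu; returns the two threshold values (t1 < t2).
otsu3_thresholds <- function(values, bins = 256L) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(c(rng[2], rng[2]))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- pmin(findInterval(values, edges, rightmost.closed = TRUE), bins)
  h <- tabulate(idx, bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  tot <- cm[bins]
  best <- -Inf; best_t <- c(1L, 2L)
  for (t1 in 1:(bins - 2L)) {
    w1 <- cw[t1]
    if (w1 <= 0) next
    term1 <- cm[t1]^2 / w1
    t2 <- (t1 + 1L):(bins - 1L)
    w2 <- cw[t2] - w1
    w3 <- 1 - cw[t2]
    m2 <- cm[t2] - cm[t1]
    m3 <- tot - cm[t2]
    obj <- term1 +
      ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    k <- which.max(obj)
    if (obj[k] > best) { best <- obj[k]; best_t <- c(t1, t2[k]) }
  }
  c(edges[best_t[1] + 1L], edges[best_t[2] + 1L])
}

# Fill holes: background components (4-connected) not touching the image
# border are interior holes.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)$labels
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | !(bg %in% c(0L, border_labels))
}

#' Segment nuclei on the nuclei channel
#'
#' Otsu-thresholds the nuclei channel, fills interior holes, labels
#' 8-connected components and removes objects smaller than
#' `min_area_px`. An all-constant image yields an empty label map.
#'
#' @param nuclei an [image_channel()] with role `"nuclei"`.
#' @param min_area_px minimum object area in pixels.
#' @return a `label_map`.
#' @export
segment_nuclei <- function(nuclei, min_area_px = 100) {
  stopifnot(inherits(nuclei, "image_channel"))
  if (nuclei$role != "nuclei")
    stop("segment_nuclei() expects the nuclei channel, got role '",
         nuclei$role, "'")
  px <- nuclei$pixels
  if (min(px) == max(px))
    return(new_label_map(matrix(0L, nrow(px), ncol(px)), 0L))
  thr <- otsu_threshold(px)
  mask <- px > thr
  mask <- matrix(fill_holes(mask), nrow(px), ncol(px))
  lm <- label_components(mask, FRAGMENT_CONNECTIVITY)
  if (lm$n_objects == 0L) return(lm)
  areas <- tabulate(lm$labels[lm$labels > 0L], lm$n_objects)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L)
    return(new_label_map(matrix(0L, nrow(px), ncol(px)), 0L))
  relabel_consecutive(lm$labels, keep)$map
}

#' Build the perinuclear exclusion mask by Euclidean expansion
#'
#' The mask contains every pixel whose Euclidean distance to the nearest
#' nucleus pixel is at most `expansion_distance_px`; it is monotone in
#' the distance. Fragment detection never assigns pixels inside this
#' mask, which removes perinuclear fluorescence from the measurement.
#'
#' @param nuclei_labels a `label_map` of segmented nuclei.
#' @param expansion_distance_px non-negative expansion distance (pixels).
#' @return logical matrix (TRUE = excluded).
#' @export
build_exclusion_mask <- function(nuclei_labels, expansion_distance_px) {
  stopifnot(inherits(nuclei_labels, "label_map"),
            expansion_distance_px >= 0)
  nuc <- nuclei_labels$labels > 0L
  if (!any(nuc)) return(matrix(FALSE, nrow(nuc), ncol(nuc)))
  d <- distance_to_mask_cpp(nuc)
  d <= expansion_distance_px
}

#' Detect candidate membrane fragments on the signal channel
#'
#' Thresholds the signal channel outside the exclusion mask and labels
#' 8-connected components. The default `"otsu3"` method computes a
#' three-class Otsu split of the non-excluded pixels and keeps the top
#' class (background and diffuse cytoplasm form the lower two classes);
#' `"otsu"` is the two-class version, `"quantile"` keeps pixels above a
#' configured quantile, `"fixed"` uses an absolute threshold.
#'
#' @param signal an [image_channel()] with role `"signal"`.
#' @param exclusion logical matrix from [build_exclusion_mask()].
#' @param threshold_method one of `"otsu3"`, `"otsu"`, `"quantile"`,
#'   `"fixed"`.
#' @param threshold_params list: `quantile` (default 0.95) for
#'   `"quantile"`; `value` for `"fixed"`.
#' @return a `label_map` with attribute `"threshold"`.
#' @export
detect_membrane_fragments <- function(signal, exclusion,
                                      threshold_method = "otsu3",
                                      threshold_params = list()) {
  stopifnot(inherits(signal, "image_channel"))
  if (signal$role != "signal")
    stop("detect_membrane_fragments() expects the signal channel, got role '",
         signal$role, "'")
  px <- signal$pixels
  if (!is.matrix(exclusion) || !all(dim(exclusion) == dim(px)))
    stop("exclusion mask shape does not match the signal channel")
  cand <- px[!exclusion]
  thr <- switch(threshold_method,
    otsu3 = otsu3_thresholds(cand)[2],
    otsu = otsu_threshold(cand),
    quantile = quantile(cand, threshold_params$quantile %||% 0.95,
                        names = FALSE, type = 7),
    fixed = threshold_params$value %||%
      stop("fixed threshold requires threshold_params$value"),
    stop("unknown threshold method: ", threshold_method))
  mask <- px > thr & !exclusion
  lm <- label_components(mask, FRAGMENT_CONNECTIVITY)
  attr(lm, "threshold") <- thr
  lm
}

# -- shape measurement ------------------------------------------------------

# Perimeter estimator: weighted border-pixel configuration counts with
# diagonal correction. The object border (pixels removed by a
# 4-connected erosion) is convolved with the kernel
#   10  2 10
#    2  1  2
#   10  2 10
# and each odd convolution value v = 1 + 2*(orthogonal border
# neighbours) + 10*(diagonal border neighbours) contributes a weight:
# 1 for straight runs, sqrt(2) for diagonal runs, (1+sqrt(2))/2 for
# corner transitions. Disks score circularity close to 1 under this
# estimator; thin bars score far below it.
PERIM_WEIGHTS <- local({
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  w
})

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

object_perimeter <- function(mask) {
  # pad so border logic needs no edge cases
  nr <- nrow(mask) + 2L; nc <- ncol(mask) + 2L
  m <- matrix(FALSE, nr, nc)
  m[2:(nr - 1L), 2:(nc - 1L)] <- mask
  eroded <- m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
  border <- m & !eroded
  orth <- shift_mat(border, 1, 0) + shift_mat(border, -1, 0) +
    shift_mat(border, 0, 1) + shift_mat(border, 0, -1)
  diag <- shift_mat(border, 1, 1) + shift_mat(border, 1, -1) +
    shift_mat(border, -1, 1) + shift_mat(border, -1, -1)
  v <- (1 + 2 * orth + 10 * diag)[border]
  sum(PERIM_WEIGHTS[pmin(v, 49) + 1])
}

#' Measure area, perimeter and circularity of one labeled object
#'
#' Circularity is the form factor \eqn{4\pi A / P^2}: close to 1 for
#' disks, far below 1 for long, thin fragments. The perimeter comes from
#' a border-configuration estimator with diagonal correction (documented
#' in the package source); all circularity-based selection uses this
#' estimator consistently.
#'
#' @param label_map a `label_map`.
#' @param label object label to measure.
#' @return a one-row data.frame: `label`, `area_px`, `perimeter_px`,
#'   `circularity`.
#' @export
measure_shape <- function(label_map, label) {
  tab <- measure_shapes(label_map, labels = label)
  if (nrow(tab) == 0) stop("label ", label, " not present in the label map")
  tab
}

#' Measure shapes of all (or selected) labeled objects
#'
#' @param label_map a `label_map`.
#' @param labels integer vector of labels to measure (default: all).
#' @return data.frame with one row per object.
#' @export
measure_shapes <- function(label_map, labels = NULL) {
  stopifnot(inherits(label_map, "label_map"))
  lab <- label_map$labels
  present <- seq_len(label_map$n_objects)
  if (!is.null(labels)) present <- intersect(present, labels)
  if (length(present) == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), circularity = numeric(0)))
  nr <- nrow(lab)
  pos <- which(lab > 0L)
  lv <- lab[pos]
  sel <- lv %in% present
  pos <- pos[sel]; lv <- lv[sel]
  rows_all <- (pos - 1L) %% nr + 1L
  cols_all <- (pos - 1L) %/% nr + 1L
  out <- lapply(split(seq_along(pos), lv), function(ii) {
    r <- rows_all[ii]; cc <- cols_all[ii]
    rmin <- min(r); cmin <- min(cc)
    crop <- matrix(FALSE, max(r) - rmin + 1L, max(cc) - cmin + 1L)
    crop[cbind(r - rmin + 1L, cc - cmin + 1L)] <- TRUE
    p <- object_perimeter(crop)
    a <- length(ii)
    data.frame(label = lv[ii[1]], area_px = a, perimeter_px = p,
               circularity = if (p > 0) 4 * pi * a / p^2 else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$label), , drop = FALSE]
}

#' Retain long-and-thin fragments by area and circularity
#'
#' Keeps objects with `area_range[1] <= area <= area_range[2]` and
#' `circularity <= circularity_max`, then relabels consecutively.
#' Filtering an already-filtered map with the same parameters is the
#' identity.
#'
#' @param label_map a `label_map` of candidate fragments.
#' @param shape_table data.frame from [measure_shapes()] covering all
#'   labels of `label_map`.
#' @param area_range numeric length-2 (min, max) area in pixels.
#' @param circularity_max maximum form factor retained.
#' @return list: `map` (filtered `label_map`), `mapping`
#'   (data.frame old -> new labels).
#' @export
filter_fragments <- function(label_map, shape_table, area_range,
                             circularity_max) {
  stopifnot(inherits(label_map, "label_map"), length(area_range) == 2)
  if (label_map$n_objects == 0L)
    return(list(map = label_map,
                mapping = data.frame(old = integer(0), new = integer(0))))
  if (!all(seq_len(label_map$n_objects) %in% shape_table$label))
    stop("shape_table does not cover all labels")
  st <- shape_table[match(seq_len(label_map$n_objects), shape_table$label), ]
  keep <- which(st$area_px >= area_range[1] & st$area_px <= area_range[2] &
                  st$circularity <= circularity_max)
  if (length(keep) == 0L)
    return(list(map = new_label_map(matrix(0L, nrow(label_map$labels),
                                           ncol(label_map$labels)), 0L),
                mapping = data.frame(old = integer(0), new = integer(0))))
  relabel_consecutive(label_map$labels, keep)
}
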