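#' Specification of a synthetic two-channel microscopy scene
#'
#' Describes a field of non-overlapping model cells. Each cell is a 2D
#' disk with a nuclear disk (painted on the nuclei channel), a cytoplasm
#' region, a bright perinuclear halo just outside the nucleus (the
#' artifact the exclusion mask must remove), and a membrane annulus whose
#' mean intensity exceeds the cytoplasm by `membrane_enrichment`. The
#' annulus is broken by seed-controlled angular gaps so that detected
#' objects are long, thin fragments rather than closed rings. Noise is
#' applied Poisson-first, then additive Gaussian, then values are clipped
#' and quantized to `bit_depth`.
#'
#' Geometry is scaled down relative to a real confocal field (cells of
#' 35-55 px radius rather than the hundreds of pixels a 15-20 um cell
#' would span at 0.082 um/px) to keep runtimes small; every statistic the
#' pipeline reports is scale-free in cell size.
#'
#' @param image_height_px,image_width_px scene dimensions in pixels.
#' @param n_cells number of cells to attempt to place (rejection
#'   sampling; if placement fails the scene records fewer cells).
#' @param cell_radius_px length-2 range of cell radii (pixels).
#' @param nucleus_radius_fraction nucleus radius as a fraction of the
#'   cell radius, in (0, 1).
#' @param membrane_thickness_px thickness of the membrane annulus.
#' @param cytoplasm_intensity mean cytoplasm intensity (camera counts).
#' @param membrane_enrichment ratio of membrane-annulus mean to cytoplasm
#'   mean for the control condition.
#' @param perinuclear_intensity halo intensity (camera counts).
#' @param halo_thickness_px thickness of the perinuclear halo annulus.
#' @param nuclei_channel_intensity painted nucleus intensity on the
#'   nuclei channel.
#' @param cell_brightness_cv coefficient of variation of a per-cell
#'   log-normal brightness factor (median 1) applied to all signal-channel
#'   paints of a cell; models cell-to-cell expression variability.
#' @param membrane_gap_count number of angular gaps in the annulus,
#'   evenly spaced with jitter.
#' @param membrane_gap_width_deg length-2 range of gap widths (degrees).
#' @param gaussian_noise_sd additive Gaussian (read) noise SD in counts.
#' @param poisson_noise apply Poisson (shot) noise before Gaussian noise.
#' @param bit_depth quantization depth; values clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size_um physical pixel size recorded as metadata.
#' @param seed RNG seed; identical spec + seed reproduces the scene
#'   bit for bit.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_height_px = 640, image_width_px = 640,
                       n_cells = 10, cell_radius_px = c(35, 55),
                       nucleus_radius_fraction = 0.4,
                       membrane_thickness_px = 4,
                       cytoplasm_intensity = 3000,
                       membrane_enrichment = 2.5,
                       perinuclear_intensity = 6000,
                       halo_thickness_px = 5,
                       nuclei_channel_intensity = 10000,
                       cell_brightness_cv = 0.2,
                       membrane_gap_count = 3,
                       membrane_gap_width_deg = c(10, 25),
                       gaussian_noise_sd = 50,
                       poisson_noise = TRUE,
                       bit_depth = 16L,
                       pixel_size_um = 0.082,
                       seed = 1L) {
  spec <- structure(as.list(environment()), class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  with(spec, {
    stopifnot(image_height_px >= 1, image_width_px >= 1, n_cells >= 0,
              length(cell_radius_px) == 2, membrane_thickness_px >= 1,
              cytoplasm_intensity > 0, membrane_enrichment > 0,
              perinuclear_intensity >= 0, nuclei_channel_intensity > 0,
              cell_brightness_cv >= 0, gaussian_noise_sd >= 0,
              halo_thickness_px >= 0, membrane_gap_count >= 0)
    if (any(cell_radius_px <= 0)) stop("cell radii must be positive")
    if (cell_radius_px[1] > cell_radius_px[2]) stop("cell_radius_px must be (min, max)")
    if (!(nucleus_radius_fraction > 0 && nucleus_radius_fraction < 1))
      stop("impossible geometry: nucleus radius must be smaller than the cell radius")
    r_min <- cell_radius_px[1]
    if (nucleus_radius_fraction * r_min + halo_thickness_px >=
        r_min - membrane_thickness_px)
      stop("impossible geometry: nucleus + halo would reach the membrane annulus ",
           "at the smallest cell radius")
  })
  spec
}

# angular membership of theta (radians, in [-pi, pi]) in any gap
in_angular_gap <- function(theta, centers, widths) {
  hit <- rep(FALSE, length(theta))
  for (g in seq_along(centers)) {
    d <- abs(((theta - centers[g] + pi) %% (2 * pi)) - pi)
    hit <- hit | d < widths[g] / 2
  }
  hit
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @param enrichment_multiplier scales `membrane_enrichment` relative to
#'   the control condition (see [condition_preset()]).
#' @param condition_label optional label recorded in the output.
#' @return an object of class `scene`: `channels` (named list of
#'   [image_channel()]: `nuclei`, `signal`), and `ground_truth` with
#'   `nucleus_labels`, `membrane_labels`, `halo_labels`,
#'   `cytoplasm_labels` (`label_map` objects, one label per cell) and
#'   `cell_table` (per-cell center, radii, brightness factor and true
#'   membrane/cytoplasm enrichment ratio).
#' @export
generate_scene <- function(spec, enrichment_multiplier = 1,
                           condition_label = NULL) {
  validate_scene_spec(spec)
  if (enrichment_multiplier <= 0) stop("enrichment_multiplier must be positive")
  set.seed(spec$seed)
  H <- spec$image_height_px; W <- spec$image_width_px

  nuclei <- matrix(0, H, W)
  signal <- matrix(0, H, W)
  nuc_lab <- matrix(0L, H, W)
  mem_lab <- matrix(0L, H, W)
  halo_lab <- matrix(0L, H, W)
  cyto_lab <- matrix(0L, H, W)

  # rejection placement of non-overlapping disks fully inside the frame
  margin <- 3
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  max_attempts <- max(300L * spec$n_cells, 1L)
  while (length(radii) < spec$n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, spec$cell_radius_px[1], spec$cell_radius_px[2])
    if (2 * r + 2 >= min(H, W)) next
    cy <- runif(1, r + 1, H - r)
    cx <- runif(1, r + 1, W - r)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      if (any(d < radii + r + margin)) next
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
  }
  n_placed <- length(radii)
  if (n_placed < spec$n_cells)
    warning("placed only ", n_placed, " of ", spec$n_cells,
            " requested cells (crowded field)")

  sdlog <- if (spec$cell_brightness_cv > 0)
    sqrt(log(1 + spec$cell_brightness_cv^2)) else 0
  cell_rows <- vector("list", n_placed)

  for (i in seq_len(n_placed)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
    r_n <- spec$nucleus_radius_fraction * r
    b <- if (sdlog > 0) rlnorm(1, 0, sdlog) else 1
    c_val <- spec$cytoplasm_intensity * b
    m_val <- spec$cytoplasm_intensity * spec$membrane_enrichment *
      enrichment_multiplier * b
    h_val <- spec$perinuclear_intensity * b

    ng <- spec$membrane_gap_count
    if (ng > 0) {
      gap_centers <- (2 * pi * (seq_len(ng) - 1) / ng) +
        runif(ng, -10, 10) * pi / 180
      gap_widths <- runif(ng, spec$membrane_gap_width_deg[1],
                          spec$membrane_gap_width_deg[2]) * pi / 180
    } else {
      gap_centers <- numeric(0); gap_widths <- numeric(0)
    }

    rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    dy <- rows - cy
    dx <- cols - cx
    d <- sqrt(outer(dy^2, dx^2, `+`))
    theta <- atan2(matrix(dy, length(dy), length(dx)),
                   matrix(dx, length(dy), length(dx), byrow = TRUE))

    nuc <- d <= r_n
    halo <- d > r_n & d <= r_n + spec$halo_thickness_px
    band <- d > r - spec$membrane_thickness_px & d <= r
    mem <- band & !in_angular_gap(as.vector(theta), gap_centers, gap_widths)
    dim(mem) <- dim(band)
    cyto <- d > r_n & d <= r & !halo & !mem

    sub_sig <- signal[rows, cols]
    sub_sig[cyto] <- c_val
    sub_sig[halo] <- h_val
    sub_sig[mem] <- m_val
    signal[rows, cols] <- sub_sig

    sub <- nuclei[rows, cols]; sub[nuc] <- spec$nuclei_channel_intensity
    nuclei[rows, cols] <- sub
    sub <- nuc_lab[rows, cols]; sub[nuc] <- i; nuc_lab[rows, cols] <- sub
    sub <- mem_lab[rows, cols]; sub[mem] <- i; mem_lab[rows, cols] <- sub
    sub <- halo_lab[rows, cols]; sub[halo] <- i; halo_lab[rows, cols] <- sub
    sub <- cyto_lab[rows, cols]; sub[cyto] <- i; cyto_lab[rows, cols] <- sub

    cell_rows[[i]] <- data.frame(
      cell = i, center_row = cy, center_col = cx, radius_px = r,
      nucleus_radius_px = r_n, brightness = b,
      enrichment = spec$membrane_enrichment * enrichment_multiplier)
  }

  apply_noise <- function(img) {
    v <- as.vector(img)
    if (spec$poisson_noise) {
      pos <- v > 0
      v[pos] <- rpois(sum(pos), v[pos])
    }
    if (spec$gaussian_noise_sd > 0)
      v <- v + rnorm(length(v), 0, spec$gaussian_noise_sd)
    v <- round(pmin(pmax(v, 0), 2^spec$bit_depth - 1))
    matrix(as.integer(v), nrow(img), ncol(img))
  }
  nuclei_q <- apply_noise(nuclei)
  signal_q <- apply_noise(signal)

  cell_table <- if (n_placed > 0) do.call(rbind, cell_rows) else
    data.frame(cell = integer(0), center_row = numeric(0),
               center_col = numeric(0), radius_px = numeric(0),
               nucleus_radius_px = numeric(0), brightness = numeric(0),
               enrichment = numeric(0))

  structure(list(
    channels = list(
      nuclei = image_channel(nuclei_q, "nuclei", spec$bit_depth,
                             spec$pixel_size_um),
      signal = image_channel(signal_q, "signal", spec$bit_depth,
                             spec$pixel_size_um)),
    ground_truth = list(
      nucleus_labels = new_label_map(nuc_lab, n_placed),
      membrane_labels = new_label_map(mem_lab, n_placed),
      halo_labels = new_label_map(halo_lab, n_placed),
      cytoplasm_labels = new_label_map(cyto_lab, n_placed),
      cell_table = cell_table),
    n_cells_requested = spec$n_cells,
    n_cells_placed = n_placed,
    enrichment_multiplier = enrichment_multiplier,
    condition_label = condition_label,
    spec = spec), class = "scene")
}

#' Define an experimental condition preset
#'
#' A preset scales the control membrane enrichment by
#' `enrichment_multiplier`; the control preset must have multiplier
#' exactly 1.
#'
#' @param condition_label condition name.
#' @param enrichment_multiplier positive scale factor relative to control.
#' @return an object of class `condition_preset`.
#' @export
condition_preset <- function(condition_label, enrichment_multiplier) {
  stopifnot(is.character(condition_label), length(condition_label) == 1,
            nzchar(condition_label))
  if (enrichment_multiplier <= 0)
    stop("enrichment_multiplier must be positive")
  structure(list(condition_label = condition_label,
                 enrichment_multiplier = enrichment_multiplier),
            class = "condition_preset")
}

#' Default condition presets
#'
#' Four conditions mirroring a sensitized secretagogue experiment:
#' untreated control (CTRL, multiplier 1), a cAMP-raising stimulus (FK,
#' 1.347), a calcium-raising stimulus (TH, 1.331), and their combination
#' (FK+TH, 1.331). The non-control multipliers equal the normalized
#' perimembrane-intensity medians those stimuli produce after
#' indomethacin sensitization, so the synthetic experiment reproduces
#' that effect structure by construction.
#'
#' @return list of [condition_preset()] objects.
#' @export
condition_presets_default <- function() {
  list(condition_preset("CTRL", 1),
       condition_preset("FK", 1.347),
       condition_preset("TH", 1.331),
       condition_preset("FK+TH", 1.331))
}

#' Generate a seeded multi-condition image set on disk
#'
#' Writes one two-page TIFF (nuclei, signal) per image plus a
#' `manifest.csv` mapping file to condition, replicate and derived seed.
#' Per-image seeds derive deterministically from the base spec's seed via
#' [substream_seed()], so the whole set is reproducible.
#'
#' @param base a [scene_spec()]; its seed is the set's master seed.
#' @param presets list of [condition_preset()]; exactly one must have
#'   multiplier 1 (the control).
#' @param images_per_condition independent images per condition
#'   (default 3, matching a three-experiment design).
#' @param out_dir output directory (created if needed).
#' @param write_truth also write ground-truth label maps as 16-bit TIFFs.
#' @return the manifest data.frame (columns `file`, `condition`,
#'   `replicate`, `seed`), invisibly; scenes are regenerable from it.
#' @export
generate_condition_set <- function(base, presets,
                                   images_per_condition = 3,
                                   out_dir, write_truth = FALSE) {
  labels <- vapply(presets, function(p) p$condition_label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  mult <- vapply(presets, function(p) p$enrichment_multiplier, numeric(1))
  if (sum(mult == 1) != 1)
    stop("exactly one preset must have enrichment_multiplier 1 (the control)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (p in presets) {
    for (i in seq_len(images_per_condition)) {
      im_seed <- substream_seed(base$seed, "scene", p$condition_label, i)
      sp <- base; sp$seed <- im_seed
      scene <- generate_scene(sp, p$enrichment_multiplier, p$condition_label)
      fname <- paste0(gsub("[^A-Za-z0-9_-]", "_", p$condition_label),
                      "_", i, ".tif")
      write_tiff(list(scene$channels$nuclei$pixels,
                      scene$channels$signal$pixels),
                 file.path(out_dir, fname))
      if (write_truth) {
        base_name <- sub("\\.tif$", "", fname)
        write_tiff(scene$ground_truth$nucleus_labels$labels,
                   file.path(out_dir, paste0(base_name, "_nuclei_labels.tif")))
        write_tiff(scene$ground_truth$membrane_labels$labels,
                   file.path(out_dir, paste0(base_name, "_membrane_labels.tif")))
      }
      rows[[length(rows) + 1]] <- data.frame(
        file = fname, condition = p$condition_label, replicate = i,
        seed = im_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write_atomic(file.path(out_dir, "manifest.csv"), function(tmp)
    write.csv(manifest, tmp, row.names = FALSE))
  invisible(manifest)
}

#' Draw fragment-level upper-quartile intensities from the measurement
#' model
#'
#' Measurement-level ("pipeline-lite") simulator used for statistical
#' calibration: fragment scores are log-normal around the condition's
#' membrane intensity, with the same cell-brightness coefficient of
#' variation as the image generator. Avoids rendering images when only
#' the score distribution matters (null calibration, power checks).
#'
#' @param n number of fragments to draw.
#' @param spec a [scene_spec()] providing intensity parameters.
#' @param enrichment_multiplier condition multiplier.
#' @return numeric vector of simulated UpQ intensities.
#' @export
simulate_fragment_upq <- function(n, spec = scene_spec(),
                                  enrichment_multiplier = 1) {
  m <- spec$cytoplasm_intensity * spec$membrane_enrichment *
    enrichment_multiplier
  sdlog <- sqrt(log(1 + spec$cell_brightness_cv^2))
  v <- rlnorm(n, log(m), sdlog)
  # shot + read noise on the per-fragment score
  sigma <- sqrt(v + spec$gaussian_noise_sd^2)
  pmax(v + rnorm(n, 0, sigma / sqrt(50)), 0)
}
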