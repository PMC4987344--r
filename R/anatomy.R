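#' Cell density in a region of interest
#'
#' @param counts cell count(s).
#' @param area ROI area(s) in mm^2 (positive).
#' @return Density in cells/mm^2; linear in counts, inversely linear in
#'   area.
#' @export
density_per_mm2 <- function(counts, area) {
  if (any(area <= 0)) stop("ROI area must be positive")
  counts / area
}

#' Per-animal density aggregation
#'
#' Densities are averaged across an animal's sections first, then across
#' animals.
#'
#' @param table data frame with columns `animal`, `section`, `count`,
#'   `area_mm2` (optionally `layer` to aggregate within).
#' @return list with `per_animal` (data frame) and `grand_mean`.
#' @export
density_summary <- function(table) {
  stopifnot(all(c("animal", "count", "area_mm2") %in% names(table)))
  d <- density_per_mm2(table$count, table$area_mm2)
  per_animal <- tapply(d, table$animal, mean)
  list(per_animal = data.frame(animal = names(per_animal),
                               density = as.numeric(per_animal),
                               row.names = NULL),
       grand_mean = mean(per_animal))
}

#' Co-labelling percentage
#'
#' Percentage of cells positive for both markers relative to the chosen
#' denominator marker. The numerator is symmetric in the two markers; the
#' denominator choice is not.
#'
#' @param colabel_count cells positive for both markers.
#' @param denominator_count cells positive for the denominator marker.
#' @return percentage in 0..100, or `NA` with a message attribute when the
#'   denominator is zero (flagged, never divided).
#' @export
colabel_percent <- function(colabel_count, denominator_count) {
  stopifnot(colabel_count >= 0, denominator_count >= 0)
  if (colabel_count > denominator_count)
    stop("co-label count exceeds the denominator marker count")
  if (denominator_count == 0)
    return(structure(NA_real_, reason = "zero denominator"))
  100 * colabel_count / denominator_count
}

#' Fluorescence intensity ratio between layers
#'
#' Mean pixel intensity of the L1B patch divided by the mean of the
#' equal-area L1A patch; invariant to global illumination scaling.
#'
#' @param patch_l1b,patch_l1a numeric intensity arrays of equal size.
#' @return dimensionless ratio.
#' @export
intensity_ratio <- function(patch_l1b, patch_l1a) {
  if (length(patch_l1b) != length(patch_l1a))
    stop("patches must have equal area")
  m <- mean(patch_l1a)
  if (m == 0) stop("zero mean intensity in the reference (L1A) patch")
  mean(patch_l1b) / m
}

#' Generate a homogeneous labelled point pattern
#'
#' Cells are placed as a homogeneous Poisson process in a square ROI;
#' every cell carries the reporter, and each additional marker is drawn
#' independently with its co-label probability.
#'
#' @param roi_area ROI area in mm^2.
#' @param intensity expected density, cells/mm^2 (>= 0).
#' @param colabel_probs named numeric vector of marker probabilities (e.g.
#'   `c(SST = 0.75)`).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return A `point_pattern`: list with `roi_area`, `positions` (data frame
#'   of x/y in um), logical `labels` columns per marker, and the generating
#'   `probs`.
#' @export
generate_point_pattern <- function(roi_area, intensity, colabel_probs = NULL,
                                   seed = NULL) {
  stopifnot(roi_area > 0, intensity >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, intensity * roi_area)
  side_um <- sqrt(roi_area) * 1000
  pos <- data.frame(x = stats::runif(n, 0, side_um),
                    y = stats::runif(n, 0, side_um))
  labels <- data.frame(reporter = rep(TRUE, n))
  for (mk in names(colabel_probs)) {
    p <- colabel_probs[[mk]]
    stopifnot(p >= 0, p <= 1)
    labels[[mk]] <- stats::runif(n) < p
  }
  structure(list(roi_area = roi_area, positions = pos, labels = labels,
                 probs = colabel_probs),
            class = "point_pattern")
}

#' Count table of a point pattern
#'
#' @param pattern a `point_pattern`.
#' @return one-row data frame with the ROI area, reporter count, and per
#'   marker the single-marker and reporter co-label counts.
#' @export
pattern_counts <- function(pattern) {
  labs <- pattern$labels
  out <- data.frame(area_mm2 = pattern$roi_area, reporter = nrow(labs))
  for (mk in setdiff(names(labs), "reporter")) {
    out[[mk]] <- sum(labs[[mk]])
    out[[paste0("reporter_", mk)]] <- sum(labs$reporter & labs[[mk]])
  }
  out
}

#' Marker presets for the transgenic reporter lines
#'
#' Registry of reporter-line densities and co-label probabilities used by
#' the synthetic anatomy generator: the SST reporter line (high density,
#' 75% somatostatin co-labelling) and the PV reporter line (lower density,
#' 95% parvalbumin co-labelling).
#'
#' @param name `"SST-line"` or `"PV-line"`.
#' @return list with `density` (cells/mm^2), `colabel_probs`, and the
#'   default `section_area` (mm^2).
#' @export
marker_preset <- function(name = c("SST-line", "PV-line")) {
  name <- match.arg(name)
  switch(name,
         "SST-line" = list(density = 100, colabel_probs = c(SST = 0.75),
                           section_area = 0.83),
         "PV-line" = list(density = 48.2, colabel_probs = c(PV = 0.95),
                          section_area = 0.83))
}

#' Generate a pair of fluorescence-intensity patches
#'
#' Two square pixel arrays (1 um^2 pixels) with the stated mean
#' intensities plus Gaussian pixel noise, emulating the small L1A/L1B
#' areas used for the layer fluorescence ratio.
#'
#' @param mean_intensity_l1a,mean_intensity_l1b mean intensities (>= 0).
#' @param noise_sd pixel noise standard deviation.
#' @param patch_area_um2 patch area (default 140 um^2).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return list with matrices `l1a` and `l1b`.
#' @export
generate_image_patch <- function(mean_intensity_l1a, mean_intensity_l1b,
                                 noise_sd = 0, patch_area_um2 = 140,
                                 seed = NULL) {
  stopifnot(mean_intensity_l1a >= 0, mean_intensity_l1b >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  side <- max(1L, round(sqrt(patch_area_um2)))
  mk <- function(mu) matrix(mu + stats::rnorm(side^2, 0, noise_sd),
                            side, side)
  list(l1a = mk(mean_intensity_l1a), l1b = mk(mean_intensity_l1b))
}
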