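#' Morphometry configuration
#'
#' Parameters of RI-threshold morphometry. The segmentation threshold
#' `tau_seg` separates cell from medium (default: `medium_ri + 0.005`,
#' resolved per tomogram when `NULL`); the nuclear threshold `tau_nuc`
#' (default 1.38) selects nuclear-component pixels; `alpha` is the protein
#' refraction increment in mL/g linking RI excess to protein concentration
#' (default 0.19, the middle of the 0.18-0.21 mL/g protein range).
#'
#' @param tau_seg segmentation RI threshold, or `NULL` for
#'   `medium_ri + 0.005`.
#' @param tau_nuc nuclear-component RI threshold.
#' @param alpha refraction increment, mL/g (> 0).
#' @param section_axis axis for cross-sections: `"z"`, `"y"` or `"x"`.
#' @param feature_space `"section_2d"` (RI features on the central
#'   cross-section, the default) or `"full_3d"` (over the whole mask).
#' @return an object of class `morphometry_config`.
#' @export
morphometry_config <- function(tau_seg = NULL, tau_nuc = 1.38, alpha = 0.19,
                               section_axis = c("z", "y", "x"),
                               feature_space = c("section_2d", "full_3d")) {
  section_axis <- match.arg(section_axis)
  feature_space <- match.arg(feature_space)
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (!is.null(tau_seg) && !is.null(tau_nuc) && tau_nuc <= tau_seg) {
    warning("expected tau_nuc > tau_seg; nuclear threshold does not exceed ",
            "the segmentation threshold")
  }
  structure(list(tau_seg = tau_seg, tau_nuc = tau_nuc, alpha = alpha,
                 section_axis = section_axis, feature_space = feature_space),
            class = "morphometry_config")
}

resolve_tau_seg <- function(tom, config) {
  tau <- if (is.null(config$tau_seg)) tom$medium_ri + 0.005 else config$tau_seg
  if (tau <= tom$medium_ri) {
    warning("segmentation threshold does not exceed the medium RI")
  }
  tau
}

#' Segment a cell by RI threshold
#'
#' The mask is the largest 26-connected component of voxels with RI above
#' the segmentation threshold; stray super-threshold noise voxels are
#' thereby discarded.
#'
#' @param tom a [tomogram()].
#' @param config a [morphometry_config()].
#' @return logical 3D array (the cell mask), with the threshold used
#'   attached as attribute `"threshold"`.
#' @export
segment_cell <- function(tom, config = morphometry_config()) {
  stopifnot(inherits(tom, "tomogram"))
  tau <- resolve_tau_seg(tom, config)
  fg <- tom$ri > tau
  if (!any(fg)) stop("no cell found: no voxel exceeds the segmentation threshold ", tau)
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  attr(mask, "threshold") <- tau
  mask
}

#' Cell centre and radius from a binary mask
#'
#' The centre is the arithmetic mean of the mask voxel coordinates (array
#' indices, real-valued); the radius is the maximum distance from the
#' centre to any mask voxel, measured in physical units when `spacing` is
#' given (the default handles anisotropic voxels) or in voxel units with
#' `spacing = c(1, 1, 1)`.
#'
#' @param mask logical 3D array.
#' @param spacing per-axis scale factors for distances (z, y, x).
#' @return list with `center` (length-3, array-index coordinates) and
#'   `radius` (scalar, in `spacing` units).
#' @export
cell_center_radius <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask)) stop("empty mask")
  spacing <- as_triple(spacing, "spacing")
  coords <- which(mask, arr.ind = TRUE)
  center <- colMeans(coords)
  d2 <- (t(coords) - center) * spacing
  radius <- sqrt(max(colSums(d2^2)))
  list(center = unname(center), radius = radius)
}

#' Cell volume from a mask
#'
#' Volume is the voxel count times the voxel volume; with spacing in
#' micrometres the result is in cubic micrometres, i.e. femtolitres.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (z, y, x) in micrometres.
#' @return volume in fL.
#' @export
compute_volume <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask")
  spacing <- as_triple(spacing, "spacing")
  sum(mask) * prod(spacing)
}

#' Protein density from RI excess
#'
#' Mean RI over the mask minus the medium RI, divided by the refraction
#' increment `alpha` (mL/g), gives protein concentration in g/mL; the
#' factor 100 converts to g/dL.
#'
#' @param tom a [tomogram()].
#' @param mask logical 3D array (cell mask).
#' @param config a [morphometry_config()].
#' @return protein density in g/dL. Negative values (mean RI below the
#'   medium) are allowed but warned about.
#' @export
protein_density <- function(tom, mask, config = morphometry_config()) {
  if (config$alpha <= 0) stop("'alpha' must be > 0")
  if (!any(mask)) stop("empty mask")
  C <- 100 * (mean(tom$ri[mask]) - tom$medium_ri) / config$alpha
  if (C < 0) warning("negative protein density: mean cell RI below medium RI")
  C
}

#' Dry mass from protein density and volume
#'
#' `m = C * V * 1e-2`: g/dL times fL, scaled by 1e-2, gives picograms.
#'
#' @param C protein density, g/dL.
#' @param V volume, fL.
#' @return dry mass in pg.
#' @export
dry_mass <- function(C, V) C * V * 1e-2

#' Sectional RI features
#'
#' Extracts the 2D cross-section through the cell centre along the
#' configured axis and measures the mean overall RI (over in-mask pixels)
#' and the mean nuclear-component RI (over pixels above `tau_nuc`). When no
#' section pixel exceeds the nuclear threshold, the nuclear mean is `NA`
#' and the fraction is 0.
#'
#' @param tom a [tomogram()].
#' @param mask logical 3D array (cell mask).
#' @param config a [morphometry_config()].
#' @param center optional precomputed centre (array-index coordinates);
#'   computed from the mask when `NULL`.
#' @return list with `mean_overall_ri`, `mean_nuclear_ri`,
#'   `nuclear_pixel_fraction`, `section_image` (matrix), `section_mask`
#'   (matrix) and `section_index`.
#' @export
sectional_ri_features <- function(tom, mask, config = morphometry_config(),
                                  center = NULL) {
  if (is.null(center)) center <- cell_center_radius(mask)$center
  ax <- match(config$section_axis, c("z", "y", "x"))
  idx <- as.integer(round(center[ax]))
  idx <- min(max(idx, 1L), dim(tom$ri)[ax])
  section <- switch(config$section_axis,
                    z = tom$ri[idx, , ], y = tom$ri[, idx, ], x = tom$ri[, , idx])
  msec <- switch(config$section_axis,
                 z = mask[idx, , ], y = mask[, idx, ], x = mask[, , idx])
  if (!any(msec)) stop("section through the cell centre misses the mask entirely")
  nuc <- msec & section > config$tau_nuc
  list(mean_overall_ri = mean(section[msec]),
       mean_nuclear_ri = if (any(nuc)) mean(section[nuc]) else NA_real_,
       nuclear_pixel_fraction = sum(nuc) / sum(msec),
       section_image = section,
       section_mask = msec,
       section_index = idx)
}

#' Full morphometry of one cell
#'
#' Segments the tomogram and computes the structural and biochemical
#' feature set: volume (fL), protein density (g/dL), dry mass (pg), mean
#' overall and nuclear RI, nuclear pixel fraction, centre and radius. With
#' `feature_space = "full_3d"` the RI features are measured over the whole
#' 3D mask instead of the central section.
#'
#' @param tom a [tomogram()].
#' @param config a [morphometry_config()].
#' @return one-row data.frame of class `cell_morphology`.
#' @export
cell_morphometry <- function(tom, config = morphometry_config()) {
  mask <- segment_cell(tom, config)
  cr <- cell_center_radius(mask, spacing = tom$voxel_spacing_um)
  V <- compute_volume(mask, tom$voxel_spacing_um)
  C <- protein_density(tom, mask, config)
  m <- dry_mass(C, V)
  if (config$feature_space == "section_2d") {
    sf <- sectional_ri_features(tom, mask, config,
                                center = cell_center_radius(mask)$center)
    overall <- sf$mean_overall_ri
    nuclear <- sf$mean_nuclear_ri
    nfrac <- sf$nuclear_pixel_fraction
  } else {
    overall <- mean(tom$ri[mask])
    nuc <- mask & tom$ri > config$tau_nuc
    nuclear <- if (any(nuc)) mean(tom$ri[nuc]) else NA_real_
    nfrac <- sum(nuc) / sum(mask)
  }
  ctr <- cell_center_radius(mask)$center
  out <- data.frame(cell_id = tom$cell_id,
                    volume_fl = V,
                    protein_density_gdl = C,
                    dry_mass_pg = m,
                    mean_overall_ri = overall,
                    mean_nuclear_ri = nuclear,
                    nuclear_pixel_fraction = nfrac,
                    center_z = ctr[1], center_y = ctr[2], center_x = ctr[3],
                    radius_um = cr$radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_morphology", class(out))
  out
}

#' Morphometry feature table for a set of cells
#'
#' Applies [cell_morphometry()] to every tomogram and joins any labels
#' stored with them (group, outcome, subject id).
#'
#' @param tomograms list of [tomogram()] objects, or a directory containing
#'   tomogram files with sidecars.
#' @param config a [morphometry_config()].
#' @return data.frame, one row per cell.
#' @export
extract_features <- function(tomograms, config = morphometry_config()) {
  tomograms <- as_tomogram_list(tomograms)
  rows <- lapply(tomograms, function(tom) {
    row <- cell_morphometry(tom, config)
    for (nm in names(tom$labels)) row[[nm]] <- tom$labels[[nm]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# accept a list of tomograms, a list of file paths, or a directory
as_tomogram_list <- function(x) {
  if (inherits(x, "tomogram")) return(list(x))
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    x <- list.files(x, pattern = "\\.(tif|tiff|raw)$", full.names = TRUE)
  }
  lapply(x, function(el) {
    if (inherits(el, "tomogram")) el else read_tomogram(el)
  })
}
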