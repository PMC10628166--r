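#' Equal-count radial shell partition of a 2D section
#'
#' Ranks every analyzed pixel by its Euclidean distance from the cell
#' centre (in physical units, so anisotropic spacing yields elliptical
#' iso-distance contours) and splits the ranked list into `n_shells`
#' contiguous blocks whose sizes differ by at most one; when the pixel
#' count is not divisible, the remainder pixels are assigned to the
#' innermost shells. Distance ties are broken by row-major pixel index, so
#' the partition is a pure function of its inputs.
#'
#' @param section numeric matrix (a 2D cross-section).
#' @param center length-2 centre in array-index coordinates (row, column).
#' @param n_shells number of shells (default 8).
#' @param spacing physical pixel spacing along (row, column).
#' @param max_radius optional: restrict the analyzed pixel set to pixels
#'   within this physical distance of the centre (by default the whole
#'   rectangular section is analyzed).
#' @return list of `n_shells` integer vectors of (column-major) pixel
#'   indices, innermost first; attribute `"counts"` holds the shell sizes.
#' @export
shell_partition <- function(section, center, n_shells = 8L,
                            spacing = c(1, 1), max_radius = NULL) {
  stopifnot(is.matrix(section), length(center) == 2L, length(spacing) == 2L)
  nr <- nrow(section); nc <- ncol(section)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop("centre lies outside the section bounds")
  }
  k <- seq_len(nr * nc)
  row <- ((k - 1L) %% nr) + 1L
  col <- ((k - 1L) %/% nr) + 1L
  d <- sqrt(((row - center[1]) * spacing[1])^2 + ((col - center[2]) * spacing[2])^2)
  keep <- if (is.null(max_radius)) k else k[d <= max_radius]
  if (length(keep) < n_shells) {
    stop("fewer than ", n_shells, " analyzed pixels; cannot build shells")
  }
  rm_idx <- (row - 1L) * nc + col  # row-major tie-break
  ord <- keep[order(d[keep], rm_idx[keep])]
  n <- length(ord)
  sizes <- rep(n %/% n_shells, n_shells)
  r <- n %% n_shells
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  shells <- lapply(seq_len(n_shells), function(s) ord[starts[s]:ends[s]])
  attr(shells, "counts") <- sizes
  shells
}

#' Shell densities of a section
#'
#' The density of shell k is the fraction of its pixels whose value
#' exceeds `threshold`.
#'
#' @param section numeric matrix.
#' @param shells partition from [shell_partition()].
#' @param threshold intensity (RI) threshold.
#' @return object of class `shell_profile`: list with `densities` (ordered
#'   innermost to outermost), `counts` and `threshold`.
#' @export
shell_density <- function(section, shells, threshold) {
  counts <- vapply(shells, length, 0L)
  if (any(counts == 0L)) stop("internal error: empty shell in partition")
  d <- vapply(shells, function(s) mean(section[s] > threshold), 0.0)
  structure(list(densities = d, counts = counts, threshold = threshold),
            class = "shell_profile")
}

#' @export
print.shell_profile <- function(x, ...) {
  cat("<shell_profile> threshold ", signif(x$threshold, 6), "\n", sep = "")
  print(round(stats::setNames(x$densities, paste0("d", seq_along(x$densities))), 4))
  invisible(x)
}

#' Shell profiles of one cell
#'
#' Segments the cell, takes the central cross-section, and computes the
#' eight-shell density profile for the overall component (threshold =
#' segmentation threshold) and the nuclear component (threshold =
#' `tau_nuc`).
#'
#' @param tom a [tomogram()].
#' @param config a [morphometry_config()].
#' @param n_shells number of shells.
#' @param restrict `"section"` (analyze the full rectangular section, the
#'   default) or `"cell"` (restrict to pixels within the cell radius of the
#'   centre, so background does not dilute outer shells).
#' @return named list with `overall` and `nuclear` [shell_density()]
#'   profiles.
#' @export
shell_profile <- function(tom, config = morphometry_config(), n_shells = 8L,
                          restrict = c("section", "cell")) {
  restrict <- match.arg(restrict)
  mask <- segment_cell(tom, config)
  tau <- attr(mask, "threshold")
  ctr <- cell_center_radius(mask)$center
  ax <- match(config$section_axis, c("z", "y", "x"))
  idx <- min(max(as.integer(round(ctr[ax])), 1L), dim(tom$ri)[ax])
  section <- switch(config$section_axis,
                    z = tom$ri[idx, , ], y = tom$ri[, idx, ], x = tom$ri[, , idx])
  sp2 <- tom$voxel_spacing_um[-ax]
  c2 <- ctr[-ax]
  max_radius <- if (restrict == "cell") {
    cell_center_radius(mask, spacing = tom$voxel_spacing_um)$radius
  } else NULL
  shells <- shell_partition(section, c2, n_shells = n_shells, spacing = sp2,
                            max_radius = max_radius)
  list(overall = shell_density(section, shells, tau),
       nuclear = shell_density(section, shells, config$tau_nuc))
}

#' Shell-density table for a cohort
#'
#' Two rows per cell (components `"overall"` and `"nuclear"`) with columns
#' `d1..dK`, joined to any labels stored with each tomogram.
#'
#' @inheritParams shell_profile
#' @param tomograms list of [tomogram()] objects or a directory.
#' @return data.frame with columns cell_id, component, d1..dK and labels.
#' @export
shell_profiles_for_cohort <- function(tomograms, config = morphometry_config(),
                                      n_shells = 8L,
                                      restrict = c("section", "cell")) {
  restrict <- match.arg(restrict)
  tomograms <- as_tomogram_list(tomograms)
  rows <- lapply(tomograms, function(tom) {
    prof <- shell_profile(tom, config, n_shells = n_shells, restrict = restrict)
    out <- do.call(rbind, lapply(names(prof), function(comp) {
      row <- as.data.frame(as.list(stats::setNames(prof[[comp]]$densities,
                                                   paste0("d", seq_len(n_shells)))))
      cbind(data.frame(cell_id = tom$cell_id, component = comp,
                       stringsAsFactors = FALSE), row)
    }))
    for (nm in names(tom$labels)) out[[nm]] <- tom$labels[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
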