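#' Construct a tomogram object
#'
#' A tomogram is a 3D array of refractive indices with axis order (z, y, x),
#' its voxel spacing in micrometres, the refractive index of the surrounding
#' medium, a cell identifier and optional labels.
#'
#' @param ri numeric 3D array of refractive indices; all finite, minimum
#'   of at least 1.0.
#' @param voxel_spacing_um positive spacing triple (z, y, x), micrometres.
#' @param medium_ri refractive index of the immersion medium.
#' @param cell_id identifier string.
#' @param labels named list of labels (e.g. group, outcome, subject_id).
#' @return an object of class `tomogram`.
#' @export
tomogram <- function(ri, voxel_spacing_um, medium_ri, cell_id = "cell",
                     labels = list()) {
  if (!is.array(ri) || length(dim(ri)) != 3L) stop("'ri' must be a 3D array")
  if (!all(is.finite(ri))) stop("tomogram contains non-finite values")
  if (min(ri) < 1.0) stop("refractive indices must be >= 1.0")
  sp <- as_triple(voxel_spacing_um, "voxel_spacing_um")
  if (any(sp <= 0)) stop("'voxel_spacing_um' must be positive")
  if (!is.numeric(medium_ri) || length(medium_ri) != 1L || !is.finite(medium_ri)) {
    stop("'medium_ri' must be a finite scalar")
  }
  structure(list(ri = ri, voxel_spacing_um = sp, medium_ri = medium_ri,
                 cell_id = as.character(cell_id), labels = labels),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  cat("<tomogram> ", x$cell_id, "\n", sep = "")
  cat("  grid (z,y,x): ", paste(dim(x$ri), collapse = " x "),
      ", spacing: ", paste(signif(x$voxel_spacing_um, 4), collapse = " x "),
      " um\n", sep = "")
  cat("  RI range: [", signif(min(x$ri), 6), ", ", signif(max(x$ri), 6),
      "], medium RI: ", x$medium_ri, "\n", sep = "")
  if (length(x$labels)) {
    cat("  labels: ", paste(names(x$labels), unlist(x$labels), sep = "=",
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# TIFF samples hold (RI - RI_STORE_OFFSET), keeping values inside the
# [0, 1] range the TIFF writer quantizes over; the offset is recorded in
# the sidecar.
RI_STORE_OFFSET <- 1.0

#' Write a tomogram to disk
#'
#' Two on-disk formats, each with a JSON sidecar carrying the metadata
#' contract (`voxel_spacing_um`, `medium_ri`, `shape`, `cell_id`, labels):
#' * `"tiff"`: multi-page TIFF, one page per z-slice; samples store
#'   RI - 1 on a 32-bit integer grid (round-trip accurate to ~5e-10 RI).
#' * `"raw"`: little-endian float32 binary in (z, y, x) column-major order;
#'   round-trips bit-exactly once written.
#'
#' @param tom a [tomogram()].
#' @param dir output directory (created if absent).
#' @param format `"tiff"` or `"raw"`.
#' @return invisibly, the path of the volume file.
#' @export
write_tomogram <- function(tom, dir, format = c("tiff", "raw")) {
  stopifnot(inherits(tom, "tomogram"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, tom$cell_id)
  sidecar <- list(format = format,
                  shape = dim(tom$ri),
                  voxel_spacing_um = tom$voxel_spacing_um,
                  medium_ri = tom$medium_ri,
                  cell_id = tom$cell_id,
                  labels = tom$labels)
  if (format == "tiff") {
    vol_path <- paste0(base, ".tif")
    sidecar$ri_offset <- RI_STORE_OFFSET
    pages <- lapply(seq_len(dim(tom$ri)[1]), function(z) tom$ri[z, , ] - RI_STORE_OFFSET)
    suppressWarnings(tiff::writeTIFF(pages, vol_path, bits.per.sample = 32L,
                                     compression = "none", reduce = FALSE))
  } else {
    vol_path <- paste0(base, ".raw")
    sidecar$dtype <- "float32"
    sidecar$byte_order <- "little"
    con <- file(vol_path, "wb")
    on.exit(close(con))
    writeBin(as.vector(tom$ri), con, size = 4L, endian = "little")
  }
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vol_path)
}

#' Read a tomogram from disk
#'
#' Accepts the path of the volume file (`.tif`/`.raw`) or of its JSON
#' sidecar. Errors name any missing sidecar key; a mismatch between the
#' declared shape and the stored pages is an error.
#'
#' @param path path to the `.tif`, `.raw` or `.json` file.
#' @return a [tomogram()].
#' @export
read_tomogram <- function(path) {
  base <- sub("\\.(tif|tiff|raw|json)$", "", path)
  sidecar_path <- paste0(base, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar file: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("format", "shape", "voxel_spacing_um", "medium_ri", "cell_id")) {
    if (is.null(meta[[key]])) stop("sidecar is missing required key '", key, "'")
  }
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L) stop("sidecar 'shape' must have length 3")
  if (meta$format == "tiff") {
    vol_path <- if (file.exists(paste0(base, ".tif"))) paste0(base, ".tif") else paste0(base, ".tiff")
    if (!file.exists(vol_path)) stop("missing TIFF volume for sidecar: ", sidecar_path)
    pages <- tiff::readTIFF(vol_path, all = TRUE)
    if (length(pages) != shape[1]) {
      stop("shape mismatch: sidecar declares ", shape[1], " z-slices but TIFF has ",
           length(pages), " pages")
    }
    if (!all(vapply(pages, function(p) identical(dim(p), shape[2:3]), TRUE))) {
      stop("shape mismatch: TIFF page dimensions differ from sidecar shape")
    }
    off <- if (!is.null(meta$ri_offset)) meta$ri_offset else RI_STORE_OFFSET
    ri <- array(0, dim = shape)
    for (z in seq_len(shape[1])) ri[z, , ] <- pages[[z]] + off
  } else if (meta$format == "raw") {
    vol_path <- paste0(base, ".raw")
    if (!file.exists(vol_path)) stop("missing raw volume for sidecar: ", sidecar_path)
    n <- prod(shape)
    con <- file(vol_path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n + 1L, size = 4L, endian = "little")
    if (length(v) != n) {
      stop("shape mismatch: sidecar declares ", n, " voxels but raw file holds ",
           length(v))
    }
    ri <- array(v, dim = shape)
  } else {
    stop("unknown tomogram format '", meta$format, "'")
  }
  labels <- if (is.null(meta$labels)) list() else as.list(meta$labels)
  tomogram(ri, voxel_spacing_um = as.numeric(meta$voxel_spacing_um),
           medium_ri = meta$medium_ri, cell_id = meta$cell_id, labels = labels)
}

#' Automated tomogram quality control
#'
#' Replaces manual curation of acquisitions with explicit rules: a volume is
#' rejected when its super-threshold foreground (i) occupies a fraction of
#' the volume outside `[min_fraction, max_fraction]`, (ii) splits into more
#' than one connected component at least `min_component_fraction` the size
#' of the largest (two or more adjoined cells), or (iii) touches the volume
#' border (truncated cell).
#'
#' @param tomograms list of [tomogram()] objects.
#' @param threshold segmentation threshold; default `medium_ri + 0.005` per
#'   tomogram.
#' @param min_component_fraction components at least this fraction of the
#'   largest count as separate cells.
#' @param min_fraction,max_fraction admissible foreground volume fraction.
#' @return list with `kept` (list of tomograms) and `rejected` (data.frame
#'   with columns cell_id, reason).
#' @export
qc_filter <- function(tomograms, threshold = NULL,
                      min_component_fraction = 0.1,
                      min_fraction = 0.001, max_fraction = 0.6) {
  kept <- list()
  rej <- list()
  for (tom in tomograms) {
    thr <- if (is.null(threshold)) tom$medium_ri + 0.005 else threshold
    fg <- tom$ri > thr
    frac <- mean(fg)
    reason <- NULL
    if (frac < min_fraction || frac > max_fraction) {
      reason <- sprintf("foreground fraction %.4g outside [%g, %g]",
                        frac, min_fraction, max_fraction)
    } else {
      lab <- label_components(fg)
      sizes <- tabulate(lab[lab > 0])
      big <- which(sizes >= min_component_fraction * max(sizes))
      if (length(big) > 1L) {
        reason <- sprintf("multiple components (%d of comparable size)", length(big))
      } else {
        comp <- lab == big[1L]
        d <- dim(comp)
        border <- any(comp[1, , ]) || any(comp[d[1], , ]) ||
          any(comp[, 1, ]) || any(comp[, d[2], ]) ||
          any(comp[, , 1]) || any(comp[, , d[3]])
        if (border) reason <- "border contact"
      }
    }
    if (is.null(reason)) {
      kept[[tom$cell_id]] <- tom
    } else {
      rej[[tom$cell_id]] <- data.frame(cell_id = tom$cell_id, reason = reason,
                                       stringsAsFactors = FALSE)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(cell_id = character(), reason = character(), stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
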