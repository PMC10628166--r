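#' Phantom specification for a simulated RI tomogram
#'
#' Describes an ellipsoidal cell of constant cytoplasmic refractive index
#' (RI) containing a concentric ellipsoidal nucleus, immersed in medium and
#' optionally carrying a dense peripheral rim and i.i.d. Gaussian RI noise.
#' Phantoms stand in for holotomographic acquisitions so that the full
#' analysis chain can be exercised without instrument data.
#'
#' @param cell_radius_um cell semi-axes in micrometres; a scalar gives a
#'   sphere, a length-3 vector (z, y, x) an ellipsoid.
#' @param nucleus_radius_fraction nucleus semi-axes as a fraction of the cell
#'   semi-axes, in (0, 1).
#' @param cytoplasm_ri,nucleus_ri,medium_ri refractive indices
#'   (dimensionless); all must lie in \[1.30, 1.45\]. `nucleus_ri` is free to
#'   be below `cytoplasm_ri`.
#' @param noise_sd standard deviation of additive Gaussian RI noise (>= 0).
#' @param voxel_spacing_um voxel spacing (z, y, x) in micrometres.
#' @param grid_shape integer grid shape (z, y, x).
#' @param center_offset_vox integer offset of the cell centre from the grid
#'   centre, in voxels.
#' @param peripheral_weight weight in \[0, 1\] of a dense rim at the cell
#'   periphery: rim voxels take RI `cytoplasm_ri + peripheral_weight *
#'   (nucleus_ri - cytoplasm_ri)`. 0 disables the rim.
#' @param rim_inner_fraction inner radial fraction of the rim region.
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(cell_radius_um = 5, grid_shape = c(64, 64, 64))
#' tom <- make_phantom(spec, seed = 1)
phantom_spec <- function(cell_radius_um = 5,
                         nucleus_radius_fraction = 0.55,
                         cytoplasm_ri = 1.356,
                         nucleus_ri = 1.39,
                         medium_ri = 1.337,
                         noise_sd = 0,
                         voxel_spacing_um = 0.2,
                         grid_shape = c(64, 64, 64),
                         center_offset_vox = c(0, 0, 0),
                         peripheral_weight = 0,
                         rim_inner_fraction = 0.75) {
  r <- as_triple(cell_radius_um, "cell_radius_um")
  sp <- as_triple(voxel_spacing_um, "voxel_spacing_um")
  gs <- as_triple(grid_shape, "grid_shape")
  off <- as_triple(center_offset_vox, "center_offset_vox")
  if (any(r <= 0)) stop("'cell_radius_um' must be positive")
  if (any(sp <= 0)) stop("'voxel_spacing_um' must be positive")
  if (any(gs < 1) || any(gs != round(gs))) stop("'grid_shape' must be positive integers")
  if (any(off != round(off))) stop("'center_offset_vox' must be integers")
  if (!(nucleus_radius_fraction > 0 && nucleus_radius_fraction < 1)) {
    stop("'nucleus_radius_fraction' must lie in (0, 1)")
  }
  ris <- c(cytoplasm_ri = cytoplasm_ri, nucleus_ri = nucleus_ri, medium_ri = medium_ri)
  if (any(ris < 1.30 - 1e-12) || any(ris > 1.45 + 1e-12)) {
    stop("all refractive indices must lie in [1.30, 1.45]")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (peripheral_weight < 0 || peripheral_weight > 1) {
    stop("'peripheral_weight' must lie in [0, 1]")
  }
  if (rim_inner_fraction <= 0 || rim_inner_fraction >= 1) {
    stop("'rim_inner_fraction' must lie in (0, 1)")
  }
  if (any(r / sp + abs(off) >= gs / 2)) {
    stop("grid too small: cell of radius ", paste(signif(r, 4), collapse = "x"),
         " um does not fit in grid ", paste(gs, collapse = "x"),
         " at spacing ", paste(sp, collapse = "x"),
         " um with offset (", paste(off, collapse = ", "), ")")
  }
  structure(list(cell_radius_um = r,
                 nucleus_radius_fraction = nucleus_radius_fraction,
                 cytoplasm_ri = cytoplasm_ri,
                 nucleus_ri = nucleus_ri,
                 medium_ri = medium_ri,
                 noise_sd = noise_sd,
                 voxel_spacing_um = sp,
                 grid_shape = as.integer(gs),
                 center_offset_vox = as.integer(off),
                 peripheral_weight = peripheral_weight,
                 rim_inner_fraction = rim_inner_fraction),
            class = "phantom_spec")
}

# squared ellipsoidal radial coordinate of every voxel centre, as an array;
# membership is decided at voxel centres.
phantom_radial2 <- function(spec) {
  gs <- spec$grid_shape
  ctr <- (gs - 1) / 2 + spec$center_offset_vox
  ax <- lapply(1:3, function(a) {
    (((seq_len(gs[a]) - 1) - ctr[a]) * spec$voxel_spacing_um[a] / spec$cell_radius_um[a])^2
  })
  u2 <- array(0, dim = gs)
  u2 <- u2 + ax[[1]]                                # z varies fastest
  u2 <- u2 + rep(ax[[2]], each = gs[1])
  u2 <- u2 + rep(ax[[3]], each = gs[1] * gs[2])
  u2
}

#' Simulate a single-cell RI tomogram phantom
#'
#' Builds the piecewise-constant RI volume described by a [phantom_spec()]
#' (medium everywhere except the cell ellipsoid; nucleus and optional rim
#' inside it) and adds i.i.d. Gaussian noise. A voxel belongs to a region
#' iff its centre lies inside the region's ellipsoid.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same (spec, seed) pair reproduces the
#'   volume exactly. `NULL` uses the session RNG stream.
#' @param cell_id identifier stored with the tomogram.
#' @param labels optional named list of labels (group, outcome, subject id).
#' @return a [tomogram()] object.
#' @export
make_phantom <- function(spec, seed = NULL, cell_id = "phantom", labels = list()) {
  stopifnot(inherits(spec, "phantom_spec"))
  u2 <- phantom_radial2(spec)
  ri <- array(spec$medium_ri, dim = spec$grid_shape)
  in_cell <- u2 <= 1
  ri[in_cell] <- spec$cytoplasm_ri
  if (spec$peripheral_weight > 0) {
    rim <- in_cell & u2 >= spec$rim_inner_fraction^2
    ri[rim] <- spec$cytoplasm_ri +
      spec$peripheral_weight * (spec$nucleus_ri - spec$cytoplasm_ri)
  }
  ri[u2 <= spec$nucleus_radius_fraction^2] <- spec$nucleus_ri
  if (spec$noise_sd > 0) {
    ri <- ri + with_seed(seed, array(rnorm(length(ri), 0, spec$noise_sd),
                                     dim = spec$grid_shape))
  }
  tomogram(ri, voxel_spacing_um = spec$voxel_spacing_um,
           medium_ri = spec$medium_ri, cell_id = cell_id, labels = labels)
}

#' Group effect specification for cohort simulation
#'
#' Defines how one cohort group (healthy control or a sepsis-recovery time
#' point, optionally split by outcome) deviates from the base phantom:
#' a multiplicative radius scale, an additive RI offset, and a peripheral
#' density weight controlling how much high-RI mass sits near the cell
#' boundary. Subjects within a group receive Gaussian random effects on
#' log-radius and additive effects on RI; cells add further jitter.
#'
#' @param group group label, one of `"H"`, `"T1"`, `"T2"`, `"T3"`.
#' @param outcome `"survivor"`, `"non-survivor"` or `"not-applicable"`.
#' @param radius_scale multiplicative scale on the base cell radius.
#' @param ri_offset additive RI offset applied to cytoplasm and nucleus.
#' @param peripheral_weight rim weight in \[0, 1\] (see [phantom_spec()]).
#' @param n_cells,n_subjects counts with `n_cells >= n_subjects >= 1`.
#' @param subject_sd_log_radius,subject_sd_ri subject-level random-effect
#'   standard deviations (log-radius; RI).
#' @param cell_sd_log_radius,cell_sd_ri cell-level jitter standard deviations.
#' @return an object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(group, outcome = "not-applicable",
                              radius_scale = 1, ri_offset = 0,
                              peripheral_weight = 0,
                              n_cells = 50, n_subjects = 5,
                              subject_sd_log_radius = 0.04,
                              subject_sd_ri = 0.0008,
                              cell_sd_log_radius = 0.03,
                              cell_sd_ri = 0.0006) {
  group <- match.arg(group, c("H", "T1", "T2", "T3"))
  outcome <- match.arg(outcome, c("not-applicable", "survivor", "non-survivor"))
  if (!is_count(n_cells) || !is_count(n_subjects) || n_cells < n_subjects) {
    stop("need n_cells >= n_subjects >= 1")
  }
  if (radius_scale <= 0) stop("'radius_scale' must be positive")
  if (peripheral_weight < 0 || peripheral_weight > 1) {
    stop("'peripheral_weight' must lie in [0, 1]")
  }
  structure(list(group = group, outcome = outcome,
                 radius_scale = radius_scale, ri_offset = ri_offset,
                 peripheral_weight = peripheral_weight,
                 n_cells = as.integer(n_cells), n_subjects = as.integer(n_subjects),
                 subject_sd_log_radius = subject_sd_log_radius,
                 subject_sd_ri = subject_sd_ri,
                 cell_sd_log_radius = cell_sd_log_radius,
                 cell_sd_ri = cell_sd_ri),
            class = "group_effect_spec")
}

#' Clinical covariate specification
#'
#' A covariate is generated per subject as a linear function of the
#' subject's mean cellular RI plus Gaussian noise, with the slope and noise
#' variance solved in closed form so that the expected Pearson correlation
#' with subject mean RI equals `rho` and the marginal standard deviation
#' equals `sd`.
#'
#' @param name covariate name.
#' @param rho target Pearson correlation with subject mean RI, in \[-1, 1\].
#' @param mean,sd marginal mean and standard deviation.
#' @return an object of class `clinical_covariate_spec`.
#' @export
clinical_covariate_spec <- function(name, rho, mean, sd) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1) {
    stop("target correlation 'rho' must lie in [-1, 1]")
  }
  if (sd < 0) stop("'sd' must be >= 0")
  structure(list(name = as.character(name), rho = rho, mean = mean, sd = sd),
            class = "clinical_covariate_spec")
}

#' Default clinical covariate panel
#'
#' Inflammatory laboratory values and cytokines routinely followed in
#' sepsis, with target correlations against subject mean RI. All correlate
#' positively except lymphocyte percentage, which moves opposite to the
#' inflammatory markers during recovery.
#'
#' @return list of [clinical_covariate_spec()] objects.
#' @export
default_covariates <- function() {
  list(clinical_covariate_spec("CRP", 0.88, 80, 60),
       clinical_covariate_spec("WBC", 0.68, 12000, 5000),
       clinical_covariate_spec("neutrophil_pct", 0.76, 75, 12),
       clinical_covariate_spec("lymphocyte_pct", -0.81, 15, 8),
       clinical_covariate_spec("CCL2_MCP1", 0.944, 300, 200),
       clinical_covariate_spec("IL10", 0.994, 50, 40),
       clinical_covariate_spec("IL2", 0.995, 10, 6),
       clinical_covariate_spec("TNFa", 0.991, 25, 15))
}

#' Default cohort group structure
#'
#' Mirrors the scale of a sepsis-recovery study: 20 healthy subjects and 8
#' sepsis subjects sampled at three time points, with the septic-shock time
#' point (T1) split by outcome. Effects are ordered T1 > T2 > T3 = H in
#' radius and RI, and non-survivors carry more peripheral high-RI mass than
#' survivors at T1.
#'
#' @param cells_per_subject average number of cells per subject.
#' @return list of [group_effect_spec()] objects.
#' @export
default_cohort_groups <- function(cells_per_subject = 16) {
  n <- function(ns) as.integer(round(ns * cells_per_subject))
  list(group_effect_spec("H", n_cells = n(20), n_subjects = 20,
                         radius_scale = 1.00, ri_offset = 0, peripheral_weight = 0.10),
       group_effect_spec("T1", "survivor", n_cells = n(5), n_subjects = 5,
                         radius_scale = 1.10, ri_offset = 0.006, peripheral_weight = 0.30),
       group_effect_spec("T1", "non-survivor", n_cells = n(3), n_subjects = 3,
                         radius_scale = 1.13, ri_offset = 0.008, peripheral_weight = 0.60),
       group_effect_spec("T2", n_cells = n(8), n_subjects = 8,
                         radius_scale = 1.05, ri_offset = 0.003, peripheral_weight = 0.20),
       group_effect_spec("T3", n_cells = n(8), n_subjects = 8,
                         radius_scale = 1.01, ri_offset = 0.001, peripheral_weight = 0.10))
}

# expected in-cell mean RI of a phantom with the given parameters: a
# volume-weighted mixture of nucleus, rim and cytoplasm compartments.
expected_cell_mean_ri <- function(cyto, nuc, nf, pw, rif) {
  rim_ri <- cyto + pw * (nuc - cyto)
  v_nuc <- nf^3
  v_rim <- max(0, 1 - max(rif, nf)^3)
  v_cyt <- 1 - v_nuc - v_rim
  v_nuc * nuc + v_rim * rim_ri + v_cyt * cyto
}

#' Simulate a cohort of cell tomograms with metadata and covariates
#'
#' Generates per-cell phantoms for every group in `groups`, applying
#' subject-level random effects (Gaussian on log-radius, additive on RI)
#' and cell-level jitter around them, and builds a cohort table joining
#' cell id, subject id, group, outcome and per-subject clinical covariates.
#' Covariates are linear in the subject's expected mean cellular RI with
#' slope and noise variance solved analytically from the target correlation
#' and marginal standard deviation.
#'
#' @param groups list of [group_effect_spec()] objects (at least 2).
#' @param covariates list of [clinical_covariate_spec()] objects.
#' @param base base [phantom_spec()] shared by all groups.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param out_dir optional directory: tomograms are written there with
#'   [write_tomogram()] instead of (in addition to) being returned.
#' @param keep_volumes logical; set `FALSE` with `out_dir` to avoid holding
#'   all volumes in memory.
#' @return list with elements `tomograms` (list of [tomogram()], or file
#'   paths when `keep_volumes = FALSE`) and `table` (data.frame with columns
#'   cell_id, subject_id, group, outcome, subject_mean_ri and one column per
#'   covariate).
#' @export
make_cohort <- function(groups, covariates = default_covariates(),
                        base = phantom_spec(), seed = 1L,
                        out_dir = NULL, keep_volumes = TRUE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  stopifnot(all(vapply(groups, inherits, TRUE, "group_effect_spec")),
            all(vapply(covariates, inherits, TRUE, "clinical_covariate_spec")))
  if (is.null(out_dir) && !keep_volumes) stop("need 'out_dir' when keep_volumes = FALSE")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(seed, {
    rows <- list(); toms <- list(); subj_rows <- list()
    cell_no <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      # distribute cells over subjects as evenly as possible
      per_subj <- rep(g$n_cells %/% g$n_subjects, g$n_subjects)
      extra <- g$n_cells %% g$n_subjects
      if (extra > 0) per_subj[seq_len(extra)] <- per_subj[seq_len(extra)] + 1L
      for (sj in seq_len(g$n_subjects)) {
        subj_id <- sprintf("g%d_%s_s%02d", gi, g$group, sj)
        subj_logr <- rnorm(1, log(g$radius_scale), g$subject_sd_log_radius)
        subj_ri <- rnorm(1, g$ri_offset, g$subject_sd_ri)
        cell_mean_ris <- numeric(per_subj[sj])
        for (ci in seq_len(per_subj[sj])) {
          cell_no <- cell_no + 1L
          logr <- subj_logr + rnorm(1, 0, g$cell_sd_log_radius)
          dri <- subj_ri + rnorm(1, 0, g$cell_sd_ri)
          clamp <- function(x) pmin(1.45, pmax(1.30, x))
          spec <- phantom_spec(
            cell_radius_um = base$cell_radius_um * exp(logr),
            nucleus_radius_fraction = base$nucleus_radius_fraction,
            cytoplasm_ri = clamp(base$cytoplasm_ri + dri),
            nucleus_ri = clamp(base$nucleus_ri + dri),
            medium_ri = base$medium_ri,
            noise_sd = base$noise_sd,
            voxel_spacing_um = base$voxel_spacing_um,
            grid_shape = base$grid_shape,
            center_offset_vox = base$center_offset_vox,
            peripheral_weight = g$peripheral_weight,
            rim_inner_fraction = base$rim_inner_fraction)
          cell_id <- sprintf("cell%05d", cell_no)
          labels <- list(group = g$group, outcome = g$outcome, subject_id = subj_id)
          tom <- make_phantom(spec, seed = NULL, cell_id = cell_id, labels = labels)
          cell_mean_ris[ci] <- expected_cell_mean_ri(
            spec$cytoplasm_ri, spec$nucleus_ri, spec$nucleus_radius_fraction,
            spec$peripheral_weight, spec$rim_inner_fraction)
          if (!is.null(out_dir)) {
            write_tomogram(tom, out_dir)
          }
          toms[[cell_id]] <- if (keep_volumes) tom else file.path(out_dir, paste0(cell_id, ".tif"))
          rows[[cell_no]] <- data.frame(cell_id = cell_id, subject_id = subj_id,
                                        group = g$group, outcome = g$outcome,
                                        stringsAsFactors = FALSE)
        }
        subj_rows[[subj_id]] <- data.frame(subject_id = subj_id,
                                           subject_mean_ri = mean(cell_mean_ris),
                                           stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    subj <- do.call(rbind, subj_rows)

    # covariates: cov = mean + a * (x - mean(x)) + eps, a = rho * sd / sd(x),
    # var(eps) = sd^2 (1 - rho^2) -> E[cor(cov, x)] = rho, marginal sd = sd
    x <- subj$subject_mean_ri
    sx <- sd(x)
    for (cv in covariates) {
      if (nrow(subj) > 1 && sx > 0) {
        a <- cv$rho * cv$sd / sx
        eps <- rnorm(nrow(subj), 0, cv$sd * sqrt(1 - cv$rho^2))
        subj[[cv$name]] <- cv$mean + a * (x - mean(x)) + eps
      } else {
        warning("no between-subject RI variation; covariate '", cv$name,
                "' drawn from its marginal only")
        subj[[cv$name]] <- rnorm(nrow(subj), cv$mean, cv$sd)
      }
    }
    tab <- merge(tab, subj, by = "subject_id", sort = FALSE)
    tab <- tab[order(tab$cell_id), c("cell_id", "subject_id", "group", "outcome",
                                     "subject_mean_ri",
                                     vapply(covariates, `[[`, "", "name"))]
    rownames(tab) <- NULL
    if (!is.null(out_dir)) {
      write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    }
    list(tomograms = toms, table = tab)
  })
}
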