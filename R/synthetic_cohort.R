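# Synthetic phantom cohorts: co-registered 3D volumes with a shared template
# texture, per-subject noise, and group-specific alterations planted in known
# patches, so every downstream stage is testable without clinical data.

#' Specify a synthetic phantom cohort
#'
#' Collects and validates the parameters of a two-group phantom cohort of
#' co-registered 3D volumes. Group effects are planted in patches of the grid
#' implied by `patch_shape` (the same anchored tiling [build_grid()] uses), so
#' the planted truth is expressed in the coordinate system the network
#' pipeline analyses.
#'
#' @param volume_shape Integer triple, volume dimensions in voxels.
#' @param mask_kind `"ellipsoid"` (brain-like centred ellipsoid) or `"full"`.
#' @param n_control,n_case Subjects per group; at least 2 each.
#' @param patch_shape A [patch_shape()] (or integer triple) defining the grid
#'   in which `effect_patches` are indexed.
#' @param effect_patches Integer indices of grid boxes receiving the group
#'   effect (may be empty).
#' @param effect_kind `"mean_shift"` (adds a constant intensity offset) or
#'   `"decorrelate"` (replaces the patch texture with an independent smooth
#'   field of matched variance).
#' @param effect_magnitude Nonnegative effect size in units of the template
#'   intensity SD; 0 disables the effect entirely.
#' @param noise_sd Nonnegative SD of the i.i.d. Gaussian subject noise, in
#'   template-SD units.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(c(20, 20, 20), "full", n_control = 3, n_case = 2,
#'                     patch_shape = c(10, 10, 10), seed = 1)
cohort_spec <- function(volume_shape, mask_kind = c("ellipsoid", "full"),
                        n_control, n_case,
                        patch_shape = c(8, 8, 8),
                        effect_patches = integer(0),
                        effect_kind = c("decorrelate", "mean_shift"),
                        effect_magnitude = 0, noise_sd = 0.5, seed = 1) {
  mask_kind <- match.arg(mask_kind)
  effect_kind <- match.arg(effect_kind)
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3)
  if (!inherits(patch_shape, "patch_shape")) {
    patch_shape <- do.call(new_patch_shape, as.list(as.integer(patch_shape)))
  }
  if (n_control < 2 || n_case < 2) {
    stop("each group needs at least 2 subjects (got ", n_control, " control, ",
         n_case, " case)", call. = FALSE)
  }
  if (effect_magnitude < 0) stop("effect_magnitude must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n_boxes <- nrow(build_grid(volume_shape, patch_shape)$boxes)
  effect_patches <- as.integer(effect_patches)
  if (length(effect_patches) &&
      (min(effect_patches) < 1 || max(effect_patches) > n_boxes)) {
    stop("effect_patches must lie inside the grid (1..", n_boxes, ")",
         call. = FALSE)
  }
  structure(list(volume_shape = volume_shape, mask_kind = mask_kind,
                 n_control = as.integer(n_control), n_case = as.integer(n_case),
                 patch_shape = patch_shape, effect_patches = effect_patches,
                 effect_kind = effect_kind,
                 effect_magnitude = as.numeric(effect_magnitude),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build the shared template volume and brain mask
#'
#' The template emulates the registered, skull-stripped T1 every subject is a
#' noisy copy of. Its texture is a smooth random field made periodic with
#' period `tile_shape`: homologous patches then share texture, which gives the
#' strong between-patch intensity correlations that real structural covariance
#' shows and that a plain white-noise phantom would lack. A low-amplitude
#' large-scale field is superimposed so the template is not exactly periodic.
#' Intensities are normalised to SD 1 inside the mask (offset +10 so values
#' are positive, as in a real T1) and set to zero outside it.
#'
#' @param volume_shape Integer triple; each dimension must be at least 8.
#' @param mask_kind `"ellipsoid"` or `"full"`.
#' @param seed Integer seed.
#' @param tile_shape Integer triple, texture period in voxels. For the planted
#'   effects to be detectable the period should divide the analysis patch
#'   dimensions; [simulate_cohort()] passes its `patch_shape`.
#' @param smooth_sigma Gaussian smoothing width (voxels) of the texture.
#' @return A list with `template` (3D array) and `mask` (3D 0/1 array,
#'   mirror-symmetric about the medial sagittal x-midplane).
#' @export
make_template <- function(volume_shape, mask_kind = c("ellipsoid", "full"),
                          seed = 1, tile_shape = c(4, 4, 4),
                          smooth_sigma = 2) {
  mask_kind <- match.arg(mask_kind)
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3)
  axes <- c("x", "y", "z")
  small <- which(volume_shape < 8)
  if (length(small)) {
    stop("volume dimension on axis ", axes[small[1]], " is ",
         volume_shape[small[1]], "; need >= 8 voxels", call. = FALSE)
  }
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(tile_shape) == 3, all(tile_shape >= 2))

  mask <- array(1, volume_shape)
  if (mask_kind == "ellipsoid") {
    ctr <- (volume_shape + 1) / 2
    semi <- 0.45 * volume_shape
    xs <- (seq_len(volume_shape[1]) - ctr[1]) / semi[1]
    ys <- (seq_len(volume_shape[2]) - ctr[2]) / semi[2]
    zs <- (seq_len(volume_shape[3]) - ctr[3]) / semi[3]
    d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
    mask <- array(as.numeric(d2 <= 1), volume_shape)
  }

  template <- with_seed(seed, {
    # One seamless smooth tile, repeated periodically across the volume.
    tile <- smooth3d(array(stats::rnorm(prod(tile_shape)), tile_shape),
                     sigma = smooth_sigma, periodic = TRUE)
    ix <- ((seq_len(volume_shape[1]) - 1) %% tile_shape[1]) + 1
    iy <- ((seq_len(volume_shape[2]) - 1) %% tile_shape[2]) + 1
    iz <- ((seq_len(volume_shape[3]) - 1) %% tile_shape[3]) + 1
    tex <- tile[ix, iy, iz]
    tex <- tex / stats::sd(tex)
    # Large-scale anatomical-gradient stand-in; small so patch texture
    # dominates the correlations.
    glob <- smooth3d(array(stats::rnorm(prod(volume_shape)), volume_shape),
                     sigma = max(volume_shape) / 4)
    glob <- 0.2 * glob / stats::sd(glob)
    tex + glob
  })
  inside <- mask > 0
  template[inside] <- (template[inside] - mean(template[inside])) /
    stats::sd(template[inside]) + 10
  template[!inside] <- 0
  list(template = template, mask = mask)
}

#' Simulate one subject's volume
#'
#' Adds i.i.d. Gaussian noise to the template inside the mask and, for case
#' subjects, plants the group effect in the given patches — emulating the
#' localized intensity and texture alterations (edema, hemorrhage, contusion)
#' that follow brain injury. `mean_shift` adds
#' `effect_magnitude * sd(template)` to the patch. `decorrelate` replaces the
#' centred patch texture by
#' `sqrt(1 - lambda^2) * texture + lambda * independent_field` with
#' `lambda = min(effect_magnitude, 1)` and the independent field scaled to the
#' patch SD: the variance is matched by construction while the correlation
#' with the shared template texture decays monotonically, reaching full
#' replacement at magnitude 1.
#'
#' @param template,mask As returned by [make_template()]; same shape.
#' @param group 0 (control) or 1 (case).
#' @param effect_boxes Tibble of grid boxes (as in `build_grid()$boxes`) to
#'   alter for case subjects; may have zero rows.
#' @param effect_kind `"mean_shift"` or `"decorrelate"`.
#' @param effect_magnitude,noise_sd See [cohort_spec()].
#' @param seed Integer seed for this subject's noise stream.
#' @return A 3D intensity array.
#' @export
simulate_subject <- function(template, mask, group, effect_boxes = NULL,
                             effect_kind = "decorrelate",
                             effect_magnitude = 0, noise_sd = 0.5, seed = 1) {
  stopifnot(identical(dim(template), dim(mask)))
  if (!effect_kind %in% c("mean_shift", "decorrelate")) {
    stop("unknown effect_kind: ", effect_kind, call. = FALSE)
  }
  inside <- mask > 0
  tpl_sd <- stats::sd(template[inside])
  with_seed(seed, {
    vol <- template
    if (group == 1 && effect_magnitude > 0 && !is.null(effect_boxes) &&
        nrow(effect_boxes) > 0) {
      for (b in seq_len(nrow(effect_boxes))) {
        bx <- effect_boxes[b, ]
        sl <- vol[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1]
        if (effect_kind == "mean_shift") {
          sl <- sl + effect_magnitude * tpl_sd
        } else {
          lam <- min(effect_magnitude, 1)
          mu <- mean(sl)
          sdv <- stats::sd(sl)
          fld <- smooth3d(array(stats::rnorm(length(sl)), dim(sl)), sigma = 1)
          fld <- fld / stats::sd(fld) * sdv
          sl <- mu + sqrt(1 - lam^2) * (sl - mu) + lam * fld
        }
        vol[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1] <- sl
      }
    }
    if (noise_sd > 0) {
      noise <- array(stats::rnorm(length(vol), sd = noise_sd * tpl_sd),
                     dim(vol))
      vol[inside] <- vol[inside] + noise[inside]
    }
    vol[!inside] <- 0
    vol
  })
}

#' Simulate a full phantom cohort
#'
#' Generates the template once from `spec$seed`, then each subject from a
#' deterministic per-subject substream, so the cohort is bit-reproducible and
#' independent of evaluation order. Controls come first, then cases.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `syn_cohort`: list with `volumes` (named list of
#'   3D arrays), `mask`, `labels` (tibble `subject_id`, `group`), `truth`
#'   (planted patch indices), `template`, and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tm <- make_template(spec$volume_shape, spec$mask_kind, seed = spec$seed,
                      tile_shape = unlist(spec$patch_shape[c("dx", "dy", "dz")]))
  grid <- build_grid(spec$volume_shape, spec$patch_shape)
  effect_boxes <- grid$boxes[spec$effect_patches, , drop = FALSE]
  n <- spec$n_control + spec$n_case
  groups <- c(rep(0L, spec$n_control), rep(1L, spec$n_case))
  ids <- sprintf("sub%03d", seq_len(n))
  volumes <- lapply(seq_len(n), function(i) {
    simulate_subject(tm$template, tm$mask, groups[i], effect_boxes,
                     spec$effect_kind, spec$effect_magnitude, spec$noise_sd,
                     seed = derive_seed(spec$seed, i))
  })
  names(volumes) <- ids
  structure(list(volumes = volumes, mask = tm$mask,
                 labels = tibble::tibble(subject_id = ids, group = groups),
                 truth = spec$effect_patches, template = tm$template,
                 spec = spec),
            class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("<syn_cohort> ", length(x$volumes), " subjects (",
      x$spec$n_control, " control / ", x$spec$n_case, " case), volumes ",
      paste(x$spec$volume_shape, collapse = "x"), ", ",
      length(x$truth), " planted patch(es), effect '", x$spec$effect_kind,
      "' magnitude ", x$spec$effect_magnitude, "\n", sep = "")
  invisible(x)
}

#' Reference phantom study cohort
#'
#' The package's standard desk-scale phantom: 40^3-voxel volumes under an
#' ellipsoid brain mask, tiled by 8^3-voxel patches (V = 512), 15 control and
#' 15 case subjects with noise SD 0.5, and a decorrelation effect planted in
#' 3 fully-brain patches spread across the mask. It is the cohort the
#' package's recovery and null-calibration checks run on: at magnitude 1 the
#' planted patches lose their texture correlation entirely, at magnitude 0
#' the two groups are exchangeable.
#'
#' @param effect_magnitude Decorrelation magnitude (default 1, full
#'   replacement; 0 gives the null cohort).
#' @param seed Integer seed.
#' @param n_per_group Subjects per group (default 15).
#' @param n_effect Number of planted patches (default 3).
#' @return A `syn_cohort` whose `truth` holds the planted patch indices.
#' @export
phantom_cohort <- function(effect_magnitude = 1, seed = 1, n_per_group = 15,
                           n_effect = 3) {
  volume_shape <- c(40L, 40L, 40L)
  shape <- new_patch_shape(8, 8, 8)
  tm <- make_template(volume_shape, "ellipsoid", seed = seed,
                      tile_shape = c(8, 8, 8))
  grid <- apply_mask(build_grid(volume_shape, shape), tm$mask)
  full <- grid$boxes$box[grid$boxes$brain_fraction >= 0.999]
  planted <- full[unique(round(seq(1, length(full), length.out = n_effect)))]
  spec <- cohort_spec(volume_shape, "ellipsoid", n_control = n_per_group,
                      n_case = n_per_group, patch_shape = shape,
                      effect_patches = planted, effect_kind = "decorrelate",
                      effect_magnitude = effect_magnitude, noise_sd = 0.5,
                      seed = seed)
  simulate_cohort(spec)
}

#' Write a cohort to disk
#'
#' One gzipped NIfTI per subject plus `mask.nii.gz`, a `labels.csv`
#' (`subject_id,group`) and a `truth.json` echoing the planted patches and
#' the generating parameters.
#'
#' @param cohort A `syn_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the tibble of subject file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(cohort$volumes), function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    RNifti::writeNifti(cohort$volumes[[id]], p)
    p
  }, character(1))
  RNifti::writeNifti(cohort$mask, file.path(dir, "mask.nii.gz"))
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  sp <- cohort$spec
  jsonlite::write_json(
    list(effect_patches = sp$effect_patches,
         spec = list(volume_shape = sp$volume_shape, mask_kind = sp$mask_kind,
                     n_control = sp$n_control, n_case = sp$n_case,
                     patch_shape = c(sp$patch_shape$dx, sp$patch_shape$dy,
                                     sp$patch_shape$dz),
                     effect_kind = sp$effect_kind,
                     effect_magnitude = sp$effect_magnitude,
                     noise_sd = sp$noise_sd, seed = sp$seed)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(tibble::tibble(subject_id = names(cohort$volumes), path = paths))
}
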