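# Reading and validating co-registered volumes, masks and label volumes.
# The pipeline assumes all inputs already share one registered space
# (registration, skull stripping and bias correction are upstream concerns);
# this module enforces that contract at load time.

#' Load a cohort of co-registered volumes
#'
#' Reads one NIfTI per subject plus a labels table, verifies the shared-space
#' contract (identical array shape and voxel size across subjects), aligns
#' labels to subjects by id, and derives or reads the brain mask. Subject ids
#' are the file base names without the `.nii`/`.nii.gz` extension.
#'
#' @param paths Character vector of NIfTI files, one per subject.
#' @param labels_path CSV with header `subject_id,group` (group coded 0 =
#'   control / 1 = case).
#' @param mask_path Optional NIfTI brain mask in the shared space. If `NULL`,
#'   the mask is the set of voxels with intensity > 0 in at least half the
#'   subjects (skull-stripped volumes have zero background).
#' @return An object of class `brain_cohort`: `volumes` (named list of 3D
#'   arrays), `labels` (tibble `subject_id`, `group`), `mask`, `voxel_size`.
#' @export
load_cohort <- function(paths, labels_path, mask_path = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  imgs <- lapply(paths, RNifti::readNifti)
  names(imgs) <- ids
  shapes <- lapply(imgs, function(v) as.integer(dim(v)))
  for (i in seq_along(imgs)) {
    if (length(shapes[[i]]) != 3) {
      stop("subject ", ids[i], " is not a 3D volume", call. = FALSE)
    }
    if (!identical(shapes[[i]], shapes[[1]])) {
      stop("shape mismatch between subjects ", ids[1], " (",
           paste(shapes[[1]], collapse = "x"), ") and ", ids[i], " (",
           paste(shapes[[i]], collapse = "x"),
           "): volumes must share one registered space", call. = FALSE)
    }
  }
  vox <- RNifti::pixdim(imgs[[1]])[1:3]
  for (i in seq_along(imgs)) {
    if (max(abs(RNifti::pixdim(imgs[[i]])[1:3] - vox)) > 1e-6) {
      stop("voxel size mismatch between subjects ", ids[1], " and ", ids[i],
           call. = FALSE)
    }
  }
  volumes <- lapply(imgs, function(v) {
    a <- array(as.numeric(v), dim(v))
    if (any(!is.finite(a))) stop("non-finite intensities found", call. = FALSE)
    a
  })

  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(lab))) {
    stop("labels CSV must have columns subject_id,group", call. = FALSE)
  }
  unlabelled <- setdiff(ids, lab$subject_id)
  if (length(unlabelled)) {
    stop("missing label for subject ", paste(unlabelled, collapse = ", "),
         call. = FALSE)
  }
  lab <- lab[match(ids, lab$subject_id), ]
  counts <- table(factor(lab$group, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop("each class needs at least 2 subjects (got ", counts[["0"]],
         " control, ", counts[["1"]], " case)", call. = FALSE)
  }

  if (!is.null(mask_path)) {
    mask <- array(as.numeric(RNifti::readNifti(mask_path) > 0), shapes[[1]])
    if (!identical(as.integer(dim(mask)), shapes[[1]])) {
      stop("mask shape does not match cohort volumes", call. = FALSE)
    }
  } else {
    pos <- Reduce(`+`, lapply(volumes, function(v) v > 0))
    mask <- array(as.numeric(pos >= length(volumes) / 2), shapes[[1]])
  }
  structure(list(volumes = volumes,
                 labels = tibble::tibble(subject_id = ids,
                                         group = as.integer(lab$group)),
                 mask = mask, voxel_size = as.numeric(vox)),
            class = "brain_cohort")
}

#' @export
print.brain_cohort <- function(x, ...) {
  cat("<brain_cohort> ", length(x$volumes), " subjects (",
      sum(x$labels$group == 0), " control / ", sum(x$labels$group == 1),
      " case), volumes ", paste(dim(x$volumes[[1]]), collapse = "x"),
      ", voxel ", paste(signif(x$voxel_size, 3), collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

# A simulated cohort satisfies the same contract as a loaded one.
#' Convert a synthetic cohort to the loaded-cohort representation
#' @param cohort A `syn_cohort`.
#' @return A `brain_cohort`.
#' @export
as_brain_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "syn_cohort"))
  structure(list(volumes = cohort$volumes, labels = cohort$labels,
                 mask = cohort$mask, voxel_size = c(1, 1, 1)),
            class = "brain_cohort")
}

#' Load an anatomical label volume with its lookup table
#'
#' The label volume assigns each voxel an integer region code (0 =
#' unlabeled); the lookup table names the codes. Every nonzero code present
#' in the volume must have a name.
#'
#' @param path NIfTI file of integer region codes in the shared space.
#' @param lut_path CSV with header `code,region_name`.
#' @param volume_shape Optional integer triple to validate the shape against.
#' @return An object of class `label_volume`: `data` (3D integer array) and
#'   `lut` (tibble `code`, `region_name`).
#' @export
load_label_volume <- function(path, lut_path, volume_shape = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.integer(round(as.numeric(img))), dim(img))
  if (!is.null(volume_shape) &&
      !identical(as.integer(dim(data)), as.integer(volume_shape))) {
    stop("label volume shape (", paste(dim(data), collapse = "x"),
         ") does not match cohort shape (",
         paste(volume_shape, collapse = "x"), ")", call. = FALSE)
  }
  lut <- utils::read.csv(lut_path, stringsAsFactors = FALSE)
  if (!all(c("code", "region_name") %in% names(lut))) {
    stop("lookup table must have columns code,region_name", call. = FALSE)
  }
  codes <- setdiff(unique(as.vector(data)), 0L)
  unknown <- setdiff(codes, lut$code)
  if (length(unknown)) {
    stop("label codes without a lookup entry: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  structure(list(data = data,
                 lut = tibble::tibble(code = as.integer(lut$code),
                                      region_name = lut$region_name)),
            class = "label_volume")
}
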