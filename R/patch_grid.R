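# Homologous patch grids: tile the shared registered space into
# non-overlapping parallelepipeds of V voxels, anchored at the medial
# sagittal plane so both hemispheres are covered uniformly, and decide patch
# validity from the brain fraction under the cohort mask.

#' Construct a patch shape
#'
#' @param dx,dy,dz Positive patch dimensions in voxels; the patch volume is
#'   `V = dx * dy * dz`.
#' @return An object of class `patch_shape`.
#' @export
#' @examples
#' patch_shape(10, 10, 10)$V  # 1000
patch_shape <- function(dx, dy, dz) new_patch_shape(dx, dy, dz)

new_patch_shape <- function(dx, dy, dz) {
  stopifnot(dx >= 1, dy >= 1, dz >= 1)
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 dz = as.integer(dz), V = as.integer(dx * dy * dz)),
            class = "patch_shape")
}

#' @export
print.patch_shape <- function(x, ...) {
  cat("<patch_shape> ", x$dx, " x ", x$dy, " x ", x$dz, " = ", x$V,
      " voxels\n", sep = "")
  invisible(x)
}

#' Choose patch dimensions for a target patch volume
#'
#' Factorises `V` into the most nearly cubic parallelepiped: among all ordered
#' factor triples `(dx, dy, dz)` with `dx * dy * dz = V`, returns the one
#' minimising the aspect ratio `max(dims) / min(dims)`, breaking ties by the
#' lexicographically smallest triple. Near-cubic patches sample the local
#' texture as isotropically as a given V allows.
#'
#' @param V Target patch volume in voxels (>= 1).
#' @return A `patch_shape`. If even the best factorisation is strongly
#'   anisotropic (aspect ratio > 8, e.g. `V` prime) a warning is emitted but
#'   the shape is still returned.
#' @export
#' @examples
#' choose_patch_shape(1000)  # 10 x 10 x 10
choose_patch_shape <- function(V) {
  V <- as.integer(V)
  stopifnot(V >= 1)
  divs <- which(V %% seq_len(V) == 0)
  cand <- purrr::map_dfr(divs, function(dx) {
    rem <- V %/% dx
    dys <- divs[divs <= rem & rem %% divs == 0]
    tibble::tibble(dx = dx, dy = dys, dz = rem %/% dys)
  })
  cand$ratio <- pmax(cand$dx, cand$dy, cand$dz) / pmin(cand$dx, cand$dy, cand$dz)
  cand <- cand[order(cand$ratio, cand$dx, cand$dy, cand$dz), ]
  best <- cand[1, ]
  if (best$ratio > 8) {
    warning("patch volume ", V, " admits no near-cubic factorisation; using ",
            best$dx, "x", best$dy, "x", best$dz, " (aspect ratio ",
            signif(best$ratio, 3), ")", call. = FALSE)
  }
  new_patch_shape(best$dx, best$dy, best$dz)
}

#' Tile a volume into homologous patches
#'
#' Builds the fixed grid every subject shares at one scale. Along the
#' left-right (x) axis, tiling starts at the medial sagittal plane
#' `x = floor(Xdim / 2)` and grows outward in both directions so each
#' hemisphere is covered by an equal number of boxes (mirror-homologous when
#' `Xdim` is even); along y and z it starts at voxel 0. Only complete boxes
#' of exactly V voxels are kept — thin boundary slabs are dropped, since
#' network nodes must be equal-size patch vectors.
#'
#' @param volume_shape Integer triple (voxels).
#' @param shape A `patch_shape` (or integer triple).
#' @return An object of class `patch_grid`: the `shape`, the `volume_shape`,
#'   and a `boxes` tibble with 0-based half-open voxel intervals
#'   (`x0,x1,y0,y1,z0,z1`), plus `brain_fraction`/`valid` columns filled by
#'   [apply_mask()] (`NA` until then).
#' @export
#' @examples
#' g <- build_grid(c(20, 20, 20), choose_patch_shape(1000))
#' nrow(g$boxes)  # 8
build_grid <- function(volume_shape, shape) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3)
  if (!inherits(shape, "patch_shape")) {
    shape <- do.call(new_patch_shape, as.list(as.integer(shape)))
  }
  d <- c(shape$dx, shape$dy, shape$dz)
  axes <- c("x", "y", "z")
  over <- which(d > volume_shape)
  if (length(over)) {
    stop("patch dimension exceeds volume on axis ", axes[over[1]], " (",
         d[over[1]], " > ", volume_shape[over[1]], ")", call. = FALSE)
  }
  if (volume_shape[1] < 2 * d[1]) {
    stop("volume x-dimension (", volume_shape[1], ") must be at least twice ",
         "the patch x-dimension (", d[1], ") to cover both hemispheres",
         call. = FALSE)
  }
  mid <- volume_shape[1] %/% 2
  right <- seq.int(mid, by = d[1], length.out = (volume_shape[1] - mid) %/% d[1])
  left <- rev(seq.int(mid - d[1], by = -d[1], length.out = mid %/% d[1]))
  xs <- c(left, right)
  ys <- seq.int(0, by = d[2], length.out = volume_shape[2] %/% d[2])
  zs <- seq.int(0, by = d[3], length.out = volume_shape[3] %/% d[3])
  boxes <- tidyr::expand_grid(z0 = zs, y0 = ys, x0 = xs)
  boxes <- tibble::tibble(
    box = seq_len(nrow(boxes)),
    x0 = boxes$x0, x1 = boxes$x0 + d[1],
    y0 = boxes$y0, y1 = boxes$y0 + d[2],
    z0 = boxes$z0, z1 = boxes$z0 + d[3],
    brain_fraction = NA_real_, valid = NA)
  structure(list(shape = shape, volume_shape = volume_shape, boxes = boxes,
                 n_nodes = NA_integer_),
            class = "patch_grid")
}

#' Score patches against the brain mask
#'
#' Computes each box's brain fraction (mask voxels inside the box divided by
#' V) and marks a patch valid when its non-brain fraction does not exceed 10%
#' (i.e. brain fraction >= `min_fraction`); partially extracranial patches
#' would otherwise contribute spurious links. "Exceeding" is strict: a patch
#' at exactly 10% non-brain is kept.
#'
#' @param grid A `patch_grid`.
#' @param mask 3D 0/1 array of the grid's `volume_shape`.
#' @param min_fraction Minimum brain fraction for validity (default 0.9).
#' @return The grid with `brain_fraction`, `valid` and `n_nodes` filled in.
#' @export
apply_mask <- function(grid, mask, min_fraction = 0.9) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!identical(as.integer(dim(mask)), grid$volume_shape)) {
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match grid volume shape (",
         paste(grid$volume_shape, collapse = "x"), ")", call. = FALSE)
  }
  V <- grid$shape$V
  b <- grid$boxes
  frac <- vapply(seq_len(nrow(b)), function(i) {
    sum(mask[(b$x0[i] + 1):b$x1[i], (b$y0[i] + 1):b$y1[i],
             (b$z0[i] + 1):b$z1[i]] > 0) / V
  }, numeric(1))
  grid$boxes$brain_fraction <- frac
  grid$boxes$valid <- frac >= min_fraction - 1e-12
  grid$n_nodes <- sum(grid$boxes$valid)
  if (grid$n_nodes == 0) {
    stop("no patch has brain fraction >= ", min_fraction,
         "; grid too coarse for this mask", call. = FALSE)
  }
  grid
}

#' @export
print.patch_grid <- function(x, ...) {
  cat("<patch_grid> ", nrow(x$boxes), " boxes of ",
      x$shape$dx, "x", x$shape$dy, "x", x$shape$dz, " voxels in a ",
      paste(x$volume_shape, collapse = "x"), " volume", sep = "")
  if (!is.na(x$n_nodes)) cat("; ", x$n_nodes, " valid nodes", sep = "")
  cat("\n")
  invisible(x)
}

#' Serialize a grid to JSON
#'
#' Box coordinates are written as 0-based half-open voxel intervals.
#'
#' @param grid A `patch_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "patch_grid"))
  jsonlite::write_json(
    list(patch_shape = c(grid$shape$dx, grid$shape$dy, grid$shape$dz),
         volume_shape = grid$volume_shape,
         boxes = grid$boxes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
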