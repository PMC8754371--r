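# 1 mm isotropic voxel grids in MNI mm. A grid is defined by its integer
# `origin` (mm coordinate of the corner of voxel [1,1,1]) and dimensions;
# voxel membership is floor(coord - origin) + 1 (half-open 1 mm voxels).

voxel_index <- function(coords, origin) {
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1)
  floor(sweep(coords, 2, origin)) + 1L
}

#' Endpoint density map for one tract and subject
#'
#' Counts streamline endpoints ("first" or "last" nodes of a reoriented
#' set) per 1 mm isotropic voxel and smooths the counts with a normalized
#' uniform spherical kernel of the given radius (all voxels whose centers lie
#' within `smoothing_radius` mm share the mass equally), so the total count
#' is preserved.
#'
#' @param set A reoriented `streamline_set` (see [reorient_streamlines()]).
#' @param collection `"first"` or `"last"` endpoint collection.
#' @param smoothing_radius Kernel radius in mm (0 = raw counts).
#' @param origin,dim Optional grid origin (mm) and dimensions; defaults to a
#'   bounding box around the endpoints padded by the kernel radius plus 2 mm.
#' @return A list of class `density_volume`: `values` (3D array), `origin`,
#'   `tract`, `subject`, `collection`, `n_endpoints`.
#' @export
endpoint_density_map <- function(set, collection = c("first", "last"),
                                 smoothing_radius = 3, origin = NULL,
                                 dim = NULL) {
  collection <- match.arg(collection)
  if (!length(set$streamlines)) stop("empty streamline set")
  pts <- t(vapply(set$streamlines, function(m)
    if (collection == "first") m[1, ] else m[nrow(m), ], numeric(3)))

  pad <- ceiling(smoothing_radius) + 2
  if (is.null(origin)) origin <- floor(apply(pts, 2, min)) - pad
  if (is.null(dim)) dim <- ceiling(apply(pts, 2, max)) - origin + pad + 1

  vox <- voxel_index(pts, origin)
  if (any(vox < 1) || any(sweep(vox, 2, dim) > 0))
    stop("endpoints outside the voxel grid")
  counts <- array(0, dim)
  for (i in seq_len(nrow(vox)))
    counts[vox[i, 1], vox[i, 2], vox[i, 3]] <-
      counts[vox[i, 1], vox[i, 2], vox[i, 3]] + 1

  if (smoothing_radius > 0) {
    r <- smoothing_radius
    off <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r),
                       dz = -floor(r):floor(r))
    off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, ]
    sm <- array(0, dim)
    nz <- which(counts > 0, arr.ind = TRUE)
    w <- 1 / nrow(off)
    for (k in seq_len(nrow(nz))) {
      v <- counts[nz[k, 1], nz[k, 2], nz[k, 3]]
      xs <- nz[k, 1] + off$dx; ys <- nz[k, 2] + off$dy; zs <- nz[k, 3] + off$dz
      ok <- xs >= 1 & xs <= dim[1] & ys >= 1 & ys <= dim[2] &
        zs >= 1 & zs <= dim[3]
      idx <- cbind(xs[ok], ys[ok], zs[ok])
      sm[idx] <- sm[idx] + v * w
    }
    counts <- sm
  }
  structure(list(values = counts, origin = origin, tract = set$tract,
                 subject = set$subject, collection = collection,
                 n_endpoints = nrow(pts)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf(
    "Density volume: tract '%s', subject '%s', %s endpoints, grid %s, sum %.3f\n",
    x$tract, x$subject, x$collection,
    paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Aggregate per-subject density volumes into a group subject-count mask
#'
#' Each subject's volume is thresholded at `density_threshold` (strictly
#' greater), binarized, and the binary maps are summed, giving per voxel the
#' number of subjects with suprathreshold endpoint density there. By default
#' the threshold applies to the per-subject density normalized by that
#' subject's total endpoint count, making it invariant to streamline count;
#' `normalize = FALSE` thresholds the raw smoothed counts instead.
#'
#' @param volumes List of `density_volume`s on a common grid.
#' @param density_threshold Threshold (strict >).
#' @param normalize Normalize each volume by its total endpoint count first.
#' @return A list of class `group_endpoint_mask`: `values` (subject counts),
#'   `origin`, `tract`, `collection`, `n_subjects`.
#' @export
group_endpoint_mask <- function(volumes, density_threshold = 0.01,
                                normalize = TRUE) {
  stopifnot(length(volumes) >= 1)
  org <- volumes[[1]]$origin; dm <- dim(volumes[[1]]$values)
  acc <- array(0L, dm)
  for (v in volumes) {
    if (!identical(v$origin, org) || !identical(dim(v$values), dm))
      stop("volumes are not on a common grid")
    vals <- if (normalize) v$values / max(v$n_endpoints, 1) else v$values
    acc <- acc + (vals > density_threshold)
  }
  structure(list(values = acc, origin = org, tract = volumes[[1]]$tract,
                 collection = volumes[[1]]$collection,
                 n_subjects = length(volumes)),
            class = "group_endpoint_mask")
}

#' Overlap between electrode-site coordinates and tract endpoint masks
#'
#' For every row group of sites (typically ROI x response class) and every
#' group endpoint mask, computes the proportion of site coordinates that lie
#' in *valid* mask voxels — voxels whose subject count is at least
#' `validity_threshold` (endpoints from >= 100 of 1000+ subjects in the
#' motivating analysis). Sites outside a mask's grid count as not inside
#' (with a warning). Mask columns with zero overlap for every row group are
#' dropped from the matrix and recorded.
#'
#' @param sites Data frame with `x`, `y`, `z` (MNI mm) and a grouping column.
#' @param masks Named list of `group_endpoint_mask`s.
#' @param group Name of the grouping column (default `"group"`).
#' @param validity_threshold Minimum subject count for a voxel to be valid.
#' @return A list of class `overlap_matrix`: `matrix` (row groups x masks,
#'   proportions in [0, 1]), `dropped` (names of all-zero columns),
#'   `validity_threshold`.
#' @export
compute_overlap <- function(sites, masks, group = "group",
                            validity_threshold = 100) {
  grp <- factor(sites[[group]])
  mk_names <- names(masks)
  M <- matrix(0, nlevels(grp), length(masks),
              dimnames = list(levels(grp), mk_names))
  warned <- FALSE
  for (j in seq_along(masks)) {
    mask <- masks[[j]]
    dm <- dim(mask$values)
    valid <- mask$values >= validity_threshold
    vox <- voxel_index(as.matrix(sites[, c("x", "y", "z")]), mask$origin)
    inside_grid <- vox[, 1] >= 1 & vox[, 1] <= dm[1] &
      vox[, 2] >= 1 & vox[, 2] <= dm[2] & vox[, 3] >= 1 & vox[, 3] <= dm[3]
    if (any(!inside_grid) && !warned) {
      warning(sum(!inside_grid), " site(s) outside the '", mk_names[j],
              "' mask grid counted as not inside")
      warned <- TRUE
    }
    hit <- logical(nrow(sites))
    hit[inside_grid] <- valid[vox[inside_grid, , drop = FALSE]]
    M[, j] <- tapply(hit, grp, mean)
  }
  drop_cols <- colnames(M)[colSums(M) == 0]
  kept <- M[, setdiff(colnames(M), drop_cols), drop = FALSE]
  structure(list(matrix = kept, dropped = drop_cols,
                 validity_threshold = validity_threshold),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Overlap matrix (valid voxels: >= %g subjects)\n",
              x$validity_threshold))
  print(round(x$matrix, 3))
  if (length(x$dropped))
    cat("Dropped all-zero tract columns:",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Export a density volume or group mask as NIfTI
#'
#' Writes the voxel grid as a NIfTI-1 file with a diagonal 1 mm affine whose
#' translation places the grid at its MNI origin. Requires the RNifti
#' package.
#'
#' @param vol A `density_volume` or `group_endpoint_mask`.
#' @param path Output `.nii` path.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(vol$values)
  aff <- diag(4)
  aff[1:3, 4] <- vol$origin + 0.5     # voxel centers
  RNifti::qform(img) <- structure(aff, code = 4L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
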