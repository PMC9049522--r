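#' Synthetic brain atlas
#'
#' Generates an ellipsoidal brain mask on the requested grid and partitions
#' it into contiguous parcels by seeded Voronoi growth (each in-mask voxel
#' is assigned to the nearest of `n_structures` randomly placed seed voxels,
#' distances measured in millimetres). Every parcel receives a hemisphere
#' (by seed position relative to the midline) and one of `n_groups`
#' functional groups, emulating an indexed digital rat brain atlas with
#' left/right structures grouped into functional systems.
#'
#' @param shape Integer triple: grid dimensions (x, y, z). Full scale is
#'   c(64, 64, 22); the desk-scale default elsewhere is c(32, 32, 8).
#' @param n_structures Number of parcels (full scale: 202).
#' @param seed Integer seed; the atlas is fully determined by it.
#' @param voxel_size Voxel edge lengths in mm.
#' @param n_groups Number of functional groups (>= 6).
#' @return An object of class `synthetic_atlas`: list with `labels`
#'   (3D integer array, 0 = background), `brain_mask` (3D logical),
#'   `structure_table` (data.frame: label_id, name, hemisphere,
#'   functional_group, n_voxels), `voxel_size`, `seed`.
#' @export
build_synthetic_atlas <- function(shape, n_structures, seed,
                                  voxel_size = c(0.391, 0.391, 1),
                                  n_groups = 8) {
  stopifnot(length(shape) == 3, n_structures >= 2, n_groups >= 6)
  rng <- local_rng(seed)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.47 * nx; ay <- 0.47 * ny; az <- 0.47 * nz
  ix <- array(rep(seq_len(nx), times = ny * nz), dim = shape)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = shape)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = shape)
  mask <- ((ix - cx) / ax)^2 + ((iy - cy) / ay)^2 + ((iz - cz) / az)^2 <= 1
  in_idx <- which(mask)
  if (length(in_idx) < n_structures)
    stop("grid too small to host ", n_structures, " parcels")
  seeds <- sample(in_idx, n_structures)
  # mm coordinates of voxel centers
  pts <- cbind(ix[in_idx] * voxel_size[1],
               iy[in_idx] * voxel_size[2],
               iz[in_idx] * voxel_size[3])
  sp <- cbind(ix[seeds] * voxel_size[1],
              iy[seeds] * voxel_size[2],
              iz[seeds] * voxel_size[3])
  # nearest-seed assignment, blockwise to bound memory
  lab_in <- integer(length(in_idx))
  block <- 20000L
  for (start in seq(1, length(in_idx), by = block)) {
    sel <- start:min(start + block - 1L, length(in_idx))
    d2 <- outer(rowSums(pts[sel, , drop = FALSE]^2), rowSums(sp^2), "+") -
      2 * pts[sel, , drop = FALSE] %*% t(sp)
    lab_in[sel] <- max.col(-d2, ties.method = "first")
  }
  labels <- array(0L, dim = shape)
  labels[in_idx] <- lab_in
  hemi <- ifelse(ix[seeds] <= cx, "L", "R")
  groups <- paste0(
    c("sensory_cortex", "motor_cortex", "association_cortex", "thalamus",
      "hypothalamus", "basal_ganglia", "brainstem", "cerebellum",
      "limbic", "olfactory")[((seq_len(n_structures) - 1) %% n_groups) + 1])
  st <- data.frame(
    label_id = seq_len(n_structures),
    name = sprintf("structure_%03d_%s", seq_len(n_structures), hemi),
    hemisphere = hemi,
    functional_group = groups,
    n_voxels = as.integer(tabulate(lab_in, nbins = n_structures)),
    stringsAsFactors = FALSE
  )
  if (any(st$n_voxels == 0)) stop("infeasible packing: empty parcel generated")
  structure(list(labels = labels, brain_mask = mask, structure_table = st,
                 voxel_size = voxel_size, seed = seed),
            class = "synthetic_atlas")
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat(sprintf("Synthetic atlas: %s grid, %d structures, %d brain voxels\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$structure_table), sum(x$brain_mask)))
  invisible(x)
}

#' Voxel indices of one structure
#' @param atlas A `synthetic_atlas`.
#' @param label_id Structure label.
#' @return Integer vector of linear voxel indices.
#' @export
structure_voxels <- function(atlas, label_id) which(atlas$labels == label_id)

#' Write atlas to disk
#'
#' Label volume as NIfTI-1 and the structure table as TSV.
#' @param atlas A `synthetic_atlas`.
#' @param nifti_path Path for the label volume (.nii or .nii.gz).
#' @param table_path Path for the structure table TSV.
#' @export
write_atlas <- function(atlas, nifti_path, table_path) {
  img <- RNifti::asNifti(atlas$labels,
                         reference = list(pixdim = c(1, atlas$voxel_size, 1, 0, 0, 0)))
  RNifti::writeNifti(img, nifti_path)
  utils::write.table(atlas$structure_table, table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}

#' Center of mass of each structure, in mm
#'
#' Unweighted mean of the member voxel centers. Used for seed placement and
#' for 3D network node positions (center of gravity).
#' @param atlas A `synthetic_atlas`.
#' @return Matrix (n_structures x 3) of mm coordinates.
#' @export
structure_centers <- function(atlas) {
  dims <- dim(atlas$labels)
  idx <- which(atlas$labels > 0)
  lab <- atlas$labels[idx]
  co <- arrayInd(idx, dims)
  n <- nrow(atlas$structure_table)
  mm <- sweep(co, 2, atlas$voxel_size, "*")
  s <- rowsum(mm, lab)
  cnt <- as.numeric(table(factor(lab, levels = seq_len(n))))
  out <- s[match(seq_len(n), as.integer(rownames(s))), , drop = FALSE] / cnt
  dimnames(out) <- list(atlas$structure_table$label_id, c("x", "y", "z"))
  out
}
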