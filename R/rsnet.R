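#' Seed voxels for a brain structure
#'
#' Places a spherical seed (default diameter 1.173 mm) at the center of
#' mass of the parcel and returns the in-mask voxels whose centers lie
#' inside the sphere. If the center of mass falls outside the parcel
#' (non-convex parcels), it is snapped to the nearest parcel voxel. If no
#' voxel center falls inside the sphere, the single nearest in-mask voxel
#' is returned with a warning.
#'
#' @param atlas A `synthetic_atlas`.
#' @param label_id Structure label.
#' @param diameter Seed diameter, mm.
#' @return Integer vector of linear voxel indices; attribute `center` holds
#'   the seed center (mm).
#' @export
seed_voxels <- function(atlas, label_id, diameter = 1.173) {
  stopifnot(diameter > 0)
  vox <- structure_voxels(atlas, label_id)
  if (length(vox) == 0) stop("empty parcel ", label_id)
  d <- dim(atlas$labels)
  co <- arrayInd(vox, d)
  mm <- sweep(co, 2, atlas$voxel_size, "*")
  ctr <- colMeans(mm)
  # snap to the parcel if the center of mass lies outside it
  ctr_vox <- round(ctr / atlas$voxel_size)
  inside <- all(ctr_vox >= 1) && all(ctr_vox <= d) &&
    atlas$labels[matrix(ctr_vox, 1)] == label_id
  if (!inside) {
    nearest <- which.min(colSums((t(mm) - ctr)^2))
    ctr <- mm[nearest, ]
  }
  all_vox <- which(atlas$brain_mask)
  am <- sweep(arrayInd(all_vox, d), 2, atlas$voxel_size, "*")
  d2 <- colSums((t(am) - ctr)^2)
  sel <- all_vox[d2 <= (diameter / 2)^2]
  if (length(sel) == 0) {
    warning("seed sphere for structure ", label_id,
            " contains no voxel center; using nearest voxel")
    sel <- all_vox[which.min(d2)]
  }
  attr(sel, "center") <- ctr
  sel
}

#' Seed-based correlation volume
#'
#' Pearson correlation between the mean seed time course and every in-mask
#' voxel, with a per-volume BH-FDR significance mask from the standard
#' correlation t-test.
#'
#' @param series A preprocessed (low-pass filtered) `bold_series`.
#' @param seed_vox Voxel indices of the seed (from [seed_voxels()]).
#' @param brain_mask 3D logical mask; defaults to the series mask.
#' @param q FDR level.
#' @return List with `r` (3D array, NA outside mask), `fdr_mask` (3D
#'   logical), `n` (time points); NULL if the seed trace is constant (the
#'   seed is skipped with a warning).
#' @export
seed_correlation_volume <- function(series, seed_vox,
                                    brain_mask = series$brain_mask,
                                    q = 0.05) {
  seed_tc <- if (length(seed_vox) == 1) {
    as.numeric(series_matrix(series, seed_vox))
  } else rowMeans(series_matrix(series, seed_vox))
  if (stats::sd(seed_tc) == 0) {
    warning("constant seed trace; seed skipped")
    return(NULL)
  }
  vox <- which(brain_mask)
  X <- series_matrix(series, vox)
  r <- suppressWarnings(as.numeric(stats::cor(seed_tc, X)))
  r[!is.finite(r)] <- 0
  nt <- length(seed_tc)
  tstat <- r * sqrt((nt - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), nt - 2)
  d <- dim(series$data)[1:3]
  rvol <- array(NA_real_, dim = d)
  rvol[vox] <- r
  pvol <- array(NA_real_, dim = d)
  pvol[vox] <- p
  list(r = rvol, fdr_mask = fdr_correct(pvol, q, brain_mask), n = nt)
}

#' Multi-seed asymmetric connectivity matrix
#'
#' For every structure, a seed correlation volume is computed; after the
#' Fisher transform, the z-values of all voxels belonging to each target
#' structure are averaged, yielding one row per seed of an asymmetric
#' (directed) structure-by-structure connectivity matrix. By default all
#' structure voxels enter the average (the per-volume FDR mask is computed
#' and reported but not applied); `significant_only = TRUE` averages only
#' FDR-significant voxels (NA when a structure has none).
#'
#' @param series A preprocessed `bold_series`.
#' @param atlas A `synthetic_atlas`.
#' @param diameter Seed diameter, mm.
#' @param q FDR level for the per-volume masks.
#' @param significant_only Average only FDR-significant voxels?
#' @return N x N matrix (class `adjacency_matrix`) of mean Fisher-z values,
#'   rows = seeds, columns = target structures, NA diagonal; attribute
#'   `skipped_seeds` lists seeds with constant traces.
#' @export
multi_seed_matrix <- function(series, atlas, diameter = 1.173, q = 0.05,
                              significant_only = FALSE) {
  st <- atlas$structure_table
  n <- nrow(st)
  d <- dim(series$data)[1:3]
  lab_vec <- atlas$labels[which(series$brain_mask)]
  vox <- which(series$brain_mask)
  X <- series_matrix(series, vox)
  nt <- nrow(X)
  # seed mean traces
  seeds <- lapply(st$label_id, function(id) seed_voxels(atlas, id, diameter))
  seed_tc <- vapply(seeds, function(sv) {
    if (length(sv) == 1) as.numeric(series_matrix(series, sv))
    else rowMeans(series_matrix(series, sv))
  }, numeric(nt))
  sds <- apply(seed_tc, 2, stats::sd)
  skipped <- which(sds == 0)
  out <- matrix(NA_real_, n, n,
                dimnames = list(st$label_id, st$label_id))
  ok <- setdiff(seq_len(n), skipped)
  if (length(ok)) {
    R <- suppressWarnings(stats::cor(seed_tc[, ok, drop = FALSE], X))
    R[!is.finite(R)] <- 0
    Z <- fisher_z(R)                          # seeds x voxels
    if (significant_only) {
      tstat <- R * sqrt((nt - 2) / pmax(1 - R^2, 1e-12))
      P <- 2 * stats::pt(-abs(tstat), nt - 2)
      for (iRow in seq_along(ok)) {
        padj <- stats::p.adjust(P[iRow, ], method = "BH")
        Z[iRow, padj > q] <- NA_real_
      }
    }
    grp <- factor(lab_vec, levels = st$label_id)
    for (iRow in seq_along(ok)) {
      zz <- tapply(Z[iRow, ], grp, mean, na.rm = TRUE)
      out[ok[iRow], ] <- as.numeric(zz)
    }
  }
  diag(out) <- NA_real_
  out[!is.finite(out)] <- NA_real_
  attr(out, "skipped_seeds") <- skipped
  class(out) <- c("adjacency_matrix", class(out))
  out
}
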