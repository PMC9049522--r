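# Volume resampling and registration: rigid (motion correction) and
# 6-DOF affine (translation x-y-z, scaling x-y, rotation z) for
# cross-animal registration.

# Trilinear interpolation of `vol` at voxel coordinates `pts` (n x 3,
# 1-based, fractional). Outside the grid the volume is treated as 0.
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  at <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(i))
    out[ok] <- vol[cbind(i[ok], j[ok], k[ok])]
    out
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

# Grid of voxel coordinates for a volume, cached per call site.
voxel_grid <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

# 4x4 voxel-space matrix for a rigid transform (translations in voxels,
# rotations in radians, about the volume center).
rigid_matrix <- function(par, d) {
  cx <- (d + 1) / 2
  Rx <- rot3(1, par[4]); Ry <- rot3(2, par[5]); Rz <- rot3(3, par[6])
  R <- Rz %*% Ry %*% Rx
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- cx - R %*% cx + par[1:3]
  A
}

rot3 <- function(axis, th) {
  c2 <- cos(th); s2 <- sin(th)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c2; R[ij[2], ij[2]] <- c2
  R[ij[1], ij[2]] <- -s2; R[ij[2], ij[1]] <- s2
  R
}

# Resample `vol` through a 4x4 voxel-space transform mapping output
# coordinates to input coordinates.
resample_affine <- function(vol, A, grid = NULL) {
  d <- dim(vol)
  if (is.null(grid)) grid <- voxel_grid(d)
  pts <- grid %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4], nrow(grid), 3, byrow = TRUE)
  array(trilinear_sample(vol, pts), dim = d)
}

#' Rigid-body motion correction
#'
#' Aligns every volume to the first by a 6-parameter rigid transform
#' (3 translations, 3 rotations) estimated by minimizing the mean squared
#' difference, with trilinear resampling. A coarse integer-translation grid
#' search seeds a Nelder-Mead refinement. A volume whose optimization fails
#' keeps the identity transform and is flagged.
#'
#' @param series A `bold_series` with at least 2 volumes.
#' @param max_shift Half-width of the coarse translation search, voxels.
#' @return List with `series` (corrected) and `motion` (data.frame: volume,
#'   tx, ty, tz in voxels, rx, ry, rz in radians, flagged).
#' @export
rigid_motion_correct <- function(series, max_shift = 2) {
  nt <- n_volumes(series)
  if (nt < 2) stop("motion correction needs at least 2 volumes")
  d <- dim(series$data)[1:3]
  grid <- voxel_grid(d)
  ref <- series$data[, , , 1]
  trace <- data.frame(volume = seq_len(nt), tx = 0, ty = 0, tz = 0,
                      rx = 0, ry = 0, rz = 0, flagged = FALSE)
  cost <- function(par, vol) {
    mean((ref - resample_affine(vol, rigid_matrix(par, d), grid))^2)
  }
  for (i in 2:nt) {
    vol <- series$data[, , , i]
    # coarse in-plane translation search
    best <- c(0, 0, 0); bc <- cost(c(best, 0, 0, 0), vol)
    for (sx in -max_shift:max_shift) for (sy in -max_shift:max_shift) {
      cc <- cost(c(sx, sy, 0, 0, 0, 0), vol)
      if (cc < bc) { bc <- cc; best <- c(sx, sy, 0) }
    }
    fit <- try(stats::optim(c(best, 0, 0, 0), cost, vol = vol,
                            method = "Nelder-Mead",
                            control = list(maxit = 300, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      trace$flagged[i] <- TRUE
      next
    }
    par <- fit$par
    trace[i, 2:7] <- as.list(par)
    series$data[, , , i] <- resample_affine(vol, rigid_matrix(par, d), grid)
  }
  series <- log_step(series, "rigid_motion_correct")
  list(series = series, motion = trace)
}

#' Write a motion trace as TSV
#' @param motion Motion data.frame from [rigid_motion_correct()].
#' @param path Output path.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' 6-DOF affine transform (translation x-y-z, scaling x-y, rotation z)
#'
#' The transform used for cross-animal registration to a center-positioned
#' reference: in-plane rotation and scaling about the volume center plus a
#' 3D translation. Stored in voxel units / radians.
#'
#' @param tx,ty,tz Translations, voxels.
#' @param sx,sy In-plane scale factors (> 0).
#' @param rz In-plane rotation, radians.
#' @return An object of class `affine6`.
#' @export
affine6 <- function(tx = 0, ty = 0, tz = 0, sx = 1, sy = 1, rz = 0) {
  stopifnot(sx > 0, sy > 0)
  structure(list(tx = tx, ty = ty, tz = tz, sx = sx, sy = sy, rz = rz),
            class = "affine6")
}

# 4x4 voxel-space matrix mapping reference coords -> moving coords.
affine6_matrix <- function(tf, d) {
  cx <- (d + 1) / 2
  S <- diag(c(tf$sx, tf$sy, 1))
  R <- rot3(3, tf$rz)
  M <- R %*% S
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- cx - M %*% cx + c(tf$tx, tf$ty, tf$tz)
  A
}

#' Apply (or invert) a 6-DOF affine transform to a volume
#'
#' `inverse = FALSE` resamples the moving volume into the reference frame;
#' `inverse = TRUE` maps a reference-space volume (e.g. atlas labels) back
#' into subject space. `nearest = TRUE` uses nearest-neighbour sampling
#' (for label volumes).
#'
#' @param vol 3D array.
#' @param transform An `affine6`.
#' @param inverse Apply the inverse mapping?
#' @param nearest Nearest-neighbour instead of trilinear interpolation?
#' @export
apply_affine6 <- function(vol, transform, inverse = FALSE, nearest = FALSE) {
  d <- dim(vol)
  A <- affine6_matrix(transform, d)
  if (inverse) A <- solve(A)
  if (!nearest) return(resample_affine(vol, A))
  grid <- voxel_grid(d)
  pts <- round(grid %*% t(A[1:3, 1:3]) +
                 matrix(A[1:3, 4], nrow(grid), 3, byrow = TRUE))
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  out <- array(0, dim = d)
  out[ok] <- vol[pts[ok, , drop = FALSE]]
  out
}

#' Write / read a 6-DOF transform as JSON
#' @param transform An `affine6`.
#' @param path JSON path.
#' @export
write_affine6_json <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_affine6_json
#' @export
read_affine6_json <- function(path) {
  do.call(affine6, jsonlite::read_json(path))
}

#' Estimate a 6-DOF affine registration
#'
#' Finds the transform maximizing the grey-value correlation between the
#' resampled moving volume and the reference. Nelder-Mead from the
#' identity; on failure returns the identity with a warning.
#'
#' @param moving,reference 3D anatomical volumes on congruent grids.
#' @return An `affine6`.
#' @export
register_affine6 <- function(moving, reference) {
  d <- dim(moving)
  stopifnot(all(d == dim(reference)))
  grid <- voxel_grid(d)
  refv <- as.numeric(reference)
  cost <- function(p) {
    tf <- affine6(p[1], p[2], p[3], exp(p[4]), exp(p[5]), p[6])
    mov <- resample_affine(moving, affine6_matrix(tf, d), grid)
    r <- suppressWarnings(stats::cor(refv, as.numeric(mov)))
    if (!is.finite(r)) return(2)
    1 - r
  }
  fit <- try(stats::optim(c(0, 0, 0, 0, 0, 0), cost, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10,
                                         parscale = c(1, 1, 1, 0.1, 0.1, 0.1))),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$value > 1) {
    warning("affine registration did not converge; returning identity")
    return(affine6())
  }
  p <- fit$par
  affine6(p[1], p[2], p[3], exp(p[4]), exp(p[5]), p[6])
}
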