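#' Voxel-wise first-order GLM
#'
#' Ordinary least squares per in-mask voxel. Each voxel's time course is
#' first converted to % signal change about its temporal mean, so the
#' estimated coefficients are in %BOLD units (with peak-normalized
#' regressors, a coefficient is the peak %signal change of an isolated
#' response). Two-sided t statistics and p-values are returned for every
#' temperature predictor.
#'
#' @param series A preprocessed `bold_series`.
#' @param design A `glm_design`; `nrow(design$X)` must equal the number of
#'   volumes.
#' @param brain_mask Optional 3D logical mask; defaults to the series mask.
#' @return An object of class `sp_map`: list with 4D arrays `beta`, `tstat`,
#'   `p` (x, y, z, predictor), `predictor_names`, `brain_mask`, `df`.
#' @export
fit_glm <- function(series, design, brain_mask = NULL) {
  X <- design$X
  nt <- n_volumes(series)
  if (nrow(X) != nt)
    stop("design error: design has ", nrow(X), " rows but series has ",
         nt, " volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design error: collinear columns: ", paste(bad, collapse = ", "))
  }
  if (is.null(brain_mask)) brain_mask <- series$brain_mask
  vox <- which(brain_mask)
  Y <- series_matrix(series, vox)
  mu <- colMeans(Y)
  mu[mu == 0] <- 1
  Y <- 100 * sweep(Y, 2, mu, "/") - 100     # % signal change
  B <- qr.coef(qrX, Y)
  E <- Y - X %*% B
  df <- nt - ncol(X)
  sigma2 <- colSums(E^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  pred_idx <- match(design$predictor_names, colnames(X))
  d <- dim(series$data)[1:3]
  np <- length(pred_idx)
  beta <- tstat <- pval <- array(NA_real_, dim = c(d, max(np, 1)))
  for (k in seq_len(np)) {
    j <- pred_idx[k]
    se <- sqrt(sigma2 * XtXinv[j, j])
    tv <- B[j, ] / se
    tv[se == 0] <- sign(B[j, se == 0]) * 1e8   # perfect fit cap
    tv[se == 0 & B[j, ] == 0] <- 0
    bvol <- tvol <- pvol <- array(NA_real_, dim = d)
    bvol[vox] <- B[j, ]; tvol[vox] <- tv
    pvol[vox] <- 2 * stats::pt(-abs(tv), df)
    beta[, , , k] <- bvol; tstat[, , , k] <- tvol; pval[, , , k] <- pvol
  }
  structure(list(beta = beta, tstat = tstat, p = pval,
                 predictor_names = design$predictor_names,
                 brain_mask = brain_mask, df = df),
            class = "sp_map")
}

#' @export
print.sp_map <- function(x, ...) {
  cat(sprintf("SPM: %s grid, %d predictors (%s), df %d\n",
              paste(dim(x$beta)[1:3], collapse = "x"),
              length(x$predictor_names),
              paste(x$predictor_names, collapse = ", "), x$df))
  invisible(x)
}

#' Benjamini-Hochberg FDR voxel mask
#'
#' Applies the BH step-up procedure to the in-mask p-values at level `q`
#' and returns the binary mask of rejected voxels (confined to the brain
#' mask).
#'
#' @param p_volume 3D array of p-values.
#' @param q FDR level.
#' @param brain_mask 3D logical mask.
#' @return 3D logical array of significant voxels.
#' @export
fdr_correct <- function(p_volume, q = 0.05, brain_mask) {
  out <- array(FALSE, dim = dim(p_volume))
  vox <- which(brain_mask)
  if (length(vox) == 0) {
    warning("empty brain mask; returning empty FDR mask")
    return(out)
  }
  padj <- stats::p.adjust(p_volume[vox], method = "BH")
  out[vox] <- padj <= q
  out
}

#' FDR masks for every predictor of an SPM
#'
#' @param spmap An `sp_map`.
#' @param q FDR level.
#' @return 4D logical array (x, y, z, predictor).
#' @export
fdr_masks <- function(spmap, q = 0.05) {
  d <- dim(spmap$p)
  out <- array(FALSE, dim = d)
  for (k in seq_len(d[4]))
    out[, , , k] <- fdr_correct(spmap$p[, , , k], q, spmap$brain_mask)
  out
}

#' Persist an SPM as NIfTI volumes plus a JSON sidecar
#'
#' Writes one NIfTI per statistic per predictor
#' (`<prefix>_<stat>_<predictor>.nii.gz`) and a JSON sidecar with the
#' predictor names and FDR level.
#'
#' @param spmap An `sp_map`.
#' @param prefix Output path prefix.
#' @param q FDR level recorded in the sidecar.
#' @param voxel_size Voxel size for the NIfTI headers, mm.
#' @export
write_spmap <- function(spmap, prefix, q = 0.05,
                        voxel_size = c(0.391, 0.391, 1)) {
  for (k in seq_along(spmap$predictor_names)) {
    for (stat in c("beta", "tstat", "p")) {
      vol <- spmap[[stat]][, , , k]
      vol[is.na(vol)] <- 0
      img <- RNifti::asNifti(vol, reference = list(pixdim = c(1, voxel_size, 1, 0, 0, 0)))
      RNifti::writeNifti(img, sprintf("%s_%s_%s.nii.gz", prefix, stat,
                                      spmap$predictor_names[k]))
    }
  }
  jsonlite::write_json(list(predictors = spmap$predictor_names, q = q,
                            df = spmap$df),
                       paste0(prefix, "_spmap.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
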