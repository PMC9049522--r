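# Group inference: network-based statistic, paired max-T permutation test,
# voxel-wise permutation test, ANOVA + Tukey HSD, t-tests with BH-FDR.

# Vectorized two-sample homoscedastic t statistics, columns of A (nA x m)
# vs columns of B (nB x m). Returns the t vector; zero-pooled-variance
# columns yield NA.
two_sample_t <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums(sweep(A, 2, mA)^2)
  vB <- colSums(sweep(B, 2, mB)^2)
  sp2 <- (vA + vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0] <- NA_real_
  t
}

# Upper-triangle vectorization of a list of symmetric matrices.
stack_upper <- function(mats) {
  ut <- upper.tri(mats[[1]])
  do.call(rbind, lapply(mats, function(m) m[ut]))
}

#' Network-based statistic (unpaired)
#'
#' Edge-wise two-sample homoscedastic t-tests between the per-animal
#' adjacency matrices of two groups, thresholded at `alpha`; the size of
#' the biggest connected component of suprathreshold edges (size = number
#' of edges; `size = "nodes"` counts nodes instead) is compared against its
#' permutation distribution under random reassignment of animals to groups
#' (group sizes preserved). The family-wise p-value is the fraction of
#' permutations with a component at least as big as observed.
#'
#' @param groupA,groupB Lists of N x N symmetric matrices (>= 2 each,
#'   common node set).
#' @param alpha Edge-level threshold on the t-test p-value.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param size Component size measure: `"edges"` (extent) or `"nodes"`.
#' @param include_observed Use p = (b+1)/(m+1) instead of b/m.
#' @return An object of class `nbs_result`: list with `p_value`,
#'   `max_component_size`, `components` (list of edge data.frames with
#'   sign of the group difference), `edges` (all suprathreshold edges),
#'   `perm_sizes`, `excluded_edges`, `alpha`, `n_perm`, `seed`.
#' @export
nbs_unpaired <- function(groupA, groupB, alpha = 0.05, n_perm = 1000,
                         seed = 1, size = c("edges", "nodes"),
                         include_observed = FALSE) {
  size <- match.arg(size)
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  n <- nrow(groupA[[1]])
  ut_idx <- which(upper.tri(groupA[[1]]), arr.ind = TRUE)
  X <- rbind(stack_upper(groupA), stack_upper(groupB))
  nA <- length(groupA)
  ntot <- nrow(X)
  ok <- apply(X, 2, function(col) all(is.finite(col)) && stats::sd(col) > 0)
  excluded <- which(!ok)
  df <- ntot - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  comp_size <- function(labA) {
    t <- two_sample_t(X[labA, ok, drop = FALSE], X[!labA, ok, drop = FALSE])
    supra <- which(abs(t) >= tcrit)
    if (length(supra) == 0) return(list(size = 0, supra = integer(0), t = t))
    eidx <- which(ok)[supra]
    g <- igraph::graph_from_edgelist(
      cbind(ut_idx[eidx, 1], ut_idx[eidx, 2]), directed = FALSE)
    cmp <- igraph::components(g)
    sizes <- if (size == "nodes") cmp$csize else
      tabulate(cmp$membership[ut_idx[eidx, 1]], cmp$no)
    list(size = max(sizes), supra = eidx, t = t,
         membership = cmp$membership, node_ids = seq_len(igraph::vcount(g)))
  }
  labA <- c(rep(TRUE, nA), rep(FALSE, ntot - nA))
  obs <- comp_size(labA)
  rng <- local_rng(seed)
  perm_sizes <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm_sizes[i] <- comp_size(sample(labA))$size
  }
  b <- sum(perm_sizes >= obs$size)
  p <- if (include_observed) (b + 1) / (n_perm + 1) else b / n_perm
  if (obs$size == 0) p <- 1
  # components as edge sets with direction of difference
  comps <- list()
  if (length(obs$supra)) {
    tv <- obs$t[match(obs$supra, which(ok))]
    edf <- data.frame(from = ut_idx[obs$supra, 1], to = ut_idx[obs$supra, 2],
                      t = tv, direction = ifelse(tv > 0, "increased",
                                                 "decreased"))
    memb <- obs$membership[edf$from]
    comps <- split(edf, memb)
    comps <- comps[order(-vapply(comps, nrow, 1L))]
  }
  structure(list(p_value = p, max_component_size = obs$size,
                 components = comps,
                 edges = if (length(comps)) do.call(rbind, comps) else NULL,
                 perm_sizes = perm_sizes, excluded_edges = excluded,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 size_measure = size),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: max component %d %s, p = %.4g (%d permutations)\n",
              x$max_component_size, x$size_measure, x$p_value, x$n_perm))
  invisible(x)
}

#' Paired permutation matrix test (max-T FWE)
#'
#' Element-wise paired t statistics between matched pre/post matrices with
#' family-wise error control by the max-|t| permutation distribution under
#' random within-pair sign flips.
#'
#' @param pre,post Lists of N x N symmetric matrices in matched animal
#'   order (>= 2 pairs).
#' @param n_perm Number of sign-flip permutations.
#' @param seed RNG seed.
#' @param threshold FWE significance level.
#' @return An object of class `perm_test_result`: `tstat` and `fwe_p`
#'   (N x N symmetric matrices), `significant` (logical matrix at
#'   `threshold`), `direction` ("increased" where post > pre), `n_perm`,
#'   `excluded` (degenerate elements).
#' @export
paired_perm_matrix_test <- function(pre, post, n_perm = 1000, seed = 1,
                                    threshold = 0.05) {
  if (length(pre) != length(post)) stop("unmatched pre/post lengths")
  stopifnot(length(pre) >= 2)
  D <- stack_upper(post) - stack_upper(pre)   # pairs x edges
  np <- nrow(D)
  ok <- apply(D, 2, function(col) all(is.finite(col)))
  excluded <- which(!ok)
  Dk <- D[, ok, drop = FALSE]
  paired_t <- function(M) {
    m <- colMeans(M)
    s <- sqrt(colSums(sweep(M, 2, m)^2) / (np - 1))
    t <- m / (s / sqrt(np))
    t[s == 0 & m == 0] <- 0
    t[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
    t
  }
  t_obs <- paired_t(Dk)
  rng <- local_rng(seed)
  max_null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), np, replace = TRUE)
    max_null[i] <- max(abs(paired_t(Dk * flips)), na.rm = TRUE)
  }
  fwe <- vapply(abs(t_obs), function(tt) mean(max_null >= tt), numeric(1))
  n <- nrow(pre[[1]])
  ut <- upper.tri(pre[[1]])
  tmat <- pmat <- matrix(NA_real_, n, n, dimnames = dimnames(pre[[1]]))
  tfull <- pfull <- rep(NA_real_, sum(ut))
  tfull[ok] <- t_obs; pfull[ok] <- fwe
  tmat[ut] <- tfull; pmat[ut] <- pfull
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  structure(list(tstat = tmat, fwe_p = pmat,
                 significant = !is.na(pmat) & pmat <= threshold,
                 direction = ifelse(tmat > 0, "increased", "decreased"),
                 threshold = threshold, n_perm = n_perm, seed = seed,
                 excluded = excluded),
            class = "perm_test_result")
}

#' Voxel-wise two-sample permutation test (max-T FWE)
#'
#' Homoscedastic two-sample t-test per voxel between registered group maps
#' with family-wise error control by the max-|t| distribution under random
#' group reassignment; significant voxels are reported with the signed
#' group difference (%change of maximal BOLD response amplitude).
#'
#' @param mapsA,mapsB Lists of 3D arrays on a common grid.
#' @param mask 3D logical analysis mask.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param threshold FWE significance level.
#' @return An object of class `perm_test_result` with 3D `tstat`, `fwe_p`,
#'   `significant` and `difference` (mean A - mean B) volumes.
#' @export
voxelwise_perm_ttest <- function(mapsA, mapsB, mask, n_perm = 1000, seed = 1,
                                 threshold = 0.05) {
  vox <- which(mask)
  A <- do.call(rbind, lapply(mapsA, function(m) m[vox]))
  B <- do.call(rbind, lapply(mapsB, function(m) m[vox]))
  X <- rbind(A, B)
  nA <- nrow(A); ntot <- nrow(X)
  ok <- apply(X, 2, function(col) all(is.finite(col)) && stats::sd(col) > 0)
  Xk <- X[, ok, drop = FALSE]
  labA <- c(rep(TRUE, nA), rep(FALSE, ntot - nA))
  t_obs <- two_sample_t(Xk[labA, , drop = FALSE], Xk[!labA, , drop = FALSE])
  rng <- local_rng(seed)
  max_null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    lp <- sample(labA)
    max_null[i] <- max(abs(two_sample_t(Xk[lp, , drop = FALSE],
                                        Xk[!lp, , drop = FALSE])), na.rm = TRUE)
  }
  fwe <- vapply(abs(t_obs), function(tt) mean(max_null >= tt), numeric(1))
  d <- dim(mask)
  tvol <- pvol <- dvol <- array(NA_real_, dim = d)
  okv <- vox[ok]
  tvol[okv] <- t_obs
  pvol[okv] <- fwe
  dvol[okv] <- colMeans(Xk[labA, , drop = FALSE]) -
    colMeans(Xk[!labA, , drop = FALSE])
  sig <- array(FALSE, dim = d)
  sig[okv] <- fwe <= threshold
  structure(list(tstat = tvol, fwe_p = pvol, significant = sig,
                 difference = dvol, threshold = threshold, n_perm = n_perm,
                 seed = seed, excluded = vox[!ok]),
            class = "perm_test_result")
}

#' One-way ANOVA over stimulation temperatures with Tukey HSD post hoc
#'
#' Tests group-wise differences of a response metric across the eight
#' stimulation temperatures (one-factor ANOVA, temperature as factor),
#' followed by Tukey's honestly-significant-difference test for pairwise
#' comparisons. Temperatures with fewer than 2 observations are excluded
#' with a warning.
#'
#' @param values Numeric response values (e.g. response amplitudes).
#' @param temperature Temperature of each observation.
#' @return List with `F`, `p`, `df`, `tukey` (data.frame: comparison, diff,
#'   lwr, upr, p_adj), `excluded_levels`.
#' @export
anova_tukey <- function(values, temperature) {
  f <- factor(temperature)
  cnt <- table(f)
  drop_lv <- names(cnt)[cnt < 2]
  if (length(drop_lv)) {
    warning("excluding temperatures with < 2 observations: ",
            paste(drop_lv, collapse = ", "))
    keep <- !(as.character(f) %in% drop_lv)
    values <- values[keep]
    f <- droplevels(f[keep])
  }
  if (nlevels(f) < 2) stop("need at least 2 temperatures with >= 2 observations")
  fit <- stats::aov(values ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$f
  list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
       df = c(an[1, "Df"], an[2, "Df"]),
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       excluded_levels = drop_lv)
}

#' Group t-tests with Benjamini-Hochberg FDR
#'
#' Homoscedastic two-tailed Student's t-tests of a per-structure (or
#' per-temperature) metric between two groups, or paired t-tests within a
#' group, with BH-FDR correction at level `q` across all tests.
#'
#' @param metric data.frame with columns `value`, `unit` (structure /
#'   temperature label) and, for unpaired mode, `group`.
#' @param q FDR level.
#' @param paired For paired mode, `metric` must have columns `value_pre`
#'   and `value_post` instead of `value`/`group`.
#' @return data.frame: unit, t, p, p_adj, significant, n (per group or
#'   pairs).
#' @export
group_ttests_fdr <- function(metric, q = 0.05, paired = FALSE) {
  units <- unique(metric$unit)
  res <- lapply(units, function(u) {
    m <- metric[metric$unit == u, , drop = FALSE]
    if (paired) {
      d <- m$value_post - m$value_pre
      if (length(d) < 2 || all(d == d[1])) {
        tt <- list(statistic = if (all(d == 0)) 0 else NA, p.value = 1)
        if (length(d) >= 2 && all(d == d[1]) && d[1] != 0)
          tt$p.value <- 0  # exact uniform shift, degenerate variance
      } else tt <- stats::t.test(d)
      data.frame(unit = u, t = as.numeric(tt$statistic), p = tt$p.value,
                 n = length(d))
    } else {
      gs <- split(m$value, m$group)
      if (length(gs) != 2 || any(lengths(gs) < 2))
        stop("need exactly 2 groups with >= 2 observations for unit ", u)
      if (stats::sd(gs[[1]]) == 0 && stats::sd(gs[[2]]) == 0) {
        p <- if (mean(gs[[1]]) == mean(gs[[2]])) 1 else 0
        data.frame(unit = u, t = NA_real_, p = p, n = length(m$value))
      } else {
        tt <- stats::t.test(gs[[1]], gs[[2]], var.equal = TRUE)
        data.frame(unit = u, t = as.numeric(tt$statistic), p = tt$p.value,
                   n = length(m$value))
      }
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= q
  out
}
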