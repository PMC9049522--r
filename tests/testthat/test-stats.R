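test_that("an empty suprathreshold graph gives NBS p = 1", {
  A <- null_matrices(5, 8, seed = 1)
  B <- lapply(A, function(m) m + 0)  # identical groups, zero t everywhere
  res <- nbs_unpaired(A, B, alpha = 1e-12, n_perm = 50, seed = 2)
  expect_equal(res$max_component_size, 0)
  expect_equal(res$p_value, 1)
})

test_that("NBS p-values have permutation granularity and reproduce", {
  A <- null_matrices(6, 10, seed = 3)
  B <- null_matrices(6, 10, seed = 4)
  r1 <- nbs_unpaired(A, B, n_perm = 40, seed = 5)
  r2 <- nbs_unpaired(A, B, n_perm = 40, seed = 5)
  expect_identical(r1$perm_sizes, r2$perm_sizes)
  expect_equal(r1$p_value * 40, round(r1$p_value * 40))
})

test_that("NBS detects a planted connected difference at the study group sizes", {
  # a 10-edge connected path among nodes 1..11, effect 3x noise SD
  edges <- cbind(1:10, 2:11)
  hits <- 0; covered <- 0
  n_reps <- 25
  for (rep_i in seq_len(n_reps)) {
    A <- null_matrices(18, 20, seed = 100 + rep_i, shift_edges = edges,
                       shift = 3)
    B <- null_matrices(9, 20, seed = 200 + rep_i)
    res <- nbs_unpaired(A, B, n_perm = 200, seed = rep_i)
    if (res$p_value <= 0.05) hits <- hits + 1
    if (!is.null(res$edges)) {
      found <- paste(res$edges$from, res$edges$to)
      planted <- paste(edges[, 1], edges[, 2])
      if (sum(planted %in% found) >= 8) covered <- covered + 1
    }
  }
  expect_gte(hits / n_reps, 0.9)
  expect_gte(covered / n_reps, 0.9)
})

test_that("zero-variance edges are excluded, not silently dropped", {
  A <- null_matrices(4, 6, seed = 6)
  B <- null_matrices(4, 6, seed = 7)
  for (i in seq_along(A)) A[[i]][1, 2] <- A[[i]][2, 1] <- 0.5
  for (i in seq_along(B)) B[[i]][1, 2] <- B[[i]][2, 1] <- 0.5
  res <- nbs_unpaired(A, B, n_perm = 20, seed = 8)
  expect_true(1 %in% res$excluded_edges)
})

test_that("the paired max-T test finds planted shifts and nothing else", {
  pre <- null_matrices(9, 10, seed = 9)
  post0 <- lapply(pre, function(m) m)  # post = pre exactly
  res0 <- paired_perm_matrix_test(pre, post0, n_perm = 100, seed = 10)
  expect_false(any(res0$significant, na.rm = TRUE))
  # planted uniform shift on 5 edges, 5x the pairwise noise SD
  edges <- cbind(1:5, 6:10)
  found <- 0
  n_reps <- 20
  for (rep_i in seq_len(n_reps)) {
    pre <- null_matrices(9, 10, seed = 300 + rep_i)
    post <- lapply(pre, function(m) {
      d <- matrix(rnorm(100), 10, 10); d <- (d + t(d)) / 2
      m2 <- m + 0.3 * d
      for (e in 1:5) {
        m2[edges[e, 1], edges[e, 2]] <- m2[edges[e, 1], edges[e, 2]] +
          5 * 0.3
        m2[edges[e, 2], edges[e, 1]] <- m2[edges[e, 1], edges[e, 2]]
      }
      diag(m2) <- NA
      m2
    })
    res <- paired_perm_matrix_test(pre, post, n_perm = 200, seed = rep_i)
    sig <- which(res$significant, arr.ind = TRUE)
    sig <- sig[sig[, 1] < sig[, 2], , drop = FALSE]
    planted_found <- sum(paste(edges[, 1], edges[, 2]) %in%
                           paste(sig[, 1], sig[, 2]))
    if (planted_found == 5) found <- found + 1
    expect_true(all(res$direction[edges] == "increased"))
  }
  expect_gte(found / n_reps, 0.9)
  expect_error(paired_perm_matrix_test(pre, post0[1:3], n_perm = 10,
                                       seed = 1), "unmatched")
})

test_that("voxel-wise permutation maps localize a planted parcel effect", {
  a <- tiny_atlas(shape = c(12, 12, 3), n = 5)
  d <- dim(a$labels)
  mk <- function(seed, effect = 0) {
    set.seed(seed)
    v <- array(rnorm(prod(d)), dim = d)
    if (effect > 0) v[a$labels == 2] <- v[a$labels == 2] + effect
    v
  }
  A <- lapply(1:10, function(i) mk(i, effect = 3))
  B <- lapply(11:18, function(i) mk(i))
  res <- voxelwise_perm_ttest(A, B, a$brain_mask, n_perm = 200, seed = 1)
  sig <- which(res$significant)
  expect_gt(length(sig), 0)
  expect_gte(mean(a$labels[sig] == 2), 0.8)
  expect_true(all(res$difference[sig] > 0))
  # identical groups: nothing significant
  res0 <- voxelwise_perm_ttest(A, A, a$brain_mask, n_perm = 100, seed = 2)
  expect_false(any(res0$significant))
})

test_that("ANOVA with Tukey HSD separates means the way the closed form does", {
  set.seed(13)
  vals <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  temp <- rep(c(40, 42, 44), each = 10)
  res <- anova_tukey(vals, temp)
  expect_lt(res$p, 1e-6)
  p13 <- res$tukey$p_adj[res$tukey$comparison == "44-40"]
  p23 <- res$tukey$p_adj[res$tukey$comparison == "44-42"]
  p12 <- res$tukey$p_adj[res$tukey$comparison == "42-40"]
  expect_lt(p13, 0.001); expect_lt(p23, 0.001); expect_gt(p12, 0.05)
  # two identical groups: adjusted p ~ 1
  v2 <- rep(c(1, 2, 3), 2)
  res2 <- anova_tukey(c(v2, v2), rep(c(50, 52), each = 6))
  expect_gt(res2$tukey$p_adj[1], 0.99)
  # under-filled levels are excluded with a warning
  expect_warning(res3 <- anova_tukey(c(vals, 1), c(temp, 46)), "excluding")
  expect_equal(res3$excluded_levels, "46")
})

test_that("Tukey decisions match the studentized-range oracle on random draws", {
  set.seed(14)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    n_per <- sample(4:8, 1)
    vals <- rnorm(k * n_per) + rep(runif(k, 0, 2), each = n_per)
    grp <- rep(seq(40, by = 2, length.out = k), each = n_per)
    res <- anova_tukey(vals, grp)
    orc <- tukey_oracle(vals, grp)
    got <- setNames(res$tukey$p_adj, res$tukey$comparison)
    expect_equal(sort(names(got)), sort(names(orc)))
    expect_equal(got[names(orc)] < 0.05, orc < 0.05)
    expect_equal(unname(got[names(orc)]), unname(orc), tolerance = 1e-6)
  }
})

test_that("group t-tests with BH-FDR behave on null, shifted and paired data", {
  set.seed(15)
  # identical samples: no rejections
  df0 <- data.frame(value = rep(rnorm(10), 2),
                    group = rep(c("a", "b"), each = 10),
                    unit = rep(1:5, 4))
  expect_false(any(group_ttests_fdr(df0)$significant))
  # paired uniform shift: p below 0.01 (degenerate-variance shortcut)
  dfp <- data.frame(value_pre = rnorm(9), unit = 1)
  dfp$value_post <- dfp$value_pre + 2
  resp <- group_ttests_fdr(dfp, paired = TRUE)
  expect_lt(resp$p, 0.01)
  # 100 null + 10 shifted units: FDR among rejections controlled
  n_reps <- 40
  fdrs <- numeric(0)
  for (rep_i in seq_len(n_reps)) {
    set.seed(1000 + rep_i)
    mk_unit <- function(u, shift) data.frame(
      value = c(rnorm(6), rnorm(6) + shift),
      group = rep(c("a", "b"), each = 6), unit = u)
    df <- do.call(rbind, c(lapply(1:100, mk_unit, shift = 0),
                           lapply(101:110, mk_unit, shift = 4)))
    res <- group_ttests_fdr(df, q = 0.05)
    rej <- res$unit[res$significant]
    if (length(rej)) fdrs <- c(fdrs, mean(rej <= 100))
  }
  expect_lte(mean(fdrs), 0.10)
})
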