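# Independent brute-force oracles used to cross-check the pipeline's
# statistics, plus small fixture builders.

# Benjamini-Hochberg step-up by exhaustive threshold scan: reject all
# p <= p_(k*) where k* is the largest k with p_(k) <= k/m * q.
bh_oracle <- function(p, q) {
  m <- length(p)
  sp <- sort(p)
  ks <- which(sp <= seq_len(m) / m * q)
  if (length(ks) == 0) return(rep(FALSE, m))
  p <- p
  p <= sp[max(ks)]
}

# Mean local clustering coefficient by explicit neighbour-pair counting
# on a binary adjacency matrix; degree < 2 nodes contribute 0.
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] > 0) links <- links + 1
    }
    vals[v] <- links / (k * (k - 1) / 2)
  }
  mean(vals)
}

# Characteristic path length by Floyd-Warshall; mean over connected
# ordered pairs (infinite distances excluded).
pathlen_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# Tukey HSD pairwise adjusted p-values from first principles: studentized
# range statistic per pair against ptukey.
tukey_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum((values - mi[groups])^2) / df
  out <- list()
  lv <- levels(groups)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
    q <- abs(mi[a] - mi[b]) / se
    out[[paste(lv[b], lv[a], sep = "-")]] <- as.numeric(1 - ptukey(q, k, df))
  }
  unlist(out)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  sij <- sc(tab)
  si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Small fixtures -------------------------------------------------------

tiny_atlas <- function(shape = c(14, 14, 4), n = 8, seed = 42) {
  build_synthetic_atlas(shape, n, seed = seed)
}

# Effect model with every stochastic nuisance switched off.
quiet_model <- function(group = "baseline", n = 8, ...) {
  effect_model(group, n, noise_sigma = 0, drift_amplitude = 0,
               global_signal_sigma = 0, ar1_coefficient = 0, ...)
}

# Hand-built protocol holding only the stated temperatures.
single_temp_protocol <- function(temps = 54, onsets = 120, duration = 20,
                                 tr = 2) {
  structure(list(
    events = data.frame(onset_s = onsets, ramp_s = 5, plateau_s = 15,
                        duration_s = duration,
                        temperature_C = rep(temps, length.out = length(onsets)),
                        set_index = 1L),
    lead_in = onsets[1], inter_stimulus_rest = 220, tr = tr,
    temperatures = sort(unique(temps)),
    duration_s = max(onsets) + duration + 220, seed = NA_integer_),
    class = "stim_protocol")
}

# Random symmetric matrix with positive and negative entries.
random_sym_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- NA
  m
}

# Symmetric null matrices with optional planted edge shifts.
null_matrices <- function(n_animals, n_nodes, seed, shift_edges = NULL,
                          shift = 0) {
  set.seed(seed)
  lapply(seq_len(n_animals), function(i) {
    m <- matrix(rnorm(n_nodes * n_nodes), n_nodes, n_nodes)
    m <- (m + t(m)) / 2
    if (!is.null(shift_edges)) {
      for (e in seq_len(nrow(shift_edges))) {
        a <- shift_edges[e, 1]; b <- shift_edges[e, 2]
        m[a, b] <- m[a, b] + shift
        m[b, a] <- m[a, b]
      }
    }
    diag(m) <- NA
    m
  })
}
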