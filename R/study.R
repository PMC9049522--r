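#' Phantom study configuration
#'
#' Bundles every parameter of the baseline-vs-RTX phantom study. Two scale
#' presets are provided: `"desk"` (32x32x8 grid, 40 structures, 1
#' stimulation set, 1020 stimulus volumes, 300 resting-state volumes) for
#' routine runs, and `"full"` (64x64x22, 202 structures, 3 sets, 3000
#' stimulus volumes) matching the full acquisition geometry. Group sizes
#' default to 18 baseline vs 9 RTX animals.
#'
#' @param scale `"desk"` or `"full"`.
#' @param n_baseline,n_rtx Animals per group.
#' @param k Mean degree for k-standardization.
#' @param q FDR level.
#' @param alpha NBS edge threshold.
#' @param n_perm Permutations for NBS / max-T tests.
#' @param n_random_sw Random reference graphs per small-world evaluation.
#' @param seed Master seed; all per-animal seeds derive from it.
#' @param rs_planted Planted resting-state correlation structure (see
#'   [effect_model()]).
#' @param ... Overrides for `shape`, `n_structures`, `n_sets`,
#'   `n_volumes`, `rs_volumes`, `tr`, `hrf`, `baseline_model_args`,
#'   `rtx_model_args`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(scale = c("desk", "full"), n_baseline = 18,
                         n_rtx = 9, k = 10, q = 0.05, alpha = 0.05,
                         n_perm = 1000, n_random_sw = 20, seed = 1,
                         rs_planted = "functional_blocks", ...) {
  scale <- match.arg(scale)
  base <- if (scale == "desk") {
    list(shape = c(32, 32, 8), n_structures = 40, n_sets = 1,
         n_volumes = 1020, rs_volumes = 300, tr = 2)
  } else {
    list(shape = c(64, 64, 22), n_structures = 202, n_sets = 3,
         n_volumes = 3000, rs_volumes = 300, tr = 2)
  }
  over <- list(...)
  base[names(over)] <- over
  structure(c(list(scale = scale, n_baseline = n_baseline, n_rtx = n_rtx,
                   k = k, q = q, alpha = alpha, n_perm = n_perm,
                   n_random_sw = n_random_sw, seed = seed,
                   rs_planted = rs_planted,
                   hrf = base$hrf %||% hrf_params()),
              base[setdiff(names(base), "hrf")]),
            class = "study_config")
}

#' Read a study configuration from YAML
#' @param path YAML file of `study_config` arguments.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Run one animal through the stimulus-driven chain
#'
#' Simulation, preprocessing, GLM, FDR masks, structure time courses and
#' per-temperature adjacency matrices (global regression + Fisher-z) for a
#' single phantom animal.
#'
#' @param atlas,protocol,model,cfg Study ingredients.
#' @param animal_seed Per-animal seed.
#' @param keep_series Return the preprocessed series as well?
#' @return List with `stc` (structure time courses), `adjacency` (list per
#'   temperature), `max_amp` (4D max-amplitude maps), `whole_brain`,
#'   `spmap_summary`.
#' @export
run_animal_stimulus <- function(atlas, protocol, model, cfg, animal_seed,
                                keep_series = FALSE) {
  ser <- simulate_session(atlas, protocol, model, cfg$hrf, tr = cfg$tr,
                          n_volumes = cfg$n_volumes, seed = animal_seed)
  pp <- preprocess_config()
  ser <- preprocess_stimulus(ser, pp)
  des <- build_design(protocol, cfg$hrf, n_volumes(ser), ser$tr,
                      t0 = ser$time_offset,
                      highpass_cycles = pp$highpass_cycles)
  spm <- fit_glm(ser, des)
  masks <- fdr_masks(spm, cfg$q)
  stc <- structure_timecourses(ser, atlas, protocol, masks)
  adj <- lapply(seq_along(stc$temperatures), function(ti) {
    tr <- stc$traces[, , ti]
    ok <- stats::complete.cases(tr)
    res <- global_regression(tr[ok, , drop = FALSE])
    A <- matrix(NA_real_, nrow(tr), nrow(tr),
                dimnames = list(rownames(tr), rownames(tr)))
    A[ok, ok] <- build_adjacency(res)
    class(A) <- c("adjacency_matrix", class(A))
    A
  })
  names(adj) <- paste0("T", stc$temperatures)
  mam <- max_amplitude_map(ser, protocol)
  out <- list(stc = stc, adjacency = adj, max_amp = mam,
              whole_brain = stc$whole_brain,
              spmap_summary = list(df = spm$df,
                                   predictors = spm$predictor_names))
  if (keep_series) out$series <- ser
  out
}

#' Run the full baseline-vs-RTX phantom study
#'
#' End-to-end orchestration: generates the shared stimulation protocol and
#' atlas, simulates every animal of both groups, runs the stimulus-driven
#' chain (preprocessing, GLM, FDR, ROI metrics, networks), the
#' resting-state chain (multi-seed matrices for RS_pre and RS_post), and
#' the group statistics (amplitude t-tests with BH-FDR, ANOVA + Tukey,
#' per-temperature NBS, small-world comparison, paired RS_pre/RS_post
#' max-T test). All stages are batch-processed with no per-animal input;
#' every seed derives from `cfg$seed`.
#'
#' @param cfg A `study_config`.
#' @param out_dir Optional directory: tidy TSV tables and a manifest JSON
#'   are written there.
#' @param resting_state Run the resting-state arm too?
#' @param verbose Print stage progress?
#' @return An object of class `phantom_study` (see elements in source).
#' @export
run_phantom_study <- function(cfg = study_config(), out_dir = NULL,
                              resting_state = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  protocol <- build_stimulus_protocol(cfg$n_sets, seed = sub_seed(cfg$seed, 2L),
                                      tr = cfg$tr)
  atlas <- build_synthetic_atlas(cfg$shape, cfg$n_structures,
                                 seed = sub_seed(cfg$seed, 3L))
  models <- list(
    baseline = do.call(effect_model, c(list(
      group = "baseline", n_structures = cfg$n_structures,
      rs_planted = cfg$rs_planted, seed = sub_seed(cfg$seed, 4L)),
      cfg$baseline_model_args %||% list())),
    rtx = do.call(effect_model, c(list(
      group = "rtx", n_structures = cfg$n_structures,
      rs_planted = cfg$rs_planted, seed = sub_seed(cfg$seed, 4L)),
      cfg$rtx_model_args %||% list())))
  groups <- rep(c("baseline", "rtx"), c(cfg$n_baseline, cfg$n_rtx))
  animals <- seq_along(groups)
  temps <- protocol$temperatures
  roi_tab <- list(); adj_all <- list(); wb_tab <- list(); sw_tab <- list()
  max_amps <- list()
  for (i in animals) {
    say("animal %d/%d (%s): stimulus chain", i, length(animals), groups[i])
    res <- run_animal_stimulus(atlas, protocol, models[[groups[i]]], cfg,
                               animal_seed = sub_seed(cfg$seed, 100L + i))
    roi_tab[[i]] <- roi_table(res$stc, animal = i, group = groups[i])
    wb_tab[[i]] <- cbind(animal = i, group = groups[i], res$whole_brain)
    adj_all[[i]] <- res$adjacency
    max_amps[[i]] <- res$max_amp
    for (ti in seq_along(temps)) {
      net <- k_standardize(res$adjacency[[ti]], k = cfg$k)
      sw <- small_world(net, n_random = cfg$n_random_sw,
                        seed = sub_seed(cfg$seed, 500L + i * 8L + ti))
      sw_tab[[length(sw_tab) + 1]] <- data.frame(
        animal = i, group = groups[i], temperature = temps[ti],
        gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
        n_edges = n_edges(net))
    }
  }
  roi_tab <- do.call(rbind, roi_tab)
  wb_tab <- do.call(rbind, wb_tab)
  sw_tab <- do.call(rbind, sw_tab)
  # group-mean networks, communities, condensed networks
  say("group networks and communities")
  centers <- structure_centers(atlas)
  group_nets <- list(); communities <- list(); condensed <- list()
  for (g in c("baseline", "rtx")) {
    for (ti in seq_along(temps)) {
      key <- paste0(g, "_T", temps[ti])
      mats <- lapply(which(groups == g), function(i) adj_all[[i]][[ti]])
      gm <- adjacency_group_mean(mats)
      net <- k_standardize(gm, k = cfg$k,
                           node_info = atlas$structure_table)
      cm <- blondel_communities(net, seed = sub_seed(cfg$seed, 900L + ti))
      group_nets[[key]] <- net
      communities[[key]] <- cm
      condensed[[key]] <- aggregate_functional_groups(
        net, atlas$structure_table, respect_communities = TRUE,
        communities = cm, positions = centers)
    }
  }
  # NBS per temperature
  say("network-based statistics")
  nbs <- lapply(seq_along(temps), function(ti) {
    A <- lapply(which(groups == "baseline"), function(i) adj_all[[i]][[ti]])
    B <- lapply(which(groups == "rtx"), function(i) adj_all[[i]][[ti]])
    nbs_unpaired(A, B, alpha = cfg$alpha, n_perm = cfg$n_perm,
                 seed = sub_seed(cfg$seed, 700L + ti))
  })
  names(nbs) <- paste0("T", temps)
  # amplitude statistics
  say("amplitude statistics")
  amp <- stats::aggregate(amplitude ~ animal + group + temperature,
                          roi_tab[roi_tab$trace_defined, ], mean)
  anova_res <- lapply(split(amp, amp$group), function(d)
    anova_tukey(d$amplitude, d$temperature))
  amp_tests <- group_ttests_fdr(
    data.frame(value = amp$amplitude, group = amp$group,
               unit = amp$temperature), q = cfg$q)
  sw_tests <- lapply(c("gamma", "lambda", "sigma"), function(mm)
    group_ttests_fdr(data.frame(value = sw_tab[[mm]], group = sw_tab$group,
                                unit = sw_tab$temperature), q = cfg$q))
  names(sw_tests) <- c("gamma", "lambda", "sigma")
  # voxel-wise max-amplitude comparison at the top temperature
  ti_top <- length(temps)
  vox_test <- voxelwise_perm_ttest(
    lapply(which(groups == "baseline"), function(i) max_amps[[i]][, , , ti_top]),
    lapply(which(groups == "rtx"), function(i) max_amps[[i]][, , , ti_top]),
    mask = atlas$brain_mask, n_perm = cfg$n_perm,
    seed = sub_seed(cfg$seed, 800L))
  # resting state
  rs <- NULL
  if (resting_state) {
    say("resting-state chain")
    rs_mats <- list(pre = list(), post = list())
    for (i in animals) {
      for (sess in c("pre", "post")) {
        ser <- simulate_resting_state(
          atlas, models[[groups[i]]], tr = cfg$tr,
          n_volumes = cfg$rs_volumes,
          seed = sub_seed(cfg$seed, (if (sess == "pre") 2000L else 3000L) + i))
        ser <- preprocess_resting(ser)
        rs_mats[[sess]][[i]] <- multi_seed_matrix(ser, atlas, q = cfg$q)
      }
    }
    rs_nets <- lapply(rs_mats$pre, k_standardize, k = cfg$k, mode = "directed")
    rs_nbs_pre <- nbs_unpaired(
      lapply(which(groups == "baseline"), function(i) sym_part(rs_mats$pre[[i]])),
      lapply(which(groups == "rtx"), function(i) sym_part(rs_mats$pre[[i]])),
      alpha = cfg$alpha, n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, 4000L))
    rs_paired <- lapply(c("baseline", "rtx"), function(g) {
      idx <- which(groups == g)
      paired_perm_matrix_test(
        lapply(idx, function(i) sym_part(rs_mats$pre[[i]])),
        lapply(idx, function(i) sym_part(rs_mats$post[[i]])),
        n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, 5000L))
    })
    names(rs_paired) <- c("baseline", "rtx")
    rs <- list(matrices = rs_mats, networks_pre = rs_nets,
               nbs_pre = rs_nbs_pre, paired = rs_paired)
  }
  out <- structure(list(
    config = cfg, protocol = protocol, atlas = atlas, models = models,
    groups = groups, roi = roi_tab, whole_brain = wb_tab,
    amplitudes = amp, small_world = sw_tab, group_networks = group_nets,
    communities = communities, condensed = condensed, nbs = nbs,
    anova = anova_res, amplitude_tests = amp_tests, sw_tests = sw_tests,
    voxel_test = vox_test, resting = rs,
    adjacency = adj_all
  ), class = "phantom_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Symmetrized view of a directed connectivity matrix (mean of z(i,j),
# z(j,i)) for statistics that expect symmetric matrices.
sym_part <- function(m) {
  s <- (m + t(m)) / 2
  class(s) <- c("adjacency_matrix", "matrix", "array")
  s
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("Phantom study (%s scale): %d baseline vs %d RTX animals\n",
              x$config$scale, x$config$n_baseline, x$config$n_rtx))
  ps <- vapply(x$nbs, function(n) n$p_value, numeric(1))
  cat("NBS p-values by temperature:\n")
  print(round(ps, 3))
  invisible(x)
}

#' Persist the study's tidy tables and manifest
#'
#' Writes the ROI table, whole-brain activated volume, amplitudes,
#' small-world metrics, test results, per-condition edge lists and a
#' manifest JSON (stage parameters + seeds) under `dir`.
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(study$roi, "roi_metrics.tsv")
  wt(study$whole_brain, "whole_brain_volume.tsv")
  wt(study$amplitudes, "amplitudes.tsv")
  wt(study$small_world, "small_world.tsv")
  wt(study$amplitude_tests, "amplitude_group_tests.tsv")
  for (key in names(study$group_networks))
    write_network_tsv(study$group_networks[[key]],
                      file.path(dir, paste0("network_", key, ".tsv")))
  nbs_df <- data.frame(
    temperature = sub("^T", "", names(study$nbs)),
    p_value = vapply(study$nbs, function(n) n$p_value, numeric(1)),
    max_component_size = vapply(study$nbs, function(n)
      n$max_component_size, numeric(1)))
  wt(nbs_df, "nbs_by_temperature.tsv")
  manifest <- list(
    config = unclass(study$config),
    stages = c("simulate", "preprocess", "glm", "roi", "network",
               "small_world", "communities", "nbs", "resting_state",
               "group_stats"),
    outputs = list.files(dir),
    protocol_seed = study$protocol$seed,
    atlas_seed = study$atlas$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
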