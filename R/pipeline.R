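#' Study configuration for the full workflow
#'
#' Assembles (with defaults) the configuration consumed by
#' [run_study_pipeline()]. Defaults mirror a 32-channel, 250 Hz resting
#' acquisition with 205 scans at TR 2 s; the synthetic cohort plants
#' per-subject frontal asymmetries and behavioral scores with a known
#' correlation so recovery can be verified end to end.
#'
#' @param n_subjects cohort size (>= 3).
#' @param n_channels,sfreq,duration_s EEG geometry; `duration_s = NULL`
#'   covers exactly `n_scans * tr_s` seconds.
#' @param k_true planted prototype count for synthesis.
#' @param noise_sd EEG sensor noise SD (microvolts).
#' @param asym_sd between-subject SD of the planted log-ratios.
#' @param score_rho planted correlation between the planted F4/F3 log-ratio
#'   and the negative-affect score.
#' @param k microstate count: an integer for a fixed K, or `"cv"` to select
#'   K by minimum CV over `k_range` after initializing at its maximum.
#' @param prototype_level `"subject"` fits prototypes per subject before
#'   back-fitting (matched to a cohort whose topographies differ by
#'   subject, as the synthetic cohort's do); `"group"` fits one prototype
#'   set on the concatenated peak maps and back-fits it to every subject
#'   (the two-level scheme used for a real cohort with shared microstate
#'   classes).
#' @param k_range candidate K values when `k = "cv"`.
#' @param n_restarts,max_iter,tol modified K-means settings.
#' @param min_peak_distance_ms,gfp_threshold_sd GFP peak selection.
#' @param band alpha band edges, Hz.
#' @param tr_s,n_scans fMRI acquisition grid.
#' @param n_voxels_per_region synthetic BOLD region size.
#' @param bold_noise_sd,bold_ar1 synthetic BOLD noise settings.
#' @param amp_right,amp_left planted HRF response heights.
#' @param run_neurovascular run the BOLD/GLM/HLI stages.
#' @param cor_methods robust-correlation methods for the score battery.
#' @param cor_pairs channel pairs entering the correlation battery.
#' @param cor_scores score columns entering the battery; the Bonferroni
#'   family size is `length(cor_pairs) * length(cor_scores)`.
#' @param n_boot bootstrap resamples for CIs.
#' @param seed master seed; every stage derives its own from it.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return a `study_config` list.
#' @export
study_config <- function(n_subjects = 20, n_channels = 32, sfreq = 250,
                         duration_s = NULL, k_true = 4, noise_sd = 1,
                         asym_sd = 0.3, score_rho = 0.5,
                         k = 4, prototype_level = c("subject", "group"),
                         k_range = 2:8, n_restarts = 5,
                         max_iter = 1000, tol = 1e-6,
                         min_peak_distance_ms = 20, gfp_threshold_sd = 1.0,
                         band = c(8, 12), tr_s = 2, n_scans = 205,
                         n_voxels_per_region = 10, bold_noise_sd = 0.1,
                         bold_ar1 = 0.3, amp_right = 2, amp_left = 1,
                         run_neurovascular = TRUE,
                         cor_methods = c("pearson", "spearman", "bend20"),
                         cor_pairs = c("FA", "FTA"),
                         cor_scores = c(
                           "negative_affect", "positive_affect",
                           "bis", "bas"
                         ),
                         n_boot = 599, seed = 1, output_dir = NULL) {
  prototype_level <- match.arg(prototype_level)
  if (is.null(duration_s)) duration_s <- n_scans * tr_s
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Load a study configuration from YAML
#'
#' Reads a YAML mapping of [study_config()] argument names and builds the
#' configuration (unknown keys are an error; omitted keys take defaults).
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, vals)
}

#' Run the full microstate-asymmetry workflow on a synthetic cohort
#'
#' Executes the complete chain: synthesize per-subject EEG with planted
#' frontal asymmetries and scores; GFP and peak selection; group
#' concatenation; modified K-means (fixed K or CV selection); per-subject
#' back-fitting and re-expression; alpha power and both asymmetry indices
#' (microstate branch on the re-expressed average-referenced data, standard
#' branch on CSD-referenced data) for both channel pairs; TR-locked
#' asymmetry regressors; per-subject synthetic BOLD, parametric-modulation
#' GLM and amplitude summaries; robust group statistics with FDR + cluster
#' thresholding; blind HRF deconvolution and per-subject HLI; and the
#' robust-correlation battery of asymmetries (and HLI) against the scores
#' with Bonferroni adjustment over pairs x scores.
#'
#' @param config a `study_config` from [study_config()] /
#'   [read_study_config()].
#' @param verbose emit stage messages.
#' @return a `study_result_bundle`: `asymmetries` (per subject x pair x
#'   method), `prototypes`, `cv_by_k` (when CV selection ran), `scores`,
#'   `correlations` (tidy table), `hli` (per subject), `group_stats`,
#'   `truth` (planted quantities), `manifest`.
#' @export
run_study_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (config$n_subjects < 3) stop("need at least 3 subjects")
  seed0 <- config$seed
  ns <- config$n_subjects

  # --- planted subject-level truth -----------------------------------------
  planted <- with_seed(derive_seed(seed0, 1), {
    data.frame(
      subject_id = sprintf("sub-%02d", seq_len(ns)),
      ratio_F4F3 = stats::rnorm(ns, 0, config$asym_sd),
      ratio_F8F7 = stats::rnorm(ns, 0, config$asym_sd)
    )
  })
  scores <- data.frame(
    subject_id = planted$subject_id,
    negative_affect = generate_behavioral_scores(
      planted$ratio_F4F3, config$score_rho,
      seed = derive_seed(seed0, 2)
    ),
    positive_affect = generate_behavioral_scores(
      planted$ratio_F4F3, 0,
      seed = derive_seed(seed0, 3)
    ),
    bis = generate_behavioral_scores(
      planted$ratio_F8F7, 0,
      seed = derive_seed(seed0, 4)
    ),
    bas = generate_behavioral_scores(
      planted$ratio_F8F7, 0,
      seed = derive_seed(seed0, 5)
    )
  )

  # --- EEG synthesis and peak maps -----------------------------------------
  msg_stage(verbose, "eeg", "synthesizing ", ns, " subjects")
  recordings <- vector("list", ns)
  gfps <- vector("list", ns)
  for (i in seq_len(ns)) {
    g <- generate_microstate_eeg(
      n_channels = config$n_channels, sfreq = config$sfreq,
      duration_s = config$duration_s, k_true = config$k_true,
      noise_sd = config$noise_sd,
      planted_log_ratios = c(
        F4F3 = planted$ratio_F4F3[i],
        F8F7 = planted$ratio_F8F7[i]
      ),
      seed = derive_seed(seed0, 10 + i)
    )
    recordings[[i]] <- g$recording
    gfps[[i]] <- select_gfp_peaks(
      compute_gfp(g$recording),
      min_peak_distance_ms = config$min_peak_distance_ms,
      threshold_sd = config$gfp_threshold_sd
    )
  }
  chi <- concatenate_peak_maps(recordings, lapply(gfps, `[[`, "peak_indices"))

  # --- group prototypes -----------------------------------------------------
  msg_stage(verbose, "microstates", "clustering ", nrow(chi), " peak maps")
  cv_by_k <- NULL
  if (identical(config$k, "cv")) {
    sel <- select_active_k(chi,
      k_range = config$k_range,
      max_iter = config$max_iter, tol = config$tol,
      n_restarts = config$n_restarts, seed = derive_seed(seed0, 30)
    )
    proto <- sel$best
    cv_by_k <- sel$cv_by_k
  } else {
    proto <- fit_modified_kmeans(chi,
      k = config$k, max_iter = config$max_iter,
      tol = config$tol, n_restarts = config$n_restarts,
      seed = derive_seed(seed0, 30)
    )
  }

  # --- per-subject asymmetries ---------------------------------------------
  msg_stage(verbose, "asymmetry", "per-subject indices")
  asym_rows <- list()
  tr_series <- vector("list", ns)
  for (i in seq_len(ns)) {
    rec <- recordings[[i]]
    proto_i <- if (config$prototype_level == "subject") {
      chi_i <- concatenate_peak_maps(recordings[i], list(gfps[[i]]$peak_indices))
      fit_modified_kmeans(chi_i,
        k = if (identical(config$k, "cv")) proto$k else config$k,
        max_iter = config$max_iter, tol = config$tol,
        n_restarts = config$n_restarts, seed = derive_seed(seed0, 40 + i)
      )
    } else {
      proto
    }
    lab <- backfit(rec, proto_i)
    rex <- reexpress(rec, lab, proto_i)
    pw_ms <- alpha_band_power(rex, band = config$band)
    pw_sd <- alpha_band_power(csd_transform(rec), band = config$band)
    for (pair in c("FA", "FTA")) {
      asym_rows[[length(asym_rows) + 1]] <- data.frame(
        subject_id = planted$subject_id[i], pair = pair,
        method = "microstate",
        value = as.numeric(asymmetry_index(pw_ms, pair))
      )
      asym_rows[[length(asym_rows) + 1]] <- data.frame(
        subject_id = planted$subject_id[i], pair = pair,
        method = "standard",
        value = as.numeric(asymmetry_index(pw_sd, pair))
      )
    }
    if (config$run_neurovascular) {
      tr_series[[i]] <- alpha_to_tr_series(rex,
        tr_s = config$tr_s,
        n_scans = config$n_scans, pair = "FA"
      )$asymmetry
    }
  }
  asymmetries <- do.call(rbind, asym_rows)

  # --- neurovascular stage --------------------------------------------------
  hli_tab <- NULL
  group_stats <- NULL
  if (config$run_neurovascular) {
    msg_stage(verbose, "neurovasc", "GLM + deconvolution + HLI")
    amps <- NULL
    hli_rows <- list()
    masks <- NULL
    for (i in seq_len(ns)) {
      bd <- generate_bold_dataset(
        n_voxels_per_region = config$n_voxels_per_region,
        tr_s = config$tr_s, n_volumes = config$n_scans,
        amp_right = config$amp_right, amp_left = config$amp_left,
        noise_sd = config$bold_noise_sd, ar1_coef = config$bold_ar1,
        seed = derive_seed(seed0, 100 + i)
      )
      masks <- bd$masks
      des <- build_parametric_design(tr_series[[i]], config$tr_s, config$n_scans)
      fl <- fit_first_level_glm(bd$bold, des)
      amps <- rbind(amps, fl$amplitude)
      dec <- deconvolve_mask(bd$bold, bd$masks$left | bd$masks$right, config$tr_s)
      hli_rows[[i]] <- cbind(
        subject_id = planted$subject_id[i],
        compute_hli(dec$amplitude, list(frontal = bd$masks))
      )
    }
    hli_tab <- do.call(rbind, hli_rows)
    grp <- group_robust_regression(amps)
    pa <- array(grp$p, dim(masks$left))
    thr <- fdr_threshold(pa, q = 0.05, min_cluster = 20)
    group_stats <- list(irls = grp, fdr = thr)
  }

  # --- robust correlations ---------------------------------------------------
  msg_stage(verbose, "correlate", "asymmetry-score battery")
  score_names <- config$cor_scores
  m_bonf <- length(config$cor_pairs) * length(score_names)
  cor_rows <- list()
  for (pair in config$cor_pairs) {
    for (meth in c("microstate", "standard")) {
      av <- asymmetries$value[asymmetries$pair == pair & asymmetries$method == meth]
      for (sc in score_names) {
        res <- robust_correlate(av, scores[[sc]],
          methods = config$cor_methods,
          n_boot = config$n_boot, bonferroni_m = m_bonf,
          seed = derive_seed(seed0, 200)
        )
        tab <- attr(res, "table")
        tab <- cbind(
          pair = pair, asym_method = meth, score = sc, tab,
          stringsAsFactors = FALSE
        )
        cor_rows[[length(cor_rows) + 1]] <- tab
      }
    }
  }
  correlations <- do.call(rbind, cor_rows)
  rownames(correlations) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("msasym")),
    seed = seed0,
    parameters = unclass(config)[setdiff(names(config), "output_dir")],
    n_peak_maps = nrow(chi),
    k_used = proto$k
  )
  bundle <- structure(
    list(
      asymmetries = asymmetries, prototypes = proto, cv_by_k = cv_by_k,
      scores = scores, correlations = correlations, hli = hli_tab,
      group_stats = group_stats,
      truth = planted, manifest = manifest
    ),
    class = "study_result_bundle"
  )
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.study_result_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_result_bundle> %d subjects, K = %d, %d correlation rows\n",
    length(unique(x$asymmetries$subject_id)), x$manifest$k_used,
    nrow(x$correlations)
  ))
  invisible(x)
}

#' Write a result bundle's tables to a directory
#'
#' CSV tables (asymmetries, scores, correlations, HLI), JSON manifest, and
#' the prototype set as JSON.
#'
#' @param bundle a `study_result_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$asymmetries, file.path(dir, "asymmetries.csv"),
    row.names = FALSE
  )
  utils::write.csv(bundle$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(bundle$correlations, file.path(dir, "correlations.csv"),
    row.names = FALSE
  )
  if (!is.null(bundle$hli)) {
    utils::write.csv(bundle$hli, file.path(dir, "hli.csv"), row.names = FALSE)
  }
  proto <- bundle$prototypes
  jsonlite::write_json(
    list(
      k = proto$k, channel_labels = proto$channel_labels,
      gev_total = proto$gev_total, cv = proto$cv,
      prototypes = proto$prototypes
    ),
    file.path(dir, "prototypes.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
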