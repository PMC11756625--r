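# End-to-end study replica on synthetic data: simulate a preterm cohort,
# preprocess, compute SI maps and surrogate nulls per subject, run the
# electrode-level inference and cluster detection for the full cohort and
# the <33 / >=33 weeks-GA groups, and the group-level statistics
# (GA correlations, 3x2 mixed ANOVA, phase analyses, band-power controls).

#' Pipeline run configuration
#'
#' The `"desk"` profile (default) runs the identical analysis chain at a
#' scale suited to a single CPU: 256 Hz simulation resampled to 128 Hz, 6
#' trials per subject. The `"full"` profile mirrors the acquisition
#' protocol (1000 Hz to 512 Hz, 54 trials).
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param profile `"desk"` or `"full"`.
#' @param n_subjects cohort size.
#' @param ga_range recording-age range (weeks GA).
#' @param montage_n recording montage size (64 or 124; 124 is spatially
#'   downsampled to 64 for analysis).
#' @param analysis_rate_hz rate after resampling (`NULL`: 128 for desk,
#'   512 for full).
#' @param low_hz,high_hz broad band-pass edges.
#' @param bw_hz narrow-band SI filter bandwidth.
#' @param trim_s seconds trimmed from each trial edge.
#' @param n_surrogates surrogate count per electrode and frequency.
#' @param q_fdr FDR level for the electrode mask.
#' @param min_neighbors cluster neighbor rule.
#' @param control_freqs_hz control frequencies (halfway between the
#'   stimulus-related peaks, absent from the stimulus spectrum).
#' @param si_variant variant used for coupling strength.
#' @param gen a [generative_config()] (`NULL`: defaults for the profile).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, profile = c("desk", "full"),
                            n_subjects = 46, ga_range = c(28, 36),
                            montage_n = 64, analysis_rate_hz = NULL,
                            low_hz = 0.5, high_hz = 15, bw_hz = 0.2,
                            trim_s = 2, n_surrogates = 1000, q_fdr = 0.05,
                            min_neighbors = 3,
                            control_freqs_hz = c(1.389, 2.500, 3.055),
                            si_variant = "absolute", gen = NULL) {
  profile <- match.arg(profile)
  cfg <- list(seed = seed, profile = profile, n_subjects = n_subjects,
              ga_range = ga_range, montage_n = montage_n,
              analysis_rate_hz = analysis_rate_hz %||%
                switch(profile, desk = 128, full = 512),
              low_hz = low_hz, high_hz = high_hz, bw_hz = bw_hz,
              trim_s = trim_s, n_surrogates = n_surrogates, q_fdr = q_fdr,
              min_neighbors = min_neighbors,
              control_freqs_hz = control_freqs_hz,
              si_variant = si_variant,
              gen = gen %||% generative_config(profile))
  class(cfg) <- "pipeline_config"
  cfg
}

# Observed SI (both variants) and binned surrogate |SI| for one subject.
subject_sync <- function(rec, grid, freqs_hz, bw_hz, trim_s, keep, n_surr,
                         seed0, bins = 512) {
  E <- ncol(rec$data)
  F_ <- length(freqs_hz)
  si_abs <- matrix(NA_real_, E, F_)
  si_sgn <- matrix(NA_complex_, E, F_)
  surr <- vector("list", F_)
  for (j in seq_len(F_)) {
    dl <- subject_phase_diffs(rec, grid, freqs_hz[j], bw_hz, trim_s, keep)
    si_abs[, j] <- Mod(si_from_diffs(dl, "absolute"))
    si_sgn[, j] <- si_from_diffs(dl, "signed")
    surr[[j]] <- surrogate_timeshift(dl, n_surr, derive_seed(seed0, j),
                                     "absolute", bins)
  }
  list(si_abs = si_abs, si_signed = si_sgn, surr = surr)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Deterministic given `config$seed`. See the package vignette for the
#' analysis logic stage by stage.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return object of class `rhythm_analysis`; see [print.rhythm_analysis()]
#'   and [report()].
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- event_grid()
  rec_montage <- make_montage(config$montage_n)
  target64 <- if (config$montage_n > 64) make_montage(64) else NULL
  meta <- cohort_meta(config$n_subjects, config$ga_range, config$seed,
                      config$gen$ga_split)
  tf <- grid_frequencies(grid)
  freqs <- c(tf, setNames(config$control_freqs_hz,
                          paste0("control", seq_along(config$control_freqs_hz))))
  F_ <- length(freqs)
  S <- nrow(meta)

  an_montage <- NULL
  si_abs <- NULL
  si_signed <- NULL
  sum_full <- sum_young <- sum_old <- NULL
  n_young <- sum(meta$group == "younger")
  n_old <- S - n_young
  bp_lo <- bp_mid <- NULL
  n_trials_kept <- integer(S)

  for (s in seq_len(S)) {
    say("subject %d/%d", s, S)
    rec <- simulate_subject(meta[s, ], grid, config$gen, rec_montage)
    pp <- preprocess(rec, filter_spec(config$low_hz, config$high_hz),
                     config$analysis_rate_hz, target64)
    rec_p <- pp$rec
    keep <- pp$keep
    n_trials_kept[s] <- length(keep)
    if (is.null(an_montage)) {
      an_montage <- rec_p$montage
      E <- ncol(rec_p$data)
      si_abs <- array(NA_real_, c(S, E, F_))
      si_signed <- array(NA_complex_, c(S, E, F_))
      sum_full <- lapply(seq_len(F_), function(j)
        matrix(0, E, config$n_surrogates))
      sum_young <- lapply(seq_len(F_), function(j)
        matrix(0, E, config$n_surrogates))
      sum_old <- lapply(seq_len(F_), function(j)
        matrix(0, E, config$n_surrogates))
      bp_lo <- matrix(NA_real_, S, E)
      bp_mid <- matrix(NA_real_, S, E)
    }
    sync <- subject_sync(rec_p, grid, freqs, config$bw_hz, config$trim_s,
                         keep, config$n_surrogates,
                         derive_seed(config$seed, 100000 + s))
    si_abs[s, , ] <- sync$si_abs
    si_signed[s, , ] <- sync$si_signed
    for (j in seq_len(F_)) {
      sum_full[[j]] <- sum_full[[j]] + sync$surr[[j]]
      if (meta$group[s] == "younger") {
        sum_young[[j]] <- sum_young[[j]] + sync$surr[[j]]
      } else {
        sum_old[[j]] <- sum_old[[j]] + sync$surr[[j]]
      }
    }
    ep <- epoch_recording(rec_p, keep)
    bp_lo[s, ] <- band_power(ep, 1, 1.7)
    bp_mid[s, ] <- band_power(ep, 1, 3.4)
  }

  scopes <- list(full = seq_len(S),
                 younger = which(meta$group == "younger"),
                 older = which(meta$group == "older"))
  nulls <- list(full = lapply(sum_full, function(m) m / S),
                younger = lapply(sum_young, function(m) m / n_young),
                older = lapply(sum_old, function(m) m / n_old))

  say("electrode-level inference and clusters")
  inference <- list()
  for (sc in names(scopes)) {
    rows <- scopes[[sc]]
    per_freq <- vector("list", F_)
    for (j in seq_len(F_)) {
      obs <- colMeans(si_abs[rows, , j, drop = FALSE][, , 1])
      pv <- erfc_pvalue(obs, nulls[[sc]][[j]])
      fdr <- bh_fdr(pv$p, config$q_fdr)
      cl <- detect_clusters(fdr$significant, an_montage,
                            config$min_neighbors, fdr$p_adjusted)
      per_freq[[j]] <- list(freq_hz = unname(freqs[j]), observed = obs,
                            p_raw = pv$p, p_rank = pv$p_rank,
                            p_adjusted = fdr$p_adjusted,
                            significant = fdr$significant, clusters = cl,
                            null_mean = pv$mean, null_sd = pv$sd)
    }
    names(per_freq) <- names(freqs)
    inference[[sc]] <- per_freq
  }

  # regions of interest: full-cohort cluster electrodes per target
  # frequency; frontocentral profile electrodes when no cluster emerged
  w <- frontocentral_profile(an_montage)
  profile_roi <- which(w > 0.5)
  roi <- lapply(names(tf), function(b) {
    cl <- inference$full[[b]]$clusters$clusters
    if (length(cl)) sort(unique(unlist(cl))) else profile_roi
  })
  names(roi) <- names(tf)
  shared <- Reduce(intersect, roi)
  if (!length(shared)) shared <- sort(unique(unlist(roi)))
  beat_roi <- roi$beat
  phase_roi <- intersect(beat_roi, which(w > 0.25))
  if (!length(phase_roi)) phase_roi <- profile_roi

  say("group statistics")
  ga <- meta$ga_record_weeks
  grp <- factor(meta$group, levels = c("younger", "older"))
  z_by_freq <- lapply(seq_len(F_), function(j)
    zscore_population(si_abs[, , j]))
  ga_corr <- lapply(names(freqs), function(b) {
    j <- match(b, names(freqs))
    r <- if (b %in% names(tf)) roi[[b]] else beat_roi
    zbar <- rowMeans(z_by_freq[[j]][, r, drop = FALSE])
    c(list(freq_hz = unname(freqs[j]), band = b),
      spearman_corr(ga, zbar))
  })
  names(ga_corr) <- names(freqs)

  # raw coupling strength (not z-scores: per-frequency standardization
  # would remove the within-subject frequency effect by construction)
  adf <- do.call(rbind, lapply(names(tf), function(b) {
    j <- match(b, names(freqs))
    data.frame(subject = meta$subject_id, group = grp, frequency = b,
               value = rowMeans(si_abs[, shared, j, drop = FALSE][, , 1,
                                                                  drop = FALSE]))
  }))
  anova_res <- mixed_anova(adf)
  lm_full <- stats::lm(value ~ group * frequency, data = adf)
  lm_add <- stats::lm(value ~ group + frequency, data = adf)
  bf_inter <- bayes_factor_aic(lm_add, lm_full)

  phases <- Arg(vapply(seq_len(S), function(s)
    sum(si_signed[s, phase_roi, match("beat", names(freqs))]),
    complex(1)))
  rayleigh <- list(older = rayleigh_test(phases[grp == "older"]),
                   younger = rayleigh_test(phases[grp == "younger"]))
  circlin <- circ_linear_corr(phases, ga)

  bp_lo_bar <- rowMeans(bp_lo[, shared, drop = FALSE])
  bp_mid_bar <- rowMeans(bp_mid[, shared, drop = FALSE])
  power_ga <- pearson_corr(ga, bp_lo_bar)
  bf_power_ga <- bayes_factor_aic(stats::lm(bp_lo_bar ~ 1),
                                  stats::lm(bp_lo_bar ~ ga))
  power_group <- si_ttest(bp_mid_bar[grp == "older"],
                          bp_mid_bar[grp == "younger"])
  bf_power_group <- bayes_factor_aic(stats::lm(bp_mid_bar ~ 1),
                                     stats::lm(bp_mid_bar ~ grp))

  # one-tailed one-sample t-tests of group-mean coupling vs the surrogate
  # 95% bound over the ROI
  above_chance <- do.call(rbind, lapply(c("younger", "older"), function(g) {
    rows <- scopes[[g]]
    do.call(rbind, lapply(names(tf), function(b) {
      j <- match(b, names(freqs))
      x <- rowMeans(si_abs[rows, roi[[b]], j, drop = FALSE][, , 1,
                                                            drop = FALSE])
      thr <- stats::quantile(colMeans(nulls[[g]][[j]][roi[[b]], ,
                                                      drop = FALSE]), 0.95)
      tt <- si_ttest(x, mode = "one_sample_one_tailed", threshold = thr)
      data.frame(group = g, band = b, threshold = unname(thr),
                 mean_si = mean(x), t = tt$t, df = tt$df, p = tt$p)
    }))
  }))

  structure(list(
    config = config, grid = grid, montage = an_montage, meta = meta,
    freqs_hz = freqs, target_bands = names(tf),
    si_abs = si_abs, si_signed = si_signed,
    n_trials_kept = n_trials_kept,
    inference = inference, roi = roi, shared_electrodes = shared,
    ga_correlations = ga_corr, anova = anova_res,
    bf_interaction = bf_inter,
    phase = list(angles = phases, rayleigh = rayleigh, circlin = circlin,
                 roi = phase_roi),
    power = list(ga = power_ga, bf_ga = bf_power_ga, group = power_group,
                 bf_group = bf_power_group),
    above_chance = above_chance
  ), class = "rhythm_analysis")
}

cluster_count <- function(x, scope, band) {
  length(x$inference[[scope]][[band]]$clusters$clusters)
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat(sprintf("Rhythm synchronization analysis: %d subjects, %d electrodes, seed %s (%s profile)\n",
              nrow(x$meta), nrow(x$montage$pos), x$config$seed,
              x$config$profile))
  cat("Significant sensor clusters (count):\n")
  for (b in names(x$freqs_hz)) {
    cat(sprintf("  %-9s %5.2f Hz  full: %d  younger: %d  older: %d\n",
                b, x$freqs_hz[[b]], cluster_count(x, "full", b),
                cluster_count(x, "younger", b),
                cluster_count(x, "older", b)))
  }
  cat("Spearman correlation of z-scored |SI| with gestational age:\n")
  for (b in x$target_bands) {
    g <- x$ga_correlations[[b]]
    cat(sprintf("  %-9s rho = %.2f, p = %.3g\n", b, g$rho, g$p))
  }
  cat("Mixed ANOVA (frequency x age group):\n")
  print(x$anova)
  cat(sprintf("Rayleigh (beat phase): older z = %.2f, p = %.3g; younger p = %.3g\n",
              x$phase$rayleigh$older$z, x$phase$rayleigh$older$p,
              x$phase$rayleigh$younger$p))
  cat(sprintf("Circular-linear phase~GA: Rc = %.2f, p = %.3g\n",
              x$phase$circlin$Rc, x$phase$circlin$p))
  invisible(x)
}

#' @export
summary.rhythm_analysis <- function(object, ...) print(object)

# Deterministic 31-bit polynomial rolling hash of a string.
content_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write pipeline results to disk
#'
#' Emits `cohort.csv`, `sync.csv` (per subject/electrode/frequency SI),
#' `inference_<scope>.csv` (electrode-level p-values and masks),
#' `clusters.json`, `stats.csv` (one row per group-level test) and
#' `manifest.json` (config echo, config hash, seed, package version).
#' Result tables are deterministic given the seed.
#'
#' @param x a `rhythm_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  S <- dim(x$si_abs)[1]
  E <- dim(x$si_abs)[2]
  sync <- data.frame(
    subject_id = rep(x$meta$subject_id, times = E * length(x$freqs_hz)),
    electrode = rep(rep(x$montage$labels, each = S),
                    times = length(x$freqs_hz)),
    frequency_hz = rep(unname(x$freqs_hz), each = S * E),
    si_abs = as.vector(x$si_abs),
    si_angle = as.vector(Arg(x$si_signed)))
  write.csv(sync, file.path(dir, "sync.csv"), row.names = FALSE)
  for (sc in names(x$inference)) {
    tab <- do.call(rbind, lapply(names(x$freqs_hz), function(b) {
      pf <- x$inference[[sc]][[b]]
      data.frame(band = b, frequency_hz = pf$freq_hz,
                 electrode = x$montage$labels, observed = pf$observed,
                 p_raw = pf$p_raw, p_adjusted = pf$p_adjusted,
                 significant = pf$significant)
    }))
    write.csv(tab, file.path(dir, sprintf("inference_%s.csv", sc)),
              row.names = FALSE)
  }
  clusters <- lapply(x$inference, function(per_freq) {
    lapply(per_freq, function(pf) {
      list(freq_hz = pf$freq_hz,
           clusters = lapply(seq_along(pf$clusters$clusters), function(k) {
             list(electrodes = pf$clusters$labels[[k]],
                  size = length(pf$clusters$clusters[[k]]),
                  min_p_adjusted = pf$clusters$cluster_p[k])
           }))
    })
  })
  jsonlite::write_json(clusters, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  stats_tab <- rbind(
    do.call(rbind, lapply(x$target_bands, function(b) {
      g <- x$ga_correlations[[b]]
      data.frame(test = paste0("spearman_ga_", b), statistic = g$rho,
                 df = g$n - 2, p = g$p, effect = g$rho, bf = NA_real_)
    })),
    data.frame(test = paste0("anova_", x$anova$effect),
               statistic = x$anova$F, df = x$anova$df2, p = x$anova$p,
               effect = x$anova$peta2,
               bf = c(NA, NA, x$bf_interaction$bf_effect_over_null)),
    data.frame(test = c("rayleigh_older", "rayleigh_younger"),
               statistic = c(x$phase$rayleigh$older$z,
                             x$phase$rayleigh$younger$z),
               df = NA_real_,
               p = c(x$phase$rayleigh$older$p, x$phase$rayleigh$younger$p),
               effect = c(x$phase$rayleigh$older$R,
                          x$phase$rayleigh$younger$R), bf = NA_real_),
    data.frame(test = "circ_linear_phase_ga", statistic = x$phase$circlin$Rc,
               df = 2, p = x$phase$circlin$p, effect = x$phase$circlin$Rc,
               bf = NA_real_),
    data.frame(test = c("pearson_power_ga", "ttest_power_group"),
               statistic = c(x$power$ga$r, x$power$group$t),
               df = c(x$power$ga$n - 2, x$power$group$df),
               p = c(x$power$ga$p, x$power$group$p),
               effect = c(x$power$ga$r, NA),
               bf = c(x$power$bf_ga$bf_effect_over_null,
                      x$power$bf_group$bf_effect_over_null)))
  write.csv(stats_tab, file.path(dir, "stats.csv"), row.names = FALSE)
  cfg_yaml <- yaml::as.yaml(strip_functions(x$config))
  writeLines(cfg_yaml, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(config_hash = content_hash(cfg_yaml), seed = x$config$seed,
         package_version = as.character(packageVersion("rhythmtag"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

strip_functions <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}

#' Plot pipeline results
#'
#' `type = "topo"`: scalp map of group-mean |SI| with cluster electrodes
#' crossed, one panel per target frequency. `type = "ga"`: scatter of
#' ROI-averaged z-scored |SI| against gestational age with a linear fit.
#' `type = "phase"`: preferred beat-coupling phase per subject by group.
#'
#' @param x a `rhythm_analysis`.
#' @param type plot type.
#' @param scope `"full"`, `"younger"` or `"older"` (topo maps).
#' @param ... ignored.
#' @export
plot.rhythm_analysis <- function(x, type = c("topo", "ga", "phase"),
                                 scope = "full", ...) {
  type <- match.arg(type)
  bands <- x$target_bands
  old <- par(mfrow = c(1, length(bands)), mar = c(1, 1, 3, 1))
  on.exit(par(old))
  rows <- switch(scope, full = seq_len(nrow(x$meta)),
                 which(x$meta$group == scope))
  if (type == "topo") {
    for (b in bands) {
      j <- match(b, names(x$freqs_hz))
      v <- colMeans(x$si_abs[rows, , j, drop = FALSE][, , 1])
      cl <- unlist(x$inference[[scope]][[b]]$clusters$clusters)
      plot(x$montage, values = v, highlight = cl,
           main = sprintf("%s %.2f Hz (%s)", b, x$freqs_hz[[b]], scope))
    }
  } else if (type == "ga") {
    old2 <- par(mar = c(4, 4, 3, 1))
    for (b in bands) {
      j <- match(b, names(x$freqs_hz))
      z <- rowMeans(zscore_population(x$si_abs[, , j])[, x$roi[[b]],
                                                       drop = FALSE])
      ga <- x$meta$ga_record_weeks
      plot(ga, z, xlab = "GA at recording (weeks)", ylab = "z(|SI|)",
           main = b, pch = 19)
      abline(stats::lm(z ~ ga))
    }
    par(old2)
  } else {
    for (g in c("younger", "older")) {
      rows <- which(x$meta$group == g)
      a <- x$phase$angles[rows]
      plot(cos(a), sin(a), xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
           asp = 1, pch = 19, main = sprintf("beat phase (%s)", g),
           xlab = "", ylab = "")
      tt <- seq(0, 2 * pi, length.out = 200)
      lines(cos(tt), sin(tt), col = "grey70")
      m <- atan2(mean(sin(a)), mean(cos(a)))
      segments(0, 0, cos(m), sin(m), lwd = 2)
      if (length(bands) == 3) plot.new()
      break
    }
  }
  invisible(x)
}
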