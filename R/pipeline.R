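#' Simulate a full two-site experiment
#'
#' Builds `n_dyads` dyads with a UK (88-channel, 12.34 Hz) and a US
#' (134-channel, 8.13 Hz) partner each, counterbalanced live/static run
#' orders, and per-dyad ground truth derived from `truth_template` with
#' dyad-specific seeds. The mask geometry is the ideal US montage. With
#' `write_dir` the dataset is also written in the package's on-disk layout
#' (one directory per dyad with recordings, geometries and events; mask
#' geometry at the top level).
#'
#' @param n_dyads number of dyads.
#' @param truth_template a [ground_truth()]; its seed is re-derived per
#'   dyad.
#' @param seed master seed.
#' @param n_repeats paradigm repeats of the live/static run order.
#' @param write_dir optional output directory.
#' @return A list of class `dyad_experiment`: `dyads` (each with `id`,
#'   `raw_a`, `raw_b`, `geom_a`, `geom_b`, `paradigm`, `truth`),
#'   `mask_geometry`, `seed`.
#' @export
simulate_experiment <- function(n_dyads = 20,
                                truth_template = ground_truth(),
                                seed = 1L, n_repeats = 2,
                                write_dir = NULL) {
  orders <- condition_orders(c("live", "static"))
  mask_geometry <- generate_geometry(site_config("US"),
                                     seed = child_seed(seed, 0L))
  dyads <- lapply(seq_len(n_dyads), function(i) {
    truth <- truth_template
    truth$seed <- child_seed(seed, i)
    paradigm <- generate_paradigm(orders[[(i - 1) %% length(orders) + 1]],
                                  n_repeats = n_repeats)
    geom_a <- generate_geometry(site_config("UK"),
                                seed = child_seed(seed, 1000L + i))
    geom_b <- generate_geometry(site_config("US"),
                                seed = child_seed(seed, 2000L + i))
    sim <- simulate_dyad(geom_a, geom_b, paradigm, truth)
    list(id = sprintf("dyad%02d", i), raw_a = sim$raw_a, raw_b = sim$raw_b,
         geom_a = geom_a, geom_b = geom_b, paradigm = paradigm,
         truth = truth, conc_a = sim$conc_a, conc_b = sim$conc_b)
  })
  exp <- structure(list(dyads = dyads, mask_geometry = mask_geometry,
                        seed = seed),
                   class = "dyad_experiment")
  if (!is.null(write_dir)) write_experiment(exp, write_dir)
  exp
}

#' Write / read a simulated experiment dataset
#'
#' @param exp a `dyad_experiment`.
#' @param dir dataset directory.
#' @return `write_experiment` the dir; `read_experiment` the experiment
#'   (dyads with a missing partner are skipped with a warning; an empty
#'   dataset is an error).
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geometry(exp$mask_geometry, file.path(dir, "mask_geometry.csv"))
  for (d in exp$dyads) {
    dd <- file.path(dir, d$id)
    dir.create(dd, showWarnings = FALSE)
    write_recording(d$raw_a, file.path(dd, "a"))
    write_recording(d$raw_b, file.path(dd, "b"))
    write_geometry(d$geom_a, file.path(dd, "a_geometry.csv"))
    write_geometry(d$geom_b, file.path(dd, "b_geometry.csv"))
    write_events(as_tibble(d$paradigm), file.path(dd, "events.tsv"))
  }
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  mask_geometry <- read_geometry(file.path(dir, "mask_geometry.csv"))
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  dyads <- list()
  for (id in ids) {
    dd <- file.path(dir, id)
    ok <- dir.exists(file.path(dd, "a")) && dir.exists(file.path(dd, "b"))
    if (!ok) {
      warn(sprintf("dyad '%s' is missing a partner; skipped.", id))
      next
    }
    dyads[[length(dyads) + 1L]] <- list(
      id = id,
      raw_a = read_recording(file.path(dd, "a")),
      raw_b = read_recording(file.path(dd, "b")),
      geom_a = read_geometry(file.path(dd, "a_geometry.csv")),
      geom_b = read_geometry(file.path(dd, "b_geometry.csv")),
      paradigm = read_events(file.path(dd, "events.tsv"))
    )
  }
  if (length(dyads) == 0) abort("no complete dyads in dataset.")
  structure(list(dyads = dyads, mask_geometry = mask_geometry, seed = NA),
            class = "dyad_experiment")
}

# preprocess one participant: raw -> QC'd, resampled, filtered, GMR'd series
preprocess_participant <- function(raw, geometry, cfg) {
  hb <- mbll_convert(raw, geometry, dpf = cfg$dpf)
  qc <- qc_exclude_channels(raw, hb)
  hb <- apply_qc(hb, qc)
  hb <- resample_series(hb, cfg$target_rate)
  hb <- bandpass(hb, cfg$filter_low, cfg$filter_high, cfg$filter_order)
  hb <- global_mean_removal(hb, cfg$gmr_components)
  list(hb = hb, qc = qc)
}

#' Run the full dyadic analysis pipeline
#'
#' Chains every stage on a simulated or on-disk dataset: MBLL conversion,
#' channel QC, resampling to the common rate, band-pass, global mean
#' removal, Gaussian co-localisation onto the 134-channel mask, HbDiff GLM
#' per mask channel with the group live-static contrast and FDR, HHb ROI
#' residual extraction, real- and shuffled-dyad wavelet coherence in the
#' angular gyrus, the per-period paired condition test, and the 2x2
#' dyad-type x condition ANOVA. Deterministic for a given config (the
#' shuffled pairing derives from `cfg$seed`).
#'
#' @param cfg a [run_config()].
#' @param dataset a `dyad_experiment` or a dataset directory path.
#' @param out_dir optional directory for the result TSVs and provenance
#'   record.
#' @return A list of class `pipeline_result`: `qc`, `glm_channels`,
#'   `contrast`, `coherence`, `profile`, `anova`, `condition_test`,
#'   `provenance`.
#' @export
run_pipeline <- function(cfg, dataset, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  validate_config(cfg)
  if (is.character(dataset)) dataset <- read_experiment(dataset)
  mask <- dataset$mask_geometry
  rois <- roi_table()
  assignment <- assign_rois(mask, rois)
  grid <- build_scale_grid(cfg$grid$octaves, cfg$grid$voices,
                           cfg$grid$base_period, cfg$grid$spacing)

  qc_rows <- list(); betas <- list(); residual_ag <- list()
  glm_rows <- list()
  for (d in dataset$dyads) {
    for (side in c("a", "b")) {
      raw <- d[[paste0("raw_", side)]]
      geom <- d[[paste0("geom_", side)]]
      pp <- preprocess_participant(raw, geom, cfg)
      qc_rows[[length(qc_rows) + 1L]] <- glance(pp$qc) %>%
        mutate(dyad = d$id, side = side, .before = 1)
      kern <- build_kernel(pairwise_distances(geom, mask), cfg$sigma,
                           cfg$kernel_form)
      hb_mask <- colocalise(pp$hb, kern)
      design <- do.call(build_design, c(
        list(paradigm = d$paradigm, rate = cfg$target_rate,
             n_samples = ncol(hb_mask$hbo2)),
        list(hrf = do.call(canonical_hrf,
                           c(list(sampling_rate = cfg$target_rate), cfg$hrf)))
      ))
      fit <- fit_glm(hbdiff(hb_mask), design)
      betas[[length(betas) + 1L]] <- tibble(
        dyad = d$id, side = side,
        live = fit$betas[, "live"], static = fit$betas[, "static"],
        channel = seq_len(nrow(fit$betas))
      )
      glm_rows[[length(glm_rows) + 1L]] <- glance(fit) %>%
        mutate(dyad = d$id, side = side, .before = 1)
      roi_hb <- roi_average(hb_mask, assignment)
      roi_fit <- fit_glm(roi_hb$hhb, design)
      residual_ag[[paste(d$id, side, sep = "_")]] <-
        roi_fit$residuals[match(cfg$coherence_roi, rownames(roi_hb$hhb)), ]
    }
  }
  qc_table <- bind_rows(qc_rows)

  # group contrast across all participants (both sites), paired within
  beta_tab <- bind_rows(betas)
  wide_live <- beta_tab %>%
    tidyr::pivot_wider(id_cols = c("dyad", "side"), names_from = "channel",
                       values_from = "live") %>%
    select(-"dyad", -"side") %>% as.matrix()
  wide_static <- beta_tab %>%
    tidyr::pivot_wider(id_cols = c("dyad", "side"), names_from = "channel",
                       values_from = "static") %>%
    select(-"dyad", -"side") %>% as.matrix()
  contrast <- group_contrast_test(wide_live, wide_static) %>%
    mutate(significant_fdr = fdr_correct(.data$p, cfg$fdr_q))

  # inter-brain coherence: real and shuffled cross-site pairs
  paradigms <- setNames(lapply(dataset$dyads, `[[`, "paradigm"),
                        vapply(dataset$dyads, `[[`, "", "id"))
  ids <- names(paradigms)
  real_rows <- lapply(ids, function(id) {
    dyad_coherence(residual_ag[[paste0(id, "_a")]],
                   residual_ag[[paste0(id, "_b")]],
                   paradigms[[id]], cfg$target_rate, grid,
                   order = cfg$wavelet_order,
                   smooth_periods = cfg$smooth_periods) %>%
      mutate(dyad = id, kind = "real", .before = 1)
  })
  shuffled <- make_shuffled_pairs(tibble(uk = ids, us = ids),
                                  n_pairs = cfg$n_shuffled, seed = cfg$seed)
  shuf_rows <- lapply(seq_len(nrow(shuffled)), function(i) {
    a_id <- shuffled$uk[i]; b_id <- shuffled$us[i]
    dyad_coherence(residual_ag[[paste0(a_id, "_a")]],
                   residual_ag[[paste0(b_id, "_b")]],
                   paradigms[[a_id]], cfg$target_rate, grid,
                   paradigm_b = paradigms[[b_id]],
                   order = cfg$wavelet_order,
                   smooth_periods = cfg$smooth_periods) %>%
      mutate(dyad = sprintf("%s x %s", a_id, b_id), kind = "shuffled",
             .before = 1)
  })
  coherence <- bind_rows(c(real_rows, shuf_rows)) %>%
    mutate(roi_pair = paste(cfg$coherence_roi, cfg$coherence_roi, sep = "-"))
  profile <- coherence_profile(coherence)
  condition_test <- per_period_condition_test(
    coherence %>% filter(.data$kind == "real"), fdr = TRUE)
  anova_tab <- anova_2x2(coherence)

  provenance <- list(
    config = unclass(cfg), config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed, n_dyads = length(dataset$dyads),
    package_version = as.character(utils::packageVersion("fnirsdyad")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  res <- structure(
    list(qc = qc_table, glm_channels = bind_rows(glm_rows),
         betas = beta_tab, contrast = contrast, coherence = coherence,
         profile = profile, condition_test = condition_test,
         anova = anova_tab, provenance = provenance),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write the pipeline result bundle
#'
#' TSV per table plus a machine-readable provenance record (config, config
#' hash, seed, versions).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$qc, file.path(dir, "qc.tsv"))
  readr::write_tsv(res$contrast, file.path(dir, "glm_contrast.tsv"))
  readr::write_tsv(res$betas, file.path(dir, "glm_betas.tsv"))
  readr::write_tsv(res$coherence, file.path(dir, "coherence.tsv"))
  readr::write_tsv(res$profile, file.path(dir, "coherence_profile.tsv"))
  readr::write_tsv(res$condition_test, file.path(dir, "condition_test.tsv"))
  readr::write_tsv(res$anova, file.path(dir, "anova.tsv"))
  jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d participants QC'd; %d channels contrasted (%d FDR-significant);\n  coherence: %d rows; ANOVA interaction df = (%g, %g)\n",
    nrow(x$qc), nrow(x$contrast), sum(x$contrast$significant_fdr),
    nrow(x$coherence), x$anova$df_effect[1], x$anova$df_error[1]))
  invisible(x)
}
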