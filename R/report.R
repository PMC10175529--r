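#' Write the robustness report files
#'
#' Emits CSV tables mirroring the standard layout of multi-platform
#' robustness studies — a class-by-metric dispersion table, a
#' class-by-metric pairwise-agreement table, a CT-number table, the
#' per-feature heatmap values, per-ROI and per-pair percentage tables, the
#' top-feature ranking and shortlist report — plus a JSON run summary with
#' the seed and configuration. Output contains no timestamps, so identical
#' runs produce byte-identical reports.
#'
#' @param study a `robustness_study` from [run_robustness_study()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, the vector of written file paths
#' @export
report_robustness <- function(study, out_dir) {
  if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_radrobust("cannot create out_dir: ", out_dir,
                   class = "radrobust_io_error")
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(
    wr(study$repeatability$per_platform, "repeatability_per_platform.csv"),
    wr(study$repeatability$summary, "repeatability_summary.csv"),
    wr(study$dispersion$per_class, "table2_analog.csv"),
    wr(study$dispersion$per_roi, "roi_percentages.csv"),
    wr(study$dispersion$summary, "dispersion_summary.csv"),
    wr(study$dispersion$per_feature, "feature_heatmap.csv"),
    wr(study$pairwise$per_class, "table3_analog.csv"),
    wr(study$pairwise$per_pair, "pair_percentages.csv"),
    wr(study$pairwise$summary, "pairwise_summary.csv"),
    wr(study$pairwise$top_features, "top_features.csv"),
    wr(study$pairwise$shortlist_report, "shortlist_report.csv"),
    wr(rbind_fill_ct(study$ct), "table4_analog.csv"),
    wr(study$ct$correlations, "ct_correlations.csv")
  )
  summary_json <- list(
    seed = study$meta$seed,
    n_platforms = study$meta$n_platforms,
    image_types = study$meta$image_types,
    n_repeats = study$meta$n_repeats,
    repeat_policy = study$meta$repeat_policy,
    config = study$meta$config,
    config_hash = config_hash(study$meta$config),
    n_feature_records = nrow(study$features),
    panel_size = nrow(feature_panel())
  )
  json_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary_json, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, json_path))
}

# CT-number table: dispersion rollup (per 16 ROIs) stacked over agreement
# rollup (per platform pairs).
rbind_fill_ct <- function(ct) {
  d <- ct$dispersion_summary
  a <- ct$agreement_summary
  data.frame(
    image_type = c(d$image_type, a$image_type),
    block = c(rep("roi_dispersion", nrow(d)), rep("pair_agreement", nrow(a))),
    pct_meeting_cutoff_1 = c(d$pct_roi_cv_lt, a$pct_pair_icc_gt),
    metric_mean_1 = c(d$cv_mean_pct, a$icc_mean),
    pct_meeting_cutoff_2 = c(d$pct_roi_qcd_lt, a$pct_pair_ccc_gt),
    metric_mean_2 = c(d$qcd_mean_pct, a$ccc_mean),
    n = c(d$n_rois, a$n_pairs))
}

# Small deterministic FNV-1a hash of the serialized configuration.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
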