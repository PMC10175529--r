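# Robustness pipeline: aggregate the feature table exactly as the study
# design requires (per-platform test-retest repeatability; per-ROI
# dispersion across platforms; per-pair agreement across ROIs; CT-number
# correlation analysis).

panel_classes <- function() c("firstorder", "glcm", "gldm", "glrlm",
                              "glszm", "ngtdm")

# QCD is defined for n >= 4 observations; with fewer platforms the QCD
# columns are NA and never counted as reproducible.
safe_qcd <- function(v) if (length(v) >= 4L) as.numeric(qcd_pct(v)) else NA_real_

# Select one value per (platform, type, roi, feature) according to the
# repeat policy used for inter-platform analyses.
select_repeat <- function(features, repeat_policy = c("first", "second", "mean")) {
  repeat_policy <- match.arg(repeat_policy)
  if (repeat_policy == "mean") {
    agg <- stats::aggregate(
      value ~ platform_id + image_type + roi_id + feature_class + feature_name,
      data = features, FUN = mean)
    return(agg)
  }
  idx <- if (repeat_policy == "first") 1L else 2L
  out <- features[features$repeat_idx == idx, ]
  if (!nrow(out))
    stop_radrobust("no rows for repeat ", idx, " in feature table")
  out
}

# Dense value array [platform, roi, feature] for one image type, with
# canonical orderings; errors on missing cells.
feature_array <- function(df, panel = feature_panel()) {
  plats <- sort(unique(df$platform_id))
  rois <- sort(unique(df$roi_id))
  fkey <- paste(panel$feature_class, panel$feature_name, sep = "/")
  arr <- array(NA_real_,
               dim = c(length(plats), length(rois), nrow(panel)),
               dimnames = list(plats, rois, fkey))
  pi <- match(df$platform_id, plats)
  ri <- match(df$roi_id, rois)
  fi <- match(paste(df$feature_class, df$feature_name, sep = "/"), fkey)
  if (anyNA(fi))
    stop_radrobust("feature table contains features outside the 94-panel")
  arr[cbind(pi, ri, fi)] <- df$value
  if (anyNA(arr))
    stop_radrobust("incomplete feature table: missing (platform, roi, feature) cells")
  arr
}

#' Test-retest repeatability (Bland-Altman) summary
#'
#' For every (platform, image type, feature), a Bland-Altman analysis of the
#' 16 paired ROI values from scan and rescan. A feature is repeatable on a
#' platform when at least 90% of its 16 scan-rescan differences fall within
#' the 95% limits of agreement.
#'
#' @param features FeatureTable data frame containing repeats 1 and 2
#' @param cutoff required within-limits fraction (default 0.90)
#' @return list of class `repeatability_summary`: `per_feature` (one row per
#'   platform/type/feature with bias, limits, `frac_within`, `repeatable`,
#'   `p_bias`), `per_platform` (percent repeatable of the 94 features) and
#'   `summary` (mean +/- SD of that percent across platforms, per image
#'   type)
#' @export
run_repeatability <- function(features, cutoff = 0.90) {
  have <- unique(features$repeat_idx)
  if (!all(c(1L, 2L) %in% have))
    stop_radrobust("repeatability needs repeats 1 and 2; found: ",
                   paste(sort(have), collapse = ", "))
  r1 <- features[features$repeat_idx == 1L, ]
  r2 <- features[features$repeat_idx == 2L, ]
  keys <- c("platform_id", "image_type", "roi_id", "feature_class", "feature_name")
  m <- merge(r1[, c(keys, "value")], r2[, c(keys, "value")],
             by = keys, suffixes = c("_scan", "_rescan"))
  if (nrow(m) != nrow(r1))
    stop_radrobust("scan and rescan tables do not pair completely")
  grp <- paste(m$platform_id, m$image_type, m$feature_class, m$feature_name,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(m)), grp), function(ix) {
    sub <- m[ix, ]
    sub <- sub[order(sub$roi_id), ]
    ba <- bland_altman(sub$value_scan, sub$value_rescan, cutoff)
    data.frame(platform_id = sub$platform_id[1],
               image_type = sub$image_type[1],
               feature_class = sub$feature_class[1],
               feature_name = sub$feature_name[1],
               bias = ba$bias, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               frac_within = ba$frac_within, repeatable = ba$repeatable,
               p_bias = ba$p_bias, stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  rownames(per_feature) <- NULL
  per_platform <- stats::aggregate(
    repeatable ~ platform_id + image_type, data = per_feature,
    FUN = function(z) 100 * mean(z))
  names(per_platform)[3] <- "pct_repeatable"
  summary <- do.call(rbind, lapply(split(per_platform, per_platform$image_type),
    function(s) data.frame(image_type = s$image_type[1],
                           mean_pct = mean(s$pct_repeatable),
                           sd_pct = stats::sd(s$pct_repeatable),
                           n_platforms = nrow(s))))
  rownames(summary) <- NULL
  structure(list(per_feature = per_feature, per_platform = per_platform,
                 summary = summary, cutoff = cutoff),
            class = "repeatability_summary")
}

class_rollup <- function(cells, pass_col, metric_col) {
  mk <- function(name, sel) {
    sub <- cells[sel, ]
    fin <- is.finite(sub[[metric_col]])
    data.frame(feature_class = name,
               pct = 100 * mean(sub[[pass_col]]),
               metric_mean = mean(sub[[metric_col]][fin]),
               n_cells = nrow(sub))
  }
  tex <- cells$feature_class != "firstorder"
  out <- rbind(
    mk("First order", cells$feature_class == "firstorder"),
    mk("Texture", tex),
    mk("GLCM", cells$feature_class == "glcm"),
    mk("GLDM", cells$feature_class == "gldm"),
    mk("GLRLM", cells$feature_class == "glrlm"),
    mk("GLSZM", cells$feature_class == "glszm"),
    mk("NGTDM", cells$feature_class == "ngtdm"),
    mk("Overall", rep(TRUE, nrow(cells)))
  )
  rownames(out) <- NULL
  out
}

#' Inter-platform dispersion (CV / QCD) summary
#'
#' For every (image type, ROI, feature), the coefficient of variation and
#' quartile coefficient of dispersion of the feature value across platforms
#' (one scan per platform, chosen by `repeat_policy`). Strict cutoffs
#' classify reproducibility (CV < 10, QCD < 10 by default; degenerate
#' statistics fail). Percentages of reproducible features are aggregated per
#' ROI (mean +/- SD across the 16 ROIs), per feature (ROI-averaged heatmap
#' values) and per feature class; class metric means are reported as
#' fractions (CV of 50% appears as 0.50).
#'
#' @param features FeatureTable data frame covering >= 2 platforms
#' @param repeat_policy which repeat feeds inter-platform analyses
#' @param cutoff_pct reproducibility cutoff in percent
#' @return list of class `dispersion_summary` with elements `per_cell`,
#'   `per_roi`, `summary`, `per_feature`, `per_class`
#' @export
run_dispersion <- function(features, repeat_policy = "first",
                           cutoff_pct = 10) {
  sel <- select_repeat(features, repeat_policy)
  if (length(unique(sel$platform_id)) < 2L)
    stop_radrobust("dispersion analysis needs >= 2 platforms")
  panel <- feature_panel()
  types <- sort(unique(sel$image_type))
  cell_list <- list()
  for (ty in types) {
    arr <- feature_array(sel[sel$image_type == ty, ], panel)
    rois <- as.integer(dimnames(arr)[[2]])
    nf <- dim(arr)[3]
    cv_v <- qcd_v <- matrix(NA_real_, length(rois), nf)
    for (r in seq_along(rois)) for (f in seq_len(nf)) {
      v <- arr[, r, f]
      cv_v[r, f] <- as.numeric(cv_pct(v))
      qcd_v[r, f] <- safe_qcd(v)
    }
    cell_list[[ty]] <- data.frame(
      image_type = ty,
      roi_id = rep(rois, times = nf),
      feature_class = rep(panel$feature_class, each = length(rois)),
      feature_name = rep(panel$feature_name, each = length(rois)),
      cv_pct = as.vector(cv_v), qcd_pct = as.vector(qcd_v),
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_list)
  rownames(cells) <- NULL
  cells$pass_cv <- is.finite(cells$cv_pct) & cells$cv_pct < cutoff_pct
  cells$pass_qcd <- is.finite(cells$qcd_pct) & cells$qcd_pct < cutoff_pct
  per_roi <- do.call(rbind, lapply(
    split(cells, list(cells$image_type, cells$roi_id), drop = TRUE),
    function(s)
      data.frame(image_type = s$image_type[1], roi_id = s$roi_id[1],
                 pct_cv_lt = 100 * mean(s$pass_cv),
                 pct_qcd_lt = 100 * mean(s$pass_qcd))))
  per_roi <- per_roi[order(per_roi$image_type, per_roi$roi_id,
                         method = "radix"), ]
  rownames(per_roi) <- NULL
  summary <- do.call(rbind, lapply(split(per_roi, per_roi$image_type),
    function(s) data.frame(image_type = s$image_type[1],
                           mean_pct_cv = mean(s$pct_cv_lt),
                           sd_pct_cv = stats::sd(s$pct_cv_lt),
                           mean_pct_qcd = mean(s$pct_qcd_lt),
                           sd_pct_qcd = stats::sd(s$pct_qcd_lt),
                           n_rois = nrow(s))))
  rownames(summary) <- NULL
  per_feature <- do.call(rbind, lapply(
    split(cells, list(cells$image_type, cells$feature_class,
                      cells$feature_name), drop = TRUE), function(s)
      data.frame(image_type = s$image_type[1],
                 feature_class = s$feature_class[1],
                 feature_name = s$feature_name[1],
                 mean_cv_pct = mean(s$cv_pct[is.finite(s$cv_pct)]),
                 mean_qcd_pct = mean(s$qcd_pct[is.finite(s$qcd_pct)]),
                 pct_roi_cv_lt = 100 * mean(s$pass_cv),
                 pct_roi_qcd_lt = 100 * mean(s$pass_qcd))))
  per_feature <- per_feature[order(per_feature$image_type,
                                   per_feature$feature_class,
                                   per_feature$feature_name,
                                   method = "radix"), ]
  rownames(per_feature) <- NULL
  per_class <- do.call(rbind, lapply(split(cells, cells$image_type),
    function(s) {
      cv <- class_rollup(s, "pass_cv", "cv_pct")
      qc <- class_rollup(s, "pass_qcd", "qcd_pct")
      data.frame(image_type = s$image_type[1],
                 feature_class = cv$feature_class,
                 pct_cv_lt = cv$pct, cv_mean = cv$metric_mean / 100,
                 pct_qcd_lt = qc$pct, qcd_mean = qc$metric_mean / 100,
                 n_cells = cv$n_cells)
    }))
  rownames(per_class) <- NULL
  structure(list(per_cell = cells, per_roi = per_roi, summary = summary,
                 per_feature = per_feature, per_class = per_class,
                 cutoff_pct = cutoff_pct, repeat_policy = repeat_policy),
            class = "dispersion_summary")
}

#' Default shortlist of 14 clinically reported radiomics features
#'
#' A configurable placeholder list of widely reported biomarker features
#' (not a prescription): users studying a specific panel should supply
#' their own.
#' @return data frame with `feature_class`, `feature_name` (14 rows)
#' @export
default_feature_shortlist <- function() {
  data.frame(
    feature_class = c(rep("firstorder", 7), rep("glcm", 3),
                      rep("glrlm", 2), "glszm", "ngtdm"),
    feature_name = c("Mean", "Median", "Entropy", "Energy", "Uniformity",
                     "Skewness", "Kurtosis",
                     "Contrast", "Correlation", "JointEntropy",
                     "GrayLevelNonUniformity", "RunLengthNonUniformity",
                     "GrayLevelNonUniformity", "Coarseness"),
    stringsAsFactors = FALSE)
}

#' Pairwise inter-platform agreement (ICC / CCC) summary
#'
#' For every platform pair and feature, ICC(A,1) on the 16 x 2 matrix of ROI
#' values and Lin's CCC on the two 16-vectors. With `n` platforms there are
#' `choose(n, 2)` pairs per image type (45 pairs for 10 platforms, 90
#' comparisons over two image types). Degenerate statistics fail the
#' cutoff.
#'
#' @inheritParams run_dispersion
#' @param cutoff agreement cutoff (strict; default 0.90)
#' @param top_k size of the most-reproducible-feature ranking
#' @param shortlist data frame (`feature_class`, `feature_name`) of features
#'   reported separately
#' @return list of class `pairwise_summary` with `per_value` (pair x feature
#'   ICC/CCC), `per_pair` (percent above cutoff), `summary` (mean +/- SD
#'   across pairs), `per_class`, `ranking`, `top_features`,
#'   `shortlist_report`
#' @export
run_pairwise <- function(features, repeat_policy = "first", cutoff = 0.90,
                         top_k = 10L, shortlist = default_feature_shortlist()) {
  sel <- select_repeat(features, repeat_policy)
  if (length(unique(sel$platform_id)) < 2L)
    stop_radrobust("pairwise analysis needs >= 2 platforms")
  panel <- feature_panel()
  types <- sort(unique(sel$image_type))
  vals <- list()
  for (ty in types) {
    arr <- feature_array(sel[sel$image_type == ty, ], panel)
    plats <- as.integer(dimnames(arr)[[1]])
    prs <- utils::combn(seq_along(plats), 2)
    npair <- ncol(prs); nf <- dim(arr)[3]
    icc_m <- ccc_m <- deg_m <- matrix(NA_real_, npair, nf)
    for (q in seq_len(npair)) {
      a <- prs[1, q]; b <- prs[2, q]
      for (f in seq_len(nf)) {
        x <- arr[a, , f]; y <- arr[b, , f]
        ic <- icc_a1(cbind(x, y))
        cc <- ccc(x, y)
        icc_m[q, f] <- as.numeric(ic)
        ccc_m[q, f] <- as.numeric(cc)
        deg_m[q, f] <- is_degenerate(ic) || is_degenerate(cc)
      }
    }
    vals[[ty]] <- data.frame(
      image_type = ty,
      platform_a = rep(plats[prs[1, ]], times = nf),
      platform_b = rep(plats[prs[2, ]], times = nf),
      feature_class = rep(panel$feature_class, each = npair),
      feature_name = rep(panel$feature_name, each = npair),
      icc = as.vector(icc_m), ccc = as.vector(ccc_m),
      degenerate = as.vector(deg_m) > 0,
      stringsAsFactors = FALSE)
  }
  per_value <- do.call(rbind, vals)
  rownames(per_value) <- NULL
  per_value$pass_icc <- !per_value$degenerate & per_value$icc > cutoff
  per_value$pass_ccc <- !per_value$degenerate & per_value$ccc > cutoff
  pair_key <- paste(per_value$image_type, per_value$platform_a,
                    per_value$platform_b, sep = "\r")
  per_pair <- do.call(rbind, lapply(split(per_value, pair_key), function(s)
    data.frame(image_type = s$image_type[1], platform_a = s$platform_a[1],
               platform_b = s$platform_b[1],
               pct_icc_gt = 100 * mean(s$pass_icc),
               pct_ccc_gt = 100 * mean(s$pass_ccc))))
  per_pair <- per_pair[order(per_pair$image_type, per_pair$platform_a,
                             per_pair$platform_b, method = "radix"), ]
  rownames(per_pair) <- NULL
  summary <- do.call(rbind, lapply(split(per_pair, per_pair$image_type),
    function(s) data.frame(image_type = s$image_type[1],
                           mean_pct_icc = mean(s$pct_icc_gt),
                           sd_pct_icc = stats::sd(s$pct_icc_gt),
                           mean_pct_ccc = mean(s$pct_ccc_gt),
                           sd_pct_ccc = stats::sd(s$pct_ccc_gt),
                           n_pairs = nrow(s))))
  rownames(summary) <- NULL
  per_class <- do.call(rbind, lapply(split(per_value, per_value$image_type),
    function(s) {
      ic <- class_rollup(s, "pass_icc", "icc")
      cc <- class_rollup(s, "pass_ccc", "ccc")
      data.frame(image_type = s$image_type[1],
                 feature_class = ic$feature_class,
                 pct_icc_gt = ic$pct, icc_mean = ic$metric_mean,
                 pct_ccc_gt = cc$pct, ccc_mean = cc$metric_mean,
                 n_cells = ic$n_cells)
    }))
  rownames(per_class) <- NULL
  fk <- paste(per_value$image_type, per_value$feature_class,
              per_value$feature_name, sep = "\r")
  ranking <- do.call(rbind, lapply(split(per_value, fk), function(s)
    data.frame(image_type = s$image_type[1],
               feature_class = s$feature_class[1],
               feature_name = s$feature_name[1],
               mean_icc = mean(s$icc), mean_ccc = mean(s$ccc))))
  # rank by mean ICC, ties broken lexicographically for reproducibility
  ranking <- ranking[order(ranking$image_type, -ranking$mean_icc,
                           ranking$feature_class, ranking$feature_name,
                           method = "radix"), ]
  rownames(ranking) <- NULL
  top_features <- do.call(rbind, lapply(split(ranking, ranking$image_type),
    function(s) utils::head(s, top_k)))
  rownames(top_features) <- NULL
  sl_key <- paste(shortlist$feature_class, shortlist$feature_name)
  sl <- per_value[paste(per_value$feature_class,
                        per_value$feature_name) %in% sl_key, ]
  shortlist_report <- do.call(rbind, lapply(
    split(sl, paste(sl$image_type, sl$feature_class, sl$feature_name,
                    sep = "\r")),
    function(s) data.frame(image_type = s$image_type[1],
                           feature_class = s$feature_class[1],
                           feature_name = s$feature_name[1],
                           icc_min = min(s$icc), icc_mean = mean(s$icc),
                           icc_max = max(s$icc),
                           ccc_min = min(s$ccc), ccc_mean = mean(s$ccc),
                           ccc_max = max(s$ccc))))
  shortlist_report <- shortlist_report[order(
    shortlist_report$image_type, shortlist_report$feature_class,
    shortlist_report$feature_name, method = "radix"), ]
  rownames(shortlist_report) <- NULL
  structure(list(per_value = per_value, per_pair = per_pair,
                 summary = summary, per_class = per_class, ranking = ranking,
                 top_features = top_features,
                 shortlist_report = shortlist_report, cutoff = cutoff,
                 repeat_policy = repeat_policy),
            class = "pairwise_summary")
}

#' CT-number variability analysis and its link to first-order robustness
#'
#' The CT number of a ROI is its mean HU (identically the first-order Mean
#' feature). This analysis (i) summarizes inter-platform dispersion (CV,
#' QCD across platforms, per ROI) and pairwise agreement (ICC, CCC across
#' the 16 ROIs, per platform pair) of the CT numbers, and (ii) correlates
#' CT-number reproducibility with the percentage of the 19 first-order
#' features meeting the matching cutoff, via Spearman rank correlation
#' (n = 16 for ROI-level metrics, n = choose(platforms, 2) for pair-level
#' metrics).
#'
#' @inheritParams run_dispersion
#' @param cutoff_agree agreement cutoff for ICC/CCC
#' @return list of class `ct_number_report`: `per_roi`, `per_pair`,
#'   `dispersion_summary`, `agreement_summary` (Table-4-style rollups) and
#'   `correlations` (rho, rho-squared, p per metric and image type;
#'   `undefined` flags degenerate inputs)
#' @export
run_ct_analysis <- function(features, repeat_policy = "first",
                            cutoff_pct = 10, cutoff_agree = 0.90) {
  sel <- select_repeat(features, repeat_policy)
  fo <- sel[sel$feature_class == "firstorder", ]
  ct <- sel[sel$feature_class == "firstorder" & sel$feature_name == "Mean", ]
  if (!nrow(ct)) stop_radrobust("feature table lacks the first-order Mean feature")
  types <- sort(unique(sel$image_type))
  per_roi <- per_pair <- corr <- list()
  for (ty in types) {
    ct_ty <- ct[ct$image_type == ty, ]
    plats <- sort(unique(ct_ty$platform_id))
    rois <- sort(unique(ct_ty$roi_id))
    cmat <- matrix(NA_real_, length(plats), length(rois))
    cmat[cbind(match(ct_ty$platform_id, plats),
               match(ct_ty$roi_id, rois))] <- ct_ty$value
    cvv <- apply(cmat, 2, function(v) as.numeric(cv_pct(v)))
    qcv <- apply(cmat, 2, safe_qcd)
    # first-order pass percentages per ROI
    fo_ty <- fo[fo$image_type == ty, ]
    fo_pct_cv <- fo_pct_qcd <- numeric(length(rois))
    for (r in seq_along(rois)) {
      sub <- fo_ty[fo_ty$roi_id == rois[r], ]
      byf <- split(sub$value, sub$feature_name)
      cvs <- vapply(byf, function(v) as.numeric(cv_pct(v)), numeric(1))
      qcs <- vapply(byf, safe_qcd, numeric(1))
      fo_pct_cv[r] <- 100 * mean(is.finite(cvs) & cvs < cutoff_pct)
      fo_pct_qcd[r] <- 100 * mean(is.finite(qcs) & qcs < cutoff_pct)
    }
    per_roi[[ty]] <- data.frame(
      image_type = ty, roi_id = rois, ct_cv_pct = cvv, ct_qcd_pct = qcv,
      firstorder_pct_cv_lt = fo_pct_cv, firstorder_pct_qcd_lt = fo_pct_qcd)
    prs <- utils::combn(seq_along(plats), 2)
    icc_v <- ccc_v <- fo_icc <- fo_ccc <- numeric(ncol(prs))
    fo_arr <- feature_array(fo_ty, panel = unique(
      data.frame(feature_class = "firstorder",
                 feature_name = sort(unique(fo_ty$feature_name)))))
    for (q in seq_len(ncol(prs))) {
      a <- prs[1, q]; b <- prs[2, q]
      ic <- icc_a1(cbind(cmat[a, ], cmat[b, ]))
      cc <- ccc(cmat[a, ], cmat[b, ])
      icc_v[q] <- as.numeric(ic); ccc_v[q] <- as.numeric(cc)
      ics <- ccs <- logical(dim(fo_arr)[3])
      for (f in seq_len(dim(fo_arr)[3])) {
        x <- fo_arr[a, , f]; y <- fo_arr[b, , f]
        i2 <- icc_a1(cbind(x, y)); c2 <- ccc(x, y)
        ics[f] <- !is_degenerate(i2) && as.numeric(i2) > cutoff_agree
        ccs[f] <- !is_degenerate(c2) && as.numeric(c2) > cutoff_agree
      }
      fo_icc[q] <- 100 * mean(ics); fo_ccc[q] <- 100 * mean(ccs)
    }
    per_pair[[ty]] <- data.frame(
      image_type = ty, platform_a = plats[prs[1, ]],
      platform_b = plats[prs[2, ]], ct_icc = icc_v, ct_ccc = ccc_v,
      firstorder_pct_icc_gt = fo_icc, firstorder_pct_ccc_gt = fo_ccc)
    sp <- function(x, y) {
      # too few points (e.g. a single platform pair) or missing metrics
      # leave the correlation undefined rather than failing the report
      if (length(x) < 4L || anyNA(x) || anyNA(y))
        return(data.frame(rho = NA_real_, rho_squared = NA_real_,
                          p = NA_real_, n = length(x), undefined = TRUE))
      tryCatch({
        r <- spearman_cor(x, y)
        data.frame(rho = r$rho, rho_squared = r$rho_squared, p = r$p,
                   n = r$n, undefined = FALSE)
      }, radrobust_degenerate_stat = function(e)
        data.frame(rho = NA_real_, rho_squared = NA_real_, p = NA_real_,
                   n = length(x), undefined = TRUE))
    }
    corr[[ty]] <- cbind(
      data.frame(image_type = ty,
                 metric = c("cv", "qcd", "icc", "ccc")),
      rbind(sp(cvv, fo_pct_cv), sp(qcv, fo_pct_qcd),
            sp(icc_v, fo_icc), sp(ccc_v, fo_ccc)))
  }
  per_roi <- do.call(rbind, per_roi); rownames(per_roi) <- NULL
  per_pair <- do.call(rbind, per_pair); rownames(per_pair) <- NULL
  correlations <- do.call(rbind, corr); rownames(correlations) <- NULL
  dispersion_summary <- do.call(rbind, lapply(split(per_roi, per_roi$image_type),
    function(s) data.frame(
      image_type = s$image_type[1],
      pct_roi_cv_lt = 100 * mean(is.finite(s$ct_cv_pct) &
                                   s$ct_cv_pct < cutoff_pct),
      cv_mean_pct = mean(s$ct_cv_pct[is.finite(s$ct_cv_pct)]),
      pct_roi_qcd_lt = 100 * mean(is.finite(s$ct_qcd_pct) &
                                    s$ct_qcd_pct < cutoff_pct),
      qcd_mean_pct = mean(s$ct_qcd_pct[is.finite(s$ct_qcd_pct)]),
      n_rois = nrow(s))))
  rownames(dispersion_summary) <- NULL
  agreement_summary <- do.call(rbind, lapply(split(per_pair, per_pair$image_type),
    function(s) data.frame(
      image_type = s$image_type[1],
      pct_pair_icc_gt = 100 * mean(s$ct_icc > cutoff_agree),
      icc_mean = mean(s$ct_icc),
      pct_pair_ccc_gt = 100 * mean(s$ct_ccc > cutoff_agree),
      ccc_mean = mean(s$ct_ccc),
      n_pairs = nrow(s))))
  rownames(agreement_summary) <- NULL
  structure(list(per_roi = per_roi, per_pair = per_pair,
                 dispersion_summary = dispersion_summary,
                 agreement_summary = agreement_summary,
                 correlations = correlations,
                 cutoff_pct = cutoff_pct, cutoff_agree = cutoff_agree),
            class = "ct_number_report")
}

#' Run the complete robustness study
#'
#' Simulate -> register -> extract -> analyze, returning all four summaries
#' and, when `out_dir` is given, writing the report files.
#'
#' @inheritParams simulate_features
#' @param repeat_policy repeat used for inter-platform analyses
#' @param out_dir optional report directory
#' @return list of class `robustness_study`: `features`, `scans`,
#'   `repeatability`, `dispersion`, `pairwise`, `ct`, `meta`
#' @export
run_robustness_study <- function(spec = default_phantom_spec(),
                                 platforms = default_platform_models(),
                                 image_types = image_types_all(),
                                 n_repeats = 2L, seed = 1L,
                                 config = extraction_config(),
                                 repeat_policy = "first", out_dir = NULL) {
  sim <- simulate_features(spec, platforms, image_types, n_repeats, seed,
                           config)
  res <- structure(
    list(features = sim$features, scans = sim$scans,
         repeatability = run_repeatability(sim$features),
         dispersion = run_dispersion(sim$features, repeat_policy),
         pairwise = run_pairwise(sim$features, repeat_policy),
         ct = run_ct_analysis(sim$features, repeat_policy),
         meta = list(seed = seed, n_platforms = length(platforms),
                     image_types = image_types, n_repeats = n_repeats,
                     repeat_policy = repeat_policy, config = config)),
    class = "robustness_study")
  if (!is.null(out_dir)) report_robustness(res, out_dir)
  res
}
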