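#' Run the full particle metrology pipeline on one micrograph
#'
#' Segmentation (dynamic thresholding), contour extraction, convexity
#' filtering of aggregates and truncated border particles, Hu-moment shape
#' parameterization, average-linkage clustering with automatic selection
#' of the number of shape classes, and the per-class summary table.
#'
#' @param img A [gray_image].
#' @param threshold_cfg A [threshold_config]; `NULL` uses defaults with a
#'   window of four times the median particle diameter estimated from a
#'   first segmentation pass.
#' @param solidity_threshold Convexity cutoff for aggregate rejection.
#' @param feature Clustering feature: `"log_hu"` (signed-log Hu with
#'   noise-floor masking and standardization, see [feature_matrix()]) or
#'   `"hu"` (raw invariants).
#' @param mask_floor,standardize Feature preparation, see
#'   [feature_matrix()].
#' @param k_max Largest number of clusters evaluated.
#' @param sd_type Standard-deviation convention for the report.
#' @return List of class `nanoshapes_result` with elements `mask`,
#'   `contours`, `filter` (kept/rejected/verdicts), `records` (kept,
#'   non-degenerate particles with cluster labels), `cvi` (the
#'   [select_k()] profile), `report` (per-cluster summary), and `config`.
#' @export
analyze_micrograph <- function(img,
                               threshold_cfg = NULL,
                               solidity_threshold = 0.96,
                               feature = c("log_hu", "hu"),
                               mask_floor = 1e-5,
                               standardize = TRUE,
                               k_max = 10L,
                               sd_type = c("population", "sample")) {
  stopifnot(inherits(img, "gray_image"))
  feature <- match.arg(feature)
  sd_type <- match.arg(sd_type)
  if (is.null(threshold_cfg)) threshold_cfg <- auto_threshold_config(img)
  mask <- dynamic_threshold(img, threshold_cfg)
  contours <- trace_contours(mask)
  if (!length(contours)) stop_input("no particles segmented")
  filt <- convexity_filter(contours, solidity_threshold)
  if (!length(filt$kept)) stop_input("no particles kept after filtering")
  sol <- filt$verdicts$solidity[filt$verdicts$kept]
  records <- shape_records(filt$kept, img$nm_per_px, solidity = sol)
  feats <- feature_matrix(records, feature, mask_floor = mask_floor,
                          standardize = standardize)
  records <- records[attr(feats, "row_index"), , drop = FALSE]
  d <- stats::dist(feats)
  tree <- average_linkage(d)
  cvi <- select_k(tree, feats, d, k_max = k_max)
  records$cluster <- cvi$labels
  report <- summarize_clusters(records, cvi$labels, sd_type = sd_type)
  structure(list(
    mask = mask, contours = contours, filter = filt, records = records,
    cvi = cvi, report = report,
    config = list(threshold_cfg = threshold_cfg,
                  solidity_threshold = solidity_threshold,
                  feature = feature, mask_floor = mask_floor,
                  standardize = standardize, k_max = k_max,
                  sd_type = sd_type, nm_per_px = img$nm_per_px,
                  polarity = img$polarity)
  ), class = "nanoshapes_result")
}

#' @export
print.nanoshapes_result <- function(x, ...) {
  cat(sprintf(
    "<nanoshapes_result> %d contours, %d kept, %d clusters (rule: %s)\n",
    length(x$contours), nrow(x$records), x$cvi$chosen_k,
    x$cvi$selection_rule_used))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Threshold configuration tuned to the particle scale of an image
#'
#' Runs a coarse first segmentation pass (box-mean window of 1/4 of the
#' image side) to estimate the median particle equivalent diameter, then
#' sets the final window to about four times that diameter, so the local
#' background statistic is dominated by background rather than by any one
#' particle.
#'
#' @param img A [gray_image].
#' @return A [threshold_config].
#' @export
auto_threshold_config <- function(img) {
  side <- min(dim(img$pixels))
  w0 <- as.integer(side %/% 4)
  if (w0 %% 2L == 0L) w0 <- w0 + 1L
  cfg0 <- threshold_config(window_px = w0, local_statistic = "mean")
  diam <- tryCatch({
    mask <- dynamic_threshold(img, cfg0)
    contours <- trace_contours(mask)
    areas <- vapply(contours, function(ct) ct$area_px, numeric(1))
    areas <- areas[areas >= cfg0$min_area_px]
    if (!length(areas)) NA_real_ else 2 * sqrt(stats::median(areas) / pi)
  }, error = function(e) NA_real_)
  w <- if (is.na(diam)) w0 else as.integer(round(4 * diam))
  w <- max(15L, min(w, side - 2L))
  if (w %% 2L == 0L) w <- w + 1L
  threshold_config(window_px = w)
}
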