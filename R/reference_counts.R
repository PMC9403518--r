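#' Benchmark detection tallies for the six band combinations
#'
#' Published per-combination tree-detection tallies from a UAV oil-tea
#' orchard benchmark (235 reference crowns): the number of predicted crowns,
#' true/false positives, omissions, and the reported IoU, precision, recall
#' and F1 percentages. Bundled so the detection-metric formulas can be
#' exercised against known printed values and re-reported.
#'
#' @return data frame with columns `combination`, `n_predicted`, `tp`, `fp`,
#'   `fn`, `iou_pct`, `precision_pct`, `recall_pct`, `f1_pct`.
#' @examples
#' counts <- reference_detection_counts()
#' with(counts[counts$combination == "RGB-CHM", ],
#'      detection_metrics(detection_counts(tp, fp, fn)))
#' @export
reference_detection_counts <- function() {
  utils::read.csv(system.file("extdata", "band_combo_counts.csv",
                              package = "crownscope"),
                  stringsAsFactors = FALSE)
}
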