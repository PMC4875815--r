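#' Bundled reference tables for the 33-species Furnariides study
#'
#' Two published summary tables for 33 sexually monochromatic (to humans)
#' Amazonian Furnariides are bundled as pipeline inputs:
#' * `"patch_counts"` — per-species dichromatic-patch counts at the 1.0,
#'   1.5, and 2.0 jnd thresholds under the ideal and habitat-matched (real)
#'   illuminant scenarios, with light-level group and number of patches
#'   measured. Columns follow the [threshold_summary()] convention, so the
#'   aggregation functions consume the table directly.
#' * `"delta_aicc"` — per-descriptor ΔAICc values for the BM, single-optimum
#'   OU, and light-regime OU models, with the reported significance of the
#'   likelihood ratio test against the simpler model, for
#'   [select_model_from_table()].
#'
#' @param which `"patch_counts"` or `"delta_aicc"`.
#' @return A data.frame.
#' @export
furnariides_reference <- function(which = c("patch_counts", "delta_aicc")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("furnariides_", which, ".tsv"),
                   package = "plumalight", mustWork = TRUE)
  df <- utils::read.table(f, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}
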