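# Bundled reference dataset: published AOC values (mean +/- SD across
# replicates) from a ROS1-rearranged NSCLC TKI screen comparing a wild-type
# line with three kinase-domain mutant lines (G2032R, L2026M, S1986Y) in 2D
# monolayer and 3D spheroid culture, across five TKIs. These printed values
# serve as *inputs* to the fold-change worked examples; the package does not
# (and cannot, without the wet-lab screen) reproduce them from scratch.

#' Published reference AOC table
#'
#' AOC (area over the NGR curve) values from a ROS1 TKI-resistance screen:
#' wild-type plus G2032R / L2026M / S1986Y mutant lines, five TKIs, 2D and
#' 3D culture. Used as inputs to [fold_change()] worked examples.
#'
#' @return data.frame with columns `culture`, `cell_line`, `drug`,
#'   `AOC_mean`, `AOC_sd`.
#' @export
published_aoc_reference <- function() {
  path <- system.file("extdata", "reference_aoc_published.csv",
                      package = "ngrscreen")
  if (!nzchar(path)) abort_io("bundled reference AOC table not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
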