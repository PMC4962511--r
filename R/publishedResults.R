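#' Published online benchmark results bundled with the package
#'
#' Per-subject online results of the nine-subject reference study of this
#' paradigm: optimal averaging count, mean accuracy (percent) and ITR
#' (bits/min) for both omission patterns. These printed cells serve as
#' inputs for the ITR-arithmetic checks ([table1Check()]); the package does
#' not claim to regenerate them from EEG.
#'
#' @return data.frame with columns `subject`, `averaging_times`, `pattern`
#'   (`"black"`/`"white"`), `accuracy_pct`, `itr_bits_min`.
#' @examples
#' pub <- publishedResults()
#' mean(pub$accuracy_pct[pub$pattern == "black"])  # 79.29
#' @export
publishedResults <- function() {
  utils::read.csv(system.file("extdata", "online_results_published.csv",
                              package = "ssvepOSP"))
}
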