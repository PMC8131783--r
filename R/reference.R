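#' Published reference values from the Shiretoko Rusha-area bear study
#'
#' Summary numbers published for the long-term brown-bear monitoring study on
#' the Shiretoko Peninsula (Rusha area, 2012--2018) that this package's
#' pipeline is designed around. They serve as reference inputs for
#' consistency checks and for anchoring the synthetic generator: monthly scat
#' collection totals and the printed study total; monthly point-frame sample
#' sizes and their printed total; the thirteen published AICc differences of
#' the candidate body-condition models; the published August pine-nut EDC
#' values of the high-consumption years with the all-year mean; the published
#' September salmon EDC values of the high-consumption years; and the
#' published log-scale reproductive-status effect.
#'
#' @return named list of reference vectors.
#' @export
shiretoko_reference <- function() {
  list(
    monthly_scats = c(June = 267, July = 403, August = 552,
                      September = 507, October = 350),
    total_scats = 2079,
    pointframe_monthly = c(June = 242, July = 308, August = 476,
                           September = 466, October = 272),
    pointframe_total = 1764,
    visual_total = 315,
    delta_aicc = c(0.0, 0.7, 3.0, 3.1, 4.8, 5.2, 5.8, 5.8,
                   21.2, 25.4, 27.1, 27.4, 29.0),
    top_weights = c(0.4, 0.3),
    pine_august_high = c(`2013` = 47.4, `2014` = 47.5, `2016` = 47.3,
                         `2018` = 42.9),
    pine_august_mean = 34.9,
    salmon_september_high = c(`2013` = 54.4, `2016` = 65.4, `2018` = 72.2),
    diet1_years = c(2013, 2016, 2018),
    diet2_years = c(2012, 2015, 2017),
    rst_offset = -0.025
  )
}
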