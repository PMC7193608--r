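#' Bundled in vivo strip-field summary measurements
#'
#' Intracranial field magnitudes (mV/mm) recorded with a subdural strip
#' in beagles at 1 kHz stimulation and 1-5 mA, under three conditions:
#' scalp-applied current (TES), skull-applied current with the scalp
#' retracted (SES, scalp removed) and skull-applied current with the
#' scalp closed over the electrode. These published summary values serve
#' as the worked-example input for the shunting-ratio analysis: the
#' scalp-removed/TES ratio is about 4, the scalp-closed/TES ratio about
#' 3, and closing the scalp costs 20-30% of the field.
#'
#' @return Data frame with columns `condition` (`TES`, `SES-removed`,
#'   `SES-closed`), `intensity_mA` and `field_mV_mm`.
#' @examples
#' ref <- strip_field_reference()
#' split(ref$field_mV_mm, ref$condition)
#' @export
strip_field_reference <- function() {
  data.frame(
    condition = rep(c("TES", "SES-removed", "SES-closed"), each = 5),
    intensity_mA = rep(1:5, 3),
    field_mV_mm = c(0.348, 0.687, 1.019, 1.362, 1.704,
                    1.395, 2.783, 4.166, 5.534, 6.877,
                    0.996, 1.981, 2.965, 3.953, 4.928),
    stringsAsFactors = FALSE)
}

#' Reported per-milliamp dose slopes
#'
#' Median per-milliamp intracranial field slopes from the in vivo
#' dose-response recordings: 0.20 mV/mm/mA for scalp-applied (TES) and
#' 0.85 mV/mm/mA for skull-applied (SES) stimulation. Feeding these into
#' [required_current()] reproduces the reported currents needed to reach
#' the 1 mV/mm neuronal-effect threshold (5.0 and 1.2 mA).
#'
#' @return Named numeric vector (mV/mm/mA).
#' @export
dose_slope_reference <- function() {
  c(TES = 0.20, SES = 0.85)
}

#' Convert reference measurements into field-measurement objects
#'
#' Wraps each row of a summary table (as from [strip_field_reference()])
#' into the `field_measurement` structure used by
#' [per_milliamp_slope()] and [shunting_ratio()].
#'
#' @param df data frame with columns `condition`, `intensity_mA`,
#'   `field_mV_mm` and optionally `frequency_hz`.
#' @return List of `field_measurement` objects.
#' @export
as_field_measurements <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(pair_fields_mV_mm = df$field_mV_mm[i],
                   summary_mV_mm = df$field_mV_mm[i],
                   p2p_mV = NA_real_,
                   intensity_mA = df$intensity_mA[i],
                   frequency_hz = if ("frequency_hz" %in% names(df))
                     df$frequency_hz[i] else NA_real_,
                   condition = df$condition[i],
                   montage_id = NA_character_),
              class = "field_measurement")
  })
}
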