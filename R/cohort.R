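#' @keywords internal
"_PACKAGE"

#' Harmonic variable names
#'
#' Column names of the twelve normalized harmonic power variables, in
#' harmonic order: `P_FF` (fundamental), `P_2H`, ..., `P_12H`.
#'
#' @return Character vector of length 12.
#' @export
harmonic_variables <- function() {
  c("P_FF", paste0("P_", 2:12, "H"))
}

# Embedded cohort: clinical/operational data for the 11 HVAD recordings.
# HW-D1/D2 and HW-F1/F2 are repeat recordings of the same patients; each
# recording is treated as an independent row (a known leakage caveat for
# the cross-validation protocol, see the methods vignette).
.hvad_clinical <- function() {
  df <- read.csv(text = "patient_id,ldh,pump_speed,pump_fundamental,pump_power,hvad_age,outcome
HW-A,190,2560,42.67,3.1,1853,NO
HW-B,348,2600,43.33,3.6,1597,NO
HW-C,213,2620,43.67,3.9,959,NO
HW-D1,4458,2540,42.33,7.0,2258,YES
HW-D2,3585,2540,42.33,12.2,2262,YES
HW-E,275,2660,44.33,3.9,1472,NO
HW-F1,292,2700,45,4.7,818,NO
HW-F2,3330,2800,46.67,6.2,1253,YES
HW-G,253,2600,43.33,3.7,1444,NO
HW-H,154,2700,45,4.1,2034,NO
HW-I,311,2800,46.67,4.8,3461,NO",
    stringsAsFactors = FALSE)
  df
}

# Embedded cohort: normalized harmonic power profiles (dB, 0 dB sum) for the
# same 11 recordings, to the printed 4 decimal places.
.hvad_profiles <- function() {
  df <- read.csv(text = "patient_id,P_FF,P_2H,P_3H,P_4H,P_5H,P_6H,P_7H,P_8H,P_9H,P_10H,P_11H,P_12H,outcome
HW-A,-0.0709,-24.5376,-42.7136,-19.0600,-46.5642,-47.9261,-50.3521,-40.3536,-48.5813,-49.5637,-49.7301,-46.0885,NO
HW-B,-3.5042,-8.7993,-22.1829,-3.8459,-29.3450,-34.5989,-35.1714,-33.5871,-36.9125,-37.9513,-34.1700,-34.3805,NO
HW-C,-0.0157,-28.4070,-36.9364,-27.5495,-43.5894,-46.8234,-46.3518,-41.9392,-54.6824,-53.3172,-54.4150,-44.9496,NO
HW-D1,-1.4809,-10.6403,-23.9485,-7.2912,-27.4535,-26.5844,-27.9201,-27.7818,-30.2167,-30.1508,-28.6569,-28.2910,YES
HW-D2,-0.2563,-13.8401,-21.2248,-22.7990,-32.9389,-33.3901,-33.4354,-34.9352,-34.0925,-34.6498,-34.4029,-34.1315,YES
HW-E,-0.1489,-28.2704,-31.7187,-15.5442,-32.5102,-33.0632,-33.5801,-34.0536,-33.0876,-34.0219,-32.7320,-34.8687,NO
HW-F1,-0.0551,-24.2720,-37.3658,-20.9277,-39.5058,-40.5999,-40.6656,-40.6629,-41.5667,-42.2361,-42.7583,-42.0199,NO
HW-F2,-0.2059,-14.6536,-27.4858,-20.0872,-41.3635,-43.3848,-43.0292,-37.5080,-45.6187,-45.9965,-45.1245,-45.2195,YES
HW-G,-4.1746,-13.2433,-22.2679,-2.6211,-22.8487,-26.5414,-32.6231,-20.9933,-39.5206,-41.2349,-41.5568,-29.1602,NO
HW-H,-0.0583,-30.1282,-36.7897,-19.3974,-39.3128,-40.2933,-41.0277,-39.5763,-42.1642,-41.5989,-42.2536,-40.8596,NO
HW-I,-9.1241,-23.4190,-27.7626,-0.6080,-32.2090,-35.7505,-40.1552,-30.3619,-42.9335,-44.7409,-46.1173,-41.1794,NO",
    stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Load the embedded HVAD cohort
#'
#' Returns the published 11-recording HVAD cohort compiled into the package:
#' clinical/operational metadata (LDH in U/L, pump speed in rpm, pump
#' fundamental frequency in Hz, pump power in W, device age in days, and the
#' thrombosis diagnosis) and the normalized harmonic power profiles (`P_FF`
#' through `P_12H`, in dB relative to the FF-12H total so that the linearized
#' powers of each row sum to 1). Thrombosis `YES` is the positive class
#' throughout the package; the cohort contains 3 `YES` and 8 `NO` recordings.
#'
#' @return A list with two data frames, `clinical` and `profiles`, each with
#'   11 rows keyed by the same `patient_id` set.
#' @examples
#' cohort <- load_embedded_cohort()
#' table(cohort$profiles$outcome)
#' @export
load_embedded_cohort <- function() {
  list(clinical = .hvad_clinical(), profiles = .hvad_profiles())
}

#' Validate a harmonic power feature table
#'
#' Checks the schema used throughout the package: a `patient_id` column,
#' the twelve harmonic power columns `P_FF`...`P_12H`, and an `outcome`
#' column with values in `{YES, NO}`; `patient_id` must be unique.
#'
#' @param profiles Data frame to validate.
#' @param require_outcome Require the `outcome` column (default `TRUE`).
#' @return The validated data frame, invisibly.
#' @export
validate_profiles <- function(profiles, require_outcome = TRUE) {
  stopifnot(is.data.frame(profiles))
  needed <- c("patient_id", harmonic_variables(), if (require_outcome) "outcome")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0)
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(profiles), c("patient_id", harmonic_variables(), "outcome"))
  if (length(extra) > 0)
    stop("feature table has unexpected column(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(profiles$patient_id))
    stop("duplicate patient_id in feature table: ",
         paste(unique(profiles$patient_id[duplicated(profiles$patient_id)]), collapse = ", "))
  if ("outcome" %in% names(profiles) && !all(profiles$outcome %in% c("YES", "NO")))
    stop("outcome must be 'YES' or 'NO'")
  invisible(profiles)
}
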