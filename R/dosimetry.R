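# AAPM TG-204 exponential fit of the 32-cm-phantom size conversion factor
# as a function of effective diameter (cm).
TG204_A32 <- 3.704369
TG204_B32 <- 0.03671937
TG204_RANGE_CM <- c(6, 55)

#' Scan dose model
#'
#' Radiation-dose bookkeeping for a protocol: one reference per-volume
#' CTDIvol (32-cm phantom) at a reference tube current, a table of acquired
#' volumes, the cranio-caudal scan length, the subject's effective diameter
#' and the DLP-to-effective-dose coefficient.  Only linear mA scaling is
#' supported; all volumes must share the reference kVp.
#'
#' @param ref_ctdi_mgy Per-volume CTDIvol32 (mGy) at the reference settings.
#' @param ref_ma,ref_kvp Reference tube current (mA) and voltage (kVp).
#' @param volumes Data frame with columns `component`, `kvp`, `ma`, `count`.
#' @param scan_length_cm Cranio-caudal coverage in cm.
#' @param effective_diameter_cm Subject effective diameter in cm.
#' @param k_msv_per_mgy_cm DLP conversion coefficient (mSv per mGy.cm);
#'   standard chest value 0.014.
#'
#' @return An object of class `fpa_dose_model`.
#' @export
scan_dose_model <- function(ref_ctdi_mgy, ref_ma, ref_kvp, volumes,
                            scan_length_cm = 16, effective_diameter_cm = 23,
                            k_msv_per_mgy_cm = 0.014) {
  volumes <- as_tibble(as.data.frame(volumes))
  need <- c("component", "kvp", "ma", "count")
  if (!all(need %in% names(volumes)))
    abort("`volumes` needs columns component, kvp, ma, count.")
  if (ref_ctdi_mgy <= 0 || ref_ma <= 0 || scan_length_cm <= 0 ||
      k_msv_per_mgy_cm <= 0 || any(volumes$ma <= 0) || any(volumes$count < 0))
    abort("doses, currents, lengths and coefficients must be positive.")
  if (any(volumes$kvp != ref_kvp))
    abort(sprintf("kVp scaling unsupported: volume at %g kVp vs reference %g kVp.",
                  volumes$kvp[volumes$kvp != ref_kvp][1], ref_kvp))
  structure(list(ref_ctdi_mgy = ref_ctdi_mgy, ref_ma = ref_ma,
                 ref_kvp = ref_kvp, volumes = volumes,
                 scan_length_cm = scan_length_cm,
                 effective_diameter_cm = effective_diameter_cm,
                 k = k_msv_per_mgy_cm),
            class = "fpa_dose_model")
}

#' Low-dose protocol dose model
#'
#' The four-volume protocol: rest V1 at low current plus rest V2 at
#' diagnostic current (doubling as the CTA), and stress V1/V2 both at low
#' current.
#'
#' @param ref_ctdi_mgy Per-volume CTDIvol32 at `ref_ma` (default 4.6 mGy at
#'   200 mA, 100 kVp).
#' @param ref_ma,ref_kvp Reference settings.
#' @param low_ma,high_ma Perfusion and CTA tube currents.
#' @param ... Passed to [scan_dose_model()].
#' @return An `fpa_dose_model`.
#' @export
lowdose_protocol_model <- function(ref_ctdi_mgy = 4.6, ref_ma = 200,
                                   ref_kvp = 100, low_ma = 50, high_ma = 200,
                                   ...) {
  vols <- tibble(
    component = c("rest+CTA", "rest+CTA", "stress", "stress"),
    kvp = ref_kvp,
    ma = c(low_ma, high_ma, low_ma, low_ma),
    count = 1L
  )
  scan_dose_model(ref_ctdi_mgy, ref_ma, ref_kvp, vols, ...)
}

#' Reference-standard protocol dose model
#'
#' Two dynamic acquisitions (rest with CTA, stress) of `n_volumes`
#' consecutive volume scans each, all at the diagnostic current.
#'
#' @inheritParams lowdose_protocol_model
#' @param n_volumes Volumes per dynamic acquisition (default 20).
#' @return An `fpa_dose_model`.
#' @export
reference_protocol_model <- function(ref_ctdi_mgy = 4.6, ref_ma = 200,
                                     ref_kvp = 100, n_volumes = 20L, ...) {
  vols <- tibble(
    component = c("rest+CTA", "stress"),
    kvp = ref_kvp,
    ma = ref_ma,
    count = as.integer(n_volumes)
  )
  scan_dose_model(ref_ctdi_mgy, ref_ma, ref_kvp, vols, ...)
}

#' Per-volume CTDIvol at a tube current
#'
#' Linear mA scaling from the reference:
#' `CTDIvol(mA) = ref_ctdi * mA / ref_ma`.
#'
#' @param model An [scan_dose_model()].
#' @param ma Tube current in mA (> 0).
#' @param kvp Tube voltage; must equal the reference (no kVp scaling).
#' @return CTDIvol32 in mGy.
#' @export
ctdi_per_volume <- function(model, ma, kvp = model$ref_kvp) {
  stopifnot(inherits(model, "fpa_dose_model"))
  if (ma <= 0) abort("`ma` must be > 0.")
  if (kvp != model$ref_kvp)
    abort("kVp scaling unsupported: query kVp differs from the reference.")
  model$ref_ctdi_mgy * ma / model$ref_ma
}

#' Protocol CTDIvol by component
#'
#' Sums per-volume CTDIvol over the model's volume table.
#'
#' @param model An [scan_dose_model()].
#' @return Tibble with one row per component plus a `total` row:
#'   `component`, `n_volumes`, `ctdi_mgy`.
#' @export
protocol_ctdi <- function(model) {
  stopifnot(inherits(model, "fpa_dose_model"))
  v <- model$volumes
  per <- v |>
    dplyr::mutate(dose = ctdi_per_volume(model, 1) * .data$ma * .data$count) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(n_volumes = sum(.data$count),
                     ctdi_mgy = sum(.data$dose), .groups = "drop")
  dplyr::bind_rows(per, tibble(component = "total",
                               n_volumes = sum(per$n_volumes),
                               ctdi_mgy = sum(per$ctdi_mgy)))
}

#' TG-204 size conversion factor (32-cm phantom)
#'
#' Exponential fit `f(D) = a * exp(-b * D)` of the size-specific dose
#' estimate conversion factor versus effective diameter `D` (cm), referenced
#' to the 32-cm body phantom.  Monotone decreasing; equals 1 near
#' `D = ln(a)/b` (about 35.7 cm).
#'
#' @param effective_diameter_cm Effective diameter in cm, within the
#'   published fit range (6-55 cm).
#' @return Dimensionless conversion factor.
#' @export
ssde_factor <- function(effective_diameter_cm) {
  if (any(effective_diameter_cm < TG204_RANGE_CM[1]) ||
      any(effective_diameter_cm > TG204_RANGE_CM[2]))
    abort(sprintf("effective diameter outside the %g-%g cm fit range.",
                  TG204_RANGE_CM[1], TG204_RANGE_CM[2]))
  TG204_A32 * exp(-TG204_B32 * effective_diameter_cm)
}

#' Effective dose from CTDIvol
#'
#' `DLP = CTDIvol * scan length`; `E = k * DLP`.  No rounding is applied;
#' round at presentation.
#'
#' @param ctdi_mgy CTDIvol in mGy.
#' @param length_cm Scan length in cm.
#' @param k DLP conversion coefficient in mSv per mGy.cm (chest: 0.014).
#' @return Tibble with `dlp_mgy_cm` and `effective_dose_msv`.
#' @export
effective_dose <- function(ctdi_mgy, length_cm, k = 0.014) {
  if (any(ctdi_mgy < 0) || length_cm <= 0 || k <= 0)
    abort("dose inputs must be non-negative (lengths/coefficients positive).")
  dlp <- ctdi_mgy * length_cm
  tibble(dlp_mgy_cm = dlp, effective_dose_msv = dlp * k)
}

#' Full dose report for a protocol
#'
#' Per-component and total CTDIvol32, SSDE (one shared size factor), DLP,
#' effective dose and size-specific effective dose.
#'
#' @param model An [scan_dose_model()].
#' @return An `fpa_dose_report`: tibble of components plus attributes
#'   (`ssde_factor`, `effective_diameter_cm`).
#' @export
dose_report <- function(model) {
  ct <- protocol_ctdi(model)
  f <- ssde_factor(model$effective_diameter_cm)
  ed <- effective_dose(ct$ctdi_mgy, model$scan_length_cm, model$k)
  out <- ct |>
    dplyr::mutate(ssde_mgy = .data$ctdi_mgy * f,
                  dlp_mgy_cm = ed$dlp_mgy_cm,
                  effective_dose_msv = ed$effective_dose_msv,
                  ssde_effective_dose_msv = .data$ssde_mgy *
                    model$scan_length_cm * model$k)
  attr(out, "ssde_factor") <- f
  attr(out, "effective_diameter_cm") <- model$effective_diameter_cm
  class(out) <- c("fpa_dose_report", class(out))
  out
}

#' @export
print.fpa_dose_report <- function(x, ...) {
  cat(sprintf("<fpa_dose_report> effective diameter %.1f cm, SSDE factor %.3f\n",
              attr(x, "effective_diameter_cm"), attr(x, "ssde_factor")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
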