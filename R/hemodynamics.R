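# Doppler haemodynamics: BSA, cardiac index, stroke volume from aortic
# diameter x velocity-time integral, and replicate aggregation.
# Internal units: cm, kg, mL, L/min, m^2. Conversions happen only here.

#' Mosteller body surface area
#'
#' BSA in square metres from height and weight using the Mosteller formula
#' `sqrt(height_cm * weight_kg / 3600)`.
#'
#' @param height_cm Height in centimetres (> 0). Vectorised.
#' @param weight_kg Weight in kilograms (> 0). Vectorised.
#' @return Body surface area in m^2.
#' @examples
#' mosteller_bsa(163.7, 66.5)
#' @export
mosteller_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("mosteller_bsa: height and weight must be finite and positive")
  }
  sqrt(height_cm * weight_kg / 3600)
}

#' Cardiac index
#'
#' Cardiac output normalised by body surface area.
#'
#' @param co Cardiac output, L/min (>= 0). Vectorised.
#' @param bsa Body surface area, m^2 (> 0). Vectorised.
#' @return Cardiac index, L/min/m^2.
#' @export
cardiac_index <- function(co, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("cardiac_index: body surface area must be finite and positive")
  }
  if (any(!is.finite(co)) || any(co < 0)) {
    stop("cardiac_index: cardiac output must be finite and non-negative")
  }
  co / bsa
}

#' Aortic cross-sectional area from diameter
#'
#' Circular cross-section `pi * (d/2)^2`, used in the Doppler stroke-volume
#' chain (area in cm^2 from diameter in cm).
#'
#' @param diameter_cm Aortic (LVOT/valve) diameter, cm (> 0). Vectorised.
#' @return Cross-sectional area, cm^2.
#' @export
aortic_cross_section <- function(diameter_cm) {
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0)) {
    stop("aortic_cross_section: diameter must be finite and positive")
  }
  pi * (diameter_cm / 2)^2
}

#' Doppler stroke volume
#'
#' Stroke volume (mL) as aortic cross-sectional area times the velocity-time
#' integral of the Doppler envelope; cm^2 x cm = cm^3 = mL.
#'
#' @param diameter_cm Aortic diameter, cm (> 0).
#' @param vti_cm Velocity-time integral, cm (> 0).
#' @return Stroke volume, mL.
#' @examples
#' doppler_stroke_volume(2.0, 20)  # 62.83 mL
#' @export
doppler_stroke_volume <- function(diameter_cm, vti_cm) {
  if (any(!is.finite(vti_cm)) || any(vti_cm <= 0)) {
    stop("doppler_stroke_volume: VTI must be finite and positive")
  }
  aortic_cross_section(diameter_cm) * vti_cm
}

#' Cardiac output from stroke volume and heart rate
#'
#' `sv_ml * hr / 1000`, L/min.
#'
#' @param sv_ml Stroke volume, mL (> 0).
#' @param hr Heart rate, beats/min (> 0).
#' @return Cardiac output, L/min.
#' @export
tte_cardiac_output <- function(sv_ml, hr) {
  if (any(!is.finite(sv_ml)) || any(sv_ml <= 0) ||
      any(!is.finite(hr)) || any(hr <= 0)) {
    stop("tte_cardiac_output: stroke volume and heart rate must be positive")
  }
  sv_ml * hr / 1000
}

#' Aggregate replicate VTI traces
#'
#' Echo acquisition records three sets of three traces per measurement. Each
#' set is averaged, then the set means are averaged (balanced design, so the
#' grand mean equals the mean of all nine traces; the set structure is kept
#' for generalisation to unbalanced input and for repeatability analysis).
#'
#' @param vti_sets A list of numeric vectors, one per set (default acquisition:
#'   3 sets of 3 positive traces), or a numeric matrix with one row per set.
#' @param fun Aggregation within and across sets: `"mean"` (default) or
#'   `"median"`.
#' @return A list with `set_means` (numeric vector) and `grand_mean` (scalar).
#' @export
average_replicates <- function(vti_sets, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  agg <- if (fun == "mean") mean else stats::median
  if (is.matrix(vti_sets)) {
    vti_sets <- split(vti_sets, row(vti_sets))
  }
  if (!is.list(vti_sets) || length(vti_sets) == 0) {
    stop("average_replicates: vti_sets must be a non-empty list of sets")
  }
  for (s in vti_sets) {
    if (length(s) == 0) stop("average_replicates: empty replicate set")
    if (any(!is.finite(s)) || any(s <= 0)) {
      stop("average_replicates: all traces must be finite and positive")
    }
  }
  set_means <- vapply(vti_sets, agg, numeric(1))
  list(set_means = unname(set_means), grand_mean = agg(set_means))
}
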