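# Poiseuille-law calculators, ABI computation/classification, and the
# limb-pressure scaling rule that derives per-patient arterial and capillary
# haemodynamic profiles from reference (ABI = 1) vessel constants.

#' Vessel geometry and fluid constants
#'
#' Container for the physical description of a vessel segment used by the
#' Poiseuille-law calculators. Lengths follow the conventions of the reference
#' constant table: diameter and wall thickness in millimetres, vessel length
#' in metres.
#'
#' @param diameter Inner diameter in mm.
#' @param length Vessel length in m.
#' @param wall_thickness Wall thickness in mm.
#' @param viscosity Dynamic viscosity of blood in Pa·s.
#' @param density Blood mass density in kg/m^3.
#' @param reference_pressure Driving pressure drop across the segment in mmHg.
#'
#' @return An object of class `vessel_geometry`.
#' @export
#' @examples
#' vessel_geometry(diameter = 0.007, length = 0.0007, wall_thickness = 0.0005,
#'                 viscosity = 0.0012, density = 1060, reference_pressure = 25)
vessel_geometry <- function(diameter, length, wall_thickness,
                            viscosity, density, reference_pressure) {
  check_positive_scalar(diameter, "diameter")
  check_positive_scalar(length, "length")
  check_positive_scalar(wall_thickness, "wall_thickness")
  check_positive_scalar(viscosity, "viscosity")
  check_positive_scalar(density, "density")
  check_positive_scalar(reference_pressure, "reference_pressure")
  structure(
    list(diameter = diameter, length = length, wall_thickness = wall_thickness,
         viscosity = viscosity, density = density,
         reference_pressure = reference_pressure),
    class = "vessel_geometry"
  )
}

#' Reference capillary geometry
#'
#' The literature-derived capillary constants used throughout: diameter
#' 0.007 mm, length 0.0007 m, wall thickness 0.0005 mm, viscosity 0.0012 Pa·s,
#' density 1060 kg/m^3, reference pressure 25 mmHg. The effective radius is
#' always diameter/2 (0.0035 mm); this is the only radius convention that is
#' consistent with the reference capillary resistance of 1.43e16 Pa·s/m^3.
#'
#' @return A [vessel_geometry()] object.
#' @export
capillary_geometry <- function() {
  vessel_geometry(diameter = 0.007, length = 0.0007, wall_thickness = 0.0005,
                  viscosity = 0.0012, density = 1060, reference_pressure = 25)
}

#' Reference arterial (posterior tibial artery) baseline values
#'
#' Baseline haemodynamics at ABI = 1 (ankle systolic pressure 120 mmHg).
#' The arterial resistance (3.02e7 Pa·s/m^3) and arterial flow
#' (5.30e-4 m^3/s) are literature constants taken as given, never recomputed
#' from geometry; the capillary resistance and flow are computed from
#' [capillary_geometry()] by Poiseuille's law and kept at full precision.
#'
#' @param capillary_geom Capillary geometry; defaults to [capillary_geometry()].
#' @return A list with elements `arterial_pressure` (120 mmHg),
#'   `capillary_pressure` (25 mmHg), `arterial_flow`, `capillary_flow` (m^3/s),
#'   `arterial_resistance`, `capillary_resistance` (Pa·s/m^3).
#' @export
artery_capillary_baseline <- function(capillary_geom = capillary_geometry()) {
  r_cap <- poiseuille_resistance(capillary_geom)
  q_cap <- poiseuille_flow(mmhg_to_pa(capillary_geom$reference_pressure), r_cap)
  list(
    arterial_pressure = 120,
    capillary_pressure = 25,
    arterial_flow = 5.30e-4,
    capillary_flow = q_cap,
    arterial_resistance = 3.02e7,
    capillary_resistance = r_cap
  )
}

#' Hydraulic resistance by Poiseuille's law
#'
#' Computes the laminar-flow hydraulic resistance R = 8*eta*l / (pi*r^4),
#' with the radius r = diameter/2 converted from mm to m.
#'
#' @param geom A [vessel_geometry()] object.
#' @return Resistance in Pa·s/m^3.
#' @export
#' @examples
#' poiseuille_resistance(capillary_geometry())  # ~1.43e16 Pa·s/m^3
poiseuille_resistance <- function(geom) {
  if (!inherits(geom, "vessel_geometry")) {
    stop_invalid("'geom' must be a vessel_geometry object")
  }
  radius_m <- (geom$diameter / 2) * 1e-3
  8 * geom$viscosity * geom$length / (pi * radius_m^4)
}

#' Volumetric flow by Poiseuille's law
#'
#' Q = delta_p / R for a pressure drop `delta_p` (Pa) across a hydraulic
#' resistance `resistance` (Pa·s/m^3).
#'
#' @param delta_p Pressure drop in Pa.
#' @param resistance Hydraulic resistance in Pa·s/m^3; must be positive.
#' @return Flow in m^3/s.
#' @export
poiseuille_flow <- function(delta_p, resistance) {
  check_number(delta_p, "delta_p")
  if (!is.numeric(resistance) || length(resistance) != 1L ||
      !is.finite(resistance) || resistance <= 0) {
    stop_invalid("'resistance' must be a single positive number")
  }
  delta_p / resistance
}

#' Convert pressure from mmHg to Pa
#'
#' @param p Pressure in mmHg (vectorised).
#' @return Pressure in Pa (`p * 133.322`).
#' @export
mmhg_to_pa <- function(p) {
  if (!is.numeric(p)) stop_invalid("'p' must be numeric")
  p * MMHG_TO_PA
}

#' Ankle-brachial index
#'
#' Ratio of ankle to brachial systolic pressure, the standard non-invasive
#' marker of peripheral arterial disease.
#'
#' @param ankle Ankle systolic pressure in mmHg.
#' @param brachial Brachial systolic pressure in mmHg; must be positive.
#' @return The dimensionless ABI.
#' @export
compute_abi <- function(ankle, brachial) {
  check_number(ankle, "ankle")
  if (!is.numeric(brachial) || length(brachial) != 1L ||
      !is.finite(brachial) || brachial <= 0) {
    stop_invalid("'brachial' must be a single positive number")
  }
  ankle / brachial
}

#' Classify an ABI value into clinical strata
#'
#' Uses the printed strata with inclusive boundaries: severe impairment
#' (<= 0.4), moderate impairment (0.41-0.7), normal (0.9-1.3), Moenckeberg
#' medial calcification (>= 1.4). Values falling in the gaps between strata
#' ((0.4, 0.41), (0.7, 0.9), (1.3, 1.4)) are reported as `"unclassified"`
#' rather than forced into a neighbouring band.
#'
#' @param abi Positive ABI value.
#' @return One of `"severe"`, `"moderate"`, `"normal"`, `"moenckeberg"`,
#'   `"unclassified"`.
#' @export
#' @examples
#' classify_abi(0.6)   # moderate
#' classify_abi(1.35)  # unclassified (gap between normal and Moenckeberg)
classify_abi <- function(abi) {
  if (!is.numeric(abi) || length(abi) != 1L || !is.finite(abi) || abi <= 0) {
    stop_invalid("'abi' must be a single positive number")
  }
  if (abi <= 0.4) return("severe")
  if (abi >= 0.41 && abi <= 0.7) return("moderate")
  if (abi >= 0.9 && abi <= 1.3) return("normal")
  if (abi >= 1.4) return("moenckeberg")
  "unclassified"
}

#' Patient haemodynamic record
#'
#' @param patient_id Label for the patient.
#' @param brachial_systolic Brachial (upper-limb) systolic pressure, mmHg.
#' @param ankle_systolic Ankle (lower-limb) systolic pressure, mmHg.
#' @param abi Recorded ankle-brachial index. Must agree with
#'   `ankle_systolic / brachial_systolic` within 0.03 (printed rounding).
#' @param wound_area Wound area in cm^2.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, brachial_systolic, ankle_systolic,
                           abi, wound_area) {
  check_positive_scalar(brachial_systolic, "brachial_systolic")
  check_positive_scalar(ankle_systolic, "ankle_systolic")
  check_positive_scalar(abi, "abi")
  check_number(wound_area, "wound_area")
  if (abs(abi - ankle_systolic / brachial_systolic) > 0.03) {
    stop_invalid(sprintf(
      "recorded ABI %.3f inconsistent with ankle/brachial = %.3f",
      abi, ankle_systolic / brachial_systolic))
  }
  structure(
    list(patient_id = as.character(patient_id),
         brachial_systolic = brachial_systolic,
         ankle_systolic = ankle_systolic,
         abi = abi, wound_area = wound_area),
    class = "patient_record"
  )
}

#' Read patient records from CSV
#'
#' Expects columns `patient_id, brachial_systolic_mmHg, ankle_systolic_mmHg,
#' abi, wound_area_cm2` (header required). The three study patients ship as
#' a fixture; see [fixture_patients()].
#'
#' @param path Path to a CSV file.
#' @return A list of [patient_record()] objects.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "brachial_systolic_mmHg", "ankle_systolic_mmHg",
              "abi", "wound_area_cm2")
  if (!all(needed %in% names(df))) {
    stop_invalid(paste0("patient CSV must have columns: ",
                        paste(needed, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    patient_record(df$patient_id[i], df$brachial_systolic_mmHg[i],
                   df$ankle_systolic_mmHg[i], df$abi[i], df$wound_area_cm2[i])
  })
}

#' Built-in study patients
#'
#' The three diabetic-ulcer patients whose pressures and ABIs drive the
#' worked examples: A (brachial 160, ankle 100, ABI 0.6), B (140, 160, 1.14),
#' C (150, 200, 1.33).
#'
#' @return A list of three [patient_record()] objects, named A, B, C.
#' @export
fixture_patients <- function() {
  path <- system.file("extdata", "patients.csv", package = "capfit",
                      mustWork = TRUE)
  recs <- read_patients(path)
  names(recs) <- vapply(recs, function(r) sub("^Patient ", "", r$patient_id),
                        character(1))
  recs
}

#' Limb-pressure-scaled haemodynamic profile
#'
#' Derives a patient's arterial and capillary pressures and flows by scaling
#' the ABI = 1 baseline with the factor s = ankle_systolic / 120. Capillary
#' pressure becomes 25*s mmHg, arterial flow 5.30e-4*s m^3/s, capillary flow
#' the (unrounded) Poiseuille capillary flow times s. Resistances are
#' geometric properties and are copied from the baseline unchanged. This
#' scaling is linear in the lower-limb pressure, which is the quantity the
#' capillaries under study actually see.
#'
#' @param patient A [patient_record()].
#' @param baseline Baseline values, as from [artery_capillary_baseline()].
#' @param capillary_geom Capillary geometry (used when `baseline` is missing).
#' @return An object of class `hemodynamic_profile`: a list with
#'   `arterial_pressure`, `capillary_pressure` (mmHg), `arterial_flow`,
#'   `capillary_flow` (m^3/s), `arterial_resistance`, `capillary_resistance`
#'   (Pa·s/m^3), plus `patient_id` and `abi`.
#' @export
#' @examples
#' p <- patient_record("Patient A", 160, 100, 0.6, 3.978)
#' prof <- limb_scaled_profile(p)
#' signif(prof$capillary_pressure, 4)  # 20.83 mmHg
limb_scaled_profile <- function(patient,
                                baseline = artery_capillary_baseline(capillary_geom),
                                capillary_geom = capillary_geometry()) {
  if (!inherits(patient, "patient_record")) {
    stop_invalid("'patient' must be a patient_record")
  }
  needed <- c("arterial_pressure", "capillary_pressure", "arterial_flow",
              "capillary_flow", "arterial_resistance", "capillary_resistance")
  if (!is.list(baseline) || !all(needed %in% names(baseline))) {
    stop_config("baseline must supply arterial/capillary pressures, flows and resistances")
  }
  s <- patient$ankle_systolic / baseline$arterial_pressure
  structure(
    list(patient_id = patient$patient_id,
         abi = patient$abi,
         arterial_pressure = patient$ankle_systolic,
         capillary_pressure = baseline$capillary_pressure * s,
         arterial_flow = baseline$arterial_flow * s,
         capillary_flow = baseline$capillary_flow * s,
         arterial_resistance = baseline$arterial_resistance,
         capillary_resistance = baseline$capillary_resistance),
    class = "hemodynamic_profile"
  )
}

#' Capillary flow scaled by lower-limb pressure
#'
#' The Poiseuille capillary flow at the 25 mmHg reference pressure, scaled by
#' `ankle / 120`. This is the per-patient capillary flow amplitude used as the
#' target-signal peak in system identification. Full precision is retained.
#'
#' @param ankle Lower-limb (ankle) systolic pressure in mmHg.
#' @param capillary_geom Capillary geometry; defaults to [capillary_geometry()].
#' @return Flow in m^3/s.
#' @export
#' @examples
#' signif(abi_scaled_capillary_flow(100), 6)  # 1.94856e-13
abi_scaled_capillary_flow <- function(ankle,
                                      capillary_geom = capillary_geometry()) {
  check_positive_scalar(ankle, "ankle")
  r_cap <- poiseuille_resistance(capillary_geom)
  q_ref <- poiseuille_flow(mmhg_to_pa(capillary_geom$reference_pressure), r_cap)
  q_ref * ankle / 120
}

#' @export
print.hemodynamic_profile <- function(x, ...) {
  cat("Haemodynamic profile:", x$patient_id, sprintf("(ABI %.2f)\n", x$abi))
  cat(sprintf("  arterial:  %s mmHg, %s m^3/s, R = %s Pa.s/m^3\n",
              format(signif(x$arterial_pressure, 4)),
              format(signif(x$arterial_flow, 3)),
              format(signif(x$arterial_resistance, 3))))
  cat(sprintf("  capillary: %s mmHg, %s m^3/s, R = %s Pa.s/m^3\n",
              format(signif(x$capillary_pressure, 4)),
              format(signif(x$capillary_flow, 3)),
              format(signif(x$capillary_resistance, 3))))
  invisible(x)
}
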