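#' Blood gas chemistry
#'
#' Standard adult blood-gas correlations used throughout the simulator:
#' the Kelman rational-polynomial oxyhaemoglobin dissociation curve with
#' Bohr/temperature corrections, whole-blood CO2 content with a Haldane
#' correction (Douglas-type), and numeric inversions from contents back to
#' gas tensions. All tensions are in mmHg, contents in ml per dl of blood.
#'
#' @name blood-chemistry
NULL

# Kelman (1966) coefficients for the standard dissociation curve
.kelman_a <- c(-8532.2289, 2121.401, -67.073989, 935960.87,
               -31346.258, 2396.1674, -67.104406)

#' Oxyhaemoglobin saturation
#'
#' Fractional haemoglobin saturation as a function of oxygen tension, with
#' shifts of the curve for CO2 tension (Bohr effect via pH), pH and
#' temperature. Uses the Kelman virtual-PO2 transformation followed by the
#' rational polynomial of the standard curve; below a virtual PO2 of
#' 10 mmHg a quadratic limb is used, as in the original correlation.
#'
#' @param po2 Oxygen tension (mmHg), vectorised.
#' @param pco2 Carbon dioxide tension (mmHg). Default 40.
#' @param ph Plasma pH. Default 7.4.
#' @param temp Blood temperature (degrees C). Default 37.
#' @return Saturation as a fraction in \[0, 1\].
#' @export
o2_saturation <- function(po2, pco2 = 40, ph = 7.4, temp = 37) {
  stopifnot(all(po2 >= 0))
  # virtual PO2: value on the standard curve with the same saturation
  x <- po2 * 10^(0.024 * (37 - temp) + 0.4 * (ph - 7.4) +
                   0.06 * (log10(40) - log10(pmax(pco2, 1e-6))))
  a <- .kelman_a
  s_hi <- (a[1] * x + a[2] * x^2 + a[3] * x^3 + x^4) /
    (a[4] + a[5] * x + a[6] * x^2 + a[7] * x^3 + x^4)
  s_lo <- 0.003683 * x + 0.000584 * x^2
  s <- ifelse(x < 10, s_lo, s_hi)
  pmin(pmax(s, 0), 1)
}

#' Oxygen content of whole blood
#'
#' Bound plus dissolved oxygen: 1.34 ml O2 per g of saturated haemoglobin
#' plus 0.003 ml per dl per mmHg dissolved.
#'
#' @param po2 Oxygen tension (mmHg).
#' @param so2 Fractional saturation (from [o2_saturation()]).
#' @param hb Haemoglobin concentration (g/dl).
#' @return Content in ml O2 per dl blood.
#' @export
o2_content <- function(po2, so2, hb) {
  1.34 * hb * so2 + 0.003 * po2
}

# pH from PCO2 by Henderson-Hasselbalch along the whole-blood buffer
# line: bicarbonate rises as pH falls with slope `beta` (non-bicarbonate
# buffer value, mmol/l per pH unit) around the normal point (pH 7.4,
# HCO3 24 mmol/l, zero base excess). Full acid-base is out of scope.
#' @param pco2 CO2 tension (mmHg).
#' @param hco3 Standard bicarbonate (mmol/l) at pH 7.4, default 24.
#' @param beta Blood buffer value (mmol/l/pH), default 25.
#' @rdname blood-chemistry
#' @export
ph_from_pco2 <- function(pco2, hco3 = 24, beta = 25) {
  p <- pmax(pco2, 1e-3)
  ph <- rep_len(7.4, length(p))
  for (i in 1:8) {
    ph <- 6.1 + log10(pmax(hco3 + beta * (7.4 - ph), 1) / (0.0307 * p))
  }
  ph
}

#' Carbon dioxide content of whole blood
#'
#' Plasma CO2 (dissolved plus bicarbonate, Henderson-Hasselbalch) scaled
#' to whole blood with the Douglas haemoglobin/saturation correction, which
#' carries the Haldane effect: at equal PCO2, desaturated blood carries
#' more CO2.
#'
#' @param pco2 CO2 tension (mmHg).
#' @param so2 Fractional oxyhaemoglobin saturation.
#' @param hb Haemoglobin (g/dl).
#' @param temp Temperature (degrees C), default 37.
#' @return CO2 content in ml per dl blood.
#' @export
co2_content <- function(pco2, so2, hb, temp = 37) {
  stopifnot(all(pco2 >= 0))
  ph <- ph_from_pco2(pco2)
  pk <- 6.086 + 0.042 * (7.4 - ph) +
    (38 - temp) * (0.00472 + 0.00139 * (7.4 - ph))
  sol <- 0.0307 + 0.00057 * (37 - temp) + 2e-5 * (37 - temp)^2
  # plasma content, mmol/l
  c_plasma <- sol * pco2 * (1 + 10^(ph - pk))
  ratio <- 1 - (0.0289 * hb) / ((3.352 - 0.456 * so2) * (8.142 - ph))
  # 22.26 ml CO2 per mmol; /10 converts per-litre to per-dl
  2.226 * c_plasma * ratio
}

#' Invert oxygen content to tension
#'
#' Finds the PO2 whose whole-blood O2 content (at the given PCO2-dependent
#' pH shift) equals the supplied content, by bisection. Monotonicity of the
#' dissociation curve guarantees a unique root.
#'
#' @param content Target O2 content (ml/dl), vectorised.
#' @param hb Haemoglobin (g/dl).
#' @param pco2 CO2 tension used for the Bohr shift (mmHg).
#' @param lo,hi Bracketing tensions (mmHg).
#' @return PO2 in mmHg.
#' @export
po2_from_content <- function(content, hb, pco2 = 40, lo = 0.01, hi = 750) {
  ph <- ph_from_pco2(pco2)
  f <- function(p) o2_content(p, o2_saturation(p, pco2, ph), hb)
  cmax <- f(hi)
  content <- pmin(pmax(content, 0), cmax - 1e-9)
  a <- rep_len(lo, length(content)); b <- rep_len(hi, length(content))
  for (i in 1:45) {
    m <- 0.5 * (a + b)
    too_high <- f(m) > content
    b <- ifelse(too_high, m, b)
    a <- ifelse(too_high, a, m)
  }
  0.5 * (a + b)
}

#' Invert CO2 content to tension
#'
#' Bisection inverse of [co2_content()] at fixed saturation and
#' haemoglobin. Round-trip error is below 0.1 mmHg.
#'
#' @param content Target CO2 content (ml/dl), vectorised.
#' @param so2 Fractional saturation.
#' @param hb Haemoglobin (g/dl).
#' @param lo,hi Bracketing tensions (mmHg).
#' @return PCO2 in mmHg.
#' @export
pco2_from_content <- function(content, so2, hb, lo = 0.1, hi = 250) {
  a <- rep_len(lo, length(content)); b <- rep_len(hi, length(content))
  so2 <- rep_len(so2, length(content))
  for (i in 1:40) {
    m <- 0.5 * (a + b)
    too_high <- co2_content(m, so2, hb) > content
    b <- ifelse(too_high, m, b)
    a <- ifelse(too_high, a, m)
  }
  0.5 * (a + b)
}

#' Construct a blood sample record
#'
#' Bundles tensions, saturation and contents for one blood pool (arterial,
#' mixed venous or end-capillary). Contents are computed from the tensions
#' so the record is internally consistent by construction.
#'
#' @param po2,pco2 Gas tensions (mmHg).
#' @param hb Haemoglobin (g/dl).
#' @param temp Temperature (degrees C).
#' @return An object of class `blood_sample`: list with `po2`, `pco2`,
#'   `so2`, `o2_content`, `co2_content`, `hb`.
#' @export
blood_sample <- function(po2, pco2, hb, temp = 37) {
  stopifnot(po2 >= 0, pco2 >= 0, hb > 0)
  ph <- ph_from_pco2(pco2)
  so2 <- o2_saturation(po2, pco2, ph, temp)
  structure(list(
    po2 = po2, pco2 = pco2, so2 = so2,
    o2_content = o2_content(po2, so2, hb),
    co2_content = co2_content(pco2, so2, hb, temp),
    hb = hb
  ), class = "blood_sample")
}

#' @export
print.blood_sample <- function(x, ...) {
  cat(sprintf(
    "blood sample: PO2 %.1f mmHg, PCO2 %.1f mmHg, SO2 %.3f, CO2ct %.2f, O2ct %.2f ml/dl\n",
    x$po2, x$pco2, x$so2, x$co2_content, x$o2_content))
  invisible(x)
}
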