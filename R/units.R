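#' Convert between field-scale and column-scale nitrogen units
#'
#' The column solver works in mg N per cm^2 of soil surface; field rates are
#' quoted in kg N per hectare. 1 kg ha^-1 = 1e6 mg / 1e8 cm^2 = 0.01 mg cm^-2.
#'
#' @param x numeric vector of area densities.
#' @return numeric vector in the target unit.
#' @examples
#' kg_ha_to_mg_cm2(144)   # 1.44
#' mg_cm2_to_kg_ha(1.44)  # 144
#' @export
kg_ha_to_mg_cm2 <- function(x) x * 1e-2

#' @rdname kg_ha_to_mg_cm2
#' @export
mg_cm2_to_kg_ha <- function(x) x * 1e2

# van Genuchten retention and Mualem conductivity (R-side mirror of the
# compiled kernels; used for initialization and as test oracles).
vg_theta_r <- function(psi, hyd) {
  se <- ifelse(psi >= 0, 1,
               (1 + (hyd$alpha * abs(psi))^hyd$n_vg)^(-(1 - 1 / hyd$n_vg)))
  hyd$theta_r + (hyd$theta_s - hyd$theta_r) * se
}

vg_k_r <- function(psi, hyd) {
  m <- 1 - 1 / hyd$n_vg
  se <- ifelse(psi >= 0, 1, (1 + (hyd$alpha * abs(psi))^hyd$n_vg)^(-m))
  inner <- 1 - (1 - se^(1 / m))^m
  ifelse(se >= 1, hyd$ks, hyd$ks * sqrt(se) * inner^2)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  x
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) abort(sprintf("`%s` must be a single %s number",
                         name, if (strict) "positive" else "non-negative"))
  x
}
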