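#' Nuclear-data constants
#'
#' Named configuration constants used throughout the dose chain. They live in
#' one place so that no computation hard-codes a nuclear-data literal:
#'
#' * `lu177_half_life_h`: 6.647 d expressed in hours.
#' * `lu177_mean_energy_keV`: mean locally deposited energy per decay for
#'   ^177Lu, 147.9 keV (electron emissions; photons are ignored under the
#'   local-deposition method because at mouse-organ scale the ^177Lu dose is
#'   electron-dominated).
#' * `keV_to_J`: 1 keV in joule (exact, via the 2019 SI elementary charge).
#'
#' @format A named list.
#' @export
nuclear_constants <- list(
  lu177_half_life_h    = 6.647 * 24,
  lu177_mean_energy_keV = 147.9,
  keV_to_J             = 1.602176634e-16
)

#' Define a radionuclide
#'
#' A radionuclide carries the two nuclear-data quantities the dose chain
#' needs: the physical half-life (hence the decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}}) and the mean energy deposited locally per
#' decay, \eqn{\Delta}.
#'
#' @param name Character label, e.g. `"Lu-177"`.
#' @param half_life_h Physical half-life in hours; must be positive.
#' @param mean_energy_per_decay_keV Mean locally absorbed energy per decay in
#'   keV; must be positive. For beta emitters at mouse-organ scale this is the
#'   mean electron energy per decay (absorbed fraction handled separately).
#'
#' @return An object of class `radionuclide`: a list with fields `name`,
#'   `half_life_h`, `mean_energy_per_decay_keV` and the derived decay
#'   constant `lambda_per_h`.
#' @seealso [lu177()] for the packaged ^177Lu entry.
#' @export
#' @examples
#' radionuclide("Lu-177", 6.647 * 24, 147.9)
radionuclide <- function(name, half_life_h, mean_energy_per_decay_keV) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1 ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("`half_life_h` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(mean_energy_per_decay_keV) ||
      length(mean_energy_per_decay_keV) != 1 ||
      !is.finite(mean_energy_per_decay_keV) ||
      mean_energy_per_decay_keV <= 0) {
    stop("`mean_energy_per_decay_keV` must be a single positive number.",
         call. = FALSE)
  }
  structure(
    list(
      name = name,
      half_life_h = half_life_h,
      mean_energy_per_decay_keV = mean_energy_per_decay_keV,
      lambda_per_h = log(2) / half_life_h
    ),
    class = "radionuclide"
  )
}

#' The packaged ^177Lu radionuclide
#'
#' Convenience constructor returning the default ^177Lu entry built from
#' [nuclear_constants] (half-life 6.647 d, mean locally deposited energy
#' 147.9 keV per decay).
#'
#' @return A `radionuclide` object.
#' @export
#' @examples
#' lu177()$lambda_per_h
lu177 <- function() {
  radionuclide(
    "Lu-177",
    nuclear_constants$lu177_half_life_h,
    nuclear_constants$lu177_mean_energy_keV
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf(
    "<radionuclide> %s: T1/2 = %.3f h (lambda = %.6g /h), Delta = %.1f keV/decay\n",
    x$name, x$half_life_h, x$lambda_per_h, x$mean_energy_per_decay_keV
  ))
  invisible(x)
}

is_radionuclide <- function(x) inherits(x, "radionuclide")
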