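#' Organ mean absorbed dose by local energy deposition
#'
#' Converts cumulated activity to mean absorbed dose (MAD, cGy per MBq
#' injected) under the local-deposition assumption: every decay deposits its
#' mean energy \eqn{\Delta} in the source tissue itself, scaled by an
#' absorbed fraction \eqn{\phi}. For ^177Lu at mouse-organ scale the dose is
#' electron-dominated, so photon cross-dose is ignored on this path (use
#' [svalue_dose()] when cross-organ S-values are available).
#'
#' The unit chain for a cumulated activity \eqn{\tilde a} in %IA/g.h:
#' \deqn{MAD = \tilde a \times 10^{-2} \times 3600 \times 10^{6}
#'   \times \Delta_J \times 10^{3} \times 10^{2} \times \phi}
#' (fraction per gram, seconds per hour, decays per second per MBq, joules
#' per decay, grams per kilogram, cGy per Gy). At \eqn{\Delta} = 147.9 keV
#' and \eqn{\phi} = 1 this is about 0.0853 cGy/MBq per 1 %IA/g.h.
#'
#' @param cum A `cumact` tibble from [integrate_tac()] or [auc_table()], or
#'   any data frame with columns `organ` and `value` (%IA/g.h on the
#'   physical-activity scale) and optionally `sd` and `cohort`.
#' @param nuclide A [radionuclide()]; supplies \eqn{\Delta}. Default
#'   [lu177()].
#' @param absorbed_fraction \eqn{\phi} in (0, 1]; default 1.
#' @param decay_corrected Set `TRUE` only to assert that the cumulated
#'   activities were computed on the decay-corrected scale, which is an
#'   error: dose needs physical decays.
#' @return A `dose_report` tibble: `cohort`, `organ`, `mad_cGy_per_MBq`,
#'   `sd_cGy_per_MBq`, `method`.
#' @export
#' @examples
#' local_deposition_dose(data.frame(organ = "kidney", value = 1615))
local_deposition_dose <- function(cum, nuclide = lu177(),
                                  absorbed_fraction = 1,
                                  decay_corrected = FALSE) {
  stopifnot(is_radionuclide(nuclide))
  if (isTRUE(decay_corrected)) {
    stop("cumulated activity is on the decay-corrected scale; rebuild it ",
         "after apply_physical_decay().", call. = FALSE)
  }
  if (!is.numeric(absorbed_fraction) || absorbed_fraction <= 0 ||
      absorbed_fraction > 1) {
    stop("`absorbed_fraction` must be in (0, 1].", call. = FALSE)
  }
  cum <- as_tibble(cum)
  stopifnot(all(c("organ", "value") %in% names(cum)))
  coef <- mad_coefficient(nuclide, absorbed_fraction)
  tibble(
    cohort = if ("cohort" %in% names(cum)) cum$cohort else NA_character_,
    organ = cum$organ,
    mad_cGy_per_MBq = cum$value * coef,
    sd_cGy_per_MBq = if ("sd" %in% names(cum)) cum$sd * coef else NA_real_,
    method = "local"
  ) |>
    structure(class = c("dose_report", class(tibble())))
}

# cGy/MBq per 1 %IA/g.h
mad_coefficient <- function(nuclide, absorbed_fraction = 1) {
  delta_J <- nuclide$mean_energy_per_decay_keV * nuclear_constants$keV_to_J
  (1 / 100) * 3600 * 1e6 * delta_J * 1000 * 100 * absorbed_fraction
}

#' Read an S-value table with organ masses
#'
#' The S-value CSV is a matrix with target organs as the first column
#' (`target`) and source organs as the remaining column headers, entries in
#' Gy/(MBq.s). The masses CSV has columns `organ`, `mass_g`.
#'
#' @param s_path Path to the S-value matrix CSV.
#' @param masses_path Path to the organ-mass CSV.
#' @return An `svalue_table` list with fields `S` (matrix, targets x
#'   sources) and `mass_g` (named vector).
#' @export
read_svalue_table <- function(s_path, masses_path) {
  s_tab <- readr::read_csv(s_path, show_col_types = FALSE, progress = FALSE)
  if (!"target" %in% names(s_tab)) {
    stop("S-value table must have a `target` column.", call. = FALSE)
  }
  S <- as.matrix(s_tab[setdiff(names(s_tab), "target")])
  rownames(S) <- normalize_organ(s_tab$target)
  colnames(S) <- normalize_organ(colnames(S))
  m_tab <- readr::read_csv(masses_path, show_col_types = FALSE,
                           progress = FALSE)
  masses <- stats::setNames(m_tab$mass_g, normalize_organ(m_tab$organ))
  svalue_table(S, masses)
}

#' Construct an S-value table
#'
#' @param S Matrix of S-values in Gy/(MBq.s), rows = target organs,
#'   columns = source organs, dimnames set to organ labels.
#' @param mass_g Named numeric vector of source-organ masses in grams.
#' @return An `svalue_table` object.
#' @export
svalue_table <- function(S, mass_g) {
  stopifnot(is.matrix(S), !is.null(rownames(S)), !is.null(colnames(S)))
  if (any(S < 0)) stop("S-values must be non-negative.", call. = FALSE)
  missing_mass <- setdiff(colnames(S), names(mass_g))
  if (length(missing_mass) > 0) {
    stop("no mass for source organ(s): ",
         paste(missing_mass, collapse = ", "), call. = FALSE)
  }
  structure(list(S = S, mass_g = mass_g), class = "svalue_table")
}

#' Organ mean absorbed dose from an S-value table
#'
#' MIRD-style dose: \eqn{D_{target} = \sum_{source} \tilde A_{source}
#' \times S(target \leftarrow source)}. Cumulated activities in %IA/g.h are
#' converted to organ-level MBq.s per MBq injected via the source-organ
#' masses (\eqn{\tilde A = \tilde a \times m_g / 100 \times 3600}), and the
#' result is reported in cGy/MBq.
#'
#' @param cums A `cumact` tibble (columns `organ`, `value`; one cohort).
#' @param table An [svalue_table()].
#' @return A `dose_report` tibble with `method = "svalue"`.
#' @export
svalue_dose <- function(cums, table) {
  stopifnot(inherits(table, "svalue_table"))
  cums <- as_tibble(cums)
  missing_org <- setdiff(cums$organ, colnames(table$S))
  if (length(missing_org) > 0) {
    stop("organ(s) missing from the S-value table: ",
         paste(missing_org, collapse = ", "), call. = FALSE)
  }
  # MBq.s per MBq injected, per source organ
  A_tilde <- stats::setNames(rep(0, ncol(table$S)), colnames(table$S))
  A_tilde[cums$organ] <- cums$value * table$mass_g[cums$organ] / 100 * 3600
  d_Gy <- as.vector(table$S %*% A_tilde)
  tibble(
    cohort = if ("cohort" %in% names(cums)) cums$cohort[1] else NA_character_,
    organ = rownames(table$S),
    mad_cGy_per_MBq = d_Gy * 100,
    sd_cGy_per_MBq = NA_real_,
    method = "svalue"
  ) |>
    structure(class = c("dose_report", class(tibble())))
}

#' Therapeutic indices from a dose report
#'
#' TI of an organ at risk is the tumor MAD divided by the organ MAD. The
#' tumor row carries no TI (the self-ratio is excluded). Reported TIs follow
#' the dosimetry-table convention of two decimals below 10 and whole numbers
#' at 10 and above; the unrounded ratio is always retained in `ti_raw`.
#' Organs with zero MAD get `NA` TI and a `ti_defined = FALSE` flag.
#'
#' @param doses A `dose_report` tibble (one arm).
#' @param tumor_label Organ label of the tumor row; default `"tumor"`.
#' @param arm Optional arm label stored in the output.
#' @return A `ti_report` tibble: `arm`, `organ`, `mad_cGy_per_MBq`,
#'   `ti_raw`, `ti`, `ti_defined`.
#' @export
#' @examples
#' d <- tibble::tibble(organ = c("blood", "kidney", "tumor"),
#'                     mad_cGy_per_MBq = c(0.55, 15.64, 37.54))
#' therapeutic_index(d)
therapeutic_index <- function(doses, tumor_label = "tumor", arm = NA_character_) {
  doses <- as_tibble(doses)
  stopifnot(all(c("organ", "mad_cGy_per_MBq") %in% names(doses)))
  tumor_label <- normalize_organ(tumor_label)
  tum <- doses$mad_cGy_per_MBq[doses$organ == tumor_label]
  if (length(tum) != 1 || !is.finite(tum) || tum <= 0) {
    stop("exactly one positive tumor MAD (organ '", tumor_label,
         "') is required.", call. = FALSE)
  }
  is_tumor <- doses$organ == tumor_label
  raw <- ifelse(is_tumor, NA_real_,
                ifelse(doses$mad_cGy_per_MBq > 0,
                       tum / doses$mad_cGy_per_MBq, NA_real_))
  tibble(
    arm = arm,
    organ = doses$organ,
    mad_cGy_per_MBq = doses$mad_cGy_per_MBq,
    ti_raw = raw,
    ti = round_reported(raw),
    ti_defined = !is_tumor & doses$mad_cGy_per_MBq > 0
  ) |>
    structure(class = c("ti_report", class(tibble())))
}

# dosimetry-table reporting convention: 2 decimals below 10, integer >= 10
round_reported <- function(x) {
  ifelse(is.na(x), NA_real_, ifelse(abs(x) < 10, round(x, 2), round(x)))
}
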