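# Derived hydraulic and anatomical variables.
#
# Input symbols follow the wood-anatomy convention: VD vessel diameter (um),
# VF vessel frequency (per mm^2), VA vessel area (um^2), F_L/F_W/F_D fibre
# lumen / wall / total diameter (um), WD wood density (g cm^-3).

#' Derived vessel variables
#'
#' Computes the four variables derived from vessel measurements: the vessel
#' composition index \eqn{S = VA/VF}, the vessel lumen fraction
#' \eqn{F = VF \cdot VA \cdot 10^{-6}}, Carlquist's vulnerability index
#' \eqn{VI = VD/VF} and the relative hydraulic conductivity
#' \eqn{RC = r^4 VF} with \eqn{r = VD/2} (a Hagen-Poiseuille-proportional
#' efficiency index, reported in um^4 mm^-2 without a viscosity constant).
#'
#' When `VA` is not supplied it is reconstructed as the equivalent-circle
#' area \eqn{\pi (VD/2)^2} of the mean diameter and flagged as such; note
#' that averaging diameters and then squaring is not the same as averaging
#' per-vessel areas, so supply measured areas when available.
#'
#' @param VD vessel diameter, um (vector).
#' @param VF vessel frequency, vessels per mm^2.
#' @param VA vessel area, um^2; reconstructed from `VD` when `NULL`.
#' @param lumen_fraction_scale unit factor applied to the raw product
#'   `VF * VA` (um^2 per mm^2). The default `1e-6` converts the product to a
#'   true dimensionless lumen fraction; use `1` to reproduce the raw index
#'   as sometimes tabulated.
#'
#' @return A `data.frame` with columns `VA`, `S`, `F`, `VI`, `RC` and a
#'   logical attribute `"va_reconstructed"`. Where `VF = 0`, `S` and `VI`
#'   are `NA` and `RC = 0`; missing inputs propagate as `NA`.
#'
#' @examples
#' derive_vessel_variables(VD = 200, VF = 4)
#' @export
derive_vessel_variables <- function(VD, VF, VA = NULL,
                                    lumen_fraction_scale = 1e-6) {
  .check_nonnegative(VD, "VD")
  .check_nonnegative(VF, "VF")
  n <- max(length(VD), length(VF))
  VD <- rep_len(VD, n)
  VF <- rep_len(VF, n)
  reconstructed <- is.null(VA)
  if (reconstructed) {
    VA <- pi * (VD / 2)^2
  } else {
    .check_nonnegative(VA, "VA")
    VA <- rep_len(VA, n)
  }
  S <- ifelse(VF == 0, NA_real_, VA / VF)
  VI <- ifelse(VF == 0, NA_real_, VD / VF)
  RC <- (VD / 2)^4 * VF
  F_frac <- VF * VA * lumen_fraction_scale
  out <- data.frame(VA = VA, S = S, F = F_frac, VI = VI, RC = RC)
  attr(out, "va_reconstructed") <- reconstructed
  out
}

#' Fibre total diameter
#'
#' \eqn{F_D = F_L + 2 F_W}: lumen diameter plus the wall crossed twice.
#'
#' @param F_L fibre lumen diameter, um.
#' @param F_W fibre wall thickness, um.
#' @return Fibre total diameter, um.
#' @examples
#' fibre_total_diameter(10, 5)
#' @export
fibre_total_diameter <- function(F_L, F_W) {
  .check_nonnegative(F_L, "F_L")
  .check_nonnegative(F_W, "F_W")
  F_L + 2 * F_W
}

#' Wood density by water displacement
#'
#' Basic (dry-mass over green-volume) wood density, the quantity obtained by
#' the water-displacement method: saturated volume from displaced water mass,
#' dry mass after oven drying to constant weight.
#'
#' @param dry_mass oven-dry mass, g.
#' @param green_volume saturated (green) volume, cm^3; must be positive.
#' @return Wood density, g cm^-3.
#' @export
wood_density <- function(dry_mass, green_volume) {
  .check_nonnegative(dry_mass, "dry_mass")
  if (any(!is.na(green_volume) & green_volume <= 0))
    stop("'green_volume' must be positive", call. = FALSE)
  dry_mass / green_volume
}

#' Species-level trait means
#'
#' Averages individual-level trait values to species level, optionally after
#' a log10 transform of the individual values (the transform is applied
#' before averaging, so the species value is a mean of logs).
#'
#' @param records data.frame with a `species` column and numeric trait
#'   columns.
#' @param traits character vector of trait column names; defaults to every
#'   numeric column except identifiers.
#' @param log10 apply `log10` to individual values before averaging;
#'   requires strictly positive values.
#' @return data.frame, one row per species, mean of each trait; `NA`
#'   measurements are dropped per trait (never treated as zero).
#' @export
species_means <- function(records, traits = NULL, log10 = FALSE) {
  .check_scalar_flag(log10, "log10")
  if (!"species" %in% names(records))
    stop("'records' must have a 'species' column", call. = FALSE)
  if (is.null(traits)) {
    num <- vapply(records, is.numeric, logical(1))
    traits <- setdiff(names(records)[num], c("species", "plot"))
  }
  missing_cols <- setdiff(traits, names(records))
  if (length(missing_cols))
    stop("trait column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  vals <- records[traits]
  if (log10) {
    for (tr in traits) {
      bad <- which(!is.na(vals[[tr]]) & vals[[tr]] <= 0)
      if (length(bad))
        stop("log10 requires positive values; trait '", tr,
             "' is nonpositive in record(s) ", paste(bad, collapse = ", "),
             call. = FALSE)
      vals[[tr]] <- log10(vals[[tr]])
    }
  }
  agg <- stats::aggregate(vals, by = list(species = records$species),
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$species), , drop = FALSE]
}
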