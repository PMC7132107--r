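## Combined NMR chemical-shift deviations between two states, using the
## standard nucleus-weighted formulas for methyl (13C) and amide (15N)
## groups.

#' Combined methyl chemical-shift deviation
#'
#' `CSD = sqrt( (dH^2 + dC^2 / 4) / 2 )` in ppm; symmetric in the sign of
#' both inputs and zero only when both are zero.
#'
#' @param delta_H Proton shift difference (ppm).
#' @param delta_C Carbon shift difference (ppm).
#' @return Combined deviation (ppm), vectorized.
#' @export
#' @examples
#' csd_methyl(0.1, 0.2)  # 0.1
csd_methyl <- function(delta_H, delta_C) {
  sqrt((delta_H^2 + delta_C^2 / 4) / 2)
}

#' Combined amide chemical-shift deviation
#'
#' `CSD = sqrt( (dH^2 + dN^2 / 25) / 2 )` in ppm.
#'
#' @param delta_H Proton shift difference (ppm).
#' @param delta_N Nitrogen shift difference (ppm).
#' @return Combined deviation (ppm), vectorized.
#' @export
#' @examples
#' csd_amide(0.1, 0.5)  # 0.1
csd_amide <- function(delta_H, delta_N) {
  sqrt((delta_H^2 + delta_N^2 / 25) / 2)
}

#' Per-residue combined CSDs from a shift-difference table
#'
#' @param shifts Data frame with columns `atom_group` (`"methyl"` or
#'   `"amide"`), `delta_H`, and `delta_C` (methyl rows) and/or `delta_N`
#'   (amide rows); extra columns (chain, residue, ...) are carried through.
#' @return The input tibble with a `csd` column appended.
#' @export
#' @examples
#' csd_table(data.frame(atom_group = c("methyl", "amide"),
#'                      delta_H = c(0.1, 0.1), delta_C = c(0.2, NA),
#'                      delta_N = c(NA, 0.5)))
csd_table <- function(shifts) {
  shifts <- tibble::as_tibble(shifts)
  stopifnot(all(c("atom_group", "delta_H") %in% names(shifts)))
  bad <- setdiff(unique(shifts$atom_group), c("methyl", "amide"))
  if (length(bad) > 0) {
    stop("csd_table: unknown atom_group values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dC <- shifts$delta_C %||% rep(NA_real_, nrow(shifts))
  dN <- shifts$delta_N %||% rep(NA_real_, nrow(shifts))
  shifts$csd <- ifelse(shifts$atom_group == "methyl",
                       csd_methyl(shifts$delta_H, dC),
                       csd_amide(shifts$delta_H, dN))
  shifts
}
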