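## ABEGO torsion-bin classification: A = alpha region, B = beta region,
## G/E = positive-phi helical/strand regions, O = cis peptide bond.

#' Classify backbone torsions into ABEGO bins
#'
#' Deterministic, total classification of (phi, psi, omega) triples into the
#' five-letter ABEGO alphabet. The cis-peptide bin O takes precedence
#' (`|omega| < 90` degrees); otherwise A and B require `phi < 0` (A when psi
#' lies in the alpha band, B otherwise) and G and E require `phi >= 0`
#' (G when psi lies in the positive-phi helical band, E otherwise). Angles
#' are wrapped into (-180, 180] first; the bins partition the torus.
#'
#' @param phi,psi,omega Backbone torsions in degrees (vectorized).
#' @return Character vector of bins in `c("A","B","E","G","O")`.
#' @export
#' @examples
#' classify_abego(-57, -47, 180)   # "A"
#' classify_abego(-120, 135, 180)  # "B"
#' classify_abego(60, 40, 180)     # "G"
#' classify_abego(0, 0, 0)         # "O"
classify_abego <- function(phi, psi, omega = 180) {
  k <- max(length(phi), length(psi), length(omega))
  phi <- wrap_angle(rep_len(phi, k))
  psi <- wrap_angle(rep_len(psi, k))
  omega <- wrap_angle(rep_len(omega, k))
  b <- HS_ABEGO
  out <- character(k)
  cis <- abs(omega) < b$omega_cis_max
  out[cis] <- "O"
  neg <- !cis & phi < 0
  a <- neg & psi >= b$a_psi_min & psi < b$a_psi_max
  out[a] <- "A"
  out[neg & !a] <- "B"
  pos <- !cis & phi >= 0
  g <- pos & psi >= b$g_psi_min & psi < b$g_psi_max
  out[g] <- "G"
  out[pos & !g] <- "E"
  out
}

#' ABEGO string of a torsion table
#'
#' @param torsions Data frame with columns `phi`, `psi`, `omega` (degrees);
#'   rows with missing torsions yield `"-"`.
#' @return A single character string, one letter per row.
#' @export
abego_string <- function(torsions) {
  ok <- stats::complete.cases(torsions[, c("phi", "psi", "omega")])
  out <- rep("-", nrow(torsions))
  if (any(ok)) {
    out[ok] <- classify_abego(torsions$phi[ok], torsions$psi[ok], torsions$omega[ok])
  }
  paste(out, collapse = "")
}
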