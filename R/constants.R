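## Module-level numerical constants. Every tunable geometric threshold lives
## here so that the coarse-grained model is auditable in one place.

# Ideal alpha-helix constants (canonical values).
HS_HELIX <- list(
  rise  = 1.51,   # A per residue along the helix axis
  twist = 100,    # deg per residue about the minor-helix axis
  r1    = 2.26,   # A, CA radius about the helix axis
  ca_ca = 3.8     # A, ideal consecutive CA-CA distance
)

# Ideal helical backbone torsions used to annotate helical segments.
HS_HELICAL_TORSION <- c(phi = -57, psi = -47, omega = 180)

# ABEGO bin boundaries (degrees). O takes precedence when |omega| < 90.
HS_ABEGO <- list(
  omega_cis_max = 90,
  a_psi_min = -75, a_psi_max = 50,    # A: phi < 0 and psi in [-75, 50)
  g_psi_min = -100, g_psi_max = 100   # G: phi >= 0 and psi in [-100, 100)
)

# Representative backbone torsions for each ABEGO bin (used by the
# turn-template builder; omega is trans except O).
HS_ABEGO_TORSIONS <- list(
  A = c(phi = -63, psi = -41, omega = 180),
  B = c(phi = -120, psi = 135, omega = 180),
  E = c(phi = 75, psi = 160, omega = 180),
  G = c(phi = 60, psi = 35, omega = 180),
  O = c(phi = -75, psi = 160, omega = 0)
)

# Fixed ABEGO turn-template library for hinge closure, by hinge length.
HS_TURN_TEMPLATES <- list(
  `2` = c("GB", "BB"),
  `3` = c("GBB", "BAB", "BBG", "GBA"),
  `4` = c("GBBA", "BABB", "GBAB"),
  `5` = c("GBBAB", "BABAB"),
  `6` = c("GBBABB", "BABABB"),
  `7` = c("GBBABBA", "BABABAB")
)

# State-builder thresholds (A unless noted).
HS_BUILDER <- list(
  clash_min_ca          = 2.5,   # global inter-chain CA-CA clash threshold
  long_flip_approach    = 12,    # long state: max of min inter-chain flip CA dist
  short_flip_inner_max  = 10,    # short state: max of min flip-to-inner CA dist
  long_axis_tol_deg     = 15,    # long state: flip axis vs outer axis
  short_anti_min_deg    = 150,   # short state: flip axis vs inner axis
  ion_offset            = 2.4,   # pseudo side-chain offset from CA toward axis
  ion_window            = c(2.2, 3.0),  # coordination distance window
  axis_tol              = 1e-6,  # C3 symmetry tolerance
  long_pack_radius      = 5.2,   # superhelical radius of packed flipping helices
  short_flip_radius     = 12.8,  # axis radius of the folded-back flipping helix
  short_flip_azimuth    = 20,    # deg, azimuth of the folded-back flipping helix
  short_flip_drop_base  = 1.6,   # A; with the per-residue term below, the flip
  short_flip_drop_res   = 1.5,   # start sits base + res * hinge_len below the
                                 # outer top, so longer hinges arch further down
  turn_roll_step_deg    = 1      # roll scan resolution for turn placement
)

# Interface-design constants.
HS_INTERFACE <- list(
  contact_cutoff = 10,           # A, CA-CA cutoff defining interface contacts
  a_identities   = c("N", "S", "T"),  # polar network layer (Asn core)
  x_identities   = c("L", "I", "V"),  # hydrophobic layer
  hbond_window   = c(2.6, 3.2),  # A, cyclic network pseudo-atom distances
  hbond_offset   = 2.4           # A, pseudo donor/acceptor offset toward axis
)

# Frozen state-preference weights, hinge-proximal position first.
# Calibrated once against the observed states (XXA/XAX/XAA short, AAA long)
# and then frozen; positive scores favor the long state.
HS_SCORE_WEIGHTS <- list(
  w_A = c(0.30, 0.20, 0.15),
  w_X = c(0.60, 0.35, 0.25)
)

# Shrake-Rupley SASA on CA pseudo-residues.
HS_SASA <- list(
  probe     = 1.4,   # A
  radius    = 3.0,   # A, uniform CA pseudo-residue radius
  n_points  = 960    # sphere quadrature points
)

# State classification.
HS_CLASSIFY <- list(threshold = 3.0, tie_tol = 1e-6)

# SAXS defaults.
HS_SAXS <- list(
  q_min = 0, q_max = 0.4, q_n = 201,   # default grid, 1/A
  sigma_frac = 0.01,                   # default sigma = 1% of I
  sigma_floor = 1e-9,
  qmax_rg = 0.9                        # Guinier window limit q*Rg; kept below
                                       # the globular 1.3 convention because
                                       # the bundles are mildly elongated
)

#' Package geometric constants
#'
#' Returns the full table of frozen numerical constants used by the
#' coarse-grained model: ideal helix geometry, ABEGO bin boundaries, builder
#' thresholds, interface identity tables, state-preference weights, SASA and
#' SAXS defaults.
#'
#' @return A named list of constant tables.
#' @export
#' @examples
#' hs_constants()$builder$clash_min_ca
hs_constants <- function() {
  list(
    helix = HS_HELIX,
    abego = HS_ABEGO,
    abego_torsions = HS_ABEGO_TORSIONS,
    turn_templates = HS_TURN_TEMPLATES,
    builder = HS_BUILDER,
    interface = HS_INTERFACE,
    score_weights = HS_SCORE_WEIGHTS,
    sasa = HS_SASA,
    classify = HS_CLASSIFY,
    saxs = HS_SAXS
  )
}
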