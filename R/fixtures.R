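## Seeded synthetic test-input generation: reference state models, noised
## decoys, synthetic scattering profiles and a synthetic chemical-shift
## table, all reproducible from a single seed.

#' Add isotropic Gaussian coordinate noise to a model
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param model A [bundle_model()].
#' @param sd Per-coordinate noise standard deviation (Angstrom).
#' @return A perturbed [bundle_model()] with `state_tag = "unknown"`.
#' @export
perturb_model <- function(model, sd = 0.5) {
  out <- model
  n <- nrow(out)
  out$x <- out$x + stats::rnorm(n, 0, sd)
  out$y <- out$y + stats::rnorm(n, 0, sd)
  out$z <- out$z + stats::rnorm(n, 0, sd)
  attr(out, "state_tag") <- "unknown"
  out
}

#' Generate a directory of synthetic test inputs
#'
#' Builds the short and long reference models of a design and emits, under
#' `dir`: the two reference PDBs, `n_decoys` noised decoys per state
#' (isotropic Gaussian CA noise), synthetic scattering profiles for both
#' states with multiplicative Gaussian noise, and a CSV of synthetic
#' per-residue chemical-shift differences (large at the hinge and flipping
#' helix, where the conformational change is localized; small elsewhere).
#' All outputs are reproducible byte-for-byte from the seed, which is
#' recorded in every file header.
#'
#' @param seed Integer RNG seed.
#' @param spec An [architecture_spec()] (default design if omitted).
#' @param dir Output directory (created if missing).
#' @param n_decoys Decoys per state.
#' @param decoy_noise Per-coordinate decoy noise sd (Angstrom).
#' @param saxs_noise Relative multiplicative profile noise.
#' @return Invisibly, a tibble listing the files written (`file`, `kind`,
#'   `source_state`).
#' @export
#' @examples
#' \donttest{
#' files <- generate_fixtures(1, dir = tempfile())
#' }
generate_fixtures <- function(seed, spec = default_architecture(), dir,
                              n_decoys = 5, decoy_noise = 0.5,
                              saxs_noise = 0.02) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("generate_fixtures: cannot create directory ", dir, call. = FALSE)
  }
  seed <- as.integer(seed)
  set.seed(seed)
  short <- build_short_state(spec)
  long <- build_long_state(spec)
  manifest <- list()
  add <- function(file, kind, src) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = file, kind = kind, source_state = src)
  }

  for (st in c("short", "long")) {
    model <- if (st == "short") short else long
    f <- file.path(dir, paste0(st, ".pdb"))
    write_pdb(model, f, seed = seed, config = spec)
    add(f, "reference", st)
    for (i in seq_len(n_decoys)) {
      fd <- file.path(dir, sprintf("decoy_%s_%02d.pdb", st, i))
      write_pdb(perturb_model(model, decoy_noise), fd, seed = seed, config = spec)
      add(fd, "decoy", st)
    }
    prof <- debye_profile(model)
    noisy <- scattering_profile(
      prof$q, prof$I * (1 + stats::rnorm(nrow(prof), 0, saxs_noise)))
    fp <- file.path(dir, paste0("saxs_", st, ".dat"))
    write_saxs(noisy, fp, header = c(
      sprintf("helixswitch %s synthetic SAXS, state %s", hs_version(), st),
      sprintf("seed %d  noise %.3f  config %s", seed, saxs_noise, config_hash(spec))))
    add(fp, "saxs", st)
  }

  shifts <- synthetic_shift_table(short)
  fs <- file.path(dir, "shifts.csv")
  hdr <- sprintf("# helixswitch %s synthetic shift differences, seed %d",
                 hs_version(), seed)
  writeLines(c(hdr, paste(names(shifts), collapse = ",")), fs)
  utils::write.table(shifts, fs, sep = ",", row.names = FALSE, col.names = FALSE,
                     append = TRUE, quote = FALSE)
  add(fs, "shifts", NA_character_)

  invisible(dplyr::bind_rows(manifest))
}

## Synthetic per-residue shift differences between states: mobile segments
## (hinge, flipping) carry large differences, the static base small ones.
synthetic_shift_table <- function(model) {
  ch <- model[model$chain == sort(unique(model$chain))[1], ]
  mobile <- ch$segment %in% c("hinge", "flipping")
  n <- nrow(ch)
  scale_H <- ifelse(mobile, 0.12, 0.015)
  tibble::tibble(
    chain = ch$chain,
    residue = ch$resno,
    atom_group = rep_len(c("methyl", "amide"), n),
    delta_H = round(stats::rnorm(n, 0, scale_H), 4),
    delta_C = round(ifelse(rep_len(c(TRUE, FALSE), n),
                           stats::rnorm(n, 0, 4 * scale_H), NA), 4),
    delta_N = round(ifelse(rep_len(c(FALSE, TRUE), n),
                           stats::rnorm(n, 0, 8 * scale_H), NA), 4)
  )
}

#' Read a chemical-shift difference CSV
#'
#' @param path CSV with columns `chain`, `residue`, `atom_group`, `delta_H`,
#'   `delta_C`, `delta_N` (comment lines starting with `#` allowed).
#' @return A tibble.
#' @export
read_shift_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
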