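## ArchitectureSpec: everything needed to build both states of one design.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Architecture of a two-state bundle design
#'
#' Describes a single design from which both the short and the long state can
#' be built: the Crick parameters of the inner and outer base helices, the
#' flipping-helix length, the hinge (length, mode and sequence), the key and
#' backup hinge residue positions, and optionally precomputed interface layer
#' positions.
#'
#' The hinge sequence covers the hinge residues plus the backup residue at
#' the hinge/flipping junction (the four-letter window naming convention,
#' e.g. `"GGGT"`); the key residue is the last hinge residue and the backup
#' residue is the first flipping-helix residue.
#'
#' @param inner_helix,outer_helix [crick_params()] for the base helices.
#' @param flipping_helix_len Flipping-helix length in residues (>= 8).
#' @param hinge_len Hinge length in residues (2-7).
#' @param hinge_mode `"turn"` (short state buildable) or `"helical"`.
#' @param hinge_sequence Hinge + backup amino-acid string of length
#'   `hinge_len + 1`.
#' @param key_hinge_index,backup_hinge_index 1-based per-chain residue
#'   indices; defaults place the key residue at the last hinge position and
#'   the backup immediately after.
#' @param layer_positions Optional list of three residue-index sets
#'   (hinge-proximal first) as produced by [assign_layers()].
#' @return An object of class `architecture_spec`.
#' @export
#' @examples
#' spec <- default_architecture()
#' spec$hinge_sequence
architecture_spec <- function(inner_helix, outer_helix,
                              flipping_helix_len = 21L,
                              hinge_len = 3L,
                              hinge_mode = c("turn", "helical"),
                              hinge_sequence = NULL,
                              key_hinge_index = NULL,
                              backup_hinge_index = NULL,
                              layer_positions = NULL) {
  hinge_mode <- match.arg(hinge_mode)
  if (!inherits(inner_helix, "crick_params")) inner_helix <- do.call(crick_params, inner_helix)
  if (!inherits(outer_helix, "crick_params")) outer_helix <- do.call(crick_params, outer_helix)
  hinge_len <- as.integer(hinge_len)
  flipping_helix_len <- as.integer(flipping_helix_len)
  if (hinge_len < 2 || hinge_len > 7) {
    stop("architecture_spec: hinge_len must be between 2 and 7 residues", call. = FALSE)
  }
  if (flipping_helix_len < 8) {
    stop("architecture_spec: flipping_helix_len must be >= 8", call. = FALSE)
  }
  if (is.null(hinge_sequence)) {
    hinge_sequence <- paste0(strrep("G", hinge_len), "T")
  }
  check_hinge_sequence(hinge_sequence, hinge_len)
  n_in <- inner_helix$n_res
  n_out <- outer_helix$n_res
  hinge_start <- n_in + n_out + 1L
  if (is.null(key_hinge_index)) key_hinge_index <- hinge_start + hinge_len - 1L
  if (is.null(backup_hinge_index)) backup_hinge_index <- key_hinge_index + 1L
  if (key_hinge_index < hinge_start || key_hinge_index > hinge_start + hinge_len - 1L) {
    stop("architecture_spec: key_hinge_index must fall inside the hinge segment",
         call. = FALSE)
  }
  if (backup_hinge_index < hinge_start ||
      backup_hinge_index > hinge_start + hinge_len) {
    stop("architecture_spec: backup_hinge_index must fall inside the hinge window",
         call. = FALSE)
  }
  structure(list(
    inner_helix = inner_helix, outer_helix = outer_helix,
    flipping_helix_len = flipping_helix_len,
    hinge_len = hinge_len, hinge_mode = hinge_mode,
    hinge_sequence = hinge_sequence,
    key_hinge_index = as.integer(key_hinge_index),
    backup_hinge_index = as.integer(backup_hinge_index),
    layer_positions = layer_positions
  ), class = "architecture_spec")
}

check_hinge_sequence <- function(seq, hinge_len) {
  letters1 <- strsplit(seq, "")[[1]]
  if (length(letters1) != hinge_len + 1L) {
    stop(sprintf(
      "hinge_sequence must have length hinge_len + 1 = %d (hinge plus backup residue), got %d",
      hinge_len + 1L, length(letters1)), call. = FALSE)
  }
  bad <- setdiff(letters1, AA1)
  if (length(bad) > 0) {
    stop("hinge_sequence contains invalid amino-acid letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec>\n")
  cat(sprintf("  inner helix: %d res, r0 %.2f A | outer helix: %d res, r0 %.2f A\n",
              x$inner_helix$n_res, x$inner_helix$r0,
              x$outer_helix$n_res, x$outer_helix$r0))
  cat(sprintf("  flipping helix: %d res | hinge: %d res (%s) '%s'\n",
              x$flipping_helix_len, x$hinge_len, x$hinge_mode, x$hinge_sequence))
  cat(sprintf("  key hinge residue %d, backup %d\n",
              x$key_hinge_index, x$backup_hinge_index))
  invisible(x)
}

#' Frozen default two-state architecture
#'
#' The package's reference design: an untwisted idealized C3 bundle with a
#' 45-residue inner helix (superhelical radius 4.8 Angstrom), a 43-residue
#' outer helix (radius 9.2 Angstrom, phases chosen so the key hinge residue
#' presents an axial coordination geometry in the long state), a 21-residue
#' flipping helix and a 3-residue glycine hinge with threonine backup
#' (`"GGGT"`). Built once to reproduce the ~66 Angstrom short and ~100
#' Angstrom long axial heights and then frozen.
#'
#' @return An `architecture_spec`.
#' @export
#' @examples
#' measure_height(build_short_state(default_architecture()))
default_architecture <- function() {
  architecture_spec(
    inner_helix = crick_params(r0 = 4.8, omega0 = 0, omega1 = HS_HELIX$twist,
                               phi0 = 0, phi1 = 0, n_res = 45L),
    outer_helix = crick_params(r0 = 9.2, omega0 = 0, omega1 = HS_HELIX$twist,
                               phi0 = 60, phi1 = 48.5, n_res = 43L),
    flipping_helix_len = 21L, hinge_len = 3L, hinge_mode = "turn"
  )
}

#' Replace the hinge window sequence of a design
#'
#' Pure function returning a spec identical to the input except for the
#' hinge + backup sequence window (e.g. parent `"GGGT"` to calcium-site
#' variant `"GVDQ"` or nickel-site variant `"GGHN"`).
#'
#' @param spec An [architecture_spec()].
#' @param new_sequence Replacement amino-acid string of length
#'   `hinge_len + 1`.
#' @return A new `architecture_spec`.
#' @export
#' @examples
#' mutate_hinge(default_architecture(), "GVDQ")$hinge_sequence
mutate_hinge <- function(spec, new_sequence) {
  stopifnot(inherits(spec, "architecture_spec"))
  check_hinge_sequence(new_sequence, spec$hinge_len)
  out <- spec
  out$hinge_sequence <- new_sequence
  out
}

#' Write an architecture spec to JSON
#'
#' @param spec An [architecture_spec()].
#' @param path File path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to a file.
#' @export
architecture_to_json <- function(spec, path = NULL) {
  lst <- unclass(spec)
  lst$inner_helix <- unclass(lst$inner_helix)
  lst$outer_helix <- unclass(lst$outer_helix)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an architecture spec from JSON
#'
#' @param x JSON string or file path.
#' @return An [architecture_spec()].
#' @export
architecture_from_json <- function(x) {
  lst <- jsonlite::fromJSON(x)
  lst$inner_helix <- do.call(crick_params, lst$inner_helix)
  lst$outer_helix <- do.call(crick_params, lst$outer_helix)
  do.call(architecture_spec, lst)
}
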