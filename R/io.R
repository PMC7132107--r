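## PDB and FASTA input/output. Coordinate records go through bio3d; the
## package adds REMARK 300 metadata lines (tool version, seed, config hash,
## state tag) that bio3d ignores on read and this module parses back.

SEGID_MAP <- c(base_inner = "BINN", base_outer = "BOUT",
               hinge = "HING", flipping = "FLIP")

hs_version <- function() {
  as.character(utils::packageVersion("helixswitch"))
}

#' Short fingerprint of a configuration object
#'
#' Deterministic 31-bit polynomial rolling hash of the serialized object,
#' reported as 8 hex digits; used to stamp outputs with the configuration
#' they came from.
#'
#' @param x Any R object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

metadata_remarks <- function(state_tag = "unknown", seed = NA, config = NULL) {
  c(sprintf("REMARK 300 HELIXSWITCH VERSION %s", hs_version()),
    sprintf("REMARK 300 HELIXSWITCH STATE %s", state_tag),
    if (!is.na(seed)) sprintf("REMARK 300 HELIXSWITCH SEED %d", as.integer(seed)),
    if (!is.null(config)) sprintf("REMARK 300 HELIXSWITCH CONFIG %s", config_hash(config)))
}

#' Write a bundle model to a PDB file
#'
#' Fixed-width ATOM records (CA only) with chain IDs, 1-based residue
#' numbering, segment labels in the segid column, and REMARK 300 metadata
#' lines carrying the tool version, state tag and optionally the RNG seed
#' and a configuration hash. Coordinates are serialized at PDB precision
#' (3 decimals).
#'
#' @param model A [bundle_model()].
#' @param path Output file path.
#' @param seed Optional integer seed recorded in the header.
#' @param config Optional configuration object hashed into the header.
#' @return The path, invisibly.
#' @export
write_pdb <- function(model, path, seed = NA, config = NULL) {
  writeLines(metadata_remarks(state_tag(model), seed, config), path)
  n <- nrow(model)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    resno = model$resno,
    resid = bio3d::aa123(model$aa),
    chain = model$chain,
    elety = rep("CA", n),
    eleno = seq_len(n),
    o = rep(1, n), b = rep(0, n),
    segid = unname(SEGID_MAP[model$segment]),
    print.segid = TRUE,
    append = TRUE
  )
  invisible(path)
}

#' Read a bundle model from a PDB file
#'
#' Extracts CA atoms per chain in residue order, preserving chain IDs and
#' residue numbering. Segment labels are restored from the segid column when
#' present (defaulting to `base_inner`), and the state tag from the
#' REMARK 300 metadata if the file was written by [write_pdb()]. Files with
#' a chain count other than 3 load with a warning; duplicate CA records for
#' a residue keep the first occurrence with a warning.
#'
#' @param path PDB file path.
#' @return A [bundle_model()].
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("read_pdb: ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", ]
  if (nrow(at) == 0) stop("read_pdb: no CA ATOM records in ", path, call. = FALSE)
  at$chain[is.na(at$chain)] <- "A"
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    warning("read_pdb: duplicate CA records; keeping first occurrence")
    at <- at[!duplicated(key), ]
  }
  seg_rev <- stats::setNames(names(SEGID_MAP), SEGID_MAP)
  segment <- seg_rev[as.character(at$segid)]
  segment[is.na(segment)] <- "base_inner"
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | aa == "X"] <- "A"
  state <- "unknown"
  head_lines <- grep("^REMARK 300 HELIXSWITCH STATE",
                     readLines(path, n = 10, warn = FALSE), value = TRUE)
  if (length(head_lines) > 0) {
    st <- sub("^REMARK 300 HELIXSWITCH STATE\\s+", "", head_lines[1])
    if (st %in% c("short", "long", "unknown")) state <- st
  }
  n_chain <- length(unique(at$chain))
  if (n_chain != 3) {
    warning(sprintf("read_pdb: %d chain(s) found (expected 3 for a trimer)", n_chain))
  }
  bundle_model(tibble::tibble(
    chain = at$chain, resno = at$resno, segment = unname(segment),
    aa = unname(aa), x = at$x, y = at$y, z = at$z
  ), state_tag = state)
}

#' Write designed sequences to a FASTA file
#'
#' @param model A [bundle_model()] (one record per chain) or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(model, path) {
  seqs <- if (is.character(model)) model else bundle_sequence(model)
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) strsplit(s, "")[[1]]),
    names = names(seqs), file.out = path)
  invisible(path)
}
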