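## Symmetry-aware structural comparison: Kabsch superposition, minimum RMSD
## over the cyclic chain permutations of a C3 trimer, and short/long/other
## state classification of candidate structures.

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of `P` onto `Q` by singular value
#' decomposition, with the proper-rotation (determinant +1) branch enforced
#' so reflections are never used.
#'
#' @param P,Q Equal-length coordinate matrices or data frames (>= 3 points,
#'   non-degenerate).
#' @return List with `rotation` (3x3), `translation` (length 3; the
#'   superposed coordinates are `P %*% t(rotation) + translation`), and
#'   `rmsd` (Angstrom).
#' @export
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(P, P)$rmsd
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(as.data.frame(P)); Q <- as.matrix(as.data.frame(Q))
  if (ncol(P) > 3) P <- P[, c("x", "y", "z")]
  if (ncol(Q) > 3) Q <- Q[, c("x", "y", "z")]
  if (nrow(P) != nrow(Q)) stop("kabsch_superpose: length mismatch", call. = FALSE)
  if (nrow(P) < 3) stop("kabsch_superpose: need at least 3 points", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2) {
    stop("kabsch_superpose: rank-deficient input", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

cyclic_permutations <- function(chains) {
  n <- length(chains)
  lapply(seq_len(n) - 1, function(s) chains[((seq_len(n) - 1 + s) %% n) + 1])
}

stacked_xyz <- function(model, chain_order) {
  do.call(rbind, lapply(chain_order, function(ch) {
    d <- model[model$chain == ch, ]
    as.matrix(d[order(d$resno), c("x", "y", "z")])
  }))
}

#' Symmetry-aware RMSD between two trimers
#'
#' Minimum Kabsch RMSD over the three cyclic chain permutations of the model
#' against the reference. Only cyclic mappings are searched: the chains are
#' oriented (N to C), so anti-cyclic mappings are invalid for a C3 assembly.
#' The result is never larger than the identity-mapping RMSD.
#'
#' @param model,reference Three-chain [bundle_model()]s with equal per-chain
#'   residue counts.
#' @return List with `rmsd` (Angstrom) and `mapping` (model chains in the
#'   order matched to the reference chains).
#' @export
#' @examples
#' long <- build_long_state(default_architecture())
#' symmetric_rmsd(long, long)$rmsd
symmetric_rmsd <- function(model, reference) {
  mc <- sort(unique(model$chain)); rc <- sort(unique(reference$chain))
  if (length(mc) != 3 || length(rc) != 3) {
    stop("symmetric_rmsd: both structures must have exactly 3 chains", call. = FALSE)
  }
  if (nrow(model) != nrow(reference)) {
    stop("symmetric_rmsd: residue counts differ", call. = FALSE)
  }
  ref_xyz <- stacked_xyz(reference, rc)
  best <- NULL
  for (perm in cyclic_permutations(mc)) {
    r <- kabsch_superpose(stacked_xyz(model, perm), ref_xyz)$rmsd
    if (is.null(best) || r < best$rmsd) best <- list(rmsd = r, mapping = perm)
  }
  best
}

#' Classify a structure as short, long or other
#'
#' Computes the symmetric RMSD of the candidate structure to the short and
#' long reference backbones and labels it `short` or `long` when the smaller
#' RMSD is below the threshold, `other` otherwise; exact ties are `other`.
#' The call is invariant to global rotation and translation of the
#' candidate.
#'
#' @param structure,short_ref,long_ref Three-chain [bundle_model()]s with
#'   compatible residue counts.
#' @param threshold RMSD cutoff (Angstrom) for resembling a reference.
#' @return A `classification_result`: list with `label`, `rmsd_short`,
#'   `rmsd_long`, `chain_mapping`, `threshold`.
#' @export
#' @examples
#' spec <- default_architecture()
#' s <- build_short_state(spec); l <- build_long_state(spec)
#' classify_state(s, s, l)$label
classify_state <- function(structure, short_ref, long_ref,
                           threshold = HS_CLASSIFY$threshold) {
  rs <- symmetric_rmsd(structure, short_ref)
  rl <- symmetric_rmsd(structure, long_ref)
  tie <- abs(rs$rmsd - rl$rmsd) < HS_CLASSIFY$tie_tol
  label <- if (tie) "other"
  else if (rs$rmsd < rl$rmsd && rs$rmsd <= threshold) "short"
  else if (rl$rmsd < rs$rmsd && rl$rmsd <= threshold) "long"
  else "other"
  mapping <- if (label == "long") rl$mapping else rs$mapping
  structure(list(label = label, rmsd_short = rs$rmsd, rmsd_long = rl$rmsd,
                 chain_mapping = mapping, threshold = threshold),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result>  %s (rmsd short %.3f A, long %.3f A, threshold %.1f A)\n",
    x$label, x$rmsd_short, x$rmsd_long, x$threshold))
  invisible(x)
}

#' State fractions over a set of decoys
#'
#' Classifies every decoy against the short and long references and reports
#' the fraction labelled short, long and other (summing to 1).
#'
#' @param decoys Non-empty list of [bundle_model()]s.
#' @inheritParams classify_state
#' @return A tibble with columns `f_short`, `f_long`, `f_other`, `n`.
#' @export
state_fractions <- function(decoys, short_ref, long_ref,
                            threshold = HS_CLASSIFY$threshold) {
  if (length(decoys) == 0) stop("state_fractions: empty decoy list", call. = FALSE)
  labels <- vapply(decoys, function(d) {
    classify_state(d, short_ref, long_ref, threshold)$label
  }, character(1))
  n <- length(labels)
  tibble::tibble(
    f_short = sum(labels == "short") / n,
    f_long = sum(labels == "long") / n,
    f_other = sum(labels == "other") / n,
    n = n
  )
}
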