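## The bundle_model container: a tidy per-residue CA table for a C3 trimer,
## with segment labels, one-letter sequence and optional torsion annotations.

SEGMENT_LEVELS <- c("base_inner", "base_outer", "hinge", "flipping")

#' Construct a bundle model
#'
#' A `bundle_model` is a tibble with one row per CA atom and columns `chain`,
#' `resno` (1-based, continuous through the hinge), `segment` (one of
#' `base_inner`, `base_outer`, `hinge`, `flipping`), `aa` (one-letter code),
#' `x`, `y`, `z` (Angstrom) and torsion annotations `phi`, `psi`, `omega`
#' (degrees, `NA` where not assigned). The state tag (`short`, `long` or
#' `unknown`) is stored as an attribute.
#'
#' @param df Data frame with at least `chain`, `resno`, `x`, `y`, `z`.
#' @param state_tag One of `"short"`, `"long"`, `"unknown"`.
#' @return A `bundle_model` tibble.
#' @export
bundle_model <- function(df, state_tag = "unknown") {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(df)))
  if (is.null(df[["segment"]])) df$segment <- "base_inner"
  if (is.null(df[["aa"]])) df$aa <- "A"
  for (col in c("phi", "psi", "omega")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$segment <- as.character(df$segment)
  bad <- setdiff(unique(df$segment), SEGMENT_LEVELS)
  if (length(bad) > 0) {
    stop("bundle_model: unknown segment labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, c("chain", "resno", "segment", "aa", "x", "y", "z",
               "phi", "psi", "omega")]
  df <- dplyr::arrange(df, .data$chain, .data$resno)
  structure(df, state_tag = match.arg(state_tag, c("short", "long", "unknown")),
            class = c("bundle_model", class(tibble::tibble())))
}

#' @export
print.bundle_model <- function(x, ...) {
  cat(sprintf("<bundle_model>  state: %s  chains: %s  residues/chain: %s\n",
              state_tag(x), paste(unique(x$chain), collapse = ""),
              paste(unique(table(x$chain)), collapse = "/")))
  NextMethod()
}

#' State tag of a bundle model
#' @param model A [bundle_model()].
#' @return `"short"`, `"long"` or `"unknown"`.
#' @export
state_tag <- function(model) attr(model, "state_tag") %||% "unknown"

#' Per-chain sequences of a bundle model
#' @param model A [bundle_model()].
#' @return Named character vector of one-letter sequences.
#' @export
bundle_sequence <- function(model) {
  sp <- split(model$aa, model$chain)
  vapply(sp, paste, character(1), collapse = "")
}

bundle_xyz <- function(model, chain = NULL, segment = NULL, resno = NULL) {
  d <- model
  if (!is.null(chain)) d <- d[d$chain %in% chain, ]
  if (!is.null(segment)) d <- d[d$segment %in% segment, ]
  if (!is.null(resno)) d <- d[d$resno %in% resno, ]
  as.matrix(d[, c("x", "y", "z")])
}

#' Maximum C3 deviation of a trimer model
#'
#' Rotates chain A by 120/240 degrees about z and reports the largest
#' coordinate deviation from chains B and C.
#'
#' @param model A three-chain [bundle_model()].
#' @return Deviation in Angstrom.
#' @export
c3_deviation <- function(model) {
  ch <- sort(unique(model$chain))
  stopifnot(length(ch) == 3)
  a <- bundle_xyz(model, ch[1])
  max(
    max(abs(a %*% t(rot_z(120)) - bundle_xyz(model, ch[2]))),
    max(abs(a %*% t(rot_z(240)) - bundle_xyz(model, ch[3])))
  )
}

#' Minimum inter-chain CA-CA distance
#'
#' @param model A [bundle_model()].
#' @return A list with `min_dist` (Angstrom) and `pair` (a tibble naming the
#'   closest residue pair).
#' @export
min_interchain_distance <- function(model) {
  chains <- unique(model$chain)
  best <- list(min_dist = Inf, pair = NULL)
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i) next
      a <- model[model$chain == chains[i], ]
      b <- model[model$chain == chains[j], ]
      d2 <- outer(rowSums(bundle_xyz(a)^2), rowSums(bundle_xyz(b)^2), "+") -
        2 * bundle_xyz(a) %*% t(bundle_xyz(b))
      k <- arrayInd(which.min(d2), dim(d2))
      dmin <- sqrt(max(d2[k], 0))
      if (dmin < best$min_dist) {
        best <- list(min_dist = dmin, pair = tibble::tibble(
          chain1 = chains[i], resno1 = a$resno[k[1]],
          chain2 = chains[j], resno2 = b$resno[k[2]]))
      }
    }
  }
  best
}

check_clashes <- function(model, threshold = HS_BUILDER$clash_min_ca, what = "model") {
  mc <- min_interchain_distance(model)
  if (mc$min_dist < threshold) {
    p <- mc$pair
    stop(sprintf(
      "%s construction failed: inter-chain CA clash (%.2f A < %.2f A) between %s%d and %s%d",
      what, mc$min_dist, threshold, p$chain1, p$resno1, p$chain2, p$resno2),
      call. = FALSE)
  }
  invisible(mc$min_dist)
}

## Principal-axis direction of an ordered trace, signed first -> last.
segment_axis <- function(m) {
  m <- as.matrix(m)
  c0 <- colMeans(m)
  v <- svd(sweep(m, 2, c0))$v[, 1]
  if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

axis_angle_deg <- function(v1, v2) {
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  rad2deg(acos(pmin(pmax(ct, -1), 1)))
}
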