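## Interface-layer configurations: each of three interface positions between
## the inner and flipping helices is either a hydrogen-bond-network layer
## ("A") or a hydrophobic layer ("X"), named hinge-proximal first.

#' Layer configuration
#'
#' @param code Length-3 string over the alphabet `{A, X}`, hinge-proximal
#'   position first (e.g. `"XAX"`).
#' @return A `layer_config` object.
#' @export
#' @examples
#' layer_config("XAX")
layer_config <- function(code) {
  stopifnot(is.character(code), length(code) == 1)
  letters1 <- strsplit(code, "")[[1]]
  if (length(letters1) != 3 || !all(letters1 %in% c("A", "X"))) {
    stop("layer_config: code must be 3 characters over {A, X}", call. = FALSE)
  }
  structure(list(code = code, layers = letters1), class = "layer_config")
}

#' @export
print.layer_config <- function(x, ...) {
  cat(sprintf("<layer_config> %s (%d hydrogen-bond layers)\n",
              x$code, sum(x$layers == "A")))
  invisible(x)
}

#' Parse a layer-configuration name
#'
#' Inverse of the naming convention: `parse_config(x$code)` round-trips.
#'
#' @param name Config name such as `"XAA"`.
#' @return A [layer_config()].
#' @export
parse_config <- function(name) layer_config(name)

#' Enumerate all interface-layer configurations
#'
#' All permutations of the two layer types over `k` interface positions
#' (2^k configurations), lexicographically sorted. With the default `k = 3`
#' this is the eight-member design family spanning `AAA` to `XXX`.
#'
#' @param k Number of interface positions.
#' @return A tibble with columns `code` and `n_networks` (count of A layers),
#'   sorted by `code`.
#' @export
#' @examples
#' enumerate_configs()
enumerate_configs <- function(k = 3) {
  grid <- do.call(expand.grid, rep(list(c("A", "X")), k))
  codes <- sort(apply(as.matrix(grid), 1, paste, collapse = ""))
  tibble::tibble(code = codes,
                 n_networks = vapply(strsplit(codes, ""),
                                     function(x) sum(x == "A"), integer(1)))
}

#' Assign interface residues to three layers
#'
#' Finds the inner/flipping interface of the short state (CA-CA contacts
#' within a cutoff between the `base_inner` and `flipping` segments of one
#' monomer) and partitions the contact residues into three z slabs of equal
#' thickness, ordered hinge-proximal first. The assignment is defined on the
#' short state and reused unchanged for the long state of the same design.
#'
#' @param model A short-state [bundle_model()].
#' @param n_layers Number of layers (slabs).
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `layer_assignment`: tibble with columns `layer`, `side`
#'   (`inner`/`flipping`), `resno`.
#' @export
#' @examples
#' short <- build_short_state(default_architecture())
#' assign_layers(short)
assign_layers <- function(model, n_layers = 3,
                          cutoff = HS_INTERFACE$contact_cutoff) {
  ch <- sort(unique(model$chain))[1]
  inner <- model[model$chain == ch & model$segment == "base_inner", ]
  flip <- model[model$chain == ch & model$segment == "flipping", ]
  if (nrow(inner) == 0 || nrow(flip) == 0) {
    stop("assign_layers: model needs base_inner and flipping segments", call. = FALSE)
  }
  mi <- as.matrix(inner[, c("x", "y", "z")])
  mf <- as.matrix(flip[, c("x", "y", "z")])
  d2 <- outer(rowSums(mi^2), rowSums(mf^2), "+") - 2 * mi %*% t(mf)
  contact <- d2 <= cutoff^2
  # The interface is the side-by-side packed region: inner residues must lie
  # within the axial span of the flipping helix, not merely near its end.
  in_span <- inner$z >= min(flip$z) - 1e-9 & inner$z <= max(flip$z) + 1e-9
  inner_hit <- apply(contact, 1, any) & in_span
  flip_hit <- apply(contact, 2, any)
  if (!any(inner_hit) || !any(flip_hit)) {
    stop(paste("assign_layers: no packed inner/flipping interface contacts",
               "found (the assignment is defined on the short state)"),
         call. = FALSE)
  }
  pts <- dplyr::bind_rows(
    tibble::tibble(side = "inner", resno = inner$resno[inner_hit],
                   z = inner$z[inner_hit]),
    tibble::tibble(side = "flipping", resno = flip$resno[flip_hit],
                   z = flip$z[flip_hit])
  )
  if (nrow(pts) == 0) stop("assign_layers: no interface contacts found", call. = FALSE)
  zr <- range(pts$z)
  # Hinge sits at the top of the interface: layer 1 = highest z slab.
  # Slab boundary ties go to the lower-index (more hinge-proximal) layer.
  edges <- seq(zr[2], zr[1], length.out = n_layers + 1)
  lay <- vapply(pts$z, function(z) min(which(z >= edges[-1] - 1e-9)),
                integer(1))
  pts$layer <- lay
  out <- dplyr::arrange(pts[, c("layer", "side", "resno")],
                        .data$layer, .data$side, .data$resno)
  if (length(unique(out$layer)) < n_layers) {
    stop("assign_layers: fewer than ", n_layers, " contact shells found", call. = FALSE)
  }
  structure(out, class = c("layer_assignment", class(tibble::tibble())))
}

#' Apply a layer configuration to a model's sequence
#'
#' Sets layer residues (on all chains) to the frozen identity tables: A
#' layers become polar network identities (Asn core with Ser/Thr support),
#' X layers become hydrophobic identities (Leu/Ile/Val). Residues outside
#' the layers are untouched; the function is pure and idempotent.
#'
#' @param model A [bundle_model()].
#' @param assignment A [assign_layers()] result.
#' @param config A [layer_config()] or its code string.
#' @return A new [bundle_model()] with the designed sequence.
#' @export
#' @examples
#' short <- build_short_state(default_architecture())
#' designed <- apply_config(short, assign_layers(short), "XAX")
#' bundle_sequence(designed)[["A"]]
apply_config <- function(model, assignment, config) {
  if (is.character(config)) config <- layer_config(config)
  n_layers <- length(unique(assignment$layer))
  if (length(config$layers) != n_layers) {
    stop("apply_config: config length does not match assignment layers", call. = FALSE)
  }
  out <- model
  for (l in seq_len(n_layers)) {
    ids <- if (config$layers[l] == "A") HS_INTERFACE$a_identities else HS_INTERFACE$x_identities
    res <- sort(assignment$resno[assignment$layer == l])
    aa_new <- rep_len(ids, length(res))
    for (i in seq_along(res)) {
      out$aa[out$resno == res[i]] <- aa_new[i]
    }
  }
  attr(out, "layer_config") <- config$code
  out
}
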