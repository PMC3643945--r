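#' Kinship and inbreeding coefficients
#'
#' Computes pairwise kinship coefficients \eqn{\phi_{ij}} and inbreeding
#' coefficients \eqn{h_i} by the standard tabular recursion, evaluated in
#' topological order over generations so that consanguineous loops are
#' handled exactly: founders have \eqn{\phi_{ii} = 1/2} and are unrelated to
#' all earlier members; for a non-founder with parents \eqn{(f, m)},
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for any \eqn{j} that is not a
#' descendant, and \eqn{\phi_{ii} = (1 + \phi_{fm})/2}.
#'
#' @param ped a [pedigree()].
#' @param ids optional character vector: the member subset for which the
#'   matrix is returned (all ancestors must be in `ped`, which is automatic
#'   for a validated pedigree).  Default: all members.
#' @return An object of class `"kinship_matrix"`: a list with `ids` (the
#'   subset, in the order given), `phi` (symmetric kinship matrix with
#'   dimnames), and `h` (inbreeding coefficients, `2 * diag(phi) - 1`).
#' @export
kinship <- function(ped, ids = NULL) {
  topo <- ped_topology(ped)
  if (is.null(ids)) ids <- ped$id
  miss <- setdiff(ids, ped$id)
  if (length(miss))
    ped_stop("id_not_found", "id(s) not in pedigree: %s",
             paste(miss, collapse = ", "))
  phi_full <- .kinship_tabular(topo$father, topo$mother)
  idx <- match(ids, topo$ids)
  phi <- phi_full[idx, idx, drop = FALSE]
  dimnames(phi) <- list(ids, ids)
  structure(list(ids = ids, phi = phi, h = 2 * diag(phi) - 1),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Kinship matrix over %d members; mean phi %.4g; %d inbred (h > 0)\n",
              length(x$ids), mean(x$phi[upper.tri(x$phi)]), sum(x$h > 1e-12)))
  invisible(x)
}

# covariance-scale matrix: K_ii = 1 + h_i, K_ij = 2 phi_ij  (== 2 * phi)
kinship_K <- function(km) 2 * km$phi
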