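# Conformational metrics: radius of gyration, RMSD with optimal
# least-squares superposition (proper rotation only), and per-domain RMSD
# that removes interdomain translation/rotation by superposing each domain
# independently.

.masses_for <- function(system) {
  el <- toupper(system$atoms$element)
  m <- .atomic_masses[el]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon-like
  unname(m)
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - \bar r|^2 / \sum_i m_i}}, mass
#' weighted by default (unit masses otherwise).
#'
#' @param system A `molecular_system`.
#' @param selection Integer atom indices (default: all atoms).
#' @param mass_weighted Use atomic masses (default `TRUE`).
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(system, selection = NULL,
                               mass_weighted = TRUE) {
  sel <- if (is.null(selection)) seq_len(n_atoms(system)) else selection
  if (!length(sel)) stop("empty selection")
  x <- system$xyz[sel, , drop = FALSE]
  m <- if (mass_weighted) .masses_for(system)[sel] else rep(1, length(sel))
  ctr <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, ctr)^2)) / sum(m))
}

# Optimal proper rotation (least squares, reflections excluded) aligning
# row-vector coordinates P onto Q, both already centered: the M minimizing
# ||P M - Q||_F subject to det(M) = +1.
.kabsch_rotation <- function(P, Q) {
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation between two structures
#'
#' With `superpose = TRUE` (default) the minimal RMSD over rigid
#' transforms is returned (optimal least-squares rotation after centering,
#' proper rotations only); otherwise the raw coordinate RMSD.
#'
#' @param system,reference `molecular_system`s with matching selections.
#' @param selection Integer atom indices applied to both (default: all).
#' @param superpose Remove the optimal rigid-body transform first.
#' @return RMSD in nm.
#' @export
rmsd <- function(system, reference, selection = NULL, superpose = TRUE) {
  if (is.null(selection) && n_atoms(system) != n_atoms(reference))
    stop("selection sizes differ between structures")
  sel <- if (is.null(selection)) seq_len(n_atoms(system)) else selection
  P <- system$xyz[sel, , drop = FALSE]
  Q <- reference$xyz[sel, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection sizes differ between structures")
  if (superpose) {
    if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
    P <- sweep(P, 2, colMeans(P))
    Q <- sweep(Q, 2, colMeans(Q))
    P <- P %*% .kabsch_rotation(P, Q)
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Define structural domains by residue ranges
#'
#' @param ... Named integer vectors of residue indices, e.g.
#'   `fab1 = 1:220, fc = 441:660`. Ranges must be non-empty and
#'   non-overlapping.
#' @return Object of class `domain_definition` (named list).
#' @export
domain_definition <- function(...) {
  doms <- list(...)
  if (!length(doms) || is.null(names(doms)) || any(names(doms) == ""))
    stop("domains must be named")
  if (any(vapply(doms, length, 1L) == 0)) stop("domains must be non-empty")
  all_res <- unlist(doms)
  if (anyDuplicated(all_res)) stop("domain residue ranges overlap")
  structure(doms, class = "domain_definition")
}

#' Per-domain RMSD
#'
#' Each domain is superposed independently on its counterpart in the
#' reference and its internal RMSD is computed, which removes the
#' contribution of interdomain translation/rotation by construction.
#'
#' @param system,reference `molecular_system`s over the same topology.
#' @param domains A `domain_definition`.
#' @return Named numeric per-domain RMSD (nm).
#' @export
domain_rmsd <- function(system, reference, domains) {
  stopifnot(inherits(domains, "domain_definition"))
  vapply(names(domains), function(dn) {
    res <- domains[[dn]]
    sel <- which(system$atoms$residue_index %in% res)
    sel_ref <- which(reference$atoms$residue_index %in% res)
    if (!length(sel) || length(sel) != length(sel_ref))
      stop("domain '", dn, "' not resolvable in both structures")
    rmsd(system, reference, selection = sel, superpose = TRUE)
  }, numeric(1))
}
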