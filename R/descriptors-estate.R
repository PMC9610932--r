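# Electrotopological state (E-state) framework: per-atom intrinsic states,
# pairwise distance-damped perturbations, and the atom-type maxima used as
# descriptors (maxHBd, maxdO, MAXDP).

#' Electrotopological state table of a molecule
#'
#' For every heavy atom computes the simple connectivity `delta` (number of
#' heavy-atom neighbours), the valence connectivity `delta_v` (valence
#' electrons minus formal charge minus attached hydrogens), the intrinsic
#' state `I = ((2/N)^2 * delta_v + 1) / delta` with `N` the principal
#' quantum number (so second-row atoms reduce to `(delta_v + 1)/delta`),
#' the perturbation `dI_i = sum_j (I_i - I_j) / (d_ij + 1)^2` over all other
#' heavy atoms at topological distance `d_ij` on the hydrogen-suppressed
#' graph, and the E-state `S = I + dI`. Perturbations are pairwise
#' antisymmetric, so they sum to zero over the molecule. A single isolated
#' heavy atom has `delta = 0`; it is treated as `delta = 1` so the intrinsic
#' state stays defined.
#'
#' @param m a `molecule` with at least one heavy atom.
#' @return a data frame (class `estate_table`) with one row per heavy atom:
#'   `atom` (index into `m$atoms`), `element`, `delta`, `delta_v`, `I`,
#'   `dI`, `S`.
#' @examples
#' estate_table(parse_smiles("CO"))  # S = 7 on oxygen, 1 on carbon
#' @export
estate_table <- function(m) {
  stopifnot(inherits(m, "molecule"))
  heavy <- which(m$atoms$element != "H")
  if (length(heavy) == 0L)
    stop("estate_table needs at least one heavy atom", call. = FALSE)
  sub <- subset_molecule(m, heavy)
  a <- sub$atoms
  n <- nrow(a)
  deg <- tabulate_bond_ends(sub$bonds, n)
  delta <- pmax(deg, 1L)                       # isolated atom: delta -> 1
  zv <- VALENCE_ELECTRONS[a$element]
  delta_v <- zv - a$charge - a$nH
  qn <- PRINCIPAL_QN[a$element]
  I <- ((2 / qn)^2 * delta_v + 1) / delta
  D <- topological_distances(sub)
  dI <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    ok <- is.finite(d) & seq_len(n) != i
    dI[i] <- sum((I[i] - I[ok]) / (d[ok] + 1)^2)
  }
  out <- data.frame(atom = heavy, element = a$element, delta = deg,
                    delta_v = unname(delta_v), I = unname(I),
                    dI = dI, S = unname(I) + dI,
                    stringsAsFactors = FALSE)
  class(out) <- c("estate_table", "data.frame")
  out
}

# Heavy-atom attributes needed by the atom-type selectors, aligned to the
# estate table rows.
estate_atom_info <- function(m, est) {
  idx <- est$atom
  nH <- m$atoms$nH[idx]
  has_double <- vapply(idx, function(at) {
    rows <- which(m$bonds$i == at | m$bonds$j == at)
    any(m$bonds$order[rows] == 2 & !m$bonds$aromatic[rows])
  }, logical(1L))
  list(nH = nH, has_double = has_double)
}

#' Maximum E-state of strong hydrogen-bond donors (maxHBd)
#'
#' Maximum `S` over heavy atoms that are strong hydrogen-bond donors:
#' oxygen or nitrogen bearing at least one attached hydrogen. Sulfur S-H is
#' excluded by default (the descriptor family separates strong from weak
#' donors) but can be included via `include_sh`. Returns 0 when the
#' molecule has no such atom.
#'
#' @param m a `molecule`.
#' @param include_sh also count S-H as a donor (default `FALSE`).
#' @return a non-negative number (E-state units).
#' @examples
#' max_hbd(parse_smiles("CO"))   # methanol: 7
#' max_hbd(parse_smiles("C1CCCCC1"))  # no donor: 0
#' @export
max_hbd <- function(m, include_sh = FALSE) {
  est <- estate_table(m)
  info <- estate_atom_info(m, est)
  donors <- c("O", "N", if (include_sh) "S")
  sel <- est$element %in% donors & info$nH > 0L
  if (!any(sel)) return(0)
  max(est$S[sel])
}

#' Maximum E-state of doubly bonded oxygen (maxdO)
#'
#' Maximum `S` over oxygen atoms that take part in a double bond (the
#' atom-type E-state "=O"); 0 when the molecule has none.
#'
#' @param m a `molecule`.
#' @return a non-negative number (E-state units).
#' @examples
#' max_do(parse_smiles("CC(=O)C"))  # acetone: 9.444
#' @export
max_do <- function(m) {
  est <- estate_table(m)
  info <- estate_atom_info(m, est)
  sel <- est$element == "O" & info$has_double
  if (!any(sel)) return(0)
  max(est$S[sel])
}

#' Maximum positive intrinsic-state perturbation (MAXDP)
#'
#' The largest positive per-atom perturbation `dI` in the molecule, floored
#' at zero; related to the molecule's electrophilicity.
#'
#' @param m a `molecule`.
#' @return a non-negative number (E-state units).
#' @examples
#' maxdp(parse_smiles("CCC"))  # propane: 0.125
#' @export
maxdp <- function(m) {
  est <- estate_table(m)
  max(0, max(est$dI))
}
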