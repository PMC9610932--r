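#' Deterministic canonical SMILES
#'
#' Produces a canonical writing of a molecule: two SMILES of the same
#' molecule map to identical text and `canonical_form(parse_smiles(x))` is
#' idempotent. Ranking uses iterative neighbourhood refinement of atom
#' invariants (element, aromaticity, charge, attached H, degree, bond
#' orders) with deterministic tie-breaking; the writer emits a depth-first
#' traversal with ring-closure digits, neighbours ordered by canonical rank.
#' Only internal consistency is promised, not parity with any external
#' toolkit's canonical form. Disconnected components are canonicalized
#' separately and joined by `.` in sorted order.
#'
#' @param m a `molecule` (from [parse_smiles()]).
#' @return a single SMILES string.
#' @examples
#' canonical_form(parse_smiles("OCC")) == canonical_form(parse_smiles("CCO"))
#' @export
canonical_form <- function(m) {
  stopifnot(inherits(m, "molecule"))
  comp <- graph_components(m)
  parts <- vapply(seq_len(max(comp)), function(cid) {
    canonical_component(subset_molecule(m, which(comp == cid)))
  }, character(1L))
  paste(sort(parts), collapse = ".")
}

# Restrict a molecule to a set of atom indices (used per component).
subset_molecule <- function(m, keep) {
  remap <- integer(n_atoms(m)); remap[keep] <- seq_along(keep)
  b <- m$bonds[m$bonds$i %in% keep & m$bonds$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  rownames(b) <- NULL
  out <- list(atoms = m$atoms[keep, , drop = FALSE], bonds = b,
              smiles = m$smiles)
  rownames(out$atoms) <- NULL
  class(out) <- "molecule"
  out
}

# Canonical ranks via iterative refinement; ties broken by promoting one
# member of the smallest tied class and re-refining (tied atoms after full
# refinement are treated as interchangeable).
canonical_ranks <- function(m) {
  n <- n_atoms(m)
  nb <- neighbour_list(m)
  border <- bond_order_lookup(m)
  inv <- vapply(seq_len(n), function(at) {
    rows <- which(m$bonds$i == at | m$bonds$j == at)
    ords <- sort(ifelse(m$bonds$aromatic[rows], 1.5, m$bonds$order[rows]))
    paste(m$atoms$element[at], as.integer(m$atoms$aromatic[at]),
          m$atoms$charge[at], m$atoms$nH[at], length(rows),
          paste(ords, collapse = ","))
  }, character(1L))
  ranks <- match(inv, sort(unique(inv)))
  refine <- function(ranks) {
    repeat {
      keys <- vapply(seq_len(n), function(at) {
        nbr <- nb[[at]]
        env <- sort(paste0(vapply(nbr, function(w) border(at, w),
                                  character(1L)), ":",
                           formatC(ranks[nbr], width = 6, flag = "0")))
        paste(formatC(ranks[at], width = 6, flag = "0"),
              paste(env, collapse = "|"))
      }, character(1L))
      new_ranks <- match(keys, sort(unique(keys)))
      if (identical(new_ranks, ranks)) return(ranks)
      ranks <- new_ranks
    }
  }
  ranks <- refine(ranks)
  while (length(unique(ranks)) < n) {
    tied <- min(ranks[duplicated(ranks) | duplicated(ranks, fromLast = TRUE)])
    pick <- which(ranks == tied)[1L]
    ranks <- ranks + (seq_len(n) > 0) * 0  # keep numeric
    ranks[ranks > tied | (ranks == tied & seq_len(n) != pick)] <-
      ranks[ranks > tied | (ranks == tied & seq_len(n) != pick)] + 1L
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- refine(ranks)
  }
  ranks
}

bond_order_lookup <- function(m) {
  key <- paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j))
  code <- ifelse(m$bonds$aromatic, "a", as.character(m$bonds$order))
  tab <- stats::setNames(code, key)
  function(i, j) unname(tab[paste(min(i, j), max(i, j))])
}

canonical_component <- function(m) {
  n <- n_atoms(m)
  ranks <- canonical_ranks(m)
  nb <- neighbour_list(m)
  border <- bond_order_lookup(m)

  visited <- logical(n)
  ring_digit <- 0L
  ring_open <- list()    # per atom: character vector of digit tokens
  for (at in seq_len(n)) ring_open[[at]] <- character(0)
  ring_bond_sym <- list()

  # First pass: DFS to discover ring-closure edges (to visited non-parent).
  closures <- list()
  order_visit <- integer(0)
  dfs_edges <- function(at, parent) {
    visited[at] <<- TRUE
    order_visit <<- c(order_visit, at)
    for (w in nb[[at]][order(ranks[nb[[at]]])]) {
      if (w == parent) next
      if (visited[w]) {
        key <- paste(min(at, w), max(at, w))
        if (is.null(closures[[key]])) closures[[key]] <<- c(at, w)
      } else dfs_edges(w, at)
    }
  }
  start <- which.min(ranks)
  dfs_edges(start, 0L)

  # Assign digits to closure bonds.
  digit_of <- list()
  for (key in names(closures)) {
    ring_digit <- ring_digit + 1L
    digit_of[[key]] <- ring_digit
  }
  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  bond_sym <- function(i, j) {
    code <- border(i, j)
    if (code == "a") return("")
    if (code == "2") return("=")
    if (code == "3") return("#")
    # single bond: explicit '-' between two aromatic atoms
    if (m$atoms$aromatic[i] && m$atoms$aromatic[j]) "-" else ""
  }

  atom_token <- function(at) {
    a <- m$atoms[at, ]
    sym <- if (a$aromatic) tolower(a$element) else a$element
    rows <- which(m$bonds$i == at | m$bonds$j == at)
    n_arom <- sum(m$bonds$aromatic[rows])
    plain <- sum(m$bonds$order[rows][!m$bonds$aromatic[rows]])
    plain_ok <- a$charge == 0L && a$element %in% ORGANIC_SUBSET &&
      a$nH == implied_h(a$element, a$aromatic, n_arom, plain)
    if (plain_ok) return(sym)
    hpart <- if (a$nH == 1L) "H" else if (a$nH > 1L) paste0("H", a$nH) else ""
    cpart <- if (a$charge == 0L) ""
             else if (a$charge == 1L) "+"
             else if (a$charge == -1L) "-"
             else sprintf("%+d", a$charge)
    paste0("[", sym, hpart, cpart, "]")
  }

  visited2 <- logical(n)
  emit <- function(at, parent) {
    visited2[at] <<- TRUE
    out <- atom_token(at)
    # ring-closure digits opened/closed at this atom
    nbrs <- nb[[at]][order(ranks[nb[[at]]])]
    for (w in nbrs) {
      key <- paste(min(at, w), max(at, w))
      d <- digit_of[[key]]
      if (!is.null(d)) {
        sym <- if (visited2[w]) "" else bond_sym(at, w)
        out <- paste0(out, sym, digit_token(d))
      }
    }
    branches <- character(0)
    for (w in nbrs) {
      if (w == parent || visited2[w]) next
      key <- paste(min(at, w), max(at, w))
      if (!is.null(digit_of[[key]])) next
      branches <- c(branches, paste0(bond_sym(at, w), emit(w, at)))
    }
    if (length(branches) > 1L)
      out <- paste0(out, paste0("(", branches[-length(branches)], ")",
                                collapse = ""), branches[length(branches)])
    else if (length(branches) == 1L) out <- paste0(out, branches)
    out
  }
  emit(start, 0L)
}

# The attached-H count the parser would infer for a bare organic-subset atom
# with the given bonds (mirror of assign_implicit_hydrogens).
implied_h <- function(element, aromatic, n_arom, plain_sum) {
  if (aromatic) {
    if (element %in% c("C", "B"))
      return(max(0L, 3L - as.integer(n_arom + plain_sum)))
    return(0L)
  }
  defs <- DEFAULT_VALENCES[[element]]
  if (is.null(defs)) return(-1L)
  need <- ceiling(plain_sum + 1.5 * n_arom)
  ok <- defs[defs >= need]
  if (length(ok) == 0L) return(-1L)
  as.integer(min(ok) - need)
}

#' Permute the atom numbering of a molecule
#'
#' Renumbers atoms by `perm` (a permutation of `1:n_atoms(m)`); used to test
#' that descriptors and the canonical form are invariant under input atom
#' order.
#'
#' @param m a `molecule`.
#' @param perm integer permutation vector.
#' @return a `molecule` with the same graph and permuted indices.
#' @export
permute_atoms <- function(m, perm) {
  stopifnot(length(perm) == n_atoms(m), all(sort(perm) == seq_len(n_atoms(m))))
  inv <- order(perm)
  out <- m
  out$atoms <- m$atoms[perm, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds$i <- inv[m$bonds$i]
  out$bonds$j <- inv[m$bonds$j]
  out
}
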