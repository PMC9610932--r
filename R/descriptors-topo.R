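# Topological descriptors: molecular walk counts and information-content
# (neighbourhood-symmetry entropy) indices.

#' Molecular walk count of order 4 (MWC4)
#'
#' Counts directed walks of length 4 on the hydrogen-suppressed graph (the
#' full sum of the entries of \eqn{A^4}, `A` the heavy-atom adjacency
#' matrix; aromatic bonds count as edges) and returns `ln(1 + w4)`.
#' `walk_count()` exposes the raw count for any length, with options for
#' the halved (undirected) convention and for self-returning walks
#' (`trace(A^k)`), which some descriptor software uses at order 4.
#'
#' @param m a `molecule`.
#' @param length walk length (default 4).
#' @param halved divide the directed count by two.
#' @param self_returning count only walks that return to their start atom.
#' @return `mwc4()`: `ln(1 + w4)`; `walk_count()`: a non-negative count.
#' @examples
#' mwc4(parse_smiles("CC"))      # ln(3)
#' mwc4(parse_smiles("C1CC1"))   # ln(49)
#' @export
mwc4 <- function(m) log(1 + walk_count(m, length = 4L))

#' @rdname mwc4
#' @export
walk_count <- function(m, length = 4L, halved = FALSE,
                       self_returning = FALSE) {
  stopifnot(length >= 1L)
  heavy <- which(m$atoms$element != "H")
  if (length(heavy) <= 1L) return(0)
  A <- adjacency_matrix(subset_molecule(m, heavy))
  Ak <- diag(nrow(A))
  for (k in seq_len(length)) Ak <- Ak %*% A
  w <- if (self_returning) sum(diag(Ak)) else sum(Ak)
  if (halved) w / 2 else w
}

#' Information-content index of neighbourhood symmetry (IC0, IC2)
#'
#' Partitions all atoms of the hydrogen-included graph into equivalence
#' classes and returns the Shannon entropy of the partition in bits,
#' \eqn{-\sum_g p_g \log_2 p_g} with \eqn{p_g} the fraction of atoms in
#' class g. At order 0 two atoms are equivalent iff they are the same
#' element; each further order refines classes by the multiset of
#' (bond order, neighbour class) pairs, so `order = 2` applies two rounds
#' of refinement and `IC2 >= IC0` always.
#'
#' @param m a `molecule`.
#' @param order neighbourhood order, 0 or a small positive integer.
#' @return entropy in bits (non-negative).
#' @examples
#' information_content(parse_smiles("C"), 0)  # methane: 0.7219 bits
#' @export
information_content <- function(m, order = 0L) {
  stopifnot(order >= 0L)
  # hydrogen-included graph: attach nH explicit H nodes to each atom
  elements <- m$atoms$element
  n_heavy <- length(elements)
  h_parent <- rep(seq_len(n_heavy), m$atoms$nH)
  n <- n_heavy + length(h_parent)
  el_all <- c(elements, rep("H", length(h_parent)))

  nbr <- vector("list", n)
  ord <- vector("list", n)
  addedge <- function(i, j, o) {
    nbr[[i]] <<- c(nbr[[i]], j); ord[[i]] <<- c(ord[[i]], o)
    nbr[[j]] <<- c(nbr[[j]], i); ord[[j]] <<- c(ord[[j]], o)
  }
  if (nrow(m$bonds)) for (r in seq_len(nrow(m$bonds))) {
    addedge(m$bonds$i[r], m$bonds$j[r],
            if (m$bonds$aromatic[r]) 1.5 else m$bonds$order[r])
  }
  if (length(h_parent)) for (k in seq_along(h_parent)) {
    addedge(h_parent[k], n_heavy + k, 1)
  }

  cls <- match(el_all, sort(unique(el_all)))
  it <- 0L
  while (it < order) {
    it <- it + 1L
    keys <- vapply(seq_len(n), function(at) {
      env <- sort(paste0(ord[[at]], ":",
                         formatC(cls[nbr[[at]]], width = 5, flag = "0")))
      paste(formatC(cls[at], width = 5, flag = "0"),
            paste(env, collapse = "|"))
    }, character(1L))
    cls <- match(keys, sort(unique(keys)))
  }
  p <- as.numeric(table(cls)) / n
  -sum(p * log2(p))
}
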