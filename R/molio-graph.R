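# Graph utilities on the hydrogen-suppressed molecular graph: adjacency,
# connectivity, ring perception and aromaticity.

#' Number of atoms and accessors
#'
#' `n_atoms()` counts graph nodes (heavy atoms; explicit hydrogens are folded
#' into attached-H counts at parse time). `heavy_atom_count()` excludes any
#' residual H nodes (e.g. from `[H][H]`). `total_h_count()` sums attached
#' hydrogens.
#'
#' @param m a `molecule`.
#' @return an integer.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' @rdname n_atoms
#' @export
heavy_atom_count <- function(m) sum(m$atoms$element != "H")

#' @rdname n_atoms
#' @export
total_h_count <- function(m) sum(m$atoms$nH) + sum(m$atoms$element == "H")

# Adjacency list (indices of bonded neighbours per atom).
neighbour_list <- function(m) {
  n <- n_atoms(m)
  nb <- vector("list", n)
  for (r in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Adjacency matrix of the hydrogen-suppressed graph
#'
#' Unweighted symmetric 0/1 matrix; aromatic bonds count as edges like any
#' other bond order.
#'
#' @param m a `molecule`.
#' @return an `n x n` integer matrix.
#' @export
adjacency_matrix <- function(m) {
  n <- n_atoms(m)
  A <- matrix(0L, n, n)
  if (nrow(m$bonds) > 0L) {
    idx <- cbind(m$bonds$i, m$bonds$j)
    A[idx] <- 1L
    A[idx[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

# All-pairs topological distances by per-source BFS; Inf across components.
topological_distances <- function(m) {
  n <- n_atoms(m)
  nb <- neighbour_list(m)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
    D[s, ] <- d
  }
  D
}

# Connected components; returns an integer membership vector.
graph_components <- function(m) {
  n <- n_atoms(m)
  nb <- neighbour_list(m)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) if (comp[w] == 0L) {
        comp[w] <- cid
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# Which bonds lie on a cycle: endpoints remain connected once the bond is cut.
ring_bond_flags <- function(m) {
  nb <- neighbour_list(m)
  n <- n_atoms(m)
  vapply(seq_len(nrow(m$bonds)), function(r) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    seen <- logical(n); seen[i] <- TRUE
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if ((v == i && w == j) || (v == j && w == i)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[j]
  }, logical(1L))
}

# Smallest rings: for every ring bond, the shortest cycle through it
# (bond + shortest path between its endpoints avoiding it). Returns a list
# of atom-index vectors, deduplicated; rings larger than `max_size` dropped.
perceive_rings <- function(m, max_size = 8L) {
  flags <- ring_bond_flags(m)
  if (!any(flags)) return(list())
  nb <- neighbour_list(m)
  n <- n_atoms(m)
  rings <- list()
  for (r in which(flags)) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    # BFS from i to j avoiding the bond itself
    prev <- integer(n); d <- rep(Inf, n); d[i] <- 0
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if ((v == i && w == j) || (v == j && w == i)) next
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1; prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.infinite(d[j]) || d[j] + 1 > max_size) next
    path <- j
    while (path[length(path)] != i) path <- c(path, prev[path[length(path)]])
    key <- paste(sort(path), collapse = "-")
    if (!key %in% names(rings)) rings[[key]] <- path
  }
  unname(rings)
}

# Aromaticity post-processing:
#  1. provisional aromatic bonds not on a cycle are demoted to single;
#  2. aromatic-written atoms left without aromatic bonds are demoted;
#  3. Kekule-written rings of size 5-7 are perceived aromatic when every
#     ring atom is sp2 (in-ring double bond, exocyclic double bond, or a
#     lone-pair donor N/O/S) and the pi-electron count satisfies 4n+2.
perceive_aromaticity <- function(m, text) {
  b <- m$bonds
  if (any(b$aromatic)) {
    on_ring <- ring_bond_flags(m)
    demote <- b$aromatic & !on_ring
    b$aromatic[demote] <- FALSE
    b$order[demote] <- 1
  }
  arom_deg <- tabulate_bond_ends(b[b$aromatic, , drop = FALSE], n_atoms(m))
  m$atoms$aromatic[m$atoms$aromatic & arom_deg == 0L] <- FALSE
  m$bonds <- b

  rings <- perceive_rings(m, max_size = 7L)
  for (ring in rings) {
    if (length(ring) < 5L) next
    if (all(m$atoms$aromatic[ring])) next
    verdict <- huckel_ring(m, ring)
    if (isTRUE(verdict)) {
      m$atoms$aromatic[ring] <- TRUE
      in_ring <- m$bonds$i %in% ring & m$bonds$j %in% ring
      both_adjacent <- vapply(which(in_ring), function(r) {
        ring_has_edge(ring, m$bonds$i[r], m$bonds$j[r])
      }, logical(1L))
      sel <- which(in_ring)[both_adjacent]
      m$bonds$aromatic[sel] <- TRUE
      m$bonds$order[sel] <- 1
    }
  }
  m
}

# Is (i, j) an edge of the cycle `ring` (consecutive on the cycle)?
ring_has_edge <- function(ring, i, j) {
  k <- length(ring)
  pos_i <- match(i, ring); pos_j <- match(j, ring)
  if (is.na(pos_i) || is.na(pos_j)) return(FALSE)
  diff <- abs(pos_i - pos_j)
  diff == 1L || diff == k - 1L
}

tabulate_bond_ends <- function(bonds, n) {
  out <- integer(n)
  if (nrow(bonds)) {
    t1 <- tabulate(bonds$i, nbins = n)
    t2 <- tabulate(bonds$j, nbins = n)
    out <- t1 + t2
  }
  out
}

# Hueckel check for one ring; returns TRUE / FALSE.
huckel_ring <- function(m, ring) {
  b <- m$bonds
  pi_e <- 0L
  for (at in ring) {
    el <- m$atoms$element[at]
    if (!el %in% c("C", "N", "O", "S")) return(FALSE)
    rows <- which(b$i == at | b$j == at)
    dbl <- rows[b$order[rows] == 2]
    if (length(dbl) > 0L) {
      partners <- ifelse(b$i[dbl] == at, b$j[dbl], b$i[dbl])
      if (any(ring_has_edge_vec(ring, at, partners))) {
        pi_e <- pi_e + 1L          # part of an in-ring double bond
      } else {
        pi_e <- pi_e + 0L          # exocyclic double bond: sp2, no pi to ring
      }
    } else if (m$atoms$aromatic[at]) {
      pi_e <- pi_e + 1L
    } else if (el %in% c("N", "O", "S")) {
      pi_e <- pi_e + 2L            # lone-pair donor
    } else {
      return(FALSE)                # sp3 carbon
    }
  }
  pi_e >= 6L && pi_e %% 4L == 2L
}

ring_has_edge_vec <- function(ring, at, partners) {
  vapply(partners, function(p) ring_has_edge(ring, at, p), logical(1L))
}

# Implicit-hydrogen assignment and the structural valence check.
assign_implicit_hydrogens <- function(m, text) {
  a <- m$atoms; b <- m$bonds
  unparseable <- function(why) {
    stop(sprintf("unparseable structure: %s in \"%s\"", why, text),
         call. = FALSE)
  }
  for (at in seq_len(nrow(a))) {
    rows <- which(b$i == at | b$j == at)
    n_arom <- sum(b$aromatic[rows])
    plain_sum <- sum(b$order[rows][!b$aromatic[rows]])
    el <- a$element[at]
    if (a$bracket[at]) {
      bondsum <- plain_sum + 1.5 * n_arom
      if (bondsum + a$nH[at] > max_valence_of(el) + abs(a$charge[at]) + 0.5)
        unparseable(sprintf("valence of bracketed %s exceeded", el))
      next
    }
    if (a$aromatic[at]) {
      deg_eff <- n_arom + plain_sum
      if (el %in% c("C", "B")) {
        if (deg_eff > 4) unparseable(sprintf("aromatic %s over-bonded", el))
        a$nH[at] <- max(0L, 3L - as.integer(deg_eff))
      } else {
        a$nH[at] <- 0L   # aromatic N/O/P/S carries H only when bracketed
      }
      next
    }
    bondsum <- plain_sum + 1.5 * n_arom   # non-aromatic atom in arom. system
    defs <- DEFAULT_VALENCES[[el]]
    need <- ceiling(bondsum)
    ok <- defs[defs >= need]
    if (length(ok) == 0L)
      unparseable(sprintf("valence of %s exceeded (%g bonds)", el, bondsum))
    a$nH[at] <- as.integer(min(ok) - need)
  }
  m$atoms <- a
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s\n", x$smiles))
  cat(sprintf("  %d atoms (%d heavy), %d bonds, %d attached H\n",
              n_atoms(x), heavy_atom_count(x), nrow(x$bonds),
              sum(x$atoms$nH)))
  invisible(x)
}

#' Molecular formula-style summary used in tests
#' @param m a `molecule`.
#' @return named list with heavy-atom count, bond count and total H.
#' @keywords internal
molecule_summary <- function(m) {
  list(heavy = heavy_atom_count(m), bonds = nrow(m$bonds),
       hydrogens = total_h_count(m))
}
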