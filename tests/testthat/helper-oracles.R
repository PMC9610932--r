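# Fixture molecules and brute-force oracles kept deliberately independent
# of the package's computational paths.

fixture_smiles <- c(
  "C", "CC", "CCC", "C1CC1", "CO", "CCO", "CC(=O)C", "CCCCCC",
  "Clc1ccccc1", "Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl", "CCOCC",
  "c1ccccc1", "c1ccncc1", "CC(C)CC(=O)O", "CCN(CC)CC", "CS(=O)(=O)C",
  "c1ccc2ccccc2c1", "OC(=O)c1ccccc1", "CC(=O)CC(=O)C", "FC(F)(F)CO"
)

# Directed walks of a given length by explicit DFS enumeration over the
# heavy-atom graph (independent of the matrix-power route).
brute_walk_count <- function(m, len) {
  heavy <- which(m$atoms$element != "H")
  if (length(heavy) <= 1L) return(0L)
  idx <- match(seq_len(nrow(m$atoms)), heavy)
  nbr <- vector("list", length(heavy))
  for (r in seq_len(nrow(m$bonds))) {
    i <- idx[m$bonds$i[r]]; j <- idx[m$bonds$j[r]]
    if (is.na(i) || is.na(j)) next
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  count <- 0L
  walk <- function(at, remaining) {
    if (remaining == 0L) { count <<- count + 1L; return(invisible(NULL)) }
    for (w in nbr[[at]]) walk(w, remaining - 1L)
  }
  for (s in seq_along(heavy)) walk(s, len)
  count
}

# Pairwise E-state perturbation by a literal double loop over atom pairs,
# with Floyd-Warshall distances built directly from the bond list.
brute_estate <- function(m) {
  heavy <- which(m$atoms$element != "H")
  n <- length(heavy)
  idx <- match(seq_len(nrow(m$atoms)), heavy)
  D <- matrix(Inf, n, n); diag(D) <- 0
  deg <- integer(n)
  for (r in seq_len(nrow(m$bonds))) {
    i <- idx[m$bonds$i[r]]; j <- idx[m$bonds$j[r]]
    if (is.na(i) || is.na(j)) next
    D[i, j] <- D[j, i] <- 1
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  zv <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
          Cl = 7, Br = 7, I = 7)
  qn <- c(B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
          Cl = 3, Br = 4, I = 5)
  el <- m$atoms$element[heavy]
  dv <- zv[el] - m$atoms$charge[heavy] - m$atoms$nH[heavy]
  I <- ((2 / qn[el])^2 * dv + 1) / pmax(deg, 1)
  dI <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || is.infinite(D[i, j])) next
    dI[i] <- dI[i] + (I[i] - I[j]) / (D[i, j] + 1)^2
  }
  data.frame(element = el, I = unname(I), dI = dI, S = unname(I) + dI)
}

# Atom equivalence classes by literal neighbourhood-refinement, tracking
# (element, bonds) environments; returns the partition entropy in bits.
brute_ic <- function(m, order) {
  n_heavy <- nrow(m$atoms)
  h_parent <- rep(seq_len(n_heavy), m$atoms$nH)
  n <- n_heavy + length(h_parent)
  el <- c(m$atoms$element, rep("H", length(h_parent)))
  edges <- list()
  for (r in seq_len(nrow(m$bonds)))
    edges[[length(edges) + 1L]] <- c(m$bonds$i[r], m$bonds$j[r],
                                     if (m$bonds$aromatic[r]) 1.5
                                     else m$bonds$order[r])
  for (k in seq_along(h_parent))
    edges[[length(edges) + 1L]] <- c(h_parent[k], n_heavy + k, 1)
  sig <- el
  for (round in seq_len(order)) {
    new_sig <- character(n)
    for (at in seq_len(n)) {
      env <- character(0)
      for (e in edges) {
        if (e[1L] == at) env <- c(env, paste0(e[3L], sig[e[2L]]))
        if (e[2L] == at) env <- c(env, paste0(e[3L], sig[e[1L]]))
      }
      new_sig[at] <- paste(sig[at], paste(sort(env), collapse = "+"))
    }
    sig <- new_sig
  }
  p <- as.numeric(table(sig)) / n
  -sum(p * log2(p))
}

# Moore-Penrose least squares through the normal equations, as an
# independent check on the QR fit.
pinv_coef <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}
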