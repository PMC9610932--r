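# Topological polar surface area: sum of tabulated fragment contributions
# over N, O, S and P atoms classified by their bonding environment.

# Fragment contribution table (Angstrom^2). Keys encode
# element|aromatic|nH|charge|n_single|n_double|n_triple|in3ring.
TPSA_VERSION <- "ertl-2000"
TPSA_TABLE <- local({
  e <- function(el, arom, nH, chg, s, d, t, r3, value)
    data.frame(element = el, aromatic = arom, nH = nH, charge = chg,
               n_single = s, n_double = d, n_triple = t, in3ring = r3,
               value = value, stringsAsFactors = FALSE)
  rbind(
    # --- nitrogen ---
    e("N", FALSE, 0L,  0L, 3L, 0L, 0L, FALSE,  3.24),
    e("N", FALSE, 0L,  0L, 1L, 1L, 0L, FALSE, 12.36),
    e("N", FALSE, 0L,  0L, 0L, 0L, 1L, FALSE, 23.79),
    e("N", FALSE, 0L,  0L, 1L, 2L, 0L, FALSE, 11.68),
    e("N", FALSE, 0L,  0L, 0L, 1L, 1L, FALSE, 13.60),
    e("N", FALSE, 0L,  0L, 3L, 0L, 0L, TRUE,   3.01),
    e("N", FALSE, 1L,  0L, 2L, 0L, 0L, FALSE, 12.03),
    e("N", FALSE, 1L,  0L, 2L, 0L, 0L, TRUE,  21.94),
    e("N", FALSE, 1L,  0L, 0L, 1L, 0L, FALSE, 23.85),
    e("N", FALSE, 2L,  0L, 1L, 0L, 0L, FALSE, 26.02),
    e("N", FALSE, 0L,  1L, 4L, 0L, 0L, FALSE,  0.00),
    e("N", FALSE, 0L,  1L, 2L, 1L, 0L, FALSE,  3.01),
    e("N", FALSE, 0L,  1L, 1L, 0L, 1L, FALSE,  4.36),
    e("N", FALSE, 1L,  1L, 3L, 0L, 0L, FALSE,  4.44),
    e("N", FALSE, 1L,  1L, 1L, 1L, 0L, FALSE, 13.97),
    e("N", FALSE, 2L,  1L, 2L, 0L, 0L, FALSE, 16.61),
    e("N", FALSE, 2L,  1L, 0L, 1L, 0L, FALSE, 25.59),
    e("N", FALSE, 3L,  1L, 1L, 0L, 0L, FALSE, 27.64),
    e("N", TRUE,  0L,  0L, 0L, 0L, 0L, FALSE, 12.89),  # :n:
    e("N", TRUE,  0L,  0L, 1L, 0L, 0L, FALSE,  4.93),  # n with substituent
    e("N", TRUE,  0L,  0L, 0L, 1L, 0L, FALSE,  8.39),  # n with exocyclic =
    e("N", TRUE,  1L,  0L, 0L, 0L, 0L, FALSE, 15.79),  # [nH]
    e("N", TRUE,  0L,  1L, 1L, 0L, 0L, FALSE,  4.10),  # [n+](-)
    e("N", TRUE,  1L,  1L, 0L, 0L, 0L, FALSE, 14.14),  # [nH+]
    # --- oxygen ---
    e("O", FALSE, 0L,  0L, 2L, 0L, 0L, FALSE,  9.23),
    e("O", FALSE, 0L,  0L, 2L, 0L, 0L, TRUE,  12.53),
    e("O", FALSE, 0L,  0L, 0L, 1L, 0L, FALSE, 17.07),
    e("O", FALSE, 1L,  0L, 1L, 0L, 0L, FALSE, 20.23),
    e("O", FALSE, 0L, -1L, 1L, 0L, 0L, FALSE, 23.06),
    e("O", TRUE,  0L,  0L, 0L, 0L, 0L, FALSE, 13.14),
    # --- sulfur ---
    e("S", FALSE, 0L,  0L, 2L, 0L, 0L, FALSE, 25.30),
    e("S", FALSE, 0L,  0L, 0L, 1L, 0L, FALSE, 32.09),
    e("S", FALSE, 0L,  0L, 2L, 1L, 0L, FALSE, 19.21),
    e("S", FALSE, 0L,  0L, 2L, 2L, 0L, FALSE,  8.38),
    e("S", FALSE, 1L,  0L, 1L, 0L, 0L, FALSE, 38.80),
    e("S", TRUE,  0L,  0L, 0L, 0L, 0L, FALSE, 28.24),
    # --- phosphorus ---
    e("P", FALSE, 0L,  0L, 3L, 0L, 0L, FALSE, 13.59),
    e("P", FALSE, 0L,  0L, 1L, 1L, 0L, FALSE, 34.14),
    e("P", FALSE, 0L,  0L, 3L, 1L, 0L, FALSE,  9.81),
    e("P", FALSE, 1L,  0L, 2L, 1L, 0L, FALSE, 23.47)
  )
})

#' Topological polar surface area (TopoPSA)
#'
#' Sums fragment contributions over N, O, S and P atoms, each classified by
#' aromaticity, attached hydrogens, formal charge, bond-order pattern and
#' membership of a three-membered ring. The contribution table
#' (`TPSA_VERSION`) covers the common neutral and charged environments; an
#' environment not in the table contributes 0 with a warning.
#'
#' @param m a `molecule`.
#' @return surface area in Angstrom^2 (non-negative).
#' @examples
#' topopsa(parse_smiles("CO"))       # hydroxyl O: 20.23
#' topopsa(parse_smiles("CC(=O)C"))  # carbonyl O: 17.07
#' @export
topopsa <- function(m) {
  stopifnot(inherits(m, "molecule"))
  polar <- which(m$atoms$element %in% c("N", "O", "S", "P"))
  if (length(polar) == 0L) return(0)
  rings3 <- Filter(function(r) length(r) == 3L, perceive_rings(m))
  in3 <- unique(unlist(rings3))
  total <- 0
  for (at in polar) {
    rows <- which(m$bonds$i == at | m$bonds$j == at)
    arom <- m$atoms$aromatic[at]
    nonarom <- rows[!m$bonds$aromatic[rows]]
    key <- list(element = m$atoms$element[at], aromatic = arom,
                nH = m$atoms$nH[at], charge = m$atoms$charge[at],
                n_single = sum(m$bonds$order[nonarom] == 1),
                n_double = sum(m$bonds$order[nonarom] == 2),
                n_triple = sum(m$bonds$order[nonarom] == 3),
                in3ring = at %in% in3)
    hit <- TPSA_TABLE$element == key$element &
      TPSA_TABLE$aromatic == key$aromatic &
      TPSA_TABLE$nH == key$nH & TPSA_TABLE$charge == key$charge &
      TPSA_TABLE$n_single == key$n_single &
      TPSA_TABLE$n_double == key$n_double &
      TPSA_TABLE$n_triple == key$n_triple
    # the 3-ring rows are the only ones where ring membership matters
    cand <- TPSA_TABLE[hit, , drop = FALSE]
    if (nrow(cand) > 1L) cand <- cand[cand$in3ring == key$in3ring, ,
                                      drop = FALSE]
    else if (nrow(cand) == 1L && cand$in3ring && !key$in3ring)
      cand <- cand[0L, , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning(sprintf(
        "TopoPSA: no fragment contribution for %s environment (atom %d); 0 used",
        key$element, at))
      next
    }
    total <- total + cand$value[1L]
  }
  total
}
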