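# A linear-chain SMARTS matcher sufficient for the substructure-count
# descriptors: bracket atoms with comma-separated primitives (#n atomic
# number, element symbols, aromatic lowercase symbols), bare organic-subset
# and aromatic atoms, and the bond primitives ~ (any), - (single), = , #,
# : (aromatic) and default (single or aromatic).

parse_smarts <- function(pattern) {
  bad <- function(why) stop(sprintf("invalid SMARTS: %s in \"%s\"",
                                    why, pattern), call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  atoms <- list(); bonds <- character(0)
  expect_atom <- TRUE
  k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "[") {
      end <- k
      while (end <= length(chars) && chars[end] != "]") end <- end + 1L
      if (end > length(chars)) bad("unmatched '['")
      inner <- paste(chars[(k + 1L):(end - 1L)], collapse = "")
      prims <- strsplit(inner, ",", fixed = TRUE)[[1L]]
      if (length(prims) == 0L) bad("empty bracket atom")
      atoms[[length(atoms) + 1L]] <- lapply(prims, parse_smarts_primitive,
                                            bad = bad)
      if (!expect_atom) bonds <- c(bonds, "")
      expect_atom <- FALSE
      k <- end + 1L
    } else if (ch %in% c("~", "-", "=", "#", ":")) {
      if (expect_atom && length(atoms) == 0L) bad("bond before first atom")
      if (k + 1L > length(chars)) bad("dangling bond")
      bonds <- c(bonds, ch)
      expect_atom <- TRUE
      k <- k + 1L
      # '#' directly before a digit outside brackets is not supported
      if (ch == "#" && grepl("^[0-9]$", chars[k]))
        bad("atomic-number primitive must be bracketed")
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (k < length(chars)) {
        two <- paste0(ch, chars[k + 1L])
        if (two %in% c("Cl", "Br")) sym <- two
      }
      atoms[[length(atoms) + 1L]] <- list(list(kind = "element",
                                               element = sym,
                                               aromatic = FALSE))
      if (!expect_atom) bonds <- c(bonds, "")
      expect_atom <- FALSE
      k <- k + nchar(sym)
    } else if (ch %in% AROMATIC_SYMBOLS) {
      atoms[[length(atoms) + 1L]] <- list(list(kind = "element",
                                               element = toupper(ch),
                                               aromatic = TRUE))
      if (!expect_atom) bonds <- c(bonds, "")
      expect_atom <- FALSE
      k <- k + 1L
    } else bad(sprintf("unsupported character '%s'", ch))
  }
  if (length(atoms) == 0L) bad("no atoms")
  if (length(bonds) != length(atoms) - 1L) bad("dangling bond")
  list(atoms = atoms, bonds = bonds)
}

parse_smarts_primitive <- function(p, bad) {
  if (grepl("^#[0-9]+$", p))
    return(list(kind = "number", z = as.integer(sub("#", "", p))))
  if (grepl("^[A-Z][a-z]?$", p) && p %in% names(ATOMIC_NUMBERS))
    return(list(kind = "element", element = p, aromatic = FALSE))
  if (p %in% AROMATIC_SYMBOLS)
    return(list(kind = "element", element = toupper(p), aromatic = TRUE))
  bad(sprintf("unsupported atom primitive '%s'", p))
}

smarts_atom_matches <- function(prims, m, at) {
  el <- m$atoms$element[at]
  arom <- m$atoms$aromatic[at]
  for (pr in prims) {
    if (pr$kind == "number") {
      if (!is.na(ATOMIC_NUMBERS[el]) && ATOMIC_NUMBERS[[el]] == pr$z)
        return(TRUE)
    } else {
      if (el == pr$element) {
        # bracketed/bare uppercase element primitive matches aliphatic atoms;
        # for elements that can never be aromatic it matches regardless
        if (pr$aromatic == arom ||
            (!pr$aromatic && !el %in% c("B", "C", "N", "O", "P", "S")))
          return(TRUE)
      }
    }
  }
  FALSE
}

smarts_bond_matches <- function(sym, m, row) {
  arom <- m$bonds$aromatic[row]
  ord <- m$bonds$order[row]
  switch(sym,
         "~" = TRUE,
         "-" = !arom && ord == 1,
         "=" = !arom && ord == 2,
         "#" = !arom && ord == 3,
         ":" = arom,
         (!arom && ord == 1) || arom)   # default: single or aromatic
}

#' Count distinct substructure matches of a linear SMARTS pattern
#'
#' Matches a chain pattern against the molecular graph and counts distinct
#' matches, where two matches are the same when they cover the same set of
#' atoms (so a symmetric two-atom pattern counts each bond once). The
#' supported SMARTS subset covers element symbols, aromatic lowercase
#' symbols, `[#n]` atomic numbers, comma-disjunctions inside brackets and
#' the bond primitives `~ - = # :` plus the single-or-aromatic default —
#' enough for the modelled fingerprints `[Cl][c]` (aryl chloride,
#' SubFPC171) and `[#6]~[#7,#8,#16]` (carbon to N/O/S bonds, SubFPC295).
#'
#' @param m a `molecule`.
#' @param pattern a SMARTS string.
#' @return a non-negative integer count.
#' @examples
#' substructure_count(parse_smiles("Clc1ccccc1"), "[Cl][c]")      # 1
#' substructure_count(parse_smiles("CCOCC"), "[#6]~[#7,#8,#16]")  # 2
#' @export
substructure_count <- function(m, pattern) {
  stopifnot(inherits(m, "molecule"))
  pat <- parse_smarts(pattern)
  n_pat <- length(pat$atoms)
  n <- n_atoms(m)
  if (n_pat == 1L) {
    return(sum(vapply(seq_len(n), function(at)
      smarts_atom_matches(pat$atoms[[1L]], m, at), logical(1L))))
  }
  bond_rows <- function(at) which(m$bonds$i == at | m$bonds$j == at)
  seen <- character(0)
  extend <- function(path) {
    pos <- length(path)
    if (pos == n_pat) {
      key <- paste(sort(path), collapse = "-")
      seen <<- unique(c(seen, key))
      return(invisible(NULL))
    }
    at <- path[pos]
    for (row in bond_rows(at)) {
      nxt <- if (m$bonds$i[row] == at) m$bonds$j[row] else m$bonds$i[row]
      if (nxt %in% path) next
      if (!smarts_bond_matches(pat$bonds[pos], m, row)) next
      if (!smarts_atom_matches(pat$atoms[[pos + 1L]], m, nxt)) next
      extend(c(path, nxt))
    }
  }
  for (at in seq_len(n)) {
    if (smarts_atom_matches(pat$atoms[[1L]], m, at)) extend(at)
  }
  length(seen)
}
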