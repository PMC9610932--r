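#' Parse a SMILES string into a molecular graph
#'
#' Builds a hydrogen-suppressed molecular graph from a SMILES line notation:
#' atoms carry element, formal charge, attached-hydrogen count and an
#' aromaticity flag; bonds carry order (1, 2, 3) or an aromatic flag.
#' Aromaticity written in lowercase is validated (aromatic atoms must sit on
#' an aromatic ring); Kekule-written rings are perceived aromatic by a
#' Hueckel-style 4n+2 pi-electron count, so `c1ccccc1` and `C1=CC=CC=C1`
#' yield the same graph. Implicit hydrogens are filled to the lowest standard
#' valence; explicit `[H]` neighbours are folded into the attached-H count.
#'
#' @param text a single non-empty SMILES string.
#' @return an object of class `molecule`: a list with `atoms` (data frame
#'   with columns `element`, `charge`, `nH`, `aromatic`, `bracket`), `bonds`
#'   (data frame with `i`, `j`, `order`, `aromatic`) and `smiles`, the
#'   original text.
#' @examples
#' m <- parse_smiles("CCO")
#' m$atoms
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("invalid SMILES: empty or non-string input", call. = FALSE)

  fail <- function(why) {
    stop(sprintf("invalid SMILES: %s in \"%s\"", why, text), call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n_ch <- length(chars)

  element <- character(0); charge <- integer(0); aromatic <- logical(0)
  bracket <- logical(0); h_exp <- integer(0)
  bi <- integer(0); bj <- integer(0); bsym <- character(0)

  cur <- NA_integer_
  stack <- integer(0)
  pending <- NULL          # bond symbol awaiting its second atom
  ring <- list()           # open ring-closure digits

  add_bond <- function(a, b, sym) {
    if (a == b) fail("self-bond")
    dup <- any((bi == a & bj == b) | (bi == b & bj == a))
    if (dup) fail("duplicate bond")
    bi <<- c(bi, a); bj <<- c(bj, b); bsym <<- c(bsym, sym)
  }
  add_atom <- function(el, arom, chg = 0L, hx = NA_integer_, brk = FALSE) {
    element <<- c(element, el); charge <<- c(charge, as.integer(chg))
    aromatic <<- c(aromatic, arom); bracket <<- c(bracket, brk)
    h_exp <<- c(h_exp, as.integer(hx))
    idx <- length(element)
    if (!is.na(cur)) {
      add_bond(cur, idx, pending %||% "")
      pending <<- NULL
    } else if (!is.null(pending)) fail("bond with no preceding atom")
    cur <<- idx
  }
  close_ring <- function(num) {
    if (is.na(cur)) fail("ring closure before any atom")
    key <- as.character(num)
    if (!is.null(ring[[key]])) {
      open <- ring[[key]]
      sym <- ""
      if (nzchar(open$sym) && nzchar(pending %||% "")) {
        if (open$sym != pending) fail("conflicting ring-closure bond orders")
        sym <- open$sym
      } else sym <- if (nzchar(open$sym)) open$sym else pending %||% ""
      add_bond(open$atom, cur, sym)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- list(atom = cur, sym = pending %||% "")
    }
    pending <<- NULL
  }

  k <- 1L
  while (k <= n_ch) {
    ch <- chars[k]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) fail("two consecutive bond symbols")
      if (is.na(cur)) fail("bond with no preceding atom")
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      k <- k + 1L
    } else if (ch == "(") {
      if (is.na(cur)) fail("branch with no preceding atom")
      if (!is.null(pending)) fail("bond before branch opening")
      stack <- c(stack, cur)
      k <- k + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched closing parenthesis")
      if (!is.null(pending)) fail("dangling bond before closing parenthesis")
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- k + 1L
    } else if (ch == ".") {
      if (!is.null(pending)) fail("bond across component separator")
      cur <- NA_integer_
      k <- k + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch))
      k <- k + 1L
    } else if (ch == "%") {
      if (k + 2L > n_ch || !grepl("^[0-9][0-9]$",
                                  paste0(chars[k + 1L], chars[k + 2L])))
        fail("malformed %nn ring closure")
      close_ring(as.integer(paste0(chars[k + 1L], chars[k + 2L])))
      k <- k + 3L
    } else if (ch == "[") {
      end <- k
      while (end <= n_ch && chars[end] != "]") end <- end + 1L
      if (end > n_ch) fail("unmatched '['")
      inner <- paste(chars[(k + 1L):(end - 1L)], collapse = "")
      at <- parse_bracket_atom(inner, fail)
      add_atom(at$element, at$aromatic, at$charge, at$h, brk = TRUE)
      k <- end + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (k < n_ch) {
        two <- paste0(ch, chars[k + 1L])
        if (two %in% c("Cl", "Br")) sym <- two
      }
      if (!sym %in% ORGANIC_SUBSET)
        fail(sprintf("atom '%s' outside the organic subset must be bracketed",
                     sym))
      add_atom(sym, FALSE)
      k <- k + nchar(sym)
    } else if (ch %in% AROMATIC_SYMBOLS) {
      add_atom(toupper(ch), TRUE)
      k <- k + 1L
    } else {
      fail(sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0L) fail("unmatched opening parenthesis")
  if (!is.null(pending)) fail("dangling bond symbol")
  if (length(ring) > 0L) fail("unclosed ring bond")
  if (length(element) == 0L) fail("no atoms")

  m <- list(
    atoms = data.frame(element = element, charge = charge,
                       nH = ifelse(is.na(h_exp), 0L, h_exp),
                       aromatic = aromatic, bracket = bracket,
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, sym = bsym, stringsAsFactors = FALSE),
    smiles = text
  )
  m$atoms$h_explicit <- !is.na(h_exp)
  m <- fold_explicit_hydrogens(m)
  m <- resolve_bond_orders(m, text)
  m <- perceive_aromaticity(m, text)
  m <- assign_implicit_hydrogens(m, text)
  m$bonds$sym <- NULL
  class(m) <- "molecule"
  m
}

# Parse the inside of a bracket atom: [isotope? symbol stereo? Hn? charge?]
parse_bracket_atom <- function(inner, fail) {
  pat <- paste0("^([0-9]+)?",                       # isotope (ignored)
                "([A-Z][a-z]?|[a-z]{1,2})",         # element / aromatic
                "(@@?|@TH[12])?",                    # stereo (ignored)
                "(H([0-9]*))?",                      # attached hydrogens
                "((\\+{1,3}|-{1,3})([0-9]+)?)?",     # formal charge
                "(:[0-9]+)?$")                       # atom class (ignored)
  mm <- regmatches(inner, regexec(pat, inner))[[1L]]
  if (length(mm) == 0L) fail(sprintf("malformed bracket atom [%s]", inner))
  sym <- mm[3L]
  arom <- FALSE
  if (sym %in% AROMATIC_SYMBOLS) {
    arom <- TRUE
    sym <- toupper(sym)
  } else if (grepl("^[a-z]", sym)) {
    fail(sprintf("unknown aromatic symbol '%s'", sym))
  }
  if (!sym %in% names(ATOMIC_NUMBERS))
    fail(sprintf("unknown element '%s'", sym))
  h <- 0L
  if (nzchar(mm[5L])) h <- if (nzchar(mm[6L])) as.integer(mm[6L]) else 1L
  chg <- 0L
  if (nzchar(mm[7L])) {
    sgn <- if (startsWith(mm[8L], "+")) 1L else -1L
    chg <- if (nzchar(mm[9L])) sgn * as.integer(mm[9L])
           else sgn * nchar(mm[8L])
  }
  list(element = sym, aromatic = arom, h = h, charge = chg)
}

# Explicit [H] atoms bonded to one heavy atom by a single bond become part of
# that atom's attached-H count; remaining H atoms (isolated, H2, charged)
# stay as graph nodes.
fold_explicit_hydrogens <- function(m) {
  a <- m$atoms; b <- m$bonds
  is_h <- a$element == "H" & a$charge == 0L
  fold <- logical(nrow(a))
  for (idx in which(is_h)) {
    hit <- which((b$i == idx | b$j == idx))
    if (length(hit) != 1L) next
    if (nzchar(b$sym[hit]) && b$sym[hit] != "-") next
    other <- if (b$i[hit] == idx) b$j[hit] else b$i[hit]
    if (a$element[other] == "H") next
    a$nH[other] <- a$nH[other] + 1L
    a$h_explicit[other] <- TRUE
    fold[idx] <- TRUE
    b <- b[-hit, , drop = FALSE]
  }
  if (any(fold)) {
    keep <- which(!fold)
    remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
    a <- a[keep, , drop = FALSE]
    rownames(a) <- NULL
    b$i <- remap[b$i]; b$j <- remap[b$j]
    rownames(b) <- NULL
  }
  m$atoms <- a; m$bonds <- b
  m
}

# Turn bond symbols into numeric orders plus an aromatic flag; an unmarked
# bond between two aromatic-written atoms is provisionally aromatic.
resolve_bond_orders <- function(m, text) {
  b <- m$bonds
  arom_in <- m$atoms$aromatic
  order <- numeric(nrow(b)); arom <- logical(nrow(b))
  for (r in seq_len(nrow(b))) {
    s <- b$sym[r]
    if (s == "=") order[r] <- 2
    else if (s == "#") order[r] <- 3
    else if (s == ":") { order[r] <- 1; arom[r] <- TRUE }
    else if (s == "-") order[r] <- 1
    else { # unmarked
      order[r] <- 1
      arom[r] <- arom_in[b$i[r]] && arom_in[b$j[r]]
    }
  }
  m$bonds$order <- order
  m$bonds$aromatic <- arom
  m
}
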