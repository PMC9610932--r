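# Internal helpers shared across modules.

# Elements the modellable-organic filter accepts; everything else is treated
# as a metal/metalloid exclusion.
ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Br", "I")

# Bare (unbracketed) atoms allowed by the SMILES organic subset.
ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

# Atomic numbers for the elements the engine can meet (organic set plus the
# common counter-ions that show up in salt exclusions).
ATOMIC_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  Al = 13L, Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L,
  Fe = 26L, Cu = 29L, Zn = 30L, As = 33L, Se = 34L, Br = 35L, Ag = 47L,
  Cd = 48L, Sn = 50L, I = 53L, Ba = 56L, Hg = 80L, Pb = 82L
)

# Valence-electron counts used for the valence connectivity delta-v.
VALENCE_ELECTRONS <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                       S = 6, Cl = 7, Br = 7, I = 7, H = 1)

# Principal quantum number (row) per element, for the (2/N)^2 intrinsic-state
# scaling of higher-row atoms.
PRINCIPAL_QN <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3,
                  S = 3, Cl = 3, Br = 4, I = 5)

# Default valences used for implicit-hydrogen filling on bare organic-subset
# atoms (lowest valence not below the bond-order sum is used).
DEFAULT_VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

# Generous upper valence bounds for the structural sanity check.
MAX_VALENCES <- c(H = 1, B = 4, C = 4, N = 5, O = 3, F = 1, Si = 6, P = 6,
                  S = 6, Cl = 7, Br = 7, I = 7)

#' @keywords internal
max_valence_of <- function(element) {
  v <- MAX_VALENCES[element]
  ifelse(is.na(v), 8, v)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero, the convention of the printed percentage tables
# (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer percent view of a proportion.
as_percent <- function(x) round_half_up(100 * x)

`%||%` <- function(a, b) if (is.null(a)) b else a
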