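# Seeded generators of synthetic molecules and modelling datasets, so that
# every module is exercisable without external downloads. The defaults
# emulate the modelled data structure: a continuous response linear in a
# small descriptor subset with Gaussian noise at the published training
# error scale (sd 0.8), and binary classes separable in four descriptors
# with sizes echoing the balanced modelling subset (225 B / 192 not-B).

#' Curated worked molecules with hand-derived descriptor values
#'
#' A fixed set of small molecules whose descriptor values were derived by
#' hand from the defining formulas (intrinsic states and perturbations,
#' walk enumeration, partition entropies, fragment contributions,
#' substructure counting). Each entry lists the SMILES and the expected
#' values it pins down, with a note on the derivation. Used as the
#' descriptor-engine oracle throughout the tests.
#'
#' @return a named list; each element has `smiles`, `expected` (named
#'   numeric), `note`.
#' @export
worked_molecules <- function() {
  list(
    methane = list(
      smiles = "C",
      expected = c(MWC4 = 0, IC0 = 0.7219281, IC2 = 0.7219281,
                   maxHBd = 0, maxdO = 0, MAXDP = 0, TopoPSA = 0,
                   SubFPC171 = 0, SubFPC295 = 0),
      note = "single heavy atom: no walks; CH4 partition {C:1,H:4} entropy"),
    ethane = list(
      smiles = "CC",
      expected = c(MWC4 = log(3), maxHBd = 0, maxdO = 0, MAXDP = 0,
                   TopoPSA = 0, SubFPC171 = 0, SubFPC295 = 0),
      note = "w4 = sum(A^4) = 2 on the 2-node path; symmetric, all dI = 0"),
    propane = list(
      smiles = "CCC",
      expected = c(MWC4 = log(13), MAXDP = 0.125, maxHBd = 0, maxdO = 0),
      note = "w4 = 12 on the 3-node path; terminal-C dI = (2-1.5)/4"),
    cyclopropane = list(
      smiles = "C1CC1",
      expected = c(MWC4 = log(49), maxHBd = 0, maxdO = 0, TopoPSA = 0),
      note = "w4 = 48 on the 3-cycle (eigenvalue 2 walk count)"),
    methanol = list(
      smiles = "CO",
      expected = c(maxHBd = 7, MAXDP = 1, maxdO = 0, TopoPSA = 20.23,
                   MWC4 = log(3), IC0 = 1.2516292),
      note = "I_O = 6, I_C = 2; dI_O = (6-2)/4 = 1, S_O = 7; hydroxyl-O TPSA"),
    ethanol = list(
      smiles = "CCO",
      expected = c(maxHBd = 7.5694444, TopoPSA = 20.23, maxdO = 0,
                   SubFPC295 = 1),
      note = "S_O = 6 + 4.5/4 + 4/9"),
    acetone = list(
      smiles = "CC(=O)C",
      expected = c(maxdO = 9.4444444, maxHBd = 0, TopoPSA = 17.07,
                   SubFPC295 = 1, MWC4 = log(37)),
      note = "S_O = 7 + (7 - 5/3)/4 + 2(7-2)/9; carbonyl-O TPSA; w4 = 36"),
    hexane = list(
      smiles = "CCCCCC",
      expected = c(maxHBd = 0, maxdO = 0, TopoPSA = 0, SubFPC171 = 0,
                   SubFPC295 = 0),
      note = "apolar alkane: all polar/E-state maxima zero"),
    chlorobenzene = list(
      smiles = "Clc1ccccc1",
      expected = c(SubFPC171 = 1, maxHBd = 0, maxdO = 0, TopoPSA = 0,
                   SubFPC295 = 0),
      note = "one Cl on aromatic carbon"),
    hexachlorobenzene = list(
      smiles = "Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl",
      expected = c(SubFPC171 = 6, maxHBd = 0, TopoPSA = 0),
      note = "six aryl chlorides"),
    diethyl_ether = list(
      smiles = "CCOCC",
      expected = c(SubFPC295 = 2, TopoPSA = 9.23, maxHBd = 0, maxdO = 0),
      note = "two C-O bonds; ether-O TPSA")
  )
}

#' Simulation specification
#'
#' @param n number of records (>= 10).
#' @param coefficients named true slopes over descriptor-like columns.
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation (default 0.8, the
#'   published training error scale).
#' @param separation class mean shift, in within-class sd units, for
#'   classification data.
#' @param n_pos,n_neg class sizes (defaults 225 B / 192 not-B).
#' @param n_decoys uninformative extra columns.
#' @param seed RNG seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n = 500L,
                     coefficients = c(MWC4 = 0.8, maxHBd = -1.2, IC0 = -0.5),
                     intercept = -1.4, noise_sd = 0.8,
                     separation = 3, n_pos = 225L, n_neg = 192L,
                     n_decoys = 0L, seed = 1L) {
  stopifnot(n >= 10L, noise_sd >= 0, separation >= 0)
  structure(list(n = as.integer(n), coefficients = coefficients,
                 intercept = intercept, noise_sd = noise_sd,
                 separation = separation, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), n_decoys = as.integer(n_decoys),
                 seed = seed),
            class = "sim_spec")
}

# Descriptor-like marginals: non-negative, mixed continuous/count, ranges
# loosely mimicking the real descriptors (counts 0-6, E-state 0-10,
# ln-walk 0-6).
rdescriptor_col <- function(name, n) {
  if (grepl("^SubFPC", name)) return(stats::rpois(n, 1.2))
  if (name %in% c("maxHBd", "maxdO", "MAXDP"))
    return(stats::rexp(n, rate = 0.25) * (stats::runif(n) < 0.7))
  if (name == "TopoPSA") return(stats::rexp(n, rate = 0.04))
  if (name == "MWC4") return(log(1 + stats::rpois(n, 25)))
  if (name %in% c("IC0", "IC2")) return(stats::runif(n, 0.5, 3.5))
  abs(stats::rnorm(n, 2, 1.2))
}

#' Generate a synthetic regression dataset
#'
#' Draws descriptor-like columns (plus optional decoys) and a response
#' `y = b0 + X b + N(0, sd^2)`; pure function of the spec.
#'
#' @param spec a [sim_spec()].
#' @return list with `X`, `y`, `beta` (named true slopes), `intercept`.
#' @export
gen_regression <- function(spec = sim_spec()) {
  with_seed(spec$seed, {
    vars <- names(spec$coefficients)
    decoys <- if (spec$n_decoys > 0L)
      paste0("decoy", seq_len(spec$n_decoys)) else character(0)
    cols <- c(vars, decoys)
    X <- vapply(cols, function(nm) rdescriptor_col(nm, spec$n),
                numeric(spec$n))
    colnames(X) <- cols
    y <- spec$intercept +
      drop(X[, vars, drop = FALSE] %*% spec$coefficients) +
      stats::rnorm(spec$n, 0, spec$noise_sd)
    list(X = X, y = y, beta = spec$coefficients,
         intercept = spec$intercept)
  })
}

#' Generate a synthetic two-class dataset
#'
#' Two Gaussian classes over four informative variables whose means differ
#' by `separation` within-class standard deviations, plus `n_decoys`
#' uninformative variables; class sizes default to the balanced modelling
#' subset (225 B, 192 not-B).
#'
#' @param spec a [sim_spec()].
#' @return list with `X` and `labels` (`"B"` / `"not-B"`).
#' @export
gen_classification <- function(spec = sim_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_pos + spec$n_neg
    labels <- c(rep("B", spec$n_pos), rep("not-B", spec$n_neg))
    shift <- spec$separation / sqrt(4)   # per-variable shift, 4 vars jointly
    inf <- vapply(1:4, function(j)
      stats::rnorm(n, ifelse(labels == "B", shift, 0), 1), numeric(n))
    colnames(inf) <- paste0("v", 1:4)
    X <- inf
    if (spec$n_decoys > 0L) {
      dec <- vapply(seq_len(spec$n_decoys), function(j)
        stats::rnorm(n, 0, 1), numeric(n))
      colnames(dec) <- paste0("decoy", seq_len(spec$n_decoys))
      X <- cbind(inf, dec)
    }
    list(X = X, labels = labels)
  })
}

#' Write a synthetic dataset as a standard dataset CSV
#'
#' Emits `id`, `smiles` (worked molecules recycled), `logbcf` and `class`
#' columns, so that file-based workflows can run end to end on synthetic
#' records.
#'
#' @param n number of rows; @param seed RNG seed; @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(n, seed, path) {
  wm <- worked_molecules()
  smls <- vapply(wm, `[[`, character(1L), "smiles")
  with_seed(seed, {
    y <- stats::rnorm(n, 1.6, 1.4)   # roughly the curated log BCF spread
    df <- data.frame(id = sprintf("SYN-%04d", seq_len(n)),
                     smiles = rep_len(smls, n),
                     logbcf = round(y, 3),
                     class = ifelse(y > 3.30, "B", "not-B"),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  })
  invisible(path)
}
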