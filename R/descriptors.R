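#' Names of the nine modelled descriptors
#'
#' The six variables of the published regression equation (MWC4, SubFPC171,
#' SubFPC295, maxHBd, maxdO, IC0) plus the three additional variables of
#' the linear discriminant classifier (IC2, TopoPSA, MAXDP).
#'
#' @return character vector of length 9.
#' @export
descriptor_names <- function() {
  c("MWC4", "IC0", "IC2", "maxHBd", "maxdO", "MAXDP",
    "TopoPSA", "SubFPC171", "SubFPC295")
}

# SMARTS defaults of the two fingerprint-count descriptors.
SMARTS_ARYL_CHLORIDE <- "[Cl][c]"
SMARTS_C_HETERO <- "[#6]~[#7,#8,#16]"

#' Compute the nine modelled descriptors for one molecule
#'
#' Assembles MWC4 (`ln(1 + w4)` walk count), IC0 and IC2 (neighbourhood
#' symmetry entropies in bits), maxHBd, maxdO and MAXDP (E-state maxima),
#' TopoPSA (Angstrom^2) and the fingerprint counts SubFPC171 (aryl
#' chloride `[Cl][c]`) and SubFPC295 (carbon-to-N/O/S bonds). Deterministic
#' and invariant under the input atom order; never emits NaN.
#'
#' @param m a `molecule`, or a SMILES string.
#' @param smarts named list overriding the two fingerprint SMARTS patterns
#'   (`SubFPC171`, `SubFPC295`).
#' @return a named numeric vector of length 9 (class `descriptor_vector`).
#' @examples
#' compute_descriptors("Clc1ccccc1")
#' @export
compute_descriptors <- function(m, smarts = list()) {
  if (is.character(m)) m <- parse_smiles(m)
  stopifnot(inherits(m, "molecule"))
  pat171 <- smarts$SubFPC171 %||% SMARTS_ARYL_CHLORIDE
  pat295 <- smarts$SubFPC295 %||% SMARTS_C_HETERO
  wrap <- function(name, expr) {
    v <- tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
    if (!is.finite(v)) stop(sprintf("%s: non-finite value", name),
                            call. = FALSE)
    v
  }
  out <- c(
    MWC4      = wrap("MWC4", mwc4(m)),
    IC0       = wrap("IC0", information_content(m, 0L)),
    IC2       = wrap("IC2", information_content(m, 2L)),
    maxHBd    = wrap("maxHBd", max_hbd(m)),
    maxdO     = wrap("maxdO", max_do(m)),
    MAXDP     = wrap("MAXDP", maxdp(m)),
    TopoPSA   = wrap("TopoPSA", topopsa(m)),
    SubFPC171 = wrap("SubFPC171", substructure_count(m, pat171)),
    SubFPC295 = wrap("SubFPC295", substructure_count(m, pat295))
  )
  class(out) <- c("descriptor_vector", "numeric")
  out
}

#' Descriptor matrix for a set of records
#'
#' Computes the nine descriptors for every record's SMILES and returns a
#' matrix aligned to the records.
#'
#' @param records list of `bcf_record` objects, or a character vector of
#'   SMILES.
#' @param smarts as in [compute_descriptors()].
#' @return numeric matrix, one row per record, nine named columns.
#' @export
descriptor_matrix <- function(records, smarts = list()) {
  smls <- if (is.character(records)) records
          else vapply(records, function(r) r$smiles, character(1L))
  X <- t(vapply(smls, function(s)
    as.numeric(compute_descriptors(s, smarts)), numeric(9L)))
  colnames(X) <- descriptor_names()
  rownames(X) <- if (is.character(records)) NULL
                 else vapply(records, function(r) r$id, character(1L))
  X
}
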