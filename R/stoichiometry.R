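# Rule-based elimination among candidate regulatory-complex architectures.
#
# Five candidate stoichiometries for the catalytic subunit (alpha), its
# essential partner (beta) and the regulatory micropeptide (PLM):
#   A: alpha-beta-PLM          (1, 1, 1)  simplest complex
#   B: PLM-alphabeta-PLM       (1, 1, 2)  two micropeptide sites
#   C: alphabeta-PLM4          (1, 1, 4)  micropeptide tetramer bound
#   D: (alphabeta-PLM)2        (2, 2, 2)  dimer of protomers
#   E: higher-order oligomer   (>= 3 alpha; counts open-ended)

#' Candidate stoichiometry models
#'
#' @return A tibble with one row per candidate model: `model`, `alpha`,
#'   `beta`, `plm` subunit counts (`NA` for the open-ended oligomer) and a
#'   description.
#' @export
stoichiometry_models <- function() {
  tibble::tibble(
    model = c("A", "B", "C", "D", "E"),
    alpha = c(1L, 1L, 1L, 2L, NA_integer_),
    beta = c(1L, 1L, 1L, 2L, NA_integer_),
    plm = c(1L, 2L, 4L, 2L, NA_integer_),
    description = c(
      "alphabeta-PLM: single protomer, one micropeptide",
      "PLM-alphabeta-PLM: one protomer, two micropeptide sites",
      "alphabeta-PLM4: one protomer, micropeptide tetramer",
      "(alphabeta-PLM)2: dimer of protomers",
      "higher-order oligomer/aggregate (>= 3 catalytic subunits)"
    )
  )
}

#' Construct a stoichiometry evidence record
#'
#' Pairwise multiplicity findings from photobleaching/FRET experiments:
#' how many acceptor-labeled micropeptides (`plm_multiplicity`) and
#' essential subunits (`beta_multiplicity`) the donor-labeled catalytic
#' subunit sees (`"single"`, `"multiple"`, `"unknown"`), and the assembly
#' state of the catalytic subunit itself (`"monomer"`, `"dimer"`,
#' `"higher_order"`, `"unknown"`).
#'
#' @param plm_multiplicity,beta_multiplicity One of `"single"`,
#'   `"multiple"`, `"unknown"`.
#' @param alpha_assembly One of `"monomer"`, `"dimer"`, `"higher_order"`,
#'   `"unknown"`.
#' @return A list of class `stoich_evidence`.
#' @export
#' @examples
#' stoich_evidence("multiple", "multiple", "dimer")
stoich_evidence <- function(plm_multiplicity = "unknown",
                            beta_multiplicity = "unknown",
                            alpha_assembly = "unknown") {
  plm_multiplicity <- rlang::arg_match(plm_multiplicity, c("single", "multiple", "unknown"))
  beta_multiplicity <- rlang::arg_match(beta_multiplicity, c("single", "multiple", "unknown"))
  alpha_assembly <- rlang::arg_match(
    alpha_assembly,
    c("monomer", "dimer", "higher_order", "unknown")
  )
  structure(
    list(
      plm_multiplicity = plm_multiplicity,
      beta_multiplicity = beta_multiplicity,
      alpha_assembly = alpha_assembly
    ),
    class = "stoich_evidence"
  )
}

#' Stoichiometry models consistent with the evidence
#'
#' Applies the elimination rules to the five candidate architectures:
#' \itemize{
#' \item multiple micropeptides eliminate A (the only single-micropeptide
#'   model); a single micropeptide eliminates B, C, D, E;
#' \item multiple beta subunits eliminate A, B, C (monomeric in beta); a
#'   single beta eliminates D and E;
#' \item a catalytic-subunit dimer eliminates A, B, C (monomeric) and E
#'   (higher than dimer); a monomer eliminates D and E; a higher-order
#'   finding eliminates A through D;
#' \item `"unknown"` fields eliminate nothing.
#' }
#' Contradictory evidence yields an empty set (reported, not an error).
#'
#' @param evidence A [stoich_evidence()] record.
#' @return A tibble of surviving models (possibly zero rows), the
#'   [stoichiometry_models()] table filtered; attribute `eliminated` maps
#'   each eliminated model to the finding that removed it.
#' @export
#' @examples
#' consistent_models(stoich_evidence("multiple", "multiple", "dimer")) # model D
consistent_models <- function(evidence) {
  stopifnot(inherits(evidence, "stoich_evidence"))
  models <- stoichiometry_models()
  eliminated <- character(0)
  drop <- function(ids, reason) {
    ids <- setdiff(ids, names(eliminated))
    stats::setNames(rep(reason, length(ids)), ids)
  }
  eliminated <- c(eliminated, switch(evidence$plm_multiplicity,
    multiple = drop("A", "multiple micropeptides observed"),
    single = drop(c("B", "C", "D", "E"), "single micropeptide observed"),
    unknown = character(0)
  ))
  eliminated <- c(eliminated, switch(evidence$beta_multiplicity,
    multiple = drop(c("A", "B", "C"), "multiple beta subunits observed"),
    single = drop(c("D", "E"), "single beta subunit observed"),
    unknown = character(0)
  ))
  eliminated <- c(eliminated, switch(evidence$alpha_assembly,
    dimer = drop(c("A", "B", "C", "E"), "catalytic-subunit dimer observed"),
    monomer = drop(c("D", "E"), "monomeric catalytic subunit observed"),
    higher_order = drop(c("A", "B", "C", "D"), "higher-order oligomer observed"),
    unknown = character(0)
  ))
  out <- models[!models$model %in% names(eliminated), ]
  attr(out, "eliminated") <- eliminated
  attr(out, "evidence") <- evidence
  class(out) <- c("stoich_result", class(out))
  out
}

#' @export
print.stoich_result <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No consistent stoichiometry model: the evidence is contradictory.\n")
  } else {
    cat(
      "Consistent stoichiometry model(s):",
      paste(x$model, collapse = ", "), "\n"
    )
  }
  NextMethod()
}
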