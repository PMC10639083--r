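# Ancestral intron count and density estimation from three-species shared
# intron counts. For sister lineages alpha and beta with outgroup gamma,
# introns shared by any species pair are ancestral under negligible parallel
# gain; the fraction of ancestral introns retained in a lineage is the
# three-way count over the pair count excluding that lineage, and the
# ancestral count solves N_abg = N_Omega * P_a * P_b * P_g:
#
#   N_Omega_hat = (N_ab * N_ag * N_bg) / N_abg^2 .
#
# Densities are the minor share of ancestral introns, normalized to a
# reference species measured in the same aligned genes, and aggregated as
# mean +/- SEM over species combinations.

as_triple <- function(counts) {
  if (inherits(counts, "triple_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 4) {
    return(structure(list(N_ab = counts[[1]], N_ag = counts[[2]],
                          N_bg = counts[[3]], N_abg = counts[[4]],
                          type = "unspecified"), class = "triple_counts"))
  }
  stop_param("counts must be a triple_counts object or a numeric vector ",
             "(N_ab, N_ag, N_bg, N_abg)")
}

#' Per-lineage retained fraction of ancestral introns
#'
#' The retention of lineage beta is N_abg / N_ag: of the introns known to be
#' ancestral because alpha and gamma share them, the fraction also present
#' in beta.
#'
#' @param counts a `triple_counts` object (or numeric `c(N_ab, N_ag, N_bg,
#'   N_abg)`).
#' @param lineage "alpha", "beta" or "gamma".
#' @return list with `lineage` and `P_hat`.
#' @export
retention_fraction <- function(counts, lineage = c("alpha", "beta", "gamma")) {
  lineage <- match.arg(lineage)
  x <- as_triple(counts)
  denom <- switch(lineage, alpha = x$N_bg, beta = x$N_ag, gamma = x$N_ab)
  if (denom <= 0) {
    stop_param("pair count excluding ", lineage,
               " is zero; retention undefined")
  }
  list(lineage = lineage, P_hat = x$N_abg / denom)
}

#' Estimate the ancestral intron count in the aligned regions
#'
#' @inheritParams retention_fraction
#' @return estimated ancestral count (real-valued; round for reporting).
#' @export
estimate_ancestral_count <- function(counts) {
  x <- as_triple(counts)
  if (x$N_abg <= 0) {
    stop_param("N_abg is zero; ancestral count undefined for this ",
               "species combination")
  }
  (as.numeric(x$N_ab) * x$N_ag * x$N_bg) / as.numeric(x$N_abg)^2
}

#' Ancestral minor intron density
#'
#' @param minor,major ancestral count estimates for each type.
#' @return percentage 100 * minor / (minor + major).
#' @export
ancestral_density <- function(minor, major) {
  if (minor + major <= 0) stop_param("minor + major must be > 0")
  100 * minor / (minor + major)
}

#' Density relative to a reference species
#'
#' @param rho_hat ancestral minor intron density (percent).
#' @param reference_density minor intron density (percent) of the reference
#'   species in the same aligned genes.
#' @return ratio rho_hat / reference_density.
#' @export
relative_density <- function(rho_hat, reference_density) {
  if (reference_density <= 0) stop_param("reference_density must be > 0")
  rho_hat / reference_density
}

#' Aggregate estimates over species combinations
#'
#' @param x numeric vector of per-combination estimates.
#' @return list with `mean`, `sem` (sample sd over sqrt(n)) and `n`.
#' @export
aggregate_estimates <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop_param("no finite estimates to aggregate")
  list(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else 0, n = n)
}

#' Full ancestral-density chain for one species combination
#'
#' Convenience wrapper: ancestral counts for both types, the ancestral minor
#' density and (optionally) the reference-normalized value.
#'
#' @param minor_counts,major_counts `triple_counts` for each intron type.
#' @param reference_density optional reference species density (percent).
#' @param round_counts round the count estimates to integers before the
#'   density (the reporting convention for these reconstructions); the raw
#'   real-valued estimates are returned either way.
#' @return list with `N_minor`, `N_major`, `rho_hat` and `relative` (NA when
#'   no reference given).
#' @export
reconstruct_node <- function(minor_counts, major_counts,
                             reference_density = NULL,
                             round_counts = TRUE) {
  nm <- estimate_ancestral_count(minor_counts)
  nM <- estimate_ancestral_count(major_counts)
  rho <- if (round_counts) ancestral_density(round(nm), round(nM)) else
    ancestral_density(nm, nM)
  list(N_minor = nm, N_major = nM, rho_hat = rho,
       relative = if (is.null(reference_density)) NA_real_ else
         relative_density(rho, reference_density))
}

#' Decompose loss of one intron type into deletion versus conversion
#'
#' The ancestral set for the focal lineage comprises introns present as the
#' focal type in both the sister and the outgroup. Among these, the focal
#' state classifies each intron as retained (same type), converted (present
#' as the other type) or deleted (absent). Conversion estimates are
#' conservative: a conversion followed by deletion is indistinguishable from
#' a deletion.
#'
#' @param states data frame with per-intron state columns (values
#'   minor/major/absent) for the three lineages.
#' @param focal,sister,outgroup column names (defaults: `state_alpha`,
#'   `state_beta`, `state_gamma`).
#' @param type ancestral intron type to decompose (default "minor").
#' @return list with `n_ancestral` and fractions `retained`, `converted`,
#'   `deleted` (summing to 1).
#' @export
loss_decomposition <- function(states, focal = "state_alpha",
                               sister = "state_beta",
                               outgroup = "state_gamma",
                               type = c("minor", "major")) {
  type <- match.arg(type)
  if (inherits(states, "three_taxon_sim")) states <- states$states
  other <- if (type == "minor") "major" else "minor"
  anc <- states[[sister]] == type & states[[outgroup]] == type
  n <- sum(anc)
  if (n == 0) {
    return(list(n_ancestral = 0L, retained = NA_real_, converted = NA_real_,
                deleted = NA_real_))
  }
  f <- states[[focal]][anc]
  list(n_ancestral = n,
       retained = mean(f == type),
       converted = mean(f == other),
       deleted = mean(f == "absent"))
}
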