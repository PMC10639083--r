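# The survey's statistical battery: conservation percentages and Fisher
# tests, positional-bias testing (exact binomial on 5'-half occupancy +
# Mann-Whitney on positions + median direction), clade enrichment, phase
# distributions with an exact unconditional comparison, and MIG versus
# non-MIG summaries. Standard tests are delegated to base R (fisher.test,
# binom.test with the minimum-likelihood two-tail, wilcox.test, p.adjust);
# Boschloo's unconditional test is implemented here by maximizing the exact
# Fisher tail over a grid of the nuisance parameter.

#' Conservation percentage from conserved/variable counts
#'
#' @param n_cons introns conserved as the same type in both species.
#' @param n_var introns of the type present where the partner position lacks
#'   the type.
#' @return 100 * n_cons / (n_cons + n_var).
#' @export
conservation_percentage <- function(n_cons, n_var) {
  if (any(n_cons + n_var <= 0)) stop_param("n_cons + n_var must be > 0")
  100 * n_cons / (n_cons + n_var)
}

as_table2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
  } else if (length(x) == 4) {
    x <- matrix(x, 2, 2, byrow = TRUE)
  } else {
    stop_param("need a 2x2 table (matrix or length-4 vector, row-major)")
  }
  if (any(x < 0) || any(x != round(x))) {
    stop_param("table cells must be non-negative integers")
  }
  if (sum(x) == 0) stop_param("all-zero table")
  x
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric p-value (two-sided by default), via
#' `stats::fisher.test`.
#'
#' @param table 2x2 matrix or row-major length-4 vector.
#' @param alternative "two.sided", "greater" or "less".
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  tab <- as_table2x2(table)
  fisher.test(tab, alternative = alternative)$p.value
}

#' Two-tailed exact binomial test of 5'-half occupancy
#'
#' Minimum-likelihood two-tail at p = 0.5 (the `binom.test` convention):
#' success is presence in the transcript's 5' half.
#'
#' @param n_5prime introns in the 5' half.
#' @param n_total total introns.
#' @return p-value.
#' @export
binomial_bias_test <- function(n_5prime, n_total) {
  check_count(n_5prime, "n_5prime")
  check_count(n_total, "n_total", min = 1)
  binom.test(n_5prime, n_total, p = 0.5)$p.value
}

#' Positional-bias test battery for one species
#'
#' Three criteria for a 5' minor-intron bias: (a) two-tailed exact binomial
#' test of minor-intron presence in the transcript 5' half, (b) two-tailed
#' Mann-Whitney U test of minor versus major relative positions, (c) median
#' minor position more 5' than median major position. The species is flagged
#' only when all three hold at `alpha`.
#'
#' @param minor_positions,major_positions relative positions in [0, 1].
#' @param alpha significance level (default 0.05).
#' @return one-row data frame (`bias_test` result): counts, medians,
#'   `p_binomial`, `p_mwu`, `flagged_5prime_minor_bias`.
#' @export
positional_bias_battery <- function(minor_positions, major_positions,
                                    alpha = 0.05) {
  check_prob(minor_positions, "minor_positions")
  check_prob(major_positions, "major_positions")
  if (!length(minor_positions) || !length(major_positions)) {
    stop_param("need at least one intron of each type")
  }
  n5 <- sum(minor_positions < 0.5)
  n <- length(minor_positions)
  p_bin <- binomial_bias_test(n5, n)
  # exact Mann-Whitney below n = 20 per group, normal approximation with
  # continuity correction above
  exact <- n <= 20 && length(major_positions) <= 20
  p_mwu <- suppressWarnings(
    wilcox.test(minor_positions, major_positions, exact = exact,
                correct = TRUE)$p.value
  )
  med_minor <- median(minor_positions)
  med_major <- median(major_positions)
  data.frame(
    n_5prime = n5, n_total = n,
    median_minor = med_minor, median_major = med_major,
    p_binomial = p_bin, p_mwu = p_mwu,
    flagged_5prime_minor_bias = (p_bin < alpha) && (p_mwu < alpha) &&
      (med_minor < med_major),
    stringsAsFactors = FALSE
  )
}

#' Positional-bias battery across species with BH correction
#'
#' @param positions named list, one element per species: a list with
#'   `minor` and `major` position vectors.
#' @param alpha significance level.
#' @return data frame with one row per species, uncorrected and
#'   Benjamini-Hochberg-corrected p-values and flags.
#' @export
positional_bias_batch <- function(positions, alpha = 0.05) {
  rows <- lapply(names(positions), function(sp) {
    r <- positional_bias_battery(positions[[sp]]$minor,
                                 positions[[sp]]$major, alpha)
    cbind(species = sp, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_binomial <- p.adjust(out$p_binomial, "BH")
  out$q_mwu <- p.adjust(out$p_mwu, "BH")
  out$flagged_corrected <- (out$q_binomial < alpha) & (out$q_mwu < alpha) &
    (out$median_minor < out$median_major)
  out
}

#' Clade enrichment of flagged species
#'
#' Two-sided Fisher test of the 2x2 table [[flagged in focal clade,
#' unflagged in focal], [flagged elsewhere, unflagged elsewhere]].
#'
#' @param flags logical per species.
#' @param clades clade label per species.
#' @param focal_clade clade tested for enrichment.
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
clade_enrichment <- function(flags, clades, focal_clade) {
  stopifnot(length(flags) == length(clades))
  if (!focal_clade %in% clades) {
    stop_param("focal clade absent from data")
  }
  infocal <- clades == focal_clade
  tab <- matrix(c(sum(flags & infocal), sum(!flags & infocal),
                  sum(flags & !infocal), sum(!flags & !infocal)),
                2, 2, byrow = TRUE,
                dimnames = list(c(focal_clade, "other"),
                                c("flagged", "unflagged")))
  list(table = tab, p = fisher_exact_2x2(tab))
}

#' Phase distribution of a set of introns
#'
#' @param phases integer vector of phases (0, 1, 2); NAs (exon-defined
#'   introns) are dropped.
#' @return named numeric vector of proportions for phases 0, 1, 2.
#' @export
phase_distribution <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (!length(phases)) stop_param("no phased introns")
  if (!all(phases %in% 0:2)) stop_param("phases must be 0, 1 or 2")
  prop.table(table(factor(phases, levels = 0:2)))
}

#' Boschloo's exact unconditional test for two binomial proportions
#'
#' Compares x1/n1 against x2/n2 using the Fisher exact p-value as the test
#' statistic and maximizing the exact tail probability over a grid of the
#' common nuisance proportion. Intended for the modest counts of phase-0
#' fraction comparisons; for `n1 * n2` beyond `max_cells` the Fisher p-value
#' is returned with `method = "fisher_fallback"`.
#'
#' @param x1,n1,x2,n2 successes and trials in the two groups.
#' @param grid_points nuisance-parameter grid resolution (default 1000).
#' @param max_cells fallback threshold on n1 * n2 (default 250000).
#' @return list with `p`, `method` and the Fisher statistic `p_fisher`.
#' @export
boschloo_test <- function(x1, n1, x2, n2, grid_points = 1000,
                          max_cells = 250000) {
  check_count(x1, "x1")
  check_count(x2, "x2")
  check_count(n1, "n1", 1)
  check_count(n2, "n2", 1)
  stopifnot(x1 <= n1, x2 <= n2)
  fisher_p <- function(i, j) {
    fisher.test(matrix(c(i, n1 - i, j, n2 - j), 2, byrow = TRUE))$p.value
  }
  p_obs <- fisher_p(x1, x2)
  if (as.numeric(n1) * n2 > max_cells) {
    return(list(p = p_obs, method = "fisher_fallback", p_fisher = p_obs))
  }
  stat <- outer(0:n1, 0:n2, Vectorize(fisher_p))
  reject <- stat <= p_obs + 1e-12
  pis <- seq(1 / (grid_points + 1), grid_points / (grid_points + 1),
             length.out = grid_points)
  pmax_val <- 0
  for (pi in pis) {
    w <- outer(dbinom(0:n1, n1, pi), dbinom(0:n2, n2, pi))
    pmax_val <- max(pmax_val, sum(w[reject]))
  }
  list(p = min(1, pmax_val), method = "boschloo", p_fisher = p_obs)
}

#' Compare phase-0 fractions between two species
#'
#' @param x1,n1 phase-0 count and total introns in the first species.
#' @param x2,n2 same for the reference species.
#' @param method "boschloo" (exact unconditional, default) or "fisher".
#' @return list with `p` and `method`.
#' @export
compare_phase0 <- function(x1, n1, x2, n2,
                           method = c("boschloo", "fisher")) {
  method <- match.arg(method)
  if (method == "fisher") {
    return(list(p = fisher_exact_2x2(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                            byrow = TRUE)),
                method = "fisher"))
  }
  res <- boschloo_test(x1, n1, x2, n2)
  list(p = res$p, method = res$method)
}

#' MIG versus non-MIG genic density and length comparisons
#'
#' Per species, compares minor intron-containing genes (MIGs) against other
#' genes on genic intron density and coding length with two-tailed
#' Mann-Whitney U tests. Species with fewer than `min_minor` minor introns
#' are excluded (guarding against spurious minor calls). With an
#' `age_category` column, comparisons run within each category and p-values
#' are Benjamini-Hochberg-corrected across categories.
#'
#' @param genes data frame with columns `species`, `gene_id`, `is_mig`
#'   (logical), `density`, `coding_length`, optionally `age_category`.
#' @param n_minor_by_species named vector: minor intron count per species.
#' @param min_minor exclusion threshold (default 10).
#' @return data frame with one row per species (and age category when
#'   supplied): medians, Mann-Whitney p-values and BH q-values.
#' @export
mig_comparisons <- function(genes, n_minor_by_species, min_minor = 10) {
  keep <- names(n_minor_by_species)[n_minor_by_species >= min_minor]
  genes <- genes[genes$species %in% keep, , drop = FALSE]
  if (!nrow(genes)) {
    return(data.frame(species = character(0)))
  }
  strata <- if ("age_category" %in% names(genes)) {
    split(genes, list(genes$species, genes$age_category), drop = TRUE)
  } else split(genes, genes$species)
  rows <- lapply(strata, function(g) {
    mig <- g[g$is_mig, , drop = FALSE]
    non <- g[!g$is_mig, , drop = FALSE]
    if (!nrow(mig) || !nrow(non)) return(NULL)
    data.frame(
      species = g$species[1],
      age_category = if ("age_category" %in% names(g)) g$age_category[1]
      else NA_character_,
      n_mig = nrow(mig), n_non = nrow(non),
      median_density_mig = median(mig$density),
      median_density_non = median(non$density),
      median_length_mig = median(mig$coding_length),
      median_length_non = median(non$coding_length),
      p_density = suppressWarnings(
        wilcox.test(mig$density, non$density)$p.value),
      p_length = suppressWarnings(
        wilcox.test(mig$coding_length, non$coding_length)$p.value),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out$q_density <- p.adjust(out$p_density, "BH")
  out$q_length <- p.adjust(out$p_length, "BH")
  out
}

#' Spearman rank correlation helper
#'
#' @param x,y numeric vectors.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  cor(x, y, method = "spearman")
}
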