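# Per-species curation of minor-intron presence/absence, combining the
# classifier output with minor snRNA evidence (U11, U12, U4atac, U6atac) and
# BUSCO completeness.
#
# Rules (thresholds inclusive exactly as printed):
#   PRESENT:  corrected minor-intron fraction <= 0.25, >= 3 called minor
#             introns and at least two minor snRNAs.
#   ABSENT:   (<= 3 minor introns and fewer than two snRNAs), OR
#             (<= 5 minor introns, fewer than two snRNAs, fewer than five
#              uncorrected AT-AC minor introns, and either RefSeq-based
#              annotation or BUSCO >= B_Q1 - 1.5 * B_IQR for the clade).
#   UNCERTAIN override: low minor-intron/snRNA evidence as above but minor
#             intron density >= 1% (spurious-density edge cases).
#   Anything else is UNCERTAIN.

#' Clade-level BUSCO quartile statistics
#'
#' First quartile and inner quartile range of per-species BUSCO completeness
#' scores within each clade, using the linear-interpolation (type 7)
#' quantile definition. At least four species per clade are required.
#'
#' @param scores numeric BUSCO completeness percentages.
#' @param clades clade label per score.
#' @return data frame with `clade`, `n`, `B_Q1`, `B_IQR` and the absence
#'   threshold `B_Q1 - 1.5 * B_IQR`.
#' @export
clade_busco_stats <- function(scores, clades) {
  stopifnot(length(scores) == length(clades))
  out <- lapply(split(scores, clades), function(x) {
    if (length(x) < 4) {
      stop_param("clade_busco_stats needs >= 4 species per clade")
    }
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(n = length(x), B_Q1 = q[1], B_IQR = q[2] - q[1],
               threshold = q[1] - 1.5 * (q[2] - q[1]))
  })
  res <- do.call(rbind, out)
  res$clade <- names(out)
  res[, c("clade", "n", "B_Q1", "B_IQR", "threshold")]
}

#' Curate one species' minor-intron status
#'
#' @param n_minor called minor introns.
#' @param corrected_fraction fraction of minor calls with corrected
#'   boundaries.
#' @param n_snrna distinct minor snRNAs detected (0..4).
#' @param n_uncorrected_atac AT-AC minor calls without boundary correction.
#' @param minor_density minor introns as percent of all introns.
#' @param annotation_source "RefSeq" or "other".
#' @param busco BUSCO completeness percent (may be NA).
#' @param busco_threshold clade absence threshold `B_Q1 - 1.5 * B_IQR` (may
#'   be NA when not needed).
#' @return object of class `curation_verdict`: list with `verdict`
#'   ("present"/"absent"/"uncertain") and `triggered_rules`.
#' @export
curate_species <- function(n_minor, corrected_fraction, n_snrna,
                           n_uncorrected_atac = 0, minor_density = 0,
                           annotation_source = c("other", "RefSeq"),
                           busco = NA_real_, busco_threshold = NA_real_) {
  annotation_source <- match.arg(annotation_source)
  check_count(n_minor, "n_minor")
  check_prob(corrected_fraction, "corrected_fraction")
  check_count(n_snrna, "n_snrna")
  if (n_snrna > 4) stop_param("n_snrna must be 0..4")
  rules <- character(0)
  verdict <- NULL
  present <- corrected_fraction <= 0.25 && n_minor >= 3 && n_snrna >= 2
  absent1 <- n_minor <= 3 && n_snrna < 2
  absent2_core <- n_minor <= 5 && n_snrna < 2 && n_uncorrected_atac < 5
  absent2 <- FALSE
  insufficient <- FALSE
  if (absent2_core) {
    if (annotation_source == "RefSeq") {
      absent2 <- TRUE
    } else if (is.na(busco) || is.na(busco_threshold)) {
      insufficient <- !absent1 # BUSCO clause needed but unavailable
    } else {
      absent2 <- busco >= busco_threshold
    }
  }
  low_evidence <- absent1 || absent2 || (n_minor <= 5 && n_snrna < 2)
  if (present) {
    verdict <- "present"
    rules <- "present_minor_and_snrna"
  } else if (low_evidence && minor_density >= 1) {
    verdict <- "uncertain"
    rules <- "uncertain_high_density"
  } else if (absent1 || absent2) {
    verdict <- "absent"
    if (absent1) rules <- c(rules, "absent_low_minor_low_snrna")
    if (absent2) rules <- c(rules, "absent_busco_or_refseq")
  } else if (insufficient) {
    verdict <- "uncertain"
    rules <- "insufficient_evidence"
  } else {
    verdict <- "uncertain"
    rules <- "uncertain_default"
  }
  structure(list(verdict = verdict, triggered_rules = rules),
            class = "curation_verdict")
}

#' @export
print.curation_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (%s)\n", x$verdict,
              paste(x$triggered_rules, collapse = ", ")))
  invisible(x)
}

#' Curate a table of species
#'
#' Vectorized wrapper over [curate_species()]; clade BUSCO thresholds are
#' joined from [clade_busco_stats()] output when a `clade` column is present.
#'
#' @param evidence data frame with columns `species`, `n_minor`,
#'   `corrected_fraction`, `n_snrna`, and optionally `n_uncorrected_atac`,
#'   `minor_density`, `annotation_source`, `busco`, `clade`.
#' @param clade_stats optional output of [clade_busco_stats()].
#' @return `evidence` with `verdict` and `triggered_rules` columns appended.
#' @export
curate_table <- function(evidence, clade_stats = NULL) {
  n <- nrow(evidence)
  thr <- rep(NA_real_, n)
  if (!is.null(clade_stats) && "clade" %in% names(evidence)) {
    thr <- clade_stats$threshold[match(evidence$clade, clade_stats$clade)]
  }
  verdicts <- character(n)
  rules <- character(n)
  for (i in seq_len(n)) {
    v <- curate_species(
      n_minor = evidence$n_minor[i],
      corrected_fraction = evidence$corrected_fraction[i],
      n_snrna = evidence$n_snrna[i],
      n_uncorrected_atac = evidence$n_uncorrected_atac[i] %||% 0,
      minor_density = evidence$minor_density[i] %||% 0,
      annotation_source = evidence$annotation_source[i] %||% "other",
      busco = evidence$busco[i] %||% NA_real_,
      busco_threshold = thr[i]
    )
    verdicts[i] <- v$verdict
    rules[i] <- paste(v$triggered_rules, collapse = ";")
  }
  evidence$verdict <- verdicts
  evidence$triggered_rules <- rules
  evidence
}
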