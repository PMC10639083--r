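# Minor-intron scoring: position weight matrices over the 5' splice site
# (positions -3..+8 around the donor, so scoring sequences carry three exonic
# bases of context) and the branch point (9 nt, best placement within
# -40..-5 of the acceptor), combined as log-odds and calibrated to a
# percentile score in [0, 100] against a pooled minor+major reference. An
# intron is called minor when its percentile score exceeds the threshold
# (default 90; some species warrant 95).

pwm_from_windows <- function(windows, pseudocount) {
  w <- nchar(windows[1])
  m <- matrix(0, 4, w, dimnames = list(BASES, NULL))
  for (i in seq_len(w)) {
    tab <- table(factor(substr(windows, i, i), levels = BASES))
    m[, i] <- as.numeric(tab)
  }
  if (pseudocount == 0 && any(m == 0)) {
    stop_param("pseudocount 0 with unseen base at some position; ",
               "increase pseudocount")
  }
  m <- m + pseudocount
  sweep(m, 2, colSums(m), "/")
}

base_composition <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = BASES))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- BASES
  p
}

pwm_score <- function(pwm, window, bg = NULL) {
  b <- strsplit(window, "")[[1]]
  keep <- b %in% BASES
  if (!any(keep)) return(NA_real_)
  idx <- cbind(match(b[keep], BASES), which(keep))
  num <- log2(pwm[idx])
  den <- if (is.null(bg)) 0 else log2(bg[b[keep]])
  sum(num - den)
}

log_odds <- function(pwm_num, pwm_den, window) {
  b <- strsplit(window, "")[[1]]
  keep <- b %in% BASES
  if (!any(keep)) return(NA_real_)
  idx <- cbind(match(b[keep], BASES), which(keep))
  sum(log2(pwm_num[idx]) - log2(pwm_den[idx]))
}

bps_windows <- function(intron) {
  L <- nchar(intron)
  lo <- max(1L, L + BPS_SEARCH[1]) # earliest start of the search region
  hi <- L + BPS_SEARCH[2]          # last base the motif may touch
  starts <- seq.int(lo, hi - BPS_WIDTH + 1L)
  starts <- starts[starts >= 1]
  if (!length(starts)) return(character(0))
  substring(intron, starts, starts + BPS_WIDTH - 1L)
}

best_bps_score <- function(pwm, bg, intron) {
  wins <- bps_windows(intron)
  if (!length(wins)) return(NA_real_)
  max(vapply(wins, function(w) pwm_score(pwm, w, bg), numeric(1)))
}

#' Train a minor-intron scoring model from reference sequences
#'
#' Reference sequences must carry three exonic bases followed by the intron
#' (so the donor window spans the exon/intron junction). Donor PWMs are
#' estimated for both classes with a pseudocount; the branch-point PWM is
#' refined from the minor references by a few deterministic best-placement
#' re-estimation passes over the acceptor-proximal search window. The
#' percentile calibration stores the combined (donor log-odds + branch-point)
#' scores of the pooled references, so a query's minor score is its
#' percentile among all reference introns.
#'
#' @param minor_reference,major_reference character vectors of reference
#'   sequences (3 exonic nt + intron), at least 20 per class, each with at
#'   least 12 nt at the 5' end and 40 nt at the 3' end.
#' @param pseudocount added to every PWM cell (0 triggers an error if any
#'   base is unseen at a position).
#' @param refine_iterations branch-point best-placement re-estimation passes.
#' @return object of class `scoring_model`.
#' @export
train_scorer <- function(minor_reference, major_reference, pseudocount = 0.5,
                         refine_iterations = 4) {
  for (nm in c("minor_reference", "major_reference")) {
    x <- get(nm)
    if (length(x) < 20) stop_param(nm, ": need at least 20 sequences")
    if (any(nchar(x) < 12) || any(nchar(x) < 40)) {
      stop_param(nm, ": sequences need >= 12 nt of 5' end and >= 40 nt of ",
                 "3' end")
    }
  }
  minor_reference <- toupper(minor_reference)
  major_reference <- toupper(major_reference)
  bg <- base_composition(c(minor_reference, major_reference))
  donor_minor <- pwm_from_windows(substr(minor_reference, 1, DONOR_WIDTH),
                                  pseudocount)
  donor_major <- pwm_from_windows(substr(major_reference, 1, DONOR_WIDTH),
                                  pseudocount)
  if (max(abs(donor_minor - donor_major)) < 1e-9) {
    warning("minor and major donor references are indistinguishable; ",
            "calibration is degenerate", call. = FALSE)
  }
  # branch point: seed the motif from the most frequent candidate 9-mer
  # (register-anchored, unlike a flat average over windows), then
  # re-estimate from each sequence's best placement
  minor_introns <- substr(minor_reference, DONOR_EXONIC + 1L,
                          nchar(minor_reference))
  all_windows <- unlist(lapply(minor_introns, bps_windows))
  if (!length(all_windows)) stop_param("no branch-point search windows")
  tab <- table(all_windows)
  top <- sort(names(tab)[tab == max(tab)])[1]
  bps <- pwm_from_windows(all_windows[all_windows == top],
                          max(pseudocount, 0.25))
  for (iter in seq_len(refine_iterations)) {
    picked <- vapply(minor_introns, function(s) {
      wins <- bps_windows(s)
      wins[which.max(vapply(wins, function(w) pwm_score(bps, w, bg),
                            numeric(1)))]
    }, character(1))
    bps <- pwm_from_windows(picked, max(pseudocount, 0.25))
  }
  model <- structure(
    list(pwm_5ss_minor = donor_minor, pwm_5ss_major = donor_major,
         pwm_bps_minor = bps, background = bg),
    class = "scoring_model"
  )
  raw <- vapply(c(minor_reference, major_reference),
                function(s) raw_scores(model, s)$combined, numeric(1))
  minor_donor_bg <- vapply(minor_reference, function(s) {
    pwm_score(donor_minor, substr(s, 1, DONOR_WIDTH), bg)
  }, numeric(1))
  model$calibration <- sort(unname(raw))
  model$correction_cutoff <- unname(quantile(minor_donor_bg, 0.95, type = 7))
  model
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("Minor-intron scoring model\n")
  cat(sprintf("  donor window: %d nt (%d exonic + %d intronic)\n",
              DONOR_WIDTH, DONOR_EXONIC, DONOR_INTRONIC))
  cat(sprintf("  branch-point motif: %d nt, searched %d..%d of acceptor\n",
              BPS_WIDTH, BPS_SEARCH[1], BPS_SEARCH[2]))
  cat(sprintf("  calibration references: %d; correction cutoff %.2f bits\n",
              length(x$calibration), x$correction_cutoff))
  invisible(x)
}

# raw per-intron scores for a context+intron string
raw_scores <- function(model, seq_with_context) {
  donor_win <- substr(seq_with_context, 1, DONOR_WIDTH)
  intron <- substr(seq_with_context, DONOR_EXONIC + 1L,
                   nchar(seq_with_context))
  s5 <- log_odds(model$pwm_5ss_minor, model$pwm_5ss_major, donor_win)
  sb <- best_bps_score(model$pwm_bps_minor, model$background, intron)
  list(score_5ss = s5, score_bps = sb,
       combined = if (is.na(s5) || is.na(sb)) NA_real_ else s5 + sb)
}

percentile_score <- function(model, raw) {
  if (is.na(raw)) return(NA_real_)
  100 * mean(model$calibration <= raw)
}

canonical_termini <- function(five, three) {
  substr(five, 1, 2) %in% c("GT", "GC", "AT") & three %in% c("AG", "AC")
}

subtype_of <- function(five, three) {
  pair <- paste(five, three, sep = "-")
  ifelse(pair %in% c("GT-AG", "GC-AG", "AT-AC"), pair, "other")
}

#' Correct the boundaries of a non-canonically annotated intron
#'
#' If a strong minor donor motif (donor-vs-background log-odds at or above
#' the model's correction cutoff, by default the 95th percentile of the minor
#' reference donor scores) lies within `max_shift` nt of the annotated 5'
#' splice site, both boundaries are shifted by that offset (length is
#' preserved) and the corrected flag is set. Canonically terminated introns
#' are never shifted.
#'
#' @param sequence annotated intron sequence (sense strand).
#' @param upstream_flank,downstream_flank exonic sequence flanking the intron
#'   (sense strand), at least `max_shift` nt for full shift range.
#' @param model a `scoring_model`.
#' @param max_shift maximum boundary shift in nt.
#' @param cutoff donor strength cutoff; defaults to the model's.
#' @return list with `sequence`, `shift`, `corrected`, `five_prime`,
#'   `three_prime`.
#' @export
correct_boundaries <- function(sequence, upstream_flank = "",
                               downstream_flank = "", model,
                               max_shift = 10,
                               cutoff = model$correction_cutoff) {
  L <- nchar(sequence)
  five <- substr(sequence, 1, 2)
  three <- substr(sequence, L - 1, L)
  unchanged <- list(sequence = sequence, shift = 0L, corrected = FALSE,
                    five_prime = five, three_prime = three)
  if (canonical_termini(five, three)) return(unchanged)
  ext <- paste0(upstream_flank, sequence, downstream_flank)
  off <- nchar(upstream_flank) # annotated intron starts at off + 1 in ext
  best_shift <- NA_integer_
  best_score <- -Inf
  for (d in setdiff(seq(-max_shift, max_shift), 0L)) {
    start <- off + d + 1L
    win_start <- start - DONOR_EXONIC
    if (win_start < 1 || start + DONOR_INTRONIC - 1L > nchar(ext)) next
    if (off + d + L > nchar(ext)) next # shifted 3' end must stay in range
    win <- substr(ext, win_start, start + DONOR_INTRONIC - 1L)
    sc <- pwm_score(model$pwm_5ss_minor, win, model$background)
    if (is.na(sc) || sc < cutoff) next
    if (sc > best_score + 1e-12 ||
        (abs(sc - best_score) <= 1e-12 && abs(d) < abs(best_shift))) {
      best_score <- sc
      best_shift <- d
    }
  }
  if (is.na(best_shift)) return(unchanged)
  new_seq <- substr(ext, off + best_shift + 1L, off + best_shift + L)
  list(sequence = new_seq, shift = as.integer(best_shift), corrected = TRUE,
       five_prime = substr(new_seq, 1, 2),
       three_prime = substr(new_seq, L - 1, L))
}

#' Score introns and call minor versus major type
#'
#' Applies boundary correction to non-canonically terminated introns (when
#' `correct = TRUE` and flanking sequence is available), computes the donor
#' and branch-point log-odds, calibrates them to a percentile minor score and
#' calls an intron minor iff its score strictly exceeds `threshold`.
#' Sequences shorter than the scoring windows are skipped with a flag.
#'
#' @param model a `scoring_model` from [train_scorer()].
#' @param introns intron records (need `intron_id`, `sequence`; flanks and
#'   termini columns are used when present).
#' @param threshold percentile threshold in (0, 100]; default 90.
#' @param correct attempt boundary correction for non-canonical termini.
#' @param max_shift maximum correction shift.
#' @return data frame of minor calls: `intron_id`, `score_5ss`, `score_bps`,
#'   `minor_score`, `type_call` ("minor"/"major"), `subtype`,
#'   `boundary_corrected`, `shift`, `skipped`, plus `species`/`gene_id` when
#'   present in the input.
#' @export
score_and_classify <- function(model, introns, threshold = 90,
                               correct = TRUE, max_shift = 10) {
  stopifnot(inherits(model, "scoring_model"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 100) {
    stop_param("threshold must lie in (0, 100]")
  }
  n <- nrow(introns)
  up <- introns$upstream_flank %||% rep("", n)
  down <- introns$downstream_flank %||% rep("", n)
  out <- data.frame(
    intron_id = introns$intron_id,
    score_5ss = NA_real_, score_bps = NA_real_, minor_score = NA_real_,
    type_call = NA_character_, subtype = NA_character_,
    boundary_corrected = FALSE, shift = 0L, skipped = FALSE,
    stringsAsFactors = FALSE
  )
  for (extra in c("species", "gene_id", "transcript_id")) {
    if (extra %in% names(introns)) out[[extra]] <- introns[[extra]]
  }
  for (i in seq_len(n)) {
    seq <- toupper(introns$sequence[i])
    L <- nchar(seq)
    if (L < 30 || nchar(up[i]) < DONOR_EXONIC) {
      out$skipped[i] <- TRUE
      next
    }
    if (correct) {
      cb <- correct_boundaries(seq, up[i], down[i], model, max_shift)
      if (cb$corrected) {
        seq <- cb$sequence
        out$boundary_corrected[i] <- TRUE
        out$shift[i] <- cb$shift
      }
    }
    ctx <- substr(up[i], nchar(up[i]) - DONOR_EXONIC + 1L, nchar(up[i]))
    # after a downstream shift the context is the original intron's start
    if (out$shift[i] > 0) {
      ctx <- substr(paste0(up[i], toupper(introns$sequence[i])),
                    nchar(up[i]) + out$shift[i] - DONOR_EXONIC + 1L,
                    nchar(up[i]) + out$shift[i])
    } else if (out$shift[i] < 0) {
      ctx <- substr(up[i], nchar(up[i]) + out$shift[i] - DONOR_EXONIC + 1L,
                    nchar(up[i]) + out$shift[i])
    }
    rs <- raw_scores(model, paste0(ctx, seq))
    out$score_5ss[i] <- rs$score_5ss
    out$score_bps[i] <- rs$score_bps
    out$minor_score[i] <- percentile_score(model, rs$combined)
    out$subtype[i] <- subtype_of(substr(seq, 1, 2), substr(seq, L - 1, L))
    if (!is.na(out$minor_score[i])) {
      out$type_call[i] <- if (out$minor_score[i] > threshold) "minor"
      else "major"
    } else {
      out$skipped[i] <- TRUE
    }
  }
  out
}

#' Per-genome classification summary
#'
#' @param calls output of [score_and_classify()].
#' @return list with `n_scored`, `n_minor`, `minor_density` (percent of
#'   scored introns called minor), `corrected_fraction` (of minor calls) and
#'   `n_uncorrected_atac` (AT-AC minor calls without boundary correction).
#' @export
classify_summary <- function(calls) {
  scored <- calls[!calls$skipped, , drop = FALSE]
  minor <- scored[!is.na(scored$type_call) & scored$type_call == "minor", ,
                  drop = FALSE]
  list(
    n_scored = nrow(scored),
    n_minor = nrow(minor),
    minor_density = if (nrow(scored)) 100 * nrow(minor) / nrow(scored) else 0,
    corrected_fraction = if (nrow(minor)) {
      mean(minor$boundary_corrected)
    } else 0,
    n_uncorrected_atac = sum(minor$subtype == "AT-AC" &
                               !minor$boundary_corrected)
  )
}

#' Synthetic reference intron sets drawn from the default motifs
#'
#' Generates minor and major reference sequences (3 exonic nt + intron) from
#' the package's motif specification, used to train the packaged default
#' scoring model and available for building models in examples and tests.
#'
#' @param n sequences per class.
#' @param noise motif noise level passed to [default_motif_spec()].
#' @param intron_length intron length range.
#' @param seed integer seed.
#' @return list with character vectors `minor` and `major`.
#' @export
synthetic_reference_sets <- function(n = 100, noise = 0.1,
                                     intron_length = c(60L, 120L), seed = 1) {
  spec <- default_motif_spec(noise)
  with_seed(seed, {
    gen <- function(type) {
      vapply(seq_len(n), function(i) {
        ilen <- sample(intron_length[1]:intron_length[2], 1)
        it <- sample_intron(type, ilen, spec)
        paste0(it$exonic_context, it$seq)
      }, character(1))
    }
    list(minor = gen("minor"), major = gen("major"))
  })
}

#' Default scoring model trained on the packaged synthetic references
#'
#' Reads the synthetic reference FASTAs shipped with the package (generated
#' from the consensus-derived motif models at noise 0.1) and trains a
#' scoring model on them.
#'
#' @return a `scoring_model`.
#' @export
default_scoring_model <- function() {
  minor <- read_genome(system.file("extdata", "synthetic_minor_reference.fa",
                                   package = "minorintrons",
                                   mustWork = TRUE))
  major <- read_genome(system.file("extdata", "synthetic_major_reference.fa",
                                   package = "minorintrons",
                                   mustWork = TRUE))
  train_scorer(unname(minor), unname(major))
}
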