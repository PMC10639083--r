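# Synthetic-data generators. These define the study conditions under which
# the downstream estimators and tests are exercised: three-taxon intron
# presence/absence evolution with independent per-lineage retention and
# unidirectional minor-to-major conversion (and no parallel gain), toy
# genomes with motif-planted introns, junction count tables with known
# retention, and expression matrices with a planted proliferating cell type.

LINEAGES <- c("alpha", "beta", "gamma")

as_retention_matrix <- function(retention) {
  if (is.matrix(retention)) {
    stopifnot(nrow(retention) == 3, ncol(retention) == 2)
    m <- retention
  } else if (length(retention) == 1) {
    m <- matrix(retention, 3, 2)
  } else if (length(retention) == 3) {
    m <- matrix(retention, 3, 2)
  } else {
    stop_param("retention must be a scalar, length-3 vector or 3x2 matrix")
  }
  dimnames(m) <- list(LINEAGES, c("minor", "major"))
  check_prob(m, "retention")
  m
}

#' Simulate three-taxon intron presence/absence evolution
#'
#' Plants `n_ancestral_minor` + `n_ancestral_major` introns in the common
#' ancestor of two sister lineages (alpha, beta) and an outgroup (gamma).
#' Each intron is retained independently in each lineage with the lineage- and
#' type-specific retention probability; a surviving ancestral minor intron is
#' then converted to major type with the lineage's `conversion_prob`
#' (conversion is a fate of a present intron, not a loss, and is
#' unidirectional minor -> major). Parallel gain is absent by construction,
#' matching the assumption under which the ancestral-count estimator
#' ([estimate_ancestral_count()]) is derived.
#'
#' @param n_ancestral_minor,n_ancestral_major ancestral intron counts.
#' @param retention retention probability: scalar, per-lineage length-3
#'   vector (alpha, beta, gamma), or 3 x 2 matrix (lineage x type).
#' @param conversion_prob probability that a surviving ancestral minor intron
#'   is observed as major type; scalar or per-lineage length-3 vector.
#' @param seed integer seed; the simulation uses its own RNG scope.
#' @return object of class `three_taxon_sim`: list with `states` (one row per
#'   intron: `intron_id`, `ancestral_type`, `state_alpha`, `state_beta`,
#'   `state_gamma`, each state in minor/major/absent), plus the parameters.
#' @examples
#' sim <- simulate_three_taxon(50, 500, retention = 0.8,
#'                             conversion_prob = 0.1, seed = 1)
#' triple_presence_counts(sim, "minor")
#' @export
simulate_three_taxon <- function(n_ancestral_minor, n_ancestral_major,
                                 retention = 1, conversion_prob = 0,
                                 seed = NULL) {
  check_count(n_ancestral_minor, "n_ancestral_minor")
  check_count(n_ancestral_major, "n_ancestral_major")
  rmat <- as_retention_matrix(retention)
  conv <- rep_len(conversion_prob, 3)
  check_prob(conv, "conversion_prob")
  names(conv) <- LINEAGES
  n <- n_ancestral_minor + n_ancestral_major
  anc <- rep(c("minor", "major"), c(n_ancestral_minor, n_ancestral_major))
  states <- with_seed(seed, {
    out <- data.frame(
      intron_id = sprintf("anc_%05d", seq_len(max(n, 1)))[seq_len(n)],
      ancestral_type = anc,
      stringsAsFactors = FALSE
    )
    for (lin in LINEAGES) {
      kept <- runif(n) < rmat[lin, anc]
      st <- ifelse(kept, anc, "absent")
      is_minor_kept <- kept & anc == "minor"
      converted <- is_minor_kept & (runif(n) < conv[lin])
      st[converted] <- "major"
      out[[paste0("state_", lin)]] <- st
    }
    out
  })
  structure(
    list(states = states, retention = rmat, conversion_prob = conv,
         n_ancestral_minor = n_ancestral_minor,
         n_ancestral_major = n_ancestral_major, seed = seed),
    class = "three_taxon_sim"
  )
}

#' @export
print.three_taxon_sim <- function(x, ...) {
  cat("Three-taxon intron simulation\n")
  cat(sprintf("  ancestral introns: %d minor, %d major\n",
              x$n_ancestral_minor, x$n_ancestral_major))
  for (lin in LINEAGES) {
    cat(sprintf("  %-5s retention (minor/major): %.2f/%.2f, conversion: %.2f\n",
                lin, x$retention[lin, "minor"], x$retention[lin, "major"],
                x$conversion_prob[lin]))
  }
  invisible(x)
}

#' Pairwise and three-way shared intron counts of one observed type
#'
#' Counts introns observed as `type` in both members of each lineage pair and
#' in all three lineages, the quantities consumed by
#' [estimate_ancestral_count()]. Counting is by observed state, so an
#' ancestrally minor intron converted to major in a lineage contributes to
#' the major counts there and never to the minor counts.
#'
#' @param x a `three_taxon_sim` object or its `states` data frame.
#' @param type "minor" or "major".
#' @return object of class `triple_counts`: list with `N_ab`, `N_ag`, `N_bg`,
#'   `N_abg` and `type`.
#' @export
triple_presence_counts <- function(x, type = c("minor", "major")) {
  type <- match.arg(type)
  st <- if (inherits(x, "three_taxon_sim")) x$states else x
  a <- st$state_alpha == type
  b <- st$state_beta == type
  g <- st$state_gamma == type
  structure(
    list(N_ab = sum(a & b), N_ag = sum(a & g), N_bg = sum(b & g),
         N_abg = sum(a & b & g), type = type),
    class = "triple_counts"
  )
}

#' @export
print.triple_counts <- function(x, ...) {
  cat(sprintf("%s introns: N_ab=%d N_ag=%d N_bg=%d N_abg=%d\n",
              x$type, x$N_ab, x$N_ag, x$N_bg, x$N_abg))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Toy genomes

sample_intron <- function(type, ilen, spec) {
  donor_pfm <- spec[[paste0("donor_", type)]]
  bps_pfm <- spec[[paste0("bps_", type)]]
  acceptor <- spec[[paste0("acceptor_", type)]]
  donor <- sample_from_pfm(donor_pfm)
  exonic <- substr(donor, 1L, DONOR_EXONIC)
  donor5 <- substr(donor, DONOR_EXONIC + 1L, DONOR_WIDTH)
  bps <- sample_from_pfm(bps_pfm)
  # distance from the last branch-point base to the intron's last base,
  # kept inside the downstream search window
  d <- sample(7:20, 1)
  tail_comp <- if (type == "major") c(0.05, 0.45, 0.05, 0.45) else rep(0.25, 4)
  filler2 <- random_dna(d - 2L, tail_comp)
  n_fill1 <- ilen - DONOR_INTRONIC - BPS_WIDTH - (d - 2L) - 2L
  if (n_fill1 < 0) stop_param("intron length too short for motif layout")
  filler1 <- random_dna(n_fill1)
  list(exonic_context = exonic,
       seq = paste0(donor5, filler1, bps, filler2, acceptor))
}

#' Generate a toy annotated genome with planted minor and major introns
#'
#' Builds one gene per contig, each with `introns_per_gene` introns planted
#' from the motif specification (consensus-exact by default): minor introns
#' carry the AT-AC donor/branch-point consensus, major introns the U2-type
#' consensus. Emits the genome, a GFF3-style annotation
#' (gene/mRNA/exon/CDS) and a per-intron truth table, optionally written to
#' disk as FASTA + GFF3 + TSV.
#'
#' @param n_genes number of genes (one per contig).
#' @param introns_per_gene introns planted in each gene.
#' @param minor_fraction probability that a planted intron is minor type.
#' @param motif_spec motif specification as from [default_motif_spec()].
#' @param seed integer seed.
#' @param intron_length,exon_length inclusive length ranges to draw from.
#' @param minus_strand_fraction fraction of genes placed on the minus strand.
#' @param wrong_strand_fraction fraction of genes whose annotated strand is
#'   deliberately flipped relative to the sequence (an annotation-error
#'   fixture for [strand_sanity_report()]).
#' @param out_dir if non-NULL, directory to write `genome.fa`,
#'   `annotation.gff3` and `truth.tsv` into.
#' @return object of class `toy_genome`: list with `genome` (named character
#'   vector of contig sequences), `annotation` (GFF3 feature data frame),
#'   `truth` (per-intron truth table) and, when written, `files`.
#' @export
generate_toy_genome <- function(n_genes, introns_per_gene,
                                minor_fraction = 0.1,
                                motif_spec = default_motif_spec(),
                                seed = NULL,
                                intron_length = c(60L, 120L),
                                exon_length = c(60L, 120L),
                                minus_strand_fraction = 0.5,
                                wrong_strand_fraction = 0,
                                out_dir = NULL) {
  check_count(n_genes, "n_genes", min = 1)
  check_count(introns_per_gene, "introns_per_gene")
  check_prob(minor_fraction, "minor_fraction")
  check_prob(wrong_strand_fraction, "wrong_strand_fraction")
  check_motif_spec(motif_spec)
  res <- with_seed(seed, {
    genome <- character(0)
    ann <- list()
    truth <- list()
    for (gi in seq_len(n_genes)) {
      gene_id <- sprintf("g%04d", gi)
      tx_id <- paste0(gene_id, ".t1")
      contig <- paste0("ctg_", gene_id)
      n_int <- introns_per_gene
      ex_len <- sample(exon_length[1]:exon_length[2], n_int + 1, replace = TRUE)
      # exon lengths are free; phases follow from cumulative coding length
      in_len <- if (n_int > 0) {
        sample(intron_length[1]:intron_length[2], n_int, replace = TRUE)
      } else integer(0)
      types <- if (n_int > 0) {
        ifelse(runif(n_int) < minor_fraction, "minor", "major")
      } else character(0)
      exons <- vapply(ex_len, random_dna, character(1))
      introns <- vector("list", n_int)
      for (k in seq_len(n_int)) {
        introns[[k]] <- sample_intron(types[k], in_len[k], motif_spec)
        # plant the donor's exonic context as the last 3 nt of the exon
        exons[k] <- paste0(substr(exons[k], 1, ex_len[k] - DONOR_EXONIC),
                           introns[[k]]$exonic_context)
      }
      spacer1 <- random_dna(sample(20:50, 1))
      spacer2 <- random_dna(sample(20:50, 1))
      pieces <- character(0)
      coords <- matrix(0L, nrow = n_int + 1, ncol = 2) # exon start/end (sense)
      icoords <- matrix(0L, nrow = max(n_int, 1), ncol = 2)
      pos <- nchar(spacer1)
      for (k in seq_len(n_int + 1)) {
        coords[k, ] <- c(pos + 1L, pos + ex_len[k])
        pos <- pos + ex_len[k]
        pieces <- c(pieces, exons[k])
        if (k <= n_int) {
          icoords[k, ] <- c(pos + 1L, pos + in_len[k])
          pos <- pos + in_len[k]
          pieces <- c(pieces, introns[[k]]$seq)
        }
      }
      seq_plus <- paste0(spacer1, paste(pieces, collapse = ""), spacer2)
      clen <- nchar(seq_plus)
      minus <- runif(1) < minus_strand_fraction
      strand <- if (minus) "-" else "+"
      if (minus) {
        seq_final <- revcomp(seq_plus)
        flip <- function(m) {
          cbind(clen - m[, 2] + 1L, clen - m[, 1] + 1L)
        }
        coords <- flip(coords)[rev(seq_len(nrow(coords))), , drop = FALSE]
        if (n_int > 0) {
          icoords <- flip(icoords)[rev(seq_len(nrow(icoords))), , drop = FALSE]
        }
        # rows are genomic-order ascending after the flip; transcription
        # order is the reverse
        tx_order_ex <- rev(seq_len(n_int + 1))
        tx_order_in <- rev(seq_len(n_int))
      } else {
        seq_final <- seq_plus
        tx_order_ex <- seq_len(n_int + 1)
        tx_order_in <- seq_len(n_int)
      }
      ann_strand <- strand
      strand_error <- runif(1) < wrong_strand_fraction
      if (strand_error) ann_strand <- if (strand == "+") "-" else "+"
      genome[contig] <- seq_final
      gene_start <- min(coords[, 1])
      gene_end <- max(coords[, 2])
      feat <- function(type, s, e, attrs, phase = ".") {
        data.frame(seqid = contig, source = "minorintrons", type = type,
                   start = s, end = e, score = ".", strand = ann_strand,
                   phase = phase, attributes = attrs,
                   stringsAsFactors = FALSE)
      }
      rows <- list(
        feat("gene", gene_start, gene_end, paste0("ID=", gene_id)),
        feat("mRNA", gene_start, gene_end,
             paste0("ID=", tx_id, ";Parent=", gene_id))
      )
      cum <- 0L
      for (j in seq_len(n_int + 1)) {
        k <- tx_order_ex[j] # row in genomic-order coords for the j-th exon
        gff_phase <- as.character((3L - cum %% 3L) %% 3L)
        rows <- c(rows, list(
          feat("exon", coords[k, 1], coords[k, 2], paste0("Parent=", tx_id)),
          feat("CDS", coords[k, 1], coords[k, 2],
               paste0("ID=cds.", tx_id, ";Parent=", tx_id), gff_phase)
        ))
        cum <- cum + ex_len[j]
      }
      ann[[gi]] <- do.call(rbind, rows)
      if (n_int > 0) {
        cum_before <- cumsum(ex_len)[seq_len(n_int)]
        truth[[gi]] <- data.frame(
          gene_id = gene_id, transcript_id = tx_id, contig = contig,
          intron_id = sprintf("%s.i%d", tx_id, seq_len(n_int)),
          index = seq_len(n_int),
          start = icoords[tx_order_in, 1], end = icoords[tx_order_in, 2],
          strand = strand, true_type = types, length = in_len,
          phase = cum_before %% 3L,
          relative_position = cum_before / sum(ex_len),
          five_prime = vapply(introns, function(x) substr(x$seq, 1, 2),
                              character(1)),
          three_prime = vapply(introns, function(x) {
            substr(x$seq, nchar(x$seq) - 1, nchar(x$seq))
          }, character(1)),
          strand_error = strand_error,
          stringsAsFactors = FALSE
        )
      }
    }
    list(genome = genome, annotation = do.call(rbind, ann),
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
  toy <- structure(c(res, list(seed = seed)), class = "toy_genome")
  if (!is.null(out_dir)) toy$files <- write_toy_genome(toy, out_dir)
  toy
}

#' Write a toy genome to FASTA + GFF3 + truth TSV
#'
#' @param toy a `toy_genome` object.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_toy_genome <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  tr <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(toy$genome), fa)
  write_gff3(toy$annotation, gff)
  write_tsv(toy$truth, tr)
  c(genome = fa, annotation = gff, truth = tr)
}

write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(apply(ann, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Junction counts and expression matrices

#' Generate junction read-count tables with known intron retention
#'
#' For each intron and replicate, draws exon-exon (EE) and intron-exon (IE)
#' junction reads as Poisson counts around `depth`, thinned by the intron's
#' true retention: EE ~ Poisson(depth * (1 - r)) and each IE junction
#' ~ Poisson(depth * r), so the expected splicing efficiency
#' EE / (EE + mean(IE)) equals 1 - r.
#'
#' @param n_introns number of introns.
#' @param true_retention per-intron retention in [0, 1] (recycled).
#' @param depth mean read count per junction class at full support.
#' @param replicates replicates per intron.
#' @param seed integer seed.
#' @return data frame with columns `intron_id`, `replicate`, `IE_left`,
#'   `IE_right`, `EE`, `true_retention`.
#' @export
generate_junction_table <- function(n_introns, true_retention, depth,
                                    replicates = 1, seed = NULL) {
  check_count(n_introns, "n_introns", min = 1)
  check_count(replicates, "replicates", min = 1)
  r <- rep_len(true_retention, n_introns)
  check_prob(r, "true_retention")
  if (!is.finite(depth) || depth <= 0) stop_param("depth must be > 0")
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        intron = seq_len(n_introns))
    ri <- r[grid$intron]
    n <- nrow(grid)
    data.frame(
      intron_id = sprintf("intron_%04d", grid$intron),
      replicate = grid$replicate,
      IE_left = rpois(n, depth * ri),
      IE_right = rpois(n, depth * ri),
      EE = rpois(n, depth * (1 - ri)),
      true_retention = ri,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an expression matrix with a planted proliferating cell type
#'
#' Log-scale expression values (gene baselines ~ N(6, 2), sample noise
#' ~ N(0, 1)) for `replicates_per_type` replicates of each cell type. A
#' designated proliferation-index (PI) gene set is up-shifted by
#' `log2(effect_size)` in the first (proliferating) cell type only, so group
#' z-score metrics should single that type out when `effect_size > 1`.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of cell-type labels (>= 2).
#' @param replicates_per_type replicates per cell type (>= 2; z-scores need
#'   variance across samples).
#' @param pi_gene_fraction fraction of genes in the PI set.
#' @param effect_size fold-change applied to PI genes in the proliferating
#'   type; 1 plants no effect.
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples), `design` (sample,
#'   cell_type), `pi_genes`, `proliferating_type`.
#' @export
generate_expression_matrix <- function(n_genes, cell_types,
                                       replicates_per_type,
                                       pi_gene_fraction = 0.05,
                                       effect_size = 1, seed = NULL) {
  check_count(n_genes, "n_genes", min = 2)
  check_count(replicates_per_type, "replicates_per_type", min = 2)
  check_prob(pi_gene_fraction, "pi_gene_fraction")
  if (!is.finite(effect_size) || effect_size <= 0) {
    stop_param("effect_size must be a positive fold-change")
  }
  stopifnot(length(cell_types) >= 2)
  with_seed(seed, {
    samples <- paste(rep(cell_types, each = replicates_per_type),
                     seq_len(replicates_per_type), sep = "_")
    design <- data.frame(sample = samples,
                         cell_type = rep(cell_types,
                                         each = replicates_per_type),
                         stringsAsFactors = FALSE)
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    n_pi <- round(pi_gene_fraction * n_genes)
    pi_genes <- if (n_pi > 0) sample(genes, n_pi) else character(0)
    base <- rnorm(n_genes, 6, 2)
    mat <- matrix(rnorm(n_genes * nrow(design), 0, 1), n_genes,
                  dimnames = list(genes, samples)) + base
    prolif <- cell_types[1]
    shift <- log2(effect_size)
    mat[pi_genes, design$cell_type == prolif] <-
      mat[pi_genes, design$cell_type == prolif] + shift
    list(matrix = mat, design = design, pi_genes = sort(pi_genes),
         proliferating_type = prolif)
  })
}
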