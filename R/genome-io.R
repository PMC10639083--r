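# Annotation parsing, longest-isoform transcriptome construction and intron
# extraction. Coordinates are 1-based inclusive at all I/O boundaries (GFF3
# convention); transcription-order arithmetic is done on sorted segment
# matrices internally.

#' Read a genome FASTA into a named character vector
#'
#' Contig names are truncated at the first whitespace, matching common
#' annotation practice.
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences (uppercase).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Read a GFF3 or GTF annotation into the internal feature model
#'
#' Parsed with `rtracklayer`; GTF gene/transcript attributes are converted to
#' the GFF3 ID/Parent hierarchy. Only gene, mRNA/transcript, exon and CDS
#' features are interpreted.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.gtf`).
#' @return data frame with columns seqid, type, start, end, strand, ID,
#'   Parent.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if ("Parent" %in% names(mc)) {
    df$ID <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    par <- mc$Parent
    df$Parent <- vapply(as.list(par), function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
  } else if ("transcript_id" %in% names(mc)) {
    # GTF: synthesize the ID/Parent hierarchy
    df$ID <- ifelse(df$type == "gene", as.character(mc$gene_id),
                    ifelse(df$type %in% c("transcript", "mRNA"),
                           as.character(mc$transcript_id), NA_character_))
    df$Parent <- ifelse(df$type %in% c("transcript", "mRNA"),
                        as.character(mc$gene_id),
                        ifelse(df$type %in% c("exon", "CDS"),
                               as.character(mc$transcript_id), NA_character_))
    df$type[df$type == "transcript"] <- "mRNA"
  } else {
    stop_param("annotation has neither Parent attributes nor GTF gene_id/",
               "transcript_id attributes")
  }
  df[df$type %in% c("gene", "mRNA", "exon", "CDS"), , drop = FALSE]
}

normalize_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    return(read_annotation(annotation))
  }
  if (inherits(annotation, "toy_genome")) annotation <- annotation$annotation
  stopifnot(is.data.frame(annotation))
  if (!"ID" %in% names(annotation) && "attributes" %in% names(annotation)) {
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
      out <- rep(NA_character_, length(attrs))
      out[lengths(regmatches(attrs,
                             gregexpr(paste0("(^|;)", key, "=[^;]+"),
                                      attrs))) > 0] <-
        sub(paste0(".*", key, "="), "", m)
      out
    }
    annotation$ID <- attr_field(annotation$attributes, "ID")
    annotation$Parent <- attr_field(annotation$attributes, "Parent")
  }
  annotation
}

normalize_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(read_genome(genome))
  }
  if (inherits(genome, "toy_genome")) genome <- genome$genome
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

order_tx <- function(seg, strand) {
  # rows (start, end) -> transcription order
  seg[order(seg[, 1], decreasing = (strand == "-")), , drop = FALSE]
}

#' Build a longest-isoform transcriptome from an annotation
#'
#' Selects, for every gene, the isoform with the greatest coding length (sum
#' of its CDS segment lengths); ties are broken by lexicographically smaller
#' transcript id. Exon-only transcripts (no CDS) are retained with coding
#' length zero so their UTR introns can still be extracted. CDS or exon
#' features without an mRNA parent are attached permissively to a synthetic
#' transcript per gene and noted via `message()`. Genes with segments
#' exceeding contig bounds are skipped with a message.
#'
#' @param annotation annotation path, feature data frame, or `toy_genome`.
#' @param genome optional genome (path, named character vector or
#'   `toy_genome`) used to validate segment bounds.
#' @return data frame of class `transcriptome`, one row per gene: `gene_id`,
#'   `transcript_id`, `contig`, `strand`, `coding_length`, `n_cds`, plus
#'   list-columns `cds` and `exons` (two-column start/end matrices in
#'   transcription order).
#' @export
build_transcriptome <- function(annotation, genome = NULL) {
  ann <- normalize_annotation(annotation)
  seqs <- if (!is.null(genome)) normalize_genome(genome)
  tx_rows <- ann$type == "mRNA"
  tx_parent <- setNames(ann$Parent[tx_rows], ann$ID[tx_rows])
  seg_rows <- ann[ann$type %in% c("exon", "CDS"), , drop = FALSE]
  # attach segments with non-mRNA parents permissively
  known_tx <- names(tx_parent)
  orphan <- !(seg_rows$Parent %in% known_tx)
  if (any(orphan)) {
    message(sum(orphan), " exon/CDS feature(s) without an mRNA parent; ",
            "treating their parent as a single-isoform transcript")
    extra <- unique(seg_rows$Parent[orphan])
    tx_parent[paste0(extra, ".tx")] <- extra
    seg_rows$Parent[orphan] <- paste0(seg_rows$Parent[orphan], ".tx")
  }
  out <- list()
  for (gene in unique(unname(tx_parent))) {
    tx_ids <- sort(names(tx_parent)[tx_parent == gene])
    best <- NULL
    for (tid in tx_ids) {
      seg <- seg_rows[seg_rows$Parent == tid, , drop = FALSE]
      if (!nrow(seg)) next
      cds <- as.matrix(seg[seg$type == "CDS", c("start", "end"), drop = FALSE])
      ex <- as.matrix(seg[seg$type == "exon", c("start", "end"), drop = FALSE])
      if (!nrow(ex)) ex <- cds
      strand <- seg$strand[1]
      contig <- seg$seqid[1]
      if (!is.null(seqs)) {
        lim <- nchar(seqs[contig])
        if (is.na(lim) || any(rbind(cds, ex) < 1) ||
            any(rbind(cds, ex) > lim)) {
          message("gene ", gene, ": segment outside contig bounds; skipped")
          next
        }
      }
      coding <- if (nrow(cds)) sum(cds[, 2] - cds[, 1] + 1) else 0L
      cand <- list(gene_id = gene, transcript_id = tid, contig = contig,
                   strand = strand, coding_length = coding,
                   n_cds = nrow(cds),
                   cds = order_tx(cds, strand), exons = order_tx(ex, strand))
      # longest coding length wins; ties fall to the lexicographically
      # smaller transcript_id (tx_ids is sorted, so strict > keeps it)
      if (is.null(best) || cand$coding_length > best$coding_length) {
        best <- cand
      }
    }
    if (!is.null(best)) out[[gene]] <- best
  }
  if (!length(out)) stop_param("no usable transcripts in annotation")
  res <- data.frame(
    gene_id = vapply(out, `[[`, character(1), "gene_id"),
    transcript_id = vapply(out, `[[`, character(1), "transcript_id"),
    contig = vapply(out, `[[`, character(1), "contig"),
    strand = vapply(out, `[[`, character(1), "strand"),
    coding_length = vapply(out, function(x) as.numeric(x$coding_length),
                           numeric(1)),
    n_cds = vapply(out, function(x) as.integer(x$n_cds), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$cds <- I(lapply(out, `[[`, "cds"))
  res$exons <- I(lapply(out, `[[`, "exons"))
  class(res) <- c("transcriptome", class(res))
  res
}

segment_introns <- function(seg, strand, contig_seq, flank) {
  # seg in transcription order; returns per-intron genomic interval, sense
  # sequence and flanking exonic sequence
  n <- nrow(seg) - 1
  if (n < 1) return(NULL)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (strand == "+") {
      s <- seg[i, 2] + 1L
      e <- seg[i + 1, 1] - 1L
    } else {
      s <- seg[i + 1, 2] + 1L
      e <- seg[i, 1] - 1L
    }
    if (e < s) {
      warning("zero-length gap between segments; malformed annotation",
              call. = FALSE)
      out[[i]] <- NULL
      next
    }
    seq <- substr(contig_seq, s, e)
    if (strand == "+") {
      up <- substr(contig_seq, max(1, s - flank), s - 1)
      down <- substr(contig_seq, e + 1, min(nchar(contig_seq), e + flank))
    } else {
      seq <- revcomp(seq)
      up <- revcomp(substr(contig_seq, e + 1,
                           min(nchar(contig_seq), e + flank)))
      down <- revcomp(substr(contig_seq, max(1, s - flank), s - 1))
    }
    out[[i]] <- list(start = s, end = e, seq = seq, up = up, down = down,
                     index = i)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Extract introns from a longest-isoform transcriptome
#'
#' Introns are the gaps between consecutive CDS segments in transcription
#' order; gaps between exon segments not explained by CDS gaps (UTR introns)
#' are additionally reported with `defining_feature = "exon"`. Minus-strand
#' sequences and termini are reverse-complemented to sense orientation.
#' Introns shorter than `min_length` are discarded. Phase is the cumulative
#' preceding coding length mod 3 and relative position is the cumulative
#' preceding coding length over the transcript's coding length; both are `NA`
#' for exon-defined introns, which are excluded from phase and comparative
#' analyses downstream.
#'
#' @param transcripts a `transcriptome` from [build_transcriptome()].
#' @param genome genome (path, named character vector or `toy_genome`).
#' @param min_length minimum intron length retained (default 30 nt).
#' @param include_exon_defined also report UTR/exon-defined introns.
#' @param flank exonic flank length stored for boundary correction.
#' @param species species label recorded on every record.
#' @return data frame of `IntronRecord`s: identifiers, 1-based inclusive
#'   genomic interval, strand, length, phase, relative_position, sense-strand
#'   terminal dinucleotides, `defining_feature`, `n_flag` (termini contain N),
#'   sense `sequence` and exonic flanks.
#' @export
extract_introns <- function(transcripts, genome, min_length = 30,
                            include_exon_defined = TRUE, flank = 10,
                            species = "species1") {
  stopifnot(inherits(transcripts, "transcriptome"))
  seqs <- normalize_genome(genome)
  recs <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    contig_seq <- seqs[[tx$contig]]
    if (is.null(contig_seq)) {
      message("contig ", tx$contig, " absent from genome; gene ",
              tx$gene_id, " skipped")
      next
    }
    cds <- tx$cds[[1]]
    strand <- tx$strand
    cds_introns <- segment_introns(cds, strand, contig_seq, flank)
    cum <- if (nrow(cds)) cumsum(cds[, 2] - cds[, 1] + 1) else numeric(0)
    cds_keys <- character(0)
    for (it in cds_introns) {
      L <- cum[it$index]
      cds_keys <- c(cds_keys, paste(it$start, it$end))
      recs[[length(recs) + 1]] <- data.frame(
        species = species, gene_id = tx$gene_id,
        transcript_id = tx$transcript_id, contig = tx$contig,
        intron_id = sprintf("%s.i%d", tx$transcript_id, it$index),
        start = it$start, end = it$end, strand = strand,
        length = nchar(it$seq), phase = L %% 3,
        relative_position = if (tx$coding_length > 0) {
          L / tx$coding_length
        } else NA_real_,
        five_prime = substr(it$seq, 1, 2),
        three_prime = substr(it$seq, nchar(it$seq) - 1, nchar(it$seq)),
        defining_feature = "CDS",
        sequence = it$seq, upstream_flank = it$up, downstream_flank = it$down,
        stringsAsFactors = FALSE
      )
    }
    if (include_exon_defined) {
      ex_introns <- segment_introns(tx$exons[[1]], strand, contig_seq, flank)
      for (it in ex_introns) {
        if (paste(it$start, it$end) %in% cds_keys) next
        recs[[length(recs) + 1]] <- data.frame(
          species = species, gene_id = tx$gene_id,
          transcript_id = tx$transcript_id, contig = tx$contig,
          intron_id = sprintf("%s.u%d", tx$transcript_id, it$index),
          start = it$start, end = it$end, strand = strand,
          length = nchar(it$seq), phase = NA_real_,
          relative_position = NA_real_,
          five_prime = substr(it$seq, 1, 2),
          three_prime = substr(it$seq, nchar(it$seq) - 1, nchar(it$seq)),
          defining_feature = "exon",
          sequence = it$seq, upstream_flank = it$up,
          downstream_flank = it$down,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(recs)) {
    return(empty_intron_records())
  }
  out <- do.call(rbind, recs)
  out$n_flag <- grepl("N", paste0(out$five_prime, out$three_prime))
  out[out$length >= min_length, , drop = FALSE]
}

empty_intron_records <- function() {
  data.frame(species = character(0), gene_id = character(0),
             transcript_id = character(0), contig = character(0),
             intron_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), length = integer(0), phase = numeric(0),
             relative_position = numeric(0), five_prime = character(0),
             three_prime = character(0), defining_feature = character(0),
             sequence = character(0), upstream_flank = character(0),
             downstream_flank = character(0), n_flag = logical(0),
             stringsAsFactors = FALSE)
}

#' Tally intron termini and flag a wrong-strand annotation signature
#'
#' CT-AC termini are the exact reverse complement of GT-AG; an elevated
#' CT-AC fraction indicates genes annotated on the wrong strand.
#'
#' @param introns intron records from [extract_introns()].
#' @param warn_fraction CT-AC fraction above which the warning flag is set.
#' @return list with `tally` (termini pair counts), `ct_ac_fraction` and
#'   `warning` (logical).
#' @export
strand_sanity_report <- function(introns, warn_fraction = 0.01) {
  if (!nrow(introns)) stop_param("no introns supplied")
  pair <- paste(introns$five_prime, introns$three_prime, sep = "-")
  tab <- as.data.frame(table(pair), stringsAsFactors = FALSE)
  names(tab) <- c("termini", "n")
  tab <- tab[order(-tab$n), , drop = FALSE]
  frac <- sum(pair == "CT-AC") / length(pair)
  list(tally = tab, ct_ac_fraction = frac, warning = frac > warn_fraction)
}

#' Genic intron density (introns per kbp of coding sequence)
#'
#' @param transcripts a `transcriptome`.
#' @param introns intron records; only CDS-defined introns are counted.
#' @return data frame: `gene_id`, `n_introns`, `coding_length`, `density`
#'   (introns x 1000 / coding length).
#' @export
genic_intron_density <- function(transcripts, introns) {
  stopifnot(inherits(transcripts, "transcriptome"))
  cds_introns <- introns[introns$defining_feature == "CDS", , drop = FALSE]
  counts <- table(cds_introns$gene_id)
  n <- as.integer(counts[transcripts$gene_id])
  n[is.na(n)] <- 0L
  if (any(transcripts$coding_length <= 0)) {
    stop_param("genic_intron_density requires coding_length > 0 for all genes")
  }
  data.frame(gene_id = transcripts$gene_id, n_introns = n,
             coding_length = transcripts$coding_length,
             density = n * 1000 / transcripts$coding_length,
             row.names = NULL, stringsAsFactors = FALSE)
}
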