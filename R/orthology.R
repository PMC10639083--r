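# Reciprocal-best-hit (RBH) orthology. Pairwise protein similarity searches
# are consumed as tabular input (12-column BLAST/DIAMOND outfmt-6 or any
# table with query/subject/evalue/bitscore columns); the graph of RBH edges
# is built with igraph and ortholog groups are its maximal cliques with
# exactly one gene per requested species.

OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column BLAST/DIAMOND tabular hit file
#'
#' @param path outfmt-6 file (no header).
#' @return data frame with standard outfmt-6 column names.
#' @export
read_hit_table <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12) stop_param("expected 12 outfmt-6 columns")
  names(x) <- OUTFMT6
  x
}

#' Per-gene best hits per target species
#'
#' Filters hits at the E-value cutoff, then keeps each query's
#' maximum-bitscore subject in every target species; bitscore ties fall to
#' the lexicographically smaller subject id.
#'
#' @param hits data frame with columns `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (as from [read_hit_table()]).
#' @param species_of named character vector mapping gene id to species
#'   label.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @return data frame: `qseqid`, `qspecies`, `sspecies`, `sseqid`,
#'   `bitscore`.
#' @export
best_hits <- function(hits, species_of, evalue_max = 1e-10) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) {
    message("no hits pass the E-value cutoff")
    return(data.frame(qseqid = character(0), qspecies = character(0),
                      sspecies = character(0), sseqid = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  hits$qspecies <- unname(species_of[hits$qseqid])
  hits$sspecies <- unname(species_of[hits$sseqid])
  if (any(is.na(hits$qspecies)) || any(is.na(hits$sspecies))) {
    stop_param("species_of lacks entries for some hit gene ids")
  }
  hits <- hits[hits$qspecies != hits$sspecies, , drop = FALSE]
  # max bitscore, tie-break by subject id: sort so the winner comes first
  hits <- hits[order(hits$qseqid, hits$sspecies, -hits$bitscore,
                     hits$sseqid), , drop = FALSE]
  keep <- !duplicated(hits[, c("qseqid", "sspecies")])
  hits[keep, c("qseqid", "qspecies", "sspecies", "sseqid", "bitscore"),
       drop = FALSE]
}

#' Build the reciprocal-best-hit graph
#'
#' An undirected edge joins two genes of different species iff each is the
#' other's best hit in that species. An optional `subset` restricts the
#' graph to a gene list (e.g. minor intron-containing genes) before the
#' search, which reproduces the corresponding subgraph of a full run.
#'
#' @param best best-hit table from [best_hits()].
#' @param subset optional character vector of gene ids to keep.
#' @return igraph object with vertex attributes `name` (gene id) and
#'   `species`.
#' @export
rbh_graph <- function(best, subset = NULL) {
  if (!is.null(subset)) {
    best <- best[best$qseqid %in% subset & best$sseqid %in% subset, ,
                 drop = FALSE]
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  fwd <- paste(best$qseqid, best$sseqid)
  rev <- paste(best$sseqid, best$qseqid)
  mutual <- best[fwd %in% rev & best$qseqid < best$sseqid, , drop = FALSE]
  species <- unique(data.frame(
    gene = c(best$qseqid, best$sseqid),
    species = c(best$qspecies, best$sspecies),
    stringsAsFactors = FALSE
  ))
  g <- igraph::graph_from_data_frame(
    mutual[, c("qseqid", "sseqid", "bitscore")],
    directed = FALSE, vertices = species
  )
  g
}

#' Ortholog cliques spanning a species set
#'
#' Enumerates maximal cliques of the RBH graph restricted to `species_set`
#' and keeps those containing exactly one gene from every species in the
#' set (all members mutually RBH).
#'
#' @param graph igraph from [rbh_graph()].
#' @param species_set species labels the cliques must span.
#' @return list of character vectors of gene ids, each named by species;
#'   sorted for order-independence.
#' @export
ortholog_cliques <- function(graph, species_set) {
  vs <- igraph::V(graph)
  sp <- igraph::vertex_attr(graph, "species")
  if (!all(species_set %in% sp)) {
    stop_param("species_set contains species absent from the graph")
  }
  sub <- igraph::induced_subgraph(graph, vs[sp %in% species_set])
  k <- length(species_set)
  cl <- igraph::max_cliques(sub, min = k, max = k)
  sub_sp <- igraph::vertex_attr(sub, "species")
  names(sub_sp) <- igraph::vertex_attr(sub, "name")
  out <- list()
  for (c in cl) {
    genes <- igraph::vertex_attr(sub, "name", c)
    spc <- sub_sp[genes]
    if (length(unique(spc)) == k) {
      genes <- genes[order(spc)]
      out[[length(out) + 1]] <- setNames(genes, sort(spc))
    }
  }
  # deterministic order regardless of node insertion order
  if (length(out)) out <- out[order(vapply(out, paste, character(1),
                                           collapse = "|"))]
  out
}

#' Toy protein similarity scorer for synthetic end-to-end tests
#'
#' Scores every cross-species protein pair by shared k-mer count (a stand-in
#' for an external similarity search; used only on synthetic fixtures).
#' Pairs sharing at least `min_shared` k-mers are reported with
#' bitscore = shared k-mer count and a nominal E-value of 1e-30.
#'
#' @param proteins named character vector of protein sequences.
#' @param species_of named character vector mapping protein id to species.
#' @param k k-mer length.
#' @param min_shared minimum shared k-mers to report a hit.
#' @return outfmt-6-style data frame (`qseqid`, `sseqid`, `evalue`,
#'   `bitscore`, other columns zero-filled).
#' @export
toy_protein_hits <- function(proteins, species_of, k = 6, min_shared = 1) {
  kmers <- lapply(proteins, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  ids <- names(proteins)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      if (species_of[ids[i]] == species_of[ids[j]]) next
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      if (shared >= min_shared) {
        rows[[length(rows) + 1]] <- data.frame(
          qseqid = ids[i], sseqid = ids[j], pident = 0, length = 0,
          mismatch = 0, gapopen = 0, qstart = 0, qend = 0, sstart = 0,
          send = 0, evalue = 1e-30, bitscore = shared,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(setNames(data.frame(matrix(ncol = 12, nrow = 0)), OUTFMT6))
  }
  do.call(rbind, rows)
}
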