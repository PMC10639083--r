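# Intron-position conservation within protein alignments of ortholog
# cliques. An intron is mapped to the alignment column of the residue whose
# codon it interrupts (phase 1/2) or precedes the junction (phase 0); two
# introns occupy the same site iff they share both column and phase. Sites
# must pass a local ungapped alignment-quality filter before entering any
# conservation or reconstruction tally.

intron_residue <- function(preceding_cds, phase) {
  # residue index carrying the intron: after residue i for phase 0,
  # inside codon i for phase 1/2
  ifelse(phase == 0, preceding_cds / 3, floor(preceding_cds / 3) + 1)
}

ungapped_to_column <- function(aligned_seq) {
  chars <- strsplit(aligned_seq, "")[[1]]
  which(chars != "-")
}

#' Map intron positions into a protein alignment
#'
#' @param alignment named character vector of aligned protein sequences
#'   (gap character "-"), one per clique member.
#' @param introns data frame with one row per intron: `member` (matching
#'   alignment names), `intron_id`, `phase` (0/1/2) and `preceding_cds`
#'   (coding nucleotides upstream of the intron in that member's transcript).
#' @return data frame of aligned intron sites, one row per (site, member)
#'   including absent members: `site_id`, `column`, `phase`, `member`,
#'   `intron_id` (NA when absent), `present`.
#' @export
map_intron_sites <- function(alignment, introns) {
  stopifnot(!is.null(names(alignment)))
  if (!all(introns$member %in% names(alignment))) {
    stop_param("introns$member must match alignment names")
  }
  colmap <- lapply(alignment, ungapped_to_column)
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    m <- introns$member[i]
    res <- intron_residue(introns$preceding_cds[i], introns$phase[i])
    if (res != round(res) || res < 1 || res > length(colmap[[m]])) {
      message("intron ", introns$intron_id[i],
              " maps outside its aligned sequence; skipped")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      column = colmap[[m]][res], phase = introns$phase[i], member = m,
      intron_id = introns$intron_id[i], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(0), column = integer(0),
                      phase = integer(0), member = character(0),
                      intron_id = character(0), present = logical(0),
                      stringsAsFactors = FALSE))
  }
  hit <- do.call(rbind, rows)
  hit$site_id <- sprintf("c%d.p%d", hit$column, hit$phase)
  sites <- unique(hit[, c("site_id", "column", "phase")])
  grid <- merge(sites, data.frame(member = names(alignment),
                                  stringsAsFactors = FALSE))
  out <- merge(grid, hit[, c("site_id", "member", "intron_id")],
               by = c("site_id", "member"), all.x = TRUE)
  out$present <- !is.na(out$intron_id)
  out <- out[order(out$column, out$phase, out$member),
             c("site_id", "column", "phase", "member", "intron_id",
               "present")]
  rownames(out) <- NULL
  out
}

#' Local ungapped alignment-quality filter at one site
#'
#' For every pair of alignment members, the `window` columns upstream of the
#' site (including the site's residue column) and the `window` columns
#' downstream must each be gap-free in both sequences and show at least
#' `min_identity` identical residues; each side is evaluated separately.
#' Sites too close to an alignment edge fail.
#'
#' @param alignment named character vector of aligned sequences.
#' @param column alignment column of the site.
#' @param window columns evaluated on each side (default 10).
#' @param min_identity minimum per-side identity (default 0.4).
#' @return logical: does the site pass for all member pairs.
#' @export
local_quality_filter <- function(alignment, column, window = 10,
                                 min_identity = 0.4) {
  stopifnot(window >= 1)
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  up <- (column - window + 1):column
  down <- (column + 1):(column + window)
  if (min(up) < 1 || max(down) > ncol(mat)) return(FALSE)
  n <- nrow(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (side in list(up, down)) {
        a <- mat[i, side]
        b <- mat[j, side]
        if (any(a == "-") || any(b == "-")) return(FALSE)
        if (mean(a == b) < min_identity) return(FALSE)
      }
    }
  }
  TRUE
}

#' Apply the local quality filter to a site table
#'
#' @param sites output of [map_intron_sites()].
#' @param alignment the alignment the sites were mapped in.
#' @inheritParams local_quality_filter
#' @return `sites` with a logical `quality_pass` column.
#' @export
filter_sites <- function(sites, alignment, window = 10, min_identity = 0.4) {
  u <- unique(sites[, c("site_id", "column")])
  pass <- vapply(u$column, function(cc) {
    local_quality_filter(alignment, cc, window, min_identity)
  }, logical(1))
  sites$quality_pass <- pass[match(sites$site_id, u$site_id)]
  sites
}

#' Call per-site conservation states from minor scores
#'
#' Assigns each present intron a type from its minor score: minor if
#' score > `minor_min`, major if score <= `conversion_major_max`, borderline
#' otherwise. Sites containing a borderline intron are flagged
#' (`conversion_ok = FALSE`) and excluded from conversion tallies; with
#' `conversion_major_max` equal to `minor_min` no score is borderline.
#'
#' @param sites site table from [map_intron_sites()] (optionally carrying
#'   `quality_pass`, in which case failing sites are dropped).
#' @param scores data frame with `intron_id` and `minor_score` for every
#'   present intron.
#' @param minor_min percentile above which an intron is minor (default 90).
#' @param conversion_major_max percentile at or below which an intron counts
#'   as major in conversion analyses (default 60).
#' @return object of class `site_states`: data frame with one row per site
#'   (`site_id`, `column`, `phase`, `conversion_ok`) and one state column
#'   `state.<member>` per member (minor/major/borderline/absent).
#' @export
call_states <- function(sites, scores, minor_min = 90,
                        conversion_major_max = 60) {
  if ("quality_pass" %in% names(sites)) {
    sites <- sites[sites$quality_pass, , drop = FALSE]
  }
  sc <- setNames(scores$minor_score, scores$intron_id)
  if (any(sites$present & !(sites$intron_id %in% names(sc)))) {
    stop_param("every present intron needs a minor_score")
  }
  state <- rep("absent", nrow(sites))
  s <- sc[sites$intron_id]
  state[sites$present] <- ifelse(
    s[sites$present] > minor_min, "minor",
    ifelse(s[sites$present] <= conversion_major_max, "major", "borderline")
  )
  sites$state <- state
  wide <- stats::reshape(
    sites[, c("site_id", "column", "phase", "member", "state")],
    idvar = c("site_id", "column", "phase"), timevar = "member",
    direction = "wide"
  )
  state_cols <- grep("^state\\.", names(wide), value = TRUE)
  wide$conversion_ok <- !apply(wide[, state_cols, drop = FALSE] ==
                                 "borderline", 1, any)
  rownames(wide) <- NULL
  class(wide) <- c("site_states", class(wide))
  wide
}

state_col <- function(states, member) {
  col <- paste0("state.", member)
  if (!col %in% names(states)) stop_param("no member ", member)
  states[[col]]
}

#' Pairwise conservation counts for one intron type
#'
#' `N_cons` counts sites where both members carry the type; `N_var` counts
#' introns (of both members) at sites where the partner does not carry the
#' type. The conservation percentage 100 * N_cons / (N_cons + N_var) and the
#' per-row-species shared fractions (shared sites over that species' introns
#' of the type in the alignments) are included.
#'
#' @param states a `site_states` object.
#' @param a,b member names.
#' @param type "minor" or "major".
#' @return list with `N_cons`, `N_var`, `percentage`, `shared_fraction_a`,
#'   `shared_fraction_b`.
#' @export
pair_counts <- function(states, a, b, type = c("minor", "major")) {
  type <- match.arg(type)
  sa <- state_col(states, a)
  sb <- state_col(states, b)
  n_cons <- sum(sa == type & sb == type)
  n_var <- sum(sa == type & sb != type) + sum(sb == type & sa != type)
  list(
    N_cons = n_cons, N_var = n_var,
    percentage = conservation_percentage(n_cons, n_var),
    shared_fraction_a = n_cons / sum(sa == type),
    shared_fraction_b = n_cons / sum(sb == type)
  )
}

#' Three-way presence counts from called site states
#'
#' @param states a `site_states` object.
#' @param alpha,beta,gamma member names (gamma the outgroup).
#' @inheritParams pair_counts
#' @return a `triple_counts` object as from [triple_presence_counts()].
#' @export
triple_counts_from_states <- function(states, alpha, beta, gamma,
                                      type = c("minor", "major")) {
  type <- match.arg(type)
  a <- state_col(states, alpha) == type
  b <- state_col(states, beta) == type
  g <- state_col(states, gamma) == type
  structure(
    list(N_ab = sum(a & b), N_ag = sum(a & g), N_bg = sum(b & g),
         N_abg = sum(a & b & g), type = type),
    class = "triple_counts"
  )
}

#' Build cross-alignment intron clusters and tally termini
#'
#' Introns sharing a site in any alignment are linked; clusters are the
#' connected components of this graph. Terminal dinucleotides of the focal
#' type are tallied only from clusters with at least `min_same_type` members
#' of that type, guarding against isolated false-positive calls.
#'
#' @param links data frame with one row per (alignment, site, intron):
#'   columns `alignment_id`, `site_id`, `species`, `intron_id`, `type`
#'   (minor/major), `termini` (e.g. "AT-AC").
#' @param focal_type type whose termini are tallied.
#' @param min_same_type minimum focal-type members per cluster (default 2).
#' @return list with `clusters` (list of member data frames), `kept` (logical
#'   per cluster) and `termini` (frequency table over kept focal members).
#' @export
build_intron_clusters <- function(links, focal_type = c("minor", "major"),
                                  min_same_type = 2) {
  focal_type <- match.arg(focal_type)
  links$node <- paste(links$species, links$intron_id, sep = ":")
  edges <- list()
  for (key in split(seq_len(nrow(links)),
                    paste(links$alignment_id, links$site_id))) {
    nodes <- unique(links$node[key])
    if (length(nodes) > 1) {
      pr <- t(combn(nodes, 2))
      edges[[length(edges) + 1]] <- pr
    }
  }
  verts <- unique(links$node)
  g <- igraph::graph_from_data_frame(
    if (length(edges)) as.data.frame(do.call(rbind, edges)) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = verts
  )
  comp <- igraph::components(g)$membership
  meta <- unique(links[, c("node", "species", "intron_id", "type",
                           "termini")])
  meta$cluster <- comp[meta$node]
  clusters <- split(meta, meta$cluster)
  kept <- vapply(clusters, function(cl) {
    sum(cl$type == focal_type) >= min_same_type
  }, logical(1))
  focal <- do.call(rbind, clusters[kept])
  termini <- if (!is.null(focal)) {
    table(focal$termini[focal$type == focal_type])
  } else table(character(0))
  list(clusters = clusters, kept = kept, termini = termini)
}
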