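make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qseqid = r[[1]], sseqid = r[[2]],
               evalue = as.numeric(r[[3]]), bitscore = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("best hits take the top bitscore with deterministic tie-break", {
  sp <- c(a1 = "A", b1 = "B", b2 = "B")
  hits <- make_hits(list("a1", "b1", 1e-20, 100),
                    list("a1", "b2", 1e-20, 90))
  bh <- best_hits(hits, sp)
  expect_identical(bh$sseqid, "b1")
  # equal bitscores: lexicographically smaller subject
  tie <- make_hits(list("a1", "b2", 1e-20, 100),
                   list("a1", "b1", 1e-20, 100))
  expect_identical(best_hits(tie, sp)$sseqid, "b1")
  # E-value cutoff is exclusive above 1e-10
  weak <- make_hits(list("a1", "b1", 1e-9, 100))
  expect_equal(nrow(suppressMessages(best_hits(weak, sp))), 0)
  expect_equal(nrow(best_hits(weak, sp, evalue_max = 1e-8)), 1)
})

test_that("RBH edges require mutual best hits", {
  sp <- c(a1 = "A", b1 = "B", b2 = "B", c1 = "C")
  hits <- make_hits(list("a1", "b1", 1e-20, 100),
                    list("b1", "a1", 1e-20, 100),
                    list("b2", "a1", 1e-20, 50),
                    list("c1", "b1", 1e-20, 80),
                    list("b1", "c1", 1e-20, 40)) # b1's best C hit is c1
  g <- rbh_graph(best_hits(hits, sp))
  edges <- igraph::as_edgelist(g)
  expect_true(any(apply(edges, 1, function(e) setequal(e, c("a1", "b1")))))
  expect_true(any(apply(edges, 1, function(e) setequal(e, c("b1", "c1")))))
  # one-directional best is not an edge
  hits2 <- make_hits(list("a1", "b1", 1e-20, 100),
                     list("b1", "c1", 1e-20, 100),
                     list("c1", "b1", 1e-20, 100))
  g2 <- rbh_graph(best_hits(hits2, sp))
  expect_equal(igraph::ecount(g2), 1) # only b1-c1
})

test_that("triangles yield cliques, paths do not", {
  sp <- c(a1 = "A", b1 = "B", c1 = "C")
  tri <- make_hits(list("a1", "b1", 1e-20, 10), list("b1", "a1", 1e-20, 10),
                   list("a1", "c1", 1e-20, 10), list("c1", "a1", 1e-20, 10),
                   list("b1", "c1", 1e-20, 10), list("c1", "b1", 1e-20, 10))
  g <- rbh_graph(best_hits(tri, sp))
  cl <- ortholog_cliques(g, c("A", "B", "C"))
  expect_length(cl, 1)
  expect_identical(sort(unname(cl[[1]])), c("a1", "b1", "c1"))

  path <- make_hits(list("a1", "b1", 1e-20, 10), list("b1", "a1", 1e-20, 10),
                    list("b1", "c1", 1e-20, 10), list("c1", "b1", 1e-20, 10))
  g2 <- rbh_graph(best_hits(path, sp))
  expect_length(ortholog_cliques(g2, c("A", "B", "C")), 0)
})

brute_force_cliques <- function(g, species_set) {
  # exhaustive enumeration over all vertex subsets (n <= 12)
  sp <- igraph::vertex_attr(g, "species")
  nm <- igraph::vertex_attr(g, "name")
  keep <- sp %in% species_set
  nm <- nm[keep]
  sp <- sp[keep]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[nm, nm, drop = FALSE]
  n <- length(nm)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  cliques <- Filter(is_clique,
                    lapply(seq_len(2^n) - 1,
                           function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0)))
  maximal <- Filter(function(cl) {
    !any(vapply(setdiff(seq_len(n), cl),
                function(v) is_clique(c(cl, v)), logical(1)))
  }, cliques)
  out <- Filter(function(cl) {
    length(cl) == length(species_set) &&
      setequal(sp[cl], species_set) && !anyDuplicated(sp[cl])
  }, maximal)
  sort(vapply(out, function(cl) paste(sort(nm[cl]), collapse = "|"),
              character(1)))
}

test_that("clique enumeration matches exhaustive search on random graphs", {
  set.seed(77)
  for (rep in 1:12) {
    n <- 10
    species <- sample(c("A", "B", "C"), n, replace = TRUE)
    names(species) <- sprintf("%s_g%02d", tolower(species), seq_len(n))
    pairs <- t(combn(names(species), 2))
    cross <- species[pairs[, 1]] != species[pairs[, 2]]
    chosen <- cross & runif(nrow(pairs)) < 0.45
    g <- igraph::graph_from_data_frame(
      as.data.frame(pairs[chosen, , drop = FALSE]),
      directed = FALSE,
      vertices = data.frame(name = names(species), species = species)
    )
    got <- sort(vapply(ortholog_cliques(g, c("A", "B", "C")),
                       function(cl) paste(sort(unname(cl)), collapse = "|"),
                       character(1)))
    expect_identical(got, brute_force_cliques(g, c("A", "B", "C")))
  }
})

test_that("clique output is independent of node insertion order", {
  sp <- c(a1 = "A", b1 = "B", c1 = "C", a2 = "A")
  hits <- make_hits(list("a1", "b1", 1e-20, 10), list("b1", "a1", 1e-20, 10),
                    list("a1", "c1", 1e-20, 10), list("c1", "a1", 1e-20, 10),
                    list("b1", "c1", 1e-20, 10), list("c1", "b1", 1e-20, 10),
                    list("a2", "b1", 1e-20, 5), list("b1", "a2", 1e-20, 5))
  bh <- best_hits(hits, sp)
  g1 <- rbh_graph(bh)
  g2 <- rbh_graph(bh[rev(seq_len(nrow(bh))), ])
  f <- function(g) vapply(ortholog_cliques(g, c("A", "B", "C")),
                          paste, character(1), collapse = "|")
  expect_identical(f(g1), f(g2))
})

test_that("subset-restricted search equals the subgraph of a full run", {
  set.seed(5)
  species <- setNames(rep(c("A", "B", "C"), each = 4),
                      paste0(rep(c("a", "b", "c"), each = 4), 1:4))
  base <- paste0(c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
                 c("APILSRVGDGTQDNLSGAEKAVQVKVKALPDAQ"))
  proteins <- vapply(names(species), function(id) {
    fam <- as.integer(sub("^[abc]", "", id))
    s <- substr(paste0(base, base), fam * 7 + 1, fam * 7 + 40)
    s
  }, character(1))
  hits <- toy_protein_hits(proteins, species, k = 6)
  bh <- best_hits(hits, species, evalue_max = 1e-5)
  full <- rbh_graph(bh)
  migs <- names(species)[sub("^[abc]", "", names(species)) %in% c("1", "2")]
  restricted <- rbh_graph(bh, subset = migs)
  sub_full <- igraph::induced_subgraph(
    full, igraph::V(full)[igraph::V(full)$name %in% migs])
  e1 <- apply(igraph::as_edgelist(restricted), 1,
              function(e) paste(sort(e), collapse = "-"))
  e2 <- apply(igraph::as_edgelist(sub_full), 1,
              function(e) paste(sort(e), collapse = "-"))
  expect_setequal(e1, e2)
})
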