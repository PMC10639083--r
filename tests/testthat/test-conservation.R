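ident_aln <- function(seq, members) setNames(rep(seq, length(members)),
                                             members)

test_that("introns at the same column and phase share a site", {
  aln <- ident_aln(strrep("MSTPQRLKWWAAPPLLQQRR", 2), c("sp1", "sp2"))
  ints <- data.frame(member = c("sp1", "sp2"), intron_id = c("i1", "i2"),
                     phase = c(1, 1), preceding_cds = c(31, 31))
  sites <- map_intron_sites(aln, ints)
  expect_equal(length(unique(sites$site_id)), 1)
  expect_true(all(sites$present))
  expect_equal(unique(sites$column), 11) # codon 11 holds nt 31..33
})

test_that("same column but different phase are distinct sites", {
  aln <- ident_aln(strrep("MSTPQRLKWWAAPPLLQQRR", 2), c("sp1", "sp2"))
  ints <- data.frame(member = c("sp1", "sp2"), intron_id = c("i1", "i2"),
                     phase = c(1, 2), preceding_cds = c(31, 32))
  sites <- map_intron_sites(aln, ints)
  expect_equal(length(unique(sites$site_id)), 2)
  expect_equal(sum(!sites$present), 2) # each site has one absent partner
})

test_that("sites match through gapped alignment columns", {
  s <- "MSTPQRLKWWAAPPLLQQRRSSTT"
  aln <- c(sp1 = paste0("XYZ", s), sp2 = paste0("---", s))
  ints <- data.frame(member = c("sp1", "sp2"), intron_id = c("i1", "i2"),
                     phase = c(0, 0),
                     preceding_cds = c((3 + 10) * 3, 10 * 3))
  sites <- map_intron_sites(aln, ints)
  expect_equal(length(unique(sites$site_id)), 1)
  expect_true(all(sites$present))
})

test_that("introns mapping beyond the sequence are skipped with a message", {
  aln <- c(sp1 = "MSTP")
  ints <- data.frame(member = "sp1", intron_id = "i1", phase = 0,
                     preceding_cds = 60)
  expect_message(sites <- map_intron_sites(aln, ints), "skipped")
  expect_equal(nrow(sites), 0)
})

test_that("local quality filter enforces identity and gap-freedom per side", {
  good <- ident_aln(strrep("ACDEFGHIKLMNPQRSTVWY", 2), c("a", "b"))
  expect_true(local_quality_filter(good, 20))
  # 3/10 identity upstream fails the 40% requirement
  a <- strrep("ACDEFGHIKLMNPQRSTVWY", 2)
  b <- paste0("ACDWWWWWWWWWNPQRSTVWY",
              substr(a, 22, 40)) # positions 4-12 mismatched
  expect_false(local_quality_filter(c(a = a, b = substr(b, 1, 40)), 13))
  # a gap inside the window fails even with perfect identity elsewhere
  g <- c(a = a, b = paste0(substr(a, 1, 15), "-", substr(a, 17, 40)))
  expect_false(local_quality_filter(g, 20))
  # too close to the alignment edge fails
  expect_false(local_quality_filter(good, 5))
})

test_that("state calls follow the score thresholds", {
  aln <- ident_aln(strrep("MSTPQRLKWW", 3), c("a", "b"))
  mk <- function(score_a, score_b) {
    ints <- data.frame(member = c("a", "b"), intron_id = c("ia", "ib"),
                       phase = c(0, 0), preceding_cds = c(30, 30))
    sites <- map_intron_sites(aln, ints)
    call_states(sites, data.frame(intron_id = c("ia", "ib"),
                                  minor_score = c(score_a, score_b)))
  }
  both_minor <- mk(95, 95)
  expect_identical(both_minor$state.a, "minor")
  expect_identical(both_minor$state.b, "minor")
  expect_true(both_minor$conversion_ok)

  conv <- mk(95, 40)
  expect_identical(conv$state.b, "major")
  expect_true(conv$conversion_ok)

  borderline <- mk(95, 75)
  expect_identical(borderline$state.b, "borderline")
  expect_false(borderline$conversion_ok)
})

test_that("pairwise and triple counts have Table-1 semantics", {
  states <- data.frame(
    site_id = paste0("s", 1:6), column = 1:6, phase = 0,
    state.a = c("minor", "minor", "minor", "major", "absent", "major"),
    state.b = c("minor", "major", "absent", "major", "minor", "major"),
    stringsAsFactors = FALSE
  )
  class(states) <- c("site_states", class(states))
  pc <- pair_counts(states, "a", "b", "minor")
  expect_equal(pc$N_cons, 1)
  expect_equal(pc$N_var, 3) # a-minors at s2,s3 + b-minor at s5
  expect_equal(pc$percentage, 25)
  expect_equal(pc$shared_fraction_a, 1 / 3)
  pcM <- pair_counts(states, "a", "b", "major")
  expect_equal(pcM$N_cons, 2)
  expect_equal(pcM$N_var, 1)
})

test_that("identity alignments recover every planted three-taxon state", {
  sim <- simulate_three_taxon(25, 60, retention = 0.8,
                              conversion_prob = 0.2, seed = 31)
  st <- sim$states
  n <- nrow(st)
  aln <- ident_aln(strrep("ACDEFGHIKLMNPQRSTVWY", ceiling(n / 20) + 2),
                   c("alpha", "beta", "gamma"))
  rows <- list()
  scores <- list()
  for (lin in c("alpha", "beta", "gamma")) {
    state <- st[[paste0("state_", lin)]]
    present <- which(state != "absent")
    ids <- paste0(lin, ".", st$intron_id[present])
    rows[[lin]] <- data.frame(member = lin, intron_id = ids, phase = 0,
                              preceding_cds = (present + 10) * 3,
                              stringsAsFactors = FALSE)
    scores[[lin]] <- data.frame(
      intron_id = ids,
      minor_score = ifelse(state[present] == "minor", 97, 20),
      stringsAsFactors = FALSE
    )
  }
  sites <- map_intron_sites(aln, do.call(rbind, rows))
  sites <- filter_sites(sites, aln)
  expect_true(all(sites$quality_pass))
  called <- call_states(sites, do.call(rbind, scores))
  for (type in c("minor", "major")) {
    got <- triple_counts_from_states(called, "alpha", "beta", "gamma", type)
    want <- triple_presence_counts(sim, type)
    expect_identical(got$N_ab, want$N_ab)
    expect_identical(got$N_ag, want$N_ag)
    expect_identical(got$N_bg, want$N_bg)
    expect_identical(got$N_abg, want$N_abg)
  }
})

test_that("intron clusters link alignments through a hub species", {
  links <- data.frame(
    alignment_id = c("aln1", "aln1", "aln2", "aln2"),
    site_id = c("s1", "s1", "s1", "s1"),
    species = c("human", "fly", "human", "tick"),
    intron_id = c("h1", "f1", "h1", "t1"),
    type = "minor", termini = "AT-AC", stringsAsFactors = FALSE
  )
  cl <- build_intron_clusters(links, "minor")
  expect_length(cl$clusters, 1)
  expect_equal(nrow(cl$clusters[[1]]), 3)
  expect_true(cl$kept[[1]])
})

test_that("termini are tallied only from clusters with enough focal members", {
  links <- data.frame(
    alignment_id = "aln1", site_id = "s1",
    species = c("a", "b", "c"), intron_id = c("i1", "i2", "i3"),
    type = c("minor", "major", "major"),
    termini = c("AT-AC", "GT-AG", "GT-AG"), stringsAsFactors = FALSE
  )
  cl <- build_intron_clusters(links, "minor", min_same_type = 2)
  expect_false(any(cl$kept))
  expect_equal(sum(cl$termini), 0)
})

test_that("planted non-canonical termini frequencies are recovered", {
  set.seed(11)
  n_clusters <- 150
  rows <- list()
  for (i in seq_len(n_clusters)) {
    term <- ifelse(runif(3) < 0.05, "AT-AA", "AT-AC")
    rows[[i]] <- data.frame(
      alignment_id = paste0("aln", i), site_id = "s1",
      species = c("x", "y", "z"),
      intron_id = paste0("c", i, "_", 1:3),
      type = "minor", termini = term, stringsAsFactors = FALSE
    )
  }
  cl <- build_intron_clusters(do.call(rbind, rows), "minor")
  freq <- cl$termini / sum(cl$termini)
  p_hat <- unname(freq["AT-AA"])
  se <- sqrt(0.05 * 0.95 / (3 * n_clusters))
  expect_lt(abs(p_hat - 0.05), 4 * se)
})
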