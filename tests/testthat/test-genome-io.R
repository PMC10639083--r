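test_that("extracted introns round-trip the planted truth exactly", {
  toy <- toy_mixed()
  fix <- toy_mixed_introns()
  ints <- fix$introns
  tr <- toy$truth
  expect_equal(nrow(ints), nrow(tr))
  m <- merge(tr, ints, by = c("gene_id", "start", "end"))
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(m$five_prime.x == m$five_prime.y))
  expect_true(all(m$three_prime.x == m$three_prime.y))
  expect_true(all(m$phase.x == m$phase.y))
  expect_true(all(m$strand.x == m$strand.y))
  expect_equal(m$relative_position.x, m$relative_position.y,
               tolerance = 1e-12)
})

test_that("annotation coordinates survive the GFF3 writer/reader round trip", {
  dir <- withr::local_tempdir()
  toy <- generate_toy_genome(6, 2, minor_fraction = 0.5, seed = 13,
                             out_dir = dir)
  tx_mem <- build_transcriptome(toy, toy)
  tx_file <- build_transcriptome(toy$files[["annotation"]],
                                 toy$files[["genome"]])
  ord <- match(tx_mem$gene_id, tx_file$gene_id)
  expect_false(anyNA(ord))
  expect_equal(tx_mem$coding_length, tx_file$coding_length[ord])
  for (i in seq_len(nrow(tx_mem))) {
    expect_equal(unname(tx_mem$cds[[i]]),
                 unname(tx_file$cds[[ord[i]]]))
  }
  ints_mem <- extract_introns(tx_mem, toy)
  ints_file <- extract_introns(tx_file, toy$files[["genome"]])
  expect_equal(ints_mem$start[order(ints_mem$intron_id)],
               ints_file$start[order(ints_file$intron_id)])
})

test_that("longest coding isoform is selected with lexicographic tie-break", {
  ann <- data.frame(
    seqid = "c1", source = ".", type = c("gene", "mRNA", "CDS", "mRNA",
                                         "CDS", "CDS"),
    start = c(1, 1, 1, 1, 1, 401), end = c(600, 300, 300, 600, 300, 550),
    score = ".", strand = "+", phase = ".",
    attributes = c("ID=g1", "ID=tB;Parent=g1", "Parent=tB",
                   "ID=tA;Parent=g1", "Parent=tA", "Parent=tA"),
    stringsAsFactors = FALSE
  )
  tx <- build_transcriptome(ann)
  expect_identical(tx$transcript_id, "tA") # 450 nt beats 300 nt
  expect_equal(tx$coding_length, 450)

  # equal lengths: lexicographically smaller id wins
  ann2 <- ann
  ann2 <- ann2[ann2$attributes != "Parent=tA" | ann2$start != 401, ]
  tx2 <- build_transcriptome(ann2)
  expect_identical(tx2$transcript_id, "tA")
})

test_that("intron definitions force termini, phase and relative position", {
  genome <- c(c1 = paste0(strrep("A", 100),
                          "GT", strrep("C", 96), "AG",
                          strrep("A", 100)))
  ann <- data.frame(
    seqid = "c1", source = ".", type = c("gene", "mRNA", "CDS", "CDS"),
    start = c(1, 1, 1, 201), end = c(300, 300, 100, 300),
    score = ".", strand = "+", phase = ".",
    attributes = c("ID=g1", "ID=t1;Parent=g1", "Parent=t1", "Parent=t1"),
    stringsAsFactors = FALSE
  )
  tx <- build_transcriptome(ann, genome)
  ints <- extract_introns(tx, genome)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$start, 101)
  expect_equal(ints$end, 200)
  expect_equal(ints$length, 100)
  expect_identical(ints$five_prime, "GT")
  expect_identical(ints$three_prime, "AG")
  expect_equal(ints$phase, 100 %% 3)
  expect_equal(ints$relative_position, 0.5)
})

test_that("minus-strand genes give identical termini and phase", {
  plus_genome <- c(c1 = paste0(strrep("A", 100), "GT", strrep("C", 96),
                               "AG", strrep("A", 100)))
  minus_genome <- c(c1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_genome[["c1"]])
  )))
  ann <- data.frame(
    seqid = "c1", source = ".", type = c("gene", "mRNA", "CDS", "CDS"),
    start = c(1, 1, 1, 201), end = c(300, 300, 100, 300),
    score = ".", strand = "-", phase = ".",
    attributes = c("ID=g1", "ID=t1;Parent=g1", "Parent=t1", "Parent=t1"),
    stringsAsFactors = FALSE
  )
  tx <- build_transcriptome(ann, minus_genome)
  ints <- extract_introns(tx, minus_genome)
  expect_identical(ints$five_prime, "GT")
  expect_identical(ints$three_prime, "AG")
  expect_equal(ints$phase, 1)
  expect_equal(ints$relative_position, 0.5)
})

test_that("introns shorter than the minimum length are discarded", {
  genome <- c(c1 = paste0(strrep("A", 60), "GT", strrep("C", 21), "AG",
                          strrep("A", 60)))
  ann <- data.frame(
    seqid = "c1", source = ".", type = c("gene", "mRNA", "CDS", "CDS"),
    start = c(1, 1, 1, 86), end = c(145, 145, 60, 145),
    score = ".", strand = "+", phase = ".",
    attributes = c("ID=g1", "ID=t1;Parent=g1", "Parent=t1", "Parent=t1"),
    stringsAsFactors = FALSE
  )
  tx <- build_transcriptome(ann, genome)
  expect_equal(nrow(extract_introns(tx, genome)), 0) # 25 nt gap
  expect_equal(nrow(extract_introns(tx, genome, min_length = 20)), 1)
})

test_that("phase and relative position are internally consistent", {
  fix <- toy_mixed_introns()
  ints <- fix$introns[fix$introns$defining_feature == "CDS", ]
  tx <- fix$tx
  for (tid in unique(ints$transcript_id)) {
    sub <- ints[ints$transcript_id == tid, ]
    sub <- sub[order(as.integer(sub("^.*\\.i", "", sub$intron_id))), ]
    # independent recomputation of cumulative CDS from the transcript model
    cds <- tx$cds[[which(tx$transcript_id == tid)]]
    cum <- cumsum(cds[, 2] - cds[, 1] + 1)
    expect_equal(sub$phase, unname(head(cum, -1) %% 3))
    expect_true(all(diff(sub$relative_position) >= 0))
  }
})

test_that("strand sanity report flags wrong-strand annotations", {
  toy <- generate_toy_genome(40, 3, minor_fraction = 0, seed = 21)
  tx <- build_transcriptome(toy, toy)
  rep0 <- strand_sanity_report(extract_introns(tx, toy))
  expect_equal(rep0$ct_ac_fraction, 0)
  expect_false(rep0$warning)

  bad <- generate_toy_genome(40, 3, minor_fraction = 0, seed = 21,
                             wrong_strand_fraction = 0.2)
  txb <- build_transcriptome(bad, bad)
  repb <- strand_sanity_report(extract_introns(txb, bad))
  expect_gt(repb$ct_ac_fraction, 0.01)
  expect_true(repb$warning)

  expect_error(strand_sanity_report(extract_introns(tx, toy)[0, ]),
               "no introns")
})

test_that("genic intron density is introns per kbp of coding sequence", {
  genome <- c(c1 = paste0(strrep("A", 500), "GT", strrep("C", 96), "AG",
                          strrep("T", 1200)))
  ann <- data.frame(
    seqid = "c1", source = ".", type = c("gene", "mRNA", "CDS", "CDS"),
    start = c(1, 1, 1, 601), end = c(1600, 1600, 500, 1600),
    score = ".", strand = "+", phase = ".",
    attributes = c("ID=g1", "ID=t1;Parent=g1", "Parent=t1", "Parent=t1"),
    stringsAsFactors = FALSE
  )
  tx <- build_transcriptome(ann, genome)
  ints <- extract_introns(tx, genome)
  dens <- genic_intron_density(tx, ints)
  expect_equal(dens$density, 1 * 1000 / 1500)
  dens0 <- genic_intron_density(tx, ints[0, ])
  expect_equal(dens0$density, 0)
})
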