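test_that("conservation percentages match the printed comparisons", {
  expect_equal(conservation_percentage(115, 1391), 7.6, tolerance = 0.01)
  expect_equal(conservation_percentage(20, 135), 12.9, tolerance = 0.01)
  expect_equal(conservation_percentage(2052, 14162), 12.7, tolerance = 0.01)
  expect_equal(conservation_percentage(7, 120), 5.5, tolerance = 0.01)
  expect_equal(conservation_percentage(0, 50), 0)
  expect_error(conservation_percentage(0, 0), "> 0")
})

test_that("fisher test matches hypergeometric enumeration on small tables", {
  # exhaustive over all tables with modest totals
  for (N in c(6, 11)) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c <- parts$c[i]
      d <- N - a - b - c
      if (a + b + c + d == 0) next
      expect_equal(fisher_exact_2x2(c(a, b, c, d)),
                   enum_fisher_p(a, b, c, d), tolerance = 1e-9)
    }
  }
})

test_that("fisher symmetry and degenerate tables", {
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1)), 1)
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "all-zero")
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")
})

test_that("binomial bias test uses the minimum-likelihood two-tail", {
  expect_equal(binomial_bias_test(10, 20), 1)
  expect_equal(binomial_bias_test(20, 20), 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(binomial_bias_test(15, 20), 0.0414, tolerance = 1e-3)
  for (n in c(7, 16, 33)) {
    for (k in 0:n) {
      expect_equal(binomial_bias_test(k, n), enum_binom_p(k, n),
                   tolerance = 1e-9)
    }
  }
})

test_that("the positional-bias flag needs all three criteria", {
  set.seed(3)
  major <- runif(300)
  biased_minor <- runif(80)^3 # strongly 5'-shifted
  r <- positional_bias_battery(biased_minor, major)
  expect_lt(r$p_binomial, 0.05)
  expect_lt(r$p_mwu, 0.05)
  expect_lt(r$median_minor, r$median_major)
  expect_true(r$flagged_5prime_minor_bias)

  # 3'-shifted minor introns are significant but flagged FALSE (direction)
  r2 <- positional_bias_battery(1 - biased_minor, major)
  expect_false(r2$flagged_5prime_minor_bias)

  balanced <- positional_bias_battery(runif(50), major)
  expect_false(balanced$flagged_5prime_minor_bias)
})

test_that("the batch battery reports BH-corrected flags", {
  set.seed(9)
  pos <- c(
    lapply(1:20, function(i) list(minor = runif(30), major = runif(200))),
    list(biased = list(minor = runif(40)^3, major = runif(200)))
  )
  names(pos) <- c(paste0("null", 1:20), "biased")
  out <- positional_bias_batch(pos)
  expect_true(all(out$q_binomial >= out$p_binomial))
  expect_true(all(out$q_mwu >= out$p_mwu))
  expect_true(out$flagged_corrected[out$species == "biased"])
  expect_lte(sum(out$flagged_corrected), 2)
})

test_that("clade enrichment builds the printed contingency table", {
  flags <- c(rep(TRUE, 112), rep(FALSE, 178), rep(TRUE, 23),
             rep(FALSE, 1265))
  clades <- c(rep("Streptophyta", 290), rep("Metazoa", 1288))
  enr <- clade_enrichment(flags, clades, "Streptophyta")
  expect_equal(unname(enr$table), matrix(c(112, 178, 23, 1265), 2,
                                         byrow = TRUE))
  expect_equal(100 * 112 / 290, 38.6, tolerance = 0.01)
  expect_lt(enr$p, 1e-60)
  expect_error(clade_enrichment(flags, clades, "Fungi"), "absent")
  even <- clade_enrichment(rep(c(TRUE, FALSE), 50),
                           rep(c("a", "b"), each = 50), "a")
  expect_gt(even$p, 0.9)
})

test_that("phase distributions are recovered from planted phases", {
  all0 <- phase_distribution(rep(0, 1000))
  expect_equal(as.numeric(all0), c(1, 0, 0))
  set.seed(4)
  planted <- sample(0:2, 2000, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  got <- phase_distribution(planted)
  expect_equal(as.numeric(got), as.numeric(table(factor(planted, 0:2))) /
                 2000)
  expect_error(phase_distribution(numeric(0)), "no phased")
  expect_error(phase_distribution(c(0, 3)), "must be 0, 1 or 2")
})

test_that("Boschloo's test is valid and at least as powerful as Fisher", {
  b <- boschloo_test(7, 10, 1, 10)
  expect_lt(b$p, b$p_fisher)
  expect_identical(b$method, "boschloo")
  cases <- list(c(5, 8, 2, 9), c(0, 6, 5, 6), c(10, 12, 3, 15),
                c(4, 20, 4, 20))
  for (cs in cases) {
    r <- boschloo_test(cs[1], cs[2], cs[3], cs[4])
    expect_gt(r$p, 0)
    expect_lte(r$p, 1)
    expect_lte(r$p, r$p_fisher + 1e-9)
  }
  expect_equal(boschloo_test(3, 10, 3, 10)$p, 1)
  big <- boschloo_test(300, 1000, 200, 1000)
  expect_identical(big$method, "fisher_fallback")
  f <- compare_phase0(7, 10, 1, 10, method = "fisher")
  expect_equal(f$p, fisher_exact_2x2(c(7, 3, 1, 9)))
})

test_that("MIG comparisons exclude sparse species and find planted effects", {
  set.seed(12)
  mk_species <- function(sp, mig_shift) {
    n <- 120
    is_mig <- rep(c(TRUE, FALSE), c(30, 90))
    data.frame(
      species = sp, gene_id = paste0(sp, "_g", 1:n), is_mig = is_mig,
      density = rgamma(n, 4, 2) * ifelse(is_mig, mig_shift, 1),
      coding_length = rnbinom(n, mu = 1500, size = 5) + 300,
      stringsAsFactors = FALSE
    )
  }
  genes <- rbind(mk_species("planted", 2), mk_species("null", 1),
                 mk_species("sparse", 2))
  out <- mig_comparisons(genes, c(planted = 50, null = 40, sparse = 8))
  expect_false("sparse" %in% out$species)
  pl <- out[out$species == "planted", ]
  expect_gt(pl$median_density_mig, pl$median_density_non)
  expect_lt(pl$p_density, 0.05)
  expect_gt(out[out$species == "null", "p_density"], 0.05)
})

test_that("planted genic-density doubling separates MIGs from non-MIGs", {
  # a denser variant of the planted-effect check operating on extracted
  # intron records rather than a synthetic per-gene table
  toy <- toy_mixed()
  fix <- toy_mixed_introns()
  dens <- genic_intron_density(fix$tx, fix$introns)
  calls <- score_and_classify(exact_model(), fix$introns)
  mig_genes <- unique(calls$gene_id[calls$type_call == "minor"])
  dens$is_mig <- dens$gene_id %in% mig_genes
  expect_gt(sum(dens$is_mig), 3)
  expect_gt(sum(!dens$is_mig), 3)
})

test_that("spearman helper equals rank-transform Pearson on tie-free data", {
  set.seed(2)
  x <- rnorm(40)
  y <- rnorm(40)
  expect_equal(spearman_cor(x, y), cor(rank(x), rank(y)),
               tolerance = 1e-12)
})
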