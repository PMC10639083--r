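# Shared fixtures: scoring models and toy genomes are cached per test run
# since training and generation are the slow steps.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

exact_model <- function() {
  cached("exact_model", {
    refs <- synthetic_reference_sets(n = 30, noise = 0, seed = 7)
    train_scorer(refs$minor, refs$major)
  })
}

noisy_model <- function() {
  cached("noisy_model", {
    refs <- synthetic_reference_sets(n = 40, noise = 0.1, seed = 7)
    train_scorer(refs$minor, refs$major)
  })
}

toy_mixed <- function() {
  cached("toy_mixed", generate_toy_genome(30, 3, minor_fraction = 0.3,
                                          seed = 42))
}

toy_mixed_introns <- function() {
  cached("toy_mixed_introns", {
    toy <- toy_mixed()
    tx <- build_transcriptome(toy, toy)
    list(tx = tx, introns = extract_introns(tx, toy))
  })
}

truth_type_for <- function(toy, introns) {
  toy$truth$true_type[match(paste(introns$gene_id, introns$start),
                            paste(toy$truth$gene_id, toy$truth$start))]
}

# independent minimum-likelihood two-sided p-value oracles
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(k, r1, r2, c1)
  sum(pr[pr <= dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

enum_binom_p <- function(k, n, p = 0.5) {
  pr <- dbinom(0:n, n, p)
  sum(pr[pr <= dbinom(k, n, p) * (1 + 1e-7)])
}
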