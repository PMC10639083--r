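#!/usr/bin/env Rscript
# Regenerates the packaged synthetic reference intron sets
# (inst/extdata/synthetic_{minor,major}_reference.fa) from the
# consensus-derived motif models at noise 0.1, fixed seed.

devtools::load_all(".", quiet = TRUE)

refs <- synthetic_reference_sets(n = 100, noise = 0.1, seed = 20240901)
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
for (cls in names(refs)) {
  seqs <- Biostrings::DNAStringSet(refs[[cls]])
  names(seqs) <- sprintf("synthetic_%s_ref_%03d", cls, seq_along(seqs))
  Biostrings::writeXStringSet(
    seqs, sprintf("inst/extdata/synthetic_%s_reference.fa", cls)
  )
}
cat("written\n")
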