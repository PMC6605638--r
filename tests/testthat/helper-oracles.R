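# Independent reference implementations and small fixture builders used
# across the suite. The oracles are deliberately naive (textbook dynamic
# programming in plain R) and share nothing with the package's C++ paths.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

random_aa <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")
random_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")

# textbook affine-gap Smith-Waterman score (gap of length L costs
# go + (L-1)*ge, both negative), returning only the best score
sw_oracle <- function(q, s, submat = blosum62, go = -11, ge = -1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive greedy clustering computed from a precomputed identity matrix:
# the definition of cluster_identity applied literally, by a separate path
cluster_oracle <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  idm <- matrix(0, length(seqs), length(seqs))
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global")
    idm[i, j] <- Biostrings::pid(pa, type = "PID1") / 100
  }
  reps <- integer(0)
  for (k in seq_along(seqs)) {
    if (!any(idm[k, reps] >= threshold)) reps <- c(reps, k)
  }
  seqs[reps]
}

# uniform reverse translation (independent of the package's generator)
rev_translate_oracle <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  codons_of <- split(names(gc), gc)
  paste(vapply(strsplit(prot, "")[[1]], function(a) {
    cs <- codons_of[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

# an intronless coding locus embedded in random flanks; returns the segment,
# the protein, and the 1-based CDS interval within the segment
plant_orf <- function(prot_len = 60, flank = 200) {
  prot <- random_aa(prot_len)
  cds <- rev_translate_oracle(prot)
  seg <- paste0(random_nt(flank), cds, random_nt(flank))
  list(segment = seg, protein = prot, cds = cds,
       start = flank + 1L, end = flank + nchar(cds))
}

# small shared synthetic dataset (built once per test run)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fam <- make_family(rng_seed = 7)
      ds <- plant_genome(fam, n_annotated = 6, n_hidden = 4,
                         n_tandem_pairs = 2, n_pseudo = 2,
                         contig_length = 120000, rng_seed = 11)
      cache <<- list(fam = fam, ds = ds)
    }
    cache
  }
})
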