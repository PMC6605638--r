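test_that("FASTA round-trip preserves ids and residues exactly", {
  set.seed(101)
  seqs <- structure(vapply(1:8, function(k) random_aa(sample(20:80, 1)),
                           character(1)),
                    names = sprintf("prot%02d", 1:8))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f, "protein")
  expect_identical(unname(c(back)), unname(c(seqs)))
  expect_identical(names(back), names(seqs))

  dna <- c(contigA = random_nt(500), contigB = random_nt(300))
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(dna, f2)
  expect_identical(c(read_fasta(f2, "dna")), dna)
})

test_that("FASTA reader enforces its contract", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f, "dna"), "duplicate.*a")

  f2 <- withr::local_tempfile(fileext = ".fa")
  cat("", file = f2)
  expect_error(read_fasta(f2, "dna"), "empty")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU"), f3)
  expect_error(read_fasta(f3, "dna"), "position 4")

  # seed-alignment dialect: gaps retained only when allowed
  f4 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "MK-LV"), f4)
  expect_error(read_fasta(f4, "protein"), "position 3")
  gapped <- read_fasta(f4, "protein", allow_gaps = TRUE)
  expect_identical(unname(c(gapped)), "MK-LV")

  # lowercase residues are uppercased
  f5 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt"), f5)
  expect_identical(unname(c(read_fasta(f5, "dna"))), "ACGT")
})

test_that("GFF3 reader keeps gene/mRNA/CDS rows with 1-based coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "# a comment",
    "chr1\t.\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t100\t900\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\t.\tCDS\t100\t400\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\t.\tCDS\t500\t900\t.\t+\t0\tID=c2;Parent=m1",
    "chr1\t.\texon\t100\t400\t.\t+\t.\tID=e1;Parent=m1",
    "chr2\t.\tgene\t5\t50\t.\t-\t.\tID=g2"), f)
  feats <- read_gff3(f)
  expect_equal(nrow(feats), 5) # exon row dropped
  g1 <- feats[feats$feature_id == "g1", ]
  expect_equal(g1$start, 100)
  expect_equal(g1$end, 900)
  expect_equal(g1$strand, "+")
  expect_equal(g1$kind, "gene")
  expect_true(all(feats$start >= 1 & feats$start <= feats$end))
})

test_that("GFF3 reader rejects bad coordinates and synthesizes missing ids", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t0\t900\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3(f))

  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t10\t90\t.\t+\t.\tNote=x"), f2)
  expect_warning(feats <- read_gff3(f2), "synthesized")
  expect_true(nzchar(feats$feature_id[1]))
})

test_that("manifest reader resolves paths and validates existence", {
  dir <- withr::local_tempdir()
  for (f in c("g.fa", "a.gff3", "p.fa")) writeLines(">x\nACGT", file.path(dir, f))
  mf <- file.path(dir, "manifest.tab")
  writeLines("g.fa\ta.gff3\tp.fa", mf)
  m <- read_manifest(mf)
  expect_equal(nrow(m), 1)
  expect_true(all(file.exists(unlist(m))))

  writeLines("g.fa\tmissing.gff3\tp.fa", mf)
  expect_error(read_manifest(mf), "missing.gff3")
})

test_that("write_outputs emits all stepwise files, even for an empty catalog", {
  empty <- structure(list(
    genome_id = "g", prior_proteins = character(0),
    prior_domains = data.frame(), refpep = character(0),
    combined_seeds = character(0), windows = list(), trimmed_windows = list(),
    new_coding = list(),
    new_pseudogenes = data.frame(window_id = character(0), seqid = character(0),
                                 target_start = integer(0), target_end = integer(0),
                                 strand = character(0), class = character(0),
                                 low_confidence = logical(0)),
    rejected = data.frame(window_id = character(0), seqid = character(0),
                          target_start = integer(0), target_end = integer(0),
                          strand = character(0), reason = character(0))),
    class = "ctt_catalog")
  out <- withr::local_tempdir()
  files <- write_outputs(empty, out)
  expect_true(all(file.exists(files)))
  expect_gte(length(files), 10)
})

test_that("pseudogene catalog entries stay out of the peptide FASTA", {
  sd <- small_dataset()
  cat_g <- structure(list(
    genome_id = "g", prior_proteins = sd$ds$proteome[1],
    prior_domains = data.frame(), refpep = sd$ds$proteome[1],
    combined_seeds = degap(sd$fam$seed_set$members), windows = list(),
    trimmed_windows = list(),
    new_coding = list(list(model_id = "g_new_1", seqid = "chr1",
                           genomic_start = 100L, genomic_end = 400L,
                           genomic_exons = matrix(c(100L, 400L), ncol = 2),
                           strand = "+", score = 99,
                           gdna = random_nt(301), transcript = random_nt(300),
                           protein = random_aa(100), cds = random_nt(300))),
    new_pseudogenes = data.frame(window_id = "w9", seqid = "chr1",
                                 target_start = 5000L, target_end = 5200L,
                                 strand = "+", class = "pseudogene_stop",
                                 low_confidence = FALSE),
    rejected = data.frame(window_id = character(0), seqid = character(0),
                          target_start = integer(0), target_end = integer(0),
                          strand = character(0), reason = character(0))),
    class = "ctt_catalog")
  out <- withr::local_tempdir()
  write_outputs(cat_g, out)
  peps <- readLines(file.path(out, "step5_new_peptides.faa"))
  expect_true(any(grepl("g_new_1", peps)))
  expect_false(any(grepl("w9", peps)))
  ps <- read.delim(file.path(out, "step5_pseudogenes.tsv"))
  expect_equal(ps$window_id, "w9")
  expect_equal(ps$class, "pseudogene_stop")
})
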