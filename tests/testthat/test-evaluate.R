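fake_catalog <- function(coding_spans = list(), pseudo_spans = list(),
                         n_prior = 3) {
  new_coding <- lapply(seq_along(coding_spans), function(k) {
    s <- coding_spans[[k]]
    list(model_id = paste0("nc", k), seqid = "chr1",
         genomic_start = s[1], genomic_end = s[2], strand = "+",
         protein = paste(rep("A", 10), collapse = ""))
  })
  np <- if (length(pseudo_spans)) do.call(rbind, lapply(
    seq_along(pseudo_spans), function(k) {
      s <- pseudo_spans[[k]]
      data.frame(window_id = paste0("ps", k), seqid = "chr1",
                 target_start = s[1], target_end = s[2], strand = "+",
                 class = "pseudogene_stop", low_confidence = FALSE)
    })) else data.frame(window_id = character(0), seqid = character(0),
                        target_start = integer(0), target_end = integer(0),
                        strand = character(0), class = character(0),
                        low_confidence = logical(0))
  structure(list(genome_id = "g",
                 prior_proteins = structure(rep("AAAA", n_prior),
                                            names = paste0("p", seq_len(n_prior))),
                 new_coding = new_coding, new_pseudogenes = np),
            class = "ctt_catalog")
}

test_that("hold-out rediscovery uses the midpoint-in-span rule", {
  cat_g <- fake_catalog(coding_spans = list(c(1000L, 2000L)),
                        pseudo_spans = list(c(5100L, 5300L)))
  heldout <- data.frame(seqid = "chr1",
                        start = c(900L, 5000L, 8000L),
                        end = c(2100L, 5500L, 9000L),
                        feature_id = c("h1", "h2", "h3"))
  r <- holdout_rediscovery(cat_g, heldout)
  expect_equal(r$coding, 1)
  expect_equal(r$pseudo, 1)
  expect_identical(r$detail$rediscovered_as, c("coding", "pseudo", NA))

  # adjacent but outside: midpoint 1500 not inside [1600, 2100]
  outside <- data.frame(seqid = "chr1", start = 1600L, end = 2100L,
                        feature_id = "h1")
  expect_equal(holdout_rediscovery(cat_g, outside)$coding, 0)

  overlapping <- data.frame(seqid = "chr1", start = c(100L, 150L),
                            end = c(200L, 250L), feature_id = c("a", "b"))
  expect_error(holdout_rediscovery(cat_g, overlapping), "ambiguous")
})

test_that("rediscovery counts match the planted truth on a synthetic run", {
  sd <- small_dataset()
  seed_dir <- withr::local_tempdir()
  write_fasta(sd$ds$genome, file.path(seed_dir, "genome.fa"))
  # reuse the in-memory dataset through the step functions
  cfg <- pipeline_config(); sch <- scoring_scheme()
  prior <- step1_prior_members(sd$ds$proteome, sd$fam$seed_set, cfg, sch)
  refs <- step2_reference_sets(prior, sd$fam$seed_set, cfg)
  wins <- step3_putative_loci(refs$combined_seeds, sd$ds$genome,
                              sd$ds$features, cfg, sch)
  hidden <- sd$ds$truth[grepl("hidden", sd$ds$truth$class), ]
  expect_equal(length(wins), nrow(hidden)) # one anchor window per hidden locus
})

test_that("specificity metrics follow the identity and coverage definitions", {
  p <- "MKVLWAALLVTFLAGCQAKVEQAVETEP"
  r <- specificity_metrics(c(a = p), c(b = p),
                           data.frame(predicted_id = "a", original_id = "b"))
  expect_equal(unname(r$pident["mean"]), 100)
  expect_equal(unname(r$integrity["mean"]), 100)

  # prediction covering only the first half: integrity ~ 50
  half <- substr(p, 1, 14)
  r2 <- specificity_metrics(c(a = half), c(b = p),
                            data.frame(predicted_id = "a", original_id = "b"))
  expect_equal(unname(r2$integrity["mean"]), 50)

  # three constructed pairs against hand-computed stats
  p1 <- "AAAAAAAAAA"; p2 <- "CCCCCCCCCC"
  pairs <- data.frame(predicted_id = c("x", "y", "z"),
                      original_id = c("o1", "o2", "o3"))
  r3 <- specificity_metrics(c(x = p1, y = substr(p1, 1, 5), z = p2),
                            c(o1 = p1, o2 = p1, o3 = p2), pairs)
  expect_equal(unname(r3$pident["mean"]), 100)
  expect_equal(unname(r3$integrity["mean"]), mean(c(100, 50, 100)))
  expect_equal(unname(r3$integrity["sd"]), sd(c(100, 50, 100)))
  expect_error(specificity_metrics(c(a = p), c(b = p),
                                   data.frame(predicted_id = character(0),
                                              original_id = character(0))),
               "empty")
})

test_that("the combined accuracy reproduces the published worked examples", {
  expect_equal(accuracy(59, 100, 99.5, 95.1), 78.2)
  expect_equal(accuracy(65, 100, 99.2, 86.9), 79.0)
  expect_equal(accuracy(100, 100, 100, 100), 100)
  expect_equal(accuracy(0, 100, 0, 0), 0)
  # symmetric in its two halves
  expect_equal(accuracy(50, 100, 80, 60), accuracy(70, 100, 50, 50))
})

test_that("new-finding rows reproduce the published percentages", {
  r1 <- new_finding_summary(940, 63, 57)
  expect_equal(r1$total, 1060)
  expect_equal(r1$pct_new, 11.3)
  r2 <- new_finding_summary(213, 80, 133)
  expect_equal(r2$total, 426)
  expect_equal(r2$pct_new, 50.0)
  expect_equal(new_finding_summary(243, 216, 299)$pct_new, 67.9)
  expect_equal(new_finding_summary(10, 0, 0)$pct_new, 0.0)
  expect_error(new_finding_summary(0, 0, 0), "zero")
  # invariant under scaling all counts
  expect_equal(new_finding_summary(940, 63, 57)$pct_new,
               new_finding_summary(9400, 630, 570)$pct_new)
  # catalog method agrees with the explicit counts
  cat_g <- fake_catalog(coding_spans = list(c(1L, 10L)),
                        pseudo_spans = list(c(20L, 30L)), n_prior = 8)
  expect_equal(new_finding_summary(cat_g)$pct_new,
               new_finding_summary(8, 1, 1)$pct_new)
})
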