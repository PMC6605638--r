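sch <- scoring_scheme()

test_that("local alignment matches the textbook DP oracle on random pairs", {
  set.seed(42)
  for (k in 1:30) {
    q <- random_aa(sample(5:40, 1))
    s <- random_aa(sample(5:40, 1))
    h <- local_align(q, s, sch)
    got <- if (is.null(h)) 0 else h$raw_score
    expect_equal(got, sw_oracle(q, s), info = paste("pair", k))
  }
})

test_that("local alignment handles self-hits, no-hits and bad input", {
  h <- local_align("MKV", "MKV", sch)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$q_start, 1)
  expect_equal(h$q_end, 3)
  expect_null(local_align("AAAA", "WWWW", sch)) # disjoint alphabets
  expect_error(local_align("", "MKV", sch), "empty")
  expect_error(local_align("M-K", "MKV", sch), "degapped")
})

test_that("Karlin-Altschul E-values follow the closed form", {
  expect_equal(karlin_evalue(0, 10, 20, sch), sch$ka_k * 10 * 20)
  expect_equal(karlin_evalue(30, 10, 40, sch),
               2 * karlin_evalue(30, 10, 20, sch))
  expect_equal(karlin_evalue(50, 100, 100, sch),
               0.041 * 100 * 100 * exp(-0.267 * 50))
  s <- seq(0, 100, by = 10)
  ev <- karlin_evalue(s, 50, 1000, sch)
  expect_true(all(diff(ev) < 0))
})

test_that("six-frame translation and its coordinate map invert each other", {
  frames <- six_frame_translate("ATGAAA")
  plus1 <- Filter(function(f) f$frame == 1, frames)[[1]]
  expect_equal(plus1$aa, "MK")
  expect_equal(frame_to_genomic(1, 1, 1, 6), c(1, 3))
  expect_equal(frame_to_genomic(1, 2, 2, 6), c(4, 6))
  minus1 <- Filter(function(f) f$frame == -1,
                   six_frame_translate("TTTCAT"))[[1]]
  expect_equal(minus1$aa, "MK")

  set.seed(7)
  for (k in 1:20) {
    dna <- random_nt(sample(30:90, 1))
    for (fr in six_frame_translate(dna)) {
      L <- nchar(fr$aa)
      p1 <- sample(L, 1)
      p2 <- min(L, p1 + sample(0:3, 1))
      g <- frame_to_genomic(fr$frame, p1, p2, nchar(dna))
      sub <- substr(dna, g[1], g[2])
      if (fr$frame < 0)
        sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
      expect_equal(
        suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(sub), no.init.codon = TRUE))),
        substr(fr$aa, p1, p2))
    }
  }
})

test_that("translated genome search recovers a planted ORF at its coordinates", {
  set.seed(11)
  orf <- plant_orf(prot_len = 60, flank = 300)
  genome <- c(chrA = orf$segment)
  hits <- translated_genome_search(c(q = orf$protein), genome, sch, 1e-5)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$s_start[1], orf$start)
  expect_equal(hits$s_end[1], orf$end)
  expect_equal(hits$strand[1], "+")

  # reverse strand: same interval, '-'
  rcgen <- c(chrA = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(orf$segment))))
  rhits <- translated_genome_search(c(q = orf$protein), rcgen, sch, 1e-5)
  n <- nchar(orf$segment)
  expect_equal(rhits$s_start[1], n - orf$end + 1)
  expect_equal(rhits$s_end[1], n - orf$start + 1)
  expect_equal(rhits$strand[1], "-")

  # shuffle control: a scrambled query finds nothing at 1e-5
  shuffled <- paste(sample(strsplit(orf$protein, "")[[1]]), collapse = "")
  expect_equal(nrow(translated_genome_search(
    c(q = shuffled), c(chrA = random_nt(2000)), sch, 1e-5)), 0)
})

test_that("translated genome search is invariant to contig order", {
  set.seed(12)
  orf1 <- plant_orf(50, 150)
  orf2 <- plant_orf(50, 150)
  g12 <- c(c1 = orf1$segment, c2 = orf2$segment)
  g21 <- c(c2 = orf2$segment, c1 = orf1$segment)
  q <- c(q1 = orf1$protein, q2 = orf2$protein)
  h12 <- translated_genome_search(q, g12, sch, 1e-5)
  h21 <- translated_genome_search(q, g21, sch, 1e-5)
  key <- function(h) h[order(h$query_id, h$subject_id, h$s_start),
                       c("query_id", "subject_id", "s_start", "s_end",
                         "raw_score", "strand")]
  expect_equal(key(h12), key(h21), ignore_attr = TRUE)
})

test_that("DNA-vs-protein ranking is correct and deterministically tie-broken", {
  set.seed(13)
  orf <- plant_orf(70, 100)
  db <- c(bbb = orf$protein, aaa = orf$protein, zzz = random_aa(70))
  hits <- dna_vs_protein_search(orf$segment, db, sch, top_k = 3)
  expect_equal(hits$query_id[1:2], c("aaa", "bbb")) # tie -> id ascending
  expect_equal(hits$identity_pct[1], 100)

  # two planted genes: both templates in the top 2
  orf2 <- plant_orf(70, 0)
  seg <- paste0(orf$segment, random_nt(300), orf2$segment)
  db2 <- c(t1 = orf$protein, t2 = orf2$protein)
  top2 <- dna_vs_protein_search(seg, db2, sch, top_k = 2)
  expect_setequal(top2$query_id, c("t1", "t2"))
  expect_equal(nrow(dna_vs_protein_search(orf$segment, character(0), sch)), 0)
})

test_that("profile scores equal the closed-form log-odds on a toy alignment", {
  seed <- seed_set(c(a = "AC", b = "AD", c = "AC"), "toy")
  prof <- build_profile(seed)
  expect_equal(prof$length, 2)
  # column 1: three As -> log2(((3+1)/(3+20))/0.05)
  expect_equal(unname(prof$scores[1, "A"]), log2(((3 + 1) / 23) / (1 / 20)))
  expect_equal(unname(prof$scores[1, "C"]), log2(((0 + 1) / 23) / (1 / 20)))
  expect_equal(unname(prof$scores[2, "C"]), log2(((2 + 1) / 23) / (1 / 20)))
  expect_equal(unname(prof$scores[2, "D"]), log2(((1 + 1) / 23) / (1 / 20)))

  # identical members: the observed residue scores highest in every column
  dom <- random_aa(30)
  prof2 <- build_profile(seed_set(c(x = dom, y = dom, z = dom), "t"))
  obs <- strsplit(dom, "")[[1]]
  top <- colnames(prof2$scores)[apply(prof2$scores, 1, which.max)]
  expect_identical(top, obs)
  # log-odds sign: conserved residue positive, others negative
  expect_true(all(prof2$scores[cbind(1:30, match(obs, colnames(prof2$scores)))] > 0))
  expect_true(all(apply(prof2$scores, 1, function(r) sum(r > 0)) == 1))
})

test_that("domain scan finds planted domains and respects the cutoff", {
  set.seed(21)
  fam <- make_family(n_members = 6, rng_seed = 33)
  prof <- build_profile(fam$seed_set)
  member <- degap(fam$seed_set$members)[[1]]
  prot <- paste0(random_aa(40), member, random_aa(60))
  hit <- scan_domain(prot, prof, sch, 1)
  expect_false(is.null(hit))
  expect_lte(hit$d_start, 41 + 5)
  expect_gte(hit$d_end, 40 + nchar(member) - 5)

  # negative control: reversed protein
  rev <- paste(rev(strsplit(prot, "")[[1]]), collapse = "")
  expect_null(scan_domain(rev, prof, sch, 1))

  # threshold monotonicity on a weak (truncated) domain copy
  weak <- paste0(random_aa(50), substr(member, 1, 14), random_aa(50))
  at1 <- scan_domain(weak, prof, sch, 1)
  if (!is.null(at1)) expect_null(scan_domain(weak, prof, sch, 1e-5))
})

test_that("greedy identity clustering matches the exhaustive oracle", {
  dom <- random_aa(50)
  expect_equal(length(cluster_identity(c(a = dom, b = dom), 0.9)), 1)
  set.seed(31)
  distinct <- structure(vapply(1:5, function(k) random_aa(40), character(1)),
                        names = letters[1:5])
  expect_equal(length(cluster_identity(distinct, 1.0)), 5)
  expect_length(cluster_identity(character(0), 0.9), 0)

  for (rep in 1:3) {
    base <- random_aa(60)
    seqs <- c(
      vapply(1:5, function(k) {
        ch <- strsplit(base, "")[[1]]
        nmut <- sample(0:10, 1)
        if (nmut > 0) {
          at <- sample(60, nmut)
          ch[at] <- sample(AA, nmut, replace = TRUE)
        }
        paste(ch, collapse = "")
      }, character(1)),
      vapply(1:5, function(k) random_aa(sample(40:70, 1)), character(1)))
    names(seqs) <- sprintf("s%02d", 1:10)
    got <- cluster_identity(seqs, 0.9)
    want <- cluster_oracle(seqs, 0.9)
    expect_identical(got, want, info = paste("rep", rep))
  }
})
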