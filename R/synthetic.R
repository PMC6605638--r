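## synthetic: generators for genomes, annotations, proteomes and seed sets
## with planted hidden loci, tandem arrays and pseudogenes - the fixture
## machinery that makes every pipeline stage testable without downloads.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

diverge_protein <- function(prot, rate) {
  chars <- strsplit(prot, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1), character(1))
  }
  paste(chars, collapse = "")
}

# uniform synonymous codon choice, no stop codons (input must be stop-free)
reverse_translate <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  codons_of <- split(names(gc), gc)
  chars <- strsplit(prot, "")[[1]]
  paste(vapply(chars, function(a) {
    cs <- codons_of[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

#' Generate a synthetic protein family
#'
#' An ancestral protein with a fixed architecture (N-flank, signature
#' domain, C-flank) is diversified into family members: domain positions
#' mutate at `divergence_rate`, flank positions at `flank_divergence`
#' (flanks drift faster than the conserved domain). The seed set contains
#' the domain region of each member (equal length, i.e. trivially
#' aligned); full-length member proteins are also returned. Domain length
#' presets of 48, 108 and 267 residues correspond to the F-box, BTB and
#' Pkinase families.
#'
#' @param n_members Number of members (>= 3).
#' @param domain_length Signature domain length in residues.
#' @param divergence_rate Per-position substitution probability in the
#'   domain, in `[0, 0.5]`.
#' @param rng_seed Integer seed; output is deterministic per seed.
#' @param family_id Family identifier.
#' @param flank_divergence Per-position substitution probability in the
#'   flanks.
#' @param n_flank,c_flank Flank lengths in residues.
#' @return A `ctt_family`: `seed_set`, `proteins`, `ancestor`,
#'   `domain_range` (residue interval of the domain) and the parameters.
#' @export
make_family <- function(n_members = 8, domain_length = 48,
                        divergence_rate = 0.15, rng_seed = 1,
                        family_id = "PF00646", flank_divergence = 0.3,
                        n_flank = 20, c_flank = 160) {
  stopifnot(n_members >= 3, divergence_rate >= 0, divergence_rate <= 0.5)
  withr::with_seed(rng_seed, {
    ancestor <- random_protein(n_flank + domain_length + c_flank)
    dr <- c(n_flank + 1, n_flank + domain_length)
    fam <- structure(list(ancestor = ancestor, domain_range = dr,
                          divergence_rate = divergence_rate,
                          flank_divergence = flank_divergence,
                          family_id = family_id), class = "ctt_family")
    members <- vapply(seq_len(n_members), function(k) family_member(fam),
                      character(1))
    names(members) <- sprintf("%s_m%02d", family_id, seq_len(n_members))
    domains <- substr(members, dr[1], dr[2])
    names(domains) <- sprintf("%s_seed%02d", family_id, seq_len(n_members))
    fam$seed_set <- seed_set(domains, family_id)
    fam$proteins <- members
    fam
  })
}

# draw one member protein from the family's ancestor (uses the current RNG)
family_member <- function(fam) {
  dr <- fam$domain_range
  anc <- fam$ancestor
  nfl <- substr(anc, 1, dr[1] - 1)
  dom <- substr(anc, dr[1], dr[2])
  cfl <- substr(anc, dr[2] + 1, nchar(anc))
  paste0(diverge_protein(nfl, fam$flank_divergence),
         diverge_protein(dom, fam$divergence_rate),
         diverge_protein(cfl, fam$flank_divergence))
}

#' Pseudogenize a coding sequence
#'
#' `stop`: one internal codon in the middle third becomes a stop codon
#' (TAA/TAG/TGA). `frameshift`: one base in the middle third is deleted.
#' The position is deterministic per `rng_seed`.
#'
#' @param cds Coding sequence (length >= 60 and a multiple of 3).
#' @param lesion `"stop"` or `"frameshift"`.
#' @param rng_seed Integer seed.
#' @return The mutated coding sequence.
#' @export
mutate_pseudogene <- function(cds, lesion = c("stop", "frameshift"),
                              rng_seed = 1) {
  lesion <- match.arg(lesion)
  n <- nchar(cds)
  if (n < 60 || n %% 3 != 0)
    stop("cds must be >= 60 nt and a multiple of 3")
  withr::with_seed(rng_seed, {
    if (lesion == "stop") {
      n_cod <- n / 3
      lo <- ceiling(n_cod / 3) + 1L
      hi <- floor(2 * n_cod / 3)
      cod <- sample(lo:hi, 1)
      stopc <- sample(c("TAA", "TAG", "TGA"), 1)
      paste0(substr(cds, 1, 3 * (cod - 1)), stopc, substr(cds, 3 * cod + 1, n))
    } else {
      lo <- ceiling(n / 3) + 1L
      hi <- floor(2 * n / 3)
      pos <- sample(lo:hi, 1)
      paste0(substr(cds, 1, pos - 1), substr(cds, pos + 1, n))
    }
  })
}

# build one locus: derive a member, reverse-translate, optionally lesion,
# optionally insert introns after the domain span. Returns gene-orientation
# sequence, exon local coordinates, protein, cds.
build_locus <- function(fam, intron_rate, lesion = NULL) {
  prot <- family_member(fam)
  cds <- reverse_translate(prot)
  if (!is.null(lesion)) {
    cds <- mutate_pseudogene(cds, lesion,
                             rng_seed = sample.int(.Machine$integer.max, 1))
  }
  n <- nchar(cds)
  # candidate junctions: between codons strictly downstream of the domain
  dom_end_nt <- 3 * fam$domain_range[2]
  junctions <- seq(dom_end_nt, n - 3, by = 3)
  exons <- matrix(c(1L, n), ncol = 2)
  seq_out <- cds
  if (runif(1) < intron_rate && length(junctions) >= 2) {
    k <- sample(1:2, 1)
    cuts <- sort(sample(junctions, k))
    pieces <- character(0)
    exons <- matrix(integer(0), ncol = 2)
    cursor_src <- 1L   # position in cds
    cursor_out <- 0L   # position in output
    for (cut in c(cuts, n)) {
      exon_seq <- substr(cds, cursor_src, cut)
      pieces <- c(pieces, exon_seq)
      exons <- rbind(exons, c(cursor_out + 1L, cursor_out + nchar(exon_seq)))
      cursor_out <- cursor_out + nchar(exon_seq)
      cursor_src <- cut + 1L
      if (cut < n) {
        ilen <- sample(60:200, 1)
        intron <- paste0("GT", random_dna(ilen - 4), "AG")
        pieces <- c(pieces, intron)
        cursor_out <- cursor_out + ilen
      }
    }
    seq_out <- paste(pieces, collapse = "")
  }
  list(gene_seq = seq_out, exons = exons, cds = cds,
       protein = if (is.null(lesion)) prot else NA_character_)
}

#' Plant a synthetic genome with hidden family loci
#'
#' Lays out family loci along one contig: annotated members (emitted to the
#' GFF3 feature table and proteome), hidden coding loci (absent from
#' both), tandem pairs placing one annotated and one hidden copy 200-2,000
#' nt apart (the trimming loop's target case), pseudogenized hidden loci
#' (premature stop or 1-nt frameshift), and optional decoy loci from a
#' second, unrelated family. Intergenic space is i.i.d. uniform ACGT.
#' Standalone loci are separated by 3,000-9,000 nt.
#'
#' @param families A `ctt_family`, or a list whose first element is the
#'   target family and optional second element a decoy family.
#' @param n_annotated Annotated member count (must be >= `n_tandem_pairs`).
#' @param n_hidden Hidden coding loci (includes the tandem hidden copies;
#'   must be >= `n_tandem_pairs`).
#' @param n_tandem_pairs Tandem annotated+hidden pairs.
#' @param n_pseudo Hidden pseudogenized loci (alternating stop /
#'   frameshift lesions).
#' @param intron_rate Probability that a locus carries 1-2 introns.
#' @param contig_length Total contig length (error if loci do not fit).
#' @param rng_seed Integer seed; fully deterministic per seed.
#' @param n_decoy Decoy-family hidden loci (requires a decoy family).
#' @param seqid Contig name.
#' @param id_prefix Prefix for locus/feature/protein ids (keeps ids unique
#'   across genomes in a multi-genome manifest).
#' @return A list: `genome` (named character), `features` (GFF3-style
#'   data.frame), `proteome`, `truth` (planted-truth data.frame).
#' @export
plant_genome <- function(families, n_annotated = 30, n_hidden = 20,
                         n_tandem_pairs = 8, n_pseudo = 10,
                         intron_rate = 0.5, contig_length = 500000,
                         rng_seed = 1, n_decoy = 0, seqid = "chr1",
                         id_prefix = "") {
  if (inherits(families, "ctt_family")) families <- list(families)
  fam <- families[[1]]
  decoy_fam <- if (length(families) > 1) families[[2]] else NULL
  stopifnot(n_annotated >= n_tandem_pairs, n_hidden >= n_tandem_pairs,
            n_decoy == 0 || !is.null(decoy_fam))
  withr::with_seed(rng_seed, {
    units <- list()
    add_unit <- function(specs) units[[length(units) + 1]] <<- specs
    for (k in seq_len(n_tandem_pairs)) {
      pair <- list(list(class = "annotated", fam = fam, tandem = k),
                   list(class = "hidden_coding", fam = fam, tandem = k))
      if (runif(1) < 0.5) pair <- rev(pair)
      add_unit(pair)
    }
    for (k in seq_len(n_annotated - n_tandem_pairs))
      add_unit(list(list(class = "annotated", fam = fam, tandem = NA)))
    for (k in seq_len(n_hidden - n_tandem_pairs))
      add_unit(list(list(class = "hidden_coding", fam = fam, tandem = NA)))
    for (k in seq_len(n_pseudo)) {
      cls <- if (k %% 2 == 1) "hidden_pseudo_stop" else "hidden_pseudo_frameshift"
      add_unit(list(list(class = cls, fam = fam, tandem = NA)))
    }
    for (k in seq_len(n_decoy))
      add_unit(list(list(class = "decoy_family", fam = decoy_fam, tandem = NA)))
    units <- units[sample.int(length(units))]

    pieces <- character(0)
    cursor <- 0L
    truth_rows <- list()
    feat_rows <- list()
    prot_list <- character(0)
    idx <- 0L
    emit_locus <- function(spec) {
      idx <<- idx + 1L
      lesion <- switch(spec$class, hidden_pseudo_stop = "stop",
                       hidden_pseudo_frameshift = "frameshift", NULL)
      loc <- build_locus(spec$fam, intron_rate, lesion)
      strand <- sample(c("+", "-"), 1)
      L <- nchar(loc$gene_seq)
      lstart <- cursor + 1L
      lend <- cursor + L
      placed <- if (strand == "+") loc$gene_seq else revcomp(loc$gene_seq)
      pieces <<- c(pieces, placed)
      cursor <<- cursor + L
      lid <- sprintf("%slocus%03d", id_prefix, idx)
      truth_rows[[length(truth_rows) + 1]] <<- data.frame(
        locus_id = lid, seqid = seqid, start = lstart, end = lend,
        strand = strand, class = spec$class,
        family_id = spec$fam$family_id,
        tandem_group = if (is.na(spec$tandem)) NA_integer_ else spec$tandem,
        stringsAsFactors = FALSE)
      if (spec$class == "annotated") {
        gid <- paste0("gene_", lid)
        feat_rows[[length(feat_rows) + 1]] <<- data.frame(
          seqid = seqid, start = lstart, end = lend, strand = strand,
          feature_id = gid, kind = "gene", stringsAsFactors = FALSE)
        feat_rows[[length(feat_rows) + 1]] <<- data.frame(
          seqid = seqid, start = lstart, end = lend, strand = strand,
          feature_id = paste0("mrna_", lid), kind = "mRNA",
          stringsAsFactors = FALSE)
        ex <- loc$exons
        for (e in seq_len(nrow(ex))) {
          g <- if (strand == "+") c(lstart + ex[e, 1] - 1L, lstart + ex[e, 2] - 1L)
               else c(lend - ex[e, 2] + 1L, lend - ex[e, 1] + 1L)
          feat_rows[[length(feat_rows) + 1]] <<- data.frame(
            seqid = seqid, start = g[1], end = g[2], strand = strand,
            feature_id = sprintf("cds_%s.%d", lid, e), kind = "CDS",
            stringsAsFactors = FALSE)
        }
        prot_list[[gid]] <<- loc$protein
      }
    }
    for (u in units) {
      gap <- sample(3000:9000, 1)
      pieces <- c(pieces, random_dna(gap))
      cursor <- cursor + gap
      emit_locus(u[[1]])
      if (length(u) > 1) {
        tgap <- sample(200:2000, 1)
        pieces <- c(pieces, random_dna(tgap))
        cursor <- cursor + tgap
        emit_locus(u[[2]])
      }
    }
    if (cursor > contig_length)
      stop("overcrowded contig: loci need ", cursor, " nt but contig is ",
           contig_length)
    pieces <- c(pieces, random_dna(contig_length - cursor))
    genome <- structure(paste(pieces, collapse = ""), names = seqid)
    attr(genome, "moltype") <- "dna"
    truth <- do.call(rbind, truth_rows)
    truth <- truth[order(truth$start), ]
    rownames(truth) <- NULL
    list(genome = genome, features = do.call(rbind, feat_rows),
         proteome = structure(unlist(prot_list), moltype = "protein"),
         truth = truth)
  })
}

features_to_granges <- function(features) {
  parent <- vapply(seq_len(nrow(features)), function(k) {
    kind <- features$kind[k]
    id <- features$feature_id[k]
    if (kind == "mRNA") sub("^mrna_", "gene_", id)
    else if (kind == "CDS") sub("^cds_(.+)\\.[0-9]+$", "mrna_\\1", id)
    else NA_character_
  }, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  gr$type <- features$kind
  gr$ID <- features$feature_id
  gr$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (is.na(p)) character(0) else p))
  # CDS phase: offset to the next codon start, accumulated in
  # transcription order within each mRNA
  phase <- rep(NA_integer_, nrow(features))
  cds_idx <- which(features$kind == "CDS")
  if (length(cds_idx) > 0) {
    grp <- sub("\\..*$", "", features$feature_id[cds_idx])
    for (g in unique(grp)) {
      rows <- cds_idx[grp == g]
      rows <- rows[order(features$start[rows],
                         decreasing = features$strand[rows[1]] == "-")]
      cum <- 0L
      for (r in rows) {
        phase[r] <- (3L - cum %% 3L) %% 3L
        cum <- cum + features$end[r] - features$start[r] + 1L
      }
    }
  }
  gr$phase <- phase
  gr
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `proteome.fa`, `seeds.fa`,
#' `truth.tsv` and a one-row `manifest.tab`, ready for [run_pipeline()].
#' Presets set the domain length: `fbox` 48, `btb` 108, `pkinase` 267
#' residues.
#'
#' @param preset `"fbox"`, `"btb"` or `"pkinase"`.
#' @param rng_seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param ... Overrides passed to [plant_genome()].
#' @return Invisibly, a list with the in-memory dataset and file paths.
#' @export
simulate_dataset <- function(preset = c("fbox", "btb", "pkinase"),
                             rng_seed = 1, out_dir, ...) {
  preset <- match.arg(preset)
  dlen <- switch(preset, fbox = 48, btb = 108, pkinase = 267)
  fam <- make_family(domain_length = dlen, rng_seed = rng_seed,
                     family_id = switch(preset, fbox = "PF00646",
                                        btb = "PF00651", pkinase = "PF00069"))
  ds <- plant_genome(fam, rng_seed = rng_seed + 1L, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(ds$genome, p("genome.fa"))
  rtracklayer::export(features_to_granges(ds$features), p("genes.gff3"),
                      format = "gff3")
  write_fasta(ds$proteome, p("proteome.fa"))
  write_fasta(fam$seed_set$members, p("seeds.fa"))
  write.table(ds$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("genome.fa\tgenes.gff3\tproteome.fa", p("manifest.tab"))
  invisible(list(dataset = ds, family = fam, dir = out_dir,
                 manifest = p("manifest.tab")))
}
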