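## seqio: FASTA / GFF3 / manifest readers and writers.
##
## Sequence collections are named character vectors (names = record ids,
## values = uppercase residue strings) carrying a "moltype" attribute
## ("dna" or "protein"). Coordinates are 1-based inclusive everywhere.

DNA_CHARS <- c("A", "C", "G", "T", "N")
PROT_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Residues are uppercased; order is preserved. Ids must be unique and the
#' alphabet must be consistent with `moltype` (DNA: ACGTN; protein: the 20
#' amino acids plus `X` and `*`, and `-` when `allow_gaps = TRUE`, the
#' dialect of aligned Pfam-style seed files).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @param allow_gaps Permit `-` characters (seed alignments only).
#' @return Named character vector with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein"), allow_gaps = FALSE) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA id: ", dup[1], " in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  ok <- if (moltype == "dna") DNA_CHARS else PROT_CHARS
  if (allow_gaps) ok <- c(ok, "-")
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[[k]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad) > 0)
      stop("invalid ", moltype, " character '", chars[bad[1]], "' at position ",
           bad[1], " of record ", ids[k])
  }
  structure(seqs, moltype = moltype)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(as.character(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene/mRNA/CDS features from a GFF3 file
#'
#' Only `gene`, `mRNA` and `CDS` rows are retained; coordinates stay 1-based
#' inclusive. `feature_id` comes from the `ID` attribute; rows without an
#' `ID` get a synthesized stable id (with a warning).
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `feature_id`, `kind`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 (", conditionMessage(e),
                                          "): ", path))
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "CDS")
  gr <- gr[keep]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  miss <- which(is.na(ids) | !nzchar(ids))
  if (length(miss) > 0) {
    ids[miss] <- sprintf("feature_%06d", miss)
    warning(length(miss), " GFF3 row(s) lack an ID attribute; synthesized ids")
  }
  out <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_id = ids,
    kind = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 1))
    stop("GFF3 coordinate error: start < 1 for feature ", out$feature_id[which(out$start < 1)[1]])
  if (any(out$start > out$end))
    stop("GFF3 coordinate error: start > end for feature ", out$feature_id[which(out$start > out$end)[1]])
  out
}

#' Read the per-genome dataset manifest
#'
#' A three-column tab-delimited file, one row per genome: genome FASTA,
#' GFF3 annotation, proteome FASTA. Relative paths are resolved against the
#' manifest's own directory.
#'
#' @param path Path to the manifest file
#'   (`organismal_genome_gff3_proteome_files.tab` layout).
#' @return A data.frame with columns `genome_path`, `gff3_path`,
#'   `proteome_path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (nrow(tab) < 1 || ncol(tab) < 3)
    stop("manifest must have >= 1 row and 3 tab-separated columns: ", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  out <- data.frame(genome_path = resolve(tab[[1]]),
                    gff3_path = resolve(tab[[2]]),
                    proteome_path = resolve(tab[[3]]),
                    stringsAsFactors = FALSE)
  for (col in names(out)) {
    missing <- !file.exists(out[[col]])
    if (any(missing)) stop("manifest references missing file: ", out[[col]][missing][1])
  }
  out
}

#' Read a family seed file
#'
#' Seed members may arrive aligned (gapped, Pfam dialect) or unaligned.
#'
#' @param path FASTA file of seed protein sequences.
#' @param family_id Pfam-style family identifier (e.g. `"PF00646"`).
#' @return A list with elements `members` (named character, gaps retained)
#'   and `family_id`.
#' @export
read_seed_set <- function(path, family_id = "family") {
  members <- read_fasta(path, moltype = "protein", allow_gaps = TRUE)
  seed_set(members, family_id)
}

#' Construct a seed set
#' @param members Named character vector of (possibly gapped) proteins.
#' @param family_id Family identifier string.
#' @return A `ctt_seedset` list.
#' @export
seed_set <- function(members, family_id = "family") {
  if (length(members) < 2) stop("a seed set needs >= 2 members")
  degapped <- degap(members)
  if (any(!nzchar(degapped))) stop("seed member empty after degapping")
  structure(list(members = members, family_id = family_id),
            class = "ctt_seedset")
}

#' Remove alignment gaps from sequences
#' @param seqs Named character vector.
#' @return The same vector with `-` and `.` characters stripped.
#' @export
degap <- function(seqs) {
  out <- gsub("[-.]", "", seqs)
  names(out) <- names(seqs)
  out
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, n)), if.fuzzy.codon = "solve",
    no.init.codon = TRUE)))
}

#' Write the stepwise outputs of a family catalog
#'
#' Emits the per-step FASTA outputs of the pipeline (prior member proteins,
#' non-redundant references and combined seeds, candidate windows, trimmed
#' windows, predicted gDNA/transcript/peptide for new coding genes), a GFF3
#' coordinate table for new coding members, a pseudogene report, and the
#' final confirmed member list.
#'
#' @param catalog A `ctt_catalog` as returned by [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(catalog, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  written <- character(0)
  emit_fasta <- function(seqs, file) {
    if (length(seqs) == 0) {
      cat("", file = p(file)) # valid empty FASTA
    } else write_fasta(seqs, p(file))
    written <<- c(written, p(file))
  }
  emit_fasta(catalog$prior_proteins, "step1_family_members.faa")
  emit_fasta(catalog$refpep, "step2_refpep.faa")
  emit_fasta(catalog$combined_seeds, "step2_combined_seeds.faa")
  wseq <- vapply(catalog$windows, function(w) w$segment, character(1))
  if (length(wseq)) names(wseq) <- vapply(catalog$windows, function(w) w$window_id, character(1))
  emit_fasta(wseq, "step3_putative_windows.fna")
  tseq <- vapply(catalog$trimmed_windows, function(w) w$segment, character(1))
  if (length(tseq)) names(tseq) <- vapply(catalog$trimmed_windows, function(w) w$window_id, character(1))
  emit_fasta(tseq, "step4_trimmed_windows.fna")

  nc <- catalog$new_coding
  ids <- vapply(nc, function(m) m$model_id, character(1))
  gdna <- vapply(nc, function(m) m$gdna, character(1))
  tx <- vapply(nc, function(m) m$transcript, character(1))
  pep <- vapply(nc, function(m) m$protein, character(1))
  names(gdna) <- names(tx) <- names(pep) <- ids
  emit_fasta(gdna, "step5_new_gdna.fna")
  emit_fasta(tx, "step5_new_transcripts.fna")
  emit_fasta(pep, "step5_new_peptides.faa")

  # GFF3-style corrected coordinates of new coding genes
  gff <- p("step6_new_coordinates.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (m in nc) {
    writeLines(sprintf("%s\tctt\tgene\t%d\t%d\t%.1f\t%s\t.\tID=%s",
                       m$seqid, m$genomic_start, m$genomic_end, m$score,
                       m$strand, m$model_id), con)
    ex <- m$genomic_exons
    for (k in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tctt\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.cds%d;Parent=%s",
                         m$seqid, ex[k, 1], ex[k, 2], m$strand, m$model_id, k,
                         m$model_id), con)
  }
  close(con)
  written <- c(written, gff)

  ps <- catalog$new_pseudogenes
  pfile <- p("step5_pseudogenes.tsv")
  write.table(ps, pfile, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, pfile)

  final <- p("step7_confirmed_members.txt")
  writeLines(c(names(catalog$prior_proteins), ids), final)
  written <- c(written, final)

  rfile <- p("rejected_loci.tsv")
  write.table(catalog$rejected, rfile, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, rfile)
  invisible(written)
}
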