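## align: local protein alignment with Karlin-Altschul E-values, six-frame
## translated genome search (tBLASTn stand-in), DNA-vs-protein search
## (BLASTx stand-in), seed-profile domain scanning (HMMER stand-in) and
## greedy identity clustering (CD-HIT stand-in).

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties and the Karlin-Altschul
#' parameters used to convert raw scores into bit scores and E-values.
#' Defaults are the familiar BLOSUM62 / -11 / -1 combination with the
#' ungapped-approximation constants lambda = 0.267, K = 0.041.
#'
#' A gap of length L scores `gap_open + (L - 1) * gap_extend`.
#'
#' @param matrix_name Name of a substitution matrix shipped with Biostrings.
#' @param gap_open,gap_extend Negative gap penalties, `gap_open <= gap_extend < 0`.
#' @param ka_lambda,ka_k Positive Karlin-Altschul parameters.
#' @return A `ctt_scheme` list with the matrix and parameters.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = -11,
                           gap_extend = -1, ka_lambda = 0.267, ka_k = 0.041) {
  stopifnot(gap_open <= gap_extend, gap_extend < 0, ka_lambda > 0, ka_k > 0)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  submat <- get(matrix_name, envir = env)
  structure(list(matrix_name = matrix_name, submat = submat,
                 alphabet = paste(rownames(submat), collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend,
                 ka_lambda = ka_lambda, ka_k = ka_k),
            class = "ctt_scheme")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct local
#' alignments with score >= S between a random query of length `m` and a
#' database of length `n`.
#'
#' @param raw_score Raw alignment score S.
#' @param m Query length (>= 1).
#' @param n Database length (>= 1).
#' @param scheme A [scoring_scheme()].
#' @return The E-value (non-negative real).
#' @export
karlin_evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$ka_k * m * n * exp(-scheme$ka_lambda * raw_score)
}

# minimum raw score whose E-value is <= cutoff in an m x n search space
min_score_for_evalue <- function(cutoff, m, n, scheme) {
  log(scheme$ka_k * m * n / cutoff) / scheme$ka_lambda
}

bit_score <- function(raw_score, scheme) {
  (scheme$ka_lambda * raw_score - log(scheme$ka_k)) / log(2)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), identity_pct = numeric(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), frame = integer(0),
             aln_len = integer(0), stringsAsFactors = FALSE)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman with affine gaps. The search space for the E-value is the
#' pair itself (`m * n`). A raw score of 0 means no positive-scoring local
#' alignment exists and `NULL` is returned (the no-hit sentinel).
#'
#' @param query,subject Protein sequences (single residue strings, degapped).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Ids recorded in the hit.
#' @return A one-row hit data.frame, or `NULL` for no hit.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject") {
  query <- unname(as.character(query)); subject <- unname(as.character(subject))
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence in local_align")
  if (grepl("-", query, fixed = TRUE) || grepl("-", subject, fixed = TRUE))
    stop("local_align requires degapped sequences")
  h <- cpp_sw_align(query, subject, scheme$submat, scheme$alphabet,
                    scheme$gap_open, scheme$gap_extend, FALSE, 0, 1L)
  if (nrow(h) == 0 || h$raw_score[1] <= 0) return(NULL)
  data.frame(query_id = query_id, subject_id = subject_id,
             raw_score = h$raw_score, bit_score = bit_score(h$raw_score, scheme),
             evalue = karlin_evalue(h$raw_score, nchar(query), nchar(subject), scheme),
             identity_pct = 100 * h$matches / h$aln_len,
             q_start = as.integer(h$q_start), q_end = as.integer(h$q_end),
             s_start = as.integer(h$s_start), s_end = as.integer(h$s_end),
             strand = "+", frame = NA_integer_,
             aln_len = as.integer(h$aln_len), stringsAsFactors = FALSE)
}

#' Six-frame translation with codon coordinate maps
#'
#' Frames +1..+3 translate the sequence, -1..-3 its reverse complement.
#' Codons containing ambiguous bases translate to `X`; stops are `*`.
#'
#' @param dna A DNA sequence string.
#' @return A list of six entries, each `list(frame, aa, offset, n)` where
#'   residue `p` of `aa` maps to genomic positions
#'   [frame_to_genomic()] computes from `frame` and `n`.
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  out <- list()
  if (n < 3) return(out)
  rc <- revcomp(dna)
  for (f in 1:3) {
    for (sgn in c(1L, -1L)) {
      src <- if (sgn > 0) dna else rc
      if (n - f + 1 < 3) next
      aa <- translate_dna(substr(src, f, n))
      if (!nzchar(aa)) next
      out[[length(out) + 1]] <- list(frame = sgn * f, aa = aa, n = n)
    }
  }
  out
}

#' Map frame-protein coordinates back to genomic coordinates
#'
#' @param frame Frame number in -3..-1, 1..3.
#' @param p1,p2 1-based residue positions in the frame translation.
#' @param n Length of the genomic sequence.
#' @return `c(start, end)` genomic, 1-based inclusive, start <= end.
#' @export
frame_to_genomic <- function(frame, p1, p2, n) {
  f <- abs(frame)
  lo <- f + 3 * (min(p1, p2) - 1)
  hi <- f + 3 * max(p1, p2) - 1
  if (frame > 0) c(lo, hi) else c(n - hi + 1, n - lo + 1)
}

#' Translated homology search of a genome (tBLASTn stand-in)
#'
#' Aligns each protein query against all six reading frames of each contig,
#' maps hits back to genomic coordinates, and keeps hits with E-value at or
#' below the cutoff, sorted by bit score (descending).
#'
#' @param queries Named character vector of protein queries (degapped).
#' @param genome Named character vector of contig sequences.
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff Maximum E-value (> 0); database size is the total
#'   residue count of all translated frames.
#' @return A hit data.frame (possibly empty) with genomic `s_start`/`s_end`
#'   (min/max) plus `strand` and `frame`.
#' @export
translated_genome_search <- function(queries, genome, scheme = scoring_scheme(),
                                     evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  if (length(genome) == 0 || length(queries) == 0) return(empty_hits())
  frames <- lapply(genome, six_frame_translate)
  n_db <- sum(vapply(frames, function(fr)
    sum(vapply(fr, function(x) nchar(x$aa), numeric(1))), numeric(1)))
  if (n_db < 1) return(empty_hits())
  rows <- list()
  for (qi in seq_along(queries)) {
    q <- unname(queries[[qi]])
    qid <- names(queries)[qi]
    smin <- min_score_for_evalue(evalue_cutoff, nchar(q), n_db, scheme)
    for (ci in seq_along(genome)) {
      for (fr in frames[[ci]]) {
        h <- cpp_sw_align(q, fr$aa, scheme$submat, scheme$alphabet,
                          scheme$gap_open, scheme$gap_extend, TRUE, smin, 0L)
        if (nrow(h) == 0) next
        g <- t(vapply(seq_len(nrow(h)), function(k)
          frame_to_genomic(fr$frame, h$s_start[k], h$s_end[k], fr$n),
          numeric(2)))
        rows[[length(rows) + 1]] <- data.frame(
          query_id = qid, subject_id = names(genome)[ci],
          raw_score = h$raw_score,
          bit_score = bit_score(h$raw_score, scheme),
          evalue = karlin_evalue(h$raw_score, nchar(q), n_db, scheme),
          identity_pct = 100 * h$matches / h$aln_len,
          q_start = as.integer(h$q_start), q_end = as.integer(h$q_end),
          s_start = as.integer(g[, 1]), s_end = as.integer(g[, 2]),
          strand = if (fr$frame > 0) "+" else "-",
          frame = fr$frame, aln_len = as.integer(h$aln_len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  hits <- hits[order(-hits$bit_score, hits$subject_id, hits$s_start,
                     hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Rank database proteins against a DNA segment (BLASTx stand-in)
#'
#' Translates the segment in six frames, keeps the best local hit per
#' database protein, and returns the top `top_k` by bit score with a
#' deterministic tie-break (bit score desc, alignment length desc,
#' subject id asc).
#'
#' @param dna_segment DNA sequence string.
#' @param protein_db Named character vector of proteins.
#' @param scheme A [scoring_scheme()].
#' @param top_k Number of templates to return (>= 1).
#' @param evalue_cutoff Optional maximum E-value; `Inf` disables filtering.
#' @return A hit data.frame with `s_start`/`s_end` in segment (DNA)
#'   coordinates; zero rows if nothing aligns.
#' @export
dna_vs_protein_search <- function(dna_segment, protein_db,
                                  scheme = scoring_scheme(), top_k = 1,
                                  evalue_cutoff = Inf) {
  stopifnot(top_k >= 1)
  if (length(protein_db) == 0) return(empty_hits())
  frames <- six_frame_translate(dna_segment)
  if (length(frames) == 0) return(empty_hits())
  n_db <- sum(nchar(protein_db))
  rows <- list()
  for (pi in seq_along(protein_db)) {
    p <- unname(protein_db[[pi]])
    best <- NULL
    for (fr in frames) {
      h <- cpp_sw_align(p, fr$aa, scheme$submat, scheme$alphabet,
                        scheme$gap_open, scheme$gap_extend, FALSE, 0, 1L)
      if (nrow(h) == 0 || h$raw_score[1] <= 0) next
      if (is.null(best) || h$raw_score[1] > best$raw_score) {
        best <- h
        best$frame <- fr$frame
        best$n <- fr$n
      }
    }
    if (is.null(best)) next
    g <- frame_to_genomic(best$frame, best$s_start, best$s_end, best$n)
    rows[[length(rows) + 1]] <- data.frame(
      query_id = names(protein_db)[pi], subject_id = "segment",
      raw_score = best$raw_score, bit_score = bit_score(best$raw_score, scheme),
      evalue = karlin_evalue(best$raw_score, nchar(p), n_db, scheme),
      identity_pct = 100 * best$matches / best$aln_len,
      q_start = as.integer(best$q_start), q_end = as.integer(best$q_end),
      s_start = as.integer(g[1]), s_end = as.integer(g[2]),
      strand = if (best$frame > 0) "+" else "-", frame = best$frame,
      aln_len = as.integer(best$aln_len), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  hits <- hits[order(-hits$bit_score, -hits$aln_len, hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, top_k)
}

#' Build a position-specific scoring profile from a seed set
#'
#' Columns with more than 50% gaps are dropped (match columns only). Scores
#' are `log2(((count + pseudocount) / (N + 20 * pseudocount)) / background)`
#' with pseudocount 1 and a uniform background of 1/20. Unaligned input
#' (unequal lengths after gap handling) is aligned by projecting every
#' member onto the longest member with a global alignment.
#'
#' @param seed A `ctt_seedset` (members may be gapped).
#' @param pseudocount Additive pseudocount per residue (default 1).
#' @return A `ctt_profile`: list with `scores` (L x 20 matrix),
#'   `aa_order`, `length`, `family_id`.
#' @export
build_profile <- function(seed, pseudocount = 1) {
  if (!inherits(seed, "ctt_seedset")) stop("seed must be a ctt_seedset")
  mem <- seed$members
  if (length(mem) < 2) stop("profile needs >= 2 seed sequences")
  lens <- nchar(mem)
  if (length(unique(lens)) > 1) {
    mem <- align_to_reference(degap(mem))
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- do.call(rbind, strsplit(unname(mem), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) stop("no match columns in seed alignment")
  N <- length(mem)
  bg <- 1 / 20
  scores <- matrix(0, nrow = length(keep), ncol = 20,
                   dimnames = list(NULL, aa))
  for (r in seq_along(keep)) {
    col <- mat[, keep[r]]
    cnt <- table(factor(col[col %in% aa], levels = aa))
    freq <- (as.numeric(cnt) + pseudocount) / (N + 20 * pseudocount)
    scores[r, ] <- log2(freq / bg)
  }
  structure(list(scores = scores, aa_order = paste(aa, collapse = ""),
                 length = length(keep), family_id = seed$family_id),
            class = "ctt_profile")
}

# project each member onto the longest member by pairwise global alignment;
# reference columns become the profile columns (insertions are dropped)
align_to_reference <- function(members) {
  ref_i <- order(-nchar(members), names(members))[1]
  ref <- members[[ref_i]]
  out <- character(length(members))
  for (k in seq_along(members)) {
    if (k == ref_i) { out[k] <- ref; next }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(members[[k]]), Biostrings::AAString(ref),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global")
    alq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    als <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    out[k] <- paste(alq[als != "-"], collapse = "")
  }
  names(out) <- names(members)
  out
}

#' Scan a protein for the family domain (profile HMM search stand-in)
#'
#' Best local alignment of the profile against the protein
#' (Smith-Waterman over profile columns); a hit is returned only if its
#' E-value is at or below the cutoff.
#'
#' @param protein A degapped protein string.
#' @param profile A `ctt_profile` from [build_profile()].
#' @param scheme A [scoring_scheme()] (gap penalties and E-value constants).
#' @param evalue_cutoff Maximum E-value (default 1, the customary
#'   domain-presence threshold).
#' @return `NULL`, or a one-row data.frame with `protein_id`, `d_start`,
#'   `d_end`, `score`, `evalue`.
#' @export
scan_domain <- function(protein, profile, scheme = scoring_scheme(),
                        evalue_cutoff = 1) {
  protein <- unname(as.character(protein))
  if (!nzchar(protein)) return(NULL)
  r <- cpp_profile_scan(profile$scores, protein, profile$aa_order,
                        scheme$gap_open, scheme$gap_extend, -4)
  if (r$score <= 0) return(NULL)
  ev <- karlin_evalue(r$score, profile$length, nchar(protein), scheme)
  if (ev > evalue_cutoff) return(NULL)
  data.frame(protein_id = "protein", d_start = as.integer(r$s_start),
             d_end = as.integer(r$s_end), score = r$score, evalue = ev,
             stringsAsFactors = FALSE)
}

# global percent identity (matches / alignment columns) between two proteins
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Greedy identity clustering (CD-HIT stand-in)
#'
#' Sequences are sorted by length (descending, ties by id) and processed
#' greedily: a sequence joins the first cluster whose representative it
#' matches at or above `identity_threshold` global identity, otherwise it
#' founds a new cluster. Representatives are returned in founding order.
#'
#' @param sequences Named character vector of proteins.
#' @param identity_threshold Fraction in (0, 1].
#' @return Named character vector of representatives.
#' @export
cluster_identity <- function(sequences, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(sequences) == 0) return(sequences)
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(0)
  for (k in seq_along(sequences)) {
    s <- sequences[[k]]
    joined <- FALSE
    for (r in reps) {
      if (global_identity(s, sequences[[r]]) >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, names(sequences)[k])
  }
  sequences[reps]
}
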