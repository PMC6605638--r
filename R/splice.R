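## splice: spliced protein-to-genome alignment and gene-model
## classification (the GeneWise stand-in).

#' Parameters for spliced protein-to-genome alignment
#'
#' @param scheme A [scoring_scheme()] (substitution matrix, gap penalties).
#' @param intron_open_penalty Penalty (< 0) for opening a GT..AG intron.
#' @param min_intron Minimum intron length in nt (>= 4).
#' @param frameshift_penalty Penalty (< 0) per 1-nt insertion/deletion
#'   inside a codon; each use is recorded as a frameshift lesion.
#' @param stop_codon_penalty Penalty (< 0) for reading through an in-frame
#'   stop codon; each use is recorded as an internal_stop lesion.
#' @param score_threshold Minimum raw alignment score for a model to be
#'   reported (the role of the GeneWise score >= 50 stop rule; the value is
#'   in this aligner's raw DP unit and configurable).
#' @return A `ctt_splice_params` list.
#' @export
splice_params <- function(scheme = scoring_scheme(),
                          intron_open_penalty = -15, min_intron = 40,
                          frameshift_penalty = -20, stop_codon_penalty = -15,
                          score_threshold = 50) {
  stopifnot(intron_open_penalty < 0, frameshift_penalty < 0,
            stop_codon_penalty < 0, min_intron >= 4)
  structure(list(scheme = scheme, intron_open_penalty = intron_open_penalty,
                 min_intron = min_intron,
                 frameshift_penalty = frameshift_penalty,
                 stop_codon_penalty = stop_codon_penalty,
                 score_threshold = score_threshold),
            class = "ctt_splice_params")
}

#' Spliced alignment of a protein template to a DNA segment
#'
#' Dynamic program over (template residue, genomic position) with codon
#' match/insert/delete states, intron jumps between codons across GT..AG
#' pairs at least `min_intron` nt apart, single-base insertions and
#' deletions inside codons (frameshift lesions) and read-through of
#' in-frame stop codons (internal_stop lesions). Both strands are tried;
#' ties break toward `+`, then toward the leftmost start.
#'
#' @param template A degapped protein string (named or not).
#' @param dna_segment DNA segment (>= 3 nt; at most 200,000 nt).
#' @param params A [splice_params()].
#' @param template_id,window_id Ids recorded in the model.
#' @return A `ctt_model` (see Details), or `NULL` if the best score is
#'   below `params$score_threshold`.
#' @details The model carries `exons` (k x 2 matrix, segment coordinates,
#'   ascending), `strand`, `cds` (concatenated exon nucleotides in reading
#'   orientation), `transcript` (identical to `cds`; UTRs are not
#'   modelled), `protein`, `score`, `lesions` (`internal_stop`,
#'   `frameshift`) and `template_span`.
#' @export
spliced_align <- function(template, dna_segment, params = splice_params(),
                          template_id = "template", window_id = "window") {
  template <- unname(as.character(template))
  dna_segment <- toupper(unname(as.character(dna_segment)))
  n <- nchar(dna_segment)
  if (n < 3) stop("dna_segment shorter than 3 nt")
  if (n > 200000L) stop("dna_segment exceeds the 200,000 nt cap")
  sch <- params$scheme
  run <- function(seq) {
    cpp_spliced_align(template, seq, sch$submat, sch$alphabet,
                      sch$gap_open, sch$gap_extend,
                      params$intron_open_penalty, params$min_intron,
                      params$frameshift_penalty, params$stop_codon_penalty)
  }
  fw <- run(dna_segment)
  rv <- run(revcomp(dna_segment))
  pick_fw <- if (is.na(score_of(rv))) TRUE
             else if (is.na(score_of(fw))) FALSE
             else score_of(fw) >= score_of(rv) # tie -> '+'
  r <- if (pick_fw) fw else rv
  if (is.na(score_of(r)) || score_of(r) < params$score_threshold) return(NULL)
  exons <- r$exons
  strand <- if (pick_fw) "+" else "-"
  if (!pick_fw) {
    # map reverse-complement coordinates back to segment coordinates
    exons <- cbind(n - exons[, 2] + 1L, n - exons[, 1] + 1L)
    exons <- exons[order(exons[, 1]), , drop = FALSE]
  }
  structure(list(
    window_id = window_id, template_id = template_id,
    exons = exons, strand = strand,
    cds = r$cds, transcript = r$cds, protein = r$protein,
    score = r$score,
    lesions = c(internal_stop = r$n_stop, frameshift = r$n_fs),
    n_introns = r$n_intron,
    template_span = c(r$p_start, r$p_end)), class = "ctt_model")
}

score_of <- function(r) {
  if (is.null(r$score) || r$score < -1e29) NA_real_ else r$score
}

#' Classify a predicted gene model
#'
#' `coding` if a model exists with zero lesions; `pseudogene_stop` if the
#' model carries internal stop or frameshift lesions; and
#' `pseudogene_no_transcript` if no model survived the score threshold even
#' though a template hit existed for the window.
#'
#' @param model A `ctt_model` or `NULL`.
#' @param had_template_hit Logical; was there a translated-search template
#'   hit for this window?
#' @return One of `"coding"`, `"pseudogene_stop"`,
#'   `"pseudogene_no_transcript"`.
#' @export
classify_model <- function(model, had_template_hit) {
  if (is.null(model)) {
    if (!had_template_hit)
      stop("classify_model called with neither a model nor a template hit")
    return("pseudogene_no_transcript")
  }
  if (sum(model$lesions) > 0) "pseudogene_stop" else "coding"
}
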