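## evaluate: hold-out rediscovery sensitivity, prediction specificity
## (percent identity and integrity), the combined (Sn+Sp)/2 accuracy, and
## new-finding summary rows.

# genomic midpoint of a catalog entry: corrected model span for coding,
# anchor interval for pseudogenes
catalog_new_entries <- function(catalog) {
  rows <- list()
  for (m in catalog$new_coding) {
    rows[[length(rows) + 1]] <- data.frame(
      id = m$model_id, seqid = m$seqid,
      midpoint = floor((m$genomic_start + m$genomic_end) / 2),
      class = "coding", stringsAsFactors = FALSE)
  }
  ps <- catalog$new_pseudogenes
  for (k in seq_len(nrow(ps))) {
    rows[[length(rows) + 1]] <- data.frame(
      id = ps$window_id[k], seqid = ps$seqid[k],
      midpoint = floor((ps$target_start[k] + ps$target_end[k]) / 2),
      class = ps$class[k], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), seqid = character(0),
               midpoint = integer(0), class = character(0))
}

#' Count rediscovered held-out loci
#'
#' A held-out locus is rediscovered when the midpoint of a newly annotated
#' catalog entry lies within its span; the rediscovery is counted under the
#' entry's class (coding wins if both classes match the same locus).
#'
#' @param catalog A `ctt_catalog`.
#' @param heldout Data.frame of held-out features with columns `seqid`,
#'   `start`, `end` (and optionally `feature_id`). Spans must not overlap.
#' @return `list(coding, pseudo, detail)`: counts plus a per-locus
#'   data.frame with the matched class (`NA` when missed).
#' @export
holdout_rediscovery <- function(catalog, heldout) {
  stopifnot(nrow(heldout) >= 1)
  for (k in seq_len(nrow(heldout) - 1L)) {
    same <- heldout$seqid == heldout$seqid[k]
    same[seq_len(k)] <- FALSE
    if (any(same & heldout$start <= heldout$end[k] &
            heldout$end >= heldout$start[k]))
      stop("overlapping held-out features: attribution is ambiguous")
  }
  entries <- catalog_new_entries(catalog)
  matched <- character(nrow(heldout))
  for (k in seq_len(nrow(heldout))) {
    inside <- entries$seqid == heldout$seqid[k] &
      entries$midpoint >= heldout$start[k] &
      entries$midpoint <= heldout$end[k]
    cls <- entries$class[inside]
    matched[k] <- if (any(cls == "coding")) "coding"
      else if (length(cls) > 0) "pseudo" else NA_character_
  }
  detail <- cbind(heldout,
                  data.frame(rediscovered_as = matched,
                             stringsAsFactors = FALSE))
  list(coding = sum(matched == "coding", na.rm = TRUE),
       pseudo = sum(matched == "pseudo", na.rm = TRUE),
       detail = detail)
}

#' Specificity metrics: percent identity and integrity
#'
#' For each rediscovered locus, the predicted protein is locally aligned to
#' its original annotation: `Pident` is the alignment percent identity and
#' `Integrity` the fraction of the original protein covered by the
#' alignment (x 100).
#'
#' @param predicted Named character vector of predicted proteins.
#' @param original Named character vector of original proteins.
#' @param pairs Data.frame with columns `predicted_id`, `original_id`.
#' @param scheme A [scoring_scheme()].
#' @return A list with `pident` (mean, sd), `integrity` (mean, sd) and the
#'   per-pair data.frame.
#' @export
specificity_metrics <- function(predicted, original, pairs,
                                scheme = scoring_scheme()) {
  if (nrow(pairs) == 0) stop("empty pairing: nothing to compare")
  pident <- numeric(nrow(pairs)); integ <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p <- predicted[[pairs$predicted_id[k]]]
    o <- original[[pairs$original_id[k]]]
    h <- local_align(p, o, scheme)
    if (is.null(h)) { pident[k] <- 0; integ[k] <- 0; next }
    pident[k] <- h$identity_pct
    integ[k] <- 100 * (h$s_end - h$s_start + 1) / nchar(o)
  }
  per_pair <- cbind(pairs, data.frame(pident = pident, integrity = integ))
  list(pident = c(mean = mean(pident), sd = if (nrow(pairs) > 1) sd(pident) else 0),
       integrity = c(mean = mean(integ), sd = if (nrow(pairs) > 1) sd(integ) else 0),
       per_pair = per_pair)
}

#' Combined gene-finding accuracy, (Sn+Sp)/2
#'
#' Sensitivity is the percentage of held-out loci rediscovered as coding;
#' specificity is the mean of the percent-identity and integrity means.
#' The result is their average, rounded half-up to one decimal.
#'
#' @param sensitivity_coding_count Held-out loci rediscovered as coding.
#' @param n_heldout Number of held-out loci (> 0).
#' @param pident_mean,integrity_mean Specificity component means (percent).
#' @return The accuracy in percent, one decimal.
#' @export
accuracy <- function(sensitivity_coding_count, n_heldout, pident_mean,
                     integrity_mean) {
  stopifnot(n_heldout > 0)
  sp <- (pident_mean + integrity_mean) / 2
  sn <- 100 * sensitivity_coding_count / n_heldout
  round_half_up((sn + sp) / 2, 1)
}

#' New-finding summary row
#'
#' `total = prior + pseudo + coding`; the new-finding percentage is
#' `100 * (pseudo + coding) / total`, one decimal. Can be called with
#' explicit counts or with a `ctt_catalog` as the first argument.
#'
#' @param prior Prior-annotation member count, or a `ctt_catalog`.
#' @param pseudo New pseudogene count.
#' @param coding New protein-coding gene count.
#' @return A one-row data.frame: `prior`, `pseudo`, `coding`, `total`,
#'   `pct_new`.
#' @export
new_finding_summary <- function(prior, pseudo = NULL, coding = NULL) {
  if (inherits(prior, "ctt_catalog")) {
    catalog <- prior
    prior <- length(catalog$prior_proteins)
    pseudo <- nrow(catalog$new_pseudogenes)
    coding <- length(catalog$new_coding)
  }
  total <- prior + pseudo + coding
  if (total == 0) stop("empty catalog: total member count is zero")
  data.frame(prior = prior, pseudo = pseudo, coding = coding, total = total,
             pct_new = round_half_up(100 * (pseudo + coding) / total, 1))
}
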