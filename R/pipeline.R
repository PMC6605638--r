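## pipeline: the seven annotation steps, including the closing-target
## trimming iteration, orchestrated per genome from a manifest.

#' Pipeline configuration
#'
#' Holds every tunable threshold of the annotation pipeline. Defaults are
#' the standard operating point: BLASTp-style E-value 1e-5 and domain-scan
#' E-value 1 for prior-member discovery, translated-search E-value 1e-5 for
#' anchoring, 5,000 nt flanks on both sides of an anchor start (a 10,001 nt
#' window), up to six trimming iterations, a minimum spliced-alignment
#' score of 50, three consensus templates with a quorum of two, and a 0.9
#' identity threshold for redundancy removal.
#'
#' @param blastp_evalue E-value cutoff for seed-vs-proteome search.
#' @param domain_evalue E-value cutoff for the family domain scan.
#' @param tblastn_evalue E-value cutoff for the translated genome search.
#' @param blastx_evalue E-value cutoff for segment-vs-reference ranking
#'   (the "no hit" stop rule of the trimming loop).
#' @param flank_head,flank_tail Nucleotides added left/right of an anchor
#'   start when cutting a candidate window.
#' @param max_iterations Maximum trimming iterations per window.
#' @param genewise_min_score Minimum spliced-alignment score for a model.
#' @param templates_for_consensus Number of templates voted in step 5.
#' @param min_agreeing_templates Quorum for the consensus class.
#' @param cluster_threshold Identity threshold for reference clustering.
#' @param encompass `"containment"` (the target interval must lie inside
#'   the model span, same strand) or `"midpoint"` (only the target midpoint
#'   must).
#' @return A `ctt_config` list.
#' @export
pipeline_config <- function(blastp_evalue = 1e-5, domain_evalue = 1,
                            tblastn_evalue = 1e-5, blastx_evalue = 10,
                            flank_head = 5000, flank_tail = 5000,
                            max_iterations = 6, genewise_min_score = 50,
                            templates_for_consensus = 3,
                            min_agreeing_templates = 2,
                            cluster_threshold = 0.9,
                            encompass = c("containment", "midpoint")) {
  stopifnot(blastp_evalue > 0, domain_evalue > 0, tblastn_evalue > 0,
            blastx_evalue > 0, flank_head > 0, flank_tail > 0,
            max_iterations >= 1, templates_for_consensus >= 1,
            min_agreeing_templates >= 1, cluster_threshold > 0,
            cluster_threshold <= 1)
  structure(list(blastp_evalue = blastp_evalue, domain_evalue = domain_evalue,
                 tblastn_evalue = tblastn_evalue, blastx_evalue = blastx_evalue,
                 flank_head = flank_head, flank_tail = flank_tail,
                 max_iterations = max_iterations,
                 genewise_min_score = genewise_min_score,
                 templates_for_consensus = templates_for_consensus,
                 min_agreeing_templates = min_agreeing_templates,
                 cluster_threshold = cluster_threshold,
                 encompass = match.arg(encompass)),
            class = "ctt_config")
}

target_region <- function(seqid, start, end, strand, seed_id, bit_score) {
  stopifnot(start <= end)
  list(seqid = seqid, start = as.integer(start), end = as.integer(end),
       strand = strand, seed_id = seed_id, bit_score = bit_score)
}

target_midpoint <- function(target) as.integer(floor((target$start + target$end) / 2))

#' Step 1: find prior family members in annotated proteomes
#'
#' A protein is a prior member if any seed aligns to it with E-value at or
#' below `blastp_evalue` AND the family profile scan finds the domain at
#' E-value at or below `domain_evalue`. Each retained protein carries its
#' best domain hit.
#'
#' @param proteomes Named character vector of proteins (pooled across
#'   manifest rows).
#' @param seed A `ctt_seedset`.
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param profile Optional prebuilt `ctt_profile` (rebuilt from `seed`
#'   when `NULL`).
#' @return A list: `proteins` (named character) and `domains` (data.frame
#'   of best domain hits, one row per retained protein).
#' @export
step1_prior_members <- function(proteomes, seed, config = pipeline_config(),
                                scheme = scoring_scheme(), profile = NULL) {
  if (!inherits(seed, "ctt_seedset") || length(seed$members) == 0)
    stop("empty seed set")
  if (is.null(profile)) profile <- build_profile(seed)
  seeds <- degap(seed$members)
  keep <- character(0)
  dom_rows <- list()
  for (pid in names(proteomes)) {
    prot <- proteomes[[pid]]
    best_ev <- Inf
    for (sid in names(seeds)) {
      h <- local_align(seeds[[sid]], prot, scheme, sid, pid)
      if (!is.null(h)) best_ev <- min(best_ev, h$evalue)
      if (best_ev <= config$blastp_evalue) break
    }
    if (best_ev > config$blastp_evalue) next
    dh <- scan_domain(prot, profile, scheme, config$domain_evalue)
    if (is.null(dh)) next
    dh$protein_id <- pid
    keep <- c(keep, pid)
    dom_rows[[length(dom_rows) + 1]] <- dh
  }
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(protein_id = character(0), d_start = integer(0),
               d_end = integer(0), score = numeric(0), evalue = numeric(0))
  list(proteins = proteomes[keep], domains = domains)
}

#' Step 2: build non-redundant reference and seed sets
#'
#' References (RefPep) are the clustered full-length prior members; the
#' combined seed set is the clustered union of the original (degapped)
#' seeds and the best-domain subsequences of the prior members.
#'
#' @param prior Output of [step1_prior_members()].
#' @param seed The original `ctt_seedset`.
#' @param config A [pipeline_config()].
#' @return A list: `refpep` and `combined_seeds` (named character vectors).
#' @export
step2_reference_sets <- function(prior, seed, config = pipeline_config()) {
  refpep <- cluster_identity(prior$proteins, config$cluster_threshold)
  dom <- prior$domains
  slices <- character(0)
  if (nrow(dom) > 0) {
    slices <- vapply(seq_len(nrow(dom)), function(k)
      substr(prior$proteins[[dom$protein_id[k]]], dom$d_start[k], dom$d_end[k]),
      character(1))
    names(slices) <- paste0(dom$protein_id, "_domain")
  }
  pool <- c(degap(seed$members), slices)
  combined <- cluster_identity(pool, config$cluster_threshold)
  list(refpep = refpep, combined_seeds = combined)
}

#' Step 3: anchor putative new loci and cut candidate windows
#'
#' Runs the translated genome search, deduplicates hits by the mutual
#' midpoint rule (higher bit score wins; ties broken by longer hit, then
#' leftmost, then seed id), discards hits contained in an annotated gene
#' span (strand-agnostic), and cuts a window of
#' `[start - flank_head, start + flank_tail]` (clamped to the contig)
#' around each surviving anchor start.
#'
#' @param combined_seeds Named character vector of seed queries.
#' @param genome Named character vector of contigs.
#' @param annotations Feature data.frame from [read_gff3()].
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @return A list of candidate windows (`ctt_window`): each has
#'   `window_id`, `seqid`, `segment`, `offset` (genomic coordinate of
#'   segment position 1), `target`, `iteration`.
#' @export
step3_putative_loci <- function(combined_seeds, genome, annotations,
                                config = pipeline_config(),
                                scheme = scoring_scheme()) {
  hits <- translated_genome_search(combined_seeds, genome, scheme,
                                   config$tblastn_evalue)
  if (nrow(hits) == 0) return(list())
  # (b) dedup by mutual midpoint containment, best score first
  hits <- hits[order(-hits$bit_score, -(hits$s_end - hits$s_start),
                     hits$s_start, hits$query_id), , drop = FALSE]
  kept <- list()
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    mid <- floor((h$s_start + h$s_end) / 2)
    clash <- FALSE
    for (g in kept) {
      if (g$subject_id != h$subject_id) next
      gmid <- floor((g$s_start + g$s_end) / 2)
      if ((mid >= g$s_start && mid <= g$s_end) ||
          (gmid >= h$s_start && gmid <= h$s_end)) { clash <- TRUE; break }
    }
    if (!clash) kept[[length(kept) + 1]] <- h
  }
  # (c) drop hits contained in an annotated gene span
  genes <- annotations[annotations$kind == "gene", , drop = FALSE]
  survives <- vapply(kept, function(h) {
    g <- genes[genes$seqid == h$subject_id, , drop = FALSE]
    !any(g$start <= h$s_start & h$s_end <= g$end)
  }, logical(1))
  kept <- kept[survives]
  # (d) windows around anchor starts
  windows <- list()
  for (k in seq_along(kept)) {
    h <- kept[[k]]
    clen <- nchar(genome[[h$subject_id]])
    ws <- max(1L, h$s_start - as.integer(config$flank_head))
    we <- min(clen, h$s_start + as.integer(config$flank_tail))
    windows[[length(windows) + 1]] <- structure(list(
      window_id = sprintf("%s_w%03d", h$subject_id, k),
      seqid = h$subject_id,
      segment = substr(genome[[h$subject_id]], ws, we),
      offset = ws,
      target = target_region(h$subject_id, h$s_start, h$s_end, h$strand,
                             h$query_id, h$bit_score),
      iteration = 0L, trace = list()), class = "ctt_window")
  }
  windows
}

# does the model footprint (segment coords fs..fe, strand ms) encompass the
# target (window-local ts..te, strand)?
encompasses <- function(fs, fe, ms, ts, te, tstrand, mode) {
  if (ms != tstrand) return(FALSE)
  if (mode == "containment") fs <= ts && te <= fe
  else { tm <- floor((ts + te) / 2); fs <= tm && tm <= fe }
}

#' Step 4: closing-target trimming
#'
#' Iteratively exposes the anchor locus: in each round the best reference
#' template for the remaining segment is found, its gene model is
#' predicted, and either the model encompasses the target (window exposed)
#' or the model's footprint is trimmed away, keeping the contiguous
#' remainder that contains the target midpoint. Stops with a rejection
#' when no template hit is found, the model score falls below
#' `genewise_min_score`, or `max_iterations` is exhausted. The segment
#' length strictly decreases every iteration.
#'
#' @param window A `ctt_window` from [step3_putative_loci()].
#' @param refpep Named character vector of reference proteins.
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param sparams A [splice_params()].
#' @return The exposed window (with `exposed_model` attached), or a
#'   rejection: `list(rejected = TRUE, reason = ..., window = ...)`.
#' @export
step4_ctt_trim <- function(window, refpep, config = pipeline_config(),
                           scheme = scoring_scheme(),
                           sparams = splice_params(scheme,
                             score_threshold = config$genewise_min_score)) {
  stopifnot(inherits(window, "ctt_window"), window$iteration == 0L)
  reject <- function(reason) list(rejected = TRUE, reason = reason,
                                  window = window)
  repeat {
    seg <- window$segment
    tloc <- window$target
    ts <- tloc$start - window$offset + 1L
    te <- tloc$end - window$offset + 1L
    if (ts < 1L || te > nchar(seg))
      stop("internal invariant violation: target outside trimmed segment (",
           window$window_id, ")")
    hits <- dna_vs_protein_search(seg, refpep, scheme, top_k = 1,
                                  evalue_cutoff = config$blastx_evalue)
    if (nrow(hits) == 0) return(reject("no hit"))
    template <- refpep[[hits$query_id[1]]]
    model <- spliced_align(template, seg, sparams,
                           template_id = hits$query_id[1],
                           window_id = window$window_id)
    if (is.null(model)) return(reject("low score"))
    fs <- min(model$exons[, 1]); fe <- max(model$exons[, 2])
    if (encompasses(fs, fe, model$strand, ts, te, tloc$strand,
                    config$encompass)) {
      window$exposed_model <- model
      return(window)
    }
    tm <- floor((ts + te) / 2)
    if (fs <= te && ts <= fe) return(reject("footprint overlaps target"))
    window$trace[[length(window$trace) + 1]] <- list(
      iteration = window$iteration,
      removed = c(fs + window$offset - 1L, fe + window$offset - 1L),
      remaining = nchar(seg) - (fe - fs + 1L))
    if (tm < fs) {
      window$segment <- substr(seg, 1L, fs - 1L)
    } else {
      window$segment <- substr(seg, fe + 1L, nchar(seg))
      window$offset <- window$offset + fe
    }
    window$iteration <- window$iteration + 1L
    if (window$iteration >= config$max_iterations)
      return(reject("iterations exhausted"))
  }
}

#' Step 5: consensus gene model for an exposed window
#'
#' The top templates are each aligned to the exposed segment and the
#' resulting models classified; a class wins with a quorum of
#' `min_agreeing_templates` (with fewer than two available templates, all
#' must agree and the result is flagged low-confidence). For a coding
#' consensus the agreeing model with the highest score is returned.
#'
#' @param window An exposed `ctt_window` from [step4_ctt_trim()].
#' @param refpep Named character vector of reference proteins.
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param sparams A [splice_params()].
#' @return `list(model, class, low_confidence)` or a rejection
#'   `list(rejected = TRUE, reason = "no consensus", window = ...)`.
#' @export
step5_best_model <- function(window, refpep, config = pipeline_config(),
                             scheme = scoring_scheme(),
                             sparams = splice_params(scheme,
                               score_threshold = config$genewise_min_score)) {
  hits <- dna_vs_protein_search(window$segment, refpep, scheme,
                                top_k = config$templates_for_consensus,
                                evalue_cutoff = config$blastx_evalue)
  if (nrow(hits) == 0)
    return(list(rejected = TRUE, reason = "no hit", window = window))
  models <- list(); classes <- character(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    m <- spliced_align(refpep[[hits$query_id[k]]], window$segment, sparams,
                       template_id = hits$query_id[k],
                       window_id = window$window_id)
    models[[k]] <- m
    classes[k] <- classify_model(m, had_template_hit = TRUE)
  }
  n_avail <- nrow(hits)
  quorum <- if (n_avail >= 2) config$min_agreeing_templates else n_avail
  tab <- sort(table(classes), decreasing = TRUE)
  if (tab[1] < quorum)
    return(list(rejected = TRUE, reason = "no consensus", window = window))
  win_class <- names(tab)[1]
  agree <- which(classes == win_class)
  best <- NULL
  scores <- vapply(agree, function(k)
    if (is.null(models[[k]])) -Inf else models[[k]]$score, numeric(1))
  if (any(is.finite(scores))) best <- models[[agree[which.max(scores)]]]
  list(model = best, class = win_class, low_confidence = n_avail < 2)
}

#' Step 6: correct genomic coordinates of a model
#'
#' Maps exon intervals from window-local to genomic coordinates through
#' the window's offset (intact through trimming) and verifies the
#' round trip: re-extracting the genomic intervals and splicing them
#' reproduces the model's CDS exactly.
#'
#' @param model A `ctt_model` in window coordinates.
#' @param window The window the model was predicted in.
#' @return The model with `genomic_exons`, `genomic_start`, `genomic_end`,
#'   `seqid` and `gdna` added.
#' @export
step6_correct_coords <- function(model, window) {
  if (any(model$exons[, 1] < 1) || any(model$exons[, 2] > nchar(window$segment)))
    stop("exon outside the window span")
  gex <- model$exons + window$offset - 1L
  pieces <- substring(window$segment, model$exons[, 1], model$exons[, 2])
  spliced <- paste(pieces, collapse = "")
  if (model$strand == "-") spliced <- revcomp(spliced)
  if (!identical(spliced, model$cds))
    stop("coordinate round-trip failed for ", model$window_id)
  model$genomic_exons <- gex
  model$genomic_start <- min(gex)
  model$genomic_end <- max(gex)
  model$seqid <- window$seqid
  model$gdna <- substr(window$segment, min(model$exons), max(model$exons))
  model
}

#' Step 7: confirm the family domain in a new coding model
#'
#' @param model A coding `ctt_model` with a predicted protein.
#' @param profile The family `ctt_profile`.
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @return `TRUE` (accept) or `FALSE` (reject). Pseudogene candidates
#'   bypass this check.
#' @export
step7_confirm_domain <- function(model, profile, config = pipeline_config(),
                                 scheme = scoring_scheme()) {
  !is.null(scan_domain(model$protein, profile, scheme, config$domain_evalue))
}

#' Run the full annotation pipeline
#'
#' Executes steps 1-7 for every genome in the manifest. Prior members and
#' references are pooled across all manifest rows (adding well-annotated
#' genomes improves prediction), then each genome is anchored, trimmed,
#' annotated and confirmed independently. The run is deterministic given
#' the inputs and configuration.
#'
#' @param manifest Data.frame from [read_manifest()], or a path to a
#'   manifest file.
#' @param seed A `ctt_seedset` (or path to a seed FASTA).
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param sparams A [splice_params()].
#' @param verbose Emit per-step progress messages.
#' @return A named list of `ctt_catalog` objects, one per genome.
#' @export
run_pipeline <- function(manifest, seed, config = pipeline_config(),
                         scheme = scoring_scheme(),
                         sparams = splice_params(scheme,
                           score_threshold = config$genewise_min_score),
                         verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(seed)) seed <- read_seed_set(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  genomes <- lapply(manifest$genome_path, read_fasta, moltype = "dna")
  gffs <- lapply(manifest$gff3_path, read_gff3)
  prots <- lapply(manifest$proteome_path, read_fasta, moltype = "protein")
  genome_ids <- vapply(manifest$genome_path, function(p)
    sub("\\.(fa|fasta|fna)$", "", basename(p)), character(1), USE.NAMES = FALSE)

  pooled <- do.call(c, prots)
  if (anyDuplicated(names(pooled)))
    stop("duplicate protein ids across manifest proteomes")
  profile <- build_profile(seed)
  say("step1: scanning %d proteins", length(pooled))
  prior <- step1_prior_members(pooled, seed, config, scheme, profile)
  say("step1: %d prior members", length(prior$proteins))
  refs <- step2_reference_sets(prior, seed, config)
  say("step2: %d refpep, %d combined seeds", length(refs$refpep),
      length(refs$combined_seeds))

  catalogs <- list()
  for (gi in seq_along(genomes)) {
    gid <- genome_ids[gi]
    cat_g <- tryCatch(
      annotate_genome(gid, genomes[[gi]], gffs[[gi]], prots[[gi]], prior,
                      refs, profile, config, scheme, sparams, say),
      error = function(e) {
        warning("genome ", gid, " aborted: ", conditionMessage(e))
        NULL
      })
    if (!is.null(cat_g)) catalogs[[gid]] <- cat_g
  }
  catalogs
}

annotate_genome <- function(genome_id, genome, gff, proteome, prior, refs,
                            profile, config, scheme, sparams, say) {
  windows <- step3_putative_loci(refs$combined_seeds, genome, gff, config,
                                 scheme)
  say("step3 [%s]: %d candidate windows", genome_id, length(windows))
  new_coding <- list()
  pseudo_rows <- list()
  rej_rows <- list()
  trimmed <- list()
  reject_row <- function(w, reason) data.frame(
    window_id = w$window_id, seqid = w$target$seqid,
    target_start = w$target$start, target_end = w$target$end,
    strand = w$target$strand, reason = reason, stringsAsFactors = FALSE)
  for (w in windows) {
    r4 <- step4_ctt_trim(w, refs$refpep, config, scheme, sparams)
    if (isTRUE(r4$rejected)) {
      rej_rows[[length(rej_rows) + 1]] <- reject_row(r4$window, r4$reason)
      next
    }
    trimmed[[length(trimmed) + 1]] <- r4
    r5 <- step5_best_model(r4, refs$refpep, config, scheme, sparams)
    if (isTRUE(r5$rejected)) {
      rej_rows[[length(rej_rows) + 1]] <- reject_row(r5$window, r5$reason)
      next
    }
    if (r5$class == "coding") {
      m <- step6_correct_coords(r5$model, r4)
      m$model_id <- paste0(genome_id, "_new_", length(new_coding) + 1L)
      m$low_confidence <- r5$low_confidence
      m$target <- r4$target
      if (step7_confirm_domain(m, profile, config, scheme)) {
        new_coding[[length(new_coding) + 1]] <- m
      } else {
        rej_rows[[length(rej_rows) + 1]] <- reject_row(r4, "no family domain")
      }
    } else {
      pseudo_rows[[length(pseudo_rows) + 1]] <- data.frame(
        window_id = r4$window_id, seqid = r4$target$seqid,
        target_start = r4$target$start, target_end = r4$target$end,
        strand = r4$target$strand, class = r5$class,
        low_confidence = r5$low_confidence, stringsAsFactors = FALSE)
    }
  }
  prior_ids <- intersect(names(prior$proteins), names(proteome))
  say("step5-7 [%s]: %d new coding, %d pseudogenes, %d rejected", genome_id,
      length(new_coding), length(pseudo_rows), length(rej_rows))
  structure(list(
    genome_id = genome_id,
    prior_proteins = prior$proteins[prior_ids],
    prior_domains = prior$domains[prior$domains$protein_id %in% prior_ids, ,
                                  drop = FALSE],
    refpep = refs$refpep, combined_seeds = refs$combined_seeds,
    windows = windows, trimmed_windows = trimmed,
    new_coding = new_coding,
    new_pseudogenes = if (length(pseudo_rows)) do.call(rbind, pseudo_rows)
      else data.frame(window_id = character(0), seqid = character(0),
                      target_start = integer(0), target_end = integer(0),
                      strand = character(0), class = character(0),
                      low_confidence = logical(0)),
    rejected = if (length(rej_rows)) do.call(rbind, rej_rows)
      else data.frame(window_id = character(0), seqid = character(0),
                      target_start = integer(0), target_end = integer(0),
                      strand = character(0), reason = character(0))),
    class = "ctt_catalog")
}

#' @export
print.ctt_catalog <- function(x, ...) {
  cat("ctt_catalog:", x$genome_id, "\n")
  cat("  prior members:   ", length(x$prior_proteins), "\n")
  cat("  new coding:      ", length(x$new_coding), "\n")
  cat("  new pseudogenes: ", nrow(x$new_pseudogenes), "\n")
  cat("  rejected windows:", nrow(x$rejected), "\n")
  invisible(x)
}
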