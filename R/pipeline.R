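#' Default pipeline configuration
#'
#' Inputs may be file paths (FASTA / GFF3) or the data frames the readers
#' produce; thresholds default to the documented per-module values.
#'
#' @param reference Reference mature miRNA set (path or data frame with
#'   \code{name}/\code{id} and \code{seq}).
#' @param ests_female,ests_male Per-sex EST collections.
#' @param protein_db,ncrna_db Optional decoy databases for the exclusion
#'   screen.
#' @param transcripts Target transcript set (for \code{\link{run_full}}).
#' @param genome Chromosome assembly (for \code{\link{run_full}}).
#' @param annotations Optional gene features (GFF3 path or data frame).
#' @param reads_female,reads_male Per-sex read sets (for expression).
#' @param locus Gender-locus interval \code{"chrom:start-end"}.
#' @param max_mismatches Homology-scan mismatch budget (default 2: the
#'   literal "fewer than three mismatches").
#' @param window Precursor window grid \code{c(min_len, max_len, step)}.
#' @param criteria Named overrides for
#'   \code{\link{evaluate_criteria}} thresholds.
#' @param screen Named overrides: \code{min_identity},
#'   \code{min_coverage}.
#' @param max_expectation Target-prediction cutoff (default 3.0).
#' @param read_max_mismatches Read-mapping budget (default 2).
#' @param pseudocount log2 pseudocount (default 1).
#' @param candidate_mode \code{"strict"} or \code{"lenient"} locus
#'   candidate rule.
#' @param name_prefix Species prefix for assigned miRNA names.
#' @param out_dir Optional directory for TSV reports and the run log.
#' @return Config list for \code{\link{run_discovery}} /
#'   \code{\link{run_full}}.
#' @export
pipeline_config <- function(reference, ests_female, ests_male,
                            protein_db = NULL, ncrna_db = NULL,
                            transcripts = NULL, genome = NULL,
                            annotations = NULL, reads_female = NULL,
                            reads_male = NULL, locus = NULL,
                            max_mismatches = 2L,
                            window = c(50L, 350L, 10L),
                            criteria = list(), screen = list(),
                            max_expectation = 3.0,
                            read_max_mismatches = 2L, pseudocount = 1,
                            candidate_mode = "strict",
                            name_prefix = "ssu", out_dir = NULL) {
  list(reference = reference, ests_female = ests_female,
       ests_male = ests_male, protein_db = protein_db,
       ncrna_db = ncrna_db, transcripts = transcripts, genome = genome,
       annotations = annotations, reads_female = reads_female,
       reads_male = reads_male, locus = locus,
       max_mismatches = max_mismatches, window = window,
       criteria = criteria, screen = screen,
       max_expectation = max_expectation,
       read_max_mismatches = read_max_mismatches,
       pseudocount = pseudocount, candidate_mode = candidate_mode,
       name_prefix = name_prefix, out_dir = out_dir)
}

# Resolve an input that is either a path or an already-read data frame.
as_seq_records <- function(x, what, policy = "dna_to_rna") {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing input file for ", what, ": ", x)
    x <- read_fasta(x, policy)
  }
  stopifnot(is.data.frame(x))
  if (!"id" %in% names(x) && "name" %in% names(x))
    names(x)[names(x) == "name"] <- "id"
  x
}

as_annotations <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(read_gff3_genes(x))
  x
}

#' Run the discovery stage: homology scan, exclusion, hairpin validation
#'
#' Executes the sequential discovery funnel on each sex: deduplicate the
#' reference, scan ESTs for near-copies of mature miRNAs, screen the
#' matched ESTs against coding/ncRNA decoys, fold candidate windows and
#' keep the best validated hairpin per hit, and assign species-style
#' names. Per-stage survivor counts are logged.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with \code{refs} (deduplicated reference), per-sex lists
#'   (\code{female}, \code{male}: \code{hits}, \code{screen},
#'   \code{validated}, \code{inventory}, \code{funnel}),
#'   \code{comparison_family}, \code{comparison_sequence},
#'   \code{length_stats}, \code{log} (character vector). TSV reports are
#'   written when \code{config$out_dir} is set.
#' @export
run_discovery <- function(config) {
  cfg <- config
  log <- c(sprintf("mirhunt discovery run"),
           sprintf("max_mismatches=%d (reading 'fewer than three mismatches' literally as <=2 unless overridden)",
                   cfg$max_mismatches),
           sprintf("window grid: %d..%d step %d", cfg$window[1],
                   cfg$window[2], cfg$window[3]))
  reference <- as_seq_records(cfg$reference, "reference")
  ref_in <- data.frame(name = reference$id, seq = reference$seq,
                       stringsAsFactors = FALSE)
  refs <- dedupe_reference(ref_in)
  log <- c(log, sprintf("reference: %d entries -> %d nonredundant",
                        nrow(ref_in), nrow(refs)))
  sexes <- list(female = as_seq_records(cfg$ests_female, "female ESTs"),
                male = as_seq_records(cfg$ests_male, "male ESTs"))
  protein_db <- as_seq_records(cfg$protein_db, "protein decoys",
                               policy = "protein")
  ncrna_db <- as_seq_records(cfg$ncrna_db, "ncRNA decoys")
  screen_args <- utils::modifyList(list(min_identity = 0.8,
                                        min_coverage = 0.6), cfg$screen)
  out <- list(refs = refs)
  for (sx in names(sexes)) {
    ests <- sexes[[sx]]
    hits <- scan_homology(ests, refs, cfg$max_mismatches)
    est_hit <- unique(hits$est_id)
    # exclusion screen on the matched ESTs (candidate precursor carriers)
    screen_in <- data.frame(candidate_id = est_hit,
                            seq = ests$seq[match(est_hit, ests$id)],
                            stringsAsFactors = FALSE)
    decisions <- screen_candidates(screen_in, protein_db, ncrna_db,
                                   min_identity = screen_args$min_identity,
                                   min_coverage = screen_args$min_coverage)
    kept_ests <- decisions$candidate_id[decisions$verdict == "keep"]
    hits_kept <- hits[hits$est_id %in% kept_ests, , drop = FALSE]
    validated <- validate_hits(hits_kept, ests, cfg)
    validated <- assign_names(validated, prefix = cfg$name_prefix)
    inventory <- build_inventory(validated)
    funnel <- c(n_ests = nrow(ests), n_ests_with_hit = length(est_hit),
                n_ests_after_screen = length(kept_ests),
                n_hits_after_screen = nrow(hits_kept),
                n_validated = nrow(validated))
    log <- c(log, sprintf(
      "%s: %d ESTs; %d with homology hit; %d after coding/ncRNA screen; %d validated precursors",
      sx, funnel["n_ests"], funnel["n_ests_with_hit"],
      funnel["n_ests_after_screen"], funnel["n_validated"]))
    out[[sx]] <- list(hits = hits, screen = decisions,
                      validated = validated, inventory = inventory,
                      funnel = funnel)
  }
  out$comparison_family <- family_sets(out$female$inventory,
                                       out$male$inventory, by = "family")
  out$comparison_sequence <- family_sets(out$female$inventory,
                                         out$male$inventory,
                                         by = "sequence")
  all_rows <- rbind(out$female$inventory, out$male$inventory)
  out$length_stats <- if (nrow(all_rows) > 0L)
    length_distribution(all_rows) else NULL
  out$log <- log
  if (!is.null(cfg$out_dir)) write_discovery_reports(out, cfg$out_dir)
  out
}

# Fold the window grid for each hit and keep the best validated hairpin.
validate_hits <- function(hits, ests, cfg) {
  empty <- data.frame(est_id = character(), window_start = integer(),
                      window_end = integer(), strand = character(),
                      LP = integer(), arm = character(),
                      mature_seq = character(), family = character(),
                      ref_name = character(), mismatches = integer(),
                      score = numeric(), amfe = numeric(), mfei = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    hit <- hits[h, , drop = FALSE]
    est <- ests[ests$id == hit$est_id, , drop = FALSE]
    cands <- extract_candidates(hit, est, min_len = cfg$window[1],
                                max_len = cfg$window[2],
                                step = cfg$window[3])
    cands <- cands[nchar(cands$seq) >= 30L, , drop = FALSE]
    if (nrow(cands) == 0L) next
    structures <- lapply(cands$seq, fold_hairpin)
    reports <- lapply(seq_len(nrow(cands)), function(i)
      evaluate_criteria(cands[i, ], structures[[i]], cfg$criteria))
    pick <- select_best(cands, structures, reports)
    if (!pick$accepted) next
    cand <- pick$candidate
    mature <- substr(cand$seq, cand$mature_offset,
                     cand$mature_offset + cand$mature_len - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      est_id = cand$est_id, window_start = cand$window_start,
      window_end = cand$window_end, strand = cand$strand, LP = cand$LP,
      arm = pick$report$arm, mature_seq = mature,
      family = family_of(cand$ref_name), ref_name = cand$ref_name,
      mismatches = cand$mismatches, score = pick$structure$score,
      amfe = pick$report$amfe, mfei = pick$report$mfei,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline: discovery, targets, expression, locus mapping
#'
#' @param config A \code{\link{pipeline_config}} with \code{transcripts},
#'   \code{genome}, \code{reads_female}, \code{reads_male} and
#'   \code{locus} set.
#' @return The \code{\link{run_discovery}} result plus \code{mirnas}
#'   (union mature set with presence), \code{mirna_mature} (name to
#'   mature-sequence map), \code{sites}, \code{target_counts},
#'   \code{profiles}, \code{anticorrelation}, \code{placements},
#'   \code{unplaced}, \code{regulator_classes}, \code{distribution},
#'   \code{locus_candidates}.
#' @export
run_full <- function(config) {
  cfg <- config
  disc <- run_discovery(config)
  transcripts <- as_seq_records(cfg$transcripts, "transcripts")
  if (is.null(transcripts)) stop("run_full needs a transcript set")
  genome <- as_seq_records(cfg$genome, "genome")
  if (is.null(genome)) stop("run_full needs a genome assembly")
  annotations <- as_annotations(cfg$annotations)
  if (is.null(cfg$locus)) stop("run_full needs a locus interval")
  locus <- validate_locus(cfg$locus, genome)

  mirnas <- union_mirnas(disc$female$inventory, disc$male$inventory)
  disc$mirnas <- mirnas
  disc$mirna_mature <- stats::setNames(mirnas$seq, mirnas$name)
  sites <- if (nrow(mirnas) > 0L)
    find_targets(mirnas, transcripts,
                 max_expectation = cfg$max_expectation)
  else
    find_targets(data.frame(name = character(), seq = character()),
                 transcripts)
  disc$sites <- sites
  disc$target_counts <- per_mirna_target_counts(sites)

  reads_f <- as_seq_records(cfg$reads_female, "female reads")
  reads_m <- as_seq_records(cfg$reads_male, "male reads")
  profiles <- expression_profiles(transcripts, reads_f, reads_m,
                                  max_mismatches = cfg$read_max_mismatches,
                                  pseudocount = cfg$pseudocount)
  disc$profiles <- profiles
  presence <- data.frame(mirna_name = mirnas$name,
                         presence = mirnas$presence,
                         stringsAsFactors = FALSE)
  disc$anticorrelation <- anticorrelation_report(presence, sites, profiles)

  targeted <- transcripts[transcripts$id %in% sites$transcript_id, ,
                          drop = FALSE]
  pl <- place_targets(targeted, genome, annotations)
  disc$placements <- pl$placements
  disc$unplaced <- pl$unplaced
  disc$regulator_classes <- target_regulator_class(sites, presence)
  disc$distribution <- chromosome_distribution(pl$placements,
                                               disc$regulator_classes)
  disc$locus_candidates <- flag_locus_candidates(pl$placements, locus,
                                                 sites, presence, profiles,
                                                 mode = cfg$candidate_mode)
  disc$log <- c(disc$log,
                sprintf("targets: %d sites on %d transcripts; %d placed; %d locus candidate(s)",
                        nrow(sites), length(unique(sites$transcript_id)),
                        nrow(pl$placements), nrow(disc$locus_candidates)))
  if (!is.null(cfg$out_dir)) write_full_reports(disc, cfg$out_dir)
  disc
}

# Union of the two per-sex validated mature sets: one row per distinct
# mature sequence with a canonical name and a presence class.
union_mirnas <- function(inv_f, inv_m) {
  seqs <- sort(unique(c(inv_f$seq, inv_m$seq)))
  if (length(seqs) == 0L)
    return(data.frame(name = character(), seq = character(),
                      presence = character(), stringsAsFactors = FALSE))
  nm_f <- inv_f$name[match(seqs, inv_f$seq)]
  nm_m <- inv_m$name[match(seqs, inv_m$seq)]
  presence <- ifelse(!is.na(nm_f) & !is.na(nm_m), "both",
                     ifelse(!is.na(nm_f), "female", "male"))
  name <- ifelse(is.na(nm_f), nm_m, nm_f)
  name <- make.unique(name, sep = "_v")
  data.frame(name = name, seq = seqs, presence = presence,
             stringsAsFactors = FALSE)
}

write_discovery_reports <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sx in c("female", "male")) {
    write_tsv_report(res[[sx]]$hits, file.path(dir,
                                               paste0("hits_", sx, ".tsv")))
    write_tsv_report(res[[sx]]$screen,
                     file.path(dir, paste0("screen_", sx, ".tsv")))
    write_tsv_report(res[[sx]]$inventory,
                     file.path(dir, paste0("inventory_", sx, ".tsv")))
  }
  comp <- comparison_as_table(res$comparison_sequence)
  write_tsv_report(comp, file.path(dir, "comparison_sequence.tsv"))
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

comparison_as_table <- function(cmp) {
  do.call(rbind, lapply(names(cmp), function(k) {
    if (length(cmp[[k]]) == 0L) return(NULL)
    data.frame(group = k,
               name = if (!is.null(names(cmp[[k]]))) names(cmp[[k]])
                      else cmp[[k]],
               key = unname(cmp[[k]]), stringsAsFactors = FALSE)
  }))
}

write_full_reports <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_report(res$sites[, setdiff(names(res$sites),
                                       c("aln_mirna", "aln_match",
                                         "aln_target"))],
                   file.path(dir, "target_sites.tsv"))
  write_tsv_report(res$target_counts, file.path(dir, "target_counts.tsv"))
  write_tsv_report(res$profiles, file.path(dir, "expression.tsv"))
  write_tsv_report(res$anticorrelation,
                   file.path(dir, "anticorrelation.tsv"))
  write_tsv_report(res$placements, file.path(dir, "placements.tsv"))
  write_tsv_report(res$distribution,
                   file.path(dir, "chromosome_distribution.tsv"))
  write_tsv_report(res$locus_candidates,
                   file.path(dir, "locus_candidates.tsv"))
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
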