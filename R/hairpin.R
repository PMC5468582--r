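#' Fold a candidate precursor into its best stem-loop
#'
#' Hairpin-restricted folding: over all loop placements, the 5' side of
#' the sequence is globally aligned against the reverse complement of the
#' 3' side. Aligned columns forming an allowed pair (G:C, A:U, G:U wobble)
#' take the pair score; aligned non-pairable columns (internal-loop
#' mismatches) cost 0; a bulge run of length g costs
#' \code{gap_open + g * gap_extend}. The returned structure minimizes the
#' total score over all splits with loop length at least \code{min_loop};
#' ties prefer the smallest loop, then the leftmost. The score plays the
#' role of a minimum-free-energy proxy: more negative means a more stable
#' stem.
#'
#' @param seq RNA string (A/C/G/U/N), 30-1000 nt, at most 10\% N.
#' @param pair_scores Named numeric vector with elements \code{GC},
#'   \code{AU}, \code{GU} (all negative).
#' @param gap_open,gap_extend Positive bulge penalties (per run / per
#'   position).
#' @param min_loop Minimum loop length in nt.
#' @return A list of class \code{hairpin} with elements \code{score},
#'   \code{pairs} (two-column matrix of 1-based paired positions),
#'   \code{arm5}, \code{arm3}, \code{loop} (1-based inclusive intervals;
#'   an empty arm has \code{start > end}), \code{dotbracket}, \code{seq}.
#' @export
fold_hairpin <- function(seq, pair_scores = c(GC = -3, AU = -2, GU = -1),
                         gap_open = 4, gap_extend = 1, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 30L || n > 1000L)
    stop("fold_hairpin: sequence length ", n, " outside [30, 1000]")
  n_count <- lengths(regmatches(seq, gregexpr("N", seq)))
  if (n_count / n > 0.10)
    stop("fold_hairpin: more than 10% N in sequence")
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_scores)),
            all(pair_scores[c("GC", "AU", "GU")] < 0),
            gap_open > 0, gap_extend > 0, min_loop >= 0)
  res <- fold_hairpin_cpp(seq, pair_scores[["GC"]], pair_scores[["AU"]],
                          pair_scores[["GU"]], gap_open, gap_extend,
                          as.integer(min_loop))
  structure(list(
    score = res$score,
    pairs = cbind(i = res$pair_i, j = res$pair_j),
    arm5 = c(start = 1L, end = res$arm5_end),
    arm3 = c(start = res$arm3_start, end = n),
    loop = c(start = res$loop_start, end = res$loop_end),
    dotbracket = res$dotbracket,
    seq = seq
  ), class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat("Hairpin fold: score", format(x$score), "|",
      nrow(x$pairs), "pairs | loop",
      x$loop["start"], "-", x$loop["end"], "\n")
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

#' Apply plant pre-miRNA acceptance criteria to a folded candidate
#'
#' Checks the standard homology-prediction criteria for plant precursor
#' miRNAs: the mature sequence must sit entirely within one stem arm, pair
#' extensively with the opposite arm (few star-strand mismatches, no long
#' unpaired run), both mature ends must fall in paired or near-paired stem
#' context (a Dicer-site proxy), and the fold must be energetically
#' miRNA-like as measured by MFEI. AMFE is \code{score / LP * 100}; MFEI
#' is \code{|AMFE| / (GC\% )}.
#'
#' @param candidate A one-row candidate data frame as produced by
#'   \code{\link{extract_candidates}} (needs \code{seq},
#'   \code{mature_offset}, \code{mature_len}), or a list with those
#'   fields.
#' @param structure A \code{hairpin} object folded from
#'   \code{candidate$seq}.
#' @param thresholds Named list: \code{max_star_mismatches} (default 6),
#'   \code{max_unpaired_run} (4), \code{min_mfei} (0.85),
#'   \code{min_paired_fraction_mature} (0.6), \code{dicer_end_slack} (2).
#' @return A list of class \code{criteria_report}: \code{mature_in_one_arm},
#'   \code{arm} ("5p"/"3p"/NA), \code{star_mismatches},
#'   \code{max_unpaired_run_in_mature}, \code{paired_fraction_mature},
#'   \code{amfe}, \code{mfei}, \code{gc}, \code{passed}, \code{failed_rules}.
#' @export
evaluate_criteria <- function(candidate, structure,
                              thresholds = list()) {
  th <- utils::modifyList(list(max_star_mismatches = 6L,
                               max_unpaired_run = 4L,
                               min_mfei = 0.85,
                               min_paired_fraction_mature = 0.6,
                               dicer_end_slack = 2L), thresholds)
  seq <- candidate$seq
  n <- nchar(seq)
  stopifnot(identical(structure$seq, seq))
  m0 <- candidate$mature_offset          # 1-based start of mature in window
  lm <- candidate$mature_len
  m1 <- m0 + lm - 1L
  if (m0 < 1L || m1 > n) stop("mature span outside candidate window")
  mature_pos <- m0:m1

  in5 <- structure$arm5["end"] >= m1
  in3 <- structure$arm3["start"] <= m0
  mature_in_one_arm <- in5 || in3
  arm <- if (in5) "5p" else if (in3) "3p" else NA_character_

  paired <- rep(FALSE, n)
  if (nrow(structure$pairs) > 0)
    paired[c(structure$pairs[, 1], structure$pairs[, 2])] <- TRUE
  star_mismatches <- sum(!paired[mature_pos])
  runs <- rle(paired[mature_pos])
  unp <- runs$lengths[!runs$values]
  max_run <- if (length(unp)) max(unp) else 0L
  paired_frac <- mean(paired[mature_pos])

  # Dicer-site proxy: each mature end lies at, or within dicer_end_slack nt
  # of, a paired stem position
  paired_idx <- which(paired)
  end_ok <- function(p) {
    length(paired_idx) > 0 && min(abs(paired_idx - p)) <= th$dicer_end_slack
  }
  dicer_ok <- end_ok(m0) && end_ok(m1)

  gc <- gc_fraction(seq)
  amfe <- structure$score / n * 100
  mfei <- if (gc > 0) abs(amfe) / (gc * 100) else 0

  failed <- character()
  if (!mature_in_one_arm) failed <- c(failed, "mature_in_loop")
  if (star_mismatches > th$max_star_mismatches)
    failed <- c(failed, "star_mismatches")
  if (max_run > th$max_unpaired_run) failed <- c(failed, "unpaired_run")
  if (paired_frac < th$min_paired_fraction_mature)
    failed <- c(failed, "paired_fraction")
  if (!dicer_ok) failed <- c(failed, "dicer_site")
  if (mfei < th$min_mfei) failed <- c(failed, "mfei")

  structure(list(mature_in_one_arm = mature_in_one_arm, arm = arm,
                 star_mismatches = star_mismatches,
                 max_unpaired_run_in_mature = max_run,
                 paired_fraction_mature = paired_frac,
                 amfe = amfe, mfei = mfei, gc = gc,
                 passed = length(failed) == 0L, failed_rules = failed),
            class = "criteria_report")
}

#' Pick the best validated precursor window for one homology hit
#'
#' Among windows passing the criteria the winner has the lowest AMFE
#' (structure score per 100 nt); ties prefer higher MFEI, then the
#' shorter window. Length normalization matters: the raw score of a
#' window only ever improves as random flank is appended (spurious flank
#' pairings score negatively), so the per-length score is what identifies
#' the actual hairpin boundaries. When no window passes, a rejection
#' carrying the union of failure reasons is returned.
#'
#' @param candidates Candidate data frame from
#'   \code{\link{extract_candidates}} (all rows from one hit).
#' @param structures List of \code{hairpin} objects, parallel to rows.
#' @param reports List of \code{criteria_report} objects, parallel to rows.
#' @return A list with \code{accepted} (logical); if accepted:
#'   \code{candidate} (one-row data frame), \code{structure},
#'   \code{report}; else \code{failed_rules} (character union).
#' @export
select_best <- function(candidates, structures, reports) {
  if (nrow(candidates) == 0L) stop("select_best: empty candidate list")
  stopifnot(length(structures) == nrow(candidates),
            length(reports) == nrow(candidates))
  pass <- vapply(reports, function(r) r$passed, logical(1))
  if (!any(pass)) {
    return(list(accepted = FALSE,
                failed_rules = sort(unique(unlist(
                  lapply(reports, function(r) r$failed_rules))))))
  }
  idx <- which(pass)
  amfe <- vapply(reports[idx], function(r) r$amfe, numeric(1))
  mfei <- vapply(reports[idx], function(r) r$mfei, numeric(1))
  lp <- nchar(candidates$seq[idx])
  ord <- order(amfe, -mfei, lp)
  best <- idx[ord[1]]
  list(accepted = TRUE, candidate = candidates[best, , drop = FALSE],
       structure = structures[[best]], report = reports[[best]])
}

#' Assign species-style names to validated precursors
#'
#' Within each family (and one sex), members are lettered a, b, c, ... in
#' order of EST id then window start. Single-member families keep the bare
#' family name unless \code{letters_always} is set.
#'
#' @param validated Data frame with columns \code{family}, \code{est_id},
#'   \code{window_start} (one row per validated precursor).
#' @param prefix Species prefix for the names (default \code{"ssu"}).
#' @param letters_always Letter single-member families too?
#' @return \code{validated} with a \code{name} column added.
#' @export
assign_names <- function(validated, prefix = "ssu", letters_always = FALSE) {
  if (nrow(validated) == 0L) {
    validated$name <- character(0)
    return(validated)
  }
  validated$name <- NA_character_
  for (fam in sort(unique(validated$family))) {
    rows <- which(validated$family == fam)
    rows <- rows[order(validated$est_id[rows], validated$window_start[rows])]
    num <- sub("^miR", "", fam)
    if (length(rows) == 1L && !letters_always) {
      validated$name[rows] <- paste0(prefix, "-miR", num)
    } else {
      validated$name[rows] <- paste0(prefix, "-miR", num,
                                     letters[seq_along(rows)])
    }
  }
  validated
}
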