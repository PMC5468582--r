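#' Place target genes on chromosome assemblies
#'
#' A target with a matching annotation record is placed from the
#' annotation (source \code{"gff"}); otherwise its sequence is located by
#' exact substring search on both strands of the assembly (source
#' \code{"exact_match"}), taking the first chromosome in assembly order
#' and the leftmost coordinate (plus strand first) on ties. When an
#' annotated target is also found by sequence search on a different
#' chromosome, the disagreement is an error listing both placements.
#'
#' @param targets Data frame of target transcripts (\code{id}, \code{seq}).
#' @param genome Data frame of chromosome sequences (\code{id},
#'   \code{seq}), non-empty.
#' @param annotations Optional gene-feature data frame as returned by
#'   \code{\link{read_gff3_genes}} (\code{seqid}, \code{start}, \code{end},
#'   \code{strand}, \code{ID}); may be NULL or empty.
#' @return List with \code{placements} (data frame \code{target_id},
#'   \code{chrom}, \code{start}, \code{end} 1-based inclusive,
#'   \code{strand}, \code{source}) and \code{unplaced} (character vector
#'   of target ids found nowhere).
#' @export
place_targets <- function(targets, genome, annotations = NULL) {
  if (is.null(genome) || nrow(genome) == 0L) stop("empty genome")
  chrom_set <- Biostrings::RNAStringSet(genome$seq)
  names(chrom_set) <- genome$id
  ann <- if (!is.null(annotations) && nrow(annotations) > 0L) annotations
         else NULL
  rows <- list()
  unplaced <- character(0)
  for (i in seq_len(nrow(targets))) {
    tid <- targets$id[i]
    found <- search_exact(targets$seq[i], genome)
    a <- if (!is.null(ann)) ann[ann$ID == tid, , drop = FALSE] else NULL
    if (!is.null(a) && nrow(a) > 0L) {
      a <- a[1, , drop = FALSE]
      if (!a$seqid %in% genome$id)
        stop("annotation chromosome not in assembly: ", a$seqid)
      if (!is.null(found) && found$chrom != a$seqid)
        stop("placement conflict for ", tid, ": annotation says ", a$seqid,
             ":", a$start, "-", a$end, " but sequence search finds ",
             found$chrom, ":", found$start, "-", found$end)
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = tid, chrom = a$seqid, start = a$start,
                   end = a$end, strand = a$strand, source = "gff",
                   stringsAsFactors = FALSE)
    } else if (!is.null(found)) {
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = tid, chrom = found$chrom,
                   start = found$start, end = found$end,
                   strand = found$strand, source = "exact_match",
                   stringsAsFactors = FALSE)
    } else {
      unplaced <- c(unplaced, tid)
    }
  }
  placements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               source = character(), stringsAsFactors = FALSE)
  rownames(placements) <- NULL
  list(placements = placements, unplaced = unplaced)
}

# First exact occurrence of seq in the genome: chromosomes in assembly
# order, plus strand before minus, leftmost coordinate.
search_exact <- function(seq, genome) {
  rc <- revcomp_rna(seq)
  for (ci in seq_len(nrow(genome))) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else rc
      m <- Biostrings::matchPattern(pat, Biostrings::RNAString(
        genome$seq[ci]), max.mismatch = 0, fixed = TRUE)
      if (length(m) > 0L)
        hits[[length(hits) + 1L]] <-
          data.frame(start = BiocGenerics::start(m)[1],
                     end = BiocGenerics::end(m)[1], strand = strand,
                     stringsAsFactors = FALSE)
    }
    if (length(hits) > 0L) {
      h <- do.call(rbind, hits)
      h <- h[order(h$start, h$strand), , drop = FALSE]
      return(list(chrom = genome$id[ci], start = h$start[1], end = h$end[1],
                  strand = h$strand[1]))
    }
  }
  NULL
}

#' Flag gender-locus candidate genes
#'
#' A target is flagged when all three clauses hold: (1) its placement
#' overlaps the configured gender-locus interval by at least 1 bp
#' (1-based inclusive coordinates); (2) it carries at least one predicted
#' site of a miRNA detected in exactly one sex; (3) its expression class
#' is single-sex - in \code{"strict"} mode the expressed sex must differ
#' from the regulator's sex (the silencing logic: a male-specific miRNA
#' silencing its target in males leaves female-only expression), in
#' \code{"lenient"} mode any single-sex class qualifies.
#'
#' @param placements Placement data frame from \code{\link{place_targets}}.
#' @param locus List or vector with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive), or a string \code{"chrom:start-end"}.
#' @param sites Target sites from \code{\link{find_targets}}.
#' @param mirna_presence Data frame (\code{mirna_name}, \code{presence}).
#' @param profiles Expression profiles with \code{class} set.
#' @param mode \code{"strict"} (default) or \code{"lenient"}.
#' @return Data frame: \code{target_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{regulator}, \code{regulator_specificity},
#'   \code{expression_class}, \code{rationale}.
#' @export
flag_locus_candidates <- function(placements, locus, sites, mirna_presence,
                                  profiles, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  locus <- parse_locus(locus)
  known_chroms <- unique(placements$chrom)
  if (!is.null(attr(placements, "chroms")))
    known_chroms <- attr(placements, "chroms")
  empty <- data.frame(target_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      regulator = character(),
                      regulator_specificity = character(),
                      expression_class = character(),
                      rationale = character(), stringsAsFactors = FALSE)
  spec_mirs <- mirna_presence[mirna_presence$presence %in%
                              c("female", "male"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    if (p$chrom != locus$chrom) next
    if (p$end < locus$start || p$start > locus$end) next   # clause 1
    s <- sites[sites$transcript_id == p$target_id &
               sites$mirna_name %in% spec_mirs$mirna_name, , drop = FALSE]
    if (nrow(s) == 0L) next                                 # clause 2
    prof <- profiles[profiles$target_id == p$target_id, , drop = FALSE]
    if (nrow(prof) == 0L) next
    cls <- prof$class[1]
    if (!cls %in% c("female_only", "male_only")) next       # clause 3
    expressed_sex <- sub("_only", "", cls)
    s$reg_sex <- spec_mirs$presence[match(s$mirna_name,
                                          spec_mirs$mirna_name)]
    if (mode == "strict")
      s <- s[s$reg_sex != expressed_sex, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$expectation, s$mirna_name), , drop = FALSE]
    reg <- s$mirna_name[1]; reg_sex <- s$reg_sex[1]
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = p$target_id, chrom = p$chrom, start = p$start,
      end = p$end, regulator = reg, regulator_specificity = reg_sex,
      expression_class = cls,
      rationale = paste0("in_locus(", locus$chrom, ":", locus$start, "-",
                         locus$end, ");", reg_sex, "_specific_regulator(",
                         reg, ");expression_", cls),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

parse_locus <- function(locus) {
  if (is.character(locus) && length(locus) == 1L) {
    m <- regmatches(locus,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", locus))[[1]]
    if (length(m) != 4L) stop("cannot parse locus string: ", locus)
    locus <- list(chrom = m[2], start = as.integer(m[3]),
                  end = as.integer(m[4]))
  }
  locus <- as.list(locus)
  stopifnot(all(c("chrom", "start", "end") %in% names(locus)))
  locus$start <- as.integer(locus$start)
  locus$end <- as.integer(locus$end)
  if (locus$start > locus$end) stop("locus start > end")
  locus
}

#' Check that the locus chromosome exists in an assembly
#' @param locus Locus specification (see
#'   \code{\link{flag_locus_candidates}}).
#' @param genome Genome data frame (\code{id}, \code{seq}).
#' @return The parsed locus, invisibly; errors when the chromosome is
#'   absent.
#' @export
validate_locus <- function(locus, genome) {
  locus <- parse_locus(locus)
  if (!locus$chrom %in% genome$id)
    stop("locus chromosome not in assembly: ", locus$chrom)
  invisible(locus)
}

#' Regulator class of each targeted transcript
#'
#' Assigns each target one regulator class: \code{female_specific} or
#' \code{male_specific} when a sex-specific miRNA targets it (among those,
#' the minimal-expectation site decides; ties female first), else
#' \code{common}.
#'
#' @param sites Target sites from \code{\link{find_targets}}.
#' @param mirna_presence Data frame (\code{mirna_name}, \code{presence}).
#' @return Data frame \code{target_id}, \code{regulator_class}.
#' @export
target_regulator_class <- function(sites, mirna_presence) {
  if (nrow(sites) == 0L)
    return(data.frame(target_id = character(),
                      regulator_class = character(),
                      stringsAsFactors = FALSE))
  pres <- stats::setNames(mirna_presence$presence,
                          mirna_presence$mirna_name)
  rows <- lapply(split(seq_len(nrow(sites)), sites$transcript_id),
                 function(idx) {
    s <- sites[idx, , drop = FALSE]
    s$p <- pres[s$mirna_name]
    sx <- s[s$p %in% c("female", "male"), , drop = FALSE]
    cls <- if (nrow(sx) == 0L) "common" else {
      sx <- sx[order(sx$expectation, sx$p), , drop = FALSE]
      paste0(sx$p[1], "_specific")
    }
    data.frame(target_id = s$transcript_id[1], regulator_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chromosome distribution of placed targets by regulator class
#'
#' @param placements Placement data frame from \code{\link{place_targets}}.
#' @param regulator_classes Data frame from
#'   \code{\link{target_regulator_class}}.
#' @return Data frame with one row per chromosome and columns
#'   \code{chrom}, \code{common}, \code{female_specific},
#'   \code{male_specific}, \code{total}; column sums over \code{total}
#'   equal the number of placed (and classified) targets.
#' @export
chromosome_distribution <- function(placements, regulator_classes) {
  if (nrow(placements) == 0L)
    return(data.frame(chrom = character(), common = integer(),
                      female_specific = integer(),
                      male_specific = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  cls <- regulator_classes$regulator_class[
    match(placements$target_id, regulator_classes$target_id)]
  cls[is.na(cls)] <- "common"
  lv <- c("common", "female_specific", "male_specific")
  tab <- table(factor(placements$chrom), factor(cls, levels = lv))
  out <- data.frame(chrom = rownames(tab),
                    common = as.integer(tab[, "common"]),
                    female_specific = as.integer(tab[, "female_specific"]),
                    male_specific = as.integer(tab[, "male_specific"]),
                    stringsAsFactors = FALSE)
  out$total <- out$common + out$female_specific + out$male_specific
  rownames(out) <- NULL
  out
}
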