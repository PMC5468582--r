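#' Score a miRNA-target alignment by the expectation penalty scheme
#'
#' The expectation is the penalty sum over alignment columns: perfect
#' Watson-Crick pair 0, G:U wobble 0.5, mismatch 1.0, each gap position
#' 2.0; penalties are doubled at miRNA positions 2-13 counted from the
#' miRNA 5' end (the seed-extended region). An expectation of 0 means
#' perfect complementarity.
#'
#' @param mirna_aln miRNA alignment string, 5' to 3', \code{"-"} for a gap
#'   (target bulge).
#' @param target_aln Target-site alignment string written 3' to 5' so the
#'   columns line up antiparallel, \code{"-"} for a gap (miRNA bulge).
#' @param penalties Named list \code{mismatch}, \code{gu}, \code{gap}
#'   (defaults 1.0, 0.5, 2.0).
#' @param seed Integer vector \code{c(lo, hi)} of doubled miRNA positions
#'   (default \code{c(2, 13)}).
#' @return The expectation score (a single non-negative number).
#' @export
score_alignment <- function(mirna_aln, target_aln,
                            penalties = list(mismatch = 1.0, gu = 0.5,
                                             gap = 2.0),
                            seed = c(2L, 13L)) {
  m <- strsplit(mirna_aln, "")[[1]]
  t <- strsplit(target_aln, "")[[1]]
  if (length(m) != length(t))
    stop("alignment strings differ in length")
  ok <- c("A", "C", "G", "U", "N", "-")
  if (any(!m %in% ok) || any(!t %in% ok))
    stop("non-nucleotide symbol in alignment")
  if (any(m == "-" & t == "-")) stop("double-gap alignment column")
  mir_pos <- cumsum(m != "-")      # miRNA position of/after each column
  total <- 0
  for (k in seq_along(m)) {
    pos <- if (m[k] == "-") mir_pos[k] + 1L else mir_pos[k]
    mult <- if (pos >= seed[1] && pos <= seed[2]) 2 else 1
    pen <-
      if (m[k] == "-" || t[k] == "-") penalties$gap
      else if (is_wc_pair(m[k], t[k])) 0
      else if (is_wobble(m[k], t[k])) penalties$gu
      else penalties$mismatch
    total <- total + pen * mult
  }
  total
}

is_wc_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG")
}

is_wobble <- function(a, b) {
  paste0(a, b) %in% c("GU", "UG")
}

#' Predict miRNA target sites on transcripts by complementarity
#'
#' Every transcript position is aligned against each miRNA (antiparallel,
#' permitting at most one bulge per alignment side) and scored with the
#' expectation penalty scheme of \code{\link{score_alignment}}. Sites with
#' expectation at most \code{max_expectation} are reported; among
#' overlapping sites of one (miRNA, transcript) pair only the
#' minimal-expectation site is kept (ties: leftmost). A site is classified
#' as translational inhibition when the central miRNA positions 9-11
#' contain a mismatch or gap, and as cleavage otherwise.
#'
#' @param mirnas Data frame of mature miRNAs (\code{name}, \code{seq}).
#' @param transcripts Data frame of mRNA-sense transcripts (\code{id},
#'   \code{seq}).
#' @param max_expectation Reporting cutoff (default 3.0).
#' @param scan_len Minimum transcript length scanned (shorter transcripts
#'   are skipped; default 20).
#' @param allow_gaps Permit one bulge per alignment side (default TRUE).
#' @param penalties,seed As in \code{\link{score_alignment}}.
#' @param central Central window positions \code{c(lo, hi)} deciding the
#'   inhibition mode (default \code{c(9, 11)}).
#' @return Data frame: \code{mirna_name}, \code{transcript_id},
#'   \code{site_start}, \code{site_end} (1-based inclusive),
#'   \code{expectation}, \code{mode} ("cleavage"/"translation"),
#'   \code{aln_mirna}, \code{aln_match}, \code{aln_target} (target written
#'   3' to 5').
#' @export
find_targets <- function(mirnas, transcripts, max_expectation = 3.0,
                         scan_len = 20L, allow_gaps = TRUE,
                         penalties = list(mismatch = 1.0, gu = 0.5,
                                          gap = 2.0),
                         seed = c(2L, 13L), central = c(9L, 11L)) {
  empty <- data.frame(mirna_name = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), mode = character(),
                      aln_mirna = character(), aln_match = character(),
                      aln_target = character(), stringsAsFactors = FALSE)
  if (nrow(transcripts) == 0L || nrow(mirnas) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(transcripts))) {
      if (nchar(transcripts$seq[j]) < scan_len) next
      res <- scan_target_cpp(mirnas$seq[i], transcripts$seq[j],
                             max_expectation, penalties$mismatch,
                             penalties$gu, penalties$gap,
                             as.integer(seed[1]), as.integer(seed[2]),
                             as.integer(central[1]), as.integer(central[2]),
                             allow_gaps)
      if (length(res$start) == 0L) next
      df <- data.frame(mirna_name = mirnas$name[i],
                       transcript_id = transcripts$id[j],
                       site_start = res$start, site_end = res$end,
                       expectation = res$expectation,
                       mode = ifelse(res$central_bad, "translation",
                                     "cleavage"),
                       aln_mirna = res$aln_mir, aln_match = res$aln_match,
                       aln_target = res$aln_tgt, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- collapse_overlapping_sites(df)
    }
  }
  if (length(out) == 0L) return(empty)
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$mirna_name, sites$transcript_id,
                       sites$site_start), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Keep the minimal-expectation site per cluster of overlapping windows
# (one miRNA on one transcript); ties resolved leftmost.
collapse_overlapping_sites <- function(df) {
  df <- df[order(df$site_start, df$site_end), , drop = FALSE]
  cluster <- integer(nrow(df))
  cur <- 1L; cur_end <- df$site_end[1]
  cluster[1] <- 1L
  if (nrow(df) > 1) for (k in 2:nrow(df)) {
    if (df$site_start[k] <= cur_end) {
      cluster[k] <- cur
      cur_end <- max(cur_end, df$site_end[k])
    } else {
      cur <- cur + 1L
      cluster[k] <- cur
      cur_end <- df$site_end[k]
    }
  }
  picked <- vapply(split(seq_len(nrow(df)), cluster), function(idx) {
    sub <- df[idx, , drop = FALSE]
    idx[order(sub$expectation, sub$site_start)[1]]
  }, integer(1))
  df[sort(picked), , drop = FALSE]
}

#' Count distinct target transcripts per miRNA
#'
#' @param sites Data frame from \code{\link{find_targets}}.
#' @return Data frame \code{mirna_name}, \code{n_targets}, sorted by
#'   descending count then name (stable).
#' @export
per_mirna_target_counts <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(mirna_name = character(), n_targets = integer(),
                      stringsAsFactors = FALSE))
  tab <- vapply(split(sites$transcript_id, sites$mirna_name),
                function(x) length(unique(x)), integer(1))
  out <- data.frame(mirna_name = names(tab), n_targets = unname(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$mirna_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
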