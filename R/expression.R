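#' Count reads on target sequences with a mismatch budget
#'
#' Each read is assigned to its best (fewest-mismatch) ungapped hit across
#' all targets and both strands, with at most \code{max_mismatches}
#' mismatches; ties across targets go to the lexicographically smallest
#' target id so counting is deterministic. Unmapped reads are ignored.
#'
#' @param reads Data frame of reads (\code{id}, \code{seq}); plain RNA
#'   strings, no qualities.
#' @param targets Data frame of target transcripts (\code{id}, \code{seq}).
#' @param max_mismatches Per-read mismatch budget (default 2).
#' @return Named integer vector of counts, one entry per target (zeros
#'   included), in lexicographic target-id order.
#' @export
count_reads <- function(reads, targets, max_mismatches = 2L) {
  if (is.null(targets) || nrow(targets) == 0L)
    stop("count_reads: empty target set")
  t_ids <- sort(targets$id)
  counts <- stats::setNames(integer(length(t_ids)), t_ids)
  if (nrow(reads) == 0L) return(counts)
  uniq <- table(reads$seq)
  useqs <- names(uniq)
  assigned <- rep(NA_character_, length(useqs))

  # fast path: exact-substring lookup over all target windows per read length
  t_seq <- stats::setNames(targets$seq, targets$id)[t_ids]
  t_rc <- revcomp_rna(t_seq)
  for (L in sort(unique(nchar(useqs)))) {
    idxL <- which(nchar(useqs) == L & is.na(assigned))
    if (length(idxL) == 0L) next
    win <- character(0); win_t <- character(0)
    for (ti in seq_along(t_ids)) {
      for (s in c(t_seq[ti], t_rc[ti])) {
        n <- nchar(s)
        if (n < L) next
        w <- substring(s, 1:(n - L + 1L), L:n)
        win <- c(win, w); win_t <- c(win_t, rep(t_ids[ti], length(w)))
      }
    }
    if (length(win) == 0L) next
    ord <- order(win_t)  # so the first match is the smallest target id
    win <- win[ord]; win_t <- win_t[ord]
    m <- match(useqs[idxL], win)
    hit <- !is.na(m)
    assigned[idxL[hit]] <- win_t[m[hit]]
    if (max_mismatches == 0L) assigned[idxL[!hit]] <- ""
  }

  # mismatch path for the remainder
  if (max_mismatches > 0L) {
    t_set <- Biostrings::RNAStringSet(t_seq)
    t_set_rc <- Biostrings::RNAStringSet(t_rc)
    for (ui in which(is.na(assigned))) {
      u <- useqs[ui]
      assigned[ui] <- ""
      for (k in seq_len(max_mismatches)) {
        hf <- Biostrings::vcountPattern(u, t_set, max.mismatch = k,
                                        fixed = TRUE)
        hr <- Biostrings::vcountPattern(u, t_set_rc, max.mismatch = k,
                                        fixed = TRUE)
        hitset <- which(hf + hr > 0L)
        if (length(hitset) > 0L) {
          assigned[ui] <- t_ids[min(hitset)]
          break
        }
      }
    }
  }
  assigned[is.na(assigned)] <- ""
  mapped <- assigned != ""
  if (any(mapped)) {
    add <- tapply(as.integer(uniq)[mapped], assigned[mapped], sum)
    counts[names(add)] <- counts[names(add)] + as.integer(add)
  }
  counts
}

#' Transcripts-per-million normalization
#'
#' \code{rate_i = count_i / length_i}; \code{tpm_i = rate_i / sum(rate) *
#' 1e6}. When every count is zero, every TPM is zero.
#'
#' @param counts Named numeric vector of read counts.
#' @param lengths Named numeric vector of target lengths (nt), covering
#'   every counted target.
#' @return Named numeric vector of TPM values (same names as
#'   \code{counts}).
#' @export
tpm <- function(counts, lengths) {
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss) > 0L)
    stop("missing length for target(s): ", paste(miss, collapse = ", "))
  len <- lengths[names(counts)]
  if (any(len <= 0)) stop("target lengths must be positive")
  rate <- counts / len
  tot <- sum(rate)
  if (tot == 0) return(stats::setNames(rep(0, length(counts)),
                                       names(counts)))
  rate / tot * 1e6
}

#' Build per-target, per-sex expression profiles
#'
#' Counts sex-separated reads on the targets, normalizes each sex to TPM,
#' log2-transforms with a pseudocount, and classifies sex specificity from
#' the raw counts (detection threshold: count > 0).
#'
#' @param targets Data frame of target transcripts (\code{id}, \code{seq}).
#' @param reads_female,reads_male Read data frames (\code{id}, \code{seq}).
#' @param max_mismatches Read-mapping mismatch budget (default 2).
#' @param pseudocount Added inside the log2 (default 1).
#' @return Data frame: \code{target_id}, \code{length},
#'   \code{count_female}, \code{count_male}, \code{tpm_female},
#'   \code{tpm_male}, \code{log2_female}, \code{log2_male}, \code{class}
#'   (female_only / male_only / both / neither).
#' @export
expression_profiles <- function(targets, reads_female, reads_male,
                                max_mismatches = 2L, pseudocount = 1) {
  cf <- count_reads(reads_female, targets, max_mismatches)
  cm <- count_reads(reads_male, targets, max_mismatches)
  lens <- stats::setNames(nchar(targets$seq), targets$id)[names(cf)]
  tf <- tpm(cf, lens)
  tm <- tpm(cm, lens)
  prof <- data.frame(target_id = names(cf), length = unname(lens),
                     count_female = unname(cf), count_male = unname(cm),
                     tpm_female = unname(tf), tpm_male = unname(tm),
                     log2_female = unname(log2(tf + pseudocount)),
                     log2_male = unname(log2(tm + pseudocount)),
                     stringsAsFactors = FALSE)
  classify_specificity(prof)
}

#' Classify sex specificity of expression profiles
#'
#' Classification depends only on whether each sex's raw count is zero:
#' \code{female_only}, \code{male_only}, \code{both} or \code{neither}.
#'
#' @param profiles Data frame with \code{count_female} and
#'   \code{count_male} columns.
#' @return \code{profiles} with a \code{class} column set.
#' @export
classify_specificity <- function(profiles) {
  f <- profiles$count_female > 0
  m <- profiles$count_male > 0
  profiles$class <- ifelse(f & m, "both",
                    ifelse(f, "female_only",
                    ifelse(m, "male_only", "neither")))
  profiles
}

#' miRNA-target expression contrast for sex-specific miRNAs
#'
#' For each miRNA detected in exactly one sex, compares the mean log2 TPM
#' of its targets in the miRNA-present sex against the miRNA-absent sex.
#' A negative difference (present minus absent) supports the expected
#' anti-correlation between a silencing miRNA and its targets.
#'
#' @param mirna_presence Data frame (\code{mirna_name}, \code{presence}
#'   in female/male/both).
#' @param sites Target sites from \code{\link{find_targets}}.
#' @param profiles Expression profiles from
#'   \code{\link{expression_profiles}}.
#' @return Data frame: \code{mirna_name}, \code{presence},
#'   \code{n_targets}, \code{mean_log2_present}, \code{mean_log2_absent},
#'   \code{difference} (NA when the miRNA has no targets).
#' @export
anticorrelation_report <- function(mirna_presence, sites, profiles) {
  unknown <- setdiff(sites$mirna_name, mirna_presence$mirna_name)
  if (length(unknown) > 0L)
    stop("site miRNA(s) missing from presence table: ",
         paste(unique(unknown), collapse = ", "))
  spec <- mirna_presence[mirna_presence$presence %in% c("female", "male"), ,
                         drop = FALSE]
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    mir <- spec$mirna_name[i]
    sex <- spec$presence[i]
    tg <- unique(sites$transcript_id[sites$mirna_name == mir])
    tg <- tg[tg %in% profiles$target_id]
    pf <- profiles[match(tg, profiles$target_id), , drop = FALSE]
    if (length(tg) == 0L) {
      mp <- NA_real_; ma <- NA_real_
    } else if (sex == "female") {
      mp <- mean(pf$log2_female); ma <- mean(pf$log2_male)
    } else {
      mp <- mean(pf$log2_male); ma <- mean(pf$log2_female)
    }
    data.frame(mirna_name = mir, presence = sex, n_targets = length(tg),
               mean_log2_present = mp, mean_log2_absent = ma,
               difference = mp - ma, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(mirna_name = character(), presence = character(),
                      n_targets = integer(), mean_log2_present = numeric(),
                      mean_log2_absent = numeric(), difference = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
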