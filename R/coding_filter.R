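#' Screen candidate precursors against coding and ncRNA decoy databases
#'
#' Local, threshold-explicit stand-in for the usual BLAST step that
#' removes candidate precursors looking protein-coding or belonging to
#' structural RNA classes (tRNA, rRNA, snRNA, snoRNA). A candidate is
#' dropped iff some database sequence has an ungapped local match
#' (exact-word seed, extended along the diagonal) with identity at least
#' \code{min_identity} spanning at least \code{min_coverage} of the
#' candidate. Protein screening runs the six-frame translation of the
#' candidate against the protein database; stop codons break seed words
#' and count as mismatches.
#'
#' @param candidates Candidate data frame (needs \code{seq}; a
#'   \code{candidate_id} column is used if present, else one is built from
#'   \code{est_id}/coordinates).
#' @param protein_db Data frame of protein decoys (\code{id}, \code{seq},
#'   amino-acid alphabet), possibly empty or NULL.
#' @param ncrna_db Data frame of ncRNA decoys (\code{id}, \code{seq}, RNA
#'   alphabet), possibly empty or NULL.
#' @param min_identity,min_coverage Fractions in [0, 1] (defaults 0.8 and
#'   0.6).
#' @param word_nt,word_aa Seed word sizes (nucleotide / amino acid).
#' @return Data frame: \code{candidate_id}, \code{verdict} (keep/drop),
#'   \code{reason} (protein_like/ncRNA_like/none), \code{best_identity},
#'   \code{best_coverage}, \code{db_hit_id}.
#' @export
screen_candidates <- function(candidates, protein_db = NULL, ncrna_db = NULL,
                              min_identity = 0.8, min_coverage = 0.6,
                              word_nt = 8L, word_aa = 4L) {
  ids <- candidate_ids(candidates)
  n <- nrow(candidates)
  out <- data.frame(candidate_id = ids,
                    verdict = rep("keep", n), reason = rep("none", n),
                    best_identity = rep(0, n), best_coverage = rep(0, n),
                    db_hit_id = rep("", n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    cseq <- candidates$seq[i]
    best <- list(identity = 0, coverage = 0, id = "", qualified = FALSE,
                 reason = "none")
    # protein screen: six-frame translation vs protein db
    if (!is.null(protein_db) && nrow(protein_db) > 0L) {
      w <- as.integer(ceiling(min_coverage * nchar(cseq) / 3))
      frames <- six_frame_translate(cseq)
      for (d in seq_len(nrow(protein_db))) {
        for (f in frames) {
          hit <- best_diagonal_segment(f, protein_db$seq[d], word_aa, w,
                                       min_identity)
          best <- update_best(best, hit, protein_db$id[d], "protein_like",
                              nchar(cseq), aa = TRUE)
          if (best$qualified) break
        }
        if (best$qualified) break
      }
    }
    # ncRNA screen: nucleotide diagonals, both strands of the candidate
    if (!best$qualified && !is.null(ncrna_db) && nrow(ncrna_db) > 0L) {
      w <- as.integer(ceiling(min_coverage * nchar(cseq)))
      for (d in seq_len(nrow(ncrna_db))) {
        for (q in c(cseq, revcomp_rna(cseq))) {
          hit <- best_diagonal_segment(q, ncrna_db$seq[d], word_nt, w,
                                       min_identity)
          best <- update_best(best, hit, ncrna_db$id[d], "ncRNA_like",
                              nchar(cseq), aa = FALSE)
          if (best$qualified) break
        }
        if (best$qualified) break
      }
    }
    out$best_identity[i] <- best$identity
    out$best_coverage[i] <- best$coverage
    if (best$qualified) {
      out$verdict[i] <- "drop"
      out$reason[i] <- best$reason
      out$db_hit_id[i] <- best$id
    }
  }
  out
}

candidate_ids <- function(candidates) {
  if ("candidate_id" %in% names(candidates)) return(candidates$candidate_id)
  if (all(c("est_id", "window_start", "window_end", "strand") %in%
          names(candidates)))
    return(paste0(candidates$est_id, ":", candidates$window_start, "..",
                  candidates$window_end, ":", candidates$strand))
  as.character(seq_len(nrow(candidates)))
}

update_best <- function(best, hit, db_id, reason, cand_len, aa) {
  if (is.null(hit)) return(best)
  cov <- if (aa) min(1, hit$length * 3 / cand_len) else
    min(1, hit$length / cand_len)
  qualified <- hit$qualified
  if ((qualified && !best$qualified) ||
      (qualified == best$qualified && hit$identity > best$identity)) {
    return(list(identity = hit$identity, coverage = cov, id = db_id,
                qualified = qualified, reason = if (qualified) reason
                else best$reason))
  }
  best
}

# Best ungapped diagonal segment between query and subject seeded by
# shared exact words: among diagonals sharing a word, the contiguous
# segment of length >= min_len with maximal identity (match fraction).
# Returns NULL when no word is shared; else list(identity, length,
# qualified).
best_diagonal_segment <- function(query, subject, word, min_len,
                                  min_identity) {
  lq <- nchar(query); ls <- nchar(subject)
  if (lq < word || ls < word || min_len < 1L) return(NULL)
  qwords <- substring(query, 1:(lq - word + 1L), word:lq)
  swords <- substring(subject, 1:(ls - word + 1L), word:ls)
  keep_q <- !grepl("[*N]", qwords)
  sw_env <- split(seq_along(swords), swords)
  diags <- integer(0)
  for (qp in which(keep_q)) {
    sp <- sw_env[[qwords[qp]]]
    if (!is.null(sp)) diags <- c(diags, qp - sp)
  }
  diags <- unique(diags)
  if (length(diags) == 0L) return(NULL)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  best <- NULL
  for (dg in diags) {
    i_lo <- max(1L, dg + 1L); i_hi <- min(lq, ls + dg)
    len <- i_hi - i_lo + 1L
    if (len < min_len) next
    m <- as.integer(qc[i_lo:i_hi] == sc[(i_lo:i_hi) - dg] &
                    qc[i_lo:i_hi] != "*" & qc[i_lo:i_hi] != "N")
    cs <- c(0L, cumsum(m))
    # all segments of length >= min_len on this diagonal
    for (a in seq_len(len - min_len + 1L)) {
      for (b in (a + min_len - 1L):len) {
        idf <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
        cand <- list(identity = idf, length = b - a + 1L,
                     qualified = idf >= min_identity)
        if (is.null(best) ||
            (cand$qualified && !best$qualified) ||
            (cand$qualified == best$qualified &&
             cand$identity > best$identity))
          best <- cand
        if (cand$qualified) break  # longer same-start segments checked next a
      }
    }
  }
  best
}

# Translate an RNA string in all six reading frames; returns character
# vector of peptides (stop codons as "*").
six_frame_translate <- function(seq) {
  dna <- chartr("U", "T", seq)
  strands <- c(dna, chartr("ACGT", "TGCA",
                           paste(rev(strsplit(dna, "")[[1]]), collapse = "")))
  out <- character(0)
  for (s in strands) {
    for (off in 0:2) {
      sub <- substr(s, off + 1L, nchar(s))
      sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
      if (nchar(sub) < 3L) next
      pep <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))
      out <- c(out, pep)
    }
  }
  out
}
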