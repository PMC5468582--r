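#' Scan ESTs for near-exact copies of reference mature miRNAs
#'
#' Reports every ungapped occurrence of each reference mature sequence on
#' either strand of each EST with at most \code{max_mismatches} Hamming
#' mismatches. Reverse-strand hits carry strand \code{"-"} with
#' coordinates on the EST forward strand. Overlapping hits of the same
#' reference on the same EST closer than the mature length are merged to
#' the lowest-mismatch one (ties: leftmost, then plus strand).
#'
#' @param ests Data frame of EST records (\code{id}, \code{seq}).
#' @param refs Data frame of deduplicated reference matures (\code{name},
#'   \code{seq}); every reference must be at least 16 nt.
#' @param max_mismatches Maximum Hamming distance (default 2, the literal
#'   reading of "fewer than three mismatches").
#' @return Data frame with columns \code{est_id}, \code{ref_name},
#'   \code{strand}, \code{est_start}, \code{est_end} (1-based inclusive on
#'   the EST forward strand), \code{mismatches}, ordered by
#'   (\code{est_id}, \code{est_start}, \code{ref_name}).
#' @export
scan_homology <- function(ests, refs, max_mismatches = 2L) {
  stopifnot(max_mismatches >= 0)
  empty <- data.frame(est_id = character(), ref_name = character(),
                      strand = character(), est_start = integer(),
                      est_end = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ests) == 0L) return(empty)
  if (any(nchar(refs$seq) < 16L))
    stop("reference mature sequence shorter than 16 nt: ",
         paste(refs$name[nchar(refs$seq) < 16L], collapse = ", "))
  subject <- Biostrings::RNAStringSet(ests$seq)
  names(subject) <- ests$id
  rows <- vector("list", nrow(refs) * 2L)
  k <- 0L
  for (r in seq_len(nrow(refs))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") refs$seq[r] else revcomp_rna(refs$seq[r])
      mt <- Biostrings::vmatchPattern(pat, subject,
                                      max.mismatch = max_mismatches,
                                      fixed = TRUE)
      hits_per_est <- S4Vectors::elementNROWS(mt)
      if (sum(hits_per_est) == 0L) next
      est_idx <- rep(seq_along(subject), hits_per_est)
      ir <- unlist(mt)
      starts <- BiocGenerics::start(ir)
      ends <- BiocGenerics::end(ir)
      keep <- starts >= 1L & ends <= nchar(ests$seq)[est_idx]
      if (!any(keep)) next
      est_idx <- est_idx[keep]; starts <- starts[keep]; ends <- ends[keep]
      mm <- vapply(seq_along(starts), function(h) {
        hamming_chars(substr(ests$seq[est_idx[h]], starts[h], ends[h]), pat)
      }, integer(1))
      k <- k + 1L
      rows[[k]] <- data.frame(est_id = ests$id[est_idx],
                              ref_name = refs$name[r], strand = strand,
                              est_start = starts, est_end = ends,
                              mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  hits <- do.call(rbind, rows[seq_len(k)])
  hits <- merge_overlapping_hits(hits, nchar(refs$seq)[match(hits$ref_name,
                                                             refs$name)])
  hits[order(hits$est_id, hits$est_start, hits$ref_name), , drop = FALSE]
}

hamming_chars <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Merge same-(est, ref) hits whose starts are closer than the mature
# length: keep the lowest-mismatch hit, ties resolved leftmost then "+".
merge_overlapping_hits <- function(hits, mature_len) {
  key <- paste(hits$est_id, hits$ref_name)
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    lm <- mature_len[idx[1]]
    sub <- hits[idx, , drop = FALSE]
    sub <- sub[order(sub$est_start, sub$strand), , drop = FALSE]
    cluster <- cumsum(c(TRUE, diff(sub$est_start) >= lm))
    do.call(rbind, lapply(split(seq_len(nrow(sub)), cluster), function(ci) {
      cs <- sub[ci, , drop = FALSE]
      cs[order(cs$mismatches, cs$est_start,
               cs$strand)[1], , drop = FALSE]
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate candidate precursor windows around one homology hit
#'
#' Plant pre-miRNAs range roughly from 50 to 350 nt with no fixed boundary
#' rule, so a grid of windows containing the mature span is enumerated
#' (window length \code{min_len..max_len} by \code{step}; the mature
#' offset inside the window also varies by \code{step}), clipped to the
#' EST. Each window's sequence is strand-adjusted so the mature copy reads
#' 5' to 3'.
#'
#' @param hit One-row data frame from \code{\link{scan_homology}}.
#' @param est One-row data frame (\code{id}, \code{seq}) for the hit's EST.
#' @param min_len,max_len,step Window grid (nt); \code{min_len} must be at
#'   least the mature length plus 15.
#' @return Data frame of candidate windows: \code{est_id},
#'   \code{window_start}, \code{window_end} (1-based inclusive on the EST
#'   forward strand), \code{strand}, \code{seq} (strand-adjusted),
#'   \code{mature_offset}, \code{mature_len}, \code{ref_name},
#'   \code{mismatches}, \code{LP}, \code{short} (flag: EST shorter than
#'   \code{min_len}).
#' @export
extract_candidates <- function(hit, est, min_len = 50L, max_len = 350L,
                               step = 10L) {
  stopifnot(nrow(hit) == 1L, nrow(est) == 1L, hit$est_id == est$id)
  lm <- hit$est_end - hit$est_start + 1L
  if (min_len < lm + 15L)
    stop("min_len must be >= mature length + 15 (", lm + 15L, ")")
  est_len <- nchar(est$seq)
  hs <- hit$est_start; he <- hit$est_end
  if (hs < 1L || he > est_len) stop("hit does not lie on the EST")
  windows <- list()
  if (est_len < min_len) {
    windows[[1]] <- c(1L, est_len)
    short <- TRUE
  } else {
    short <- FALSE
    for (L in seq(min_len, min(max_len, est_len), by = step)) {
      s_lo <- max(1L, he - L + 1L)
      s_hi <- min(hs, est_len - L + 1L)
      if (s_hi < s_lo) next
      anchor <- he - L + 1L
      starts <- anchor + step * (0:((s_hi - anchor) %/% step))
      starts <- starts[starts >= s_lo & starts <= s_hi]
      for (s in starts) windows[[length(windows) + 1L]] <- c(s, s + L - 1L)
    }
  }
  if (length(windows) == 0L) windows[[1]] <- c(max(1L, he - min_len + 1L),
                                               min(est_len, he))
  w <- unique(do.call(rbind, windows))
  res <- lapply(seq_len(nrow(w)), function(i) {
    ws <- w[i, 1]; we <- w[i, 2]
    raw <- substr(est$seq, ws, we)
    if (hit$strand == "+") {
      seq <- raw
      off <- hs - ws + 1L
    } else {
      seq <- revcomp_rna(raw)
      off <- we - he + 1L
    }
    data.frame(est_id = est$id, window_start = ws, window_end = we,
               strand = hit$strand, seq = seq, mature_offset = off,
               mature_len = lm, ref_name = hit$ref_name,
               mismatches = hit$mismatches, LP = we - ws + 1L,
               short = short, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
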