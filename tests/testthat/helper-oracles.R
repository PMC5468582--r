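# Independent brute-force oracles, written against the definitions (not
# the implementation paths they check).

rand_rna_str <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# --- homology scan oracle: sliding-window Hamming over both strands,
# followed by the documented merge rule (same ref, same EST, starts closer
# than the mature length -> lowest mismatches, ties leftmost then "+").
oracle_scan <- function(ests, refs, k) {
  rows <- list()
  for (e in seq_len(nrow(ests))) {
    es <- ests$seq[e]
    for (r in seq_len(nrow(refs))) {
      m <- nchar(refs$seq[r])
      if (nchar(es) < m) next
      for (s in 1:(nchar(es) - m + 1)) {
        win <- substr(es, s, s + m - 1)
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") refs$seq[r] else rc_str(refs$seq[r])
          mm <- hamming_str(win, pat)
          if (mm <= k)
            rows[[length(rows) + 1]] <- data.frame(
              est_id = ests$id[e], ref_name = refs$name[r],
              strand = strand, est_start = s, est_end = s + m - 1,
              mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(est_id = character(), ref_name = character(),
                      strand = character(), est_start = integer(),
                      est_end = integer(), mismatches = integer()))
  hits <- do.call(rbind, rows)
  merged <- list()
  for (key in unique(paste(hits$est_id, hits$ref_name))) {
    sub <- hits[paste(hits$est_id, hits$ref_name) == key, , drop = FALSE]
    lm <- sub$est_end[1] - sub$est_start[1] + 1
    sub <- sub[order(sub$est_start, sub$strand), , drop = FALSE]
    cl <- cumsum(c(TRUE, diff(sub$est_start) >= lm))
    for (g in unique(cl)) {
      grp <- sub[cl == g, , drop = FALSE]
      grp <- grp[order(grp$mismatches, grp$est_start, grp$strand), ,
                 drop = FALSE]
      merged[[length(merged) + 1]] <- grp[1, , drop = FALSE]
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$est_id, out$est_start, out$ref_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- hairpin folding oracle: exhaustive enumeration of nested pair
# stacks (structure space). A structure is an ordered stack of allowed
# pairs (p1<p2<...<pk, q1>q2>...>qk); the innermost region must hold a
# loop of at least min_loop nt; the unpaired runs (a, b) between
# consecutive pairs (and outside the outermost pair) cost 0 when a == b
# and gap_open + gap_extend * |a - b| otherwise; each pair adds its pair
# score. Empty structure costs 0. Memoized over regions.
oracle_fold_score <- function(seq, gc = -3, au = -2, gu = -1,
                              gap_open = 4, gap_extend = 1, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  psc <- function(i, j) {
    a <- ch[i]; b <- ch[j]
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(gc)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(au)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(gu)
    NA_real_
  }
  runcost <- function(a, b) if (a == b) 0 else
    gap_open + gap_extend * abs(a - b)
  memo <- new.env(parent = emptyenv())
  inner <- function(i, j) {           # region strictly inside a pair
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- if (j - i + 1 >= min_loop) 0 else Inf
    if (j > i) for (p in i:(j - 1)) for (q in (p + 1):j) {
      s <- psc(p, q)
      if (is.na(s)) next
      v <- runcost(p - i, j - q) + s + inner(p + 1, q - 1)
      if (v < best) best <- v
    }
    memo[[key]] <- best
    best
  }
  best <- if (n >= min_loop) 0 else Inf
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    s <- psc(p, q)
    if (is.na(s)) next
    v <- runcost(p - 1, n - q) + s + inner(p + 1, q - 1)
    if (v < best) best <- v
  }
  best
}

# --- ungapped target-expectation oracle: best expectation over all
# ungapped placements of the miRNA against the transcript (antiparallel).
oracle_best_expectation <- function(mir, tgt, mismatch = 1, gu = 0.5,
                                    seed = c(2, 13)) {
  m <- nchar(mir); n <- nchar(tgt)
  if (n < m) return(Inf)
  mch <- strsplit(mir, "")[[1]]
  tch <- strsplit(tgt, "")[[1]]
  best <- Inf
  for (e in m:n) {
    tot <- 0
    for (i in 1:m) {
      a <- mch[i]; b <- tch[e - i + 1]
      pen <- if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
                 (a == "G" && b == "C") || (a == "C" && b == "G")) 0
             else if ((a == "G" && b == "U") || (a == "U" && b == "G")) gu
             else mismatch
      if (i >= seed[1] && i <= seed[2]) pen <- pen * 2
      tot <- tot + pen
    }
    if (tot < best) best <- tot
  }
  best
}

# --- read-counting oracle: best (fewest-mismatch) ungapped placement of
# each read over all targets/strands/offsets; ties to the smallest id.
oracle_count_reads <- function(reads, targets, k) {
  ids <- sort(targets$id)
  counts <- stats::setNames(integer(length(ids)), ids)
  for (r in seq_len(nrow(reads))) {
    best_mm <- Inf; best_t <- NULL
    rl <- nchar(reads$seq[r])
    for (t in seq_len(nrow(targets))) {
      for (s in c(targets$seq[t], rc_str(targets$seq[t]))) {
        if (nchar(s) < rl) next
        for (p in 1:(nchar(s) - rl + 1)) {
          mm <- hamming_str(substr(s, p, p + rl - 1), reads$seq[r])
          if (mm < best_mm ||
              (mm == best_mm && !is.null(best_t) && targets$id[t] < best_t)) {
            best_mm <- mm; best_t <- targets$id[t]
          }
        }
      }
    }
    if (best_mm <= k) counts[best_t] <- counts[best_t] + 1L
  }
  counts
}

# Perfect stem-loop helper for hairpin tests (WC-only arm by default so
# reverse-complement symmetry is exact).
make_perfect_hairpin <- function(arm_len = 20, loop = "GAAA",
                                 alphabet = c("A", "C", "G", "U")) {
  arm <- rand_rna_str(arm_len, alphabet)
  list(arm = arm, seq = paste0(arm, loop, rc_str(arm)))
}

# The production wrapper enforces a 30-nt minimum (real precursor scale);
# oracle comparisons on short strings call the folding engine directly.
fold_hairpin_small_for_test <- function(s) {
  mirhunt:::fold_hairpin_cpp(s, -3, -2, -1, 4, 1, 3L)$score
}
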