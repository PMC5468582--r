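test_that("a planted exact copy is found once with correct coordinates", {
  set.seed(21)
  ref <- data.frame(name = "ath-miR1a", seq = rand_rna_str(21),
                    stringsAsFactors = FALSE)
  est_seq <- paste0(rand_rna_str(40), ref$seq, rand_rna_str(39))
  ests <- data.frame(id = "e1", seq = est_seq, stringsAsFactors = FALSE)
  hits <- scan_homology(ests, ref, max_mismatches = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$est_start, 41L)       # planted after a 40-nt flank
  expect_equal(hits$est_end, 61L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$strand, "+")

  # three mutations exceed a 2-mismatch budget
  mut <- strsplit(ref$seq, "")[[1]]
  for (p in c(3, 9, 15)) mut[p] <- setdiff(c("A", "C", "G", "U"), mut[p])[1]
  est2 <- data.frame(id = "e2",
                     seq = paste0(substr(est_seq, 1, 40),
                                  paste(mut, collapse = ""),
                                  substr(est_seq, 62, 100)),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(scan_homology(est2, ref, 2)), 0L)
  expect_equal(nrow(scan_homology(est2, ref, 3)), 1L)
})

test_that("reverse-strand hits carry forward-strand coordinates", {
  set.seed(22)
  ref <- data.frame(name = "ath-miR2a", seq = rand_rna_str(20),
                    stringsAsFactors = FALSE)
  ests <- data.frame(id = "e1",
                     seq = paste0(rand_rna_str(30), rc_str(ref$seq),
                                  rand_rna_str(25)),
                     stringsAsFactors = FALSE)
  hits <- scan_homology(ests, ref, 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$est_start, 31L)
  expect_equal(hits$est_end, 50L)
})

test_that("scan equals the brute-force Hamming oracle on toy instances", {
  set.seed(23)
  for (rep in 1:5) {
    refs <- data.frame(name = paste0("ath-miR", 1:2, "a"),
                       seq = c(rand_rna_str(18), rand_rna_str(22)),
                       stringsAsFactors = FALSE)
    ests <- data.frame(id = paste0("e", 1:4),
                       seq = vapply(sample(30:60, 4), rand_rna_str,
                                    character(1)),
                       stringsAsFactors = FALSE)
    # plant some near-copies so hits actually occur
    pl <- strsplit(refs$seq[1], "")[[1]]
    pl[7] <- setdiff(c("A", "C", "G", "U"), pl[7])[1]
    ests$seq[1] <- paste0(substr(ests$seq[1], 1, 5),
                          paste(pl, collapse = ""),
                          substr(ests$seq[1], 24, nchar(ests$seq[1])))
    ests$seq[2] <- paste0(rc_str(refs$seq[2]),
                          substr(ests$seq[2], 23, nchar(ests$seq[2])))
    for (k in 0:2) {
      got <- scan_homology(ests, refs, k)
      want <- oracle_scan(ests, refs, k)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0)
        expect_equal(got[, c("est_id", "ref_name", "strand", "est_start",
                             "est_end", "mismatches")],
                     want, ignore_attr = TRUE)
    }
  }
})

test_that("hit sets grow monotonically with the mismatch budget", {
  set.seed(24)
  ref <- data.frame(name = "ath-miR3a", seq = rand_rna_str(21),
                    stringsAsFactors = FALSE)
  mut1 <- strsplit(ref$seq, "")[[1]]
  mut1[5] <- setdiff(c("A", "C", "G", "U"), mut1[5])[1]
  ests <- data.frame(
    id = c("e1", "e2"),
    seq = c(paste0(rand_rna_str(50), ref$seq, rand_rna_str(50)),
            paste0(rand_rna_str(50), paste(mut1, collapse = ""),
                   rand_rna_str(50))),
    stringsAsFactors = FALSE)
  prev <- scan_homology(ests, ref, 0)
  for (k in 1:3) {
    cur <- scan_homology(ests, ref, k)
    key_prev <- paste(prev$est_id, prev$est_start, prev$strand)
    key_cur <- paste(cur$est_id, cur$est_start, cur$strand)
    expect_true(all(key_prev %in% key_cur))
    prev <- cur
  }
})

test_that("reversing an EST mirrors the hit set with flipped strands", {
  set.seed(25)
  ref <- data.frame(name = "ath-miR4a", seq = rand_rna_str(20),
                    stringsAsFactors = FALSE)
  est_seq <- paste0(rand_rna_str(33), ref$seq, rand_rna_str(27))
  n <- nchar(est_seq)
  fwd <- scan_homology(data.frame(id = "e", seq = est_seq), ref, 1)
  rev <- scan_homology(data.frame(id = "e", seq = rc_str(est_seq)), ref, 1)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(rev$strand, ifelse(fwd$strand == "+", "-", "+"))
  expect_equal(rev$est_start, n - fwd$est_end + 1L)
  expect_equal(rev$est_end, n - fwd$est_start + 1L)
})

test_that("degenerate references are rejected and empty EST sets are fine", {
  short <- data.frame(name = "ath-miR5a", seq = "ACGUACGUACGUACG",
                      stringsAsFactors = FALSE)  # 15 nt
  ests <- data.frame(id = "e", seq = rand_rna_str(50),
                     stringsAsFactors = FALSE)
  expect_error(scan_homology(ests, short), "16 nt")
  ok <- data.frame(name = "ath-miR6a", seq = rand_rna_str(20),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(scan_homology(ests[0, ], ok)), 0L)
})

test_that("candidate windows always contain the mature span on the stated grid", {
  set.seed(26)
  est <- data.frame(id = "e", seq = rand_rna_str(300),
                    stringsAsFactors = FALSE)
  hit <- data.frame(est_id = "e", ref_name = "ath-miR7a", strand = "+",
                    est_start = 41L, est_end = 61L, mismatches = 0L,
                    stringsAsFactors = FALSE)
  cands <- extract_candidates(hit, est, min_len = 50, max_len = 90,
                              step = 20)
  expect_true(all(cands$window_start <= 41 & cands$window_end >= 61))
  expect_true(all(cands$LP %in% c(50, 70, 90)))
  expect_false(any(duplicated(cands[, c("window_start", "window_end")])))
  # mature copy is really at mature_offset inside the returned seq
  for (i in seq_len(nrow(cands)))
    expect_equal(substr(cands$seq[i], cands$mature_offset[i],
                        cands$mature_offset[i] + 20L),
                 substr(est$seq, 41, 61))
  # grid covers every legal (offset, length) pair to within one step
  for (L in c(50, 70, 90)) {
    starts <- cands$window_start[cands$LP == L]
    legal <- seq(max(1, 61 - L + 1), min(41, 300 - L + 1))
    expect_true(all(vapply(legal, function(s) min(abs(starts - s)),
                           numeric(1)) < 20))
  }
})

test_that("short ESTs yield a single flagged whole-EST window", {
  set.seed(27)
  est <- data.frame(id = "e", seq = rand_rna_str(55),
                    stringsAsFactors = FALSE)
  hit <- data.frame(est_id = "e", ref_name = "ath-miR8a", strand = "+",
                    est_start = 10L, est_end = 30L, mismatches = 0L,
                    stringsAsFactors = FALSE)
  cands <- extract_candidates(hit, est, min_len = 60)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$LP, 55L)
  expect_true(cands$short)
  expect_error(extract_candidates(hit, est, min_len = 30), "mature length")
})

test_that("minus-strand windows read the mature 5' to 3'", {
  set.seed(28)
  mat <- rand_rna_str(21)
  est <- data.frame(id = "e",
                    seq = paste0(rand_rna_str(60), rc_str(mat),
                                 rand_rna_str(60)),
                    stringsAsFactors = FALSE)
  hit <- data.frame(est_id = "e", ref_name = "ath-miR9a", strand = "-",
                    est_start = 61L, est_end = 81L, mismatches = 0L,
                    stringsAsFactors = FALSE)
  cands <- extract_candidates(hit, est, min_len = 50, max_len = 70,
                              step = 10)
  for (i in seq_len(nrow(cands)))
    expect_equal(substr(cands$seq[i], cands$mature_offset[i],
                        cands$mature_offset[i] + 20L), mat)
})
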