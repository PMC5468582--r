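test_that("planted reads are counted on their source target only", {
  set.seed(61)
  targets <- data.frame(id = c("A", "B"),
                        seq = c(rand_rna_str(200), rand_rna_str(200)),
                        stringsAsFactors = FALSE)
  starts <- sample(150, 10)
  reads <- data.frame(id = paste0("r", 1:10),
                      seq = substring(targets$seq[1], starts, starts + 49),
                      stringsAsFactors = FALSE)
  expect_equal(count_reads(reads, targets),
               c(A = 10L, B = 0L))
  # a read with 3 mismatches everywhere stays unmapped at budget 2
  bad <- strsplit(reads$seq[1], "")[[1]]
  for (p in c(5, 20, 40)) bad[p] <- setdiff(c("A", "C", "G", "U"),
                                            bad[p])[1]
  expect_equal(count_reads(data.frame(id = "x",
                                      seq = paste(bad, collapse = "")),
                           targets, 2),
               c(A = 0L, B = 0L))
  expect_error(count_reads(reads, targets[0, ]), "empty")
})

test_that("read counting equals the brute-force Hamming assignment", {
  set.seed(62)
  targets <- data.frame(id = c("tA", "tB", "tC"),
                        seq = vapply(c(120, 150, 100), rand_rna_str,
                                     character(1)),
                        stringsAsFactors = FALSE)
  mk_read <- function() {
    t <- sample(3, 1)
    p <- sample(nchar(targets$seq[t]) - 29, 1)
    s <- substr(targets$seq[t], p, p + 29)
    ch <- strsplit(s, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) for (q in sample(30, nmut))
      ch[q] <- setdiff(c("A", "C", "G", "U"), ch[q])[1]
    s <- paste(ch, collapse = "")
    if (stats::runif(1) < 0.5) s <- rc_str(s)
    s
  }
  reads <- data.frame(id = paste0("r", 1:18),
                      seq = vapply(1:18, function(i) mk_read(),
                                   character(1)),
                      stringsAsFactors = FALSE)
  for (k in 0:2)
    expect_equal(count_reads(reads, targets, k),
                 oracle_count_reads(reads, targets, k))
})

test_that("read counting is invariant to read order", {
  set.seed(63)
  targets <- data.frame(id = c("a", "b"),
                        seq = c(rand_rna_str(150), rand_rna_str(150)),
                        stringsAsFactors = FALSE)
  reads <- data.frame(id = paste0("r", 1:20),
                      seq = substring(targets$seq[sample(2, 20, TRUE)],
                                      11, 50),
                      stringsAsFactors = FALSE)
  base <- count_reads(reads, targets)
  expect_equal(count_reads(reads[sample(nrow(reads)), ], targets), base)
})

test_that("TPM follows the rate definition and normalizes to one million", {
  expect_equal(tpm(c(A = 10, B = 10), c(A = 100, B = 100)),
               c(A = 5e5, B = 5e5))
  got <- tpm(c(A = 10, B = 10), c(A = 100, B = 200))
  expect_equal(unname(got["A"]), 666666.67, tolerance = 1e-8)
  expect_equal(unname(got["B"]), 333333.33, tolerance = 1e-8)
  expect_equal(unname(got["A"] / got["B"]), 2)
  set.seed(64)
  counts <- stats::setNames(rpois(12, 40), paste0("t", 1:12))
  lens <- stats::setNames(sample(200:900, 12), paste0("t", 1:12))
  expect_equal(sum(tpm(counts, lens)), 1e6, tolerance = 1e-6)
  # scale invariance and the all-zero case
  expect_equal(tpm(counts * 2, lens), tpm(counts, lens))
  expect_true(all(tpm(counts * 0, lens) == 0))
  expect_error(tpm(c(A = 1, Z = 2), c(A = 100)), "missing length")
})

test_that("specificity classes depend only on zero versus nonzero counts", {
  prof <- data.frame(target_id = c("w", "x", "y", "z"),
                     count_female = c(576L, 0L, 3L, 0L),
                     count_male = c(0L, 4L, 7L, 0L))
  out <- classify_specificity(prof)
  expect_equal(out$class, c("female_only", "male_only", "both", "neither"))
  # invariant to count rescaling
  prof2 <- prof
  prof2$count_female <- prof2$count_female * 100L
  prof2$count_male <- prof2$count_male * 100L
  expect_equal(classify_specificity(prof2)$class, out$class)
})

test_that("anticorrelation contrast is negative for suppressed targets", {
  set.seed(65)
  targets <- data.frame(id = sprintf("t%02d", 1:8),
                        seq = vapply(rep(300, 8), rand_rna_str,
                                     character(1)),
                        stringsAsFactors = FALSE)
  # miRNA "mirM" male-only, targets t01..t04 suppressed 8x in the male
  wf <- rep(100, 8)
  wm <- c(rep(100 / 8, 4), rep(100, 4))
  sim <- function(w) {
    pick <- sample(8, 3000, TRUE, prob = w / sum(w))
    st <- vapply(pick, function(i) sample(251, 1), integer(1))
    data.frame(id = seq_len(3000),
               seq = substring(targets$seq[pick], st, st + 49),
               stringsAsFactors = FALSE)
  }
  prof <- expression_profiles(targets, sim(wf), sim(wm))
  sites <- data.frame(mirna_name = "mirM",
                      transcript_id = c("t01", "t02", "t03", "t04"),
                      site_start = 1L, site_end = 21L, expectation = 0,
                      mode = "cleavage", stringsAsFactors = FALSE)
  pres <- data.frame(mirna_name = "mirM", presence = "male",
                     stringsAsFactors = FALSE)
  rep <- anticorrelation_report(pres, sites, prof)
  expect_equal(rep$n_targets, 4L)
  expect_lt(rep$difference, 0)

  # identical expression in both sexes -> difference 0 by construction
  prof0 <- prof
  prof0$log2_male <- prof0$log2_female
  expect_equal(anticorrelation_report(pres, sites, prof0)$difference, 0)

  # a miRNA with no predicted targets yields an NA row
  pres2 <- rbind(pres, data.frame(mirna_name = "mirF", presence = "female"))
  rep2 <- anticorrelation_report(pres2, sites, prof)
  expect_true(is.na(rep2$difference[rep2$mirna_name == "mirF"]))
  expect_error(anticorrelation_report(pres, transform(sites,
                                                      mirna_name = "zz"),
                                      prof), "missing")
})

test_that("permuting target assignment drives the contrast toward zero", {
  set.seed(66)
  targets <- data.frame(id = sprintf("t%02d", 1:12),
                        seq = vapply(rep(300, 12), rand_rna_str,
                                     character(1)),
                        stringsAsFactors = FALSE)
  wf <- rep(100, 12)
  wm <- c(rep(100 / 8, 4), rep(100, 8))
  sim <- function(w) {
    pick <- sample(12, 4000, TRUE, prob = w / sum(w))
    st <- vapply(pick, function(i) sample(251, 1), integer(1))
    data.frame(id = seq_len(4000),
               seq = substring(targets$seq[pick], st, st + 49),
               stringsAsFactors = FALSE)
  }
  prof <- expression_profiles(targets, sim(wf), sim(wm))
  pres <- data.frame(mirna_name = "mirM", presence = "male",
                     stringsAsFactors = FALSE)
  real_sites <- data.frame(mirna_name = "mirM",
                           transcript_id = sprintf("t%02d", 1:4),
                           site_start = 1L, site_end = 21L,
                           expectation = 0, mode = "cleavage",
                           stringsAsFactors = FALSE)
  real <- anticorrelation_report(pres, real_sites, prof)$difference
  perm <- replicate(100, {
    s <- real_sites
    s$transcript_id <- sprintf("t%02d", sample(12, 4))
    anticorrelation_report(pres, s, prof)$difference
  })
  expect_lt(real, mean(perm))
  expect_lt(abs(mean(perm)), abs(real))
})
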