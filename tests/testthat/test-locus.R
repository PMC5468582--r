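make_toy_genome <- function(targets, arrangement) {
  # arrangement: list(chrom = c(target ids in order)); spacer 500 nt
  set.seed(71)
  rows <- list(); ann <- list()
  for (cn in names(arrangement)) {
    parts <- character(0); pos <- 0L
    for (g in arrangement[[cn]]) {
      sp <- rand_rna_str(500)
      gs <- targets$seq[targets$id == g]
      parts <- c(parts, sp, gs)
      ann[[length(ann) + 1L]] <- data.frame(
        seqid = cn, start = pos + 501L, end = pos + 500L + nchar(gs),
        strand = "+", ID = g, stringsAsFactors = FALSE)
      pos <- pos + 500L + nchar(gs)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = cn, seq = paste(c(parts, rand_rna_str(300)), collapse = ""),
      stringsAsFactors = FALSE)
  }
  list(genome = do.call(rbind, rows), ann = do.call(rbind, ann))
}

test_that("targets are placed from annotation or by exact search", {
  set.seed(72)
  targets <- data.frame(id = c("g1", "g2", "g3", "lost"),
                        seq = vapply(c(200, 250, 180, 150), rand_rna_str,
                                     character(1)),
                        stringsAsFactors = FALSE)
  toy <- make_toy_genome(targets, list(chr1 = c("g1", "g2"),
                                       chr2 = "g3"))
  # g1 via annotation; g2/g3 by search; "lost" is absent from the genome
  ann <- toy$ann[toy$ann$ID == "g1", , drop = FALSE]
  pl <- place_targets(targets, toy$genome, ann)
  p <- pl$placements
  expect_equal(p$source[p$target_id == "g1"], "gff")
  expect_equal(p$source[p$target_id == "g2"], "exact_match")
  expect_equal(p$start[p$target_id == "g1"],
               toy$ann$start[toy$ann$ID == "g1"])
  expect_equal(p$start[p$target_id == "g2"],
               toy$ann$start[toy$ann$ID == "g2"])
  expect_equal(pl$unplaced, "lost")
  expect_error(place_targets(targets, toy$genome[0, ]), "empty")
})

test_that("a reverse-complement embedding is found on the minus strand", {
  set.seed(73)
  tg <- data.frame(id = "g", seq = rand_rna_str(200),
                   stringsAsFactors = FALSE)
  genome <- data.frame(id = "chr1",
                       seq = paste0(rand_rna_str(500), rc_str(tg$seq),
                                    rand_rna_str(400)),
                       stringsAsFactors = FALSE)
  p <- place_targets(tg, genome)$placements
  expect_equal(p$strand, "-")
  expect_equal(p$start, 501L)
  expect_equal(p$end, 700L)
})

test_that("annotation/search chromosome disagreement raises an error", {
  set.seed(74)
  tg <- data.frame(id = "g", seq = rand_rna_str(150),
                   stringsAsFactors = FALSE)
  genome <- data.frame(
    id = c("chrA", "chrB"),
    seq = c(rand_rna_str(600),
            paste0(rand_rna_str(100), tg$seq, rand_rna_str(100))),
    stringsAsFactors = FALSE)
  ann <- data.frame(seqid = "chrA", start = 10L, end = 159L, strand = "+",
                    ID = "g", stringsAsFactors = FALSE)
  expect_error(place_targets(tg, genome, ann), "conflict")
})

test_that("locus candidates require all three clauses", {
  placements <- data.frame(
    target_id = c("inlocus_ok", "inlocus_nosite", "outlocus",
                  "inlocus_bothsex", "boundary"),
    chrom = c("chr2", "chr2", "chr1", "chr2", "chr2"),
    start = c(1200L, 1300L, 1200L, 1250L, 700L),
    end = c(1600L, 1700L, 1600L, 1650L, 999L),
    strand = "+", source = "gff", stringsAsFactors = FALSE)
  locus <- "chr2:1000-2000"
  sites <- data.frame(
    mirna_name = c("mirM", "mirM", "mirM", "mirBoth"),
    transcript_id = c("inlocus_ok", "outlocus", "boundary",
                      "inlocus_bothsex"),
    site_start = 1L, site_end = 21L, expectation = 0.5,
    mode = "cleavage", stringsAsFactors = FALSE)
  presence <- data.frame(mirna_name = c("mirM", "mirBoth"),
                         presence = c("male", "both"),
                         stringsAsFactors = FALSE)
  profiles <- data.frame(
    target_id = placements$target_id,
    count_female = c(50L, 50L, 50L, 20L, 50L),
    count_male = c(0L, 0L, 0L, 10L, 0L),
    tpm_female = 1, tpm_male = 0, log2_female = 1, log2_male = 0,
    stringsAsFactors = FALSE)
  profiles <- classify_specificity(profiles)
  out <- flag_locus_candidates(placements, locus, sites, presence,
                               profiles)
  expect_equal(out$target_id, "inlocus_ok")
  expect_equal(out$regulator, "mirM")
  expect_equal(out$regulator_specificity, "male")
  expect_equal(out$expression_class, "female_only")
  expect_match(out$rationale, "in_locus")
  expect_match(out$rationale, "male_specific_regulator")

  # strict mode rejects expressed-sex == regulator-sex; lenient keeps it
  prof2 <- profiles
  prof2$count_female[1] <- 0L
  prof2$count_male[1] <- 30L
  prof2 <- classify_specificity(prof2)
  expect_equal(nrow(flag_locus_candidates(placements, locus, sites,
                                          presence, prof2)), 0L)
  len <- flag_locus_candidates(placements, locus, sites, presence, prof2,
                               mode = "lenient")
  expect_equal(len$target_id, "inlocus_ok")
})

test_that("a target ending one base before the locus is never flagged", {
  placements <- data.frame(target_id = "edge", chrom = "chr2",
                           start = 800L, end = 999L, strand = "+",
                           source = "gff", stringsAsFactors = FALSE)
  sites <- data.frame(mirna_name = "mirM", transcript_id = "edge",
                      site_start = 1L, site_end = 21L, expectation = 0,
                      mode = "cleavage", stringsAsFactors = FALSE)
  presence <- data.frame(mirna_name = "mirM", presence = "male",
                         stringsAsFactors = FALSE)
  profiles <- classify_specificity(data.frame(
    target_id = "edge", count_female = 9L, count_male = 0L,
    log2_female = 1, log2_male = 0, stringsAsFactors = FALSE))
  expect_equal(nrow(flag_locus_candidates(placements, "chr2:1000-2000",
                                          sites, presence, profiles)), 0L)
  # but touching the first base flags it
  placements$end <- 1000L
  expect_equal(nrow(flag_locus_candidates(placements, "chr2:1000-2000",
                                          sites, presence, profiles)), 1L)
  expect_error(parse_locus_check <- validate_locus(
    "chrZ:1-10", data.frame(id = "chr2", seq = "ACGU")), "chrZ")
})

test_that("chromosome distribution marginals count every placed target", {
  placements <- data.frame(
    target_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = 1L, end = 10L, strand = "+", source = "gff",
    stringsAsFactors = FALSE)
  classes <- data.frame(
    target_id = c("a", "b", "c", "d"),
    regulator_class = c("common", "common", "male_specific",
                        "female_specific"),
    stringsAsFactors = FALSE)
  tab <- chromosome_distribution(placements, classes)
  expect_equal(tab$common[tab$chrom == "chr1"], 2L)
  expect_equal(tab$male_specific[tab$chrom == "chr1"], 1L)
  expect_equal(sum(tab$total), nrow(placements))
  expect_equal(nrow(chromosome_distribution(placements[0, ], classes)), 0L)
})

test_that("regulator classes prefer the strongest sex-specific site", {
  sites <- data.frame(
    mirna_name = c("mCommon", "mF", "mM", "mCommon"),
    transcript_id = c("t1", "t1", "t1", "t2"),
    site_start = c(1L, 50L, 100L, 1L), site_end = c(21L, 70L, 120L, 21L),
    expectation = c(0, 1.5, 0.5, 0), mode = "cleavage",
    stringsAsFactors = FALSE)
  presence <- data.frame(mirna_name = c("mCommon", "mF", "mM"),
                         presence = c("both", "female", "male"),
                         stringsAsFactors = FALSE)
  cls <- target_regulator_class(sites, presence)
  expect_equal(cls$regulator_class[cls$target_id == "t1"],
               "male_specific")   # mM site (0.5) beats mF (1.5)
  expect_equal(cls$regulator_class[cls$target_id == "t2"], "common")
})
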