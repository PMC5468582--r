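#' Configuration for the synthetic two-sex dataset generator
#'
#' Desk-scale defaults emulate the shape (not the size) of a sex-separated
#' flower-bud EST study: a reference mature-miRNA set with cross-species
#' duplicates, two EST pools (mean length about 389 nt) with planted
#' stem-loop precursors carrying near-copies of reference matures, coding
#' and ncRNA decoys, target transcripts with complementarity sites at
#' designed expectations, sex-biased reads with miRNA-target
#' anti-correlation, and one target placed inside a configured gender
#' locus, expressed in one sex only and regulated by a miRNA of the other
#' sex.
#'
#' @param seed Integer seed (mandatory; same seed, same bytes).
#' @param n_chromosomes,chrom_spacer Number of assembly chromosomes and
#'   random spacer length between embedded genes (nt).
#' @param n_ests_per_sex ESTs emitted per sex (precursor carriers plus
#'   random decoy ESTs).
#' @param n_ref_families Distinct reference mature sequences (each listed
#'   under 1-3 species names so reference deduplication has work to do).
#' @param n_common,n_female_specific,n_male_specific Planted precursor
#'   counts by sex class (common precursors are planted in both pools).
#' @param mature_length_range,precursor_length_range Planted lengths (nt).
#' @param mismatches_to_reference Maximum planted mature-vs-reference
#'   Hamming distance (each precursor draws 0..max).
#' @param est_mean_length Mean EST length (nt).
#' @param n_targets Target transcripts.
#' @param n_decoys Decoy sequences per database (protein / ncRNA).
#' @param n_false_precursors ESTs per sex that carry a mature copy inside
#'   an ncRNA decoy (exercises the exclusion screen).
#' @param reads_per_sex,read_length Read simulation scale.
#' @param anticorrelation_fold Expression fold-suppression of a target in
#'   the sex where its regulating miRNA is present (> 1).
#' @param plant_locus_candidate Plant the single gender-locus candidate?
#' @return A config list (class \code{synthetic_config}).
#' @export
synthetic_config <- function(seed,
                             n_chromosomes = 3L,
                             chrom_spacer = 400L,
                             n_ests_per_sex = 200L,
                             n_ref_families = 20L,
                             n_common = 5L,
                             n_female_specific = 3L,
                             n_male_specific = 7L,
                             mature_length_range = c(20L, 22L),
                             precursor_length_range = c(51L, 138L),
                             mismatches_to_reference = 2L,
                             est_mean_length = 389L,
                             n_targets = 30L,
                             n_decoys = 8L,
                             n_false_precursors = 2L,
                             reads_per_sex = 5000L,
                             read_length = 50L,
                             anticorrelation_fold = 8,
                             plant_locus_candidate = TRUE) {
  if (missing(seed)) stop("synthetic_config: seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_spacer = chrom_spacer,
              n_ests_per_sex = n_ests_per_sex,
              n_ref_families = n_ref_families, n_common = n_common,
              n_female_specific = n_female_specific,
              n_male_specific = n_male_specific,
              mature_length_range = mature_length_range,
              precursor_length_range = precursor_length_range,
              mismatches_to_reference = mismatches_to_reference,
              est_mean_length = est_mean_length, n_targets = n_targets,
              n_decoys = n_decoys,
              n_false_precursors = n_false_precursors,
              reads_per_sex = reads_per_sex, read_length = read_length,
              anticorrelation_fold = anticorrelation_fold,
              plant_locus_candidate = plant_locus_candidate)
  n_planted <- n_common + n_female_specific + n_male_specific
  if (n_planted > n_ref_families)
    stop("more planted precursors than reference families")
  lp_min <- precursor_length_range[1]
  lm_max <- mature_length_range[2]
  if (lp_min < 2L * (lm_max + 2L) + 3L)
    stop("infeasible config: shortest precursor (", lp_min,
         ") cannot hold a ", lm_max, "-nt mature in one arm plus a loop")
  if (anticorrelation_fold <= 1) stop("anticorrelation_fold must be > 1")
  structure(cfg, class = "synthetic_config")
}

rand_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_rna <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Build a perfect stem-loop precursor holding `mature` wholly inside the
# designated arm. Returns list(seq, mature_offset, arm, loop_len).
build_precursor <- function(mature, LP, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  lm <- nchar(mature)
  arm_len <- (LP - 3L) %/% 2L
  arm_len <- min(arm_len, max(lm + 2L, (LP - 8L) %/% 2L))
  loop_len <- LP - 2L * arm_len
  if (arm_len < lm + 2L || loop_len < 3L)
    stop("infeasible precursor: mature ", lm, " nt in ", LP, " nt window")
  off_in_arm <- sample(2:(arm_len - lm), 1)   # strictly inside the arm
  host <- paste0(rand_rna(off_in_arm - 1L), mature,
                 rand_rna(arm_len - lm - off_in_arm + 1L))
  loop <- rand_rna(loop_len, gc = 0.3)
  if (arm == "5p") {
    seq <- paste0(host, loop, revcomp_rna(host))
    mature_offset <- off_in_arm
  } else {
    seq <- paste0(revcomp_rna(host), loop, host)
    mature_offset <- arm_len + loop_len + off_in_arm
  }
  list(seq = seq, mature_offset = mature_offset, arm = arm,
       loop_len = loop_len)
}

#' Generate a seeded synthetic two-sex dataset with known truth
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param dir Optional output directory; when given, every component is
#'   written as FASTA / GFF3 / TSV plus a config-echo text file, and the
#'   file paths are returned in \code{$files}.
#' @return List with \code{reference}, \code{ests_female},
#'   \code{ests_male}, \code{transcripts}, \code{genome},
#'   \code{annotations}, \code{reads_female}, \code{reads_male},
#'   \code{protein_db}, \code{ncrna_db}, \code{locus} (string), and
#'   \code{truth} (precursors, sites, expression, mirna_presence,
#'   locus_candidate_id, config_echo).
#' @export
generate_synthetic <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- reference mature set (with cross-species duplicates) ----
  fam_ids <- 100L + seq_len(cfg$n_ref_families)
  species_pool <- c("ath", "osa", "ptc", "mtr", "vvi")
  ref_seqs <- character(cfg$n_ref_families)
  for (i in seq_len(cfg$n_ref_families)) {
    repeat {
      s <- rand_rna(sample(seq(cfg$mature_length_range[1],
                               cfg$mature_length_range[2]), 1))
      if (!s %in% ref_seqs) break
    }
    ref_seqs[i] <- s
  }
  ref_rows <- list()
  for (i in seq_len(cfg$n_ref_families)) {
    n_sp <- sample(1:3, 1)
    for (sp in sample(species_pool, n_sp)) {
      ref_rows[[length(ref_rows) + 1L]] <-
        data.frame(name = paste0(sp, "-miR", fam_ids[i], "a"),
                   seq = ref_seqs[i], stringsAsFactors = FALSE)
    }
  }
  reference <- do.call(rbind, ref_rows)

  ## ---- planted matures by sex class ----
  n_planted <- cfg$n_common + cfg$n_female_specific + cfg$n_male_specific
  planted_fam <- sample(cfg$n_ref_families, n_planted)
  sex_class <- rep(c("both", "female", "male"),
                   c(cfg$n_common, cfg$n_female_specific,
                     cfg$n_male_specific))
  planted <- lapply(seq_len(n_planted), function(i) {
    fi <- planted_fam[i]
    k <- sample(0:cfg$mismatches_to_reference, 1)
    list(family = paste0("miR", fam_ids[fi]),
         ref_seq = ref_seqs[fi], mature = mutate_rna(ref_seqs[fi], k),
         mismatches = k, sex = sex_class[i])
  })

  ## ---- precursors and ESTs per sex ----
  truth_prec <- list()
  ests <- list(female = list(), male = list())
  est_counter <- c(female = 0L, male = 0L)
  for (p in planted) {
    sexes <- if (p$sex == "both") c("female", "male") else p$sex
    for (sx in sexes) {
      LP <- sample(seq(cfg$precursor_length_range[1],
                       cfg$precursor_length_range[2]), 1)
      arm <- sample(c("5p", "3p"), 1)
      prec <- build_precursor(p$mature, LP, arm)
      est_counter[sx] <- est_counter[sx] + 1L
      est_id <- sprintf("%s_est%04d", substr(sx, 1, 1), est_counter[sx])
      est_len <- max(nchar(prec$seq) + 20L,
                     round(stats::rnorm(1, cfg$est_mean_length, 60)))
      flank_left <- sample(5:(est_len - nchar(prec$seq) - 5L), 1)
      strand <- sample(c("+", "-"), 1)
      embedded <- if (strand == "+") prec$seq else revcomp_rna(prec$seq)
      est_seq <- paste0(rand_rna(flank_left - 1L), embedded,
                        rand_rna(est_len - flank_left + 1L -
                                 nchar(prec$seq)))
      ests[[sx]][[length(ests[[sx]]) + 1L]] <-
        data.frame(id = est_id, seq = est_seq, stringsAsFactors = FALSE)
      w_start <- flank_left
      w_end <- flank_left + nchar(prec$seq) - 1L
      if (strand == "+") {
        m_start <- w_start + prec$mature_offset - 1L
      } else {
        m_start <- w_end - (prec$mature_offset + nchar(p$mature) - 1L) + 1L
      }
      truth_prec[[length(truth_prec) + 1L]] <- data.frame(
        sex = sx, est_id = est_id, window_start = w_start,
        window_end = w_end, strand = strand, arm = prec$arm,
        mature_seq = p$mature, mature_start = m_start,
        mature_end = m_start + nchar(p$mature) - 1L,
        family = p$family, mismatches = p$mismatches, LP = nchar(prec$seq),
        stringsAsFactors = FALSE)
    }
  }
  truth_prec <- do.call(rbind, truth_prec)

  ## ---- ncRNA decoys, plus false precursors embedded in decoys ----
  ncrna_db <- data.frame(
    id = sprintf("ncrna%02d", seq_len(cfg$n_decoys)),
    seq = vapply(seq_len(cfg$n_decoys),
                 function(i) rand_rna(sample(150:250, 1)), character(1)),
    stringsAsFactors = FALSE)
  false_ids <- list(female = character(0), male = character(0))
  for (sx in c("female", "male")) {
    for (j in seq_len(cfg$n_false_precursors)) {
      d <- sample(nrow(ncrna_db), 1)
      host <- ncrna_db$seq[d]
      mat <- planted[[sample(n_planted, 1)]]$mature
      pos <- sample(nchar(host) - nchar(mat) - 10L, 1) + 5L
      mod <- paste0(substr(host, 1, pos - 1L), mat,
                    substr(host, pos + nchar(mat), nchar(host)))
      est_counter[sx] <- est_counter[sx] + 1L
      est_id <- sprintf("%s_est%04d", substr(sx, 1, 1), est_counter[sx])
      ests[[sx]][[length(ests[[sx]]) + 1L]] <-
        data.frame(id = est_id, seq = mod, stringsAsFactors = FALSE)
      false_ids[[sx]] <- c(false_ids[[sx]], est_id)
    }
  }

  ## ---- filler decoy ESTs ----
  for (sx in c("female", "male")) {
    while (length(ests[[sx]]) < cfg$n_ests_per_sex) {
      est_counter[sx] <- est_counter[sx] + 1L
      ests[[sx]][[length(ests[[sx]]) + 1L]] <- data.frame(
        id = sprintf("%s_est%04d", substr(sx, 1, 1), est_counter[sx]),
        seq = rand_rna(max(60L, round(stats::rnorm(1, cfg$est_mean_length,
                                                   60)))),
        stringsAsFactors = FALSE)
    }
  }
  ests_female <- do.call(rbind, ests$female)
  ests_male <- do.call(rbind, ests$male)

  ## ---- protein decoys ----
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  protein_db <- data.frame(
    id = sprintf("prot%02d", seq_len(cfg$n_decoys)),
    seq = vapply(seq_len(cfg$n_decoys), function(i)
      paste(sample(aa, sample(80:150, 1), replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)

  ## ---- targets with planted complementarity sites ----
  mirna_presence_truth <- data.frame(
    mature_seq = vapply(planted, `[[`, character(1), "mature"),
    presence = vapply(planted, `[[`, character(1), "sex"),
    family = vapply(planted, `[[`, character(1), "family"),
    stringsAsFactors = FALSE)
  n_t <- cfg$n_targets
  t_ids <- sprintf("gene%03d", seq_len(n_t))
  t_len <- sample(300:600, n_t, replace = TRUE)
  t_seqs <- vapply(t_len, rand_rna, character(1))
  # designed sites: cycle planted matures over targets; designs alternate
  # perfect (0), non-seed wobble (0.5), seed mismatch (2.0)
  designs <- c(0, 0.5, 2.0)
  truth_sites <- list()
  site_targets <- seq_len(max(1L, n_t - 2L))  # leave a couple untargeted
  for (ti in site_targets) {
    mi <- ((ti - 1L) %% n_planted) + 1L
    mat <- planted[[mi]]$mature
    lm <- nchar(mat)
    design <- designs[((ti - 1L) %/% n_planted) %% length(designs) + 1L]
    site <- revcomp_rna(mat)                  # perfect complement
    if (design == 0.5) {
      # G:U wobble at miRNA position 15 (outside the doubled 2-13 region):
      # miRNA G paired to target U, or miRNA U paired to target G
      pos <- 15L
      mch <- substr(mat, pos, pos)
      tpos <- lm - pos + 1L
      repl <- if (mch == "G") "U" else if (mch == "U") "G" else NA
      if (is.na(repl)) { design <- 0 } else
        substr(site, tpos, tpos) <- repl
    }
    if (design == 2.0) {
      # mismatch at miRNA position 5 (inside 2-13): target base neither
      # complementary nor wobble-paired
      pos <- 5L
      mch <- substr(mat, pos, pos)
      tpos <- lm - pos + 1L
      bad <- setdiff(c("A", "C", "G", "U"),
                     c(chartr("ACGU", "UGCA", mch),
                       if (mch == "G") "U" else if (mch == "U") "G"))
      substr(site, tpos, tpos) <- sample(bad, 1)
    }
    pos_on_t <- sample(50:(t_len[ti] - lm - 50L), 1)
    t_seqs[ti] <- paste0(substr(t_seqs[ti], 1, pos_on_t - 1L), site,
                         substr(t_seqs[ti], pos_on_t + lm, t_len[ti]))
    truth_sites[[length(truth_sites) + 1L]] <- data.frame(
      mature_seq = mat, transcript_id = t_ids[ti],
      site_start = pos_on_t, site_end = pos_on_t + lm - 1L,
      designed_expectation = design, stringsAsFactors = FALSE)
  }
  truth_sites <- do.call(rbind, truth_sites)

  ## ---- locus candidate target ----
  locus_candidate_id <- NA_character_
  if (cfg$plant_locus_candidate) {
    male_idx <- which(mirna_presence_truth$presence == "male")[1]
    mat <- mirna_presence_truth$mature_seq[male_idx]
    lm <- nchar(mat)
    locus_candidate_id <- "gene_locus_cand"
    cl <- 450L
    cseq <- rand_rna(cl)
    pos <- sample(50:(cl - lm - 50L), 1)
    cseq <- paste0(substr(cseq, 1, pos - 1L), revcomp_rna(mat),
                   substr(cseq, pos + lm, cl))
    t_ids <- c(t_ids, locus_candidate_id)
    t_seqs <- c(t_seqs, cseq)
    t_len <- c(t_len, cl)
    truth_sites <- rbind(truth_sites, data.frame(
      mature_seq = mat, transcript_id = locus_candidate_id,
      site_start = pos, site_end = pos + lm - 1L,
      designed_expectation = 0, stringsAsFactors = FALSE))
  }
  transcripts <- data.frame(id = t_ids, seq = t_seqs,
                            stringsAsFactors = FALSE)

  ## ---- genome: chromosomes built from spacers + embedded targets ----
  n_chr <- cfg$n_chromosomes
  chrom_names <- sprintf("chr%02d", seq_len(n_chr))
  other <- setdiff(t_ids, locus_candidate_id)
  chr_assign <- stats::setNames(
    chrom_names[1L + (seq_along(other) - 1L) %% max(1L, n_chr - 1L)],
    other)
  gene_strand <- stats::setNames(
    sample(c("+", "-"), length(other), replace = TRUE, prob = c(.8, .2)),
    other)
  genome_rows <- list()
  ann_rows <- list()
  for (ci in seq_len(n_chr)) {
    cn <- chrom_names[ci]
    genes_here <- names(chr_assign)[chr_assign == cn]
    seq_parts <- character(0)
    pos <- 0L
    for (g in genes_here) {
      sp <- rand_rna(cfg$chrom_spacer + sample(0:100, 1))
      gs <- transcripts$seq[transcripts$id == g]
      if (gene_strand[g] == "-") gs <- revcomp_rna(gs)
      seq_parts <- c(seq_parts, sp, gs)
      gstart <- pos + nchar(sp) + 1L
      gend <- gstart + nchar(gs) - 1L
      pos <- gend
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        seqid = cn, start = gstart, end = gend, strand = gene_strand[g],
        ID = g, stringsAsFactors = FALSE)
    }
    if (cfg$plant_locus_candidate && ci == n_chr) {
      sp <- rand_rna(4000L)
      gs <- transcripts$seq[transcripts$id == locus_candidate_id]
      seq_parts <- c(seq_parts, sp, gs)
      gstart <- pos + nchar(sp) + 1L
      gend <- gstart + nchar(gs) - 1L
      pos <- gend
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        seqid = cn, start = gstart, end = gend, strand = "+",
        ID = locus_candidate_id, stringsAsFactors = FALSE)
      locus <- sprintf("%s:%d-%d", cn, gstart - 1000L, gend + 1000L)
    }
    seq_parts <- c(seq_parts, rand_rna(cfg$chrom_spacer))
    genome_rows[[ci]] <- data.frame(id = cn,
                                    seq = paste(seq_parts, collapse = ""),
                                    stringsAsFactors = FALSE)
  }
  if (!cfg$plant_locus_candidate)
    locus <- sprintf("%s:%d-%d", chrom_names[n_chr], 1L, 2000L)
  genome <- do.call(rbind, genome_rows)
  annotations_full <- do.call(rbind, ann_rows)
  # only half the genes get a GFF record; the rest are placed by exact
  # sequence search
  keep_ann <- sort(sample(nrow(annotations_full),
                          nrow(annotations_full) %/% 2L))
  annotations <- annotations_full[keep_ann, , drop = FALSE]
  rownames(annotations) <- NULL

  ## ---- expression design + reads ----
  base_w <- exp(stats::rnorm(length(t_ids), log(50), 0.6))
  wf <- base_w
  wm <- base_w
  tclass <- stats::setNames(rep("none", length(t_ids)), t_ids)
  pres_by_seq <- stats::setNames(mirna_presence_truth$presence,
                                 mirna_presence_truth$mature_seq)
  for (i in seq_along(t_ids)) {
    s <- truth_sites[truth_sites$transcript_id == t_ids[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    cls <- pres_by_seq[s$mature_seq]
    if (any(cls == "male")) {
      wm[i] <- wm[i] / cfg$anticorrelation_fold
      tclass[i] <- "male_regulated"
    } else if (any(cls == "female")) {
      wf[i] <- wf[i] / cfg$anticorrelation_fold
      tclass[i] <- "female_regulated"
    }
  }
  if (cfg$plant_locus_candidate) {
    i <- match(locus_candidate_id, t_ids)
    wm[i] <- 0                       # silenced in the male: female-only
    wf[i] <- max(wf[i], stats::median(base_w))
  }
  # a few single-sex targets among the untargeted filler genes
  filler <- setdiff(seq_along(t_ids),
                    c(match(truth_sites$transcript_id, t_ids)))
  if (length(filler) >= 2L) {
    wf[filler[1]] <- 0
    wm[filler[2]] <- 0
  }
  expression_truth <- data.frame(target_id = t_ids, weight_female = wf,
                                 weight_male = wm, regulated = unname(tclass),
                                 stringsAsFactors = FALSE)
  sim_reads <- function(weights, prefix) {
    pick <- sample(seq_along(t_ids), cfg$reads_per_sex, replace = TRUE,
                   prob = weights / sum(weights))
    rl <- cfg$read_length
    starts <- vapply(pick, function(i) sample(t_len[i] - rl + 1L, 1),
                     integer(1))
    strand <- sample(c("+", "-"), cfg$reads_per_sex, replace = TRUE)
    seqs <- substring(t_seqs[pick], starts, starts + rl - 1L)
    rc <- strand == "-"
    seqs[rc] <- revcomp_rna(seqs[rc])
    data.frame(id = sprintf("%s_read%05d", prefix,
                            seq_len(cfg$reads_per_sex)),
               seq = seqs, stringsAsFactors = FALSE)
  }
  reads_female <- sim_reads(wf, "f")
  reads_male <- sim_reads(wm, "m")

  config_echo <- paste(vapply(names(unclass(cfg)), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1)),
    collapse = ";")
  result <- list(reference = reference, ests_female = ests_female,
                 ests_male = ests_male, transcripts = transcripts,
                 genome = genome, annotations = annotations,
                 reads_female = reads_female, reads_male = reads_male,
                 protein_db = protein_db, ncrna_db = ncrna_db,
                 locus = locus,
                 truth = list(precursors = truth_prec, sites = truth_sites,
                              expression = expression_truth,
                              mirna_presence = mirna_presence_truth,
                              false_precursor_ests = false_ids,
                              locus_candidate_id = locus_candidate_id,
                              locus = locus, config_echo = config_echo),
                 config = cfg)
  if (!is.null(dir)) result$files <- write_synthetic(result, dir)
  result
}

# Write every generated component as plain-text standard formats.
write_synthetic <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  as_fa <- function(df) data.frame(id = df$id, seq = df$seq,
                                   stringsAsFactors = FALSE)
  ref <- data.frame(id = synth$reference$name, seq = synth$reference$seq,
                    stringsAsFactors = FALSE)
  # duplicate names across species entries are disambiguated in the file
  ref$id <- make.unique(ref$id, sep = "_dup")
  files <- list(
    reference = write_fasta(ref, p("reference_mirnas.fasta")),
    ests_female = write_fasta(as_fa(synth$ests_female),
                              p("ests_female.fasta")),
    ests_male = write_fasta(as_fa(synth$ests_male), p("ests_male.fasta")),
    transcripts = write_fasta(as_fa(synth$transcripts),
                              p("transcripts.fasta")),
    genome = write_fasta(as_fa(synth$genome), p("genome.fasta")),
    reads_female = write_fasta(as_fa(synth$reads_female),
                               p("reads_female.fasta")),
    reads_male = write_fasta(as_fa(synth$reads_male),
                             p("reads_male.fasta")),
    protein_db = write_fasta(as_fa(synth$protein_db),
                             p("decoys_protein.fasta")),
    ncrna_db = write_fasta(as_fa(synth$ncrna_db), p("decoys_ncrna.fasta")),
    annotations = write_gff3_genes(synth$annotations, p("genes.gff3")),
    truth_precursors = write_tsv_report(synth$truth$precursors,
                                        p("truth_precursors.tsv")),
    truth_sites = write_tsv_report(synth$truth$sites,
                                   p("truth_sites.tsv")),
    truth_expression = write_tsv_report(synth$truth$expression,
                                        p("truth_expression.tsv")))
  writeLines(c(paste0("locus=", synth$locus),
               paste0("locus_candidate=", synth$truth$locus_candidate_id),
               synth$truth$config_echo), p("config_echo.txt"))
  files$config_echo <- p("config_echo.txt")
  files
}

# Minimal GFF3 gene-feature writer (read side goes through rtracklayer).
write_gff3_genes <- function(ann, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$seqid, ann$start, ann$end, ann$strand, ann$ID))
  writeLines(lines, path)
  invisible(path)
}

#' Truth-recovery metrics for a pipeline run on synthetic data
#'
#' Planted precursors are matched by EST id and window coordinates within
#' \code{tolerance} nt; predicted sites are matched to planted sites by
#' mature sequence, transcript and span overlap.
#'
#' @param result A \code{\link{run_full}} (or \code{\link{run_discovery}})
#'   result from the same generated dataset.
#' @param truth The \code{$truth} element of \code{\link{generate_synthetic}}.
#' @param tolerance Coordinate slack for precursor windows (nt); defaults
#'   to one window-grid step.
#' @return List: \code{precursor_recall}, \code{precursor_precision},
#'   \code{site_recall}, \code{site_precision},
#'   \code{perfect_site_recall}, \code{locus_candidate_match} (logical).
#' @export
recovery_metrics <- function(result, truth, tolerance = 10L) {
  if (!is.null(result$config_echo) &&
      !identical(result$config_echo, truth$config_echo))
    stop("recovery_metrics: result and truth come from different configs")
  ## precursors
  tp <- truth$precursors
  found <- logical(nrow(tp))
  inv_all <- rbind(cbind(result$female$validated, sex = "female"),
                   cbind(result$male$validated, sex = "male"))
  n_pred <- nrow(inv_all)
  pred_matched <- logical(n_pred)
  for (i in seq_len(nrow(tp))) {
    cand <- which(inv_all$sex == tp$sex[i] &
                  inv_all$est_id == tp$est_id[i] &
                  abs(inv_all$window_start - tp$window_start[i]) <=
                    tolerance &
                  abs(inv_all$window_end - tp$window_end[i]) <= tolerance)
    if (length(cand) > 0L) {
      found[i] <- TRUE
      pred_matched[cand] <- TRUE
    }
  }
  prec_recall <- mean(found)
  prec_precision <- if (n_pred > 0L) mean(pred_matched) else NA_real_
  ## sites
  metrics <- list(precursor_recall = prec_recall,
                  precursor_precision = prec_precision)
  ts <- truth$sites
  sites <- result$sites
  mat_of <- result$mirna_mature    # name -> mature seq mapping
  s_found <- logical(nrow(ts))
  s_pred_matched <- if (is.null(sites)) logical(0) else
    logical(nrow(sites))
  if (!is.null(sites) && nrow(sites) > 0L) {
    sites$mature_seq <- mat_of[sites$mirna_name]
    for (i in seq_len(nrow(ts))) {
      cand <- which(sites$mature_seq == ts$mature_seq[i] &
                    sites$transcript_id == ts$transcript_id[i] &
                    sites$site_start <= ts$site_end[i] &
                    sites$site_end >= ts$site_start[i])
      if (length(cand) > 0L) {
        s_found[i] <- TRUE
        s_pred_matched[cand] <- TRUE
      }
    }
  }
  metrics$site_recall <- mean(s_found)
  metrics$site_precision <- if (length(s_pred_matched) > 0L)
    mean(s_pred_matched) else NA_real_
  perfect <- ts$designed_expectation == 0
  metrics$perfect_site_recall <- if (any(perfect)) mean(s_found[perfect])
    else NA_real_
  ## locus candidate
  lc <- result$locus_candidates
  metrics$locus_candidate_match <-
    !is.null(lc) && nrow(lc) == 1L &&
    identical(lc$target_id, truth$locus_candidate_id)
  metrics
}
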