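#' Read a FASTA file into a sequence table
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file and normalizes
#' every sequence to the RNA alphabet used internally by the package
#' (A, C, G, U, N).
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy \code{"dna_to_rna"} (the default: T/t is
#'   converted to U, lower case is upped, and IUPAC ambiguity codes other
#'   than N are collapsed to N), \code{"strict"} (sequences must already
#'   be over A/C/G/U/N; anything else is an error naming the offending
#'   record and position), or \code{"protein"} (amino-acid records:
#'   uppercased, stops kept as \code{*}, no nucleotide conversion).
#' @return A data frame with columns \code{id}, \code{description} and
#'   \code{seq} (RNA alphabet), one row per record, in file order.
#' @details Record ids must be unique within a file; a duplicated id is an
#'   error. The id is the first whitespace-delimited token of the header
#'   line, the description is the remainder (possibly empty).
#' @export
read_fasta <- function(path, alphabet_policy = c("dna_to_rna", "strict",
                                                 "protein")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_seq(seqs[[i]], alphabet_policy, id = ids[[i]])
  }, character(1))
  data.frame(id = ids, description = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

# Normalize one sequence string to the internal RNA alphabet.
normalize_seq <- function(seq, alphabet_policy = "dna_to_rna", id = "?") {
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
  s <- toupper(seq)
  if (alphabet_policy == "protein") {
    bad <- regexpr("[^A-Z*]", s)
    if (bad > 0L)
      stop("non-amino-acid character '", substr(s, bad, bad),
           "' at position ", bad, " in record '", id, "'")
    return(s)
  }
  if (alphabet_policy == "strict") {
    bad <- regexpr("[^ACGUN]", s)
    if (bad > 0L)
      stop("non-ACGUN character '", substr(s, bad, bad), "' at position ",
           bad, " in record '", id, "' (strict alphabet policy)")
    return(s)
  }
  s <- chartr("T", "U", s)
  # IUPAC ambiguity codes (R, Y, S, W, K, M, B, D, H, V) collapse to N;
  # anything outside the IUPAC nucleotide set is an input error.
  bad <- regexpr("[^ACGUNRYSWKMBDHV]", s)
  if (bad > 0L)
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ",
         bad, " in record '", id, "'")
  gsub("[RYSWKMBDHV]", "N", s)
}

#' Write a sequence table to FASTA
#'
#' @param records Data frame with columns \code{id}, \code{seq} and
#'   optionally \code{description}.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reverse-complement an RNA string
#'
#' @param seq RNA string over A/C/G/U/N.
#' @return The reverse complement, same alphabet.
#' @export
revcomp_rna <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse a reference mature-miRNA set to unique sequences
#'
#' Reference databases list the same mature sequence once per species
#' (e.g. \code{ath-miR156a} and \code{osa-miR156a}). This collapses the
#' set to one record per distinct sequence, pooling the species prefixes
#' of all merged entries, so downstream homology search runs once per
#' unique sequence and species-conservation counts stay available.
#'
#' @param records Data frame with columns \code{name} and \code{seq}
#'   (mature RNA sequences, miRBase-style species-prefixed names). An
#'   existing \code{species_set} column (comma-joined) is pooled instead
#'   of re-parsing prefixes, which makes deduplication idempotent on its
#'   own output.
#' @return Data frame with columns \code{name} (the lexicographically
#'   first merged name), \code{seq}, \code{family}, \code{species_set}
#'   (comma-joined sorted species prefixes), \code{n_species} and
#'   \code{LM}; rows sorted by sequence for determinism.
#' @export
dedupe_reference <- function(records) {
  stopifnot(is.data.frame(records), all(c("name", "seq") %in% names(records)))
  if (nrow(records) == 0L)
    return(data.frame(name = character(), seq = character(),
                      family = character(), species_set = character(),
                      n_species = integer(), LM = integer(),
                      stringsAsFactors = FALSE))
  sp <- if ("species_set" %in% names(records))
    strsplit(records$species_set, ",", fixed = TRUE)
  else as.list(species_prefix(records$name))
  groups <- split(seq_len(nrow(records)), records$seq)
  out <- lapply(groups, function(idx) {
    nm <- sort(records$name[idx])[1]
    species <- sort(unique(unlist(sp[idx])))
    data.frame(name = nm, seq = records$seq[idx[1]],
               family = family_of(nm),
               species_set = paste(species, collapse = ","),
               n_species = length(species),
               LM = nchar(records$seq[idx[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Species prefix of a miRBase-style name: characters before the first "-".
# Names without a prefix are attributed to species "unknown" with a warning.
species_prefix <- function(name) {
  has <- grepl("-", name, fixed = TRUE)
  if (any(!has))
    warning("reference name(s) without a species prefix kept as 'unknown': ",
            paste(utils::head(name[!has], 5), collapse = ", "))
  ifelse(has, sub("-.*$", "", name), "unknown")
}

#' miRNA family of a miRBase-style name
#'
#' Strips the species prefix and variant suffix letters, returning
#' \code{"miR"} plus the leading family number (e.g. \code{"ssu-miR472a"}
#' becomes \code{"miR472"}).
#'
#' @param name Character vector of miRNA names containing a
#'   \code{miR<integer>} token.
#' @return Character vector of family names.
#' @export
family_of <- function(name) {
  m <- regmatches(name, regexpr("miR[0-9]+", name))
  bad <- !grepl("miR[0-9]+", name)
  if (any(bad))
    stop("no miR<number> token in name(s): ",
         paste(name[bad], collapse = ", "))
  m
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper around \code{rtracklayer::import} that keeps only gene
#' features and the fields the pipeline needs.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param feature_type Feature type(s) to keep (default \code{"gene"}).
#' @return Data frame with columns \code{seqid}, \code{start}, \code{end},
#'   \code{strand}, \code{ID}.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             ID = as.character(gr$ID),
             stringsAsFactors = FALSE)
}

# Write a data frame as a TSV report with a header row.
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
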