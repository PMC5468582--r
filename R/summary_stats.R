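#' Compare miRNA inventories between the sexes
#'
#' Pure set algebra on the grouping key: \code{by = "family"} compares
#' family names (e.g. miR472), \code{by = "sequence"} compares distinct
#' mature sequences (published summaries of this kind list
#' sequence variants of one family on different sides of the
#' common/specific split, so both groupings are available).
#'
#' @param female_rows,male_rows Inventory data frames (need \code{name}
#'   and \code{seq}; \code{family} is derived from \code{name} when
#'   absent).
#' @param by \code{"family"} (default) or \code{"sequence"}.
#' @return List of class \code{family_comparison}: \code{common},
#'   \code{female_specific}, \code{male_specific} (sorted character
#'   vectors of grouping keys; for \code{by = "sequence"} each element is
#'   named by a representative miRNA name), plus attribute \code{by}.
#' @export
family_sets <- function(female_rows, male_rows,
                        by = c("family", "sequence")) {
  by <- match.arg(by)
  key <- function(rows) {
    if (by == "family") {
      fam <- if ("family" %in% names(rows)) rows$family else
        family_of(rows$name)
      sort(unique(fam))
    } else {
      k <- unique(rows$seq)
      stats::setNames(k, rows$name[match(k, rows$seq)])
    }
  }
  f <- key(female_rows); m <- key(male_rows)
  res <- list(common = sort(intersect(f, m)),
              female_specific = sort(setdiff(f, m)),
              male_specific = sort(setdiff(m, f)))
  if (by == "sequence") {
    nm_f <- stats::setNames(names(f), f)
    nm_m <- stats::setNames(names(m), m)
    res <- lapply(res, function(x) {
      nm <- ifelse(is.na(nm_f[x]), nm_m[x], nm_f[x])
      stats::setNames(x, nm)
    })
  }
  structure(res, by = by, class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("Inventory comparison (by ", attr(x, "by"), "):\n", sep = "")
  for (k in names(x)) {
    lab <- if (attr(x, "by") == "sequence") names(x[[k]]) else x[[k]]
    cat(sprintf("  %-16s (%d): %s\n", k, length(x[[k]]),
                paste(lab, collapse = ", ")))
  }
  invisible(x)
}

#' Mature-length histogram and precursor-length statistics
#'
#' @param rows Inventory data frame with integer columns \code{LM}
#'   (mature length) and \code{LP} (precursor length), one row per miRNA
#'   as in the per-sex inventory tables.
#' @return List: \code{lm_hist} (data frame \code{LM}, \code{count}),
#'   \code{lp_stats} (list \code{mean} round-half-up integer,
#'   \code{mean_raw}, \code{min}, \code{max}).
#' @export
length_distribution <- function(rows) {
  stopifnot(nrow(rows) > 0L, all(c("LM", "LP") %in% names(rows)))
  tab <- table(rows$LM)
  lm_hist <- data.frame(LM = as.integer(names(tab)),
                        count = as.integer(tab))
  mean_raw <- mean(rows$LP)
  list(lm_hist = lm_hist,
       lp_stats = list(mean = round_half_up(mean_raw),
                       mean_raw = mean_raw,
                       min = min(rows$LP), max = max(rows$LP)))
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Build an inventory table from validated precursors
#'
#' One row per validated precursor with the columns of the standard
#' per-sex inventory report: name, mature sequence, LM, arm, precursor
#' location (1-based inclusive \code{est:start..end:strand}) and LP.
#'
#' @param validated Data frame of validated precursors (needs
#'   \code{name}, \code{mature_seq}, \code{arm}, \code{est_id},
#'   \code{window_start}, \code{window_end}, \code{strand}, \code{LP}).
#' @return Inventory data frame: \code{name}, \code{seq}, \code{LM},
#'   \code{arm}, \code{location}, \code{LP}, \code{family}.
#' @export
build_inventory <- function(validated) {
  if (nrow(validated) == 0L)
    return(data.frame(name = character(), seq = character(),
                      LM = integer(), arm = character(),
                      location = character(), LP = integer(),
                      family = character(), stringsAsFactors = FALSE))
  data.frame(name = validated$name, seq = validated$mature_seq,
             LM = nchar(validated$mature_seq), arm = validated$arm,
             location = paste0(validated$est_id, ":",
                               validated$window_start, "..",
                               validated$window_end, ":",
                               validated$strand),
             LP = validated$LP, family = family_of(validated$name),
             stringsAsFactors = FALSE)
}

#' Read a bundled or on-disk inventory TSV
#'
#' @param path TSV with columns \code{name}, \code{seq}, \code{LM},
#'   \code{arm}, \code{location}, \code{LP}.
#' @return Inventory data frame with a \code{family} column added.
#' @export
read_inventory <- function(path) {
  inv <- read_tsv_report(path)
  stopifnot(all(c("name", "seq", "LM", "LP") %in% names(inv)))
  inv$family <- family_of(inv$name)
  inv
}
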