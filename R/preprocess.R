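#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, standardizing library size.  Samples with fewer than `depth` total
#' reads cannot be subsampled without replacement and are dropped; their IDs
#' are reported in the `dropped` attribute and a message.
#'
#' @param counts Integer sample x OTU matrix with dimnames.
#' @param depth Target depth (reads per sample), default 20,000.
#' @param seed Optional integer seed; a single draw per sample.
#' @return The rarefied integer matrix (row sums all exactly `depth`), with
#'   attribute `dropped` listing removed sample IDs.
#' @export
rarefy <- function(counts, depth = 20000, seed = NULL) {
  check_count_matrix(counts)
  if (length(depth) != 1 || depth < 1) stop_("depth must be a single count >= 1")
  depth <- as.integer(depth)
  totals <- rowSums(counts)
  keep <- totals >= depth
  dropped <- rownames(counts)[!keep]
  if (!any(keep))
    stop_("all %d samples have fewer than %d reads; nothing to rarefy",
          nrow(counts), depth)
  if (length(dropped))
    message(sprintf("rarefy: dropped %d sample(s) below depth %d: %s",
                    length(dropped), depth, paste(dropped, collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)
  # rrarefy's advisory warning about large minimum counts is noise here:
  # deep 16S libraries routinely have no singleton cells
  out <- withCallingHandlers(
    vegan::rrarefy(counts[keep, , drop = FALSE], depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Convert counts to relative abundances
#'
#' @param counts Sample x feature count matrix; every row sum must be > 0.
#' @return Matrix of proportions; each row sums to 1.
#' @export
to_relative_abundance <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_("counts must be a numeric matrix")
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop_("sample(s) with zero total counts: %s",
          paste(rownames(counts)[rs == 0], collapse = ", "))
  counts / rs
}

#' Filter OTUs on mean abundance and prevalence
#'
#' An OTU is removed iff its mean relative abundance across samples is below
#' `min_mean_abund` AND the fraction of samples where it is present (nonzero)
#' is below `min_prevalence` (the default conjunctive rule; `logic = "or"`
#' removes on either condition).  Defaults correspond to removing OTUs with
#' mean relative abundance < 0.1% that are present in < 1% of samples.
#'
#' @param ab Sample x OTU relative-abundance matrix.
#' @param min_mean_abund Mean relative-abundance threshold, default 0.001.
#' @param min_prevalence Prevalence threshold, default 0.01.
#' @param logic `"and"` (default) removes only OTUs failing both conditions;
#'   `"or"` removes OTUs failing either.
#' @return The filtered matrix (original column order preserved), with a
#'   `removal_report` attribute: a data.frame of per-OTU mean abundance,
#'   prevalence and removal flag.
#' @export
filter_otus <- function(ab, min_mean_abund = 0.001, min_prevalence = 0.01,
                        logic = c("and", "or")) {
  logic <- match.arg(logic)
  if (min_mean_abund < 0 || min_mean_abund > 1 ||
      min_prevalence < 0 || min_prevalence > 1)
    stop_("thresholds must lie in [0, 1]")
  mean_ab <- colMeans(ab)
  prev <- colMeans(ab > 0)
  low_a <- mean_ab < min_mean_abund
  low_p <- prev < min_prevalence
  removed <- if (logic == "and") low_a & low_p else low_a | low_p
  if (all(removed)) warn_("all OTUs removed by filter")
  out <- ab[, !removed, drop = FALSE]
  attr(out, "removal_report") <- data.frame(
    otu_id = colnames(ab), mean_abundance = unname(mean_ab),
    prevalence = unname(prev), removed = unname(removed),
    stringsAsFactors = FALSE)
  out
}

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

# GreenGenes-style "k__Bacteria; p__Firmicutes; ..." -> named rank vector
parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  out <- stats::setNames(rep("unclassified", 7L), TAX_RANKS)
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  for (p in parts) {
    hit <- which(startsWith(p, prefixes))
    if (length(hit) == 1L) {
      val <- sub("^[kpcofgs]__", "", p)
      if (nzchar(val)) out[hit] <- val
    }
  }
  out
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums member-OTU proportions into one column per distinct taxon name at the
#' requested rank; OTUs missing from the taxonomy map, or unclassified at
#' that rank, are pooled into an `"unclassified"` column.  Row sums are
#' preserved.
#'
#' @param ab Sample x OTU relative-abundance matrix.
#' @param tax Data.frame with columns `otu_id` and `lineage` (GreenGenes-style
#'   semicolon-delimited string), as returned by [read_taxonomy()].
#' @param level One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Sample x taxon matrix.
#' @export
aggregate_to_taxon <- function(ab, tax, level) {
  if (!level %in% TAX_RANKS[-1])
    stop_("level must be one of: %s", paste(TAX_RANKS[-1], collapse = ", "))
  lin <- stats::setNames(tax$lineage, tax$otu_id)
  labels <- vapply(colnames(ab), function(o) {
    if (!o %in% names(lin)) return("unclassified")
    parse_lineage(lin[[o]])[[level]]
  }, character(1))
  uniq <- unique(labels)
  out <- vapply(uniq, function(u) rowSums(ab[, labels == u, drop = FALSE]),
                numeric(nrow(ab)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(ab),
                                     dimnames = list(rownames(ab), uniq))
  colnames(out) <- uniq
  out
}

#' Adjust a trait for sex and body weight
#'
#' Returns the residuals of an ordinary least-squares regression of the trait
#' on intercept + sex + body weight.  Samples with missing values in any of
#' the three vectors are dropped listwise and reported.  When both covariates
#' are constant the design is degenerate and the centred trait is returned
#' with a warning.
#'
#' @param trait Numeric trait vector.
#' @param sex Binary (0/1) vector.
#' @param body_weight Numeric vector (kg).
#' @param sample_ids Optional IDs used to name the result.
#' @return Named numeric vector of residuals with attribute `dropped` (IDs or
#'   indices removed for missingness).
#' @export
adjust_trait <- function(trait, sex, body_weight, sample_ids = NULL) {
  n <- length(trait)
  if (length(sex) != n || length(body_weight) != n)
    stop_("trait, sex and body_weight must have equal length")
  ids <- sample_ids %||% names(trait) %||% as.character(seq_len(n))
  ok <- stats::complete.cases(trait, sex, body_weight)
  dropped <- ids[!ok]
  if (length(dropped))
    message(sprintf("adjust_trait: dropped %d sample(s) with missing values",
                    length(dropped)))
  trait <- trait[ok]; sex <- sex[ok]; body_weight <- body_weight[ok]
  ids <- ids[ok]
  if (length(trait) <= 3) stop_("need more than 3 complete observations")
  if (stats::var(sex) == 0 && stats::var(body_weight) == 0) {
    warn_("degenerate design (constant sex and body weight); returning centred trait")
    res <- trait - mean(trait)
  } else {
    res <- stats::residuals(stats::lm(trait ~ sex + body_weight))
  }
  res <- stats::setNames(as.numeric(res), ids)
  attr(res, "dropped") <- dropped
  res
}
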