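#' Read a sample x OTU count table from TSV
#'
#' Expects a header whose first column is `sample_id` followed by OTU IDs;
#' cells must be non-negative integers.  Duplicate sample or OTU IDs, ragged
#' rows, negative or non-integer cells are rejected with the offending
#' location.  All-zero samples are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with sample row names and OTU column names.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_("count table needs a sample_id column plus >= 1 OTU")
  if (names(df)[1] != "sample_id")
    stop_("first column must be named 'sample_id' (got '%s')", names(df)[1])
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_("duplicate sample ID(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop_("duplicate OTU ID(s): %s",
          paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop_("non-numeric cell at row %d, column '%s'",
          bad[1, 1], colnames(df[, -1, drop = FALSE])[bad[1, 2]])
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_("negative or non-integer count at sample '%s', OTU '%s'",
          ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn_("dropping all-zero sample(s): %s", paste(ids[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  m
}

#' Write a count table as TSV
#'
#' Counterpart of [read_count_table()]: first column `sample_id`, remaining
#' columns OTU IDs, tab-delimited, '.' decimal.
#'
#' @param counts Sample x OTU matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Requires columns `sample_id`, `sex` (coded 0/1), `body_weight`, and at
#' least one numeric trait column.  Missing values are allowed in traits
#' (flagged for listwise deletion downstream); a per-trait summary is logged.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with typed columns; attribute `traits` lists the trait
#'   column names.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "body_weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("missing mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  sx <- unique(df$sex[!is.na(df$sex)])
  if (!all(sx %in% c(0, 1)))
    stop_("sex must be coded 0/1; found level(s): %s",
          paste(setdiff(sx, c(0, 1)), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_("duplicate sample ID(s) in phenotype table")
  traits <- setdiff(names(df), need)
  if (length(traits) == 0) stop_("no trait columns found")
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    if (all(is.na(v)) && !all(is.na(df[[tr]])))
      stop_("trait column '%s' is not numeric", tr)
    df[[tr]] <- v
    ok <- !is.na(v)
    message(sprintf("trait %s: n = %d, mean = %.3f, SD = %.3f, range = %.3f-%.3f",
                    tr, sum(ok), mean(v[ok]), stats::sd(v[ok]),
                    min(v[ok]), max(v[ok])))
  }
  attr(df, "traits") <- traits
  df
}

#' Read a GreenGenes-style taxonomy map from TSV
#'
#' Two tab-separated columns: OTU ID and semicolon-delimited lineage string
#' (`k__...;p__...;...`).  A header line naming the first column `otu_id` is
#' accepted and skipped.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  first <- readLines(path, n = 1)
  header <- startsWith(first, "otu_id")
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_("taxonomy file needs otu_id and lineage columns")
  df <- df[, 1:2]
  names(df) <- c("otu_id", "lineage")
  if (anyDuplicated(df$otu_id)) stop_("duplicate OTU ID(s) in taxonomy")
  df
}

#' Configuration for the full analysis pipeline
#'
#' @param counts Path to the count-table TSV.
#' @param phenotypes Path to the phenotype TSV.
#' @param out_dir Output directory for stage artifacts.
#' @param taxonomy Optional taxonomy TSV; required when `aggregate_level` is
#'   set.
#' @param traits Trait column names to analyze; default: every trait column.
#' @param aggregate_level Optional taxonomic rank to aggregate to before
#'   association.
#' @param rarefaction_depth Reads per sample after rarefaction (default
#'   20,000).
#' @param min_mean_abund,min_prevalence OTU filter thresholds (defaults
#'   0.001 and 0.01).
#' @param min_present Minimum present samples for the quantitative component.
#' @param n_perms Number of FDR permutations (default 1,000).
#' @param target_fdr FDR significance threshold (default 0.1).
#' @param cv_repeats Cross-validation repeats (default 100).
#' @param train_frac Discovery fraction (default 0.7).
#' @param cv_thresholds Selection p-value grid for the variance-explained
#'   stage.
#' @param seed Master seed; stage seeds are derived from it.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(counts, phenotypes, out_dir, taxonomy = NULL,
                       traits = NULL, aggregate_level = NULL,
                       rarefaction_depth = 20000,
                       min_mean_abund = 0.001, min_prevalence = 0.01,
                       min_present = 10, n_perms = 1000, target_fdr = 0.1,
                       cv_repeats = 100, train_frac = 0.7,
                       cv_thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1),
                       seed = 1L) {
  for (p in c(counts, phenotypes, taxonomy))
    if (!file.exists(p)) stop_("input file not found: %s", p)
  if (!is.null(aggregate_level) && is.null(taxonomy))
    stop_("aggregate_level requires a taxonomy file")
  if (rarefaction_depth < 1) stop_("rarefaction_depth must be >= 1")
  if (n_perms < 1) stop_("n_perms must be >= 1")
  if (target_fdr <= 0 || target_fdr > 1) stop_("target_fdr must be in (0, 1]")
  structure(list(counts = counts, phenotypes = phenotypes, out_dir = out_dir,
                 taxonomy = taxonomy, traits = traits,
                 aggregate_level = aggregate_level,
                 rarefaction_depth = rarefaction_depth,
                 min_mean_abund = min_mean_abund,
                 min_prevalence = min_prevalence,
                 min_present = min_present, n_perms = n_perms,
                 target_fdr = target_fdr, cv_repeats = cv_repeats,
                 train_frac = train_frac, cv_thresholds = cv_thresholds,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full association pipeline
#'
#' Executes rarefaction, relative-abundance conversion, OTU filtering,
#' optional taxonomic aggregation, covariate adjustment, the two-part
#' association scan, permutation FDR and cross-validated variance explained
#' for each configured trait, writing every stage's TSV artifact plus a YAML
#' run manifest (seeds, parameters, input checksums, stage row counts).
#' Re-running with the same configuration and seed reproduces identical
#' output bytes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest and the paths written; any
#'   stage failure aborts with an error naming the stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  counts <- stage("read", read_count_table(config$counts))
  pheno <- stage("read", suppressMessages(read_phenotypes(config$phenotypes)))
  traits <- config$traits %||% attr(pheno, "traits")
  stages <- c(stages, "read")

  rare <- stage("rarefy",
                suppressMessages(rarefy(counts, config$rarefaction_depth,
                                        seed = config$seed + 1L)))
  paths["rarefied_counts"] <- write_tsv(
    data.frame(sample_id = rownames(rare), rare, check.names = FALSE),
    file.path(config$out_dir, "rarefied_counts.tsv"))
  stages <- c(stages, "rarefy")

  ab <- stage("relative_abundance", to_relative_abundance(rare))
  stages <- c(stages, "relative_abundance")

  ab <- stage("filter", filter_otus(ab, config$min_mean_abund,
                                    config$min_prevalence))
  paths["filter_report"] <- write_tsv(attr(ab, "removal_report"),
                                      file.path(config$out_dir, "filter_report.tsv"))
  stages <- c(stages, "filter")

  if (!is.null(config$aggregate_level)) {
    tax <- stage("aggregate", read_taxonomy(config$taxonomy))
    ab <- stage("aggregate", aggregate_to_taxon(ab, tax, config$aggregate_level))
    stages <- c(stages, "aggregate")
  }
  paths["feature_table"] <- write_tsv(
    data.frame(sample_id = rownames(ab), ab, check.names = FALSE),
    file.path(config$out_dir, "feature_table.tsv"))

  common <- intersect(rownames(ab), pheno$sample_id)
  if (length(common) < 10)
    stop_("pipeline: fewer than 10 samples shared between counts and phenotypes")
  ab <- ab[common, , drop = FALSE]
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]

  features <- two_part_features(ab, min_present = config$min_present)
  trait_rows <- list()
  for (tr in traits) {
    ok <- !is.na(pheno[[tr]])
    y <- stage("adjust_trait",
               suppressMessages(adjust_trait(pheno[[tr]][ok], pheno$sex[ok],
                                             pheno$body_weight[ok],
                                             sample_ids = pheno$sample_id[ok])))
    feats <- if (all(ok)) features else
      two_part_features(ab[names(y), , drop = FALSE],
                        min_present = config$min_present)
    res <- stage("associate", associate(y, feats, trait_name = tr))
    paths[paste0("association_", tr)] <- write_tsv(
      as.data.frame(res), file.path(config$out_dir,
                                    sprintf("association_%s.tsv", tr)))
    fdr <- stage("fdr", build_fdr_curve(res, y, feats,
                                        n_perms = config$n_perms,
                                        seed = config$seed + 2L,
                                        target_fdr = config$target_fdr))
    paths[paste0("fdr_curve_", tr)] <- write_tsv(
      fdr$curve, file.path(config$out_dir, sprintf("fdr_curve_%s.tsv", tr)))
    sig <- significant_set(fdr, res)
    paths[paste0("significant_", tr)] <- write_tsv(
      as.data.frame(sig), file.path(config$out_dir,
                                    sprintf("significant_%s.tsv", tr)))
    cv <- stage("variance",
                cross_validate(ab[names(y), , drop = FALSE], y,
                               cv_config(n_repeats = config$cv_repeats,
                                         train_frac = config$train_frac,
                                         thresholds = config$cv_thresholds,
                                         min_present = config$min_present,
                                         seed = config$seed + 3L),
                               trait_name = tr))
    paths[paste0("cv_", tr)] <- write_tsv(
      as.data.frame(cv), file.path(config$out_dir, sprintf("cv_%s.tsv", tr)))
    trait_rows[[tr]] <- list(n_samples = length(y),
                             n_features = length(feats$feature_ids),
                             n_significant = nrow(sig),
                             chosen_cutoff = if (is.na(fdr$chosen_cutoff))
                               "none" else fdr$chosen_cutoff)
  }
  stages <- c(stages, "adjust_trait", "associate", "fdr", "variance")

  manifest <- list(
    seed = config$seed,
    parameters = config[c("rarefaction_depth", "min_mean_abund",
                          "min_prevalence", "min_present", "n_perms",
                          "target_fdr", "cv_repeats", "train_frac")],
    inputs = list(counts = unname(tools::md5sum(config$counts)),
                  phenotypes = unname(tools::md5sum(config$phenotypes))),
    stages = stages,
    table_dimensions = list(raw = dim(counts), rarefied = dim(rare),
                            filtered = dim(ab)),
    traits = trait_rows)
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  paths["manifest"] <- manifest_path
  invisible(list(manifest = manifest, paths = paths))
}
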