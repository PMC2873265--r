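#' Assemble a pipeline configuration
#'
#' Collects input paths and analysis settings for [run_pipeline()]. Either
#' a fold phylogeny (`tree`) or a precomputed ancestry table (`ancestry`)
#' must be supplied; when both are present the tree takes precedence and
#' the derived ancestry table is written to the output directory.
#'
#' @param tree Optional path to a Newick fold phylogeny.
#' @param ancestry Optional path to an ancestry TSV.
#' @param census Path to the protein census TSV (required).
#' @param markers Optional path to a marker-fold TSV; without it the era
#'   report is skipped.
#' @param annotations Optional path to a fold-function annotation TSV.
#' @param out_dir Output directory, created if absent.
#' @param thresholds Ancestry thresholds for the summary table.
#' @param policy Missing-ancestry policy for the census join.
#' @param top_n Number of most-ancestral folds in the coverage report.
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters when the config is used to drive
#'   simulation first).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(census, tree = NULL, ancestry = NULL,
                            markers = NULL, annotations = NULL,
                            out_dir = "fold-expansion-out",
                            thresholds = c(0.19, 0.40, 1.00),
                            policy = c("drop_warn", "strict"),
                            top_n = 10, seed = 1L) {
  policy <- match.arg(policy)
  if (is.null(tree) && is.null(ancestry))
    stop_config("either a fold phylogeny or an ancestry table must be supplied")
  if (is.null(census)) stop_config("a census table is required")
  if (is.unsorted(thresholds) || any(thresholds < 0 | thresholds > 1))
    stop_config("thresholds must be sorted and within [0, 1]")
  if (top_n < 1) stop_config("top_n must be >= 1")
  cfg <- list(tree = tree, ancestry = ancestry, census = census,
              markers = markers, annotations = annotations,
              out_dir = out_dir, thresholds = thresholds, policy = policy,
              top_n = as.integer(top_n), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full fold-expansion analysis
#'
#' Executes every stage against the configured inputs: derives (or reads)
#' the ancestry table, builds per-category nonredundant censuses, computes
#' expansion curves and threshold summaries, locates era boundaries from
#' marker folds, and reports top-ancestral-fold coverage and per-class
#' minimum ancestries. All machine-readable outputs are TSV/JSON under
#' `out_dir`, and a run manifest records inputs (with checksums), the full
#' configuration, a config hash, the seed and package/R versions.
#'
#' @param config A `pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `ancestry`,
#'   `censuses`, `curves`, `summary`, `eras` (or NULL), `era_counts`,
#'   `coverage`, `rollup`, and the output `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop_config("run_pipeline() expects a pipeline_config object")
  say <- function(msg, ...) if (!quiet) message(sprintf(msg, ...))
  for (f in c("tree", "ancestry", "census", "markers", "annotations")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop_config("configured %s file does not exist: %s", f, p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$tree)) {
    say("stage ancestry: deriving ancestry values from %s", config$tree)
    anc <- ancestry_values(read_fold_tree(config$tree))
    paths$ancestry <- file.path(config$out_dir, "ancestry.tsv")
    write_ancestry_table(anc, paths$ancestry)
  } else {
    say("stage ancestry: reading ancestry table %s", config$ancestry)
    anc <- read_ancestry_table(config$ancestry)
  }

  say("stage census: reading %s", config$census)
  records <- read_census_table(config$census)
  censuses <- build_censuses(records, anc, policy = config$policy)
  for (cen in censuses)
    say("  category '%s': %d folds (%d dropped)", cen$category,
        nrow(cen$folds), length(cen$dropped))

  say("stage expansion: %d categories, thresholds %s",
      length(censuses), paste(config$thresholds, collapse = "/"))
  curves <- lapply(censuses, expansion_curve)
  summ <- summarize_categories(censuses, config$thresholds)
  paths$summary <- file.path(config$out_dir, "summary.tsv")
  write_summary_table(summ, paths$summary)
  paths$curves <- file.path(config$out_dir, "curves.tsv")
  write_curve_table(curves, paths$curves)

  eras <- NULL; ec <- NULL
  if (!is.null(config$markers)) {
    say("stage eras: markers from %s", config$markers)
    mk <- read_marker_table(config$markers)
    eras <- era_boundaries(anc, mk$rnr_catalytic, mk$domain_restricted)
    ec <- t(vapply(censuses, era_counts, integer(3), partition = eras))
    era_df <- data.frame(category = rownames(ec), ec, row.names = NULL,
                         check.names = FALSE)
    paths$eras <- file.path(config$out_dir, "eras.tsv")
    utils::write.table(
      rbind(data.frame(category = c(".boundary_b1", ".boundary_b2"),
                       rna_protein_world = c(eras$b1, eras$b2),
                       luca_era = NA, modern_era = NA, check.names = FALSE),
            era_df),
      paths$eras, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  say("stage report: top-%d ancestral folds", config$top_n)
  n_top <- min(config$top_n, nrow(anc))
  top <- top_ancestral_folds(anc, n_top)
  all_folds <- unique(unlist(lapply(censuses, function(x) x$folds$fold_id)))
  union_idx <- match(all_folds, anc$fold_id)
  union_census <- list(category = "all categories",
                       folds = data.frame(fold_id = all_folds,
                                          ancestry = anc$ancestry[union_idx],
                                          stringsAsFactors = FALSE),
                       dropped = character(0))
  class(union_census) <- "category_census"
  cov <- coverage_report(top, union_census)
  rollup <- NULL
  if (!is.null(config$annotations)) {
    ann <- read_annotation_table(config$annotations)
    rollup <- function_rollup(ann, anc)
  }
  report <- list(top_folds = top, coverage_count = cov$count,
                 coverage_absent = cov$absent,
                 class_min_ancestry = as.list(rollup))
  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    inputs = lapply(Filter(Negate(is.null),
                           config[c("tree", "ancestry", "census", "markers",
                                    "annotations")]),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    config = unclass(config),
    config_hash = fnv1a_hash(jsonlite::toJSON(unclass(config),
                                              auto_unbox = TRUE)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("foldexpansion")),
    r_version = as.character(getRversion()))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(ancestry = anc, censuses = censuses, curves = curves,
                 summary = summ, eras = eras, era_counts = ec,
                 coverage = cov, rollup = rollup, paths = paths))
}

# FNV-1a 32-bit hash over the bytes of a string; used for the manifest's
# config fingerprint.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(as.character(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor emulated on doubles to stay within R's 32-bit integer limits
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (h %/% 65536) * 65536 + lo
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Plot expansion curves with era shading
#'
#' One step trace per category over ancestry in \[0, 1\] with vertical
#' markers at the two era boundaries, axes in percent.
#'
#' @param curves Nonempty list of `expansion_curve` objects (or the path
#'   to a curve TSV written by [write_curve_table()]).
#' @param partition Optional `era_partition` for boundary markers.
#' @param path Optional output PNG path; when NULL, draws on the active
#'   device.
#' @return Invisibly, the output path (or NULL).
#' @export
plot_expansion <- function(curves, partition = NULL, path = NULL) {
  if (is.character(curves)) curves <- read_curve_table(curves)
  if (length(curves) == 0) stop_data("no curves to plot")
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 100),
                 xlab = "Ancestry value", ylab = "Fold expansion (%)",
                 main = "Fold expansion by functional category")
  if (!is.null(partition)) {
    graphics::abline(v = c(partition$b1, partition$b2), lty = 2, col = "grey40")
    mids <- c(partition$b1 / 2, (partition$b1 + partition$b2) / 2,
              (partition$b2 + 1) / 2)
    graphics::mtext(c("RNA-protein\nworld", "LUCA era", "modern era"),
                    side = 3, at = mids, line = 0.2, cex = 0.8)
  }
  for (i in seq_along(curves))
    plot(curves[[i]], add = TRUE, col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = vapply(curves, function(x) x$category, character(1)),
                   col = cols[seq_along(curves)], lwd = 2, cex = 0.8, bty = "n")
  invisible(path)
}

#' Read a curve TSV back into expansion-curve objects
#'
#' @param path Path written by [write_curve_table()].
#' @return Named list of `expansion_curve` objects.
#' @export
read_curve_table <- function(path) {
  df <- read_tsv_checked(path, c("category", "ancestry", "expansion"))
  df$ancestry <- as.numeric(df$ancestry)
  df$expansion <- as.numeric(df$expansion)
  out <- lapply(split(df, df$category), function(d) {
    d <- d[order(d$ancestry), ]
    cv <- list(category = d$category[1], breakpoints = d$ancestry,
               values = d$expansion,
               n_folds = NA_integer_)
    class(cv) <- "expansion_curve"
    cv
  })
  out[unique(df$category)]
}
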