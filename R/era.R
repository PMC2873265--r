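#' Locate evolutionary era boundaries from marker folds
#'
#' Two marker sets partition the ancestry axis into three eras. The first
#' boundary is the minimum ancestry over folds of ribonucleotide-reductase
#' catalytic domains: the enzymatic capacity for deoxyribonucleotide
#' synthesis proxies the transition from an RNA-protein genetic system to a
#' DNA genome. The second is the minimum ancestry over folds restricted to
#' a single taxonomic domain of life, proxying the divergence of the Last
#' Universal Common Ancestor (LUCA).
#'
#' @param table A `fold_ancestry` table.
#' @param rnr_folds Nonempty character vector of RNR catalytic fold ids.
#' @param domain_restricted_folds Nonempty character vector of
#'   domain-restricted fold ids.
#' @return An `era_partition`: list with boundaries `b1`, `b2` and the era
#'   `labels` `c("rna_protein_world", "luca_era", "modern_era")`.
#' @export
era_boundaries <- function(table, rnr_folds, domain_restricted_folds) {
  stopifnot(inherits(table, "fold_ancestry"))
  if (length(rnr_folds) == 0 || length(domain_restricted_folds) == 0)
    stop_data("both marker sets must be nonempty")
  miss <- setdiff(c(rnr_folds, domain_restricted_folds), table$fold_id)
  if (length(miss) > 0)
    stop_data("marker fold(s) absent from ancestry table: %s",
              paste(unique(miss), collapse = ", "))
  b1 <- min(table$ancestry[match(rnr_folds, table$fold_id)])
  b2 <- min(table$ancestry[match(domain_restricted_folds, table$fold_id)])
  if (b1 > b2)
    stop_inconsistency(
      "marker folds contradict the era model: earliest RNR fold (%.4f) is younger than earliest domain-restricted fold (%.4f)",
      b1, b2)
  era_partition(b1, b2)
}

#' Construct an era partition from two boundaries
#'
#' @param b1 Ancestry of the DNA-genome transition, in \[0, 1\].
#' @param b2 Ancestry of the LUCA divergence, with `b1 <= b2 <= 1`.
#' @export
era_partition <- function(b1, b2) {
  stopifnot(is.numeric(b1), is.numeric(b2))
  if (b1 < 0 || b2 > 1 || b1 > b2)
    stop_inconsistency("era boundaries must satisfy 0 <= b1 <= b2 <= 1 (got %g, %g)",
                       b1, b2)
  out <- list(b1 = b1, b2 = b2,
              labels = c("rna_protein_world", "luca_era", "modern_era"))
  class(out) <- "era_partition"
  out
}

#' @export
print.era_partition <- function(x, ...) {
  cat(sprintf("Era partition: RNA-protein world [0, %.3f) | LUCA era [%.3f, %.3f) | modern era [%.3f, 1]\n",
              x$b1, x$b1, x$b2, x$b2))
  invisible(x)
}

#' Assign an ancestry value to an era
#'
#' Era intervals are half-open — `[0, b1)`, `[b1, b2)`, `[b2, 1]` — so the
#' marker fold that defines a transition belongs to the era it inaugurates.
#' (Cumulative expansion statistics, by contrast, use an inclusive
#' threshold; the two conventions serve different questions.)
#'
#' @param ancestry Numeric vector of ancestry values in \[0, 1\].
#' @param partition An `era_partition`.
#' @return Character vector of era labels.
#' @export
assign_era <- function(ancestry, partition) {
  stopifnot(inherits(partition, "era_partition"),
            all(ancestry >= 0 & ancestry <= 1))
  ifelse(ancestry < partition$b1, partition$labels[1],
         ifelse(ancestry < partition$b2, partition$labels[2],
                partition$labels[3]))
}

#' The n most ancestral folds
#'
#' Folds sorted by increasing ancestry; ties are broken lexicographically
#' on fold identifier so the ranking is deterministic.
#'
#' @param table A `fold_ancestry` table.
#' @param n Number of folds, `1 <= n <= nrow(table)`.
#' @return Character vector of fold ids in rank order.
#' @export
top_ancestral_folds <- function(table, n) {
  stopifnot(inherits(table, "fold_ancestry"))
  if (n < 1 || n > nrow(table))
    stop_data("n must be between 1 and the table size (%d); got %d",
              nrow(table), n)
  ord <- order(table$ancestry, table$fold_id)
  table$fold_id[ord][seq_len(n)]
}

#' Coverage of the most ancestral folds by a category census
#'
#' Counts how many of a ranked list of top-ancestral folds occur in a
#' census (e.g. the union of translation-protein categories), and lists
#' the absent ones in rank order.
#'
#' @param top_folds Nonempty ordered character vector of fold ids.
#' @param census A `category_census`.
#' @return List with `count` (integer) and `absent` (character vector).
#' @export
coverage_report <- function(top_folds, census) {
  stopifnot(length(top_folds) >= 1)
  check_census(census)
  present <- top_folds %in% census$folds$fold_id
  list(count = sum(present), absent = top_folds[!present])
}

.general_classes <- c("phosphoryl_transfer", "rna_modification",
                      "rna_binding", "protein_binding", "other")

#' Read a fold-function annotation table
#'
#' TSV dialect: `fold_id<TAB>gene_context<TAB>specific_function<TAB>general_class`
#' with `general_class` drawn from the closed vocabulary
#' phosphoryl_transfer, rna_modification, rna_binding, protein_binding,
#' other. Functions outside the four recurrent classes (e.g. tRNA
#' aminoacylation, tRNA splicing) map to `other` with their specific
#' function preserved.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with the four columns above.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("fold_id", "gene_context",
                                 "specific_function", "general_class"))
  bad <- setdiff(unique(df$general_class), .general_classes)
  if (length(bad) > 0)
    stop_data("%s: unknown general_class value(s): %s", path,
              paste(bad, collapse = ", "))
  df
}

#' Minimum ancestry per general functional class
#'
#' For each general functional class with at least one annotated fold, the
#' minimum ancestry value among its folds — the earliest appearance of that
#' molecular capability. Classes with no annotations are omitted.
#'
#' @param annotations Data frame from [read_annotation_table()] (or with
#'   the same columns).
#' @param table A `fold_ancestry` table covering every annotated fold.
#' @return Named numeric vector, names = general classes present.
#' @export
function_rollup <- function(annotations, table) {
  stopifnot(inherits(table, "fold_ancestry"),
            all(c("fold_id", "general_class") %in% names(annotations)))
  miss <- setdiff(annotations$fold_id, table$fold_id)
  if (length(miss) > 0)
    stop_data("annotated fold(s) absent from ancestry table: %s",
              paste(unique(miss), collapse = ", "))
  anc <- table$ancestry[match(annotations$fold_id, table$fold_id)]
  res <- tapply(anc, factor(annotations$general_class,
                            levels = .general_classes), min)
  res <- res[!is.na(res)]
  stats::setNames(as.numeric(res), names(res))
}

#' Read a marker-fold table
#'
#' TSV dialect: `fold_id<TAB>marker_type` with `marker_type` one of
#' `rnr_catalytic` or `domain_restricted`.
#'
#' @param path Path to the marker TSV.
#' @return List with character vectors `rnr_catalytic` and
#'   `domain_restricted`.
#' @export
read_marker_table <- function(path) {
  df <- read_tsv_checked(path, c("fold_id", "marker_type"))
  bad <- setdiff(unique(df$marker_type), c("rnr_catalytic", "domain_restricted"))
  if (length(bad) > 0)
    stop_data("%s: unknown marker_type value(s): %s", path,
              paste(bad, collapse = ", "))
  list(rnr_catalytic = df$fold_id[df$marker_type == "rnr_catalytic"],
       domain_restricted = df$fold_id[df$marker_type == "domain_restricted"])
}

#' Per-era fold counts for a census
#'
#' @param census A `category_census`.
#' @param partition An `era_partition`.
#' @return Named integer vector over the three era labels.
#' @export
era_counts <- function(census, partition) {
  check_census(census)
  eras <- assign_era(census$folds$ancestry, partition)
  tab <- table(factor(eras, levels = partition$labels))
  out <- as.integer(tab)
  names(out) <- partition$labels
  out
}
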