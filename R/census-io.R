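#' Read a protein census table
#'
#' Parses a TSV with header `protein_id<TAB>category<TAB>fold_ids`, where
#' `fold_ids` is a comma-separated list of fold identifiers found in the
#' protein's structure. Duplicate fold identifiers within one protein are
#' permitted (multi-domain proteins); rows with an empty fold list are
#' rejected. A protein listed under two categories yields two records.
#'
#' @param path Path to the census TSV.
#' @return A data frame with columns `protein_id`, `category` (character)
#'   and `fold_ids` (list column of character vectors).
#' @export
read_census_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "category", "fold_ids"))
  empty <- which(!nzchar(trimws(df$fold_ids)))
  if (length(empty) > 0)
    stop_data("%s: empty fold_ids on data line(s) %s", path,
              paste(empty + 1L, collapse = ", "))
  bad_id <- which(!nzchar(trimws(df$protein_id)))
  if (length(bad_id) > 0)
    stop_data("%s: empty protein_id on data line(s) %s", path,
              paste(bad_id + 1L, collapse = ", "))
  folds <- lapply(strsplit(df$fold_ids, ","), trimws)
  folds <- lapply(folds, function(x) x[nzchar(x)])
  if (any(lengths(folds) == 0))
    stop_data("%s: fold_ids parses to an empty list on some line", path)
  data.frame(protein_id = df$protein_id, category = df$category,
             fold_ids = I(folds), stringsAsFactors = FALSE)
}

#' Nonredundant fold set for a functional category
#'
#' The deduplicated union of fold identifiers over all protein records
#' belonging to the category. Returns an empty character vector (with a
#' message) if no record matches.
#'
#' @param records Protein records from [read_census_table()].
#' @param category Category label, matched exactly.
#' @return Character vector of unique fold identifiers (sorted).
#' @export
nonredundant_fold_set <- function(records, category) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  hit <- records$category == category
  if (!any(hit)) return(character(0))
  sort(unique(unlist(records$fold_ids[hit], use.names = FALSE)))
}

#' Join a fold set with ancestry values into a category census
#'
#' Each fold present in the ancestry table contributes a
#' (fold_id, ancestry) pair. Folds absent from the table are dropped with a
#' warning under `policy = "drop_warn"` (the default, since real ancestry
#' databases cover fold inventories incompletely) or abort the join under
#' `policy = "strict"`. A join retaining zero folds is always an error.
#'
#' @param fold_set Nonempty character vector of fold identifiers.
#' @param table A `fold_ancestry` table.
#' @param category Category label attached to the census.
#' @param policy `"drop_warn"` or `"strict"`.
#' @return A `category_census` object: list with `category`, `folds`
#'   (data frame `fold_id`, `ancestry`) and `dropped` (character vector).
#' @export
join_ancestry <- function(fold_set, table, category = "category",
                          policy = c("drop_warn", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "fold_ancestry"))
  fold_set <- unique(as.character(fold_set))
  if (length(fold_set) == 0) stop_data("empty fold set for category '%s'", category)
  missing <- setdiff(fold_set, table$fold_id)
  if (length(missing) > 0 && policy == "strict")
    stop_data("category '%s': fold(s) missing from ancestry table: %s",
              category, paste(missing, collapse = ", "))
  kept <- setdiff(fold_set, missing)
  if (length(kept) == 0)
    stop_data("category '%s': no folds retained after ancestry join", category)
  if (length(missing) > 0)
    warning(sprintf("category '%s': dropped %d fold(s) lacking ancestry: %s",
                    category, length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  idx <- match(kept, table$fold_id)
  out <- list(category = category,
              folds = data.frame(fold_id = kept,
                                 ancestry = table$ancestry[idx],
                                 stringsAsFactors = FALSE),
              dropped = missing)
  class(out) <- "category_census"
  out
}

#' Build censuses for every category in a set of protein records
#'
#' Convenience wrapper: applies [nonredundant_fold_set()] and
#' [join_ancestry()] to each distinct category.
#'
#' @inheritParams join_ancestry
#' @param records Protein records from [read_census_table()].
#' @return Named list of `category_census` objects.
#' @export
build_censuses <- function(records, table, policy = c("drop_warn", "strict")) {
  policy <- match.arg(policy)
  cats <- unique(records$category)
  out <- lapply(cats, function(cc)
    join_ancestry(nonredundant_fold_set(records, cc), table,
                  category = cc, policy = policy))
  names(out) <- cats
  out
}

#' @export
print.category_census <- function(x, ...) {
  cat(sprintf("Category census '%s': %d folds", x$category, nrow(x$folds)))
  if (length(x$dropped) > 0)
    cat(sprintf(" (%d dropped: no ancestry)", length(x$dropped)))
  cat(sprintf("\n  ancestry range [%.4f, %.4f], mean %.4f\n",
              min(x$folds$ancestry), max(x$folds$ancestry),
              mean(x$folds$ancestry)))
  invisible(x)
}

#' Write a census table as TSV
#'
#' @param records Data frame as returned by [read_census_table()].
#' @param path Output path.
#' @export
write_census_table <- function(records, path) {
  out <- data.frame(protein_id = records$protein_id,
                    category = records$category,
                    fold_ids = vapply(records$fold_ids, paste,
                                      character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
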