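#' Parse a fold phylogeny from Newick text
#'
#' Reads a single rooted Newick statement whose leaf labels are fold
#' identifiers (e.g. SCOP-style codes such as `"c.37"`). Branch lengths, if
#' present, are parsed and ignored: fold ancestry is purely topological.
#' Multifurcations are accepted.
#'
#' @param newick Either a Newick string (must end in `";"`) or the path to a
#'   file containing one.
#' @return An object of class `fold_phylogeny`: a list with elements `tree`
#'   (an [ape::read.tree()] `phylo` object, or `NULL` for a single-leaf
#'   tree) and `leaves` (character vector of leaf labels).
#' @examples
#' tr <- read_fold_tree("(c.37,(d.58,(a.4,b.40)));")
#' tr$leaves
#' @export
read_fold_tree <- function(newick) {
  txt <- newick
  if (length(txt) == 1 && !grepl(";", txt, fixed = TRUE) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  txt <- paste(txt, collapse = "")
  validate_newick(txt)
  leaves <- newick_leaf_labels(txt)
  dup <- unique(leaves[duplicated(leaves)])
  if (length(dup) > 0)
    stop_data("duplicate leaf labels in Newick: %s", paste(dup, collapse = ", "))
  if (any(!nzchar(leaves)))
    stop_data("empty leaf label in Newick string")
  if (length(leaves) == 1 && !grepl("(", txt, fixed = TRUE)) {
    # single-leaf tree, e.g. "A;" -- ape mis-parses this form
    out <- list(tree = NULL, leaves = leaves)
    class(out) <- "fold_phylogeny"
    return(out)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop_data("failed to parse Newick string")
  tree$tip.label <- trimws(tree$tip.label)
  out <- list(tree = tree, leaves = tree$tip.label)
  class(out) <- "fold_phylogeny"
  out
}

# Structural validation of a Newick statement with character positions.
validate_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  semi_at <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_data("malformed Newick: unmatched ')' at character %d", i)
    } else if (ch == ";") { semi_at <- i; break }
  }
  if (is.na(semi_at)) {
    if (depth > 0L)
      stop_data("malformed Newick: %d unclosed '(' and no terminating ';' (string ends at character %d)",
                depth, length(chars))
    stop_data("malformed Newick: missing terminating ';' (string ends at character %d)",
              length(chars))
  }
  if (depth != 0L)
    stop_data("malformed Newick: %d unclosed '(' at terminator (character %d)",
              depth, semi_at)
  invisible(TRUE)
}

# Leaf labels in Newick order, with surrounding whitespace trimmed.
newick_leaf_labels <- function(txt) {
  body <- sub(";.*$", "", txt)
  # a leaf token is the text immediately after "(" or ","; internal labels
  # follow ")" and branch lengths follow ":", so both are excluded here
  labs <- character(0)
  cur <- ""
  prev <- "("
  chars <- strsplit(body, "")[[1]]
  for (ch in chars) {
    if (ch %in% c("(", ",", ")")) {
      if (prev %in% c("(", ",") && nzchar(trimws(cur)))
        labs <- c(labs, sub(":.*$", "", trimws(cur)))
      cur <- ""
      prev <- ch
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (prev %in% c("(", ",") && nzchar(trimws(cur)))
    labs <- c(labs, sub(":.*$", "", trimws(cur)))
  if (length(labs) == 0 && nzchar(trimws(body)))
    labs <- sub(":.*$", "", trimws(body))  # single-leaf statement "A;"
  labs
}

#' @export
print.fold_phylogeny <- function(x, ...) {
  cat(sprintf("Fold phylogeny with %d leaves\n", length(x$leaves)))
  if (length(x$leaves) <= 10) cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

# Edge counts from each leaf to the root, named by leaf label.
leaf_edge_counts <- function(phy) {
  if (is.null(phy$tree)) {
    d <- 0L
    names(d) <- phy$leaves
    return(d)
  }
  tree <- phy$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- integer(nnode)
  edge <- tree$edge
  # edges in ape's cladewise order go parent -> child top-down
  for (k in seq_len(nrow(edge)))
    depth[edge[k, 2]] <- depth[edge[k, 1]] + 1L
  d <- depth[seq_len(ntip)]
  names(d) <- tree$tip.label
  d
}

#' Node depth of a fold in the phylogeny
#'
#' Counts the internal nodes on the path from the leaf to the root, minus
#' one, so a fold attached directly to the root has depth 0. This is the
#' node count entering the ancestry-value ratio.
#'
#' @param phy A `fold_phylogeny` from [read_fold_tree()].
#' @param fold_id A leaf label of `phy`.
#' @return A nonnegative integer.
#' @examples
#' tr <- read_fold_tree("(A,(B,(C,D)));")
#' node_depth(tr, "D")  # 2
#' @export
node_depth <- function(phy, fold_id) {
  stopifnot(inherits(phy, "fold_phylogeny"))
  d <- leaf_edge_counts(phy)
  if (!fold_id %in% names(d))
    stop_data("fold '%s' is not a leaf of the phylogeny", fold_id)
  max(0L, unname(d[fold_id]) - 1L)
}

#' Ancestry values for all folds in a phylogeny
#'
#' The ancestry value of a fold is its node depth divided by the maximum
#' node depth over all leaves, yielding a relative-age proxy in \[0, 1\]
#' where 0 is the most ancient fold and 1 the most recent. On a degenerate
#' tree (all depths zero: a single leaf or a star tree) every ancestry is 0
#' and a warning is emitted.
#'
#' @param phy A `fold_phylogeny` from [read_fold_tree()].
#' @return A `fold_ancestry` object: a data frame with columns `fold_id`
#'   and `ancestry`.
#' @examples
#' ancestry_values(read_fold_tree("(A,(B,(C,D)));"))
#' @export
ancestry_values <- function(phy) {
  stopifnot(inherits(phy, "fold_phylogeny"))
  d <- leaf_edge_counts(phy)
  depths <- pmax(0L, d - 1L)
  mx <- max(depths)
  if (mx == 0L) {
    warning("degenerate tree (no depth variation): all ancestry values set to 0",
            call. = FALSE)
    anc <- rep(0, length(depths))
  } else {
    anc <- depths / mx
  }
  ancestry_table(names(d), unname(anc))
}

#' Construct an ancestry table
#'
#' @param fold_id Character vector of unique fold identifiers.
#' @param ancestry Numeric vector of ancestry values in \[0, 1\].
#' @return A `fold_ancestry` data frame.
#' @export
ancestry_table <- function(fold_id, ancestry) {
  fold_id <- as.character(fold_id)
  ancestry <- as.numeric(ancestry)
  if (length(fold_id) != length(ancestry))
    stop_data("fold_id and ancestry lengths differ")
  if (anyDuplicated(fold_id))
    stop_data("duplicate fold_id in ancestry table: %s",
              paste(unique(fold_id[duplicated(fold_id)]), collapse = ", "))
  if (any(is.na(ancestry)) || any(ancestry < 0) || any(ancestry > 1))
    stop_data("ancestry values must lie in [0, 1]")
  out <- data.frame(fold_id = fold_id, ancestry = ancestry,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_ancestry", "data.frame")
  out
}

#' @export
print.fold_ancestry <- function(x, ...) {
  cat(sprintf("Ancestry table: %d folds, ancestry range [%.4f, %.4f]\n",
              nrow(x), min(x$ancestry), max(x$ancestry)))
  NextMethod()
}

#' Read / write an ancestry table as TSV
#'
#' The dialect is a two-column TSV with header `fold_id<TAB>ancestry`;
#' ancestry is written with six decimal places.
#'
#' @param path File path.
#' @rdname ancestry_tsv
#' @export
read_ancestry_table <- function(path) {
  df <- read_tsv_checked(path, c("fold_id", "ancestry"))
  ancestry_table(df$fold_id, as.numeric(df$ancestry))
}

#' @param table A `fold_ancestry` object.
#' @rdname ancestry_tsv
#' @export
write_ancestry_table <- function(table, path) {
  stopifnot(inherits(table, "fold_ancestry"))
  out <- data.frame(fold_id = table$fold_id,
                    ancestry = sprintf("%.6f", table$ancestry))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared TSV reader with header checking; reports offending file and columns.
read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  if (file.size(path) == 0) stop_data("empty file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    stop_data("%s: missing required column(s): %s (line 1)",
              path, paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop_data("%s: no data rows", path)
  df
}
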