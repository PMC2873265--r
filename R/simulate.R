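#' Simulate a fold phylogeny
#'
#' Generates a Newick string with uniquely labelled leaves
#' (`"F0001"`, `"F0002"`, ...). The `caterpillar` shape is the fully
#' ladderized (pectinate) topology, which yields evenly spaced node depths
#' and hence an evenly spaced grid of ancestry values; `random_bifurcating`
#' repeatedly joins two uniformly chosen subtrees, giving a random rooted
#' binary topology. Identical seeds give byte-identical output.
#'
#' @param n_leaves Number of leaves, at least 1.
#' @param shape `"caterpillar"` or `"random_bifurcating"`.
#' @param seed Integer seed; only consulted for the random shape but
#'   accepted for both so callers can be shape-agnostic.
#' @return A Newick string.
#' @examples
#' simulate_fold_tree(4, "caterpillar")
#' @export
simulate_fold_tree <- function(n_leaves,
                               shape = c("caterpillar", "random_bifurcating"),
                               seed = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(n_leaves) || n_leaves < 1)
    stop_data("n_leaves must be a positive integer; got %s", format(n_leaves))
  n_leaves <- as.integer(n_leaves)
  labs <- sprintf("F%04d", seq_len(n_leaves))
  if (n_leaves == 1) return(paste0(labs, ";"))
  if (shape == "caterpillar") {
    # ladder: deepest cherry (F[n-1],F[n]), then wrap upward
    sub <- if (n_leaves == 2) paste0("(", labs[1], ",", labs[2], ")")
    else {
      s <- paste0("(", labs[n_leaves - 1], ",", labs[n_leaves], ")")
      for (i in rev(seq_len(n_leaves - 2))) s <- paste0("(", labs[i], ",", s, ")")
      s
    }
    return(paste0(sub, ";"))
  }
  with_seed(seed, {
    subs <- labs
    while (length(subs) > 1) {
      pick <- sample.int(length(subs), 2)
      merged <- paste0("(", subs[pick[1]], ",", subs[pick[2]], ")")
      subs <- c(subs[-pick], merged)
    }
    paste0(subs, ";")
  })
}

#' Specify a synthetic functional category
#'
#' A category is drawn from a shared ancestry table with selection weights
#' proportional to the Beta(`alpha`, `beta`) density evaluated at each
#' fold's ancestry: small `alpha` relative to `beta` biases the category
#' toward ancient (low-ancestry) folds, emulating early-expanding
#' categories such as tRNA-related proteins; the reverse emulates
#' late-expanding references. `redundancy` is the mean number of times each
#' selected fold is mentioned across the category's synthetic proteins, so
#' that nonredundant-set construction has real deduplication work to do.
#'
#' @param category Category label.
#' @param n_folds Number of distinct folds to sample, at least 1.
#' @param alpha,beta Beta-density shape parameters, both > 0.
#' @param redundancy Mean fold mentions per selected fold, at least 1.
#' @return A `category_spec` (one-row data frame).
#' @export
category_spec <- function(category, n_folds, alpha, beta, redundancy = 1.5) {
  stopifnot(n_folds >= 1, alpha > 0, beta > 0, redundancy >= 1)
  out <- data.frame(category = category, n_folds = as.integer(n_folds),
                    alpha = alpha, beta = beta, redundancy = redundancy,
                    stringsAsFactors = FALSE)
  class(out) <- c("category_spec", "data.frame")
  out
}

#' Six-category specification shaped like a translation-evolution study
#'
#' The bundled fixture: three translation categories (tRNA-related,
#' regulation of translation, ribosomal) and three references (canonical
#' TCA enzymes, immune system proteins, whole proteome). Beta parameters
#' are set so each category's mean fold ancestry, hence its whole-curve
#' area statistic, sits where such categories sit empirically, and so the
#' rank order of early expansion is tRNA earliest, then regulatory, then
#' ribosomal, with immune/proteome references expanding late. Rank order is
#' the design target, not any particular percentage.
#'
#' @return A `category_spec` data frame with six rows.
#' @export
translation_category_specs <- function() {
  rbind(
    category_spec("tRNA-related proteins",     53,  1.0,  2.40, redundancy = 2.0),
    category_spec("Regulation of translation", 56,  1.0,  1.52, redundancy = 2.0),
    category_spec("Ribosomal proteins",        40,  1.4,  2.30, redundancy = 2.5),
    category_spec("Canonical TCA enzymes",      7,  0.9,  3.00, redundancy = 1.5),
    category_spec("Immune system proteins",    44,  2.6,  1.40, redundancy = 2.0),
    category_spec("Whole proteome",           550,  2.2,  1.50, redundancy = 1.2)
  )
}

#' Simulate a protein census from category specifications
#'
#' For each category, samples `n_folds` distinct folds from the shared
#' ancestry table without replacement, with selection probability
#' proportional to the Beta(alpha, beta) density at each fold's ancestry.
#' Selected folds are wrapped into synthetic proteins of 1-3 folds each
#' (uniform), with folds repeated across proteins until total mentions
#' reach `round(redundancy * n_folds)`. The exact per-category fold sets
#' and their ancestries are returned as ground truth.
#'
#' @param specs A `category_spec` data frame (one or more rows).
#' @param table A `fold_ancestry` table; each spec's `n_folds` must not
#'   exceed its size.
#' @param seed Integer seed; identical seeds give identical output.
#' @param max_folds_per_protein Upper bound on folds per synthetic protein.
#' @return List with `records` (census data frame as from
#'   [read_census_table()]) and `truth` (named list of data frames
#'   `fold_id`, `ancestry` per category).
#' @export
simulate_census <- function(specs, table, seed = NULL,
                            max_folds_per_protein = 3) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1,
            inherits(table, "fold_ancestry"), max_folds_per_protein >= 1)
  if (any(specs$n_folds > nrow(table)))
    stop_data("a category requests more folds (%d) than the ancestry table holds (%d)",
              max(specs$n_folds), nrow(table))
  with_seed(seed, {
    truth <- list()
    recs <- list()
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      # clamp avoids infinite Beta density at the endpoints for shapes < 1
      a_clamped <- pmin(pmax(table$ancestry, 1e-9), 1 - 1e-9)
      w <- stats::dbeta(a_clamped, sp$alpha, sp$beta)
      sel <- sample(table$fold_id, sp$n_folds, prob = w)
      sel_anc <- table$ancestry[match(sel, table$fold_id)]
      truth[[sp$category]] <- data.frame(fold_id = sel, ancestry = sel_anc,
                                         stringsAsFactors = FALSE)
      mentions <- round(sp$redundancy * sp$n_folds)
      extra <- max(0, mentions - sp$n_folds)
      pool <- c(sel, if (extra > 0) sample(sel, extra, replace = TRUE))
      pool <- sample(pool)
      sizes <- integer(0)
      left <- length(pool)
      while (left > 0) {
        s <- min(left, sample.int(max_folds_per_protein, 1))
        sizes <- c(sizes, s)
        left <- left - s
      }
      idx_end <- cumsum(sizes)
      idx_start <- c(1, utils::head(idx_end, -1) + 1)
      fold_lists <- lapply(seq_along(sizes),
                           function(k) pool[idx_start[k]:idx_end[k]])
      recs[[i]] <- data.frame(
        protein_id = sprintf("%s_P%04d", gsub("[^A-Za-z0-9]+", "", sp$category),
                             seq_along(sizes)),
        category = sp$category,
        fold_ids = I(fold_lists), stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(records = records, truth = truth)
  })
}

#' Simulate marker folds for era recovery
#'
#' Designates as the RNR-catalytic marker the fold whose ancestry is the
#' smallest value at or above `b1_target`, and as the domain-restricted
#' marker the fold with smallest ancestry at or above `b2_target`; optional
#' decoy markers of the same types are added at strictly higher ancestries,
#' so that the minimum-taking boundary recovery is exercised.
#'
#' @param table A `fold_ancestry` table.
#' @param b1_target,b2_target Target boundaries, `0 <= b1 <= b2 <= 1`.
#' @param n_decoys Decoy markers per type (0 for none).
#' @param seed Integer seed for decoy choice.
#' @return Marker data frame with columns `fold_id`, `marker_type`.
#' @export
simulate_markers <- function(table, b1_target, b2_target, n_decoys = 0,
                             seed = NULL) {
  stopifnot(inherits(table, "fold_ancestry"))
  if (b1_target < 0 || b2_target > 1 || b1_target > b2_target)
    stop_data("marker targets must satisfy 0 <= b1_target <= b2_target <= 1 (got %g, %g)",
              b1_target, b2_target)
  pick_at <- function(target) {
    cand <- table[table$ancestry >= target, , drop = FALSE]
    if (nrow(cand) == 0)
      stop_data("no fold with ancestry >= %g available as a marker", target)
    cand <- cand[order(cand$ancestry, cand$fold_id), , drop = FALSE]
    cand$fold_id[1]
  }
  f1 <- pick_at(b1_target)
  f2 <- pick_at(b2_target)
  df <- data.frame(fold_id = c(f1, f2),
                   marker_type = c("rnr_catalytic", "domain_restricted"),
                   stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    a1 <- table$ancestry[table$fold_id == f1]
    a2 <- table$ancestry[table$fold_id == f2]
    df <- with_seed(seed, {
      add_decoys <- function(df, anchor, type) {
        pool <- setdiff(table$fold_id[table$ancestry > anchor], df$fold_id)
        if (length(pool) > 0) {
          dec <- sample(pool, min(n_decoys, length(pool)))
          df <- rbind(df, data.frame(fold_id = dec, marker_type = type,
                                     stringsAsFactors = FALSE))
        }
        df
      }
      df <- add_decoys(df, a1, "rnr_catalytic")
      add_decoys(df, a2, "domain_restricted")
    })
  }
  rownames(df) <- NULL
  df
}

#' Write a marker table as TSV
#'
#' @param markers Data frame from [simulate_markers()].
#' @param path Output path.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
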