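toy_table <- function() {
  ancestry_table(c("rnr1", "rnr2", "dom1", "dom2", "f1", "f2"),
                 c(0.25, 0.6, 0.3, 0.7, 0.0, 1.0))
}

test_that("era boundaries are the marker minima, validated for ordering", {
  eb <- era_boundaries(toy_table(), c("rnr1", "rnr2"), c("dom1", "dom2"))
  expect_equal(eb$b1, 0.25)
  expect_equal(eb$b2, 0.3)
  expect_error(era_boundaries(toy_table(), "rnr2", "dom1"),
               class = "fold_inconsistency_error")
  expect_error(era_boundaries(toy_table(), "missing", "dom1"),
               "absent", class = "fold_data_error")
  expect_error(era_boundaries(toy_table(), character(0), "dom1"),
               "nonempty", class = "fold_data_error")
})

test_that("boundaries ignore non-marker folds added to the table", {
  tab <- toy_table()
  eb1 <- era_boundaries(tab, "rnr1", "dom1")
  more <- ancestry_table(c(tab$fold_id, "extra1", "extra2"),
                         c(tab$ancestry, 0.01, 0.99))
  eb2 <- era_boundaries(more, "rnr1", "dom1")
  expect_equal(eb1$b1, eb2$b1)
  expect_equal(eb1$b2, eb2$b2)
})

test_that("era assignment uses half-open intervals inaugurated by markers", {
  part <- era_partition(0.19, 0.40)
  expect_equal(assign_era(0, part), "rna_protein_world")
  expect_equal(assign_era(0.19, part), "luca_era")   # boundary fold opens era
  expect_equal(assign_era(0.40, part), "modern_era")
  expect_equal(assign_era(1, part), "modern_era")
  expect_error(era_partition(0.5, 0.4), class = "fold_inconsistency_error")

  # the three eras partition [0,1]: counts always sum to census size
  set.seed(3)
  cen <- random_census(50)
  expect_equal(sum(era_counts(cen, part)), 50)
})

test_that("top ancestral folds sort by ancestry with lexicographic ties", {
  tab <- ancestry_table(c("X", "Y", "Z", "W"), c(0.0, 0.2, 0.1, 0.5))
  expect_equal(top_ancestral_folds(tab, 3), c("X", "Z", "Y"))
  expect_equal(top_ancestral_folds(tab, 4), c("X", "Z", "Y", "W"))
  tied <- ancestry_table(c("Y", "X"), c(0.1, 0.1))
  expect_equal(top_ancestral_folds(tied, 1), "X")
  expect_error(top_ancestral_folds(tab, 5), class = "fold_data_error")
})

test_that("coverage report counts intersections and preserves rank order of absences", {
  cen <- toy_census(c(0.1, 0.2, 0.3))
  cen$folds$fold_id <- c("Z", "Y", "Q")
  cov <- coverage_report(c("X", "Z", "Y"), cen)
  expect_equal(cov$count, 2)
  expect_equal(cov$absent, "X")
  expect_equal(cov$count + length(cov$absent), 3)
  full <- coverage_report(c("Z", "Y"), cen)
  expect_equal(full$count, 2)
  expect_length(full$absent, 0)
})

test_that("function rollup reports the minimum ancestry per general class", {
  tab <- ancestry_table(c("f1", "f2", "f3"), c(0.013, 0.2, 0.0))
  ann <- data.frame(fold_id = c("f1", "f2", "f3"),
                    gene_context = c("g1", "g2", "g3"),
                    specific_function = "fn",
                    general_class = c("rna_binding", "rna_binding",
                                      "phosphoryl_transfer"))
  roll <- function_rollup(ann, tab)
  expect_equal(roll[["rna_binding"]], 0.013)
  expect_equal(roll[["phosphoryl_transfer"]], 0.0)
  expect_false("protein_binding" %in% names(roll))
  expect_error(function_rollup(data.frame(fold_id = "nope",
                                          general_class = "other"), tab),
               "absent", class = "fold_data_error")
})

test_that("marker and annotation TSV dialects are validated on read", {
  mpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fold_id\tmarker_type", "c.37\trnr_catalytic",
               "d.58\tdomain_restricted"), mpath)
  mk <- read_marker_table(mpath)
  expect_equal(mk$rnr_catalytic, "c.37")
  expect_equal(mk$domain_restricted, "d.58")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fold_id\tmarker_type", "c.37\twhatever"), bad)
  expect_error(read_marker_table(bad), "unknown marker_type",
               class = "fold_data_error")

  apath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fold_id\tgene_context\tspecific_function\tgeneral_class",
               "c.37\tEF-G\tGTP hydrolysis\tphosphoryl_transfer",
               "b.40\tS28e\ttRNA splicing\tother"), apath)
  ann <- read_annotation_table(apath)
  expect_equal(nrow(ann), 2)
  badc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fold_id\tgene_context\tspecific_function\tgeneral_class",
               "c.37\tEF-G\tx\tnot_a_class"), badc)
  expect_error(read_annotation_table(badc), "unknown general_class",
               class = "fold_data_error")
})
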