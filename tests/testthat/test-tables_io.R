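test_that("expression matrix parsing validates values and aligns columns", {
  dir <- withr::local_tempdir()
  meta <- toy_samples()[1:4, ]
  meta_path <- file.path(dir, "meta.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # all-zero toy matrix parses to a matrix of zeros
  mat_path <- file.path(dir, "m.tsv")
  df <- data.frame(feature_id = c("a", "b"),
                   matrix(0, 2, 4, dimnames = list(NULL, meta$sample_id)),
                   check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  em <- read_expression_matrix(mat_path, meta_path)
  expect_equal(dim(em), c(2L, 4L))
  expect_true(all(em$values == 0))
  expect_identical(feature_ids(em), c("a", "b"))

  # negative cell rejected
  df_neg <- df; df_neg[[2L]][1L] <- -1.0
  write.table(df_neg, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(mat_path, meta_path), "negative")

  # empty and NA cells are missing, distinct from zero
  df_na <- df; df_na[[2L]][1L] <- NA
  write.table(df_na, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  em_na <- read_expression_matrix(mat_path, meta_path)
  expect_true(is.na(em_na$values[1L, 1L]))
  expect_false(is.na(em_na$values[2L, 1L]))
})

test_that("parsing is column-order independent given the sample sheet", {
  dir <- withr::local_tempdir()
  meta <- toy_samples()[1:4, ]
  meta_path <- file.path(dir, "meta.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2,
                 dimnames = list(c("a", "b"), meta$sample_id))

  write_file <- function(col_order, path) {
    df <- data.frame(feature_id = rownames(vals),
                     vals[, col_order, drop = FALSE], check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p1 <- file.path(dir, "canon.tsv"); write_file(1:4, p1)
  p2 <- file.path(dir, "perm.tsv");  write_file(c(3, 1, 4, 2), p2)
  em1 <- read_expression_matrix(p1, meta_path)
  em2 <- read_expression_matrix(p2, meta_path)
  expect_identical(colnames(em2$values), meta$sample_id)
  expect_equal(em1$values, em2$values)

  # a matrix sample absent from the sheet is named in the error
  df_extra <- data.frame(feature_id = rownames(vals), vals,
                         rogue = c(1, 1), check.names = FALSE)
  p3 <- file.path(dir, "extra.tsv")
  write.table(df_extra, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(p3, meta_path), "rogue")
})

test_that("write/read round trip preserves values to 12 significant digits", {
  dir <- withr::local_tempdir()
  set.seed(42)
  meta <- toy_samples()
  vals <- matrix(rlnorm(5 * 8, 5, 2), 5,
                 dimnames = list(sprintf("f%d", 1:5), meta$sample_id))
  vals[2, 3] <- NA
  em <- expression_matrix(vals, meta)
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  write_expression_matrix(em, mp, sp)
  back <- read_expression_matrix(mp, sp)
  expect_identical(feature_ids(back), feature_ids(em))
  expect_identical(back$samples$sample_id, em$samples$sample_id)
  expect_equal(back$values, em$values, tolerance = 1e-12)
})

test_that("duplicate feature ids and bad metadata are rejected", {
  meta <- toy_samples()[1:2, ]
  vals <- matrix(1, 2, 2, dimnames = list(c("a", "a"), meta$sample_id))
  expect_error(expression_matrix(vals, meta), "duplicate feature ids: a")
  meta_bad <- toy_samples()[1:2, ]
  meta_bad$condition <- c("2D", "4D")
  vals2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), meta_bad$sample_id))
  expect_error(expression_matrix(vals2, meta_bad), "condition")
})

test_that("target edges deduplicate keeping the stronger grade", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "edges.tsv")
  write.table(data.frame(mirna_id = c("m1", "m2", "m1"),
                         protein_id = c("p1", "p2", "p1"),
                         evidence = c("weak", "weak", "strong")),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  e <- read_target_edges(p)
  expect_equal(nrow(e), 2L)
  expect_equal(e$evidence[e$mirna_id == "m1"], "strong")
  # first-appearance order preserved
  expect_identical(e$mirna_id, c("m1", "m2"))

  # empty file with header -> empty list
  write.table(data.frame(mirna_id = character(0),
                         protein_id = character(0),
                         evidence = character(0)),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_target_edges(p)), 0L)

  # bad evidence grade
  write.table(data.frame(mirna_id = "m1", protein_id = "p1",
                         evidence = "maybe"),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_target_edges(p), "evidence")
})

test_that("category db reads long and GMT dialects", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cats.txt")

  writeLines(c("c1\tm1", "c1\tm2", "c2\tm3", "c2\tm4"), p)
  db <- read_category_db(p)
  expect_equal(length(db), 2L)
  expect_setequal(db$c1$members, c("m1", "m2"))
  expect_setequal(db$c2$members, c("m3", "m4"))

  writeLines("c1\tdesc\tm1\tm2", p)
  db2 <- read_category_db(p)
  expect_setequal(db2$c1$members, c("m1", "m2"))

  # duplicate member collapses to unique set
  writeLines(c("c1\tm1", "c1\tm1", "c1\tm2"), p)
  expect_equal(sort(read_category_db(p)$c1$members), c("m1", "m2"))

  expect_error(category_db(list(c1 = list(name = "c1",
                                          members = character(0)))),
               "empty category")
})

test_that("biotype labels are restricted to the closed set", {
  expect_error(biotype_map(c(f1 = "miRNA", f2 = "lncRNA")), "lncRNA")
  expect_silent(biotype_map(c(f1 = "miRNA", f2 = "snoRNA")))
})
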