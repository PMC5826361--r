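test_that("fold_change follows the treated/control ratio with degenerate cases", {
  mat <- rbind(g1 = c(100, 100, 400, 250, 350, 100),
               g2 = c(0, 50, 0, 150, 10, 10))
  tab <- tiny_expression(mat)
  expect_equal(fold_change(tab, "g1", "treat_low", 1), 4)
  expect_equal(fold_change(tab, "g1", "treat_low", 2), 2.5)
  # both zero -> 1; zero control with positive treated -> +Inf
  expect_equal(fold_change(tab, "g2", "treat_low", 1), 1)
  expect_equal(fold_change(tab, "g2", "treat_low", 2), 3)
  mat2 <- rbind(g1 = c(0, 1, 5, 1, 1, 1))
  expect_equal(fold_change(tiny_expression(mat2), "g1", "treat_low", 1), Inf)
  expect_error(fold_change(tab, "nope", "treat_low", 1), "nope")
  expect_error(fold_change(tab, "g1", "treat_low", 9), "replicate=9")
})

test_that("fold_change matches brute-force re-division on a random matrix", {
  set.seed(42)
  mat <- matrix(runif(20 * 6, 10, 1000), 20, 6,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  tab <- tiny_expression(mat)
  for (cond in c("treat_low", "treat_high")) {
    cols <- if (cond == "treat_low") c(3, 4) else c(5, 6)
    for (r in 1:2) {
      got <- vapply(rownames(mat), function(g) fold_change(tab, g, cond, r),
                    numeric(1))
      expect_equal(unname(got), unname(mat[, cols[r]] / mat[, r]))
    }
  }
})

test_that("call_upregulated applies the 3x / >100 / both-replicates rules", {
  mat <- rbind(a = c(100, 100, 400, 350, 50, 50),   # both reps pass in low
               b = c(100, 100, 400, 250, 50, 50),   # rep2 fold 2.5 < 3
               c = c(30, 30, 95, 99, 50, 50),       # fold ok, intensity <= 100
               d = c(30, 30, 101, 100, 50, 50))     # rep2 at boundary: 100 not > 100
  tab <- tiny_expression(mat)
  calls <- call_upregulated(tab, "treat_low", all_genes = TRUE)
  conc <- setNames(calls$concordant, calls$gene_id)
  expect_true(conc[["a"]])
  expect_false(conc[["b"]])
  expect_false(conc[["c"]])
  expect_false(conc[["d"]])   # strict > for intensity
  expect_error(call_upregulated(tab, "control"), "control")
})

test_that("the intensity rule can be moved to control or both samples", {
  mat <- rbind(a = c(50, 50, 400, 400, 50, 50))
  tab <- tiny_expression(mat)
  expect_true(call_upregulated(tab, "treat_low", filter_config())$concordant)
  expect_equal(nrow(call_upregulated(
    tab, "treat_low", filter_config(intensity_on = "control"))), 0L)
  expect_equal(nrow(call_upregulated(
    tab, "treat_low", filter_config(intensity_on = "both"))), 0L)
})

test_that("concordant set shrinks monotonically and refilters idempotently", {
  set.seed(7)
  se <- sim_expression(n_genes = 300, seed = 7)
  tab <- se$table
  base <- call_upregulated(tab, "treat_low")
  genes0 <- base$gene_id[base$concordant]
  for (fc in c(4, 6, 10)) {
    cs <- call_upregulated(tab, "treat_low", filter_config(fold_threshold = fc))
    expect_true(all(cs$gene_id[cs$concordant] %in% genes0))
  }
  for (it in c(200, 500)) {
    cs <- call_upregulated(tab, "treat_low",
                           filter_config(intensity_threshold = it))
    expect_true(all(cs$gene_id[cs$concordant] %in% genes0))
  }
  # idempotence on the concordant subtable
  sub <- expression_table(tab$intensity[genes0, , drop = FALSE], tab$samples)
  again <- call_upregulated(sub, "treat_low")
  expect_setequal(again$gene_id[again$concordant], genes0)
})

test_that("fold changes are scale-covariant", {
  se <- sim_expression(n_genes = 200, seed = 3)
  tab <- se$table
  k <- 7.3
  tab2 <- expression_table(tab$intensity * k, tab$samples)
  c1 <- call_upregulated(tab, "treat_high", all_genes = TRUE)
  c2 <- call_upregulated(tab2, "treat_high",
                         filter_config(intensity_threshold = 100 * k),
                         all_genes = TRUE)
  expect_equal(c2$fold_rep1, c1$fold_rep1)
  expect_equal(c2$fold_rep2, c1$fold_rep2)
  expect_equal(c2$concordant, c1$concordant)
})

test_that("combine_conditions reports per-condition membership and the union", {
  mat <- rbind(a = c(100, 100, 400, 400, 50, 50),     # low only
               b = c(100, 100, 50, 50, 400, 400),     # high only
               c = c(100, 100, 400, 400, 400, 400))   # both
  tab <- tiny_expression(mat)
  low <- call_upregulated(tab, "treat_low")
  high <- call_upregulated(tab, "treat_high")
  cmb <- combine_conditions(low, high)
  expect_equal(cmb$a, "treat_low")
  expect_equal(cmb$b, "treat_high")
  expect_equal(cmb$c, c("treat_high", "treat_low"))
  expect_equal(length(combine_conditions(low[0, ], high[0, ])), 0L)
})

test_that("expression TSV round-trips through read_expression", {
  se <- sim_expression(n_genes = 50, seed = 5)
  d <- withr::local_tempdir()
  mat <- se$table$intensity
  write.table(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
              file.path(d, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(se$table$samples, file.path(d, "s.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tab <- read_expression(file.path(d, "m.tsv"), file.path(d, "s.tsv"))
  expect_equal(tab$intensity, se$table$intensity, tolerance = 1e-12)
  expect_equal(tab$samples$condition, se$table$samples$condition)
})
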