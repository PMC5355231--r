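toy_assay <- function(path, extra = NULL) {
  lines <- c("compound_id\tlconc\tgi",
             "A\t-6.0\t20", "A\t-5.0\t-10", "B\t-6.0\t55", extra)
  writeLines(lines, path)
  path
}

test_that("dose-response loading drops bad rows with a count", {
  f <- toy_assay(withr::local_tempfile(fileext = ".tsv"), "C\t-4.0\t")
  expect_message(rec <- load_dose_response(f), "1 assay record")
  expect_equal(nrow(rec), 3L)
  expect_identical(attr(rec, "n_dropped"), 1L)
  expect_equal(nrow(rec) + attr(rec, "n_dropped"), 4L)
})

test_that("cell-line filtering and column validation work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tcell\tLCONC\tGIPRCNT",
               "A\tMCF7\t-6\t10", "A\tPC3\t-6\t60", "B\tMCF7\t-5\t-20",
               "C\tPC3\t-5\t0", "D\tHL60\t-7\t30"), f)
  cols <- c(id = "id", lconc = "LCONC", gi = "GIPRCNT")
  rec <- load_dose_response(f, cols, cell_line = "MCF7", cell_line_col = "cell")
  expect_equal(rec$compound_id, c("A", "B"))
  expect_error(load_dose_response(f, c(id = "id", lconc = "missing", gi = "GIPRCNT")),
               "missing required")
  f2 <- toy_assay(withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_dose_response(f2, cell_line = "MCF7"), "cell_line_col")
})

test_that("training sets replicate fingerprints per assay record", {
  X <- random_bits(2, seed = 1)
  rownames(X) <- c("A", "B")
  rec <- data.frame(compound_id = rep("A", 5), lconc = -8:-4, gi = 1:5 * 10,
                    stringsAsFactors = FALSE)
  ts <- build_training_set(rec, X)
  expect_equal(ts$counts$n_records, 5L)
  expect_equal(ts$counts$n_compounds, 1L)
  for (i in 2:5) expect_identical(ts$X[i, ], ts$X[1, ])

  # unresolvable ids are dropped conservatively
  rec2 <- rbind(rec, data.frame(compound_id = "Z", lconc = -5, gi = 0))
  expect_message(ts2 <- build_training_set(rec2, X), "no fingerprint")
  expect_equal(ts2$counts$n_records + ts2$counts$n_dropped, nrow(rec2))
})

test_that("norm stats are the plain column moments", {
  X <- random_bits(3, seed = 2)
  rec <- data.frame(compound_id = rownames(X), lconc = c(-7, -6, -5),
                    gi = c(10, 20, 60), stringsAsFactors = FALSE)
  ts <- build_training_set(rec, X)
  expect_equal(ts$norm_stats$lconc_mean, mean(rec$lconc))
  expect_equal(ts$norm_stats$lconc_var, var(rec$lconc))
  expect_equal(ts$norm_stats$gi_mean, mean(rec$gi))
  expect_equal(ts$norm_stats$gi_var, var(rec$gi))
})

test_that("synthetic generation honors its noise-free limits", {
  spec <- synthetic_spec(n_compounds = 40L, n_prototypes = 3L,
                         bit_flip_rate = 0, gi_noise_sd = 0, seed = 5L)
  sim <- generate_synthetic(spec)
  # every fingerprint is exactly its prototype
  for (i in seq_len(40L))
    expect_identical(unname(sim$training_set$X[i, ]),
                     unname(sim$truth$prototypes[sim$truth$assignment[i], ]))
  expect_error(synthetic_spec(bit_flip_rate = 0.5), "bit_flip_rate")
})

test_that("noise-free synthetic GI is recovered by least squares", {
  spec <- synthetic_spec(n_compounds = 400L, bit_flip_rate = 0.3,
                         gi_noise_sd = 0, gi_dose_slope = 0, seed = 9L)
  sim <- generate_synthetic(spec)
  ts <- sim$training_set
  active <- which(sim$truth$gi_coefficients != 0)
  fit <- lm(ts$gi ~ ts$X[, active] - 1)
  expect_equal(unname(coef(fit)), sim$truth$gi_coefficients[active],
               tolerance = 1e-8)
})

test_that("synthetic generation is seed-reproducible", {
  s1 <- generate_synthetic(synthetic_spec(n_compounds = 30L, seed = 11L))
  s2 <- generate_synthetic(synthetic_spec(n_compounds = 30L, seed = 11L))
  expect_identical(s1$training_set, s2$training_set)
  s3 <- generate_synthetic(synthetic_spec(n_compounds = 30L, seed = 12L))
  expect_false(identical(s1$training_set$X, s3$training_set$X))
})

test_that("training sets survive the text archive round trip", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 25L, seed = 6L))
  d <- withr::local_tempdir()
  save_training_set(sim$training_set, d)
  ts2 <- load_training_set(d)
  expect_identical(unname(ts2$X), unname(sim$training_set$X))
  expect_equal(ts2$lconc, sim$training_set$lconc)
  expect_equal(ts2$gi, sim$training_set$gi)
  expect_identical(ts2$ids, sim$training_set$ids)
  expect_equal(ts2$norm_stats, sim$training_set$norm_stats)
})

test_that("synthetic libraries reuse training prototypes when given truth", {
  spec <- synthetic_spec(n_compounds = 20L, bit_flip_rate = 0, seed = 8L)
  sim <- generate_synthetic(spec)
  lib <- synthetic_library(50L, spec, sim$truth, seed = 99L)
  expect_equal(dim(lib), c(50L, 166L))
  # with zero flip rate every library member is one of the prototypes
  proto_keys <- apply(sim$truth$prototypes, 1, paste, collapse = "")
  lib_keys <- apply(lib, 1, paste, collapse = "")
  expect_true(all(lib_keys %in% proto_keys))
})
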