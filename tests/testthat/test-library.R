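# Sequence identity, quality filters, redundancy removal, library build.

test_that("sequence identity: self, disjoint, planted substitution rate", {
  s <- random_aa_seq(60, 5)
  expect_equal(sequence_identity(s, s), 1.0)
  expect_equal(sequence_identity("AAAA", "CCCC"), 0.0)
  base <- random_aa_seq(100, 6)
  mut <- dnathread:::.mutate_sequence(base, 0.60, 7)
  expect_equal(sequence_identity(base, mut), 0.60)
  expect_error(sequence_identity("", "AAAA"), "empty")
})

test_that("sequence identity is symmetric", {
  for (seed in 1:10) {
    a <- random_aa_seq(with_seed(seed, sample(30:80, 1)), seed * 2)
    b <- random_aa_seq(with_seed(seed + 100, sample(30:80, 1)), seed * 3)
    expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  }
})

test_that("quality filters fire on the printed thresholds", {
  cfg <- library_filter_config()
  good <- template_entry(make_complex(50, n_bp = 8, offset = 8, seed = 31))
  expect_true(passes_quality_filters(good, cfg))
  expect_length(attr(passes_quality_filters(good, cfg), "violations"), 0)

  short <- template_entry(make_complex(39, n_bp = 8, offset = 8, seed = 31))
  v <- passes_quality_filters(short, cfg)
  expect_false(v)
  expect_equal(attr(v, "violations"), "min_protein_length")

  far <- template_entry(make_complex(50, n_bp = 8, offset = 30, seed = 31))
  v <- passes_quality_filters(far, cfg)
  expect_false(v)
  expect_equal(attr(v, "violations"), "min_interface_residues")

  coarse <- template_entry(make_complex(50, seed = 31, resolution = 3.5))
  expect_equal(attr(passes_quality_filters(coarse, cfg), "violations"),
               "max_resolution")
  nores <- template_entry(make_complex(50, seed = 31, resolution = NA))
  expect_equal(attr(passes_quality_filters(nores, cfg), "violations"),
               "resolution-unknown")
  fewbp <- template_entry(make_complex(50, n_bp = 4, seed = 31))
  expect_equal(attr(passes_quality_filters(fewbp, cfg), "violations"),
               "min_base_pairs")
})

test_that("redundancy removal keeps one of two near-identical entries", {
  a <- template_entry(make_complex(50, seed = 41, id = "aaa"))
  b <- template_entry(make_complex(50, seed = 42, id = "bbb",
                                   sequence = a$sequence))
  kept <- remove_redundancy(list(a, b), 0.35)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$id, "aaa")  # lexicographic tie-break at equal length
  ## all below threshold -> unchanged set
  c3 <- template_entry(make_complex(50, seed = 43, id = "ccc"))
  kept2 <- remove_redundancy(list(a, c3), 0.35)
  expect_length(kept2, 2L)
})

test_that("redundancy removal resolves identity clusters", {
  ## 3 clusters of sizes 4/3/3 at ~90% within, ~10% between
  entries <- list(); k <- 0
  for (cl in 1:3) {
    base <- random_aa_seq(80, cl * 100)
    for (m in seq_len(c(4, 3, 3)[cl])) {
      k <- k + 1
      sq <- if (m == 1) base else dnathread:::.mutate_sequence(base, 0.9,
                                                               cl * 100 + m)
      entries[[k]] <- template_entry(
        make_complex(80, seed = cl * 100 + m, id = sprintf("e%02d", k),
                     sequence = sq))
    }
  }
  kept <- remove_redundancy(entries, 0.35)
  expect_length(kept, 3L)
  ## survivors are mutually below the threshold (exhaustive check)
  for (i in seq_along(kept)) for (j in seq_len(i - 1))
    expect_lte(sequence_identity(kept[[i]]$sequence, kept[[j]]$sequence),
               0.35)
})

test_that("build_library applies the planted filter plan", {
  demo <- make_filter_demo(seed = 2)
  lib <- suppressMessages(build_library(unname(demo), quiet = TRUE))
  expect_length(lib$entries, 5L)
  kept_ids <- vapply(lib$entries, function(e) e$id, character(1))
  expect_setequal(kept_ids, c("ok1", "ok2", "ok3", "ok4", "ok5"))
  ## every survivor passes the filters; rejection log names the rules
  for (e in lib$entries) expect_true(passes_quality_filters(e))
  lg <- lib$log
  expect_equal(lg$fate[lg$id == "too_short"], "min_protein_length")
  expect_equal(lg$fate[lg$id == "few_bp"], "min_base_pairs")
  expect_equal(lg$fate[lg$id == "no_interface"], "min_interface_residues")
  expect_equal(lg$fate[lg$id == "bad_resolution"], "max_resolution")
  expect_equal(lg$fate[lg$id == "redundant"], "redundant")
})

test_that("library serialization round-trips and is idempotent", {
  demo <- make_filter_demo(seed = 2)
  d1 <- withr::local_tempdir()
  lib <- suppressMessages(build_library(unname(demo), out_dir = d1,
                                        quiet = TRUE))
  idx1 <- readLines(file.path(d1, "index.tsv"))
  back <- load_library(d1)
  expect_equal(length(back$entries), length(lib$entries))
  expect_equal(library_index(back), library_index(lib), tolerance = 1e-6)
  d2 <- withr::local_tempdir()
  write_library(back, d2)
  expect_identical(readLines(file.path(d2, "index.tsv")), idx1)
  ## empty input -> empty library with a warning
  expect_warning(empty <- build_library(list(), quiet = TRUE), "empty")
  expect_length(empty$entries, 0L)
})
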