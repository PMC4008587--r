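# Metrics, threshold optimization and leave-one-out integrity.

test_that("metric closed forms: perfect, random, and printed fold totals", {
  perfect <- metrics(confusion_counts(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_equal(perfect$sn, 1); expect_equal(perfect$pr, 1)
  expect_equal(perfect$sp, 1); expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  rand <- metrics(confusion_counts(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(rand$mcc, 0)
  ## fold-level totals: 122 binding / 301 non-binding domains, 61 true and
  ## 4 false positives under the probability+energy rule
  m <- metrics(confusion_counts(tp = 61, fp = 4, fn = 61, tn = 297))
  o <- oracle_metrics(61, 297, 4, 61)
  expect_equal(m$sn, o$sn); expect_equal(m$pr, o$pr)
  expect_equal(m$sp, o$sp); expect_equal(m$acc, o$acc)
  expect_equal(m$mcc, o$mcc)
})

test_that("undefined denominators are flagged, not silently zeroed", {
  m <- metrics(confusion_counts(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(m$sn))
  expect_false(m$defined["sn"])
  expect_equal(m$mcc, 0)
  expect_false(m$defined["mcc"])
})

test_that("metrics agree with the formula oracle on random tables", {
  for (seed in 1:200) {
    cc <- with_seed(seed, as.list(stats::setNames(sample(0:40, 4, TRUE),
                                                  c("tp", "tn", "fp", "fn"))))
    m <- metrics(confusion_counts(cc$tp, cc$tn, cc$fp, cc$fn))
    o <- oracle_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
    for (f in c("sn", "pr", "sp", "acc")) {
      if (is.nan(o[[f]])) expect_true(is.na(m[[f]]))
      else expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
    }
    if (!is.nan(o$mcc)) expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
  }
})

test_that("residue metrics over a universe match the confusion oracle", {
  expect_equal(residue_metrics(1:5, 1:5, 1:20)$mcc, 1)
  disj <- residue_metrics(1:5, 6:10, 1:20)
  expect_equal(disj$sn, 0); expect_equal(disj$pr, 0)
  expect_error(residue_metrics(1:2, 1:2, integer()), "empty")
  expect_error(residue_metrics(1:30, 1:5, 1:20), "universe")
  for (seed in 1:100) {
    u <- 1:100
    p <- with_seed(seed, sample(u, sample(0:40, 1)))
    a <- with_seed(seed + 1000, sample(u, sample(1:40, 1)))
    m <- residue_metrics(p, a, u)
    tp <- length(intersect(p, a)); fp <- length(setdiff(p, a))
    fn <- length(setdiff(a, p)); tn <- 100 - tp - fp - fn
    o <- oracle_metrics(tp, tn, fp, fn)
    if (!is.nan(o$mcc)) expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
    expect_equal(m$sn, o$sn, tolerance = 1e-12)
  }
  ## unweighted per-protein mean
  ms <- list(residue_metrics(1:5, 1:5, 1:10),
             residue_metrics(1:5, 6:10, 1:20))
  avg <- residue_metrics_mean(ms)
  expect_equal(unname(avg["sn"]), 0.5)
  expect_equal(unname(avg["mcc"]), (1 + ms[[2]]$mcc) / 2)
})

test_that("threshold optimization equals the exhaustive scan oracle", {
  for (seed in 1:100) {
    n <- 30
    rec <- with_seed(seed, data.frame(
      probability = round(stats::runif(n), 2),
      energy = round(stats::rnorm(n, -8, 3), 1),
      label = stats::runif(n) < 0.4))
    if (all(rec$label) || !any(rec$label)) next
    got <- optimize_thresholds(rec)
    ref <- oracle_optimize(rec)
    expect_equal(got$mcc, ref$mcc, tolerance = 1e-12,
                 label = sprintf("seed %d", seed))
    expect_equal(got$thresholds$p_min, ref$p)
    expect_equal(got$thresholds$e_max, ref$e)
  }
})

test_that("threshold optimization edge cases", {
  sep <- data.frame(probability = c(0.9, 0.95, 0.2, 0.3),
                    energy = c(-10, -12, -1, -2),
                    label = c(TRUE, TRUE, FALSE, FALSE))
  got <- optimize_thresholds(sep)
  expect_equal(got$mcc, 1)
  ## tie-break: highest separating p_min, lowest e_max among MCC ties
  expect_equal(got$thresholds$p_min, 0.9)
  expect_equal(got$thresholds$e_max, -10)
  ## flipping labels: original labelling scores <= 0 under flipped optimum
  flip <- sep; flip$label <- !flip$label
  gf <- optimize_thresholds(flip)
  pred <- sep$probability >= gf$thresholds$p_min &
    sep$energy <= gf$thresholds$e_max
  tp <- sum(pred & sep$label); fp <- sum(pred & !sep$label)
  fn <- sum(!pred & sep$label); tn <- sum(!pred & !sep$label)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc0 <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  expect_lte(mcc0, 0)
  expect_error(optimize_thresholds(data.frame(probability = 1, energy = -1,
                                              label = TRUE)),
               "single-class")
})

test_that("leave-one-out excludes self and identity > cutoff", {
  bm <- make_benchmark(seed = 11, n_clusters = 2, cluster_size = 2,
                       n_negatives = 4, n_res = 60)
  loo <- leave_one_out(bm, K = 4)
  ## no scored pair above the cutoff, ever
  expect_lte(loo$max_scored_identity, 0.30)
  expect_false(any(loo$scored_pairs$target == loo$scored_pairs$template))
  ## each positive had at least its own self-template excluded
  pos <- loo$records[loo$records$label, ]
  expect_true(all(pos$n_excluded >= 1))
  ## identity_cutoff = 1 -> nothing excluded
  loo_all <- leave_one_out(bm, identity_cutoff = 1, K = 4)
  expect_true(all(loo_all$records$n_excluded == 0))
  ## with every homolog excluded a lone positive cannot be recovered
  bm1 <- make_benchmark(seed = 12, n_clusters = 1, cluster_size = 1,
                        n_negatives = 3, n_res = 60)
  loo1 <- leave_one_out(bm1, thresholds = decision_thresholds(),
                        K = 2)
  r <- loo1$records[loo1$records$label, ]
  expect_false(r$is_binder)
  expect_equal(r$rationale, "no-template")
})
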