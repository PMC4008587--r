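# Performance metrics, leave-one-out benchmarking with sequence-identity
# exclusion, and MCC-based threshold optimization.

#' Confusion counts
#' @param tp,tn,fp,fn nonnegative integers.
#' @return a \code{confusion_counts} list.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Two-state performance metrics
#'
#' Sensitivity \code{TP/(TP+FN)}, precision \code{TP/(TP+FP)}, specificity
#' \code{TN/(TN+FP)}, accuracy \code{(TP+TN)/total} and the Matthews
#' correlation coefficient
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}.
#' A metric with a zero denominator is returned as NA and flagged in the
#' \code{defined} field; for the MCC the convention is 0 when any marginal
#' is empty, flagged \code{mcc_defined = FALSE}.
#'
#' @param c a \code{\link{confusion_counts}} (or tp/tn/fp/fn given
#'   directly).
#' @return object of class \code{metric_set}: sn, pr, sp, acc, mcc,
#'   defined (named logical), counts.
#' @export
metrics <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  sn <- sdiv(tp, tp + fn)
  pr <- sdiv(tp, tp + fp)
  sp <- sdiv(tn, tn + fp)
  acc <- sdiv(tp + tn, tp + tn + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc_defined <- denom > 0
  mcc <- if (mcc_defined) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(sn = sn, pr = pr, sp = sp, acc = acc, mcc = mcc,
                 defined = c(sn = !is.na(sn), pr = !is.na(pr),
                             sp = !is.na(sp), acc = !is.na(acc),
                             mcc = mcc_defined),
                 counts = c),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v, d) if (d) sprintf("%.3f", v) else "undef"
  cat(sprintf("SN %s  PR %s  SP %s  ACC %s  MCC %s\n",
              fmt(x$sn, x$defined["sn"]), fmt(x$pr, x$defined["pr"]),
              fmt(x$sp, x$defined["sp"]), fmt(x$acc, x$defined["acc"]),
              if (x$defined["mcc"]) sprintf("%.3f", x$mcc) else "0 (undef)"))
  invisible(x)
}

#' Residue-level metrics for one protein
#'
#' Builds the per-protein confusion table of predicted versus actual
#' binding residues over the protein's full residue universe, then applies
#' \code{\link{metrics}}.
#'
#' @param predicted,actual vectors of residue identifiers (positions or
#'   keys); must be subsets of \code{universe}.
#' @param universe all residues of the protein.
#' @return a \code{metric_set}.
#' @export
residue_metrics <- function(predicted, actual, universe) {
  if (length(universe) == 0L) stop("empty residue universe")
  predicted <- unique(predicted); actual <- unique(actual)
  if (!all(predicted %in% universe) || !all(actual %in% universe))
    stop("predicted and actual sets must lie within the universe")
  p <- universe %in% predicted
  a <- universe %in% actual
  metrics(confusion_counts(tp = sum(p & a), tn = sum(!p & !a),
                           fp = sum(p & !a), fn = sum(!p & a)))
}

#' Unweighted mean of per-protein metric sets
#'
#' Averages each metric across proteins with equal weight per protein
#' (undefined values dropped), the convention used for residue-level
#' benchmark summaries.
#'
#' @param sets list of \code{metric_set} objects.
#' @return named numeric vector (sn, pr, sp, acc, mcc).
#' @export
residue_metrics_mean <- function(sets) {
  get <- function(f, d) {
    v <- vapply(sets, function(s)
      if (s$defined[d]) s[[f]] else NA_real_, numeric(1))
    mean(v, na.rm = TRUE)
  }
  c(sn = get("sn", "sn"), pr = get("pr", "pr"), sp = get("sp", "sp"),
    acc = get("acc", "acc"), mcc = get("mcc", "mcc"))
}

#' Optimize the two decision thresholds by MCC maximization
#'
#' Exhaustive scan over the grid of observed probability values times
#' observed energy values (each observed value is a candidate threshold);
#' returns the (p_min, e_max) pair maximizing the MCC of the rule
#' \code{probability >= p_min & energy <= e_max}.  Ties are broken by
#' higher p_min, then lower e_max.
#'
#' @param records data.frame with columns \code{probability},
#'   \code{energy}, \code{label} (logical).  NA probability/energy rows
#'   (no template) can never be predicted positive.
#' @return list: \code{thresholds} (a
#'   \code{\link{decision_thresholds}}), \code{mcc}, \code{confusion}.
#' @export
optimize_thresholds <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("probability", "energy", "label") %in% names(records)))
  lab <- as.logical(records$label)
  if (all(lab) || !any(lab))
    stop("degenerate single-class input: cannot optimize thresholds")
  prob <- ifelse(is.na(records$probability), -Inf, records$probability)
  en <- ifelse(is.na(records$energy), Inf, records$energy)
  pc <- sort(unique(prob[is.finite(prob)]))
  ec <- sort(unique(en[is.finite(en)]))
  if (!length(pc) || !length(ec))
    stop("no finite candidate thresholds")
  P <- outer(prob, pc, ">=")          # n x np
  E <- outer(en, ec, "<=")            # n x ne
  tp <- crossprod(P[lab, , drop = FALSE], E[lab, , drop = FALSE])
  fp <- crossprod(P[!lab, , drop = FALSE], E[!lab, , drop = FALSE])
  fn <- sum(lab) - tp
  tn <- sum(!lab) - fp
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(denom > 0, (tp * tn - fp * fn) / sqrt(denom), 0)
  best <- max(mcc)
  cand <- which(mcc == best, arr.ind = TRUE)
  ## tie-break: highest p_min, then lowest e_max
  ord <- order(-pc[cand[, 1]], ec[cand[, 2]])
  sel <- cand[ord[1], ]
  th <- decision_thresholds(p_min = pc[sel[1]], e_max = ec[sel[2]])
  list(thresholds = th, mcc = best,
       confusion = confusion_counts(tp = tp[sel[1], sel[2]],
                                    tn = tn[sel[1], sel[2]],
                                    fp = fp[sel[1], sel[2]],
                                    fn = fn[sel[1], sel[2]]))
}

#' Leave-one-out evaluation with sequence-identity exclusion
#'
#' For every labeled query, all templates with sequence identity strictly
#' above \code{identity_cutoff} to the query (including the query itself
#' when it doubles as a template) are excluded; the remaining templates
#' are matched with the fallback aligner, the top \code{K} models are
#' scored, and the best probability/energy pair is recorded.  Thresholds
#' are then either applied as given or optimized by MCC over the recorded
#' pairs.  The identity of every scored (target, template) pair is
#' tracked, so the exclusion is auditable.
#'
#' @param benchmark a \code{\link{make_benchmark}} object, or a list with
#'   \code{library} (template entries) and \code{queries} (data.frame id /
#'   sequence / label).
#' @param potential a fitted \code{dna_potential}; when NULL one is
#'   trained on all positive library structures (and, with
#'   \code{retrain_per_fold}, retrained per target without the excluded
#'   structures).
#' @param thresholds a \code{\link{decision_thresholds}}, or NULL to scan.
#' @param identity_cutoff exclusion cutoff (templates with identity
#'   strictly greater are removed).
#' @param K top matches scored per query.
#' @param retrain_per_fold retrain the potential for every target with the
#'   excluded templates' structures removed.
#' @param ... passed to \code{\link{train_potential}}.
#' @return list of class \code{loo_result}: \code{records} (data.frame id,
#'   label, probability, energy, template, is_binder, rationale),
#'   \code{thresholds}, \code{confusion}, \code{metrics},
#'   \code{max_scored_identity}, \code{scored_pairs}.
#' @export
leave_one_out <- function(benchmark, potential = NULL, thresholds = NULL,
                          identity_cutoff = 0.30, K = 10,
                          retrain_per_fold = FALSE, ...) {
  lib <- benchmark$library
  if (inherits(lib, "template_library")) lib <- lib$entries
  queries <- benchmark$queries
  tmpl_ids <- vapply(lib, function(e) e$id, character(1))
  names(lib) <- tmpl_ids
  if (is.null(potential) && !retrain_per_fold)
    potential <- train_potential(lib, ...)

  scored_pairs <- list()
  recs <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    id <- queries$id[q]; seq <- queries$sequence[q]
    idents <- vapply(lib, function(e) {
      if (e$id == id) 1.0 else sequence_identity(seq, e$sequence)
    }, numeric(1))
    eligible <- lib[idents <= identity_cutoff]
    rec <- data.frame(id = id, label = queries$label[q],
                      probability = NA_real_, energy = NA_real_,
                      template = NA_character_, n_excluded =
                        sum(idents > identity_cutoff),
                      stringsAsFactors = FALSE)
    if (length(eligible)) {
      pot_q <- if (retrain_per_fold)
        train_potential(eligible, ...) else potential
      matches <- lapply(eligible, function(e) fallback_align(seq, e))
      matches <- matches[order(-vapply(matches, function(m) m$probability,
                                       numeric(1)))]
      rec$probability <- matches[[1]]$probability
      top <- matches[seq_len(min(K, length(matches)))]
      en <- vapply(top, function(m) {
        mod <- build_model(seq, m, eligible[[m$template_id]], query_id = id)
        score_complex(mod, pot_q)$total
      }, numeric(1))
      for (m in top)
        scored_pairs[[length(scored_pairs) + 1L]] <-
          data.frame(target = id, template = m$template_id,
                     identity = idents[[m$template_id]],
                     stringsAsFactors = FALSE)
      best <- order(en, -vapply(top, function(m) m$probability, numeric(1)),
                    vapply(top, function(m) m$template_id, character(1)))[1]
      rec$energy <- en[best]
      rec$template <- top[[best]]$template_id
    }
    recs[[q]] <- rec
  }
  records <- do.call(rbind, recs)
  scored_pairs <- if (length(scored_pairs)) do.call(rbind, scored_pairs)
    else data.frame(target = character(), template = character(),
                    identity = numeric())
  stopifnot(all(scored_pairs$identity <= identity_cutoff))

  if (is.null(thresholds)) {
    opt <- optimize_thresholds(records)
    thresholds <- opt$thresholds
  }
  dec <- mapply(function(p, e) decide_binding(p, e, thresholds),
                records$probability, records$energy, SIMPLIFY = FALSE)
  records$is_binder <- vapply(dec, function(d) d$is_binder, logical(1))
  records$rationale <- vapply(dec, function(d) d$rationale, character(1))
  cc <- confusion_counts(tp = sum(records$is_binder & records$label),
                         tn = sum(!records$is_binder & !records$label),
                         fp = sum(records$is_binder & !records$label),
                         fn = sum(!records$is_binder & records$label))
  structure(list(records = records, thresholds = thresholds,
                 confusion = cc, metrics = metrics(cc),
                 max_scored_identity =
                   if (nrow(scored_pairs)) max(scored_pairs$identity) else NA,
                 scored_pairs = scored_pairs,
                 identity_cutoff = identity_cutoff),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(paste0("leave-one-out over %d queries ",
                     "(identity cutoff %.2f, max scored %.3f)\n",
                     "  thresholds: p_min = %.3f, e_max = %.2f\n  "),
              nrow(x$records), x$identity_cutoff,
              x$max_scored_identity, x$thresholds$p_min,
              x$thresholds$e_max))
  print(x$metrics)
  invisible(x)
}
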