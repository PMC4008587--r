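# Per-query prediction pipeline: match -> thread -> score -> two-threshold
# decision -> binding residues.

#' Decision thresholds of the two-gate classifier
#'
#' A query is called DNA-binding when its best template match probability
#' reaches \code{p_min} and the binding energy of the best threaded model
#' is at most \code{e_max}.  Statistical-potential energies are negative
#' for attraction, so "higher affinity than the threshold" is implemented
#' as \code{E <= e_max}.  The defaults (0.84 / -8.6) are the published
#' operating point and are meaningful only with a compatible potential
#' artifact; a retrained potential should be recalibrated with
#' \code{\link{optimize_thresholds}}.
#'
#' @param p_min match-probability threshold in [0, 1].
#' @param e_max energy threshold (eta*kT units).
#' @return a \code{decision_thresholds} list.
#' @export
decision_thresholds <- function(p_min = 0.84, e_max = -8.6) {
  stopifnot(p_min >= 0, p_min <= 1)
  structure(list(p_min = p_min, e_max = e_max),
            class = "decision_thresholds")
}

#' Apply the two-threshold decision rule
#'
#' @param probability best match probability (NA when no template matched).
#' @param energy best model energy (NA when nothing was scored).
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @return list: \code{is_binder} and \code{rationale} (one of
#'   \code{"no-template"}, \code{"probability-fail"}, \code{"energy-fail"},
#'   \code{"accept"}).
#' @export
decide_binding <- function(probability, energy,
                           thresholds = decision_thresholds()) {
  if (is.na(probability))
    return(list(is_binder = FALSE, rationale = "no-template"))
  if (probability < thresholds$p_min)
    return(list(is_binder = FALSE, rationale = "probability-fail"))
  if (is.na(energy) || energy > thresholds$e_max)
    return(list(is_binder = FALSE, rationale = "energy-fail"))
  list(is_binder = TRUE, rationale = "accept")
}

#' Predict DNA-binding residues from a threaded model
#'
#' Applies the interface rule (any residue heavy atom strictly closer than
#' \code{cutoff} to any DNA-base heavy atom) to the model and reports
#' 1-based query positions.
#'
#' @param model a \code{\link{build_model}} result.
#' @param cutoff contact cutoff, Angstrom.
#' @return sorted integer vector of query positions.
#' @export
predict_binding_residues <- function(model, cutoff = 4.5) {
  iface <- interface_residues(model$structure, cutoff = cutoff)
  sort(iface$resno)
}

#' Classify one query against a template library
#'
#' Candidates are the top \code{K} matches with probability at least
#' \code{p_min}; each is threaded and scored, the minimum-energy model is
#' retained (ties broken by lower energy, then higher probability, then
#' lexicographic template id), and the query is called binding iff that
#' energy is at most \code{e_max}.
#'
#' @param query_id,query query identifier and 1-letter sequence.
#' @param matches list of \code{\link{template_match}}, sorted by
#'   descending probability.
#' @param library a \code{template_library} or list of
#'   \code{\link{template_entry}}.
#' @param potential a fitted \code{dna_potential}.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @param K number of top matches to evaluate.
#' @param contact_cutoff binding-residue cutoff, Angstrom.
#' @return object of class \code{prediction_record}.
#' @export
classify <- function(query_id, query, matches, library, potential,
                     thresholds = decision_thresholds(), K = 10,
                     contact_cutoff = 4.5) {
  entries <- if (inherits(library, "template_library")) library$entries
             else library
  names(entries) <- vapply(entries, function(e) e$id, character(1))
  rec <- list(query_id = query_id, is_binder = FALSE, best_template = NA,
              probability = NA_real_, energy = NA_real_, model = NULL,
              binding_residues = integer(), rationale = "no-template")
  if (length(matches)) {
    matches <- matches[order(-vapply(matches, function(m) m$probability,
                                     numeric(1)))]
    probs <- vapply(matches, function(m) m$probability, numeric(1))
    rec$probability <- max(probs)
    cand <- matches[probs >= thresholds$p_min]
    cand <- cand[seq_len(min(K, length(cand)))]
    if (length(cand) == 0L) {
      rec$rationale <- "probability-fail"
    } else {
      scored <- lapply(cand, function(m) {
        tpl <- entries[[m$template_id]]
        if (is.null(tpl)) return(NULL)
        mod <- build_model(query, m, tpl, query_id = query_id)
        list(match = m, model = mod,
             energy = score_complex(mod, potential)$total)
      })
      scored <- Filter(Negate(is.null), scored)
      if (length(scored) == 0L) {
        rec$rationale <- "no-template"
      } else {
        en <- vapply(scored, function(s) s$energy, numeric(1))
        pr <- vapply(scored, function(s) s$match$probability, numeric(1))
        id <- vapply(scored, function(s) s$match$template_id, character(1))
        best <- scored[[order(en, -pr, id)[1]]]
        rec$best_template <- best$match$template_id
        rec$probability <- best$match$probability
        rec$energy <- best$energy
        rec$model <- best$model
        d <- decide_binding(rec$probability, rec$energy, thresholds)
        rec$is_binder <- d$is_binder
        rec$rationale <- d$rationale
        if (rec$is_binder)
          rec$binding_residues <- predict_binding_residues(best$model,
                                                           contact_cutoff)
      }
    }
  }
  structure(rec, class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("%s: %s (%s)%s\n", x$query_id,
              if (x$is_binder) "DNA-binding" else "non-binding",
              x$rationale,
              if (is.na(x$probability)) "" else
                sprintf(" P = %.3f, E = %.2f, template %s",
                        x$probability, x$energy, x$best_template)))
  invisible(x)
}

.records_table <- function(records) {
  if (length(records) == 0L) return(NULL)
  do.call(rbind, c(lapply(records, function(r)
    data.frame(query = r$query_id, is_binder = r$is_binder,
               template = as.character(r$best_template),
               probability = r$probability, energy = r$energy,
               n_binding_residues = length(r$binding_residues),
               rationale = r$rationale, stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
}

#' Run the full prediction pipeline over a FASTA file
#'
#' For every query: use a precomputed HHR report from \code{hhr_dir} when
#' one named \code{<id>.hhr} exists, otherwise align with the fallback
#' aligner against every library entry; classify; optionally write
#' \code{predictions.tsv}, one model PDB per predicted binder and one
#' binding-residue TSV (position, amino acid, minimum distance to a DNA
#' base).  Per-query failures are logged and the run continues.
#'
#' @param fasta path to the query FASTA file.
#' @param library a \code{template_library} (or entry list).
#' @param potential a fitted \code{dna_potential}.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @param hhr_dir optional directory of precomputed HHR reports.
#' @param out_dir optional output directory.
#' @param K top matches evaluated per query.
#' @param contact_cutoff binding-residue cutoff, Angstrom.
#' @return list: \code{records} (prediction_record list), \code{table}
#'   (data.frame), \code{n_failed}.
#' @export
run_pipeline <- function(fasta, library, potential,
                         thresholds = decision_thresholds(),
                         hhr_dir = NULL, out_dir = NULL, K = 10,
                         contact_cutoff = 4.5) {
  if (!file.exists(fasta)) stop("query file not found: ", fasta)
  entries <- if (inherits(library, "template_library")) library$entries
             else library
  qs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(qs))
  if (length(qs) == 0L) warning("empty query file")
  records <- list(); n_failed <- 0L
  for (k in seq_along(qs)) {
    rec <- tryCatch({
      query <- as.character(qs[[k]])
      hhr <- if (!is.null(hhr_dir))
        file.path(hhr_dir, paste0(ids[k], ".hhr")) else ""
      matches <- if (nzchar(hhr) && file.exists(hhr)) parse_hhr(hhr)
      else {
        m <- lapply(entries, function(e) fallback_align(query, e))
        m[order(-vapply(m, function(x) x$probability, numeric(1)))]
      }
      classify(ids[k], query, matches, entries, potential, thresholds,
               K = K, contact_cutoff = contact_cutoff)
    }, error = function(e) {
      message(sprintf("query %s failed: %s", ids[k], conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) n_failed <- n_failed + 1L
    else records[[length(records) + 1L]] <- rec
  }
  tab <- .records_table(records)
  if (is.null(tab))
    tab <- data.frame(query = character(), is_binder = logical(),
                      template = character(), probability = numeric(),
                      energy = numeric(), n_binding_residues = integer(),
                      rationale = character(), stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "models"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "residues"), showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in records) {
      if (!r$is_binder) next
      writeLines(write_structure(r$model$structure),
                 file.path(out_dir, "models", paste0(r$query_id, ".pdb")))
      iface <- interface_residues(r$model$structure,
                                  cutoff = contact_cutoff)
      aa <- protein_residues(r$model$structure)
      res_tab <- data.frame(position = iface$resno,
                            aa = aa$aa[match(iface$key, aa$key)],
                            min_dist = round(iface$min_dist, 3))
      res_tab <- res_tab[order(res_tab$position), , drop = FALSE]
      utils::write.table(res_tab,
                         file.path(out_dir, "residues",
                                   paste0(r$query_id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(records = records, table = tab, n_failed = n_failed)
}
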