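# Fold-recognition alignment consumption (HHR reports or the internal
# fallback aligner) and threading: copying a query sequence onto template
# coordinates while keeping the template DNA intact.

#' Construct a template match
#'
#' @param template_id template identifier.
#' @param probability match probability in [0, 1].
#' @param aligned_pairs 2-column matrix of (query_pos, template_pos),
#'   1-based, strictly increasing in both coordinates.
#' @param identity identity fraction over aligned positions.
#' @param source \code{"hhr"} or \code{"fallback"}.
#' @return object of class \code{template_match}.
#' @export
template_match <- function(template_id, probability, aligned_pairs,
                           identity = NA_real_, source = "hhr") {
  aligned_pairs <- matrix(as.integer(aligned_pairs), ncol = 2,
                          dimnames = list(NULL, c("query", "template")))
  if (nrow(aligned_pairs)) {
    stopifnot(!is.unsorted(aligned_pairs[, 1], strictly = TRUE),
              !is.unsorted(aligned_pairs[, 2], strictly = TRUE))
  }
  stopifnot(probability >= 0, probability <= 1)
  structure(list(template_id = template_id, probability = probability,
                 aligned_pairs = aligned_pairs, identity = identity,
                 source = source),
            class = "template_match")
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("template_match -> %s: P = %.3f, %d aligned pairs%s [%s]\n",
              x$template_id, x$probability, nrow(x$aligned_pairs),
              if (is.na(x$identity)) "" else
                sprintf(", identity %.2f", x$identity), x$source))
  invisible(x)
}

.hhr_aln_row <- function(line) {
  ## "Q <name> <start> <SEQ> <end> (<len>)" alignment row
  m <- regmatches(line,
    regexec("^[QT]\\s+(\\S+)\\s+(\\d+)\\s+(\\S+)\\s+(\\d+)", line))[[1]]
  if (length(m) == 0L) return(NULL)
  list(name = m[2], start = as.integer(m[3]), seq = m[4],
       end = as.integer(m[5]))
}

#' Parse an HHsearch/HHblits HHR report
#'
#' Extracts one match per hit block: the template id from the \code{>}
#' header, the probability from the \code{Probab=} summary (percent,
#' divided by 100), the identity from \code{Identities=}, and the aligned
#' (query, template) position pairs reconstructed from the Q/T alignment
#' rows, skipping gap columns.  Consensus and secondary-structure rows are
#' ignored; malformed blocks are skipped with a warning.  Hits are
#' returned sorted by descending probability.
#'
#' @param text character vector of report lines, or one string with
#'   newlines, or a file path.
#' @return list of \code{\link{template_match}} objects (possibly empty).
#' @export
parse_hhr <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^No\\s+\\d+", text)
  hits <- list()
  for (h in seq_along(starts)) {
    block <- text[starts[h]:(if (h < length(starts)) starts[h + 1] - 1L
                             else length(text))]
    hit <- tryCatch({
      hdr <- grep("^>", block, value = TRUE)[1]
      if (is.na(hdr)) stop("missing hit header")
      template_id <- sub("^>(\\S+).*", "\\1", hdr)
      pl <- grep("Probab=", block, value = TRUE)[1]
      if (is.na(pl)) stop("missing Probab line")
      probability <- as.numeric(sub(".*Probab=([0-9.eE+-]+).*", "\\1", pl)) / 100
      identity <- if (grepl("Identities=", pl))
        as.numeric(sub(".*Identities=([0-9.]+)%.*", "\\1", pl)) / 100
      else NA_real_
      pairs <- list()
      qpos <- tpos <- NA_integer_
      qseq <- tseq <- NULL
      for (ln in block) {
        if (grepl("^Q\\s", ln)) {
          r <- .hhr_aln_row(ln)
          if (is.null(r) || r$name %in% c("Consensus") ||
              grepl("^ss_", r$name)) next
          qseq <- r$seq; qpos <- r$start
        } else if (grepl("^T\\s", ln)) {
          r <- .hhr_aln_row(ln)
          if (is.null(r) || r$name %in% c("Consensus") ||
              grepl("^ss_", r$name)) next
          tseq <- r$seq; tpos <- r$start
          if (!is.null(qseq)) {
            qs <- strsplit(qseq, "")[[1]]
            ts <- strsplit(tseq, "")[[1]]
            if (length(qs) != length(ts)) stop("ragged alignment rows")
            for (k in seq_along(qs)) {
              qg <- qs[k] == "-"; tg <- ts[k] == "-"
              if (!qg && !tg)
                pairs[[length(pairs) + 1L]] <- c(qpos, tpos)
              if (!qg) qpos <- qpos + 1L
              if (!tg) tpos <- tpos + 1L
            }
            qseq <- NULL
          }
        }
      }
      pairs <- if (length(pairs)) do.call(rbind, pairs) else
        matrix(integer(), ncol = 2)
      template_match(template_id, probability, pairs, identity,
                     source = "hhr")
    }, error = function(e) {
      warning(sprintf("skipping malformed hit block %d: %s", h,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(hit)) hits[[length(hits) + 1L]] <- hit
  }
  hits[order(-vapply(hits, function(x) x$probability, numeric(1)))]
}

## logistic pseudo-probability calibrated through two anchor points:
## identity 0.30 -> 0.84 (the operating probability threshold) and
## identity 1.00 -> 0.999
.FALLBACK_CAL <- local({
  l1 <- log(0.84 / 0.16); l2 <- log(0.999 / 0.001)
  b <- (l2 - l1) / 0.7
  c(a = l1 - 0.3 * b, b = b)
})

#' Align a query to a template with the internal fallback aligner
#'
#' Global Needleman-Wunsch (BLOSUM62, gap open 11 / extend 1) standing in
#' for an external fold-recognition tool when no HHR report is supplied.
#' The match probability is a logistic map of the sequence identity
#' (identity 0.30 maps to 0.84, identity 1.0 to 0.999); records are
#' flagged \code{source = "fallback"}.  This is a sequence aligner, not a
#' profile-HMM search: benchmark-grade runs should supply real HHR files.
#'
#' @param query 1-letter query sequence.
#' @param template a \code{\link{template_entry}} (or a plain sequence
#'   plus \code{template_id}).
#' @param template_id id override when \code{template} is a sequence.
#' @return a \code{\link{template_match}}.
#' @export
fallback_align <- function(query, template, template_id = NULL) {
  tseq <- if (inherits(template, "template_entry")) template$sequence
          else template
  if (is.null(template_id))
    template_id <- if (inherits(template, "template_entry")) template$id
                   else "template"
  if (!nzchar(query) || !nzchar(tseq)) stop("empty sequence")
  aln <- .nw_align(query, tseq)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- tpos <- 0L
  pairs <- matrix(integer(), ncol = 2)
  keep <- qa != "-" & ta != "-"
  qidx <- cumsum(qa != "-")
  tidx <- cumsum(ta != "-")
  pairs <- cbind(qidx[keep], tidx[keep])
  identity <- Biostrings::nmatch(aln) / min(nchar(query), nchar(tseq))
  probability <- stats::plogis(.FALLBACK_CAL["a"] +
                               .FALLBACK_CAL["b"] * identity)
  template_match(template_id, unname(probability), pairs, identity,
                 source = "fallback")
}

#' Thread a query sequence onto a template complex
#'
#' For each aligned (query, template) position pair one model residue is
#' emitted: the query amino acid and query numbering with the template
#' residue's main-chain (N, CA, C, O) coordinates copied verbatim.  CB is
#' copied when the query residue is non-glycine and the template residue
#' has one, synthesized from the main chain otherwise (and omitted for
#' glycine).  Unaligned template residues and query insertions are left
#' unmodeled; the template DNA is deep-copied unchanged.
#'
#' @param query 1-letter query sequence.
#' @param match a \code{\link{template_match}} against \code{template}.
#' @param template a \code{\link{template_entry}}.
#' @param query_id id for the model.
#' @return object of class \code{threaded_model}: \code{structure} (a
#'   \code{\link{complex_structure}}), \code{coverage}, \code{source_match},
#'   \code{residue_map} (query_pos -> template residue key).
#' @export
build_model <- function(query, match, template, query_id = "query") {
  pairs <- match$aligned_pairs
  if (nrow(pairs) == 0L) stop("no aligned region")
  stopifnot(max(pairs[, 1]) <= nchar(query),
            max(pairs[, 2]) <= nrow(template$residues))
  qaa <- strsplit(query, "")[[1]]
  tp <- template$structure$protein
  tkey <- res_key(tp$chain, tp$resno, tp$icode)
  rkey <- template$residues$key[pairs[, 2]]
  qpos_of <- stats::setNames(pairs[, 1], rkey)

  keep_names <- c("N", "CA", "C", "O", "CB")
  sel <- tkey %in% rkey & tp$elety %in% keep_names
  at <- tp[sel, , drop = FALSE]
  qp <- unname(qpos_of[tkey[sel]])
  aa <- qaa[qp]
  ## glycine in the query carries no CB
  drop_cb <- at$elety == "CB" & aa == "G"
  at <- at[!drop_cb, , drop = FALSE]
  qp <- qp[!drop_cb]; aa <- aa[!drop_cb]

  prot <- data.frame(chain = "A", resno = qp, icode = "",
                     resid = unname(AA_123[aa]), aa = aa,
                     elety = at$elety, elesy = at$elesy,
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  ## synthesize CB where the query residue needs one but the template
  ## residue had none
  has_cb <- unique(qp[at$elety == "CB"])
  need_cb <- setdiff(unique(qp[!(qaa[qp] == "G")]), has_cb)
  for (q in need_cb) {
    sub <- prot[prot$resno == q, , drop = FALSE]
    idx <- match(c("N", "CA", "C"), sub$elety)
    if (anyNA(idx)) next
    xyz <- as.matrix(sub[idx, c("x", "y", "z")])
    v <- .virtual_cb(xyz[1, ], xyz[2, ], xyz[3, ])
    prot <- rbind(prot, data.frame(chain = "A", resno = q, icode = "",
                                   resid = sub$resid[1], aa = sub$aa[1],
                                   elety = "CB", elesy = "C",
                                   x = v[1], y = v[2], z = v[3],
                                   stringsAsFactors = FALSE))
  }
  ord <- order(prot$resno, match(prot$elety, keep_names))
  prot <- prot[ord, , drop = FALSE]
  rownames(prot) <- NULL
  st <- complex_structure(paste0(query_id, "_on_", template$id),
                          prot, template$structure$dna,
                          template$structure$resolution)
  structure(list(query_id = query_id, template_id = template$id,
                 structure = st,
                 coverage = nrow(pairs) / nchar(query),
                 source_match = match,
                 residue_map = stats::setNames(template$residues$key[pairs[, 2]],
                                               pairs[, 1])),
            class = "threaded_model")
}

#' @export
print.threaded_model <- function(x, ...) {
  cat(sprintf("threaded_model %s -> %s: %d residues, coverage %.2f, P = %.3f\n",
              x$query_id, x$template_id, nrow(protein_residues(x$structure)),
              x$coverage, x$source_match$probability))
  invisible(x)
}
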