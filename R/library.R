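# Template library: entries, quality filters, redundancy removal,
# sequence-identity machinery, serialization.

#' Create a template-library entry from a complex structure
#'
#' Precomputes everything the pipeline needs per template: the 1-letter
#' protein sequence with its residue map, the DNA-contacting residue set at
#' the configured cutoff, the Watson-Crick base-pair count and the
#' resolution metadata.
#'
#' @param structure a \code{\link{complex_structure}}.
#' @param id entry id (defaults to the structure id).
#' @param contact_cutoff interface cutoff in Angstrom.
#' @return an object of class \code{template_entry}.
#' @export
template_entry <- function(structure, id = structure$id,
                           contact_cutoff = 4.5) {
  residues <- protein_residues(structure)
  residues$pos <- seq_len(nrow(residues))
  iface <- interface_residues(structure, cutoff = contact_cutoff)
  structure(list(
    id = id, structure = structure,
    sequence = as.character(protein_sequence(structure)),
    residues = residues,
    interface = iface$key,
    interface_pos = residues$pos[match(iface$key, residues$key)],
    resolution = structure$resolution,
    n_base_pairs = count_base_pairs(structure),
    contact_cutoff = contact_cutoff),
    class = "template_entry")
}

#' @export
print.template_entry <- function(x, ...) {
  cat(sprintf("template_entry '%s': %d aa, %d bp, %d interface residues%s\n",
              x$id, nchar(x$sequence), x$n_base_pairs, length(x$interface),
              if (is.na(x$resolution)) "" else
                sprintf(", %.2f A", x$resolution)))
  invisible(x)
}

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

.nw_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity is the number of identical aligned positions divided by the
#' length of the shorter sequence, hence symmetric and suited to
#' domain-versus-chain comparisons.
#'
#' @param a,b 1-letter amino-acid sequences.
#' @param gap_open,gap_extend positive gap penalties.
#' @return identity fraction in [0, 1].
#' @export
sequence_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- .nw_align(a, b, gap_open, gap_extend)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Template-library quality-filter configuration
#'
#' Defaults reproduce the standard curation rules for protein-DNA complex
#' template sets: resolution 3 Angstrom or better, at least 40 amino
#' acids, at least 6 base pairs of DNA, at least 5 residues contacting
#' DNA, and a 35\% sequence-identity redundancy cutoff.
#'
#' @param max_resolution worst acceptable resolution, Angstrom.
#' @param min_protein_length minimum protein length, residues.
#' @param min_base_pairs minimum Watson-Crick base pairs.
#' @param min_interface_residues minimum DNA-contacting residues.
#' @param redundancy_identity pairwise identity above which entries are
#'   redundant, fraction in (0, 1].
#' @param contact_cutoff interface distance cutoff, Angstrom.
#' @return a \code{library_filter_config} list.
#' @export
library_filter_config <- function(max_resolution = 3.0,
                                  min_protein_length = 40L,
                                  min_base_pairs = 6L,
                                  min_interface_residues = 5L,
                                  redundancy_identity = 0.35,
                                  contact_cutoff = 4.5) {
  stopifnot(max_resolution > 0, min_protein_length > 0, min_base_pairs > 0,
            min_interface_residues > 0, contact_cutoff > 0,
            redundancy_identity > 0, redundancy_identity <= 1)
  structure(list(max_resolution = max_resolution,
                 min_protein_length = min_protein_length,
                 min_base_pairs = min_base_pairs,
                 min_interface_residues = min_interface_residues,
                 redundancy_identity = redundancy_identity,
                 contact_cutoff = contact_cutoff),
            class = "library_filter_config")
}

#' Apply the template quality filters to one entry
#'
#' @param e a \code{\link{template_entry}}.
#' @param cfg a \code{\link{library_filter_config}}.
#' @return logical; attribute \code{"violations"} lists the violated rule
#'   names (\code{"resolution-unknown"} when resolution is missing).
#' @export
passes_quality_filters <- function(e, cfg = library_filter_config()) {
  v <- character()
  if (is.na(e$resolution)) v <- c(v, "resolution-unknown")
  else if (e$resolution > cfg$max_resolution) v <- c(v, "max_resolution")
  if (nchar(e$sequence) < cfg$min_protein_length)
    v <- c(v, "min_protein_length")
  if (e$n_base_pairs < cfg$min_base_pairs) v <- c(v, "min_base_pairs")
  if (length(e$interface) < cfg$min_interface_residues)
    v <- c(v, "min_interface_residues")
  structure(length(v) == 0L, violations = v)
}

#' Greedy redundancy removal at a sequence-identity threshold
#'
#' Entries are visited in deterministic order (descending protein length,
#' then id); an entry is kept iff its identity to every already-kept entry
#' is at most \code{threshold}.
#'
#' @param entries list of \code{\link{template_entry}} objects.
#' @param threshold identity fraction above which an entry is redundant.
#' @return the kept entries, in visiting order.
#' @export
remove_redundancy <- function(entries, threshold = 0.35) {
  if (length(entries) == 0L) return(entries)
  len <- vapply(entries, function(e) nchar(e$sequence), integer(1))
  ids <- vapply(entries, function(e) e$id, character(1))
  ord <- order(-len, ids)
  kept <- list()
  for (i in ord) {
    e <- entries[[i]]
    redundant <- any(vapply(kept, function(k)
      sequence_identity(e$sequence, k$sequence) > threshold, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- e
  }
  kept
}

#' Build a template library from PDB files or structures
#'
#' Parses every input, computes interfaces and base-pair counts, applies
#' the quality filters, removes redundancy, and (optionally) serializes
#' the library: a TSV index (id, length, resolution, n_base_pairs,
#' n_interface), one PDB file per entry and a JSON metadata sidecar.
#' Every rejection is logged with the rule that fired.
#'
#' @param inputs character vector of PDB file paths, or a list of
#'   \code{\link{complex_structure}} objects.
#' @param cfg a \code{\link{library_filter_config}}.
#' @param out_dir optional directory to serialize the library into.
#' @param quiet suppress per-rejection messages.
#' @return object of class \code{template_library}: list with
#'   \code{entries}, \code{log} (data.frame id / fate), \code{n_skipped}.
#' @export
build_library <- function(inputs, cfg = library_filter_config(),
                          out_dir = NULL, quiet = FALSE) {
  entries <- list(); log <- list(); n_skipped <- 0L
  if (length(inputs) == 0L) warning("empty input list: empty library")
  for (i in seq_along(inputs)) {
    x <- if (is.list(inputs)) inputs[[i]] else inputs[i]
    st <- tryCatch({
      if (inherits(x, "complex_structure")) x
      else read_structure(readLines(x), id = sub("\\.pdb$", "", basename(x)))
    }, error = function(e) e)
    if (inherits(st, "error")) {
      n_skipped <- n_skipped + 1L
      if (!quiet) message(sprintf("skipping input %d: %s", i,
                                  conditionMessage(st)))
      next
    }
    e <- template_entry(st, contact_cutoff = cfg$contact_cutoff)
    ok <- passes_quality_filters(e, cfg)
    if (ok) {
      entries[[length(entries) + 1L]] <- e
      log[[length(log) + 1L]] <- data.frame(id = e$id, fate = "kept",
                                            stringsAsFactors = FALSE)
    } else {
      rule <- paste(attr(ok, "violations"), collapse = ",")
      log[[length(log) + 1L]] <- data.frame(id = e$id, fate = rule,
                                            stringsAsFactors = FALSE)
      if (!quiet) message(sprintf("rejecting %s: %s", e$id, rule))
    }
  }
  kept <- remove_redundancy(entries, cfg$redundancy_identity)
  kept_ids <- vapply(kept, function(e) e$id, character(1))
  log <- do.call(rbind, c(log, list(NULL)))
  if (!is.null(log)) {
    drop <- log$fate == "kept" & !(log$id %in% kept_ids)
    log$fate[drop] <- "redundant"
  } else {
    log <- data.frame(id = character(), fate = character(),
                      stringsAsFactors = FALSE)
  }
  lib <- structure(list(entries = kept, log = log, n_skipped = n_skipped,
                        config = cfg),
                   class = "template_library")
  if (!is.null(out_dir)) write_library(lib, out_dir)
  lib
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template_library: %d entries (%d rejected, %d unreadable)\n",
              length(x$entries), sum(x$log$fate != "kept" &
                                     x$log$fate != "redundant") +
                sum(x$log$fate == "redundant"), x$n_skipped))
  invisible(x)
}

#' Library index as a data.frame
#' @param lib a \code{template_library}.
#' @return data.frame: id, length, resolution, n_base_pairs, n_interface.
#' @export
library_index <- function(lib) {
  if (length(lib$entries) == 0L) return(NULL)
  do.call(rbind, c(lapply(lib$entries, function(e)
    data.frame(id = e$id, length = nchar(e$sequence),
               resolution = e$resolution, n_base_pairs = e$n_base_pairs,
               n_interface = length(e$interface),
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
}

#' Serialize a template library to disk
#'
#' Writes \code{index.tsv}, one \code{entries/<id>.pdb} per template and a
#' \code{meta.json} sidecar (filter configuration, rejection log).
#'
#' @param lib a \code{template_library}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(file.path(dir, "entries"), recursive = TRUE,
             showWarnings = FALSE)
  idx <- library_index(lib)
  if (is.null(idx)) idx <- data.frame(id = character(), length = integer(),
                                      resolution = numeric(),
                                      n_base_pairs = integer(),
                                      n_interface = integer())
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (e in lib$entries)
    writeLines(write_structure(e$structure),
               file.path(dir, "entries", paste0(e$id, ".pdb")))
  meta <- list(format = "dnathread-library-v1",
               config = unclass(lib$config),
               n_skipped = lib$n_skipped, log = lib$log)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a serialized template library
#' @param dir directory written by \code{\link{write_library}}.
#' @return a \code{template_library}.
#' @export
load_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "dnathread-library-v1")
    stop("not a dnathread library directory")
  cfg <- do.call(library_filter_config, as.list(meta$config))
  idx <- utils::read.table(file.path(dir, "index.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  entries <- lapply(idx$id, function(id) {
    st <- read_structure(readLines(file.path(dir, "entries",
                                             paste0(id, ".pdb"))), id = id)
    template_entry(st, contact_cutoff = cfg$contact_cutoff)
  })
  structure(list(entries = entries,
                 log = as.data.frame(meta$log), n_skipped = meta$n_skipped,
                 config = cfg),
            class = "template_library")
}
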