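# Distance-scaled finite ideal-gas reference-state (DFIRE-type) statistical
# potential for protein main-chain / DNA atom pairs.  train_potential() is
# the fitting function; the fitted object scores threaded complex models.

#' Atom-typing scheme for the protein-DNA potential
#'
#' The protein is reduced to the main-chain classes N, CA, C, O plus CB
#' (with a virtual CB synthesized for glycine at the ideal tetrahedral
#' position, bond length 1.53 Angstrom) — the representation a threaded
#' model can always supply.  DNA heavy atoms are typed per (base,
#' atom-name) for nucleobase atoms and base-independently for the
#' sugar-phosphate backbone (OP1/OP2 collapse to one OP class).  Unknown
#' names fall into an ignored class.
#'
#' @param include_cb include the CB class (set \code{FALSE} for a strict
#'   4-atom main-chain representation).
#' @return object of class \code{atom_scheme} with \code{protein_types}
#'   and \code{dna_types} character vectors.
#' @export
atom_type_scheme <- function(include_cb = TRUE) {
  protein_types <- c("N", "CA", "C", "O", if (include_cb) "CB")
  backbone <- c("P", "OP", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                "C2'", "C1'")
  base_types <- unlist(lapply(names(BASE_ATOMS), function(b)
    paste0(b, ".", setdiff(BASE_ATOMS[[b]], "C5M"))), use.names = FALSE)
  structure(list(protein_types = protein_types,
                 dna_types = c(backbone, base_types),
                 include_cb = include_cb),
            class = "atom_scheme")
}

#' Distance binning of the potential
#'
#' Half-open bins \code{[k*width, (k+1)*width)} from zero to the
#' interaction cutoff; \code{r_cut / width} must be an integer.
#'
#' @param width bin width, Angstrom.
#' @param r_cut interaction cutoff, Angstrom.
#' @return object of class \code{distance_binning}.
#' @export
distance_binning <- function(width = 0.5, r_cut = 15.0) {
  stopifnot(width > 0, r_cut > width)
  n <- r_cut / width
  if (abs(n - round(n)) > 1e-9) stop("r_cut / width must be an integer")
  n <- as.integer(round(n))
  structure(list(width = width, r_cut = r_cut, n_bins = n,
                 mids = (seq_len(n) - 0.5) * width),
            class = "distance_binning")
}

## ideal tetrahedral CB position from main-chain N, CA, C (bond 1.53 A)
.virtual_cb <- function(n, ca, c) {
  v1 <- n - ca; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c - ca; v2 <- v2 / sqrt(sum(v2^2))
  bis <- -(v1 + v2); bis <- bis / sqrt(sum(bis^2))
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  d <- 0.604 * bis - 0.797 * nrm
  ca + 1.53 * d / sqrt(sum(d^2))
}

#' Assign potential atom types to a complex
#'
#' Protein heavy atoms named N/CA/C/O/CB receive their class; glycine gets
#' a synthesized virtual CB when the scheme includes CB and the residue's
#' N, CA and C are present.  All other protein atoms are ignored.  Every
#' DNA heavy atom maps to its backbone or (base, name) class; unknown
#' names are counted in the \code{"n_ignored"} attribute.
#'
#' @param c a \code{\link{complex_structure}}.
#' @param scheme an \code{\link{atom_type_scheme}}.
#' @return list with \code{protein} (data.frame type index / res key /
#'   coords) and \code{dna} (data.frame type index / coords).
#' @export
assign_types <- function(c, scheme = atom_type_scheme()) {
  p <- c$protein
  keep <- p$elety %in% scheme$protein_types
  prot <- data.frame(type = match(p$elety[keep], scheme$protein_types),
                     key = res_key(p$chain[keep], p$resno[keep],
                                   p$icode[keep]),
                     x = p$x[keep], y = p$y[keep], z = p$z[keep],
                     stringsAsFactors = FALSE)
  if (scheme$include_cb) {
    ## synthesize the glycine virtual CB
    gly <- protein_residues(c)
    gly <- gly[gly$aa == "G", , drop = FALSE]
    cb_type <- match("CB", scheme$protein_types)
    for (k in seq_len(nrow(gly))) {
      sub <- p[res_key(p$chain, p$resno, p$icode) == gly$key[k], ,
               drop = FALSE]
      need <- match(c("N", "CA", "C"), sub$elety)
      if (anyNA(need)) next
      xyz <- as.matrix(sub[need, c("x", "y", "z")])
      cb <- .virtual_cb(xyz[1, ], xyz[2, ], xyz[3, ])
      prot <- rbind(prot, data.frame(type = cb_type, key = gly$key[k],
                                     x = cb[1], y = cb[2], z = cb[3],
                                     stringsAsFactors = FALSE))
    }
  }
  d <- c$dna
  n_ignored <- 0L
  if (nrow(d)) {
    name <- ifelse(d$elety == "C5M", "C7", d$elety)
    name <- ifelse(name %in% c("OP1", "OP2", "OP3", "O1P", "O2P", "O3P"),
                   "OP", name)
    lab <- ifelse(d$base_atom, paste0(d$base, ".", name), name)
    type <- match(lab, scheme$dna_types)
    n_ignored <- sum(is.na(type))
    keep <- !is.na(type)
    dna <- data.frame(type = type[keep], x = d$x[keep], y = d$y[keep],
                      z = d$z[keep], stringsAsFactors = FALSE)
  } else {
    dna <- data.frame(type = integer(), x = numeric(), y = numeric(),
                      z = numeric())
  }
  structure(list(protein = prot, dna = dna), n_ignored = n_ignored)
}

.pair_counts <- function(complexes, scheme, binning) {
  np <- length(scheme$protein_types)
  nd <- length(scheme$dna_types)
  nb <- binning$n_bins
  counts <- array(0, dim = c(np, nd, nb),
                  dimnames = list(scheme$protein_types, scheme$dna_types,
                                  NULL))
  for (cx in complexes) {
    ty <- assign_types(cx, scheme)
    if (nrow(ty$protein) == 0L || nrow(ty$dna) == 0L) next
    dm <- .cross_dist(as.matrix(ty$protein[, c("x", "y", "z")]),
                      as.matrix(ty$dna[, c("x", "y", "z")]))
    bin <- floor(dm / binning$width) + 1L
    within <- which(bin <= nb)
    if (!length(within)) next
    i <- ty$protein$type[(within - 1L) %% nrow(dm) + 1L]
    j <- ty$dna$type[(within - 1L) %/% nrow(dm) + 1L]
    lin <- i + (j - 1L) * np + (bin[within] - 1L) * np * nd
    counts <- counts + array(tabulate(lin, np * nd * nb),
                             dim = c(np, nd, nb))
  }
  counts
}

#' Build a potential from a pair-count table
#'
#' Converts observed (protein type, DNA type, distance bin) counts into
#' energies under the distance-scaled finite ideal-gas reference state:
#' \deqn{u(i,j,r) = -\eta \ln\frac{N(i,j,r)+p}{(r/r_{ref})^{\alpha}\,(N(i,j,r_{ref})+p)}}
#' with \eqn{r} the bin midpoint and \eqn{r_{ref}} the midpoint of the
#' last bin below the cutoff.  Pairs whose total count falls below
#' \code{min_pair_total} score zero, as do all distances at or beyond the
#' cutoff.
#'
#' @param counts numeric array [protein types x dna types x bins].
#' @param scheme,binning the typing scheme and binning the counts use.
#' @param alpha reference-state distance exponent (1.61, the published
#'   DFIRE value for biomolecules; 2 is the pure ideal-gas limit).
#' @param eta overall energy scale (energies are in eta * kT units).
#' @param pseudo_count additive regularizer for sparse bins.
#' @param min_pair_total minimum total count for a pair to be scored.
#' @param n_structures bookkeeping: number of training structures.
#' @return object of class \code{dna_potential}.
#' @export
potential_from_counts <- function(counts, scheme = atom_type_scheme(),
                                  binning = distance_binning(),
                                  alpha = 1.61, eta = 1.0,
                                  pseudo_count = 0.5, min_pair_total = 20,
                                  n_structures = NA_integer_) {
  stopifnot(length(dim(counts)) == 3L,
            dim(counts)[1] == length(scheme$protein_types),
            dim(counts)[2] == length(scheme$dna_types),
            dim(counts)[3] == binning$n_bins)
  if (sum(counts) == 0) stop("insufficient statistics: no cross pairs")
  nb <- binning$n_bins
  r_ref <- binning$mids[nb]
  nref <- counts[, , nb, drop = FALSE][, , 1] + pseudo_count
  u <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  for (k in seq_len(nb)) {
    scale <- (binning$mids[k] / r_ref)^alpha
    u[, , k] <- -eta * log((counts[, , k] + pseudo_count) / (scale * nref))
  }
  total <- apply(counts, c(1, 2), sum)
  dead <- total < min_pair_total
  if (any(dead)) u[array(dead, dim = dim(u))] <- 0
  structure(list(scheme = scheme, binning = binning, alpha = alpha,
                 eta = eta, pseudo_count = pseudo_count,
                 min_pair_total = min_pair_total, counts = counts, u = u,
                 n_structures = n_structures),
            class = "dna_potential")
}

#' Fit the protein-DNA statistical potential on complex structures
#'
#' Accumulates cross (protein-typed atom, DNA-typed atom) distance counts
#' within the cutoff, intra-complex only, over all training structures,
#' then applies the DFIRE reference state (see
#' \code{\link{potential_from_counts}}).  Deterministic.
#'
#' @param complexes list of \code{\link{complex_structure}} objects (or
#'   \code{\link{template_entry}} objects / a \code{template_library}).
#' @inheritParams potential_from_counts
#' @return fitted \code{dna_potential} object with \code{print},
#'   \code{summary}, \code{predict} and \code{plot} methods.
#' @export
train_potential <- function(complexes, scheme = atom_type_scheme(),
                            binning = distance_binning(), alpha = 1.61,
                            eta = 1.0, pseudo_count = 0.5,
                            min_pair_total = 20) {
  if (inherits(complexes, "template_library")) complexes <- complexes$entries
  complexes <- lapply(complexes, function(x)
    if (inherits(x, "template_entry")) x$structure else x)
  counts <- .pair_counts(complexes, scheme, binning)
  if (sum(counts) == 0) stop("insufficient statistics: no cross pairs")
  potential_from_counts(counts, scheme, binning, alpha, eta, pseudo_count,
                        min_pair_total, n_structures = length(complexes))
}

#' @export
print.dna_potential <- function(x, ...) {
  cat(sprintf(paste0(
    "dna_potential: %d protein x %d DNA types, %d bins of %.2f A ",
    "(cutoff %.1f A)\n  alpha = %.2f, eta = %g, pseudo-count = %g, ",
    "%.0f pairs observed%s\n"),
    length(x$scheme$protein_types), length(x$scheme$dna_types),
    x$binning$n_bins, x$binning$width, x$binning$r_cut, x$alpha, x$eta,
    x$pseudo_count, sum(x$counts),
    if (is.na(x$n_structures)) "" else
      sprintf(" in %d structures", x$n_structures)))
  invisible(x)
}

#' @export
summary.dna_potential <- function(object, ...) {
  total <- apply(object$counts, c(1, 2), sum)
  scored <- total >= object$min_pair_total
  out <- list(n_pairs_total = sum(object$counts),
              n_type_pairs = length(total),
              n_type_pairs_scored = sum(scored),
              u_range = range(object$u),
              alpha = object$alpha, r_cut = object$binning$r_cut)
  class(out) <- "summary.dna_potential"
  out
}

#' @export
print.summary.dna_potential <- function(x, ...) {
  cat(sprintf(paste0("Fitted protein-DNA potential\n",
                     "  observed pairs: %.0f\n",
                     "  type pairs scored: %d / %d\n",
                     "  energy range: [%.3f, %.3f] (eta*kT)\n",
                     "  alpha = %.2f, cutoff = %.1f A\n"),
              x$n_pairs_total, x$n_type_pairs_scored, x$n_type_pairs,
              x$u_range[1], x$u_range[2], x$alpha, x$r_cut))
  invisible(x)
}

#' Score a protein-DNA complex model with a fitted potential
#'
#' Sums \code{u(type_i, type_j, bin(d))} over all cross protein/DNA typed
#' atom pairs with distance below the cutoff; pairs at or beyond the
#' cutoff contribute exactly zero.  Negative totals indicate predicted
#' binding affinity.
#'
#' @param model a \code{\link{complex_structure}} or
#'   \code{\link{build_model}} result.
#' @param pot a fitted \code{dna_potential}.
#' @param per_residue also return the per-residue energy decomposition.
#' @return object of class \code{energy_result}: \code{total} (eta*kT),
#'   \code{n_pairs_scored}, optional \code{per_residue} named vector
#'   summing exactly to \code{total}.
#' @export
score_complex <- function(model, pot, per_residue = FALSE) {
  if (inherits(model, "threaded_model")) model <- model$structure
  stopifnot(inherits(model, "complex_structure"),
            inherits(pot, "dna_potential"))
  if (nrow(model$dna) == 0L)
    stop("model has no DNA: cannot score binding")
  ty <- assign_types(model, pot$scheme)
  if (nrow(ty$protein) == 0L) stop("model has no typed protein atoms")
  dm <- .cross_dist(as.matrix(ty$protein[, c("x", "y", "z")]),
                    as.matrix(ty$dna[, c("x", "y", "z")]))
  bin <- floor(dm / pot$binning$width) + 1L
  np <- length(pot$scheme$protein_types)
  nd <- length(pot$scheme$dna_types)
  within <- which(bin <= pot$binning$n_bins)
  rowidx <- (within - 1L) %% nrow(dm) + 1L
  i <- ty$protein$type[rowidx]
  j <- ty$dna$type[(within - 1L) %/% nrow(dm) + 1L]
  e <- pot$u[cbind(i, j, bin[within])]
  res <- list(total = sum(e), n_pairs_scored = length(within))
  if (per_residue) {
    pr <- tapply(e, factor(ty$protein$key[rowidx],
                           levels = unique(ty$protein$key)), sum)
    pr[is.na(pr)] <- 0
    res$per_residue <- pr
  }
  structure(res, class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("binding energy %.3f (eta*kT) over %d pairs\n",
              x$total, x$n_pairs_scored))
  invisible(x)
}

#' @rdname score_complex
#' @param object a fitted \code{dna_potential}.
#' @param newdata the complex model to score.
#' @param ... passed on (\code{per_residue}).
#' @export
predict.dna_potential <- function(object, newdata, ...) {
  score_complex(newdata, object, ...)
}

#' Plot energy curves of a fitted potential
#'
#' Draws \code{u(r)} against the bin midpoints for the most populated
#' (protein type, DNA type) pairs.
#'
#' @param x a \code{dna_potential}.
#' @param n_pairs number of type pairs to draw.
#' @param ... passed to \code{matplot}.
#' @export
plot.dna_potential <- function(x, n_pairs = 6, ...) {
  total <- apply(x$counts, c(1, 2), sum)
  ord <- order(total, decreasing = TRUE)[seq_len(min(n_pairs, sum(total > 0)))]
  np <- dim(total)[1]
  curves <- sapply(ord, function(k)
    x$u[(k - 1L) %% np + 1L, (k - 1L) %/% np + 1L, ])
  lab <- sapply(ord, function(k)
    paste(x$scheme$protein_types[(k - 1L) %% np + 1L],
          x$scheme$dna_types[(k - 1L) %/% np + 1L], sep = "-"))
  graphics::matplot(x$binning$mids, curves, type = "l", lty = 1,
                    xlab = "r (Angstrom)", ylab = "u(r) (eta*kT)", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = lab, lty = 1,
                   col = seq_along(ord), cex = 0.7, bty = "n")
  invisible(x)
}

#' Serialize a fitted potential to versioned plain text
#'
#' The artifact stores the scheme, binning, reference-state parameters and
#' the raw counts; energies are re-derived from the counts on load and
#' verified against a stored checksum.
#'
#' @param pot a \code{dna_potential}.
#' @param path file path; when NULL the text lines are returned.
#' @return the text lines, invisibly when written to \code{path}.
#' @export
save_potential <- function(pot, path = NULL) {
  nz <- which(pot$counts != 0)
  np <- dim(pot$counts)[1]; nd <- dim(pot$counts)[2]
  i <- (nz - 1L) %% np + 1L
  j <- ((nz - 1L) %/% np) %% nd + 1L
  b <- (nz - 1L) %/% (np * nd) + 1L
  hdr <- c("# dnathread potential v1",
           sprintf("alpha\t%.17g", pot$alpha),
           sprintf("eta\t%.17g", pot$eta),
           sprintf("width\t%.17g", pot$binning$width),
           sprintf("r_cut\t%.17g", pot$binning$r_cut),
           sprintf("pseudo_count\t%.17g", pot$pseudo_count),
           sprintf("min_pair_total\t%.17g", pot$min_pair_total),
           sprintf("include_cb\t%d", as.integer(pot$scheme$include_cb)),
           sprintf("n_structures\t%d", pot$n_structures),
           sprintf("u_checksum\t%.17g", sum(abs(pot$u))),
           "# i\tj\tbin\tcount")
  body <- sprintf("%s\t%s\t%d\t%.17g", pot$scheme$protein_types[i],
                  pot$scheme$dna_types[j], b, pot$counts[nz])
  txt <- c(hdr, body)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Load a potential saved by \code{\link{save_potential}}
#' @param x file path or character vector of artifact lines.
#' @return a \code{dna_potential}.
#' @export
load_potential <- function(x) {
  txt <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  if (length(txt) < 11L || txt[1] != "# dnathread potential v1")
    stop("not a dnathread potential artifact (version mismatch)")
  kv <- strsplit(txt[2:10], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  scheme <- atom_type_scheme(include_cb = as.integer(vals["include_cb"]) == 1L)
  binning <- distance_binning(as.numeric(vals["width"]),
                              as.numeric(vals["r_cut"]))
  body <- txt[-seq_len(11L)]
  counts <- array(0, dim = c(length(scheme$protein_types),
                             length(scheme$dna_types), binning$n_bins),
                  dimnames = list(scheme$protein_types, scheme$dna_types,
                                  NULL))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 4L)) stop("corrupted potential table")
    i <- match(vapply(parts, `[`, character(1), 1), scheme$protein_types)
    j <- match(vapply(parts, `[`, character(1), 2), scheme$dna_types)
    b <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
    n <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4)))
    if (anyNA(i) || anyNA(j) || anyNA(b) || anyNA(n) ||
        any(b < 1L) || any(b > binning$n_bins))
      stop("corrupted potential table")
    counts[cbind(i, j, b)] <- n
  }
  pot <- potential_from_counts(counts, scheme, binning,
                               alpha = as.numeric(vals["alpha"]),
                               eta = as.numeric(vals["eta"]),
                               pseudo_count = as.numeric(vals["pseudo_count"]),
                               min_pair_total = as.numeric(vals["min_pair_total"]),
                               n_structures = as.integer(vals["n_structures"]))
  if (abs(sum(abs(pot$u)) - as.numeric(vals["u_checksum"])) > 1e-6)
    stop("corrupted potential table: energy checksum mismatch")
  pot
}
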