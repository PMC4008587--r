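# Protein-DNA complex structures: parsing, writing, interface geometry.

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_123 <- structure(names(AA_321), names = unname(AA_321))

## Heavy-atom name sets of the four deoxyribonucleotide bases.  C5M is the
## legacy spelling of the thymine methyl carbon C7.
BASE_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6", "O6", "N2", "N7", "C8", "N9"),
  C = c("N1", "C2", "O2", "N3", "N4", "C4", "C5", "C6"),
  T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C5M", "C6"))

DNA_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
                        "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
                        "O2'", "C1'")

PURINES <- c("A", "G")
WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

#' Construct a protein-DNA complex structure
#'
#' The container used throughout the package: flat atom tables for the
#' protein and DNA components of one complex.  Protein rows carry the
#' residue identity (chain, author residue number, insertion code, amino
#' acid); DNA rows additionally carry a \code{base_atom} flag marking heavy
#' atoms that belong to the nucleobase (as opposed to the sugar-phosphate
#' backbone).  That flag is the atom set the binding-residue distance rule
#' operates on.
#'
#' @param id structure identifier (e.g. a PDB id plus chain suffix).
#' @param protein data.frame with columns chain, resno, icode, resid
#'   (3-letter), aa (1-letter), elety (atom name), elesy (element), x, y, z.
#' @param dna data.frame with columns chain, resno, icode, base (one of
#'   A/C/G/T), elety, elesy, base_atom (logical), x, y, z.  May have zero
#'   rows (apo/negative inputs).
#' @param resolution crystallographic resolution in Angstrom, or NA.
#' @return an object of class \code{complex_structure}.
#' @export
complex_structure <- function(id, protein, dna = NULL, resolution = NA_real_) {
  if (is.null(dna)) {
    dna <- data.frame(chain = character(), resno = integer(),
                      icode = character(), base = character(),
                      elety = character(), elesy = character(),
                      base_atom = logical(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(protein) == 0L) stop("no protein content")
  stopifnot(all(is.finite(protein$x)), all(is.finite(protein$y)),
            all(is.finite(protein$z)))
  if (nrow(dna) > 0L) {
    stopifnot(all(dna$base %in% names(WC_COMPLEMENT)),
              all(is.finite(dna$x)))
  }
  structure(list(id = id, protein = protein, dna = dna,
                 resolution = resolution),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  pres <- protein_residues(x)
  nnt <- if (nrow(x$dna)) length(unique(res_key(x$dna$chain, x$dna$resno,
                                                x$dna$icode))) else 0L
  cat(sprintf(
    "complex_structure '%s': %d protein residues (%d chains), %d nucleotides (%d chains)%s\n",
    x$id, nrow(pres), length(unique(pres$chain)), nnt,
    length(unique(x$dna$chain)),
    if (is.na(x$resolution)) "" else sprintf(", %.2f A", x$resolution)))
  invisible(x)
}

#' Unique protein residues of a complex, in file order
#'
#' @param c a \code{complex_structure}.
#' @return data.frame with one row per residue: chain, resno, icode, resid,
#'   aa and the composite residue key.
#' @export
protein_residues <- function(c) {
  p <- c$protein
  key <- res_key(p$chain, p$resno, p$icode)
  first <- !duplicated(key)
  data.frame(chain = p$chain[first], resno = p$resno[first],
             icode = p$icode[first], resid = p$resid[first],
             aa = p$aa[first], key = key[first], stringsAsFactors = FALSE)
}

#' One-letter protein sequence of a complex
#'
#' Residues are concatenated per chain in file order; chain boundaries are
#' recorded in the \code{"chain_lengths"} attribute.
#'
#' @param c a \code{complex_structure}.
#' @return single character string with attribute \code{chain_lengths}.
#' @export
protein_sequence <- function(c) {
  pres <- protein_residues(c)
  seq <- paste(pres$aa, collapse = "")
  attr(seq, "chain_lengths") <- table(factor(pres$chain,
                                             levels = unique(pres$chain)))
  seq
}

.is_heavy <- function(elesy, elety) {
  ele <- toupper(elesy)
  blank <- is.na(ele) | ele == ""
  if (any(blank)) {
    ## fall back on the first alphabetic character of the atom name
    guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", elety[blank]))
    ele[blank] <- guess
  }
  !(ele %in% c("H", "D"))
}

.parse_remark2 <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  tail <- substring(rl[1], 23)
  m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' Read a protein-DNA complex from PDB-format text
#'
#' Standard amino acids become protein residues and standard
#' deoxyribonucleotides (DA/DC/DG/DT, plus legacy one-letter residue names
#' on chains bearing sugar atoms) become nucleotides.  Waters, ions, other
#' heteroatoms, hydrogens and alternate locations other than the first are
#' dropped; MODEL blocks beyond the first are ignored; RNA chains
#' (O2'-bearing sugars) are dropped with a warning.  Resolution is read
#' from REMARK 2 when present.
#'
#' @param pdb_text character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @param id identifier to attach to the structure.
#' @return a \code{complex_structure}.
#' @export
read_structure <- function(pdb_text, id = "struct") {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  ## first MODEL only
  endm <- grep("^ENDMDL", pdb_text)
  if (length(endm)) pdb_text <- pdb_text[seq_len(endm[1] - 1L)]
  resolution <- .parse_remark2(pdb_text)

  ## pre-scan: coordinate records must be long enough and carry numeric
  ## coordinates; bio3d silently mangles such lines, so reject them here
  ## with the offending line number.
  is_coord <- grepl("^(ATOM  |HETATM)", pdb_text)
  for (i in which(is_coord)) {
    ln <- pdb_text[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop(sprintf("unparseable coordinate record at line %d", i))
  }
  if (!any(is_coord)) stop("no protein content")

  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  writeLines(pdb_text, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, verbose = FALSE))
  at <- pdb$atom
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$elesy <- ifelse(is.na(at$elesy), "", at$elesy)

  ## keep-first for any residual duplicated alternate locations
  at <- at[!duplicated(paste(at$chain, at$resno, at$icode, at$resid,
                             at$elety)), , drop = FALSE]
  at <- at[.is_heavy(at$elesy, at$elety), , drop = FALSE]

  ## RNA chains are out of scope: drop whole chains bearing O2'
  rna_chains <- unique(at$chain[at$elety == "O2'" &
                                !(at$resid %in% names(AA_321))])
  if (length(rna_chains)) {
    warning(sprintf("dropping RNA chain(s) %s (O2'-bearing sugars)",
                    paste(rna_chains, collapse = ",")))
    at <- at[!(at$chain %in% rna_chains), , drop = FALSE]
  }

  is_aa <- at$resid %in% names(AA_321)
  is_dna_std <- at$resid %in% c("DA", "DC", "DG", "DT")
  ## legacy one-letter nucleotide names count only on chains with sugar atoms
  sugar_chains <- unique(at$chain[at$elety %in% c("C1'", "O4'")])
  is_dna_legacy <- at$resid %in% c("A", "C", "G", "T") &
    at$chain %in% sugar_chains
  is_dna <- (is_dna_std | is_dna_legacy) & !is_aa

  prot <- at[is_aa, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein content")
  protein <- data.frame(chain = prot$chain, resno = prot$resno,
                        icode = prot$icode, resid = prot$resid,
                        aa = unname(AA_321[prot$resid]),
                        elety = prot$elety, elesy = toupper(prot$elesy),
                        x = prot$x, y = prot$y, z = prot$z,
                        stringsAsFactors = FALSE)

  nt <- at[is_dna, , drop = FALSE]
  if (nrow(nt)) {
    base <- ifelse(nchar(nt$resid) == 2L, substring(nt$resid, 2L), nt$resid)
    name <- nt$elety
    dna <- data.frame(chain = nt$chain, resno = nt$resno, icode = nt$icode,
                      base = base, elety = name,
                      elesy = toupper(nt$elesy),
                      base_atom = mapply(function(b, n)
                        n %in% BASE_ATOMS[[b]], base, name,
                        USE.NAMES = FALSE),
                      x = nt$x, y = nt$y, z = nt$z,
                      stringsAsFactors = FALSE)
  } else dna <- NULL

  complex_structure(id, protein, dna, resolution)
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, icode,
                           x, y, z, elesy) {
  namef <- if (nchar(name) >= 4L) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, resname, chain, resno,
          ifelse(icode == "", " ", icode), x, y, z, 1, 0, elesy)
}

#' Write a complex structure as PDB-format text
#'
#' Emits fixed-column ATOM records, protein chains first, then DNA, with
#' TER records between chains; byte output is deterministic for equal
#' inputs.  A REMARK 2 resolution record is written when the structure
#' carries a resolution.
#'
#' @param c a \code{complex_structure}.
#' @return character vector of PDB lines.
#' @export
write_structure <- function(c) {
  out <- character()
  if (!is.na(c$resolution))
    out <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", c$resolution)
  serial <- 0L
  emit_chain <- function(df, resname_fun) {
    lines <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      serial <<- serial + 1L
      lines[i] <- .pdb_atom_line(serial, df$elety[i], resname_fun(df, i),
                                 df$chain[i], df$resno[i], df$icode[i],
                                 df$x[i], df$y[i], df$z[i], df$elesy[i])
    }
    serial <<- serial + 1L
    c(lines, sprintf("TER   %5d", serial))
  }
  for (ch in unique(c$protein$chain)) {
    sub <- c$protein[c$protein$chain == ch, , drop = FALSE]
    out <- c(out, emit_chain(sub, function(df, i) df$resid[i]))
  }
  if (nrow(c$dna)) {
    for (ch in unique(c$dna$chain)) {
      sub <- c$dna[c$dna$chain == ch, , drop = FALSE]
      out <- c(out, emit_chain(sub, function(df, i)
        sprintf(" D%s", df$base[i])))
    }
  }
  c(out, "END")
}

.cross_dist <- function(A, B) {
  ## Euclidean distances between rows of two n x 3 matrices
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' DNA-contacting residues of a complex
#'
#' A residue is reported iff the minimum distance between any of its heavy
#' atoms and any heavy atom of a DNA base is strictly below \code{cutoff}.
#' DNA backbone atoms do not count unless \code{contact_atoms = "all_dna"}.
#'
#' @param c a \code{complex_structure}.
#' @param cutoff contact distance in Angstrom (strict \code{<}).
#' @param contact_atoms \code{"base"} (default) restricts the DNA side to
#'   nucleobase heavy atoms; \code{"all_dna"} includes the backbone.
#' @return data.frame with columns chain, resno, icode, key, min_dist; zero
#'   rows when there is no DNA or no contact.
#' @export
interface_residues <- function(c, cutoff = 4.5,
                               contact_atoms = c("base", "all_dna")) {
  stopifnot(cutoff > 0)
  contact_atoms <- match.arg(contact_atoms)
  empty <- data.frame(chain = character(), resno = integer(),
                      icode = character(), key = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  dna <- c$dna
  if (contact_atoms == "base") dna <- dna[dna$base_atom, , drop = FALSE]
  if (nrow(dna) == 0L || nrow(c$protein) == 0L) return(empty)
  P <- as.matrix(c$protein[, c("x", "y", "z")])
  D <- as.matrix(dna[, c("x", "y", "z")])
  dmin <- apply(.cross_dist(P, D), 1L, min)
  key <- res_key(c$protein$chain, c$protein$resno, c$protein$icode)
  per_res <- tapply(dmin, factor(key, levels = unique(key)), min)
  hit <- per_res < cutoff
  if (!any(hit)) return(empty)
  pres <- protein_residues(c)
  keep <- pres[match(names(per_res)[hit], pres$key), , drop = FALSE]
  data.frame(chain = keep$chain, resno = keep$resno, icode = keep$icode,
             key = keep$key, min_dist = unname(per_res[hit]),
             stringsAsFactors = FALSE)
}

#' Count Watson-Crick base pairs in a complex
#'
#' Two nucleotides form a pair when they lie on distinct chains, their
#' bases are complementary (A-T, G-C) and their glycosidic-face atoms (N1
#' of a purine, N3 of a pyrimidine) are within \code{pair_dist}.  Pairs are
#' assigned greedily by ascending distance; each nucleotide participates in
#' at most one pair.
#'
#' @param c a \code{complex_structure}.
#' @param pair_dist maximum face-atom separation in Angstrom.
#' @return integer pair count.
#' @export
count_base_pairs <- function(c, pair_dist = 3.5) {
  dna <- c$dna
  if (nrow(dna) == 0L) return(0L)
  face_name <- ifelse(dna$base %in% PURINES, "N1", "N3")
  face <- dna[dna$elety == face_name, , drop = FALSE]
  if (nrow(face) < 2L) return(0L)
  D <- as.matrix(face[, c("x", "y", "z")])
  dm <- .cross_dist(D, D)
  cand <- which(upper.tri(dm) & dm < pair_dist, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0L)
  ok <- face$chain[cand[, 1]] != face$chain[cand[, 2]] &
    WC_COMPLEMENT[face$base[cand[, 1]]] == face$base[cand[, 2]]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used <- rep(FALSE, nrow(face))
  n <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used[i] && !used[j]) { used[i] <- used[j] <- TRUE; n <- n + 1L }
  }
  n
}
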