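# Deterministic synthetic protein-DNA fixtures: idealized B-form DNA
# duplexes, alpha-helical binders, rigid decoys and labeled mini-benchmarks.
# Geometry is idealized, not chemistry: every consumer rule in the package
# keys on atom names, base/backbone flags and distances, and those are what
# the generator calibrates.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' fixture generation never perturbs surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## local (x, y) layouts of nucleotide heavy atoms in the base-pair frame;
## +x points from the helix axis toward the strand-1 attachment.  The
## Watson-Crick face atom (N1 purine / N3 pyrimidine) sits at x = 1.45 so
## paired faces are 2.9 A apart; C1' sits at radius ~9.56 so consecutive
## C1' atoms on a strand are ~6.8 A apart under the 36 deg / 3.38 A rise.
.NT_BASE_XY <- list(
  A = rbind(N1 = c(1.45, 0), C2 = c(2.15, -1.10), N3 = c(3.45, -1.25),
            C4 = c(4.15, -0.10), C5 = c(3.55, 1.15), C6 = c(2.15, 1.20),
            N6 = c(1.45, 2.40), N7 = c(4.55, 2.20), C8 = c(5.75, 1.60),
            N9 = c(5.65, 0.25)),
  G = rbind(N1 = c(1.45, 0), C2 = c(2.15, -1.10), N3 = c(3.45, -1.25),
            C4 = c(4.15, -0.10), C5 = c(3.55, 1.15), C6 = c(2.15, 1.20),
            O6 = c(1.45, 2.40), N2 = c(1.50, -2.30), N7 = c(4.55, 2.20),
            C8 = c(5.75, 1.60), N9 = c(5.65, 0.25)),
  C = rbind(N3 = c(1.45, 0), C2 = c(2.15, -1.15), O2 = c(1.55, -2.25),
            N1 = c(3.55, -1.20), C6 = c(4.25, -0.05), C5 = c(3.60, 1.15),
            C4 = c(2.20, 1.20), N4 = c(1.50, 2.40)),
  T = rbind(N3 = c(1.45, 0), C2 = c(2.15, -1.15), O2 = c(1.55, -2.25),
            N1 = c(3.55, -1.20), C6 = c(4.25, -0.05), C5 = c(3.60, 1.15),
            C4 = c(2.20, 1.20), O4 = c(1.50, 2.40), C7 = c(4.30, 2.35)))

.NT_BACKBONE_XY <- rbind(
  "C1'" = c(9.55, 0.50), "O4'" = c(10.20, 1.60), "C3'" = c(11.20, 0.40),
  "O3'" = c(11.90, -0.60), "C4'" = c(11.00, 1.80), "C5'" = c(11.40, 3.00),
  "O5'" = c(10.60, 4.00), "P" = c(11.00, 5.30))

.BDNA_RISE <- 3.38
.BDNA_TWIST <- 36 * pi / 180

.nt_atoms <- function(base, theta, z, mirror) {
  xy <- rbind(.NT_BASE_XY[[base]], .NT_BACKBONE_XY)
  if (mirror) xy <- -xy
  ct <- cos(theta); st <- sin(theta)
  data.frame(elety = rownames(xy),
             elesy = toupper(substr(rownames(xy), 1, 1)),
             base_atom = rownames(xy) %in% rownames(.NT_BASE_XY[[base]]),
             x = xy[, 1] * ct - xy[, 2] * st,
             y = xy[, 1] * st + xy[, 2] * ct,
             z = z, row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate an idealized B-form DNA duplex
#'
#' Builds a two-chain duplex with 3.38 Angstrom rise and 36 degree twist
#' per step, a random complementary sequence drawn from \code{seed}, and a
#' reduced but validly named heavy-atom set per nucleotide.  Watson-Crick
#' partners' glycosidic-face atoms are placed 2.9 Angstrom apart, so
#' \code{\link{count_base_pairs}} recovers exactly \code{n_bp} pairs.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param seed integer RNG seed; equal seeds give byte-identical output.
#' @param chains chain identifiers for the two strands.
#' @return DNA atom data.frame in the \code{\link{complex_structure}} layout.
#' @export
make_bdna <- function(n_bp, seed = 1, chains = c("D", "E")) {
  stopifnot(n_bp >= 1)
  seq1 <- with_seed(seed, sample(names(WC_COMPLEMENT), n_bp, replace = TRUE))
  seq2 <- unname(WC_COMPLEMENT[seq1])
  s1 <- do.call(rbind, lapply(seq_len(n_bp), function(i) {
    df <- .nt_atoms(seq1[i], (i - 1) * .BDNA_TWIST, (i - 1) * .BDNA_RISE,
                    mirror = FALSE)
    cbind(chain = chains[1], resno = i, icode = "", base = seq1[i], df,
          stringsAsFactors = FALSE)
  }))
  ## complementary strand runs antiparallel: list it 3' -> 5' reversed so
  ## its residue numbering ascends along its own 5' -> 3' direction
  s2 <- do.call(rbind, lapply(rev(seq_len(n_bp)), function(i) {
    df <- .nt_atoms(seq2[i], (i - 1) * .BDNA_TWIST, (i - 1) * .BDNA_RISE,
                    mirror = TRUE)
    cbind(chain = chains[2], resno = n_bp - i + 1L, icode = "",
          base = seq2[i], df, stringsAsFactors = FALSE)
  }))
  rbind(s1, s2)[, c("chain", "resno", "icode", "base", "elety", "elesy",
                    "base_atom", "x", "y", "z")]
}

## backbone atom placement of one idealized alpha-helix residue:
## radius / phase offset (deg) / z offset relative to the CA position
.HELIX_ATOMS <- rbind(N = c(1.8, -28, -0.9), CA = c(2.3, 0, 0),
                      C = c(2.0, 28, 0.5), O = c(2.6, 35, 1.4),
                      CB = c(3.3, -5, 0.2))
.HELIX_RISE <- 1.5
.HELIX_TWIST <- 100 * pi / 180

#' Generate an idealized protein-DNA complex
#'
#' An alpha-helical protein backbone (1.5 Angstrom rise, 100 degrees per
#' residue; N/CA/C/O plus CB for non-glycine) is laid parallel to an ideal
#' B-DNA duplex axis at a lateral \code{offset}, z-centred on the DNA.
#' Smaller offsets yield more residues within contact distance of base
#' atoms; offsets of ~8-9 Angstrom give a realistic interface (>= 5
#' residues for proteins of >= 40 residues), while large offsets give
#' none.
#'
#' @param n_res protein length in residues.
#' @param n_bp DNA length in base pairs; 0 gives a protein-only structure.
#' @param offset lateral distance between helix axis and DNA axis, Angstrom.
#' @param seed integer RNG seed (protein and DNA sequences).
#' @param id structure id.
#' @param resolution nominal resolution metadata, Angstrom.
#' @param sequence optional explicit 1-letter protein sequence overriding
#'   the random one (length must equal \code{n_res}).
#' @return a \code{\link{complex_structure}}.
#' @export
make_complex <- function(n_res, n_bp = 8, offset = 8, seed = 1,
                         id = sprintf("syn%04d", seed), resolution = 2.0,
                         sequence = NULL) {
  stopifnot(n_res >= 1)
  if (is.null(sequence)) {
    sequence <- with_seed(seed + 1L,
                          paste(sample(names(AA_123), n_res, replace = TRUE),
                                collapse = ""))
  }
  stopifnot(nchar(sequence) == n_res)
  aa <- strsplit(sequence, "")[[1]]
  dna <- if (n_bp >= 1) make_bdna(n_bp, seed = seed) else NULL
  z_mid <- if (n_bp >= 1) (n_bp - 1) * .BDNA_RISE / 2 else 0
  z0 <- z_mid - (n_res - 1) * .HELIX_RISE / 2

  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * .HELIX_TWIST
    zc <- z0 + (i - 1) * .HELIX_RISE
    names_i <- if (aa[i] == "G") c("N", "CA", "C", "O") else rownames(.HELIX_ATOMS)
    g <- .HELIX_ATOMS[names_i, , drop = FALSE]
    ang <- phi + g[, 2] * pi / 180
    rows[[i]] <- data.frame(
      chain = "A", resno = i, icode = "", resid = unname(AA_123[aa[i]]),
      aa = aa[i], elety = names_i,
      elesy = substr(names_i, 1, 1),
      x = offset + g[, 1] * cos(ang), y = g[, 1] * sin(ang),
      z = zc + g[, 3], row.names = NULL, stringsAsFactors = FALSE)
  }
  complex_structure(id, do.call(rbind, rows), dna, resolution)
}

#' Displace the DNA of a complex rigidly (decoy generation)
#'
#' The DNA component is translated as a rigid body by \code{displacement}
#' Angstrom along a seeded random direction; the protein is untouched.
#'
#' @param c a \code{\link{complex_structure}} with DNA.
#' @param displacement translation magnitude, Angstrom (>= 0).
#' @param seed integer RNG seed for the direction.
#' @return the displaced \code{complex_structure}.
#' @export
make_decoy <- function(c, displacement, seed = 1) {
  stopifnot(displacement >= 0)
  if (displacement == 0) return(c)
  u <- with_seed(seed, stats::rnorm(3))
  u <- u / sqrt(sum(u^2)) * displacement
  c$dna$x <- c$dna$x + u[1]
  c$dna$y <- c$dna$y + u[2]
  c$dna$z <- c$dna$z + u[3]
  c$id <- paste0(c$id, "_decoy")
  c
}

.mutate_sequence <- function(seq, identity, seed) {
  ## keep exactly round(identity * L) positions, substitute the rest with a
  ## different residue
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  with_seed(seed, {
    keep <- sample(L, round(identity * L))
    for (i in setdiff(seq_len(L), keep)) {
      aa[i] <- sample(setdiff(names(AA_123), aa[i]), 1)
    }
  })
  paste(aa, collapse = "")
}

.shuffle_sequence <- function(seq, seed) {
  aa <- strsplit(seq, "")[[1]]
  paste(with_seed(seed, sample(aa)), collapse = "")
}

#' Generate a labeled synthetic benchmark
#'
#' Builds a mini template library of protein-DNA complexes arranged in
#' sequence-identity clusters (realized by seeded point mutation, so
#' planned identities are hit to within a few percentage points), plus
#' protein-only negatives with shuffled sequences.  Positives double as
#' templates; their DNA-contacting residues are recorded as ground truth.
#' The object drives \code{\link{leave_one_out}} end to end with no
#' external data.
#'
#' @param seed integer RNG seed.
#' @param n_clusters number of positive sequence clusters.
#' @param cluster_size positives per cluster.
#' @param homolog_identity planned within-cluster sequence identity.
#' @param n_negatives number of shuffled-sequence negatives.
#' @param n_res protein length of every entry.
#' @param n_bp DNA length of every positive.
#' @param offset protein-DNA axis offset of every positive, Angstrom.
#' @param contact_cutoff interface cutoff used for the truth sets, Angstrom.
#' @return list of class \code{dt_benchmark}: \code{library} (list of
#'   \code{\link{template_entry}}), \code{queries} (data.frame id /
#'   sequence / label), \code{truth} (named list of interface key sets),
#'   \code{structures} (named list of positive structures).
#' @export
make_benchmark <- function(seed = 1, n_clusters = 6, cluster_size = 2,
                           homolog_identity = 0.25, n_negatives = 30,
                           n_res = 200, n_bp = 10, offset = 8,
                           contact_cutoff = 4.5) {
  structures <- list()
  k <- 0L
  for (cl in seq_len(n_clusters)) {
    base_seed <- seed * 1000L + cl * 10L
    base_seq <- with_seed(base_seed,
                          paste(sample(names(AA_123), n_res, replace = TRUE),
                                collapse = ""))
    for (m in seq_len(cluster_size)) {
      k <- k + 1L
      sq <- if (m == 1L) base_seq else
        .mutate_sequence(base_seq, homolog_identity, base_seed + m)
      id <- sprintf("pos%02d", k)
      structures[[id]] <- make_complex(n_res, n_bp = n_bp, offset = offset,
                                       seed = base_seed + m, id = id,
                                       sequence = sq)
    }
  }
  lib <- lapply(structures, template_entry, contact_cutoff = contact_cutoff)
  truth <- lapply(lib, function(e) e$interface)
  pos_ids <- names(structures)
  neg <- data.frame(id = sprintf("neg%02d", seq_len(n_negatives)),
                    sequence = vapply(seq_len(n_negatives), function(i) {
                      src <- structures[[pos_ids[(i - 1L) %% length(pos_ids) + 1L]]]
                      .shuffle_sequence(protein_sequence(src),
                                        seed * 2000L + i)
                    }, character(1)),
                    label = FALSE, stringsAsFactors = FALSE)
  pos <- data.frame(id = pos_ids,
                    sequence = vapply(structures, function(s)
                      as.character(protein_sequence(s)), character(1)),
                    label = TRUE, stringsAsFactors = FALSE)
  structure(list(library = lib, queries = rbind(pos, neg), truth = truth,
                 structures = structures,
                 params = list(seed = seed, n_clusters = n_clusters,
                               cluster_size = cluster_size,
                               homolog_identity = homolog_identity,
                               n_res = n_res, n_bp = n_bp, offset = offset)),
            class = "dt_benchmark")
}

#' Fixture set with planted template-library filter violations
#'
#' Ten synthetic complexes: five clean entries of which two are mutually
#' redundant (~95% sequence identity), plus one violator of each library
#' quality rule (resolution worse than 3 Angstrom; protein shorter than 40
#' residues; fewer than 6 base pairs; fewer than 5 DNA-contacting
#' residues).  Under the default \code{\link{library_filter_config}} exactly
#' five entries survive \code{\link{build_library}}.
#'
#' @param seed integer RNG seed.
#' @return named list of \code{\link{complex_structure}} objects with a
#'   \code{"plan"} attribute naming the planted fate of each entry.
#' @export
make_filter_demo <- function(seed = 1) {
  s <- seed * 100L
  out <- list(
    ok1 = make_complex(50, seed = s + 1, id = "ok1"),
    ok2 = make_complex(55, seed = s + 2, id = "ok2"),
    ok3 = make_complex(60, seed = s + 3, id = "ok3"),
    ok4 = make_complex(52, seed = s + 4, id = "ok4"),
    ok5 = make_complex(58, seed = s + 5, id = "ok5"),
    redundant = NULL,
    bad_resolution = make_complex(50, seed = s + 6, id = "bad_resolution",
                                  resolution = 3.5),
    too_short = make_complex(39, seed = s + 7, id = "too_short"),
    few_bp = make_complex(50, n_bp = 4, seed = s + 8, id = "few_bp"),
    no_interface = make_complex(50, offset = 30, seed = s + 9,
                                id = "no_interface"))
  ## redundant twin of ok1: same length, ~95% identical sequence
  twin_seq <- .mutate_sequence(protein_sequence(out$ok1), 0.95, s + 10)
  out$redundant <- make_complex(50, seed = s + 11, id = "redundant",
                                sequence = twin_seq)
  attr(out, "plan") <- c(ok1 = "keep", ok2 = "keep", ok3 = "keep",
                         ok4 = "keep", ok5 = "keep",
                         redundant = "redundant-with-ok1",
                         bad_resolution = "max_resolution",
                         too_short = "min_protein_length",
                         few_bp = "min_base_pairs",
                         no_interface = "min_interface_residues")
  out
}
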