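# Independent brute-force oracles and tiny fixture builders shared by the
# test files.  The oracles deliberately use naive double loops and direct
# formula evaluation, independent of the package's vectorized paths.

## all-pairs double loop over residue heavy atoms x DNA base heavy atoms
oracle_interface <- function(cx, cutoff = 4.5) {
  dna <- cx$dna[cx$dna$base_atom, , drop = FALSE]
  if (nrow(dna) == 0L) return(character())
  p <- cx$protein
  keys <- unique(dnathread:::res_key(p$chain, p$resno, p$icode))
  hit <- character()
  for (k in keys) {
    rows <- p[dnathread:::res_key(p$chain, p$resno, p$icode) == k, ,
              drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(rows))) {
      for (j in seq_len(nrow(dna))) {
        d <- sqrt((rows$x[i] - dna$x[j])^2 + (rows$y[i] - dna$y[j])^2 +
                  (rows$z[i] - dna$z[j])^2)
        if (d < cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, k)
  }
  hit
}

## double loop over typed atoms, direct table lookup
oracle_score <- function(cx, pot) {
  ty <- assign_types(cx, pot$scheme)
  total <- 0; n <- 0L
  for (i in seq_len(nrow(ty$protein))) {
    for (j in seq_len(nrow(ty$dna))) {
      d <- sqrt((ty$protein$x[i] - ty$dna$x[j])^2 +
                (ty$protein$y[i] - ty$dna$y[j])^2 +
                (ty$protein$z[i] - ty$dna$z[j])^2)
      if (d < pot$binning$r_cut) {
        b <- floor(d / pot$binning$width) + 1L
        total <- total + pot$u[ty$protein$type[i], ty$dna$type[j], b]
        n <- n + 1L
      }
    }
  }
  list(total = total, n = n)
}

## direct formula evaluation of the reference-state energies, bin by bin
oracle_potential_u <- function(counts, binning, alpha, eta, pseudo_count,
                               min_pair_total) {
  nb <- binning$n_bins
  r_ref <- binning$mids[nb]
  u <- array(0, dim = dim(counts))
  for (i in seq_len(dim(counts)[1])) {
    for (j in seq_len(dim(counts)[2])) {
      if (sum(counts[i, j, ]) < min_pair_total) next
      for (k in seq_len(nb)) {
        u[i, j, k] <- -eta * log((counts[i, j, k] + pseudo_count) /
          ((binning$mids[k] / r_ref)^alpha * (counts[i, j, nb] + pseudo_count)))
      }
    }
  }
  u
}

## spreadsheet-style metric formulas
oracle_metrics <- function(tp, tn, fp, fn) {
  list(sn = tp / (tp + fn), pr = tp / (tp + fp), sp = tn / (tn + fp),
       acc = (tp + tn) / (tp + tn + fp + fn),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

## exhaustive scan over the candidate grid with a scalar MCC loop
oracle_optimize <- function(records) {
  prob <- ifelse(is.na(records$probability), -Inf, records$probability)
  en <- ifelse(is.na(records$energy), Inf, records$energy)
  lab <- records$label
  best <- list(mcc = -Inf)
  for (p in sort(unique(prob[is.finite(prob)]))) {
    for (e in sort(unique(en[is.finite(en)]))) {
      pred <- prob >= p & en <= e
      tp <- sum(pred & lab); fp <- sum(pred & !lab)
      fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
      better <- mcc > best$mcc ||
        (mcc == best$mcc && (p > best$p ||
                             (p == best$p && e < best$e)))
      if (better) best <- list(mcc = mcc, p = p, e = e)
    }
  }
  best
}

## a random toy complex: a handful of residues and nucleotides scattered
## near each other, exercising the geometry paths without helix regularity
random_toy_complex <- function(seed, n_res = 6, n_nt = 4, spread = 10) {
  with_seed(seed, {
    prot <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      centre <- stats::runif(3, 0, spread)
      nat <- sample(2:4, 1)
      names <- c("N", "CA", "C", "O")[seq_len(nat)]
      data.frame(chain = "A", resno = i, icode = "", resid = "ALA",
                 aa = "A", elety = names, elesy = substr(names, 1, 1),
                 x = centre[1] + stats::rnorm(nat, 0, 1),
                 y = centre[2] + stats::rnorm(nat, 0, 1),
                 z = centre[3] + stats::rnorm(nat, 0, 1),
                 stringsAsFactors = FALSE)
    }))
    base <- sample(c("A", "C", "G", "T"), n_nt, replace = TRUE)
    dna <- do.call(rbind, lapply(seq_len(n_nt), function(i) {
      centre <- stats::runif(3, 0, spread)
      names <- c("P", "C1'", "N1", "C2")
      data.frame(chain = "D", resno = i, icode = "", base = base[i],
                 elety = names, elesy = substr(names, 1, 1),
                 base_atom = names %in% dnathread:::BASE_ATOMS[[base[i]]],
                 x = centre[1] + stats::rnorm(4, 0, 1),
                 y = centre[2] + stats::rnorm(4, 0, 1),
                 z = centre[3] + stats::rnorm(4, 0, 1),
                 stringsAsFactors = FALSE)
    }))
    complex_structure(sprintf("toy%d", seed), prot, dna)
  })
}

minimal_pdb <- function() {
  c("REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  P    DA D   1       5.000   5.000   5.000  1.00  0.00           P",
    "ATOM      6  C1'  DA D   1       6.000   5.000   5.000  1.00  0.00           C",
    "ATOM      7  N9   DA D   1       7.000   5.000   5.000  1.00  0.00           N",
    "ATOM      8  N1   DA D   1       8.500   5.000   5.000  1.00  0.00           N",
    "TER",
    "END")
}

## a minimal single-hit HHR report written by the tests themselves
write_hhr <- function(hits) {
  ## hits: list of list(id, probab, qstart, tstart, qseq, tseq)
  out <- c("Query         testquery", "Match_columns 50", "",
           " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM",
           unlist(lapply(seq_along(hits), function(i)
             sprintf("  %d %-30s %5.1f   1E-10 1E-12  100.0   0.0   10    1-10      1-10  (50)",
                     i, hits[[i]]$id, hits[[i]]$probab))),
           "")
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    out <- c(out,
      sprintf("No %d", i),
      sprintf(">%s some template description", h$id),
      sprintf("Probab=%.2f  E-value=1e-10  Score=100.00  Aligned_cols=%d  Identities=40%%  Similarity=0.7  Sum_probs=9.0",
              h$probab, nchar(gsub("-", "", h$qseq))),
      "",
      sprintf("Q testquery       %2d %s %2d (50)", h$qstart, h$qseq,
              h$qstart + nchar(gsub("-", "", h$qseq)) - 1L),
      sprintf("Q Consensus       %2d %s %2d (50)", h$qstart, h$qseq,
              h$qstart + nchar(gsub("-", "", h$qseq)) - 1L),
      paste0(strrep(" ", 18), strrep("|", nchar(h$qseq))),
      sprintf("T Consensus       %2d %s %2d (60)", h$tstart, h$tseq,
              h$tstart + nchar(gsub("-", "", h$tseq)) - 1L),
      sprintf("T %-15s %2d %s %2d (60)", h$id, h$tstart, h$tseq,
              h$tstart + nchar(gsub("-", "", h$tseq)) - 1L),
      "")
  }
  out
}

random_aa_seq <- function(n, seed) {
  with_seed(seed, paste(sample(names(dnathread:::AA_123), n,
                               replace = TRUE), collapse = ""))
}
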