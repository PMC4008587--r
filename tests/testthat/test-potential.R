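# The distance-scaled finite ideal-gas reference-state potential.

test_that("atom typing: main-chain classes, glycine virtual CB", {
  gly <- make_complex(1, n_bp = 0, seed = 1, sequence = "G",
                      resolution = NA)
  ty <- assign_types(gly)
  expect_equal(nrow(ty$protein), 5L)  # N, CA, C, O + synthesized CB
  cb <- ty$protein[ty$protein$type == 5L, ]
  ca <- ty$protein[ty$protein$type == 2L, ]
  expect_equal(sqrt((cb$x - ca$x)^2 + (cb$y - ca$y)^2 + (cb$z - ca$z)^2),
               1.53, tolerance = 1e-6)
  ## ALA with a full side chain: only the 5 scheme atoms are typed
  ala <- make_complex(1, n_bp = 0, seed = 1, sequence = "A",
                      resolution = NA)
  extra <- ala$protein[1, ]; extra$elety <- "OXT"; extra$elesy <- "O"
  ala$protein <- rbind(ala$protein, extra)
  expect_equal(nrow(assign_types(ala)$protein), 5L)
  ## fixture complex type multiset matches a hand enumeration
  cx <- make_complex(10, n_bp = 4, seed = 2)
  ty <- assign_types(cx)
  n_gly <- sum(protein_residues(cx)$aa == "G")
  expect_equal(nrow(ty$protein), nrow(cx$protein) + n_gly)
  expect_equal(nrow(ty$dna), nrow(cx$dna))  # every fixture DNA atom typed
})

test_that("ideal-gas counts with alpha = 2 train to zero energy", {
  scheme <- atom_type_scheme()
  binning <- distance_binning()
  dims <- c(length(scheme$protein_types), length(scheme$dna_types),
            binning$n_bins)
  counts <- array(0, dim = dims)
  for (k in seq_len(binning$n_bins))
    counts[, , k] <- 2000 * binning$mids[k]^2 * binning$width
  pot <- potential_from_counts(counts, scheme, binning, alpha = 2)
  expect_lt(max(abs(pot$u[counts >= 1e3])), 0.05)
})

test_that("trained energies equal the direct formula, bin by bin", {
  cxs <- lapply(1:20, function(i) make_complex(30, n_bp = 6, seed = 100 + i))
  pot <- train_potential(cxs)
  u_ref <- oracle_potential_u(pot$counts, pot$binning, pot$alpha, pot$eta,
                              pot$pseudo_count, pot$min_pair_total)
  expect_lt(max(abs(unclass(pot$u) - u_ref)), 1e-9)
  ## sparse pairs (total below min_pair_total) score zero
  totals <- apply(pot$counts, c(1, 2), sum)
  if (any(totals > 0 & totals < pot$min_pair_total)) {
    dead <- which(totals > 0 & totals < pot$min_pair_total, arr.ind = TRUE)
    expect_true(all(pot$u[dead[1, 1], dead[1, 2], ] == 0))
  }
  ## ratio form: doubling every count leaves u unchanged up to pseudo-count
  pot2 <- potential_from_counts(pot$counts * 2, pot$scheme, pot$binning,
                                pot$alpha, pot$eta, pot$pseudo_count,
                                pot$min_pair_total)
  big <- pot$counts >= 1e2
  if (any(big)) expect_lt(max(abs(pot$u[big] - pot2$u[big])), 0.01)
})

test_that("scoring matches the brute-force double loop", {
  cxs <- lapply(1:12, function(i) make_complex(25, n_bp = 5, seed = 200 + i))
  pot <- train_potential(cxs)
  for (seed in 1:100) {
    cx <- random_toy_complex(seed, n_res = 5, n_nt = 3, spread = 14)
    got <- score_complex(cx, pot)
    ref <- oracle_score(cx, pot)
    expect_equal(got$total, ref$total, tolerance = 1e-9,
                 label = sprintf("seed %d", seed))
    expect_equal(got$n_pairs_scored, ref$n)
  }
})

test_that("scores are zero beyond the cutoff and rigid-motion invariant", {
  cxs <- lapply(1:10, function(i) make_complex(30, n_bp = 6, seed = 300 + i))
  pot <- train_potential(cxs)
  ## protein far from all DNA: nothing within r_cut
  far <- make_complex(30, n_bp = 6, offset = 40, seed = 311)
  sf <- score_complex(far, pot)
  expect_equal(sf$total, 0)
  expect_equal(sf$n_pairs_scored, 0L)
  ## decoy displaced far beyond any native pair distance scores zero
  cx <- make_complex(30, n_bp = 6, seed = 301)
  expect_equal(score_complex(make_decoy(cx, 90, seed = 5), pot)$total, 0)
  ## rigid rotation + translation of the whole complex
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% R
    df$x <- xyz[, 1] + 3; df$y <- xyz[, 2] - 7; df$z <- xyz[, 3] + 11
    df
  }
  rot <- cx; rot$protein <- move(rot$protein); rot$dna <- move(rot$dna)
  expect_equal(score_complex(rot, pot)$total, score_complex(cx, pot)$total,
               tolerance = 1e-9)
  ## adding DNA atoms beyond r_cut from every protein atom changes nothing
  extra <- cx$dna[1, ]; extra$x <- extra$x + 200
  aug <- cx; aug$dna <- rbind(aug$dna, extra)
  expect_equal(score_complex(aug, pot)$total, score_complex(cx, pot)$total)
})

test_that("per-residue decomposition sums exactly to the total", {
  cxs <- lapply(1:8, function(i) make_complex(30, n_bp = 6, seed = 400 + i))
  pot <- train_potential(cxs)
  e <- score_complex(cxs[[1]], pot, per_residue = TRUE)
  expect_equal(sum(e$per_residue), e$total, tolerance = 1e-9)
  expect_error(score_complex(make_complex(10, n_bp = 0, seed = 1), pot),
               "no DNA")
})

test_that("potential artifact round-trips exactly", {
  cxs <- lapply(1:6, function(i) make_complex(25, n_bp = 5, seed = 500 + i))
  pot <- train_potential(cxs)
  txt <- save_potential(pot)
  back <- load_potential(txt)
  expect_identical(back$u, pot$u)
  expect_identical(back$counts, pot$counts)
  expect_identical(save_potential(back), txt)
  ## truncated artifact errors
  expect_error(load_potential(txt[1:5]), "artifact|corrupt")
  mangled <- txt
  mangled[15] <- "N\tP\t999\tnot_a_number"
  expect_error(load_potential(mangled), "corrupt")
  expect_error(load_potential(c("# other file", txt[-1])), "version")
})

test_that("training without any cross pairs errors", {
  expect_error(train_potential(list()), "insufficient statistics")
  ## geometry entirely beyond r_cut carries no statistics either
  apo_dna <- make_complex(20, n_bp = 5, offset = 200, seed = 600)
  expect_error(train_potential(list(apo_dna)), "insufficient statistics")
})

test_that("predict method scores like score_complex", {
  cxs <- lapply(1:5, function(i) make_complex(25, n_bp = 5, seed = 700 + i))
  pot <- train_potential(cxs)
  expect_equal(predict(pot, cxs[[2]])$total,
               score_complex(cxs[[2]], pot)$total)
})
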