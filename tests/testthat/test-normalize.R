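test_that("FPKM matches its closed form and a brute-force oracle", {
  # one row of length 1000 bp, count 10, total forced to 1e6 via a filler row
  m <- matrix(c(10, 1e6 - 10), ncol = 1, dimnames = list(c("gA", "filler"), "s1"))
  attr(m, "spike_prefix") <- "ERCC-"
  lens <- c(gA = 1000, filler = 1000)
  expect_equal(compute_fpkm(m, lens)["gA", "s1"], 10)

  m2 <- matrix(c(10, 2e6 - 10), ncol = 1, dimnames = list(c("gA", "filler"), "s1"))
  expect_equal(compute_fpkm(m2, c(gA = 2000, filler = 1000))["gA", "s1"], 2.5)

  # zero counts stay exactly zero
  m3 <- toy_counts(); m3["gene_1", ] <- 0
  expect_true(all(compute_fpkm(m3, toy_lengths(m3))["gene_1", ] == 0))

  # brute-force oracle on random 10 x 4 matrices
  set.seed(31)
  for (rep in 1:3) {
    counts <- matrix(rpois(40, 200), 10, 4,
                     dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
    lens <- setNames(sample(200:3000, 10), rownames(counts))
    got <- compute_fpkm(counts, lens)
    oracle <- matrix(NA_real_, 10, 4)
    for (i in 1:10) for (j in 1:4) {
      oracle[i, j] <- counts[i, j] / (lens[i] / 1e3) / (sum(counts[, j]) / 1e6)
    }
    expect_equal(unname(unclass(got)[, ]), oracle, tolerance = 1e-12)
  }
})

test_that("FPKM preconditions are enforced", {
  m <- toy_counts()
  lens <- toy_lengths(m)
  expect_error(compute_fpkm(m, lens[-1]), "no length for row")
  lens2 <- lens; lens2[1] <- 0
  expect_error(compute_fpkm(m, lens2), "non-positive length")
  m0 <- m; m0[, 1] <- 0
  expect_error(compute_fpkm(m0, lens), "zero-depth")
})

test_that("spike-in factors follow the ratio definition", {
  m <- toy_counts(n_genes = 4, n_spikes = 3, n_samples = 2)
  fpkm <- compute_fpkm(m, toy_lengths(m))
  sp <- startsWith(rownames(fpkm), "ERCC-")
  # equalize spike totals by hand -> all factors 1
  eq <- fpkm
  for (j in 1:2) eq[sp, j] <- eq[sp, j] / sum(eq[sp, j]) * 100
  f <- spikein_scale_factors(eq)
  expect_equal(unname(as.numeric(f)), c(1, 1))

  # halve one sample's spike signal -> factor 2 against the other as anchor
  half <- eq; half[sp, 2] <- half[sp, 2] / 2
  f2 <- spikein_scale_factors(half, anchor = "s1")
  expect_equal(unname(as.numeric(f2)), c(1, 2))
})

test_that("robust factor variant resists a single outlier spike species", {
  set.seed(5)
  spikes <- matrix(rlnorm(10, 3, 0.1), 5, 2,
                   dimnames = list(sprintf("ERCC-%05d", 1:5), c("s1", "s2")))
  spikes[, 2] <- spikes[, 1] / 3        # true factor 3
  spikes["ERCC-00002", 2] <- spikes["ERCC-00002", 1] * 10  # corrupted species
  genes <- matrix(100, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- rbind(genes, spikes)
  attr(m, "spike_prefix") <- "ERCC-"
  attr(m, "norm_state") <- "raw_fpkm"
  f_rob <- spikein_scale_factors(m, anchor = "s1", method = "median_ratio")
  # oracle: brute-force median of per-species ratios without the outlier
  clean <- m[c("g1", "g2", sprintf("ERCC-%05d", c(1, 3, 4, 5))), ]
  attr(clean, "spike_prefix") <- "ERCC-"; attr(clean, "norm_state") <- "raw_fpkm"
  f_clean <- spikein_scale_factors(clean, anchor = "s1", method = "median_ratio")
  expect_lt(abs(f_rob["s2"] - f_clean["s2"]) / f_clean["s2"], 0.05)
  # whereas the sum estimator is dragged off target by the outlier
  f_sum <- spikein_scale_factors(m, anchor = "s1")
  expect_gt(abs(f_sum["s2"] - 3), abs(f_rob["s2"] - 3))
})

test_that("factor errors: no spikes, zero spike signal, unmatched reference", {
  m <- toy_counts(n_spikes = 0)
  fpkm <- compute_fpkm(m, toy_lengths(m))
  expect_error(spikein_scale_factors(fpkm), "no spike-in rows")

  m2 <- toy_counts(n_spikes = 2)
  m2[startsWith(rownames(m2), "ERCC-"), 2] <- 0
  fpkm2 <- compute_fpkm(m2, toy_lengths(m2))
  expect_error(spikein_scale_factors(fpkm2), "zero total spike signal.*s2")

  fpkm3 <- compute_fpkm(toy_counts(), toy_lengths(toy_counts()))
  ref <- data.frame(spike_id = "ERCC-99999", concentration = 1)
  expect_error(spikein_scale_factors(fpkm3, reference = ref), "not in the reference")
})

test_that("apply_normalization is linear, state-checked, and equalizes spike totals", {
  m <- toy_counts(n_genes = 5, n_spikes = 3, n_samples = 3)
  fpkm <- compute_fpkm(m, toy_lengths(m))
  ones <- structure(setNames(rep(1, 3), colnames(m)), class = "scale_factors",
                    type = "identity", method = "sum")
  expect_equal(unname(unclass(apply_normalization(fpkm, ones))[, ]),
               unname(unclass(fpkm)[, ]))

  f <- spikein_scale_factors(fpkm)
  nm <- apply_normalization(fpkm, f)
  st <- colSums(nm[startsWith(rownames(nm), "ERCC-"), ])
  expect_lt(max(abs(st - mean(st)) / mean(st)), 1e-9)
  # doubling a factor doubles every value of that sample
  f2 <- f; f2[1] <- f2[1] * 2
  attr(f2, "type") <- "library_size"  # skip the spike-total postcondition
  nm2 <- apply_normalization(fpkm, f2)
  expect_equal(nm2[, 1], nm[, 1] * 2)
  # state machine: can't re-apply
  expect_error(apply_normalization(nm, f), "raw_fpkm")
})

test_that("batch anchoring rescales to the first batch's anchor condition", {
  sim <- small_sim(n_genes = 80, seed = 17)
  mat <- normalize_sim(sim, "WT:GV")
  sheet <- sim$sheet
  # single batch: unchanged
  anchored <- batch_anchor(mat, sheet, "WT:GV")
  expect_equal(unname(unclass(anchored)[, ]), unname(unclass(mat)[, ]))

  # construct batch 2 as an exact 3x copy of batch 1
  m2 <- cbind(mat, mat * 3)
  colnames(m2) <- c(colnames(mat), paste0(colnames(mat), "_b2"))
  attr(m2, "spike_prefix") <- "ERCC-"; attr(m2, "norm_state") <- "ercc_normalized"
  sheet2 <- rbind(sheet, transform(sheet, sample_id = paste0(sample_id, "_b2"),
                                   batch = "B2"))
  out <- batch_anchor(m2, sheet2, "WT:GV")
  expect_equal(unname(out[, paste0(colnames(mat)[1], "_b2")]),
               unname(mat[, 1]), tolerance = 1e-12)

  sheet3 <- sheet2[!(sheet2$batch == "B2" & sheet2$cohort == "WT" & sheet2$stage == "GV"), ]
  m3 <- m2[, sheet3$sample_id]
  attr(m3, "spike_prefix") <- "ERCC-"; attr(m3, "norm_state") <- "ercc_normalized"
  expect_error(batch_anchor(m3, sheet3, "WT:GV"), "\"B2\"")
})

test_that("total mRNA levels: identity, symmetry, and recovery of the storage decline", {
  sim <- small_sim("mouse_aging", n_genes = 1500, seed = 23)
  mat <- normalize_sim(sim, "young:GV")
  sheet <- sim$sheet

  one <- total_mrna_level(mat, sheet, universe = "gene_00001")
  expect_equal(unname(one$per_sample[1]), unname(mat["gene_00001", 1]))
  expect_error(total_mrna_level(mat, sheet, universe = "nope"), "empty universe")

  # permutation of sample columns leaves totals unchanged
  perm <- mat[, rev(colnames(mat))]
  attr(perm, "spike_prefix") <- "ERCC-"; attr(perm, "norm_state") <- "ercc_normalized"
  tot_perm <- total_mrna_level(perm, sheet)
  tot <- total_mrna_level(mat, sheet)
  expect_equal(tot_perm$per_sample[names(tot$per_sample)], tot$per_sample)

  # aged GV totals reflect the true storage decline (factor 0.8) within 10%
  young <- mean(tot$per_sample[group_samples_for(sheet, "young", "GV")])
  aged <- mean(tot$per_sample[group_samples_for(sheet, "aged", "GV")])
  truth_ratio <- sum(sim$truth$copies[, "aged:GV"]) / sum(sim$truth$copies[, "young:GV"])
  expect_lt(abs(aged / young - truth_ratio) / truth_ratio, 0.1)
})

test_that("spike-anchored values recover absolute copies up to one global constant", {
  sim <- small_sim(n_genes = 120, seed = 29, nb_dispersion = 0)
  mat <- normalize_sim(sim)
  genes <- names(sim$truth$decay_class)
  consts <- vapply(seq_len(ncol(mat)), function(j) {
    cond <- paste(sim$sheet$cohort[j], sim$sheet$stage[j], sep = ":")
    vals <- mat[genes, j] / sim$truth$copies[, cond]
    vals[sim$truth$copies[, cond] > 0]
  }, numeric(length(genes)))
  expect_lt(max(abs(consts - mean(consts)) / mean(consts)), 1e-6)
})
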