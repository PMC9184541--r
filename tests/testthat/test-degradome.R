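make_expr <- function(values, samples, state = "ercc_normalized") {
  m <- matrix(values, ncol = length(samples),
              dimnames = list(sprintf("g%d", seq_len(length(values) / length(samples))),
                              samples), byrow = TRUE)
  attr(m, "spike_prefix") <- "ERCC-"
  attr(m, "norm_state") <- state
  m
}

test_that("expressed-gene filter applies strict thresholds with two scopes", {
  sheet <- data.frame(sample_id = c("s1", "s2", "s3"), stage = "GV",
                      cohort = "young", batch = "B1", replicate = 1:3)
  # g1 all 0.5; g2 single sample just above 1; g3 GV mean 0.9 with one sample 1.2
  m <- make_expr(c(0.5, 0.5, 0.5,
                   1.01, 0.2, 0.2,
                   1.2, 0.75, 0.75), c("s1", "s2", "s3"))
  expect_false("g1" %in% filter_expressed(m))
  expect_true("g2" %in% filter_expressed(m))
  expect_true("g3" %in% filter_expressed(m))  # any_sample sees the 1.2
  grp <- filter_expressed(m, scope = "group", sheet = sheet, group = "young:GV")
  expect_false("g3" %in% grp)                 # group mean 0.9 fails
  expect_error(filter_expressed(m, scope = "group"), "sheet and group")
})

test_that("group means aggregate replicates and respect sample order", {
  sheet <- data.frame(sample_id = c("a", "b"), stage = "GV", cohort = "y",
                      batch = "B1", replicate = 1:2)
  m <- make_expr(c(2, 4), c("a", "b"))
  expect_equal(unname(group_mean(m, sheet, "y:GV")), 3)
  # permutation invariance
  m2 <- m[, c("b", "a"), drop = FALSE]
  attr(m2, "spike_prefix") <- "ERCC-"
  expect_equal(group_mean(m2, sheet, "y:GV"), group_mean(m, sheet, "y:GV"))
  expect_error(group_mean(m, sheet, "nope:GV"), "no samples")
})

test_that("fold change uses the pseudocount closed form", {
  a <- c(g1 = 10, g2 = 3, g3 = 0)
  b <- c(g1 = 1, g2 = 3, g3 = 0)
  fc <- fold_change(a, b, pseudocount = 0.01)
  expect_equal(unname(fc["g1"]), 10.01 / 1.01)
  expect_equal(unname(fc["g2"]), 1)
  expect_equal(unname(fc["g3"]), 1)  # 0/0 guarded by the pseudocount
  expect_error(fold_change(a, b[c(2, 1, 3)]), "aligned")
})

test_that("direction classes use strict thresholds and are internally consistent", {
  fc <- c(g1 = 6, g2 = 0.3, g3 = 5, g4 = 1, g5 = 0.1)
  d <- classify_direction(fc)
  expect_equal(d$dir_2x, c("up", "down", "up", "unchanged", "down"))
  expect_equal(d$dir_5x, c("up", "unchanged", "unchanged", "unchanged", "down"))
  expect_error(classify_direction(fc, thresholds = c(1, 5)), "> 1")

  # property: down at 5x implies down at 2x (and same for up) on random FCs
  set.seed(41)
  rfc <- setNames(exp(rnorm(500, 0, 2)), sprintf("g%d", 1:500))
  rd <- classify_direction(rfc)
  expect_true(all(rd$dir_2x[rd$dir_5x == "down"] == "down"))
  expect_true(all(rd$dir_2x[rd$dir_5x == "up"] == "up"))
})

test_that("M-decay calling combines the GV filter with the fold-change cutoff", {
  sheet <- data.frame(sample_id = c("gv1", "gv2", "mii1", "mii2"),
                      stage = c("GV", "GV", "MII", "MII"),
                      cohort = "y", batch = "B1", replicate = c(1, 2, 1, 2))
  m <- make_expr(c(10, 10, 1, 1,       # g1: FC ~ 9.9 -> called
                   0.8, 0.8, 0.05, 0.05,  # g2: FC > 5 but fails GV filter
                   10, 10, 9, 9),      # g3: expressed, FC ~ 1.1
                 c("gv1", "gv2", "mii1", "mii2"))
  called <- call_m_decay(m, sheet, "y:GV", "y:MII")
  expect_equal(called, "g1")
})

test_that("M-decay calls are monotone in both thresholds", {
  sim <- small_sim(n_genes = 300, seed = 19)
  mat <- normalize_sim(sim, "WT:GV")
  base <- call_m_decay(mat, sim$sheet, "WT:GV", "WT:MII", fc_threshold = 5, gv_filter = 1)
  looser_fc <- call_m_decay(mat, sim$sheet, "WT:GV", "WT:MII", fc_threshold = 3, gv_filter = 1)
  stricter_gv <- call_m_decay(mat, sim$sheet, "WT:GV", "WT:MII", fc_threshold = 5, gv_filter = 3)
  expect_true(all(base %in% looser_fc))
  expect_true(all(stricter_gv %in% base))
})

test_that("sensitivity partition follows set semantics and conserves the reference", {
  p <- partition_sensitivity(c("a", "b", "c"), "b")
  expect_setequal(p$sensitive, c("a", "c"))
  expect_equal(p$insensitive, "b")
  expect_length(p$test_only, 0)

  same <- partition_sensitivity(c("a", "b"), c("a", "b"))
  expect_length(same$sensitive, 0)

  # the human worked sizes are internally consistent: 2090 reference M-decay
  # transcripts with 181 retained in the aged cohort force 1909 sensitive
  ref <- sprintf("t%04d", 1:2090)
  test <- ref[1:181]
  p2 <- partition_sensitivity(ref, test)
  expect_equal(length(p2$sensitive), 1909L)
  expect_equal(length(p2$sensitive) + length(p2$insensitive), 2090L)

  # conservation property on random set pairs
  set.seed(77)
  for (i in 1:50) {
    u <- sprintf("g%d", 1:100)
    r <- sample(u, sample(0:60, 1))
    t <- sample(u, sample(0:60, 1))
    pp <- partition_sensitivity(r, t)
    expect_equal(length(pp$sensitive) + length(pp$insensitive), length(r))
  }
})

test_that("venn regions cover every intersection and sum to the union", {
  r <- venn_regions(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(r[c("A", "A&B", "B")]), c(1L, 1L, 1L))

  disjoint <- venn_regions(list(A = c("a"), B = c("b")))
  expect_equal(unname(disjoint["A&B"]), 0L)

  tri <- venn_regions(list(X = letters[1:3], Y = letters[1:3], Z = letters[1:3]))
  expect_equal(unname(tri["X&Y&Z"]), 3L)
  expect_equal(sum(tri), 3L)

  expect_error(venn_regions(list(1, 2, 3, 4)), "2 or 3 sets")

  set.seed(101)
  for (i in 1:20) {
    s <- lapply(1:3, function(k) sample(letters, sample(1:20, 1)))
    names(s) <- c("A", "B", "C")
    expect_equal(sum(venn_regions(s)), length(unique(unlist(s))))
  }
})

test_that("degradation patterns summarize trajectories with a robust median", {
  sheet <- data.frame(sample_id = c("gv1", "mii1"), stage = c("GV", "MII"),
                      cohort = "y", batch = "B1", replicate = 1)
  # genes halving from GV to MII: median curve drops by ~1 log2 unit
  m <- make_expr(c(8, 4, 16, 8, 32, 16), c("gv1", "mii1"))
  pat <- degradation_pattern(m, sheet, c("g1", "g2", "g3"), c("y:GV", "y:MII"),
                             pseudocount = 0)
  expect_equal(unname(diff(pat$median)), -1)

  # one extreme outlier cannot move the median (odd set size)
  m2 <- rbind(m, g4 = c(1e6, 1e6))
  attr(m2, "spike_prefix") <- "ERCC-"; attr(m2, "norm_state") <- "ercc_normalized"
  with_out <- degradation_pattern(m2, sheet, c("g1", "g2", "g3"), c("y:GV", "y:MII"),
                                  pseudocount = 0)
  expect_equal(with_out$median, pat$median)

  expect_error(degradation_pattern(m, sheet, character(), c("y:GV", "y:MII")),
               "empty gene set")
  expect_error(degradation_pattern(m, sheet, "g1", "y:GV"), ">= 2 ordered groups")
})

test_that("sensitive transcripts stay flat in the impaired cohort but drop in the reference", {
  sim <- small_sim("mouse_aging", n_genes = 500, seed = 37)
  mat <- normalize_sim(sim, "young:GV")
  sens <- truth_sensitive(sim)
  pat_young <- degradation_pattern(mat, sim$sheet, sens, c("young:GV", "young:MII"))
  pat_aged <- degradation_pattern(mat, sim$sheet, sens, c("aged:GV", "aged:MII"))
  expect_lt(diff(pat_young$median), -2)      # strong decay in young
  expect_lt(abs(diff(pat_aged$median)), 0.5) # roughly flat when decay fails
})
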