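test_that("probability threshold implements the prefix-FDR rule", {
  # perfect confidence: everything passes
  expect_identical(probability_threshold_at_fdr(rep(1, 5), 0.01), 1)
  # hand-enumerated prefixes: ten at 0.99 give FDR 0.01, adding 0.5 gives
  # 0.6/11 ~ 0.055
  expect_identical(
    probability_threshold_at_fdr(c(rep(0.99, 10), 0.5), 0.01), 0.99)
  # a single p = 0.5 cannot meet a 1% target: sentinel above 1
  thr <- probability_threshold_at_fdr(0.5, 0.01)
  expect_gt(thr, 1)
  expect_error(probability_threshold_at_fdr(numeric(0)), "empty")
})

test_that("threshold is monotone in the FDR target", {
  set.seed(4)
  p <- c(rbeta(300, 20, 1), rbeta(50, 2, 2))
  thrs <- vapply(c(0.005, 0.01, 0.05, 0.2),
                 function(t) probability_threshold_at_fdr(p, t), numeric(1))
  expect_true(all(diff(thrs) <= 0)) # looser target, lower threshold
  n_pass <- vapply(thrs, function(t) sum(p >= t), numeric(1))
  expect_true(all(diff(n_pass) >= 0))
})

test_that("orient applies the design sign and is an involution", {
  tab <- make_peptides("a", "p", c("R1", "R2"), c(1, -1), c(0.7, 0.7))
  o <- orient(tab)
  expect_equal(o$oriented, c(0.7, -0.7))
  flipped <- tab
  flipped$design <- -flipped$design
  flipped$log2_hl <- -flipped$log2_hl
  expect_equal(orient(flipped)$oriented, o$oriented)
})

test_that("consistency filter evaluates the sqrt(2)*c bound on design means", {
  cfg <- filter_config(c = 0.4)
  base <- function(m_pos, m_neg)
    orient(make_peptides("pep1", "prot", c("R1", "R2"), c(1, -1),
                         c(m_pos, -m_neg)))
  # perfect agreement: retained
  expect_identical(nrow(consistency_filter(base(0.4, 0.4), cfg)), 2L)
  # |0.5 - (-0.2)| = 0.7 >= 0.5657: dropped
  expect_identical(nrow(consistency_filter(base(0.5, -0.2), cfg)), 0L)
  # |0.3 - (-0.1)| = 0.4 < 0.5657: retained
  expect_identical(nrow(consistency_filter(base(0.3, -0.1), cfg)), 2L)
  # single-design peptides are dropped
  single <- orient(make_peptides("pep1", "prot", "R1", 1, 0))
  expect_identical(nrow(consistency_filter(single, cfg)), 0L)
})

test_that("consistency filter agrees with a brute-force oracle", {
  sim <- small_sim(seed = 23, n = 60)
  obs <- orient(sim$peptides)
  cfg <- filter_config(c = 0.4)
  kept <- consistency_filter(obs, cfg)
  kept_keys <- unique(paste(kept$protein_id, kept$peptide_id))
  # naive per-peptide loop
  expected <- character(0)
  for (key in unique(paste(obs$protein_id, obs$peptide_id))) {
    rows <- obs[paste(obs$protein_id, obs$peptide_id) == key, ]
    mp <- mean(rows$oriented[rows$design == 1])
    mn <- mean(rows$oriented[rows$design == -1])
    if (!is.nan(mp) && !is.nan(mn) && abs(mp - mn) < sqrt(2) * 0.4)
      expected <- c(expected, key)
  }
  expect_setequal(kept_keys, expected)
})

test_that("protein retention enforces peptide count and design coverage", {
  cfg <- filter_config()
  one_pep <- orient(make_peptides("pep1", "prot", c("R1", "R2"), c(1, -1),
                                  c(0, 0)))
  expect_identical(retain_proteins(one_pep, cfg), character(0))

  two_pep <- orient(make_peptides(rep(c("pep1", "pep2"), each = 2), "prot",
                                  rep(c("R1", "R2"), 2), rep(c(1, -1), 2),
                                  rep(0, 4)))
  expect_identical(retain_proteins(two_pep, cfg), "prot")

  # two peptides but only one design: dropped unless the switch is off
  oneside <- orient(make_peptides(c("pep1", "pep2"), "prot",
                                  c("R1", "R1"), c(1, 1), c(0, 0)))
  expect_identical(retain_proteins(oneside, cfg), character(0))
  cfg_loose <- filter_config(require_both_designs = FALSE)
  expect_identical(retain_proteins(oneside, cfg_loose), "prot")
})

test_that("retention matches an exhaustive rule evaluation on random tables", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 200
    tab <- orient(make_peptides(
      peptide_id = paste0("pep", sample(4, n, replace = TRUE)),
      protein_id = paste0("P", sample(30, n, replace = TRUE)),
      replicate_id = sample(c("R1", "R2", "R3"), n, replace = TRUE),
      design = sample(c(1, -1), n, replace = TRUE),
      log2_hl = rnorm(n)))
    tab <- unique(tab)
    cfg <- filter_config(min_high_conf_peptides = 2)
    got <- retain_proteins(tab, cfg)
    expected <- character(0)
    for (prot in unique(tab$protein_id)) {
      rows <- tab[tab$protein_id == prot, ]
      ok <- length(unique(rows$peptide_id)) >= 2 &&
        all(c(1, -1) %in% rows$design)
      if (ok) expected <- c(expected, prot)
    }
    expect_setequal(got, expected)
  }
})

test_that("aggregation computes per-cell statistics and normalisation", {
  cfg <- filter_config(normalize = FALSE)
  tab <- orient(make_peptides(paste0("pep", 1:3), "prot", "R1", 1,
                              c(0.1, 0.2, 0.9)))
  mat <- aggregate_ratios(tab, "prot", cfg)
  expect_identical(unname(mat$ratios[1, 1]), 0.2)
  expect_identical(unname(mat$support[1, 1]), 3L)

  zeros <- orient(make_peptides(paste0("pep", 1:4),
                                rep(c("p1", "p2"), each = 2),
                                rep(c("R1", "R2"), 2), rep(c(1, -1), 2),
                                rep(0, 4)))
  for (norm in c(TRUE, FALSE)) {
    m <- aggregate_ratios(zeros, c("p1", "p2"),
                          filter_config(normalize = norm))
    expect_true(all(m$ratios == 0, na.rm = TRUE))
  }
})

test_that("aggregation equals an independent per-cell recomputation", {
  sim <- small_sim(seed = 37, n = 50)
  obs <- orient(sim$peptides)
  kept <- consistency_filter(obs, filter_config())
  prots <- retain_proteins(kept, filter_config())
  kept <- kept[kept$protein_id %in% prots, ]
  for (agg in c("median", "mean")) {
    cfg <- filter_config(aggregator = agg, normalize = FALSE)
    mat <- aggregate_ratios(kept, prots, cfg)
    f <- if (agg == "median") median else mean
    for (i in sample(nrow(mat$ratios), 10)) {
      for (j in seq_len(ncol(mat$ratios))) {
        cell <- kept$oriented[kept$protein_id == rownames(mat$ratios)[i] &
                                kept$replicate_id == colnames(mat$ratios)[j]]
        if (length(cell) == 0) {
          expect_true(is.na(mat$ratios[i, j]))
        } else {
          expect_equal(unname(mat$ratios[i, j]), f(cell))
          expect_identical(unname(mat$support[i, j]), length(cell))
        }
      }
    }
  }
  # normalisation centres every replicate median at 0
  matn <- aggregate_ratios(kept, prots, filter_config(normalize = TRUE))
  expect_equal(unname(apply(matn$ratios, 2, median, na.rm = TRUE)),
               rep(0, ncol(matn$ratios)))
})

test_that("retained peptide set is monotone in the allowance c", {
  sim <- small_sim(seed = 61, n = 80)
  obs <- orient(sim$peptides)
  sizes <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6), function(cc)
    nrow(consistency_filter(obs, filter_config(c = cc))), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the full filter is invariant under global label negation", {
  sim <- small_sim(seed = 83, n = 60)
  flipped <- sim$peptides
  flipped$design <- -flipped$design
  flipped$log2_hl <- -flipped$log2_hl
  a <- quant_filter(sim$peptides)
  b <- quant_filter(flipped)
  expect_identical(a$counts, b$counts)
  expect_equal(a$matrix$ratios, b$matrix$ratios)
  expect_identical(a$matrix$support, b$matrix$support)
})

test_that("filtering enriches for correct observations on contaminated data", {
  cfg <- generator_config(150, frac_wrong = 0.25, seed = 29)
  peptides <- generate_peptides(generate_truth(cfg), cfg)
  qf <- quant_filter(peptides)
  frac_in <- mean(!peptides$correct)
  frac_out <- mean(!qf$retained$correct)
  expect_lt(frac_out, frac_in)
})
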