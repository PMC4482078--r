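#' Configuration for the synthetic SILAC label-switch generator
#'
#' Bundles every tunable of the simulator with validated defaults. The
#' defaults describe a three-replicate label-switch experiment: protein
#' abundances span five orders of magnitude, the number of peptides per
#' protein grows with abundance (corpus-wide mean around 21), per-peptide
#' measurement noise has SD `sigma_meas`, and a small fraction of
#' observations are erroneous quantifications carrying low identification
#' probabilities. A subset of genes is "codon biased": their coding
#' sequences are enriched for the AAA, GAA and CAA codons and their true
#' oriented log2 ratio is shifted by `bias_effect` (positive = less
#' abundant at the higher temperature).
#'
#' @param n_proteins number of proteins/genes to simulate.
#' @param n_replicates number of biological replicates (default 3).
#' @param design_assignment vector of label-design signs (+1/-1), one per
#'   replicate; +1 means the 30 degree culture carries the heavy label.
#'   Default alternates and always contains both signs.
#' @param frac_biased fraction of genes in the codon-biased class.
#' @param bias_effect log2 shift added to the true oriented ratio of biased
#'   genes.
#' @param sigma_bio SD of baseline true log2 ratios across proteins.
#' @param sigma_meas per-peptide measurement SD on the log2 scale. The
#'   default 0.4 matches the consistency-filter allowance: the difference of
#'   two independent measurements each with SD 0.4 has SD sqrt(2) * 0.4.
#' @param frac_wrong fraction of peptide observations that are erroneous.
#' @param sigma_wrong SD of the log2 ratio of erroneous observations.
#' @param abundance_log10_range range (length 2) of log10 copies per cell;
#'   the default spans five decades.
#' @param gene_length_codons integer range (length 2) of coded codons per
#'   gene, counted including the start ATG and excluding the stop.
#' @param codon_bias_multiplier factor (> 0) multiplying the sampling weight
#'   of AAA, GAA and CAA in biased genes before renormalisation.
#' @param dropout per-replicate probability that a peptide is not observed
#'   in a given replicate (default 0).
#' @param prob_correct_shape,prob_wrong_shape Beta shape pairs for the
#'   identification probabilities of correct and erroneous observations.
#'   Defaults concentrate correct identifications above 0.95 and centre
#'   erroneous ones near 0.5.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_proteins,
                             n_replicates = 3L,
                             design_assignment = NULL,
                             frac_biased = 0.2,
                             bias_effect = 1.0,
                             sigma_bio = 0.35,
                             sigma_meas = 0.4,
                             frac_wrong = 0.05,
                             sigma_wrong = 2.0,
                             abundance_log10_range = c(1, 6),
                             gene_length_codons = c(100L, 700L),
                             codon_bias_multiplier = 3,
                             dropout = 0,
                             prob_correct_shape = c(60, 1),
                             prob_wrong_shape = c(4, 4),
                             seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_proteins) || n_proteins < 1L)
    stop("n_proteins must be a positive integer")
  if (n_replicates < 2L)
    stop("n_replicates must be at least 2 (both label designs must occur)")
  if (is.null(design_assignment))
    design_assignment <- rep_len(c(1, -1), n_replicates)
  design_assignment <- as.numeric(design_assignment)
  if (length(design_assignment) != n_replicates)
    stop("design_assignment must have one sign per replicate")
  if (!all(design_assignment %in% c(1, -1)))
    stop("design_assignment signs must be +1 or -1")
  if (!all(c(1, -1) %in% design_assignment))
    stop("design_assignment must contain both signs")
  for (f in c(frac_biased, frac_wrong, dropout))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  for (s in c(sigma_bio, sigma_meas, sigma_wrong))
    if (s < 0) stop("sigma values must be non-negative")
  if (codon_bias_multiplier <= 0)
    stop("codon_bias_multiplier must be positive")
  stopifnot(length(abundance_log10_range) == 2L,
            diff(abundance_log10_range) >= 0,
            length(gene_length_codons) == 2L,
            gene_length_codons[1] >= 2L,
            diff(gene_length_codons) >= 0)
  structure(list(
    n_proteins = n_proteins,
    n_replicates = n_replicates,
    design_assignment = design_assignment,
    frac_biased = frac_biased,
    bias_effect = bias_effect,
    sigma_bio = sigma_bio,
    sigma_meas = sigma_meas,
    frac_wrong = frac_wrong,
    sigma_wrong = sigma_wrong,
    abundance_log10_range = abundance_log10_range,
    gene_length_codons = as.integer(gene_length_codons),
    codon_bias_multiplier = codon_bias_multiplier,
    dropout = dropout,
    prob_correct_shape = prob_correct_shape,
    prob_wrong_shape = prob_wrong_shape,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# n_peptides model: round(a + b * log10(copies)) + integer noise, floored at
# 1. With abundances log-uniform over five decades the corpus-wide mean is
# approximately 21 peptides per protein.
.PEP_INTERCEPT <- -7
.PEP_SLOPE <- 8
.PEP_NOISE_SD <- 2

#' Simulate per-protein ground truth
#'
#' Draws, for each protein, a true oriented log2(30C/37C) ratio, a
#' codon-bias class, an abundance (copies per cell, log-uniform over
#' `abundance_log10_range`) and a peptide count that increases with
#' abundance. Exactly `floor(frac_biased * n_proteins)` proteins are flagged
#' biased and receive an extra `bias_effect` on their true ratio.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `protein_id`, `true_log2_ratio`,
#'   `bias_class` ("biased"/"unbiased"), `copies_per_cell`, `n_peptides`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_proteins
  with_seed(derive_seed(config$seed, "truth"), {
    ids <- sprintf("P%05d", seq_len(n))
    n_biased <- floor(config$frac_biased * n)
    biased <- rep(FALSE, n)
    if (n_biased > 0) biased[sample.int(n, n_biased)] <- TRUE
    ratio <- rnorm(n, 0, config$sigma_bio) + ifelse(biased, config$bias_effect, 0)
    log10_copies <- runif(n, config$abundance_log10_range[1],
                          config$abundance_log10_range[2])
    npep <- pmax(1L, as.integer(round(
      .PEP_INTERCEPT + .PEP_SLOPE * log10_copies + rnorm(n, 0, .PEP_NOISE_SD))))
    data.frame(
      protein_id = ids,
      true_log2_ratio = ratio,
      bias_class = ifelse(biased, "biased", "unbiased"),
      copies_per_cell = 10^log10_copies,
      n_peptides = npep,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate coding sequences
#'
#' Generates one coding sequence per protein: a start ATG, internal codons
#' drawn from the 61 sense codons, and exactly one terminal stop codon. For
#' genes in the biased class the sampling weights of AAA, GAA and CAA are
#' multiplied by `codon_bias_multiplier` before renormalisation; all other
#' sense codons are equally weighted.
#'
#' @param truth data.frame from [generate_truth()].
#' @param config the same [generator_config()].
#' @return named character vector of sequences (names = protein ids).
#' @export
generate_orfs <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"), nrow(truth) > 0)
  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  w_plain <- rep(1, length(sense))
  w_bias <- w_plain
  w_bias[sense %in% c("AAA", "GAA", "CAA")] <- config$codon_bias_multiplier
  with_seed(derive_seed(config$seed, "orfs"), {
    lens <- sample(seq(config$gene_length_codons[1], config$gene_length_codons[2]),
                   nrow(truth), replace = TRUE)
    seqs <- character(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      w <- if (truth$bias_class[i] == "biased") w_bias else w_plain
      internal <- sample(sense, lens[i] - 1L, replace = TRUE, prob = w)
      seqs[i] <- paste0("ATG", paste(internal, collapse = ""),
                        sample(stops, 1L))
    }
    names(seqs) <- truth$protein_id
    seqs
  })
}

#' Simulate peptide-level SILAC observations
#'
#' Emulates a label-switch acquisition: every peptide of every protein is
#' measured once per replicate (subject to `dropout`). With probability
#' `1 - frac_wrong` the observation is correct, carrying
#' `log2_hl = design * true_log2_ratio + N(0, sigma_meas)` and an
#' identification probability drawn from the high-confidence Beta; otherwise
#' it is erroneous, with `log2_hl ~ N(0, sigma_wrong)` and a low-centred
#' probability. Peptide ids are shared across replicates (the same peptide
#' species re-measured), which is what the consistency filter keys on.
#'
#' @param truth data.frame from [generate_truth()].
#' @param config the same [generator_config()].
#' @return data.frame with columns `peptide_id`, `protein_id`,
#'   `replicate_id`, `design`, `log2_hl`, `probability`, `correct`.
#' @export
generate_peptides <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"), nrow(truth) > 0)
  with_seed(derive_seed(config$seed, "peptides"), {
    pep_protein <- rep(truth$protein_id, truth$n_peptides)
    pep_truth <- rep(truth$true_log2_ratio, truth$n_peptides)
    pep_id <- paste0(pep_protein, "_pep",
                     sequence(truth$n_peptides))
    n_pep <- length(pep_id)
    reps <- paste0("R", seq_len(config$n_replicates))
    obs <- data.frame(
      peptide_id = rep(pep_id, times = config$n_replicates),
      protein_id = rep(pep_protein, times = config$n_replicates),
      replicate_id = rep(reps, each = n_pep),
      design = rep(config$design_assignment, each = n_pep),
      stringsAsFactors = FALSE
    )
    true_rep <- rep(pep_truth, times = config$n_replicates)
    m <- nrow(obs)
    correct <- rbinom(m, 1L, 1 - config$frac_wrong) == 1L
    log2_hl <- ifelse(correct,
                      obs$design * true_rep + rnorm(m, 0, config$sigma_meas),
                      rnorm(m, 0, config$sigma_wrong))
    probability <- ifelse(correct,
                          rbeta(m, config$prob_correct_shape[1],
                                config$prob_correct_shape[2]),
                          rbeta(m, config$prob_wrong_shape[1],
                                config$prob_wrong_shape[2]))
    obs$log2_hl <- log2_hl
    obs$probability <- probability
    obs$correct <- correct
    if (config$dropout > 0) {
      keep <- runif(m) >= config$dropout
      obs <- obs[keep, , drop = FALSE]
      rownames(obs) <- NULL
    }
    obs
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [generate_truth()], [generate_orfs()] and
#' [generate_peptides()] under one configuration, optionally writing the
#' three artefacts to a directory (`truth.tsv`, `orfs.fasta`,
#' `peptides.tsv`).
#'
#' @param config a [generator_config()].
#' @param dir optional output directory.
#' @return list with elements `truth`, `orfs`, `peptides`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  truth <- generate_truth(config)
  orfs <- generate_orfs(truth, config)
  peptides <- generate_peptides(truth, config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_truth_table(truth, file.path(dir, "truth.tsv"))
    write_fasta(orfs, file.path(dir, "orfs.fasta"))
    write_peptide_table(peptides, file.path(dir, "peptides.tsv"))
  }
  list(truth = truth, orfs = orfs, peptides = peptides)
}
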