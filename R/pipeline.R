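#' Proteome coverage percentage
#'
#' @param n_quantified number of proteins quantified.
#' @param n_reference size of the reference gene set.
#' @return `100 * n_quantified / n_reference`, rounded to 2 decimals.
#' @export
coverage_summary <- function(n_quantified, n_reference) {
  if (n_reference <= 0) stop("reference set must be non-empty")
  if (n_quantified > n_reference)
    stop("quantified count exceeds reference set size")
  round(100 * n_quantified / n_reference, 2)
}

#' Tally significant calls
#'
#' @param results moderated-test result data.frame.
#' @return named integer vector with elements `total`, `up37`, `down37`;
#'   `up37 + down37 == total` by construction (ns calls are excluded).
#' @export
tally_significant <- function(results) {
  up <- sum(results$call == "up37")
  down <- sum(results$call == "down37")
  c(total = up + down, up37 = up, down37 = down)
}

#' Configuration of a full pipeline run
#'
#' Exactly one input mode must be active: simulation (a
#' [generator_config()] in `generator`) or user data (`peptides_path`, plus
#' `fasta_path` when the codon stage is wanted). An optional rescue arm —
#' a second dataset against which down-calls are compared — is configured
#' the same way through `rescue_generator` / `rescue_peptides_path`.
#'
#' @param out_dir output directory for all stage artefacts.
#' @param generator optional [generator_config()] (simulate mode).
#' @param peptides_path optional peptide table TSV (user mode).
#' @param fasta_path optional coding-sequence FASTA (user mode, codon
#'   stage).
#' @param filter a [filter_config()].
#' @param alpha FDR level for calls (default 0.01).
#' @param run_codons whether to run the codon-importance stage (default
#'   TRUE).
#' @param n_trees random-forest size (default 1000).
#' @param rescue_generator,rescue_peptides_path optional rescue-arm input.
#' @param seed global seed, fanned out per stage with [derive_seed()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       generator = NULL,
                       peptides_path = NULL,
                       fasta_path = NULL,
                       filter = filter_config(),
                       alpha = 0.01,
                       run_codons = TRUE,
                       n_trees = 1000L,
                       rescue_generator = NULL,
                       rescue_peptides_path = NULL,
                       seed = 1L) {
  simulate <- !is.null(generator)
  if (simulate == !is.null(peptides_path))
    stop("exactly one of generator / peptides_path must be given")
  if (simulate) stopifnot(inherits(generator, "generator_config"))
  if (!simulate && run_codons && is.null(fasta_path))
    stop("codon stage requested but no FASTA configured")
  if (!is.null(rescue_generator) && !is.null(rescue_peptides_path))
    stop("configure the rescue arm by generator or by path, not both")
  structure(list(out_dir = out_dir, generator = generator,
                 peptides_path = peptides_path, fasta_path = fasta_path,
                 filter = filter, alpha = alpha, run_codons = run_codons,
                 n_trees = as.integer(n_trees),
                 rescue_generator = rescue_generator,
                 rescue_peptides_path = rescue_peptides_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

.log_stage <- function(name, t0, ...) {
  message(sprintf("[%s] %.2fs %s", name,
                  as.numeric(Sys.time()) - t0, paste(..., collapse = " ")))
}

.run_arm <- function(peptides, filter, alpha, label) {
  qf <- quant_filter(peptides, filter)
  if (is.null(qf$matrix))
    stop("stage filter (", label, "): no protein passed the filter")
  res <- moderated_test(qf$matrix, alpha = alpha)
  list(qf = qf, results = res)
}

#' Run the full pipeline
#'
#' Simulate or load peptide data, filter, test, profile codons, score codon
#' importance, and (when a rescue arm is configured) compute the rescue
#' list. All intermediate tables are written under `config$out_dir`; the
#' run is bitwise reproducible given the seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with elements `report` (data.frame of stage
#'   counts), `results`, `matrix`, and when applicable `importance`,
#'   `rescue`, `truth`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_dataset(gen, dir = config$out_dir)
    peptides <- sim$peptides
    orfs <- sim$orfs
    truth <- sim$truth
    .log_stage("simulate", t0, nrow(peptides), "peptide observations")
  } else {
    peptides <- read_peptide_table(config$peptides_path)
    orfs <- if (!is.null(config$fasta_path)) read_fasta(config$fasta_path)
            else NULL
    truth <- NULL
    .log_stage("load", t0, nrow(peptides), "peptide observations")
  }

  arm <- .run_arm(peptides, config$filter, config$alpha, "normal")
  write_ratio_matrix(arm$qf$matrix, file.path(config$out_dir,
                                              "ratio_matrix.tsv"))
  write_result_table(arm$results, file.path(config$out_dir, "results.tsv"))
  tal <- tally_significant(arm$results)
  .log_stage("filter+test", t0,
             sprintf("%d proteins retained, %d significant (%d up, %d down)",
                     arm$qf$counts[["proteins_retained"]],
                     tal[["total"]], tal[["up37"]], tal[["down37"]]))

  out <- list(results = arm$results, matrix = arm$qf$matrix, truth = truth)

  if (config$run_codons && !is.null(orfs)) {
    profiles <- codon_frequencies(orfs)
    sig <- arm$results[arm$results$call != "ns", ]
    if (length(unique(sig$call)) == 2) {
      imp <- rf_importance(profiles[sig$protein_id, , drop = FALSE],
                           sig$call, n_trees = config$n_trees,
                           seed = derive_seed(config$seed, "rf"))
      .write_tsv(imp, file.path(config$out_dir, "importance.tsv"))
      out$importance <- imp
      .log_stage("codons", t0, sum(imp$selected), "codons selected")
    } else {
      message("codon stage skipped: need both up37 and down37 calls")
    }
    out$profiles <- profiles
  }

  if (!is.null(config$rescue_generator) ||
      !is.null(config$rescue_peptides_path)) {
    if (!is.null(config$rescue_generator)) {
      gen2 <- config$rescue_generator
      gen2$seed <- derive_seed(config$seed, "rescue-simulate")
      peptides2 <- simulate_dataset(gen2)$peptides
    } else {
      peptides2 <- read_peptide_table(config$rescue_peptides_path)
    }
    arm2 <- .run_arm(peptides2, config$filter, config$alpha, "rescue")
    write_result_table(arm2$results,
                       file.path(config$out_dir, "results_rescue.tsv"))
    if (!is.null(out$profiles)) {
      resc <- rescue_list(arm$results, arm2$results, out$profiles,
                          alpha = config$alpha)
      .write_tsv(resc, file.path(config$out_dir, "rescue.tsv"))
      out$rescue <- resc
      .log_stage("rescue", t0, nrow(resc), "genes in rescue list")
    }
  }

  counts <- arm$qf$counts
  report <- data.frame(
    stage = c(names(counts), "proteins_tested", "significant_total",
              "significant_up37", "significant_down37"),
    count = c(unname(counts), nrow(arm$results), unname(tal)),
    stringsAsFactors = FALSE
  )
  .write_tsv(report, file.path(config$out_dir, "report.tsv"))
  out$report <- report
  invisible(out)
}
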