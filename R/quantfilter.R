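#' Configuration of the label-switch quantification filter
#'
#' @param fdr_target target identification FDR for the probability
#'   threshold (default 0.01, i.e. the 1 percent FDR used throughout).
#' @param c per-measurement SD allowance; the consistency bound on the
#'   difference of the two per-design means is `sqrt(2) * c` (default 0.4).
#' @param min_high_conf_peptides minimum number of distinct retained
#'   peptides a protein needs to be kept (default 2).
#' @param require_both_designs if TRUE (default) the retained peptides of a
#'   kept protein must jointly cover both label designs.
#' @param aggregator statistic combining a protein's peptide ratios within a
#'   replicate: "median" (default) or "mean".
#' @param normalize if TRUE (default) each replicate column of the final
#'   matrix is median-centred.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(fdr_target = 0.01, c = 0.4,
                          min_high_conf_peptides = 2L,
                          require_both_designs = TRUE,
                          aggregator = c("median", "mean"),
                          normalize = TRUE) {
  aggregator <- match.arg(aggregator)
  if (fdr_target <= 0 || fdr_target >= 1)
    stop("fdr_target must lie in (0, 1)")
  if (c <= 0) stop("c must be positive")
  min_high_conf_peptides <- as.integer(min_high_conf_peptides)
  if (min_high_conf_peptides < 1L)
    stop("min_high_conf_peptides must be >= 1")
  structure(list(fdr_target = fdr_target, c = c,
                 min_high_conf_peptides = min_high_conf_peptides,
                 require_both_designs = isTRUE(require_both_designs),
                 aggregator = aggregator,
                 normalize = isTRUE(normalize)),
            class = "filter_config")
}

#' Identification-probability threshold at a target FDR
#'
#' Sorts the probabilities in decreasing order and, for each prefix of size
#' k, estimates the false-discovery rate of accepting that prefix as
#' `sum(1 - p_i) / k`. Returns the probability of the last element of the
#' largest prefix whose estimated FDR is at most `fdr_target`. If no prefix
#' qualifies a sentinel value of 2 is returned so that nothing passes a
#' `probability >= threshold` test.
#'
#' @param probabilities numeric vector of identification probabilities.
#' @param fdr_target target FDR in (0, 1).
#' @return the probability threshold.
#' @export
probability_threshold_at_fdr <- function(probabilities, fdr_target = 0.01) {
  if (length(probabilities) == 0) stop("empty probability list")
  if (any(is.na(probabilities) | probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  p <- sort(probabilities, decreasing = TRUE)
  fdr <- cumsum(1 - p) / seq_along(p)
  # small epsilon guards against floating-point noise in 1 - p
  ok <- which(fdr <= fdr_target + 1e-12)
  if (length(ok) == 0) return(2)
  p[max(ok)]
}

#' Orient peptide ratios into the fixed 30C/37C convention
#'
#' Adds an `oriented` column equal to `design * log2_hl`. A positive
#' oriented ratio means the protein is more abundant at 30 degrees, i.e.
#' down-regulated at the elevated temperature.
#'
#' @param observations peptide observation data.frame.
#' @return the same data.frame with an `oriented` column.
#' @export
orient <- function(observations) {
  stopifnot(all(observations$design %in% c(1, -1)))
  observations$oriented <- observations$design * observations$log2_hl
  observations
}

#' Restrict observations to high-confidence identifications
#'
#' Computes the probability threshold at `fdr_target` over all observations
#' and keeps those with `probability >= threshold`.
#'
#' @param observations peptide observation data.frame.
#' @param config a [filter_config()].
#' @return list with elements `observations` (the retained rows) and
#'   `threshold`.
#' @export
high_confidence_filter <- function(observations, config = filter_config()) {
  thr <- probability_threshold_at_fdr(observations$probability,
                                      config$fdr_target)
  list(observations = observations[observations$probability >= thr, ,
                                   drop = FALSE],
       threshold = thr)
}

#' Label-switch consistency filter
#'
#' For every peptide (keyed by `peptide_id` within `protein_id`) the mean
#' oriented ratio is computed separately over the replicates of each label
#' design, giving R(+1) and R(-1). The peptide's observations are retained
#' iff both means exist and `|R(+1) - R(-1)| < sqrt(2) * c`; peptides
#' observed under only one design are dropped. A correctly quantified
#' peptide has the same oriented expectation under both designs, whereas a
#' quantification error (wrong isotope pair, overlapping signal) flips sign
#' under the label switch, so this filter enriches for correct
#' quantifications.
#'
#' @param observations oriented peptide observations (see [orient()]),
#'   already restricted to high confidence.
#' @param config a [filter_config()].
#' @return the retained observations.
#' @export
consistency_filter <- function(observations, config = filter_config()) {
  if (!"oriented" %in% names(observations))
    stop("observations must be oriented first (see orient())")
  if (nrow(observations) == 0) return(observations)
  key <- paste(observations$protein_id, observations$peptide_id, sep = "\r")
  mean_by <- function(mask) {
    sub <- observations[mask, , drop = FALSE]
    k <- key[mask]
    sums <- rowsum(sub$oriented, k)
    cnts <- rowsum(rep(1, nrow(sub)), k)
    stats::setNames(as.vector(sums / cnts), rownames(sums))
  }
  m_pos <- mean_by(observations$design == 1)
  m_neg <- mean_by(observations$design == -1)
  common <- intersect(names(m_pos), names(m_neg))
  ok <- common[abs(m_pos[common] - m_neg[common]) < sqrt(2) * config$c]
  out <- observations[key %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein retention rule
#'
#' A protein is kept iff it has at least `min_high_conf_peptides` distinct
#' retained peptides and (when `require_both_designs`) those peptides
#' jointly cover both label designs.
#'
#' @param retained consistency-filtered peptide observations.
#' @param config a [filter_config()].
#' @return character vector of retained protein ids.
#' @export
retain_proteins <- function(retained, config = filter_config()) {
  if (nrow(retained) == 0) return(character(0))
  pep <- unique(retained[c("protein_id", "peptide_id")])
  n_pep <- table(pep$protein_id)
  keep <- names(n_pep)[n_pep >= config$min_high_conf_peptides]
  if (config$require_both_designs) {
    des <- unique(retained[c("protein_id", "design")])
    n_des <- table(des$protein_id)
    keep <- intersect(keep, names(n_des)[n_des == 2L])
  }
  sort(keep)
}

#' Construct a protein ratio matrix
#'
#' @param ratios numeric matrix (proteins x replicates) of oriented
#'   log2(30C/37C) ratios, NA for missing cells.
#' @param support integer matrix of supporting peptide counts, same shape.
#' @return an object of class `protein_ratio_matrix`.
#' @export
protein_ratio_matrix <- function(ratios, support) {
  stopifnot(is.matrix(ratios), identical(dim(ratios), dim(support)),
            !is.null(rownames(ratios)), !is.null(colnames(ratios)))
  if (any(is.infinite(ratios), na.rm = TRUE))
    stop("ratios must be finite or NA")
  if (any(rowSums(!is.na(ratios)) == 0))
    stop("every protein must have at least one non-missing cell")
  structure(list(ratios = ratios, support = support),
            class = "protein_ratio_matrix")
}

#' @export
print.protein_ratio_matrix <- function(x, ...) {
  cat(sprintf("protein_ratio_matrix: %d proteins x %d replicates (%d cells)\n",
              nrow(x$ratios), ncol(x$ratios), sum(!is.na(x$ratios))))
  invisible(x)
}

#' Aggregate retained peptides to per-replicate protein ratios
#'
#' Each cell (protein, replicate) is the configured aggregator (median or
#' mean) over that protein's retained peptide oriented ratios in that
#' replicate, missing if none. When `normalize` is set, each replicate
#' column is centred by subtracting its median cell value, removing any
#' residual systematic bias between the isotope channels.
#'
#' @param retained consistency-filtered, oriented peptide observations.
#' @param proteins protein ids to aggregate (subset of those present).
#' @param config a [filter_config()].
#' @return a `protein_ratio_matrix`.
#' @export
aggregate_ratios <- function(retained, proteins, config = filter_config()) {
  stopifnot(all(proteins %in% retained$protein_id))
  proteins <- sort(proteins)
  sub <- retained[retained$protein_id %in% proteins, , drop = FALSE]
  reps <- sort(unique(sub$replicate_id))
  agg_fun <- if (config$aggregator == "median") median else mean
  ratios <- matrix(NA_real_, length(proteins), length(reps),
                   dimnames = list(proteins, reps))
  support <- matrix(0L, length(proteins), length(reps),
                    dimnames = list(proteins, reps))
  grp <- split(seq_len(nrow(sub)),
               list(factor(sub$protein_id, proteins),
                    factor(sub$replicate_id, reps)), drop = FALSE)
  for (nm in names(grp)) {
    idx <- grp[[nm]]
    if (length(idx) == 0) next
    i <- match(sub$protein_id[idx[1]], proteins)
    j <- match(sub$replicate_id[idx[1]], reps)
    ratios[i, j] <- agg_fun(sub$oriented[idx])
    support[i, j] <- length(idx)
  }
  if (config$normalize) {
    centre <- apply(ratios, 2, median, na.rm = TRUE)
    ratios <- sweep(ratios, 2, centre, "-")
  }
  protein_ratio_matrix(ratios, support)
}

#' Run the full quantification filter
#'
#' Orientation, probability thresholding at the target FDR, the
#' label-switch consistency filter, protein retention and aggregation, with
#' per-stage counts.
#'
#' @param peptides peptide observation data.frame.
#' @param config a [filter_config()].
#' @return list with elements `matrix` (a `protein_ratio_matrix`),
#'   `threshold`, `retained` (the retained observations) and `counts`
#'   (named vector of per-stage bookkeeping).
#' @export
quant_filter <- function(peptides, config = filter_config()) {
  oriented <- orient(peptides)
  hc <- high_confidence_filter(oriented, config)
  retained <- consistency_filter(hc$observations, config)
  proteins <- retain_proteins(retained, config)
  retained <- retained[retained$protein_id %in% proteins, , drop = FALSE]
  counts <- c(
    peptides_in = nrow(peptides),
    peptides_high_conf = nrow(hc$observations),
    peptides_retained = nrow(retained),
    proteins_quantified = length(unique(peptides$protein_id)),
    proteins_retained = length(proteins)
  )
  mat <- if (length(proteins) > 0)
    aggregate_ratios(retained, proteins, config)
  else NULL
  list(matrix = mat, threshold = hc$threshold,
       retained = retained, counts = counts)
}
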