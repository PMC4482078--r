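#' The 61 sense codons
#'
#' All 64 trinucleotides over ACGT except the three stop codons (TAA, TAG,
#' TGA), in alphabetical order. This fixed ordering indexes every codon
#' profile and importance table in the package.
#'
#' @return character vector of length 61.
#' @export
sense_codons <- function() {
  all64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T"))[, 3:1], 1, paste,
                 collapse = "")
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' Codon-usage profiles of coding sequences
#'
#' Splits each validated coding sequence into codons, counts every codon
#' from the initial ATG up to (and excluding) the single terminal stop, and
#' converts counts to relative frequencies over the 61 sense codons. Each
#' row sums to 1.
#'
#' Sequences must have length divisible by 3, end in exactly one stop codon
#' and contain no internal stop; violations raise an error naming the gene.
#'
#' @param sequences named character vector of coding sequences.
#' @return numeric matrix (genes x 61 sense codons) of frequencies.
#' @export
codon_frequencies <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  out <- matrix(0, length(sequences), length(sense),
                dimnames = list(names(sequences), sense))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    id <- names(sequences)[i]
    if (nchar(s) %% 3 != 0)
      stop("gene '", id, "': length not divisible by 3")
    n_codon <- nchar(s) %/% 3
    codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
    if (!codons[n_codon] %in% stops)
      stop("gene '", id, "': missing terminal stop codon")
    coding <- codons[-n_codon]
    if (any(coding %in% stops))
      stop("gene '", id, "': internal stop codon")
    counts <- table(factor(coding, levels = sense))
    out[i, ] <- as.numeric(counts) / length(coding)
  }
  out
}

#' Random-forest codon importance
#'
#' Trains a random-forest classifier to separate up- from down-regulated
#' genes using their 61 codon frequencies, and scores each codon by
#' permutation importance: the mean decrease in out-of-bag accuracy when
#' that codon's out-of-bag values are permuted, averaged over trees. The
#' selection threshold is the absolute value of the lowest (most negative)
#' importance — the magnitude of the noisiest predictor — and a codon is
#' selected iff its importance exceeds that threshold.
#'
#' @param profiles codon-frequency matrix from [codon_frequencies()].
#' @param labels vector of class labels (`up37`/`down37`, or any two
#'   levels), aligned with the rows of `profiles`; both classes must occur.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; results are deterministic given seed and
#'   n_trees.
#' @param mtry features tried per split (default `round(sqrt(61))` = 8).
#' @param min_node minimal node size for splitting (default 5).
#' @return data.frame with columns `codon`, `importance`, `rank`,
#'   `selected`, `threshold`, ordered by the codon index; the forest's
#'   out-of-bag error rate is attached as attribute `"oob_error"`.
#' @export
rf_importance <- function(profiles, labels, n_trees = 1000L, seed,
                          mtry = round(sqrt(ncol(profiles))),
                          min_node = 5L) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(labels))
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must contain exactly two classes, both non-empty")
  y <- as.integer(labels) - 1L
  fit <- .rf_importance_cpp(profiles, y, as.integer(n_trees),
                            as.integer(mtry), as.integer(min_node),
                            as.integer(seed))
  importance <- as.numeric(fit$importance)
  threshold <- if (any(importance < 0)) abs(min(importance)) else 0
  ord <- order(-importance, colnames(profiles))
  rank <- integer(length(importance))
  rank[ord] <- seq_along(importance)
  res <- data.frame(
    codon = colnames(profiles),
    importance = importance,
    rank = rank,
    selected = importance > threshold,
    threshold = threshold,
    stringsAsFactors = FALSE
  )
  attr(res, "oob_error") <- fit$oob_error
  res
}

#' Genes with the highest frequency of a codon
#'
#' Ranks genes by descending frequency of the given codon (ties broken by
#' ascending gene id) and returns the top `ceiling(n * percentile / 100)`.
#'
#' @param profiles codon-frequency matrix from [codon_frequencies()].
#' @param codon one of the 61 sense codons.
#' @param percentile percentage in (0, 100).
#' @return character vector of gene ids.
#' @export
top_codon_subset <- function(profiles, codon, percentile) {
  if (!codon %in% colnames(profiles))
    stop("unknown codon: ", codon)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  n <- nrow(profiles)
  k <- ceiling(n * percentile / 100)
  ord <- order(-profiles[, codon], rownames(profiles))
  rownames(profiles)[ord[seq_len(k)]]
}

#' Volcano-ready table for a gene subset
#'
#' Extracts fold change and significance for a subset of genes:
#' `mean_log2` versus `-log10(adjusted p)`. The 1 percent FDR reference
#' corresponds to a y-value of 2. Subset members absent from the results
#' are reported in a message and skipped.
#'
#' @param results moderated-test result data.frame.
#' @param subset character vector of gene ids.
#' @return data.frame with columns `gene_id`, `mean_log2`,
#'   `neg_log10_adj_p`.
#' @export
subset_volcano <- function(results, subset) {
  missing <- setdiff(subset, results$protein_id)
  if (length(missing) > 0)
    message(length(missing), " subset gene(s) absent from results, skipped")
  sub <- results[results$protein_id %in% subset, , drop = FALSE]
  data.frame(
    gene_id = sub$protein_id,
    mean_log2 = sub$mean_log2,
    neg_log10_adj_p = -log10(sub$adj_p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Genes rescued by tRNA over-expression
#'
#' Identifies genes whose transcripts rank in the top `percentile` of the
#' genome for at least one of the given codons, whose proteins are
#' significantly down-regulated (adjusted p <= alpha, positive oriented
#' mean) in the normal dataset, but not so called in the rescue dataset.
#' Only genes present in both result sets are considered; output is sorted
#' by the normal dataset's adjusted p, ascending.
#'
#' @param results_normal,results_rescue moderated-test result data.frames.
#' @param profiles codon-frequency matrix over the full gene universe.
#' @param codons codon set defining the biased class (default AAA, CAA,
#'   GAA — the codons read by thiolation-dependent tRNAs).
#' @param percentile top-frequency percentage (default 10).
#' @param alpha FDR level (default 0.01).
#' @return data.frame with per-gene criteria flags: `gene_id`,
#'   `top_codons` (comma-joined codons for which the gene is in the top
#'   percentile), `down_normal`, `down_rescue`, `adj_p_normal`,
#'   `adj_p_rescue`.
#' @export
rescue_list <- function(results_normal, results_rescue, profiles,
                        codons = c("AAA", "CAA", "GAA"),
                        percentile = 10, alpha = 0.01) {
  common <- intersect(results_normal$protein_id, results_rescue$protein_id)
  subsets <- lapply(codons, function(cod)
    top_codon_subset(profiles, cod, percentile))
  names(subsets) <- codons
  in_subset <- unique(unlist(subsets))
  a <- results_normal[match(common, results_normal$protein_id), ]
  b <- results_rescue[match(common, results_rescue$protein_id), ]
  down_normal <- a$adj_p <= alpha & a$mean_log2 > 0
  down_rescue <- b$adj_p <= alpha & b$mean_log2 > 0
  keep <- common %in% in_subset & down_normal & !down_rescue
  out <- data.frame(
    gene_id = common[keep],
    top_codons = vapply(common[keep], function(g)
      paste(codons[vapply(subsets, function(s) g %in% s, logical(1))],
            collapse = ","), character(1), USE.NAMES = FALSE),
    down_normal = rep(TRUE, sum(keep)),
    down_rescue = rep(FALSE, sum(keep)),
    adj_p_normal = a$adj_p[keep],
    adj_p_rescue = b$adj_p[keep],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[order(out$adj_p_normal, out$gene_id), , drop = FALSE]
}
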