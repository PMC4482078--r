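#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
NULL

.PEPTIDE_COLS <- c("peptide_id", "protein_id", "replicate_id",
                   "design", "log2_hl", "probability")
.TRUTH_COLS <- c("protein_id", "true_log2_ratio", "bias_class",
                 "copies_per_cell", "n_peptides")
.RESULT_COLS <- c("protein_id", "mean_log2", "n_reps", "sample_var",
                  "posterior_var", "t", "p", "adj_p", "call")

# 17 significant digits make the write/read round trip lossless for
# doubles.
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  out <- df
  out[is_num] <- lapply(df[is_num], .fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "", check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Read a coding-sequence FASTA file
#'
#' Sequences are upper-cased and restricted to the characters A, C, G, T, N;
#' record ids are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id: ", dup[1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                   substr(seqs[[i]], bad, bad), ids[i], bad))
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.check_columns <- function(df, required, optional = character(0), what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0)
    stop(what, ": unexpected column(s): ", paste(extra, collapse = ", "))
  invisible(df)
}

#' Read a peptide observation table
#'
#' Tab-separated, one header line, one row per peptide observation per
#' replicate. Columns: `peptide_id`, `protein_id`, `replicate_id`, `design`
#' (+1/-1), `log2_hl`, `probability`; an optional `correct` column (the
#' simulation truth flag) is tolerated. Validation is strict: extra columns
#' are rejected, `design` must parse to +1 or -1, `probability` must lie in
#' [0, 1] and `log2_hl` must be finite.
#'
#' @param path TSV path.
#' @return data.frame of peptide observations.
#' @export
read_peptide_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .PEPTIDE_COLS, "correct", "peptide table")
  df$design <- suppressWarnings(as.numeric(df$design))
  bad <- which(is.na(df$design) | !(df$design %in% c(1, -1)))
  if (length(bad) > 0)
    stop("peptide table: design must be +1 or -1 (row ", bad[1], ")")
  df$log2_hl <- as.numeric(df$log2_hl)
  if (any(!is.finite(df$log2_hl)))
    stop("peptide table: non-finite log2_hl (row ",
         which(!is.finite(df$log2_hl))[1], ")")
  df$probability <- as.numeric(df$probability)
  if (any(is.na(df$probability) | df$probability < 0 | df$probability > 1))
    stop("peptide table: probability outside [0, 1] (row ",
         which(is.na(df$probability) | df$probability < 0 |
                 df$probability > 1)[1], ")")
  if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
  for (col in c("peptide_id", "protein_id", "replicate_id"))
    df[[col]] <- as.character(df[[col]])
  df[c(.PEPTIDE_COLS, intersect("correct", names(df)))]
}

#' @rdname read_peptide_table
#' @param table data.frame of peptide observations.
#' @export
write_peptide_table <- function(table, path) {
  .check_columns(table, .PEPTIDE_COLS, c("correct", "oriented"),
                 "peptide table")
  .write_tsv(table[c(.PEPTIDE_COLS, intersect("correct", names(table)))],
             path)
}

#' Read/write the simulation ground-truth table
#'
#' @param path TSV path.
#' @return data.frame with columns `protein_id`, `true_log2_ratio`,
#'   `bias_class`, `copies_per_cell`, `n_peptides`.
#' @export
read_truth_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .TRUTH_COLS, character(0), "truth table")
  df$protein_id <- as.character(df$protein_id)
  df$n_peptides <- as.integer(df$n_peptides)
  df
}

#' @rdname read_truth_table
#' @param table truth data.frame.
#' @export
write_truth_table <- function(table, path) {
  .check_columns(table, .TRUTH_COLS, character(0), "truth table")
  .write_tsv(table[.TRUTH_COLS], path)
}

#' Read/write a protein ratio matrix
#'
#' Serialized as long-format TSV with columns `protein_id`, `replicate_id`,
#' `ratio`, `n_peptides` (one row per non-missing cell).
#'
#' @param path TSV path.
#' @return a `protein_ratio_matrix` (see [protein_ratio_matrix()]).
#' @export
read_ratio_matrix <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("protein_id", "replicate_id", "ratio", "n_peptides"),
                 character(0), "ratio matrix")
  proteins <- sort(unique(as.character(df$protein_id)))
  reps <- sort(unique(as.character(df$replicate_id)))
  ratios <- matrix(NA_real_, length(proteins), length(reps),
                   dimnames = list(proteins, reps))
  support <- matrix(0L, length(proteins), length(reps),
                    dimnames = list(proteins, reps))
  idx <- cbind(match(df$protein_id, proteins), match(df$replicate_id, reps))
  ratios[idx] <- as.numeric(df$ratio)
  support[idx] <- as.integer(df$n_peptides)
  protein_ratio_matrix(ratios, support)
}

#' @rdname read_ratio_matrix
#' @param mat a `protein_ratio_matrix`.
#' @export
write_ratio_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "protein_ratio_matrix"))
  keep <- which(!is.na(mat$ratios), arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  df <- data.frame(
    protein_id = rownames(mat$ratios)[keep[, 1]],
    replicate_id = colnames(mat$ratios)[keep[, 2]],
    ratio = mat$ratios[keep],
    n_peptides = mat$support[keep],
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read/write a moderated-test result table
#'
#' Fixed column order: `protein_id`, `mean_log2`, `n_reps`, `sample_var`,
#' `posterior_var`, `t`, `p`, `adj_p`, `call`. `call` must be one of
#' `up37`, `down37`, `ns`, and `adj_p >= p` must hold row-wise.
#'
#' @param path TSV path.
#' @return data.frame of moderated results.
#' @export
read_result_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .RESULT_COLS, "df", "result table")
  df$protein_id <- as.character(df$protein_id)
  if (!all(df$call %in% c("up37", "down37", "ns")))
    stop("result table: call must be one of up37, down37, ns")
  if (any(df$adj_p < df$p - 1e-12))
    stop("result table: adj_p < p")
  if (!"df" %in% names(df)) df$df <- df$n_reps - 1L
  df
}

#' @rdname read_result_table
#' @param table result data.frame.
#' @export
write_result_table <- function(table, path) {
  .check_columns(table, .RESULT_COLS, "df", "result table")
  .write_tsv(table[.RESULT_COLS], path)
}
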