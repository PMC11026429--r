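# Shared readers/writers and seed plumbing.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never disturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps `(seed, label)` to an integer below 2^31 - 1, so a
#' single pipeline seed yields independent, reproducible per-stage streams
#' without manual bookkeeping.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (v in utf8ToInt(label)) h <- (h * 48271 + v) %% 2147483647
  as.integer(h)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; duplicate record ids are an
#'   error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(set), ids)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a tab-separated table with strict shape checking
#'
#' @param path Path to a TSV with a header row.
#' @return Data frame (character/numeric columns as parsed).
#' @export
read_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L)
    return(data.frame())
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: row ", bad, " of '", path, "' has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data frame as a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
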