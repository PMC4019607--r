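# Shared helpers: alphabet normalization, reverse complement, deterministic
# TSV I/O. All sequence work is done on RNA alphabet (T -> U) uppercase.

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside \code{A,C,G,U,N} raise
#' an error.
#'
#' @param x character vector of sequences (DNA or RNA alphabet).
#' @return character vector over \code{A,C,G,U,N}.
#' @export
as_rna <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("invalid nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  out
}

#' Reverse complement of an RNA string
#'
#' @param x character vector over \code{A,C,G,U,N}.
#' @return reverse complement, RNA alphabet (A<->U, C<->G, N->N).
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Deterministic TSV writers/readers. write_tsv_plain always produces the same
# bytes for the same data frame (fixed eol, no quoting, no row names).
write_tsv_plain <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#", ...)
}

# Split condition labels of the form "<timepoint>_r<k>" into components.
split_condition_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+)_r(\\d+)$", labels))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    stop("condition labels must look like '<timepoint>_r<replicate>'; offending: ",
         paste(labels[!ok], collapse = ", "))
  }
  data.frame(label = labels,
             timepoint = vapply(m, `[`, character(1), 2L),
             replicate = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

# Derive a stage-specific RNG seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
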