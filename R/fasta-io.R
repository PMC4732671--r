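#' Read a FASTA file
#'
#' Parses a (multi-record) FASTA file into a data frame of records. Parsing is
#' done with [Biostrings::readBStringSet()]; before parsing, the file is
#' validated line by line so that malformed headers or illegal characters are
#' reported with their line number.
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet One of `"dna"` (A, C, G, T, N), `"protein"` (IUPAC amino
#'   acids, `*` allowed), or `"any"` (no residue check).
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (uppercase sequence).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT"), f)
#' read_fasta(f, alphabet = "dna")
read_fasta <- function(path, alphabet = c("any", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("FASTA parse error in '", path, "': empty file")

  re <- switch(alphabet,
    dna = "^[ACGTNacgtn]*$",
    protein = "^[ACDEFGHIKLMNPQRSTVWYXBZJUOacdefghiklmnpqrstvwyxbzjuo*]*$",
    any = NULL
  )
  seen_header <- FALSE
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(sub("^>", "", ln))) == 0L)
        stop("FASTA parse error at line ", k, ": empty header")
      seen_header <- TRUE
    } else if (nzchar(trimws(ln))) {
      if (!seen_header)
        stop("FASTA parse error at line ", k, ": sequence before first header")
      if (!is.null(re) && !grepl(re, trimws(ln)))
        stop("FASTA parse error at line ", k, ": illegal character in sequence")
    }
  }
  if (!seen_header) stop("FASTA parse error at line 1: missing '>' header")

  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) warning("duplicated FASTA ids in ", path)
  data.frame(id = ids, seq = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' Writes sequences 60 columns wide. `write_fasta()` followed by
#' [read_fasta()] round-trips ids and sequences exactly.
#'
#' @param records A data frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("a character vector of sequences must be named")
    records <- data.frame(id = names(records), seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
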