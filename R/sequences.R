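#' Read / write named sequence sets as FASTA
#'
#' Sequences are plain named uppercase character vectors; `alphabet`
#' restricts the residue set (`DNA` = ACGT, `RNA` = ACGU). Parsing and
#' serialization are delegated to Biostrings.
#'
#' @param path FASTA path.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_sequences(seqs, alphabet)
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

validate_sequences <- function(seqs, alphabet) {
  ok_chars <- if (alphabet == "DNA") "^[ACGT]+$" else "^[ACGU]+$"
  bad <- names(seqs)[!grepl(ok_chars, seqs)]
  if (length(bad))
    stop(sprintf("sequence(s) with characters outside the %s alphabet: %s",
                 alphabet, paste(head(bad, 3), collapse = ", ")))
  invisible(seqs)
}

#' Alphabet conversions and reverse complement
#'
#' `reverse_complement` operates on DNA; RNA input is converted to DNA
#' first. Vectorized over sequences.
#' @param x character vector of sequences.
#' @return Character vector.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname dna_to_rna
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    rna_to_dna(toupper(x)))))
}
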