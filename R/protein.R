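#' Protein sequence container and FASTA ingestion
#'
#' @param x a FASTA file path, a single FASTA record string (starting with
#'   `>`), or a raw amino-acid sequence string.
#' @param prot_id optional identifier; for FASTA input the header word is
#'   used, for raw strings an id is synthesized.
#' @return a `protein_seq` object: `list(prot_id, sequence)`. The sequence is
#'   uppercased; non-standard symbols are preserved, not stripped.
#' @export
read_protein <- function(x, prot_id = NULL) {
  if (length(x) != 1L || !is.character(x)) stopf("input must be a single string")
  if (!grepl("\n", x) && file.exists(x)) {
    set <- Biostrings::readAAStringSet(x)
    if (length(set) == 0L) stopf("empty FASTA file: %s", x)
    return(protein_seq(prot_id %||% strsplit(names(set)[1L], "[ \t]")[[1L]][1L],
                       as.character(set[[1L]])))
  }
  if (startsWith(trimws(x), ">")) {
    lines <- strsplit(x, "\n")[[1L]]
    hdr <- sub("^>", "", trimws(lines[1L]))
    seq <- paste(trimws(lines[-1L]), collapse = "")
    return(protein_seq(prot_id %||% strsplit(hdr, "[ \t]")[[1L]][1L], seq))
  }
  protein_seq(prot_id %||% "protein1", trimws(x))
}

#' Read all records of a FASTA file
#' @param path FASTA file path.
#' @return list of `protein_seq`.
#' @export
read_proteins <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  lapply(seq_along(set), function(i)
    protein_seq(strsplit(names(set)[i], "[ \t]")[[1L]][1L],
                as.character(set[[i]])))
}

#' @rdname read_protein
#' @param sequence amino-acid string.
#' @export
protein_seq <- function(prot_id, sequence) {
  sequence <- toupper(gsub("[ \t\n]", "", sequence))
  if (nchar(sequence) < 1L) stopf("empty protein sequence")
  structure(list(prot_id = as.character(prot_id), sequence = sequence),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$prot_id, nchar(x$sequence)))
  invisible(x)
}

#' Write protein sequences to FASTA
#' @param prots list of `protein_seq`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(prots, path, width = 70L) {
  out <- unlist(lapply(prots, function(p) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", p$sequence)
    c(paste0(">", p$prot_id), strsplit(body, "\n")[[1L]])
  }))
  writeLines(out, path)
  invisible(path)
}
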