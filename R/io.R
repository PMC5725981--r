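## Standard-format I/O wrappers: FASTA (via Biostrings), TSV outputs, and
## square PHYLIP distance matrices.

#' Read a protein FASTA into a protein table
#'
#' Header grammar: first token = protein id; optional `species=` and
#' `locus=` key tokens. `'*'` stop characters are stripped.
#'
#' @param path FASTA file.
#' @param species Species code applied where the header carries none.
#' @return data.frame `protein_id`, `species`, `locus_id`, `sequence`,
#'   `source = "proteome"`.
#' @export
read_protein_fasta <- function(path, species = "") {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(aa), "[[:space:]]+")
  grab <- function(h, key, default) {
    hit <- grep(paste0("^", key, "="), h, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  data.frame(
    protein_id = vapply(hdr, `[`, "", 1),
    species = vapply(hdr, grab, "", key = "species", default = species),
    locus_id = vapply(hdr, grab, "", key = "locus", default = ""),
    sequence = gsub("*", "", as.character(aa), fixed = TRUE),
    source = "proteome", stringsAsFactors = FALSE)
}

#' Read a nucleotide FASTA into a transcript table
#'
#' @inheritParams read_protein_fasta
#' @return data.frame `transcript_id`, `species`, `sequence` (U normalized
#'   to T).
#' @export
read_transcript_fasta <- function(path, species = "") {
  nt <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(nt), "[[:space:]]+")
  grab <- function(h, key, default) {
    hit <- grep(paste0("^", key, "="), h, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  data.frame(
    transcript_id = vapply(hdr, `[`, "", 1),
    species = vapply(hdr, grab, "", key = "species", default = species),
    sequence = chartr("Uu", "Tt", as.character(nt)),
    stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a protein/transcript table (the
#'   id column and `species`/`locus_id` are folded into the headers).
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.data.frame(seqs)) {
    idcol <- intersect(c("protein_id", "transcript_id"), names(seqs))[1]
    hdr <- seqs[[idcol]]
    if ("species" %in% names(seqs))
      hdr <- paste0(hdr, " species=", seqs$species)
    if ("locus_id" %in% names(seqs) && any(nzchar(seqs$locus_id)))
      hdr <- ifelse(nzchar(seqs$locus_id),
                    paste0(hdr, " locus=", seqs$locus_id), hdr)
    seqs <- stats::setNames(seqs$sequence, hdr)
  }
  xs <- if (type == "AA") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

#' Write a table as TSV
#' @param x data.frame or matrix.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Square PHYLIP distance-matrix I/O
#'
#' @param d Symmetric labeled distance matrix.
#' @param path File path.
#' @return `read_phylip_dist` returns the matrix; `write_phylip_dist` the
#'   path, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i],
                       formatC(d[i, ], format = "f", digits = 6)),
                     collapse = "  "), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labs <- vapply(rows, `[`, "", 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}
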