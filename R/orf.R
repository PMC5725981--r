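## Longest-ORF extraction from transcripts (Transdecoder-like stand-in).

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Extract the longest open reading frame of a transcript
#'
#' Scans all six reading frames. In `"atg"` mode (the default) an ORF runs
#' from an ATG to the first in-frame stop codon or the sequence end; in
#' `"stop"` mode ORFs are maximal stop-free codon runs from the frame start.
#' The longest ORF wins; ties are broken by frame order (+1, +2, +3, -1, -2,
#' -3), then by the 5'-most start within the frame.
#'
#' @param sequence Nucleotide string (ACGTUN; U is normalized to T).
#' @param min_aa Minimum peptide length to report (default 100, the usual
#'   transdecoding cutoff).
#' @param mode `"atg"` (ATG-initiated) or `"stop"` (stop-to-stop).
#' @return `NULL` if no ORF reaches `min_aa`; otherwise a list with
#'   `peptide`, `frame` (e.g. `"+2"`), `start` and `end` (nucleotide
#'   positions within the frame's reading direction, stop codon excluded).
#' @export
#' @examples
#' extract_longest_orf("ATGAAATGA", min_aa = 2)$peptide  # "MK"
extract_longest_orf <- function(sequence, min_aa = 100,
                                mode = c("atg", "stop")) {
  mode <- match.arg(mode)
  stopifnot(min_aa >= 1)
  if (!nzchar(sequence)) stop("empty transcript sequence")
  s <- chartr("u", "t", tolower(sequence))
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) stop("transcript alphabet must be ACGTUN")
  frames <- list(`+1` = c(s, 1), `+2` = c(s, 2), `+3` = c(s, 3),
                 `-1` = c(revcomp(s), 1), `-2` = c(revcomp(s), 2),
                 `-3` = c(revcomp(s), 3))
  best <- NULL
  for (fr in names(frames)) {
    seq_f <- frames[[fr]][1]
    off <- as.integer(frames[[fr]][2])
    n_cod <- (nchar(seq_f) - off + 1L) %/% 3L
    if (n_cod < 1) next
    starts <- off + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq_f, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    orf_starts <- if (mode == "atg") which(codons == "ATG") else {
      stops <- which(is_stop)
      sort(unique(setdiff(c(1L, stops + 1L), stops)))
    }
    orf_starts <- orf_starts[orf_starts <= n_cod & !is_stop[orf_starts]]
    for (i in orf_starts) {
      nxt <- which(is_stop & seq_len(n_cod) > i)
      stop_at <- if (length(nxt)) min(nxt) else n_cod + 1L
      len <- stop_at - i
      if (is.null(best) || len > best$len) {
        pep <- paste(translate_codons(codons[i:(stop_at - 1L)]),
                     collapse = "")
        best <- list(peptide = pep, frame = fr,
                     start = starts[i],
                     end = starts[stop_at - 1L] + 2L, len = len)
      }
    }
  }
  if (is.null(best) || best$len < min_aa) return(NULL)
  best$len <- NULL
  best
}

#' Transdecode a set of transcripts into predicted proteins
#'
#' Applies [extract_longest_orf()] to each transcript; transcripts with no
#' qualifying ORF are dropped.
#'
#' @param transcripts data.frame with columns `transcript_id`, `species`,
#'   `sequence`.
#' @param min_aa,mode Passed to [extract_longest_orf()].
#' @return Protein data.frame (`protein_id` = `<transcript_id>.p1`,
#'   `species`, `locus_id`, `sequence`, `source = "transdecoded"`).
#' @export
transdecode <- function(transcripts, min_aa = 100, mode = "atg") {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    orf <- extract_longest_orf(transcripts$sequence[i], min_aa, mode)
    if (is.null(orf)) return(NULL)
    data.frame(protein_id = paste0(transcripts$transcript_id[i], ".p1"),
               species = transcripts$species[i],
               locus_id = transcripts$transcript_id[i],
               sequence = orf$peptide, source = "transdecoded",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), species = character(0),
                      locus_id = character(0), sequence = character(0),
                      source = character(0), stringsAsFactors = FALSE)
  out
}
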