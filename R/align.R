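## Pairwise global alignment of SET domains and homology-based family
## assignment (the fallback route for bare-SET / unmatched architectures).

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y")
}

check_aa <- function(s, what = "sequence") {
  if (!nzchar(s)) stop(what, " is empty")
  bad <- setdiff(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                 c(aa_alphabet(), "X"))
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ""))
  invisible(TRUE)
}

get_submat <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment of two amino-acid sequences
#'
#' Needleman-Wunsch with a substitution matrix and affine gap penalties
#' (defaults BLOSUM62, gap open 10, gap extend 0.5). Identity is the
#' fraction of matching residues over aligned columns excluding terminal
#' gaps; coverage is the fraction of the shorter sequence that is aligned to
#' a residue of the other.
#'
#' @param a,b Amino-acid strings (standard 20 letters plus X).
#' @param substitution Matrix name (`"BLOSUM62"`, `"BLOSUM50"`, ...) or a
#'   substitution matrix.
#' @param gap_open,gap_extend Non-negative gap penalties (a gap of length k
#'   costs `gap_open + k * gap_extend`).
#' @return List with `score`, `identity`, `coverage`, and the two aligned
#'   strings `aligned_a`, `aligned_b`.
#' @export
#' @examples
#' global_align("HEAGAWGHEE", "PAWHEAE", substitution = "BLOSUM50",
#'               gap_open = 0, gap_extend = 8)$score
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  check_aa(a, "sequence a")
  check_aa(b, "sequence b")
  a <- toupper(a); b <- toupper(b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = get_submat(substitution),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  st <- aln_stats(al_a, al_b, min(nchar(a), nchar(b)))
  list(score = Biostrings::score(pa), identity = st[["identity"]],
       coverage = st[["coverage"]], aligned_a = al_a, aligned_b = al_b)
}

## identity over aligned columns excluding terminal gaps; coverage over the
## shorter sequence
aln_stats <- function(al_a, al_b, shorter) {
  ca <- strsplit(al_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  gap <- ca == "-" | cb == "-"
  inner <- which(!gap)
  identity <- if (length(inner)) {
    span <- seq(min(inner), max(inner))
    sum(ca[span] == cb[span] & !gap[span]) / length(span)
  } else 0
  c(identity = identity, coverage = sum(!gap) / shorter)
}

## one query against many subjects in a single pairwiseAlignment call
align_many <- function(query, subjects, substitution = "BLOSUM62",
                       gap_open = 10, gap_extend = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    substitutionMatrix = get_submat(substitution),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  ap <- as.character(Biostrings::alignedPattern(pa))
  aq <- as.character(Biostrings::alignedSubject(pa))
  st <- t(vapply(seq_along(subjects), function(k)
    aln_stats(ap[k], aq[k], min(nchar(subjects[k]), nchar(query))),
    numeric(2)))
  data.frame(score = Biostrings::score(pa), identity = st[, "identity"],
             coverage = st[, "coverage"],
             aligned_subject = ap, aligned_query = aq,
             stringsAsFactors = FALSE)
}

#' Read a SET-domain reference set from FASTA
#'
#' Headers are parsed as `name family species` (whitespace-separated), e.g.
#' `>CLF E(z) At`.
#'
#' @param path FASTA file of reference SET-domain sequences (typically
#'   Arabidopsis and rice).
#' @return data.frame with columns `name`, `family`, `species`, `sequence`.
#' @export
read_reference_set <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(aa), "[[:space:]]+")
  refs <- data.frame(
    name = vapply(hdr, `[`, "", 1),
    family = vapply(hdr, function(h) if (length(h) > 1) h[2] else "", ""),
    species = vapply(hdr, function(h) if (length(h) > 2) h[3] else "", ""),
    sequence = as.character(aa), stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  if (anyDuplicated(refs$name)) stop("duplicate reference names")
  len <- nchar(refs$sequence)
  if (any(len < 100 | len > 200))
    warning("reference SET domains outside the usual 100-200 aa range: ",
            paste(refs$name[len < 100 | len > 200], collapse = ", "))
  refs
}

#' Assign a family to a SET domain by homology to references
#'
#' Aligns the query against every reference, keeps references with coverage
#' at or above `min_coverage`, and takes the best identity (ties broken by
#' alignment score, then reference name order). The reference's family is
#' returned if its identity reaches `threshold`.
#'
#' @param query SET-domain amino-acid string.
#' @param refs Reference set (see [read_reference_set()]); must be nonempty.
#' @param threshold Identity threshold in `[0, 1]` (default 0.3 over the SET
#'   domain).
#' @param min_coverage Minimum coverage of the shorter sequence (default 0.8).
#' @param ... Alignment parameters passed to [global_align()].
#' @return List with `family` (`NA` if below threshold), `name`, `identity`,
#'   `score` of the nearest eligible reference (`name` is `NA` only if no
#'   reference passes the coverage gate).
#' @export
assign_family_by_homology <- function(query, refs, threshold = 0.3,
                                      min_coverage = 0.8, ...) {
  stopifnot(nrow(refs) > 0)
  check_aa(query, "query")
  res <- align_many(toupper(query), toupper(refs$sequence), ...)
  identity <- res$identity
  score <- res$score
  coverage <- res$coverage
  ok <- which(coverage >= min_coverage)
  if (!length(ok))
    return(list(family = NA_character_, name = NA_character_,
                identity = NA_real_, score = NA_real_))
  best <- ok[order(-identity[ok], -score[ok], refs$name[ok])][1]
  list(family = if (identity[best] >= threshold) refs$family[best]
       else NA_character_,
       name = refs$name[best], identity = identity[best],
       score = score[best])
}
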