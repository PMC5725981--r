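#' The 16 Archaeplastida species panel
#'
#' Returns the species panel used throughout: two/three-letter code, lineage
#' group, evolutionary rank (1 = earliest-diverging, glaucophyta, through
#' 16 = eudicot) and binomial. Read from a tab-separated config so alternative
#' panels can be supplied.
#'
#' @param path Path to a lineage config TSV with columns `code`, `rank`,
#'   `lineage`, `species`. Defaults to the bundled 16-species panel.
#' @return A data.frame with columns `code`, `rank`, `lineage`, `species`,
#'   ordered by `rank`.
#' @export
#' @examples
#' set_species()$code
set_species <- function(path = system.file("extdata", "lineage.tsv",
                                           package = "setfam")) {
  stopifnot(file.exists(path))
  sp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "rank", "lineage", "species")
  if (!all(need %in% names(sp)))
    stop("lineage config must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sp$code))
    stop("duplicate species codes in lineage config")
  if (!setequal(sp$rank, seq_len(nrow(sp))))
    stop("lineage ranks must be a permutation of 1..", nrow(sp))
  sp[order(sp$rank), , drop = FALSE]
}

#' Species codes in evolutionary (lineage) order
#'
#' @inheritParams set_species
#' @return Character vector of species codes, earliest-diverging first.
#' @export
lineage_order <- function(path = system.file("extdata", "lineage.tsv",
                                             package = "setfam")) {
  set_species(path)$code
}

# Presence columns in the tables are printed in reverse-ish order
# (At first, Cp last); this is the canonical table column order.
table_species_order <- function() {
  c("At", "Os", "Pa", "Sm", "Pp", "Mp", "Nm", "Kf",
    "Mr", "Mpu", "Ot", "Ol", "Cv", "Cr", "Vc", "Cp")
}

check_species_codes <- function(codes, panel = set_species()) {
  bad <- setdiff(codes, panel$code)
  if (length(bad))
    stop("unknown species code(s): ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}
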