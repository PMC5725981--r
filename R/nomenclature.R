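## Naming: nearest Arabidopsis/rice homolog name + lowercase species code,
## with letter suffixes when several proteins share the same nearest homolog.

suffix_letter <- function(i) {
  ## 1 -> "a", 26 -> "z", 27 -> "aa", ... (bijective base 26)
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(letters[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

base_name <- function(ref_name, species) {
  nm <- paste0(toupper(substr(ref_name, 1, 1)),
               substr(ref_name, 2, nchar(ref_name)))
  paste0(nm, tolower(species))
}

#' Name one protein after its nearest reference homolog
#'
#' The name is the capitalized homolog name followed by the species code in
#' lower case (e.g. nearest reference `SDG8` in Chlamydomonas reinhardtii
#' gives `SDG8cr`). If the base name is already taken within the species, a
#' hyphenated letter suffix is appended (`-a`, `-b`, ..., `-aa`, ...) in
#' assignment order.
#'
#' @param ref_name Name of the nearest Arabidopsis/rice reference.
#' @param species Species code (e.g. `"Cr"`).
#' @param taken_names Names already assigned within the species.
#' @return A single name not present in `taken_names`.
#' @export
name_protein <- function(ref_name, species, taken_names = character()) {
  base <- base_name(ref_name, species)
  if (!base %in% taken_names) return(base)
  i <- 1
  repeat {
    cand <- paste0(base, "-", suffix_letter(i))
    if (!cand %in% taken_names) return(cand)
    i <- i + 1
  }
}

#' Name a classified protein set
#'
#' Batch naming: proteins of the same species sharing the same nearest
#' reference all receive suffixes (`SDG8cr-a`, `SDG8cr-b`, ...) in input
#' order; a protein whose base name is unique within its species keeps the
#' bare name. Deterministic given the input order, and injective within a
#' species.
#'
#' @param classified A `set_classification` (needs `nearest_ref` filled for
#'   fallback rows) or any data.frame with `protein_id`, `species` and
#'   `nearest_ref` columns.
#' @param ref_names Optional named character vector protein_id -> reference
#'   name, overriding/completing the `nearest_ref` column (exact-match rows
#'   typically get their reference from the family's canonical homolog).
#' @return data.frame `protein_id`, `species`, `name`, `nearest_ref`.
#' @export
name_proteins <- function(classified, ref_names = NULL) {
  refs <- classified$nearest_ref
  if (!is.null(ref_names)) {
    idx <- match(classified$protein_id, names(ref_names))
    refs[!is.na(idx)] <- ref_names[idx[!is.na(idx)]]
  }
  refs[is.na(refs) | !nzchar(refs)] <- "SDG"  # generic SET-domain-group stem
  base <- base_name(refs, classified$species)
  key <- paste(classified$species, base, sep = "\r")
  n_in_group <- ave(seq_along(key), key, FUN = length)
  idx_in_group <- ave(seq_along(key), key, FUN = seq_along)
  name <- ifelse(n_in_group == 1, base,
                 paste0(base, "-", suffix_letter(idx_in_group)))
  data.frame(protein_id = classified$protein_id,
             species = classified$species, name = name,
             nearest_ref = refs, stringsAsFactors = FALSE)
}
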