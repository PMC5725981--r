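## The core procedure: map an ordered domain architecture to a hierarchical
## family label (class / subclass / subdivision) through the rule catalog,
## with a Class V signature check and a homology fallback for bare-SET and
## unmatched architectures.

empty_label <- function() {
  list(id = NA_character_, family = NA_character_, class_code = NA_character_,
       subclass = "", subdivision = "", classv_kind = "",
       family_orphan = FALSE)
}

label_fields <- function(id) {
  if (endsWith(id, "-Orphan") || id %in% c("V-SETD", "V-TPR"))
    return(parse_label_id(id))
  parse_label_id(id)
}

bigram_family_class <- function(sig) {
  set_pos <- which(sig == "SET")
  if (!length(set_pos)) return(NA_character_)
  before <- sig[seq_len(min(set_pos) - 1)]
  if ("AWS" %in% sig) return("II")
  if (any(c("SRA", "WIYLD") %in% sig)) return("IV")
  if ("PreSET" %in% before && !"SRA" %in% sig) return("IV")
  if (any(c("PWWP", "PHD", "FYR") %in% before)) return("III")
  NA_character_
}

#' Classify a domain architecture against the rule catalog
#'
#' The procedure: (1) strip extras (domains outside the class I-IV backbone
#' vocabulary) to get the signature architecture; (2) exact-match the
#' signature against the catalog backbones; (3) otherwise check the Class V
#' signatures (a Rubisco-LSMT substrate-binding domain makes a SETD, TPR
#' repeats without canonical family domains make a TPR); (4) otherwise the
#' label is deferred to the homology fallback and a provisional Orphan label
#' is returned with `match_kind = "fallback_homology"` (a family-diagnostic
#' bigram, when present, pre-selects the family's Orphan subgroup).
#'
#' Repeat counts are significant: `PHD-AWS-SET` and `PHD-PHD-PHD-AWS-SET`
#' are different entries. Exact matching cannot be ambiguous except where
#' the catalog itself declares a duplicated backbone; there the first entry
#' in table order is returned and all candidates are listed in the
#' `candidates` field.
#'
#' @param arch Character vector of canonical domain names, N->C (see
#'   [build_architecture()]).
#' @param catalog A `set_catalog` (default the bundled one).
#' @return A label list: `id`, `family`, `class_code`, `subclass`,
#'   `subdivision`, `classv_kind`, `family_orphan`, `match_kind`
#'   (`"exact"`, `"classv"` or `"fallback_homology"`), `signature`, `extras`
#'   and `candidates` (ids sharing the matched backbone).
#' @export
#' @examples
#' classify_architecture(c("AWS", "SET"))$id               # "II-1A"
#' classify_architecture(c("SRA", "PreSET", "SET", "SET"))$id  # "IV-1C"
classify_architecture <- function(arch, catalog = default_catalog()) {
  vocab <- signature_vocabulary(catalog)
  sig <- arch[arch %in% vocab]
  extras <- arch[!arch %in% vocab]
  has_set <- "SET" %in% arch
  has_tpr <- "TPR" %in% arch
  if (!has_set && !has_tpr)
    stop("not a SET-pathway protein: architecture [",
         architecture_string(arch), "] has neither SET nor TPR")
  out <- function(id, match_kind, candidates = id) {
    c(label_fields(id),
      list(match_kind = match_kind, signature = sig, extras = extras,
           candidates = candidates))
  }
  ## (2) exact backbone match (class I-IV, non-orphan rows)
  exact <- which(vapply(catalog, function(e)
    !e$orphan && e$class_code != "V" && identical(e$backbone, sig), NA))
  if (length(exact)) {
    ids <- vapply(catalog[exact], `[[`, "", "id")
    return(out(ids[1], "exact", candidates = ids))
  }
  ## (3) Class V signatures
  if ("Rubis_subs_bind" %in% arch) return(out("V-SETD", "classv"))
  if (has_tpr && !any(arch %in% setdiff(vocab, "SET")))
    return(out("V-TPR", "classv"))
  if (!has_set)
    stop("not a SET-pathway protein: architecture [",
         architecture_string(arch), "] has neither SET nor TPR")
  ## (4) provisional Orphan, to be resolved by homology
  cls <- bigram_family_class(sig)
  id <- if (is.na(cls)) "V-Orphan" else paste0(cls, "-Orphan")
  out(id, "fallback_homology")
}

family_to_orphan_id <- function(family) {
  switch(family, "Ash" = "II-Orphan", "Trx" = "III-Orphan",
         "Su(var)" = "IV-Orphan", NA_character_)
}

#' Classify a set of proteins end to end
#'
#' Builds each protein's architecture from its hits (interrupted SET hits
#' are merged first), applies [classify_architecture()], and resolves
#' proteins deferred to the fallback by aligning their SET-domain
#' subsequence against the reference set: a nearest family at or above the
#' identity threshold yields that family's Orphan subgroup (Ash, Trx or
#' Su(var) only -- the E(z) class has no Orphan subgroup); otherwise the
#' architecture's diagnostic bigram, if any, decides; otherwise the protein
#' is a Class V Orphan. Declared-ambiguous exact matches are also resolved
#' by homology when references are available.
#'
#' @param proteins Candidate protein data.frame (`protein_id`, `species`,
#'   `sequence`, ...).
#' @param hits Hit data.frame covering the proteins.
#' @param catalog A `set_catalog`.
#' @param references Reference set data.frame (see [read_reference_set()]);
#'   required when any protein needs the fallback.
#' @param threshold,min_coverage Passed to [assign_family_by_homology()].
#' @return A `set_classification` data.frame with one row per input protein:
#'   architecture and signature strings, label fields, `match_kind`,
#'   `extras`, the SET subsequence, and the nearest reference (name and
#'   identity) where homology was consulted.
#' @export
classify_all <- function(proteins, hits, catalog = default_catalog(),
                         references = NULL, threshold = 0.3,
                         min_coverage = 0.8) {
  hits <- merge_interrupted_set(hits)
  setseqs <- set_domain_sequences(proteins, hits)
  rows <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$protein_id[i]
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    arch <- build_architecture(h)
    lab <- classify_architecture(arch, catalog)
    nearest <- list(name = NA_character_, identity = NA_real_)
    setseq <- if (pid %in% names(setseqs)) setseqs[[pid]] else NA_character_
    if (lab$match_kind == "fallback_homology") {
      if (is.null(references) || !nrow(references))
        stop("protein ", pid, " needs the homology fallback but no ",
             "references were supplied")
      if (is.na(setseq))
        stop("protein ", pid, " has no SET hit to extract for homology")
      hom <- assign_family_by_homology(setseq, references, threshold,
                                       min_coverage)
      nearest <- hom
      orphan_id <- if (!is.na(hom$family))
        family_to_orphan_id(hom$family) else NA_character_
      final_id <- if (!is.na(orphan_id)) orphan_id else lab$id
      mk <- if (startsWith(final_id, "V-")) "classv" else "fallback_homology"
      lab <- c(label_fields(final_id),
               list(match_kind = mk, signature = lab$signature,
                    extras = lab$extras, candidates = final_id))
    } else if (lab$match_kind == "exact" && length(lab$candidates) > 1 &&
               !is.null(references) && nrow(references) && !is.na(setseq)) {
      ## declared-duplicate backbone: let SET homology pick among candidates
      cand_fams <- vapply(lab$candidates,
                          function(id) parse_label_id(id)$family, "")
      hom <- assign_family_by_homology(
        setseq, references[references$family %in% cand_fams, , drop = FALSE],
        threshold, min_coverage)
      nearest <- hom
      if (!is.na(hom$family)) {
        pick <- lab$candidates[match(hom$family, cand_fams)]
        lab <- c(label_fields(pick),
                 list(match_kind = "exact", signature = lab$signature,
                      extras = lab$extras, candidates = lab$candidates))
      }
    } else if (lab$match_kind == "classv") {
      lab$match_kind <- "classv"
    }
    rows[[i]] <- data.frame(
      protein_id = pid, species = proteins$species[i],
      length = nchar(proteins$sequence[i]),
      architecture = architecture_string(arch),
      signature = architecture_string(lab$signature),
      extras = paste(lab$extras, collapse = ","),
      label = lab$id, family = lab$family, class_code = lab$class_code,
      subclass = lab$subclass, subdivision = lab$subdivision,
      classv_kind = lab$classv_kind, family_orphan = lab$family_orphan,
      match_kind = lab$match_kind,
      candidates = paste(lab$candidates, collapse = ","),
      set_sequence = setseq,
      nearest_ref = nearest$name, ref_identity = nearest$identity,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), species = character(0),
                      length = integer(0), architecture = character(0),
                      signature = character(0), extras = character(0),
                      label = character(0), family = character(0),
                      class_code = character(0), subclass = character(0),
                      subdivision = character(0), classv_kind = character(0),
                      family_orphan = logical(0), match_kind = character(0),
                      candidates = character(0), set_sequence = character(0),
                      nearest_ref = character(0), ref_identity = numeric(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("set_classification", "data.frame")
  out
}

#' @export
print.set_classification <- function(x, ...) {
  cat("SET-domain classification:", nrow(x), "proteins\n")
  if (nrow(x)) {
    print(table(family = x$family))
    print(table(match = x$match_kind))
  }
  invisible(x)
}

#' @export
summary.set_classification <- function(object, ...) {
  if (!nrow(object)) return(invisible(object))
  tab <- table(label = object$label, species = object$species)
  print(tab)
  invisible(tab)
}
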