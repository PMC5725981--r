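## Comparative outputs: per-class per-species counts, phyletic
## presence/absence matrices, earliest lineage appearance of domains, and
## the inclusion filter for phylogeny.

set_families <- function() c("E(z)", "Ash", "Trx", "Su(var)", "ClassV")

#' Per-species family counts
#'
#' Tallies classified proteins into a species x family matrix (rows in
#' lineage order, columns E(z), Ash, Trx, Su(var), ClassV). Row sums equal
#' per-species totals and the grand total equals the input count.
#'
#' @param classified A `set_classification`.
#' @param panel Species panel from [set_species()].
#' @return Integer matrix, 16 x 5.
#' @export
count_by_class_species <- function(classified, panel = set_species()) {
  m <- matrix(0L, nrow = nrow(panel), ncol = length(set_families()),
              dimnames = list(panel$code, set_families()))
  if (nrow(classified)) {
    check_species_codes(classified$species, panel)
    tab <- table(classified$species, classified$family)
    m[rownames(tab), colnames(tab)] <- tab
  }
  m
}

#' Phyletic presence/absence matrix of one family
#'
#' One row per catalog entry of the family (table order, Orphan row
#' included), one column per species; a cell is `TRUE` iff at least one
#' protein of that species carries that label.
#'
#' @param classified A `set_classification`.
#' @param family One of `"E(z)"`, `"Ash"`, `"Trx"`, `"Su(var)"`.
#' @param catalog A `set_catalog` (supplies the row set and column order).
#' @return Logical matrix (catalog entry ids x species codes).
#' @export
presence_matrix <- function(classified, family,
                            catalog = default_catalog()) {
  stopifnot(family %in% c("E(z)", "Ash", "Trx", "Su(var)"))
  species <- attr(catalog, "species")
  ids <- vapply(catalog, `[[`, "", "id")
  fams <- vapply(catalog, `[[`, "", "family")
  rows <- ids[fams == family]
  m <- matrix(FALSE, nrow = length(rows), ncol = length(species),
              dimnames = list(rows, species))
  sub <- classified[classified$label %in% rows, , drop = FALSE]
  for (i in seq_len(nrow(sub)))
    m[sub$label[i], sub$species[i]] <- TRUE
  m
}

#' Transcribed presence/absence matrix of one family
#'
#' The matrix as printed in the classification tables (what
#' [presence_matrix()] should reproduce on data generated from it).
#'
#' @inheritParams presence_matrix
#' @return Logical matrix (catalog entry ids x species codes).
#' @export
catalog_presence <- function(family, catalog = default_catalog()) {
  species <- attr(catalog, "species")
  keep <- vapply(catalog, `[[`, "", "family") == family
  rows <- catalog[keep]
  m <- do.call(rbind, lapply(rows, `[[`, "presence"))
  rownames(m) <- vapply(rows, `[[`, "", "id")
  colnames(m) <- species
  m
}

#' Earliest lineage appearance of a domain
#'
#' Finds the earliest-diverging species (minimum lineage rank) in which the
#' given domain occurs, optionally restricted to one family. Works either on
#' a classified protein set (domain occurrence read from architectures) or
#' directly on the rule catalog (occurrence read from backbones + recorded
#' extras, presence from the transcribed +/- strings).
#'
#' @param x A `set_classification` or a `set_catalog`.
#' @param domain Canonical domain name (e.g. `"PostSET"`, `"SRA"`).
#' @param context_class Family name or `"any"`.
#' @param panel Species panel (gives lineage ranks and groups).
#' @param ... Unused.
#' @return `NULL` if the domain occurs nowhere in context; otherwise a list
#'   with `domain`, `context`, `species`, `lineage`, `rank`.
#' @export
earliest_appearance <- function(x, domain, context_class = "any",
                                panel = set_species(), ...) {
  UseMethod("earliest_appearance")
}

first_by_rank <- function(species, domain, context_class, panel) {
  species <- intersect(panel$code, unique(species))
  if (!length(species)) return(NULL)
  ranks <- panel$rank[match(species, panel$code)]
  s <- species[which.min(ranks)]
  list(domain = domain, context = context_class, species = s,
       lineage = panel$lineage[match(s, panel$code)],
       rank = min(ranks))
}

#' @rdname earliest_appearance
#' @export
earliest_appearance.set_classification <- function(x, domain,
                                                   context_class = "any",
                                                   panel = set_species(),
                                                   ...) {
  sub <- if (identical(context_class, "any")) x
         else x[x$family == context_class, , drop = FALSE]
  has <- vapply(strsplit(sub$architecture, "-", fixed = TRUE),
                function(a) domain %in% a, NA)
  first_by_rank(sub$species[has], domain, context_class, panel)
}

#' @rdname earliest_appearance
#' @export
earliest_appearance.set_catalog <- function(x, domain,
                                            context_class = "any",
                                            panel = set_species(), ...) {
  keep <- vapply(x, function(e) {
    (identical(context_class, "any") || e$family == context_class) &&
      (domain %in% e$backbone || domain %in% e$extras)
  }, NA)
  species <- unlist(lapply(x[keep], function(e)
    names(e$presence)[e$presence]))
  first_by_rank(species, domain, context_class, panel)
}

#' Select proteins for phylogenetic analysis
#'
#' The tree is built from the four canonical families only: Class V
#' (Orphan, SETD, TPR) and the per-family Orphan members are excluded for
#' low sequence similarity, keeping exactly the exact-architecture-match
#' class I-IV proteins. Set `include_family_orphans = TRUE` to retain
#' family-level Orphans.
#'
#' @param classified A `set_classification`.
#' @param include_family_orphans Keep II/III/IV-Orphan members too.
#' @return The retained subset, input order preserved.
#' @export
phylogeny_input_filter <- function(classified,
                                   include_family_orphans = FALSE) {
  keep <- classified$class_code %in% c("I", "II", "III", "IV") &
    (classified$match_kind == "exact" |
       (include_family_orphans & classified$family_orphan))
  out <- classified[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
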