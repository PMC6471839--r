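#' Generate a random strain-level taxonomy
#'
#' Builds a balanced taxonomy with \code{n_genera} genera (grouped into
#' families, one family per genus by default), \code{species_per_genus}
#' species each and \code{strains_per_species} strains per species.
#' Names are synthetic but unique within each rank.
#'
#' @param n_genera,species_per_genus,strains_per_species positive counts.
#' @param seed integer random seed (names are deterministic given it).
#' @return data.frame with one row per strain and columns
#'   \code{family}, \code{genus}, \code{species}, \code{strain}.
#' @export
build_taxonomy <- function(n_genera, species_per_genus, strains_per_species,
                           seed = 1L) {
  if (any(c(n_genera, species_per_genus, strains_per_species) < 1))
    stopf("all taxonomy counts must be >= 1")
  with_seed(seed, {
    genus <- sprintf("Genus%02d", seq_len(n_genera))
    family <- sprintf("Family%02d", seq_len(n_genera))
    rows <- expand.grid(sp = seq_len(species_per_genus),
                        g = seq_len(n_genera))[, 2:1]
    species <- sprintf("%s_sp%02d", genus[rows$g], rows$sp)
    out <- expand.grid(st = seq_len(strains_per_species),
                       i = seq_along(species))[, 2:1]
    data.frame(
      family = family[rows$g][out$i],
      genus = genus[rows$g][out$i],
      species = species[out$i],
      strain = sprintf("%s_str%02d", species[out$i], out$st),
      stringsAsFactors = FALSE)
  })
}

#' Assemble a taxonomy table from explicit lineages
#'
#' Convenience constructor used by the infant-community preset and by
#' tests: takes per-strain lineages and validates rank consistency
#' (every strain has exactly one species/genus/family ancestor).
#'
#' @param family,genus,species,strain equal-length character vectors.
#' @return taxonomy data.frame as in \code{\link{build_taxonomy}}.
#' @export
taxonomy_table <- function(family, genus, species, strain) {
  tx <- data.frame(family = family, genus = genus, species = species,
                   strain = strain, stringsAsFactors = FALSE)
  validate_taxonomy(tx)
  tx
}

validate_taxonomy <- function(tx) {
  if (anyDuplicated(tx$strain))
    stopf("strain names must be unique")
  for (child in c("strain", "species", "genus")) {
    parent <- TAX_RANKS[match(child, TAX_RANKS) - 1L]
    map <- unique(tx[, c(child, parent)])
    if (anyDuplicated(map[[child]]))
      stopf("rank '%s' has members with more than one '%s' ancestor",
            child, parent)
  }
  invisible(tx)
}

# ancestor taxon of each strain at a given rank
strain_rank <- function(taxonomy, strains, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  taxonomy[[rank]][match(strains, taxonomy$strain)]
}
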