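# Shared in-code fixtures: the canonical toy world plus small builders.

toy_world <- function() {
  toy <- toy_reference_db()
  toy$db <- genome_db(toy$organisms, toy$annotations)
  toy$ref <- ref_taxonomy(toy$taxonomy)
  toy
}

# a 5-taxon reference taxonomy for reconciliation unit tests
tiny_ref <- function() {
  ref_taxonomy(tibble::tibble(
    taxon_name = c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
                   "Planococcaceae"),
    rank = c("kingdom", "phylum", "class", "order", "family"),
    parent_name = c(NA, "Bacteria", "Firmicutes", "Bacilli", "Bacillales"),
    parent_rank = c(NA, "kingdom", "phylum", "class", "order")))
}

gg <- function(...) paste(..., sep = "; ")

random_world <- function(seed, n_otus = 80, n_samples = 4, ...) {
  cfg <- fixture_config(seed = seed, n_otus = n_otus,
                        n_samples = n_samples, ...)
  w <- generate_reference_db(cfg)
  w$cfg <- cfg
  w$db <- genome_db(w$organisms, w$annotations)
  w$ref <- ref_taxonomy(w$taxonomy)
  w
}

profile_as_matrix <- function(fs) {
  smp <- sample_ids(fs)
  m <- as.matrix(fs[, smp])
  rownames(m) <- fs$ko_term
  m
}

# lineage as a bare named character vector (class and flags stripped)
bare <- function(lin) setNames(as.character(lin), names(lin))
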