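# Shared builders for small in-code fixtures.

profile_from_counts <- function(counts, entity_kind = "mRNA") {
  normalize_to_pool(tibble::tibble(id = names(counts),
                                   abundance = as.numeric(counts)),
                    pool_total = sum(counts), entity_kind = entity_kind)
}

interactions_from <- function(...) {
  as_interaction_table(tibble::tibble(...))
}

# a minimal 2-gene / 2-family system with one strong and one weak pair
toy_system <- function(p_strong = -6, p_weak = -0.5) {
  list(
    mirna = profile_from_counts(c(mirA = 300L, mirB = 100L), "miRNA"),
    mrna = profile_from_counts(c(g1 = 150L, g2 = 50L), "mRNA"),
    interactions = interactions_from(
      gene = c("g1", "g2"), family = c("mirA", "mirB"),
      score = c(p_strong, p_weak))
  )
}

tiny_config <- function(mirna, mrna, n_iterations = 200L,
                        removal_delay = 50L, checkpoint_interval = 50L,
                        seed = 1L, ...) {
  simulation_config(n_iterations = n_iterations,
                    removal_delay = removal_delay,
                    checkpoint_interval = checkpoint_interval,
                    mirna_pool = sum(mirna$molecules),
                    mrna_pool = sum(mrna$molecules), seed = seed, ...)
}

write_tsv_file <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}
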