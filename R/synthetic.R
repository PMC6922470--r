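#' Specification for a synthetic cell fixture
#'
#' Describes a self-contained miRNA/mRNA/interaction fixture with planted
#' structure. Family abundances decay geometrically with ratio
#' `mirna_dominance`, mimicking real cells where the dominant family holds
#' roughly a quarter of the miRNA pool (0.75 over 20 families gives the top
#' family ~25%). Planted \emph{sensitive-like} genes carry a strong site for
#' the dominant family; planted \emph{stable-like} genes carry sites only
#' for two rare (bottom-quartile) families. Background genes get
#' density-driven records with moderate scores, at least one of them with an
#' abundance-weighted family.
#'
#' @param n_genes,n_families fixture dimensions.
#' @param mirna_pool,mrna_pool pool totals (defaults 50,000 / 25,000).
#' @param mirna_dominance geometric decay ratio of family abundances.
#' @param gene_abundance `"uniform"` (abundances drawn on 0.5..1.5) or
#'   `"geometric"` (ratio `gene_dominance`).
#' @param gene_dominance geometric ratio for `gene_abundance = "geometric"`.
#' @param density probability a background (gene, family) pair has a record.
#' @param score_lo background scores are uniform on `[score_lo, 0]`.
#' @param sensitive_score CWCS of planted sensitive records (default -6,
#'   binding probability ~0.984).
#' @param n_top_families planted sensitive genes carry strong records for
#'   this many of the most abundant families (real sensitive genes are the
#'   ones bound by nearly all dominant miRNAs).
#' @param n_anchor_records background genes carry at least this many records
#'   with families from the abundant 60% of the pool, so an un-targeted,
#'   trivially stable background cannot arise by chance.
#' @param n_stable_like,n_sensitive_like planted block sizes.
#' @param max_sites background records carry 1..`max_sites` sites spaced
#'   `min_spacing` apart.
#' @param min_spacing site spacing (default 50 nt).
#' @param validated_fraction fraction of genes contributing their strongest
#'   record to the validated-pair truth list (emulating a CLASH-style
#'   capture of a gene subset).
#' @param seed integer seed; fixtures are deterministic given the spec.
#' @return a `comics_synth_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60L, n_families = 20L,
                           mirna_pool = 50000L, mrna_pool = 25000L,
                           mirna_dominance = 0.75,
                           gene_abundance = c("uniform", "geometric"),
                           gene_dominance = 0.95,
                           density = 0.1, score_lo = -2,
                           sensitive_score = -6,
                           n_top_families = 4L, n_anchor_records = 3L,
                           n_stable_like = 6L, n_sensitive_like = 6L,
                           max_sites = 3L, min_spacing = 50L,
                           validated_fraction = 0.1, seed = 1L) {
  gene_abundance <- match.arg(gene_abundance)
  spec <- list(n_genes = as.integer(n_genes),
               n_families = as.integer(n_families),
               mirna_pool = as.integer(mirna_pool),
               mrna_pool = as.integer(mrna_pool),
               mirna_dominance = mirna_dominance,
               gene_abundance = gene_abundance,
               gene_dominance = gene_dominance,
               density = density, score_lo = score_lo,
               sensitive_score = sensitive_score,
               n_top_families = as.integer(n_top_families),
               n_anchor_records = as.integer(n_anchor_records),
               n_stable_like = as.integer(n_stable_like),
               n_sensitive_like = as.integer(n_sensitive_like),
               max_sites = as.integer(max_sites),
               min_spacing = as.integer(min_spacing),
               validated_fraction = validated_fraction,
               seed = as.integer(seed))
  stopifnot(spec$n_genes > 0, spec$n_families > 1,
            spec$density > 0, spec$density <= 1,
            spec$mirna_dominance > 0, spec$mirna_dominance < 1,
            spec$score_lo <= 0, spec$sensitive_score <= 0)
  if (spec$n_stable_like + spec$n_sensitive_like > spec$n_genes) {
    abort("Planted blocks exceed `n_genes`.")
  }
  class(spec) <- "comics_synth_spec"
  spec
}

#' Build a synthetic fixture
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `mirna` and `mrna` (`comics_profile`s),
#'   `interactions` (`comics_interactions`), `truth` (tibble `gene`,
#'   `planted` in stable_like/sensitive_like/background) and
#'   `validated_pairs` (tibble `family`, `gene`: the strongest records).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "comics_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  fams <- sprintf("fam-%02d", seq_len(spec$n_families))
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  fam_w <- spec$mirna_dominance^(seq_len(spec$n_families) - 1)
  mirna <- normalize_to_pool(tibble(id = fams, abundance = fam_w),
                             spec$mirna_pool, entity_kind = "miRNA")

  gene_w <- switch(spec$gene_abundance,
                   uniform = runif(spec$n_genes, 0.5, 1.5),
                   geometric = spec$gene_dominance^(seq_len(spec$n_genes) - 1))
  mrna <- normalize_to_pool(tibble(id = genes, abundance = gene_w),
                            spec$mrna_pool, entity_kind = "mRNA")

  idx_sens <- seq_len(spec$n_sensitive_like)
  idx_stab <- spec$n_sensitive_like + seq_len(spec$n_stable_like)
  idx_bg <- setdiff(seq_len(spec$n_genes), c(idx_sens, idx_stab))
  rare_fams <- fams[fams >= fams[ceiling(0.75 * spec$n_families)]]
  if (length(rare_fams) < 2) rare_fams <- tail(fams, 2)

  site_pos <- function(k) as.integer(seq_len(k) - 1L) * spec$min_spacing
  recs <- list()
  add <- function(gene, family, score, k_sites) {
    recs[[length(recs) + 1L]] <<-
      tibble(gene = gene, family = family, score = score,
             sites = list(site_pos(k_sites)))
  }
  top_fams <- fams[seq_len(min(spec$n_top_families, spec$n_families))]
  abundant_fams <- fams[seq_len(ceiling(0.6 * spec$n_families))]
  for (i in idx_sens) {
    # bound by (nearly) all dominant families, with strong sites
    for (f in top_fams) add(genes[i], f, spec$sensitive_score, 2L)
    extra <- sample(setdiff(fams, top_fams), 1L)
    add(genes[i], extra, runif(1, spec$score_lo, 0), 1L)
  }
  for (i in idx_stab) {
    for (f in sample(rare_fams, 2L)) {
      add(genes[i], f, runif(1, spec$score_lo, 0),
          sample.int(spec$max_sites, 1L))
    }
  }
  for (i in idx_bg) {
    hit <- fams[runif(spec$n_families) < spec$density]
    anchors <- sample(abundant_fams, min(spec$n_anchor_records,
                                         length(abundant_fams)))
    for (f in unique(c(anchors, hit))) {
      add(genes[i], f, runif(1, spec$score_lo, 0),
          sample.int(spec$max_sites, 1L))
    }
  }
  rec_df <- bind_rows(recs)
  # every family must target something, or screens over it are undefined
  missing_f <- setdiff(fams, rec_df$family)
  for (f in missing_f) {
    g <- genes[idx_bg[sample.int(length(idx_bg), 1L)]]
    rec_df <- bind_rows(rec_df,
                        tibble(gene = g, family = f,
                               score = runif(1, spec$score_lo, 0),
                               sites = list(site_pos(1L))))
  }
  interactions <- as_interaction_table(rec_df,
                                       min_spacing = spec$min_spacing)

  # validated list emulates CLASH-style evidence: a captured subset of
  # genes, each contributing its strongest interaction
  n_val <- max(1L, round(spec$validated_fraction * spec$n_genes))
  val_genes <- sample(sort(unique(interactions$gene)), n_val)
  val <- interactions |>
    filter(.data$gene %in% val_genes) |>
    group_by(.data$gene) |>
    arrange(dplyr::desc(.data$probability), .data$family) |>
    slice(1) |>
    ungroup() |>
    select("family", "gene")

  truth <- tibble(gene = genes,
                  planted = c(rep("sensitive_like", spec$n_sensitive_like),
                              rep("stable_like", spec$n_stable_like),
                              rep("background", length(idx_bg))))
  list(mirna = mirna, mrna = mrna, interactions = interactions,
       truth = truth, validated_pairs = val)
}

#' Brute-force oracle for tiny systems
#'
#' An intentionally naive, molecule-by-molecule re-implementation of the
#' iteration rules (plain R lists, no indexing, no shared code with the
#' compiled engine), averaged over independent replicate seeds. Only
#' accepts systems of at most 3 genes, 2 families and 500 molecules in
#' total, where an audit by eye is feasible.
#'
#' @param mirna,mrna `comics_profile`s (tiny).
#' @param interactions a `comics_interactions` table.
#' @param config a [simulation_config()] (pool fields must match profiles).
#' @param n_replicates replicate runs (seeds `config$seed + 0:(n-1)`).
#' @return tibble `gene`, `mean_retention`, `se`, `n_replicates`.
#' @export
tiny_system_oracle <- function(mirna, mrna, interactions, config,
                               n_replicates = 100L) {
  if (nrow(mrna) > 3 || nrow(mirna) > 2 ||
      sum(mrna$molecules) + sum(mirna$molecules) > 500) {
    abort("System too large for the brute-force oracle.")
  }
  reps <- vapply(seq_len(n_replicates), function(r) {
    oracle_once(mirna, mrna, interactions, config, config$seed + r - 1L)
  }, numeric(nrow(mrna)))
  reps <- matrix(reps, nrow = nrow(mrna))
  tibble(gene = mrna$id,
         mean_retention = rowMeans(reps),
         se = apply(reps, 1, sd) / sqrt(n_replicates),
         n_replicates = as.integer(n_replicates))
}

oracle_once <- function(mirna, mrna, interactions, config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- mrna$id
  free <- setNames(as.numeric(mirna$molecules), mirna$id)
  # every molecule is an explicit record
  cells <- lapply(seq_along(genes), function(i) {
    replicate(mrna$molecules[i],
              list(sites = integer(0), fams = character(0), deadline = NA),
              simplify = FALSE)
  })
  rec_of <- function(fam) interactions[interactions$family == fam, ]
  for (t in seq_len(config$n_iterations)) {
    for (gi in seq_along(genes)) {
      due <- vapply(cells[[gi]], function(m) {
        !is.na(m$deadline) && m$deadline <= t
      }, logical(1))
      if (any(due)) {
        for (m in cells[[gi]][due]) {
          for (f in m$fams) free[f] <- free[f] + 1
        }
        cells[[gi]] <- cells[[gi]][!due]
      }
    }
    if (sum(free) <= 0) next
    fam <- names(free)[sample.int(length(free), 1L, prob = free)]
    recs <- rec_of(fam)
    if (nrow(recs) == 0) next
    live <- vapply(recs$gene, function(g) {
      length(cells[[match(g, genes)]])
    }, numeric(1))
    if (sum(live) == 0) next
    ri <- sample.int(nrow(recs), 1L, prob = live)
    gi <- match(recs$gene[ri], genes)
    mi <- sample.int(length(cells[[gi]]), 1L)
    if (runif(1) >= recs$probability[ri]) next
    mol <- cells[[gi]][[mi]]
    cand <- recs$sites[[ri]]
    elig <- cand[vapply(cand, function(s) {
      all(abs(s - mol$sites) >= config$min_site_spacing)
    }, logical(1))]
    if (length(elig) == 0) next
    site <- elig[sample.int(length(elig), 1L)]
    mol$sites <- c(mol$sites, site)
    mol$fams <- c(mol$fams, fam)
    if (is.na(mol$deadline) || config$removal_clock == "last") {
      mol$deadline <- t + config$removal_delay
    }
    cells[[gi]][[mi]] <- mol
    free[fam] <- free[fam] - 1
  }
  vapply(seq_along(genes), function(gi) {
    100 * length(cells[[gi]]) / mrna$molecules[gi]
  }, numeric(1))
}

#' Random tiny system for oracle comparisons
#'
#' Draws a small random system (1-3 genes, 1-2 families, <= 500 molecules
#' combined, random binding probabilities) suitable for
#' [tiny_system_oracle()].
#'
#' @param seed integer seed.
#' @return list `mirna`, `mrna`, `interactions`.
#' @export
make_tiny_system <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_g <- sample.int(3L, 1L)
  n_f <- sample.int(2L, 1L)
  genes <- sprintf("g%d", seq_len(n_g))
  fams <- sprintf("f%d", seq_len(n_f))
  mrna_pool <- sample(60:150, 1L)
  mirna_pool <- sample(100:300, 1L)
  mrna <- normalize_to_pool(tibble(id = genes,
                                   abundance = runif(n_g, 0.5, 1.5)),
                            mrna_pool, entity_kind = "mRNA")
  mirna <- normalize_to_pool(tibble(id = fams,
                                    abundance = runif(n_f, 0.5, 1.5)),
                             mirna_pool, entity_kind = "miRNA")
  grid <- expand.grid(gene = genes, family = fams, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < 0.8
  # every gene needs a record or the engine would drop it from the pool
  for (g in genes) {
    rows <- which(grid$gene == g)
    if (!any(keep[rows])) keep[rows[sample.int(length(rows), 1L)]] <- TRUE
  }
  grid <- grid[keep, ]
  grid$score <- runif(nrow(grid), -4, -0.1)
  grid$n_sites <- sample.int(2L, nrow(grid), replace = TRUE)
  list(mirna = mirna, mrna = mrna,
       interactions = as_interaction_table(grid))
}
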