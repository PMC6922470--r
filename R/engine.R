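#' Simulation configuration
#'
#' Bundles the tunable engine parameters. Defaults follow the cell-scale
#' setup used throughout the package: 100,000 sampling iterations over pools
#' of 50,000 miRNA and 25,000 mRNA molecules (2:1 stoichiometry), a removal
#' delay of 1,000 iterations between a transcript's first successful binding
#' and its degradation, a 50-nt exclusion zone between simultaneously
#' occupied binding sites, and retention recorded every 1,000 iterations.
#'
#' @param n_iterations sampling iterations (one draw attempt each).
#' @param removal_delay iterations between first binding and removal.
#' @param checkpoint_interval iterations between retention checkpoints; must
#'   divide `n_iterations`.
#' @param min_site_spacing minimal nt between co-occupied sites.
#' @param seed integer seed for the run.
#' @param mirna_pool,mrna_pool molecule pool totals the profiles must match.
#' @param removal_clock `"first"`: the removal deadline is fixed by the first
#'   successful binding (default); `"last"`: later bindings restart it.
#' @return a `comics_config` list.
#' @export
simulation_config <- function(n_iterations = 100000L,
                              removal_delay = 1000L,
                              checkpoint_interval = 1000L,
                              min_site_spacing = 50L,
                              seed = 1L,
                              mirna_pool = 50000L,
                              mrna_pool = 25000L,
                              removal_clock = c("first", "last")) {
  removal_clock <- match.arg(removal_clock)
  cfg <- list(n_iterations = as.integer(n_iterations),
              removal_delay = as.integer(removal_delay),
              checkpoint_interval = as.integer(checkpoint_interval),
              min_site_spacing = as.integer(min_site_spacing),
              seed = as.integer(seed),
              mirna_pool = as.integer(mirna_pool),
              mrna_pool = as.integer(mrna_pool),
              removal_clock = removal_clock)
  stopifnot(cfg$n_iterations > 0, cfg$removal_delay > 0,
            cfg$checkpoint_interval > 0, cfg$min_site_spacing >= 0,
            cfg$mirna_pool > 0, cfg$mrna_pool > 0)
  if (cfg$n_iterations %% cfg$checkpoint_interval != 0) {
    abort("`checkpoint_interval` must divide `n_iterations`.")
  }
  class(cfg) <- "comics_config"
  cfg
}

#' Run the competition simulation
#'
#' One iteration samples a miRNA family from the free pool (abundance
#' weighted), samples a live transcript among the family's targets
#' (molecule-count weighted; occupied molecules remain eligible), and binds
#' with the pair's probability at a free, non-conflicting site. A molecule's
#' first successful binding schedules its removal `removal_delay` iterations
#' later; on removal its bound miRNAs return to the free pool. Failed
#' attempts consume nothing but count as iterations.
#'
#' Genes in the transcript profile with no interaction record never change
#' and are excluded from the simulated pool (recorded in `excluded_genes`).
#'
#' @param mirna miRNA family `comics_profile` (pool == `config$mirna_pool`).
#' @param mrna transcript `comics_profile` (pool == `config$mrna_pool`).
#' @param interactions a `comics_interactions` table.
#' @param config a [simulation_config()].
#' @return a `comics_run` object: checkpointed retention trajectory,
#'   engagement log, final state, conservation audit and the config used.
#' @export
run_comics <- function(mirna, mrna, interactions, config = simulation_config()) {
  stopifnot(inherits(config, "comics_config"))
  if (nrow(mrna) == 0) abort("Empty mRNA profile.")
  if (nrow(mirna) == 0) abort("Empty miRNA profile.")
  if (sum(mirna$molecules) != config$mirna_pool) {
    abort("miRNA profile pool does not match `config$mirna_pool`.")
  }
  if (sum(mrna$molecules) != config$mrna_pool) {
    abort("mRNA profile pool does not match `config$mrna_pool`.")
  }
  if (nrow(interactions) == 0) abort("Empty interaction table.")

  targeted <- unique(interactions$gene)
  excluded <- mrna$id[!(mrna$id %in% targeted) | mrna$molecules == 0]
  sim <- mrna[!(mrna$id %in% excluded), ]
  if (nrow(sim) == 0) abort("No simulated gene has an interaction record.")
  genes <- sim$id
  families <- sort(unique(c(mirna$id, interactions$family)))
  free0 <- setNames(integer(length(families)), families)
  free0[mirna$id] <- mirna$molecules

  rec <- interactions[interactions$gene %in% genes, ]
  gidx <- match(rec$gene, genes) - 1L
  fidx <- match(rec$family, families) - 1L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  raw <- .comics_run_cpp(as.integer(sim$molecules), unname(free0),
                         gidx, fidx, rec$probability, rec$sites,
                         config$n_iterations, config$removal_delay,
                         config$checkpoint_interval, config$min_site_spacing,
                         config$removal_clock == "last")

  trajectory <- raw$retention
  dimnames(trajectory) <- list(genes, raw$checkpoints)
  engaged <- tibble(family = families[raw$engaged_family + 1L],
                    gene = genes[raw$engaged_gene + 1L],
                    first_iteration = raw$engaged_iteration) |>
    arrange(.data$first_iteration, .data$family, .data$gene)

  structure(list(
    trajectory = trajectory,
    checkpoints = raw$checkpoints,
    genes = genes,
    initial = setNames(as.integer(sim$molecules), genes),
    live = setNames(raw$live, genes),
    free_mirna = setNames(raw$free_mirna, families),
    engaged = engaged,
    excluded_genes = excluded,
    conservation = tibble(iteration = raw$checkpoints,
                          mirna_total = raw$conservation,
                          pool = raw$mirna_pool),
    n_success = raw$n_success,
    n_failed = raw$n_failed,
    config = config
  ), class = "comics_run")
}

#' @export
print.comics_run <- function(x, ...) {
  cat(sprintf(paste0("<comics_run: %d genes, %d iterations, seed %d>\n",
                     "  successful bindings: %d; mean final retention: %.1f%%\n"),
              length(x$genes), x$config$n_iterations, x$config$seed,
              as.integer(x$n_success), mean(final_retention(x))))
  invisible(x)
}

#' Final per-gene retention of a run
#'
#' Retention is the percentage of a gene's starting molecules still live
#' (occupied-but-unremoved molecules count as live).
#'
#' @param run a `comics_run`.
#' @return named numeric vector, percent in `[0, 100]`.
#' @export
final_retention <- function(run) {
  stopifnot(inherits(run, "comics_run"))
  setNames(100 * run$live / run$initial, run$genes)
}

#' Retention trajectory in long form
#'
#' @param x a `comics_run`.
#' @param ... unused.
#' @return tibble `gene`, `iteration`, `retention`.
#' @export
tidy.comics_run <- function(x, ...) {
  as_tibble(x$trajectory, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "iteration",
                        values_to = "retention") |>
    mutate(iteration = as.integer(.data$iteration)) |>
    arrange(.data$gene, .data$iteration)
}

#' One-row run summary
#'
#' @param x a `comics_run`.
#' @param ... unused.
#' @return tibble with gene/iteration counts, binding totals, mean final
#'   retention and whether the miRNA pool was conserved at every checkpoint.
#' @export
glance.comics_run <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         n_iterations = x$config$n_iterations,
         n_bindings = as.integer(x$n_success),
         n_failed_attempts = as.integer(x$n_failed),
         mean_final_retention = mean(final_retention(x)),
         mirna_pool_conserved = all(x$conservation$mirna_total ==
                                      x$conservation$pool))
}
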