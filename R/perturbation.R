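#' Assign a minimal starting amount to an undetected miRNA family
#'
#' A family that is absent from (or negligible in) the native profile gets an
#' arbitrary starting floor of `min_fraction` of the pool (default 0.01%,
#' i.e. 5 of 50,000 molecules) before any overexpression, after which the
#' whole distribution is renormalized back to the fixed pool total.
#'
#' @param profile miRNA `comics_profile`.
#' @param family family identifier to floor.
#' @param min_fraction minimal pool fraction (default `1e-4`).
#' @return a `comics_profile` with the same pool total.
#' @export
apply_floor <- function(profile, family, min_fraction = 1e-4) {
  pt <- pool_total(profile)
  floor_n <- ceiling(min_fraction * pt)
  cur <- profile$molecules[profile$id == family]
  if (length(cur) == 1 && cur >= floor_n) return(profile)
  tbl <- profile
  if (length(cur) == 0) {
    tbl <- bind_rows(tbl, tibble(id = family, molecules = 0L)) |>
      arrange(.data$id)
  }
  w <- setNames(as.numeric(tbl$molecules), tbl$id)
  w[family] <- floor_n
  counts <- largest_remainder(w, pt)
  new_profile(tibble(id = names(counts), molecules = unname(counts)),
              pool_total = pt, entity_kind = attr(profile, "entity_kind"))
}

#' Overexpress (or knock down) one miRNA family at a fixed pool size
#'
#' The family's molecule count is multiplied by `factor` and the whole
#' distribution is renormalized so the cell still holds exactly its pool
#' total. A baseline fraction `f0` therefore becomes
#' `F * f0 / (1 + (F - 1) * f0)` up to rounding. `factor = 1` is the
#' identity; `factor = 0.5` is a knockdown.
#'
#' @param profile miRNA `comics_profile` (family present; see
#'   [apply_floor()]).
#' @param family family identifier.
#' @param factor positive multiplication factor (the study sweep uses 0.5,
#'   3, 9, 18, 90, 300 and 1000).
#' @return a `comics_profile` with the same pool total.
#' @export
overexpress <- function(profile, family, factor) {
  if (!is.numeric(factor) || factor <= 0) abort("`factor` must be positive.")
  if (!family %in% profile$id) {
    abort(paste0("Family not in profile (apply_floor first): ", family))
  }
  pt <- pool_total(profile)
  w <- setNames(as.numeric(profile$molecules), profile$id)
  w[family] <- w[family] * factor
  counts <- largest_remainder(w, pt)
  new_profile(tibble(id = names(counts), molecules = unname(counts)),
              pool_total = pt, entity_kind = attr(profile, "entity_kind"))
}

# deterministic per-family seed derived from the master seed, independent of
# the family's position in the screen list
derive_seed <- function(master_seed, family) {
  h <- 0
  for (cc in utf8ToInt(family)) h <- (h * 131 + cc) %% 2147483647
  as.integer((master_seed %% 2147483647 + h) %% 2147483647)
}

#' Exhaustive single-family overexpression screen
#'
#' For each family: floor the native profile, multiply by `factor`,
#' renormalize, and run an independent simulation. Column `j` of the result
#' is each gene's final retention under overexpression of family `j`. Each
#' column's seed is derived deterministically from `master_seed` and the
#' family identifier, so columns are reproducible and order-independent.
#'
#' @param mirna native miRNA `comics_profile`.
#' @param mrna transcript `comics_profile`.
#' @param interactions a `comics_interactions` table.
#' @param families families to overexpress (default: all in the table).
#' @param factor overexpression factor applied to every family.
#' @param config a [simulation_config()] (its `seed` is ignored).
#' @param master_seed master seed for per-column seed derivation.
#' @param floor_fraction minimal starting fraction for undetected families.
#' @return a `comics_screen`: retention matrix (genes x families, percent),
#'   plus per-column seeds, factor and config.
#' @export
run_screen <- function(mirna, mrna, interactions,
                       families = NULL, factor = 300,
                       config = simulation_config(),
                       master_seed = 1L, floor_fraction = 1e-4) {
  families <- families %||% sort(unique(interactions$family))
  if (!all(families %in% interactions$family)) {
    abort("Some families have no interaction record.")
  }
  seeds <- vapply(families, derive_seed, integer(1), master_seed = master_seed)
  cols <- purrr::map(families, function(fam) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, fam)
    prof <- overexpress(apply_floor(mirna, fam, floor_fraction), fam, factor)
    run <- run_comics(prof, mrna, interactions, cfg)
    final_retention(run)
  })
  genes <- names(cols[[1]])
  stopifnot(all(vapply(cols, function(cc) identical(names(cc), genes),
                       logical(1))))
  values <- do.call(cbind, cols)
  dimnames(values) <- list(genes, families)
  structure(list(values = values, genes = genes, families = families,
                 factor = factor, seeds = setNames(seeds, families),
                 master_seed = as.integer(master_seed), config = config),
            class = "comics_screen")
}

#' @export
print.comics_screen <- function(x, ...) {
  cat(sprintf("<comics_screen: %d genes x %d families, factor x%g>\n",
              length(x$genes), length(x$families), x$factor))
  invisible(x)
}

#' Screen retention matrix in long form
#'
#' @param x a `comics_screen`.
#' @param ... unused.
#' @return tibble `gene`, `family`, `retention`.
#' @export
tidy.comics_screen <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "family",
                        values_to = "retention") |>
    arrange(.data$gene, .data$family)
}

#' One-row screen summary
#'
#' @param x a `comics_screen`.
#' @param ... unused.
#' @return tibble with dimensions, factor and the retention grand mean.
#' @export
glance.comics_screen <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_families = length(x$families),
         factor = x$factor, mean_retention = mean(x$values))
}
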