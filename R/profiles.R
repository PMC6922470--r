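#' Largest-remainder apportionment of a fixed pool
#'
#' Distributes `pool_total` indivisible molecules over entities in proportion
#' to non-negative weights so that the result sums to `pool_total` exactly.
#' Quotas are floored and the leftover molecules go to the entities with the
#' largest fractional remainders; remainder ties are broken by identifier
#' (lexicographic), so the apportionment is deterministic.
#'
#' @param weights named non-negative numeric vector (names are identifiers).
#' @param pool_total positive integer, the exact output sum.
#' @return named integer vector, same names as `weights`, summing to
#'   `pool_total`.
#' @examples
#' largest_remainder(c(a = 1, b = 1, c = 1), 50000)
#' @export
largest_remainder <- function(weights, pool_total) {
  stopifnot(is.numeric(weights), length(weights) > 0)
  if (is.null(names(weights)) || anyDuplicated(names(weights)) > 0) {
    abort("`weights` must be uniquely named.")
  }
  if (any(weights < 0) || !all(is.finite(weights))) {
    abort("`weights` must be finite and non-negative.")
  }
  total_w <- sum(weights)
  if (total_w <= 0) abort("All weights are zero; nothing to apportion.")
  if (pool_total <= 0) abort("`pool_total` must be positive.")

  quota <- weights / total_w * pool_total
  base <- floor(quota)
  leftover <- as.integer(round(pool_total - sum(base)))
  if (leftover > 0) {
    remainder <- quota - base
    # ties on the remainder resolved by identifier order
    take <- order(-remainder, names(weights))[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(weights)
  out
}

#' Read a raw expression table
#'
#' Ingests a headered TSV/CSV with columns `id` and `abundance` (FPKM, TPM or
#' raw counts; a `units` column is tolerated and ignored). Duplicate
#' identifiers are summed; rows with negative abundance are dropped with a
#' warning.
#'
#' @param path path to a TSV or CSV file (delimiter sniffed from the header).
#' @param entity_kind `"mRNA"` or `"miRNA"`; recorded on the result.
#' @return a tibble with columns `id` (character), `abundance` (double) and
#'   attribute `entity_kind`.
#' @export
read_expression <- function(path, entity_kind = c("mRNA", "miRNA")) {
  entity_kind <- match.arg(entity_kind)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort(paste0("Empty expression file: ", path))
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_expression_table(raw, entity_kind)
}

#' Coerce a data frame to a raw expression table
#'
#' @param df data frame with identifier and abundance in the first two
#'   columns (or named `id`/`abundance`).
#' @inheritParams read_expression
#' @return tibble `id`, `abundance` with duplicates summed.
#' @export
as_expression_table <- function(df, entity_kind = c("mRNA", "miRNA")) {
  entity_kind <- match.arg(entity_kind)
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  nm <- names(df)
  id_col <- if ("id" %in% nm) "id" else nm[1]
  ab_col <- if ("abundance" %in% nm) "abundance" else nm[2]
  out <- tibble(id = as.character(df[[id_col]]),
                abundance = as.numeric(df[[ab_col]]))
  bad <- !is.na(out$abundance) & out$abundance < 0
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) with negative abundance dropped."))
    out <- out[!bad, ]
  }
  out <- out[!is.na(out$abundance), ]
  if (nrow(out) == 0) abort("No usable expression rows.")
  out <- out |>
    group_by(.data$id) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(.data$id)
  attr(out, "entity_kind") <- entity_kind
  out
}

#' Collapse mature miRNAs to family-level abundances
#'
#' Family abundance is the sum of its members' abundances. Members missing
#' from the family map are retained under their own identifier and reported.
#'
#' @param raw miRNA expression table (`id`, `abundance`).
#' @param family_map data frame with columns `mirna`, `family` (or a named
#'   character vector mature-id -> family).
#' @return tibble `id`, `abundance` at family level; attribute `unmapped`
#'   lists identifiers kept as-is.
#' @export
collapse_mirna_families <- function(raw, family_map) {
  stopifnot(is.data.frame(raw))
  if (!is.data.frame(family_map)) {
    family_map <- tibble(mirna = names(family_map),
                         family = unname(family_map))
  }
  stopifnot(all(c("mirna", "family") %in% names(family_map)))
  fam <- setNames(as.character(family_map$family),
                  as.character(family_map$mirna))
  mapped <- raw$id %in% names(fam)
  unmapped <- raw$id[!mapped]
  if (length(unmapped) > 0) {
    inform(paste0(length(unmapped),
                  " miRNA(s) absent from the family map kept under their own name."))
  }
  out <- raw |>
    mutate(id = ifelse(mapped, unname(fam[.data$id]), .data$id)) |>
    group_by(.data$id) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(.data$id)
  attr(out, "entity_kind") <- "miRNA"
  attr(out, "unmapped") <- unmapped
  out
}

#' Normalize abundances to a fixed molecule pool
#'
#' Converts relative abundances (FPKM/TPM/counts) into integer molecule
#' counts that sum exactly to `pool_total` (largest-remainder rounding).
#' Entities ending up below `min_molecules` are dropped and the pool is
#' re-apportioned over the survivors in one further pass.
#'
#' @param raw expression table (`id`, `abundance`).
#' @param pool_total molecules in the cell for this entity kind; the
#'   defaults used throughout the package are 25,000 transcripts and 50,000
#'   miRNAs (a 2:1 miRNA:mRNA stoichiometry).
#' @param min_molecules entities with fewer molecules after rounding are
#'   removed (default 1, i.e. zero-count entities).
#' @param entity_kind recorded on the profile; taken from `raw` if present.
#' @return a `comics_profile`: tibble `id`, `molecules` with attributes
#'   `pool_total` and `entity_kind`; `sum(molecules) == pool_total` exactly.
#' @export
normalize_to_pool <- function(raw, pool_total, min_molecules = 1L,
                              entity_kind = NULL) {
  stopifnot(is.data.frame(raw), nrow(raw) > 0)
  entity_kind <- entity_kind %||% attr(raw, "entity_kind") %||% "mRNA"
  ab_col <- if ("abundance" %in% names(raw)) "abundance" else "molecules"
  w <- setNames(as.numeric(raw[[ab_col]]), as.character(raw$id))
  if (all(w == 0)) abort("All abundances are zero.")
  counts <- largest_remainder(w, pool_total)
  keep <- counts >= min_molecules
  if (!all(keep)) {
    if (!any(keep)) abort("No entity survives `min_molecules`.")
    counts <- largest_remainder(w[keep], pool_total)
  }
  new_profile(tibble(id = names(counts), molecules = unname(counts)),
              pool_total = pool_total, entity_kind = entity_kind)
}

new_profile <- function(tbl, pool_total, entity_kind) {
  stopifnot(sum(tbl$molecules) == pool_total)
  attr(tbl, "pool_total") <- as.integer(pool_total)
  attr(tbl, "entity_kind") <- entity_kind
  class(tbl) <- c("comics_profile", class(tibble()))
  tbl
}

#' @export
print.comics_profile <- function(x, ...) {
  cat(sprintf("<comics_profile: %d %s entities, pool %d molecules>\n",
              nrow(x), attr(x, "entity_kind"), attr(x, "pool_total")))
  NextMethod()
}

#' Pool size of an expression profile
#' @param profile a `comics_profile`.
#' @return integer pool total.
#' @export
pool_total <- function(profile) attr(profile, "pool_total")

#' Genes above the reporting threshold
#'
#' The reporting threshold used for retention summaries: a gene is reported
#' when its share of the transcript pool is at least `min_fraction`
#' (default 0.02%, i.e. 5 of 25,000 molecules).
#'
#' @param profile a `comics_profile`.
#' @param min_fraction minimal fraction of the pool (default `2e-4`).
#' @return character vector of identifiers.
#' @export
reported_genes <- function(profile, min_fraction = 2e-4) {
  pt <- pool_total(profile)
  profile$id[profile$molecules / pt >= min_fraction]
}
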