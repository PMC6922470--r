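#' Convert a context++ score to a binding probability
#'
#' TargetScan-style cumulative weighted context++ scores (CWCS, <= 0; more
#' negative = stronger predicted repression) are mapped to a per-encounter
#' binding probability `p = 1 - 2^score`, clamped into `[0, 1)`. Positive
#' scores (invalid input) clamp to 0.
#'
#' @param score numeric vector of CWCS values.
#' @return numeric vector of probabilities in `[0, 1)`.
#' @examples
#' score_to_probability(c(0, -1, -2))  # 0, 0.5, 0.75
#' @export
score_to_probability <- function(score) {
  if (any(is.nan(score))) abort("NaN score.")
  stopifnot(is.numeric(score), all(is.finite(score)))
  pmax(0, 1 - 2^score)
}

#' Do two binding-site positions conflict?
#'
#' Neighboring miRNA binding sites closer than `min_spacing` nucleotides
#' (site starts, 0-based 3'-UTR offsets) cannot be occupied simultaneously.
#'
#' @param a,b integer site start positions.
#' @param min_spacing minimal allowed spacing in nucleotides (default 50).
#' @return logical: `TRUE` iff `|a - b| < min_spacing`.
#' @export
sites_conflict <- function(a, b, min_spacing = 50L) {
  stopifnot(all(a >= 0), all(b >= 0))
  abs(a - b) < min_spacing
}

#' Build an interaction table from a data frame
#'
#' Collapses to one record per (gene, family): the most negative (strongest)
#' score wins, site positions are unioned and sorted. A `sites` column may be
#' a comma-separated string or a list of integer vectors; when absent each
#' record receives synthetic sites spaced `min_spacing` apart (one site, or
#' `n_sites` of them when that column exists) so synthetic sites never
#' self-conflict.
#'
#' @param df data frame with columns `gene`, `family`, `score`, optional
#'   `sites` / `n_sites`.
#' @param min_spacing spacing used for synthetic site placement.
#' @param provenance tag recorded on the table (`"original"` for parsed
#'   input; randomizations override it).
#' @return a `comics_interactions` tibble: `gene`, `family`, `score`,
#'   `probability`, `sites` (list of sorted integer vectors).
#' @export
as_interaction_table <- function(df, min_spacing = 50L,
                                 provenance = "original") {
  stopifnot(is.data.frame(df))
  need <- c("gene", "family", "score")
  if (!all(need %in% names(df))) {
    abort("Interaction input needs columns gene, family, score.")
  }
  tbl <- tibble(gene = as.character(df$gene),
                family = as.character(df$family),
                score = as.numeric(df$score))
  ok <- !is.na(tbl$gene) & !is.na(tbl$family) & is.finite(tbl$score)
  if (!all(ok)) {
    warn(paste0(sum(!ok), " malformed interaction row(s) skipped."))
    df <- df[ok, , drop = FALSE]
    tbl <- tbl[ok, ]
  }
  if (any(tbl$score > 0)) {
    warn("Positive score(s): binding probability clamped to 0.")
  }

  sites <- parse_sites_column(df, min_spacing)
  tbl$sites <- sites
  out <- tbl |>
    group_by(.data$gene, .data$family) |>
    summarise(score = min(.data$score),
              sites = list(sort(unique(unlist(sites)))),
              .groups = "drop") |>
    arrange(.data$gene, .data$family)
  out$probability <- score_to_probability(out$score)
  out <- out[, c("gene", "family", "score", "probability", "sites")]
  attr(out, "provenance") <- provenance
  attr(out, "min_spacing") <- as.integer(min_spacing)
  class(out) <- c("comics_interactions", class(tibble()))
  out
}

parse_sites_column <- function(df, min_spacing) {
  n <- nrow(df)
  if ("sites" %in% names(df)) {
    raw <- df$sites
    if (is.list(raw)) {
      return(map(raw, function(s) sort(unique(as.integer(s)))))
    }
    return(map(as.character(raw), function(s) {
      if (is.na(s) || !nzchar(s)) return(0L)
      sort(unique(as.integer(strsplit(s, ",")[[1]])))
    }))
  }
  if ("n_sites" %in% names(df)) {
    k <- pmax(1L, as.integer(df$n_sites))
    return(map(k, function(m) as.integer(seq_len(m) - 1L) * min_spacing))
  }
  rep(list(0L), n)
}

#' Read an interaction score table from disk
#'
#' Canonical dialect: TSV with header `gene family score [sites]`, sites a
#' comma-separated list of 0-based 3'-UTR offsets. A column mapping can be
#' supplied for TargetScan "Summary Counts"-style exports.
#'
#' @param path TSV file.
#' @param col_map optional named character vector mapping canonical names
#'   (`gene`, `family`, `score`, `sites`, `n_sites`) to file column names.
#' @inheritParams as_interaction_table
#' @return a `comics_interactions` tibble.
#' @export
read_interactions <- function(path, col_map = NULL, min_spacing = 50L) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        abort(paste0("Mapped column not in file: ", col_map[[canon]]))
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  as_interaction_table(df, min_spacing = min_spacing)
}

#' @export
print.comics_interactions <- function(x, ...) {
  cat(sprintf("<comics_interactions: %d records, %d genes x %d families, provenance %s>\n",
              nrow(x), dplyr::n_distinct(x$gene), dplyr::n_distinct(x$family),
              attr(x, "provenance") %||% "original"))
  NextMethod()
}

#' Randomize an interaction table (network null models)
#'
#' Two controls for "is the engine's output driven by the real wiring?":
#' \describe{
#'   \item{naive}{the full multiset of scores (with their site lists) is
#'     reassigned to uniformly random distinct (gene, family) pairs drawn
#'     from the same gene and family universes.}
#'   \item{marginal}{degree-preserving rewiring: repeated checkerboard swaps
#'     keep every gene's interaction count and every family's interaction
#'     count exactly; each gene then keeps its own multiset of scores in
#'     shuffled order (row score totals exact, column totals approximate).}
#' }
#'
#' @param matrix a `comics_interactions` table.
#' @param mode `"marginal"` or `"naive"`.
#' @param seed integer; same seed, same output.
#' @param n_swaps swap attempts for marginal mode (default 10x records).
#' @return a `comics_interactions` table with provenance
#'   `"marginal_randomized"` or `"naive_randomized"`.
#' @export
randomize_interactions <- function(matrix, mode = c("marginal", "naive"),
                                   seed, n_swaps = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "comics_interactions"), nrow(matrix) > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  out <- if (mode == "naive") {
    genes <- sort(unique(matrix$gene))
    fams <- sort(unique(matrix$family))
    n <- nrow(matrix)
    total <- length(genes) * length(fams)
    if (n > total) abort("More records than available (gene, family) pairs.")
    pick <- sample.int(total, n)  # distinct cells of the bipartite grid
    gi <- ((pick - 1L) %% length(genes)) + 1L
    fi <- ((pick - 1L) %/% length(genes)) + 1L
    perm <- sample.int(n)
    tibble(gene = genes[gi], family = fams[fi],
           score = matrix$score[perm], sites = matrix$sites[perm])
  } else {
    marginal_rewire(matrix, n_swaps %||% (10L * nrow(matrix)))
  }

  res <- out |>
    arrange(.data$gene, .data$family) |>
    mutate(probability = score_to_probability(.data$score)) |>
    select("gene", "family", "score", "probability", "sites")
  attr(res, "provenance") <- paste0(mode, "_randomized")
  attr(res, "min_spacing") <- attr(matrix, "min_spacing")
  class(res) <- c("comics_interactions", class(tibble()))
  res
}

marginal_rewire <- function(matrix, n_swaps) {
  gene <- matrix$gene
  family <- matrix$family
  present <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(g, f) paste0(g, "\r", f)
  for (i in seq_along(gene)) assign(key(gene[i], family[i]), TRUE, present)
  n <- length(gene)
  swapped <- FALSE
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(n, 2L)
    i <- ij[1]; j <- ij[2]
    if (gene[i] == gene[j] || family[i] == family[j]) next
    if (exists(key(gene[i], family[j]), present) ||
        exists(key(gene[j], family[i]), present)) next
    rm(list = c(key(gene[i], family[i]), key(gene[j], family[j])),
       envir = present)
    tmp <- family[i]; family[i] <- family[j]; family[j] <- tmp
    assign(key(gene[i], family[i]), TRUE, present)
    assign(key(gene[j], family[j]), TRUE, present)
    swapped <- TRUE
  }
  if (!swapped) warn("No swappable quadruple found; matrix returned rewired-free.")
  out <- tibble(gene = gene, family = family,
                score = matrix$score, sites = matrix$sites)
  # each gene keeps its own score multiset, shuffled across its records
  out |>
    group_by(.data$gene) |>
    mutate(score = sample(.data$score),
           sites = .data$sites[sample.int(dplyr::n())]) |>
    ungroup()
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
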