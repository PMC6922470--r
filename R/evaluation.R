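#' Retention from a transcription-arrest time course
#'
#' Each gene's abundance is expressed as a percentage of its value at the
#' first timepoint (time 0 = 100%). Genes below `min_fraction` of the total
#' at time 0 are excluded, as are genes with zero baseline (warned). With
#' `cap = TRUE` values above 100 are collapsed to 100 — use the cap only for
#' distribution summaries, not correlations.
#'
#' @param timecourse data frame: `gene` column plus one numeric column per
#'   timepoint, the first of which is time 0.
#' @param min_fraction minimal fraction of the time-0 total (default 2e-4).
#' @param cap collapse retention above 100 to 100 (default `FALSE`).
#' @return tibble `gene`, `timepoint`, `retention`.
#' @export
retention_timecourse <- function(timecourse, min_fraction = 2e-4,
                                 cap = FALSE) {
  stopifnot(is.data.frame(timecourse), "gene" %in% names(timecourse),
            ncol(timecourse) >= 2)
  tp_cols <- setdiff(names(timecourse), "gene")
  t0 <- timecourse[[tp_cols[1]]]
  if (any(t0 < 0, na.rm = TRUE)) abort("Negative abundance at time 0.")
  keep <- t0 / sum(t0) >= min_fraction
  zero <- keep & t0 == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " gene(s) with zero baseline excluded."))
    keep <- keep & !zero
  }
  tc <- timecourse[keep, ]
  out <- tc |>
    tidyr::pivot_longer(dplyr::all_of(tp_cols), names_to = "timepoint",
                        values_to = "abundance") |>
    group_by(.data$gene) |>
    mutate(retention = 100 * .data$abundance /
             .data$abundance[.data$timepoint == tp_cols[1]]) |>
    ungroup() |>
    mutate(timepoint = factor(.data$timepoint, levels = tp_cols)) |>
    select("gene", "timepoint", "retention")
  if (cap) out$retention <- pmin(out$retention, 100)
  out
}

#' Split expressed genes into targets and non-targets of a family
#'
#' @param genes character vector of expressed genes.
#' @param interactions a `comics_interactions` table.
#' @param family family identifier (must occur in the table).
#' @return list with character vectors `targets` and `non_targets`
#'   (disjoint, exhaustive over `genes`).
#' @export
partition_targets <- function(genes, interactions, family) {
  if (!family %in% interactions$family) {
    abort(paste0("Unknown family: ", family))
  }
  fam_targets <- interactions$gene[interactions$family == family]
  targets <- intersect(genes, fam_targets)
  list(targets = targets, non_targets = setdiff(genes, targets))
}

#' Spearman rank correlation over shared genes
#'
#' @param a,b named numeric vectors (gene -> value); the correlation is over
#'   the name intersection (at least 3 genes). Ties get average ranks.
#' @return tibble `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) abort("Need at least 3 shared genes.")
  ct <- suppressWarnings(cor.test(a[shared], b[shared], method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Paired shift between two retention vectors
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences over shared
#' genes. All-zero differences give p = 1 by contract; fewer than 5 pairs
#' triggers a warning and the exact small-sample path.
#'
#' @param ret_a,ret_b named numeric vectors (gene -> retention).
#' @return tibble `statistic`, `p_value`, `n`.
#' @export
paired_shift_test <- function(ret_a, ret_b) {
  shared <- intersect(names(ret_a), names(ret_b))
  if (length(shared) == 0) abort("No shared genes.")
  d <- ret_a[shared] - ret_b[shared]
  if (all(d == 0)) {
    return(tibble(statistic = NA_real_, p_value = 1, n = length(shared)))
  }
  if (length(shared) < 5) warn("Fewer than 5 pairs; exact test on a tiny sample.")
  wt <- suppressWarnings(wilcox.test(ret_a[shared], ret_b[shared],
                                     paired = TRUE,
                                     exact = length(shared) < 50))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n = length(shared))
}

#' Overlap between engaged pairs and a validated interaction list
#'
#' Hypergeometric upper-tail test of whether the simulation engaged the
#' validated interactions more than chance. At `level = "gene"` (default,
#' matching how validated CLASH-style lists are usually scored) the overlap
#' is between the set of engaged genes and the set of validated genes over
#' the expressed-gene background. At `level = "pair"` the universe is all
#' (gene, family) combinations over the background genes and the engaged
#' families' universe.
#'
#' @param engaged tibble with columns `family`, `gene` (e.g. `run$engaged`),
#'   optionally filtered by `max_iteration`.
#' @param validated tibble/data frame with columns `family`, `gene` (family
#'   may be `NA` for gene-only evidence at gene level).
#' @param background_genes expressed-gene universe.
#' @param level `"gene"` or `"pair"`.
#' @param families family universe for the pair-level test (default: those
#'   in `engaged`).
#' @param max_iteration keep only engagements with
#'   `first_iteration <= max_iteration` (cumulative window), if the column
#'   is present.
#' @return tibble as [set_overlap()].
#' @export
engaged_overlap <- function(engaged, validated, background_genes,
                            level = c("gene", "pair"), families = NULL,
                            max_iteration = Inf) {
  level <- match.arg(level)
  if (length(background_genes) == 0) abort("Empty background.")
  if ("first_iteration" %in% names(engaged)) {
    engaged <- engaged[engaged$first_iteration <= max_iteration, ]
  }
  if (level == "gene") {
    eng <- intersect(unique(engaged$gene), background_genes)
    val <- intersect(unique(validated$gene), background_genes)
    return(set_overlap(eng, val, background_genes))
  }
  families <- families %||% sort(unique(engaged$family))
  universe <- as.vector(outer(background_genes, families, paste, sep = "\r"))
  pair_key <- function(d) paste(d$gene, d$family, sep = "\r")
  eng <- intersect(unique(pair_key(engaged)), universe)
  val <- intersect(unique(pair_key(validated)), universe)
  set_overlap(eng, val, universe)
}
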