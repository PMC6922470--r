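#' Classify genes as cross-miRNA stable, sensitive or other
#'
#' A gene is \emph{stable} when its final retention exceeds
#' `stable_threshold` percent in at least `coverage` of the overexpression
#' columns, and \emph{sensitive} when retention falls below
#' `sensitive_threshold` in at least `coverage` of the columns (strict
#' comparisons on retention, `>=` on coverage). Everything else is
#' \emph{other}.
#'
#' @param screen a `comics_screen` (or a genes x families retention matrix
#'   in percent).
#' @param stable_threshold percent retention above which a column counts as
#'   stable (default 85).
#' @param sensitive_threshold percent retention below which a column counts
#'   as sensitive (default 50).
#' @param coverage required fraction of columns (default 0.9).
#' @return a `comics_classification` tibble: `gene`, `label` (factor
#'   stable/sensitive/other), `n_stable_columns`, `n_sensitive_columns`;
#'   thresholds kept as attributes.
#' @export
classify_genes <- function(screen, stable_threshold = 85,
                           sensitive_threshold = 50, coverage = 0.9) {
  values <- if (inherits(screen, "comics_screen")) screen$values else screen
  stopifnot(is.matrix(values), stable_threshold > sensitive_threshold)
  nf <- ncol(values)
  if (nf == 0) abort("No overexpression columns to classify on.")
  if (anyNA(values)) abort("Retention matrix has missing cells.")
  n_stable <- rowSums(values > stable_threshold)
  n_sensitive <- rowSums(values < sensitive_threshold)
  need <- coverage * nf
  label <- ifelse(n_stable >= need, "stable",
                  ifelse(n_sensitive >= need, "sensitive", "other"))
  out <- tibble(gene = rownames(values),
                label = factor(label, levels = c("stable", "sensitive", "other")),
                n_stable_columns = as.integer(n_stable),
                n_sensitive_columns = as.integer(n_sensitive))
  attr(out, "params") <- list(stable_threshold = stable_threshold,
                              sensitive_threshold = sensitive_threshold,
                              coverage = coverage, n_families = nf)
  class(out) <- c("comics_classification", class(tibble()))
  out
}

#' Per-gene targeting features
#'
#' For each gene in the transcript profile: the number of targeting miRNA
#' families, the total number of binding sites, the initial abundance in
#' molecules, and the mean expression (molecules) of its targeting families.
#' Genes with no interaction record get zero features and `targeted = FALSE`.
#'
#' @param interactions a `comics_interactions` table.
#' @param mirna miRNA family `comics_profile`.
#' @param mrna transcript `comics_profile`.
#' @return tibble `gene`, `n_targeting_families`, `n_mbs`,
#'   `initial_abundance`, `mean_targeting_mirna_expression`, `targeted`.
#' @export
gene_features <- function(interactions, mirna, mrna) {
  mirna_counts <- setNames(mirna$molecules, mirna$id)
  feats <- interactions |>
    mutate(n_sites = map_int(.data$sites, length),
           fam_expr = as.numeric(mirna_counts[.data$family])) |>
    mutate(fam_expr = ifelse(is.na(.data$fam_expr), 0, .data$fam_expr)) |>
    group_by(.data$gene) |>
    summarise(n_targeting_families = dplyr::n(),
              n_mbs = sum(.data$n_sites),
              mean_targeting_mirna_expression = mean(.data$fam_expr),
              .groups = "drop")
  tibble(gene = mrna$id, initial_abundance = mrna$molecules) |>
    left_join(feats, by = "gene") |>
    mutate(targeted = !is.na(.data$n_targeting_families),
           n_targeting_families = ifelse(.data$targeted,
                                         .data$n_targeting_families, 0L),
           n_mbs = ifelse(.data$targeted, .data$n_mbs, 0L),
           mean_targeting_mirna_expression =
             ifelse(.data$targeted, .data$mean_targeting_mirna_expression, 0)) |>
    select("gene", "n_targeting_families", "n_mbs", "initial_abundance",
           "mean_targeting_mirna_expression", "targeted")
}

#' Compare one feature between two classification groups
#'
#' Welch two-sample t test of a gene feature between two labels.
#'
#' @param classification a `comics_classification`.
#' @param features output of [gene_features()].
#' @param feature_name column of `features` to compare.
#' @param groups character pair of labels, e.g. `c("stable", "other")`.
#' @return tibble `feature`, `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`.
#' @export
compare_feature <- function(classification, features, feature_name,
                            groups = c("stable", "sensitive")) {
  stopifnot(length(groups) == 2, feature_name %in% names(features))
  joined <- inner_join(classification, features, by = "gene")
  x <- joined[[feature_name]][joined$label == groups[1]]
  y <- joined[[feature_name]][joined$label == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 genes for a t test.")
  }
  tt <- t.test(x, y)
  tibble(feature = feature_name, group1 = groups[1], group2 = groups[2],
         n1 = length(x), n2 = length(y),
         statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Gene-set overlap significance
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene sets drawn from a common background: hypergeometric by default
#' (exact), or a 2x2 chi-square.
#'
#' @param set_a,set_b character vectors, subsets of `background`.
#' @param background character vector, the shared gene universe.
#' @param method `"hypergeometric"` (default) or `"chisq"`.
#' @return tibble `overlap`, `n_a`, `n_b`, `n_background`, `expected`,
#'   `p_value`, `method`.
#' @export
set_overlap <- function(set_a, set_b, background,
                        method = c("hypergeometric", "chisq")) {
  method <- match.arg(method)
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  if (!all(set_a %in% background) || !all(set_b %in% background)) {
    abort("Both sets must be subsets of the background.")
  }
  N <- length(background)
  k <- length(intersect(set_a, set_b))
  a <- length(set_a); b <- length(set_b)
  p <- if (method == "hypergeometric") {
    phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  } else {
    m <- matrix(c(k, a - k, b - k, N - a - b + k), nrow = 2)
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
  tibble(overlap = k, n_a = a, n_b = b, n_background = N,
         expected = a * b / N, p_value = p, method = method)
}
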