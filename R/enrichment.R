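# Per-protein differential enrichment statistics and significance calls
# for proximity-labeling experiments.

#' Significance thresholds for interactor calling
#'
#' A protein is called a significant proximity interactor when its log2
#' fold change (experimental over control) strictly exceeds
#' `min_log2_fc` and its unpaired t-test p-value is strictly below
#' `max_p`.  No multiple-testing correction enters the call; a
#' Benjamini-Hochberg adjusted column is reported for information.
#'
#' @param min_log2_fc Minimum log2 fold change, strict (default 1).
#' @param max_p Maximum p-value, strict, in (0, 1) (default 0.05).
#' @return An `enrichment_thresholds` list.
#' @export
enrichment_thresholds <- function(min_log2_fc = 1, max_p = 0.05) {
  stopifnot(is.numeric(min_log2_fc), is.numeric(max_p),
            max_p > 0, max_p < 1)
  structure(list(min_log2_fc = min_log2_fc, max_p = max_p),
            class = "enrichment_thresholds")
}

#' Compute per-protein enrichment statistics
#'
#' For each protein: log2 fold change as the difference of group means of
#' log2 intensities, a two-sided unpaired t-test p-value across the two
#' groups, the mean experimental log2 intensity, and the significance
#' flag.  The default test is the classical pooled-variance (Student)
#' two-sample test; set `var_equal = FALSE` for Welch.  A protein whose
#' six values are all identical has no evidence of difference and gets
#' p = 1.
#'
#' @param matrix A fully imputed `log_intensity_matrix` (no missing
#'   cells): impute with [impute_lod()] or [impute_nd()] first.
#' @param thresholds An [enrichment_thresholds()] object.
#' @param var_equal Use pooled variance (default `TRUE`)?
#' @return An `enrichment_table` data frame with columns `group_id`,
#'   `log2_fc`, `p_value`, `neg_log10_p`, `mean_log2_sample`,
#'   `significant`, `p_adj_bh`, `n_imputed_exp`, `n_imputed_ctrl`, and
#'   the thresholds attached as attribute `"thresholds"`.
#' @export
#' @examples
#' sim <- generate_proteome(proteome_sim_config(seed = 1))
#' m <- impute_lod(log_transform(apply_filters(sim$table)$table))
#' head(compute_enrichment(m))
compute_enrichment <- function(matrix,
                               thresholds = enrichment_thresholds(),
                               var_equal = TRUE) {
  stopifnot(inherits(matrix, "log_intensity_matrix"),
            inherits(thresholds, "enrichment_thresholds"))
  if (anyNA(matrix$values))
    stop("matrix has missing cells: impute before testing")
  design <- matrix$design
  ie <- group_index(design, "experimental")
  ic <- group_index(design, "control")
  if (length(ie) < 2 || length(ic) < 2)
    stop("need at least 2 samples per group")
  xe <- matrix$values[, ie, drop = FALSE]
  xc <- matrix$values[, ic, drop = FALSE]
  n1 <- ncol(xe); n2 <- ncol(xc)
  m1 <- rowMeans(xe); m2 <- rowMeans(xc)
  v1 <- rowSums((xe - m1)^2) / (n1 - 1)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  tstat[se == 0 & m1 == m2] <- 0      # no variance, no difference
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0          # zero variance, distinct means

  counts <- imputation_counts(matrix)
  out <- data.frame(
    group_id = rownames(matrix$values),
    log2_fc = m1 - m2,
    p_value = p,
    neg_log10_p = -log10(p),
    mean_log2_sample = m1,
    significant = (m1 - m2 > thresholds$min_log2_fc) &
                  (p < thresholds$max_p),
    p_adj_bh = stats::p.adjust(p, method = "BH"),
    n_imputed_exp = counts$n_imputed_exp,
    n_imputed_ctrl = counts$n_imputed_ctrl,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Ordered list of significant proximity interactors
#'
#' @param table An `enrichment_table`.
#' @return Character vector of `group_id`s passing both thresholds,
#'   sorted by descending log2 fold change, ties broken by ascending
#'   p-value then by `group_id`.
#' @export
significant_set <- function(table) {
  stopifnot(inherits(table, "enrichment_table"))
  sig <- table[table$significant, , drop = FALSE]
  sig$group_id[order(-sig$log2_fc, sig$p_value, sig$group_id)]
}

#' Intersection of two significant-interactor lists
#'
#' @param a,b Character vectors of group ids (typically from
#'   [significant_set()]).
#' @return Elements of `a` also present in `b`, in `a`'s order.
#' @export
intersect_significant <- function(a, b) a[a %in% b]

#' Volcano plot table
#'
#' Projection of an enrichment table onto the volcano axes: -log10
#' p-value against log2 fold change (sample/control).
#'
#' @param table An `enrichment_table`.
#' @param labels Optional named character vector mapping `group_id` to a
#'   display label (e.g. gene names); unmatched ids get their own id.
#' @return Data frame with columns `log2_fc`, `neg_log10_p`,
#'   `significant`, `label`.
#' @export
volcano_table <- function(table, labels = NULL) {
  stopifnot(inherits(table, "enrichment_table"))
  data.frame(log2_fc = table$log2_fc,
             neg_log10_p = table$neg_log10_p,
             significant = table$significant,
             label = resolve_labels(table$group_id, labels),
             stringsAsFactors = FALSE)
}

#' MA-style plot table
#'
#' Projection of an enrichment table onto the MA axes: average log2 LFQ
#' intensity of the experimental samples against log2 fold change
#' (sample/control).  Separates low-abundance proximity interactors from
#' abundant endogenously biotinylated background such as the
#' carboxylases.
#'
#' @inheritParams volcano_table
#' @return Data frame with columns `mean_log2_sample`, `log2_fc`,
#'   `significant`, `label`.
#' @export
ma_table <- function(table, labels = NULL) {
  stopifnot(inherits(table, "enrichment_table"))
  data.frame(mean_log2_sample = table$mean_log2_sample,
             log2_fc = table$log2_fc,
             significant = table$significant,
             label = resolve_labels(table$group_id, labels),
             stringsAsFactors = FALSE)
}

resolve_labels <- function(ids, labels) {
  if (is.null(labels)) return(ids)
  out <- labels[ids]
  out[is.na(out) | out == ""] <- ids[is.na(out) | out == ""]
  unname(out)
}
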