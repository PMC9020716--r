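# Record-removal rules applied to proteinGroups tables before imputation
# and differential enrichment.

#' Filter a protein group table
#'
#' Removes, in a fixed order, (1) reverse-database identifications,
#' (2) potential contaminants, (3) groups identified only by a modified
#' peptide, (4) groups with fewer than `min_group_values` quantified
#' (nonzero) LFQ values in the required group(s), and (5) groups with
#' fewer than `min_razor` razor + unique peptides.  Each removed record is
#' counted once, under the first rule that removes it; the retained set
#' itself does not depend on rule order.
#'
#' `group_value_mode` controls which group must carry the minimum number
#' of quantified values.  The default `"any_group"` retains a protein if
#' either group has enough values: true proximity interactors are often
#' entirely absent from control samples, so demanding values in both
#' groups would discard exactly the hits of interest.
#'
#' @param table A `protein_group_table` from [read_protein_groups()] or
#'   [generate_proteome()].
#' @param min_razor Minimum razor + unique peptide count (default 2).
#' @param min_group_values Minimum number of quantified values required in
#'   a group (default 2).
#' @param group_value_mode One of `"any_group"` (default),
#'   `"experimental_group"`, `"both_groups"`.
#' @return List with elements `table` (the filtered `protein_group_table`)
#'   and `report` (a `filter_report`).
#' @export
#' @examples
#' sim <- generate_proteome(proteome_sim_config(seed = 1))
#' res <- apply_filters(sim$table)
#' res$report
apply_filters <- function(table, min_razor = 2, min_group_values = 2,
                          group_value_mode = c("any_group",
                                               "experimental_group",
                                               "both_groups")) {
  stopifnot(inherits(table, "protein_group_table"))
  group_value_mode <- match.arg(group_value_mode)
  info <- table$info
  n_exp_vals <- rowSums(table$lfq[, group_index(table$design,
                                                "experimental"),
                                  drop = FALSE] > 0)
  n_ctl_vals <- rowSums(table$lfq[, group_index(table$design, "control"),
                                  drop = FALSE] > 0)
  enough_values <- switch(group_value_mode,
    any_group          = pmax(n_exp_vals, n_ctl_vals) >= min_group_values,
    experimental_group = n_exp_vals >= min_group_values,
    both_groups        = pmin(n_exp_vals, n_ctl_vals) >= min_group_values)

  # first failing rule per record, in the fixed reporting order
  rule_order <- c("reverse", "contaminant", "only-by-site",
                  "min-group-values", "min-razor")
  fails <- cbind(info$is_reverse,
                 info$is_contaminant,
                 info$only_identified_by_site,
                 !enough_values,
                 info$razor_unique_peptides < min_razor)
  first_fail <- apply(fails, 1, function(f)
    if (any(f)) which(f)[1] else 0L)
  if (nrow(info) == 0) first_fail <- integer(0)

  keep <- first_fail == 0L
  removed <- tabulate(first_fail[first_fail > 0L], nbins = 5L)
  report <- structure(list(
    n_input = nrow(info),
    removed_reverse = removed[1],
    removed_contaminant = removed[2],
    removed_only_by_site = removed[3],
    removed_min_group_values = removed[4],
    removed_min_razor = removed[5],
    n_retained = sum(keep),
    rule_order = rule_order
  ), class = "filter_report")

  filtered <- new_protein_group_table(info[keep, , drop = FALSE],
                                      table$lfq[keep, , drop = FALSE],
                                      table$design)
  rownames(filtered$info) <- NULL
  list(table = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "input,", x$n_retained, "retained\n")
  cat(sprintf("  removed: reverse %d, contaminant %d, only-by-site %d, %s",
              x$removed_reverse, x$removed_contaminant,
              x$removed_only_by_site,
              sprintf("min-group-values %d, min-razor %d\n",
                      x$removed_min_group_values, x$removed_min_razor)))
  invisible(x)
}

#' Filter report as a one-row data frame
#' @param report A `filter_report`.
#' @return Data frame with one row of counts.
#' @export
filter_report_table <- function(report) {
  data.frame(n_input = report$n_input,
             removed_reverse = report$removed_reverse,
             removed_contaminant = report$removed_contaminant,
             removed_only_by_site = report$removed_only_by_site,
             removed_min_group_values = report$removed_min_group_values,
             removed_min_razor = report$removed_min_razor,
             n_retained = report$n_retained)
}
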