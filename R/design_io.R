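# Readers and validators for the sample design and MaxQuant-style
# proteinGroups tables.

#' Default column map for MaxQuant proteinGroups tables
#'
#' Maps the fields the pipeline needs onto the column headers of a raw
#' MaxQuant `proteinGroups.txt`.  Re-exported spreadsheets often rename
#' headers; pass an edited copy of this list to [read_protein_groups()]
#' to adapt.  LFQ columns are always resolved as
#' `paste("LFQ intensity", sample_id)` with the prefix taken from
#' `lfq_prefix`.
#'
#' @return Named list of column names.
#' @export
#' @examples
#' cmap <- default_column_map()
#' cmap$gene_names <- "Gene Names"   # adapt to a re-exported sheet
default_column_map <- function() {
  list(
    protein_ids  = "Majority protein IDs",
    gene_names   = "Gene names",
    razor_unique = "Razor + unique peptides",
    reverse      = "Reverse",
    contaminant  = "Potential contaminant",
    only_by_site = "Only identified by site",
    lfq_prefix   = "LFQ intensity"
  )
}

#' Construct a sample design
#'
#' A sample design maps sample labels to experimental or control group
#' membership with a replicate index.  A two-sided unpaired t-test needs at
#' least two replicates per group, so smaller groups are rejected.
#'
#' @param sample_id Character vector of unique sample labels.  Each label
#'   must match the suffix of an LFQ intensity column in the proteinGroups
#'   table.
#' @param group Character vector, each element `"experimental"` or
#'   `"control"`.
#' @param replicate Integer replicate index, unique within each group.
#'   Defaults to 1..n within group.
#' @return A `sample_design` data frame with columns `sample_id`, `group`,
#'   `replicate`.
#' @export
#' @examples
#' sample_design(c("exp1", "exp2", "exp3", "ctl1", "ctl2", "ctl3"),
#'               rep(c("experimental", "control"), each = 3))
sample_design <- function(sample_id, group, replicate = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("sample_id and group must have the same length")
  bad <- setdiff(unique(group), c("experimental", "control"))
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "),
         " (must be 'experimental' or 'control')")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1))
    stop("replicate indices must be positive integers")
  d <- data.frame(sample_id = sample_id, group = group,
                  replicate = replicate, stringsAsFactors = FALSE)
  for (g in c("experimental", "control")) {
    n <- sum(d$group == g)
    if (n < 2)
      stop("group too small for t-test: '", g, "' has ", n,
           " sample(s); at least 2 are required")
    if (anyDuplicated(d$replicate[d$group == g]))
      stop("duplicate replicate index within group '", g, "'")
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design file
#'
#' The design file is a delimited table (tab or comma separated, with a
#' header) with columns `sample_id`, `group` and optionally `replicate`.
#' Group labels must be `experimental` or `control`, and both groups need
#' at least two samples.
#'
#' @param path Path to the design file.
#' @return A validated [sample_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8-BOM", comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% names(d)))
    stop("design file must have columns 'sample_id' and 'group'; found: ",
         paste(names(d), collapse = ", "))
  sample_design(d$sample_id, d$group,
                replicate = if ("replicate" %in% names(d)) d$replicate)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated proteinGroups table into the pipeline's data
#' model.  Boolean QC flags use MaxQuant's `"+"` convention (a `"+"` cell
#' means true, anything else false).  LFQ intensity columns are resolved
#' by exact match `"LFQ intensity <sample_id>"` for every sample in the
#' design; empty numeric cells parse as 0, which means "not quantified".
#'
#' @param path Path to the tab-separated table.
#' @param design A [sample_design()].
#' @param column_map Column-name map, see [default_column_map()].
#' @return A `protein_group_table`: list with elements `info` (data frame
#'   of `group_id`, `protein_ids`, `gene_names`, `razor_unique_peptides`,
#'   `is_reverse`, `is_contaminant`, `only_identified_by_site`), `lfq`
#'   (numeric matrix, proteins x samples, linear scale, 0 = not
#'   quantified) and `design`.
#' @export
read_protein_groups <- function(path, design,
                                column_map = default_column_map()) {
  if (!file.exists(path)) stop("proteinGroups file not found: ", path)
  stopifnot(inherits(design, "sample_design"))
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           fileEncoding = "UTF-8-BOM", comment.char = "")
  lfq_cols <- paste(column_map$lfq_prefix, design$sample_id)
  missing_cols <- setdiff(lfq_cols, names(raw))
  if (length(missing_cols))
    stop("missing LFQ columns: ", paste(missing_cols, collapse = ", "))
  if (!column_map$protein_ids %in% names(raw))
    stop("missing column: ", column_map$protein_ids)

  n <- nrow(raw)
  get_col <- function(key, default) {
    nm <- column_map[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  flag <- function(x) !is.na(x) & trimws(x) == "+"

  protein_ids <- raw[[column_map$protein_ids]]
  razor <- get_col("razor_unique", "0")
  razor_num <- suppressWarnings(as.numeric(razor))
  razor_num[is.na(razor_num) & trimws(razor) == ""] <- 0
  if (anyNA(razor_num)) {
    i <- which(is.na(razor_num))[1]
    stop("non-numeric peptide count at row ", i, ", column '",
         column_map$razor_unique, "': '", razor[i], "'")
  }

  lfq <- matrix(0, nrow = n, ncol = nrow(design),
                dimnames = list(NULL, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cell <- raw[[lfq_cols[j]]]
    val <- suppressWarnings(as.numeric(cell))
    val[is.na(val) & (is.na(cell) | trimws(cell) == "")] <- 0
    if (anyNA(val)) {
      i <- which(is.na(val))[1]
      stop("non-numeric intensity at row ", i, ", column '", lfq_cols[j],
           "': '", cell[i], "'")
    }
    if (any(val < 0) || any(!is.finite(val)))
      stop("negative or non-finite intensity in column '", lfq_cols[j], "'")
    lfq[, j] <- val
  }

  group_id <- vapply(strsplit(protein_ids, ";", fixed = TRUE),
                     function(x) if (length(x)) x[1] else NA_character_,
                     character(1))
  if (n > 0 && anyDuplicated(group_id))
    stop("duplicate protein group ids: ",
         paste(unique(group_id[duplicated(group_id)]), collapse = ", "))

  info <- data.frame(
    group_id = group_id,
    protein_ids = protein_ids,
    gene_names = get_col("gene_names", ""),
    razor_unique_peptides = as.integer(round(razor_num)),
    is_reverse = flag(get_col("reverse", "")),
    is_contaminant = flag(get_col("contaminant", "")),
    only_identified_by_site = flag(get_col("only_by_site", "")),
    stringsAsFactors = FALSE
  )
  rownames(lfq) <- info$group_id
  new_protein_group_table(info, lfq, design)
}

new_protein_group_table <- function(info, lfq, design) {
  stopifnot(nrow(info) == nrow(lfq), ncol(lfq) == nrow(design))
  structure(list(info = info, lfq = lfq, design = design),
            class = "protein_group_table")
}

#' @export
print.protein_group_table <- function(x, ...) {
  cat("protein_group_table:", nrow(x$info), "protein groups,",
      nrow(x$design), "samples (",
      sum(x$design$group == "experimental"), "experimental /",
      sum(x$design$group == "control"), "control )\n")
  invisible(x)
}

#' Number of protein groups in a table
#' @param table A `protein_group_table`.
#' @return Integer count.
#' @export
n_protein_groups <- function(table) nrow(table$info)

#' Write a protein group table back to the MaxQuant dialect
#'
#' Inverse of [read_protein_groups()] (same column map): re-reading the
#' written file yields an identical table.
#'
#' @param table A `protein_group_table`.
#' @param path Output path (tab-separated).
#' @param column_map Column-name map, see [default_column_map()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path,
                                 column_map = default_column_map()) {
  info <- table$info
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = info$protein_ids, b = info$gene_names,
    c = info$razor_unique_peptides,
    d = ifelse(info$is_reverse, "+", ""),
    e = ifelse(info$is_contaminant, "+", ""),
    f = ifelse(info$only_identified_by_site, "+", ""))
  names(out) <- c(column_map$protein_ids, column_map$gene_names,
                  column_map$razor_unique, column_map$reverse,
                  column_map$contaminant, column_map$only_by_site)
  lfq <- as.data.frame(table$lfq, check.names = FALSE)
  names(lfq) <- paste(column_map$lfq_prefix, table$design$sample_id)
  out <- cbind(out, lfq)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# sample indices of a design group, in design order
group_index <- function(design, group) which(design$group == group)
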