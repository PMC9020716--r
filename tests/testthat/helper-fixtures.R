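# In-code fixtures shared across test files.

design_3v3 <- function() {
  sample_design(c("exp1", "exp2", "exp3", "ctl1", "ctl2", "ctl3"),
                rep(c("experimental", "control"), each = 3))
}

# Build a protein_group_table directly from a flag data frame and an LFQ
# matrix (linear scale, 0 = not quantified).
toy_table <- function(info, lfq, design = design_3v3()) {
  defaults <- data.frame(
    group_id = info$group_id,
    protein_ids = info$group_id,
    gene_names = "",
    razor_unique_peptides = 5L,
    is_reverse = FALSE,
    is_contaminant = FALSE,
    only_identified_by_site = FALSE,
    stringsAsFactors = FALSE)
  for (nm in setdiff(names(info), "group_id")) defaults[[nm]] <- info[[nm]]
  rownames(lfq) <- defaults$group_id
  colnames(lfq) <- design$sample_id
  proxitome:::new_protein_group_table(defaults, lfq, design)
}

# A log_intensity_matrix with given values (NA = missing).
toy_matrix <- function(values, design = design_3v3()) {
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  proxitome:::new_log_intensity_matrix(
    values, observed_mask = !is.na(values),
    imputed_mask = array(FALSE, dim(values), dimnames(values)),
    design = design)
}

# Write a small proteinGroups fixture in the MaxQuant dialect; returns
# the path.  Content matches the hand-parse assertions in test-design_io.
write_pg_fixture <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    paste("Majority protein IDs", "Gene names", "Razor + unique peptides",
          "Reverse", "Potential contaminant", "Only identified by site",
          "LFQ intensity exp1", "LFQ intensity exp2",
          "LFQ intensity exp3", "LFQ intensity ctl1",
          "LFQ intensity ctl2", "LFQ intensity ctl3", sep = "\t"),
    paste("P1;P1b", "geneA", "7", "", "", "",
          "1048576", "2097152", "1048576", "0", "", "1024", sep = "\t"),
    paste("P2", "geneB", "3", "+", "", "",
          "2048", "2048", "2048", "2048", "2048", "2048", sep = "\t"),
    paste("P3", "", "1", "", "+", "",
          "0", "0", "4096", "8192", "8192", "8192", sep = "\t"))
  writeLines(lines, path)
  path
}
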