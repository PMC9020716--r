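# Log2 transformation and missing-value imputation for LFQ intensity
# matrices.  Two schemes are provided: deterministic lowest-of-detection
# (LOD) and left-censored normal draws (ND).

#' Log2-transform a protein group table into an intensity matrix
#'
#' Linear-scale LFQ intensities become log2 values; zeros (not
#' quantified) become missing cells.  Should be applied after
#' [apply_filters()].
#'
#' @param table A `protein_group_table`.
#' @return A `log_intensity_matrix`: list with `values` (proteins x
#'   samples, `NA` = missing), `observed_mask`, `imputed_mask` (both
#'   logical matrices), and the `design`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  lfq <- table$lfq
  if (any(lfq < 0)) stop("negative intensity encountered")
  values <- ifelse(lfq > 0, log2(lfq), NA_real_)
  dimnames(values) <- list(table$info$group_id, table$design$sample_id)
  new_log_intensity_matrix(values, observed_mask = !is.na(values),
                           imputed_mask = array(FALSE, dim(values),
                                                dimnames(values)),
                           design = table$design)
}

new_log_intensity_matrix <- function(values, observed_mask, imputed_mask,
                                     design) {
  stopifnot(identical(dim(values), dim(observed_mask)),
            identical(dim(values), dim(imputed_mask)),
            !any(observed_mask & imputed_mask))
  structure(list(values = values, observed_mask = observed_mask,
                 imputed_mask = imputed_mask, design = design),
            class = "log_intensity_matrix")
}

#' @export
print.log_intensity_matrix <- function(x, ...) {
  cat("log_intensity_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "samples;", sum(!x$observed_mask & !x$imputed_mask),
      "missing,", sum(x$imputed_mask), "imputed\n")
  invisible(x)
}

#' Lowest-of-detection (LOD) imputation
#'
#' Deterministically fills each missing cell with the lowest observed
#' log2 value of the same sample column (the same MS run).  Models
#' left-censoring at the per-run detection limit: a value that was not
#' quantified is assumed to sit at the lowest level the run detected.
#'
#' @param matrix A `log_intensity_matrix` from [log_transform()].
#' @return The matrix with all missing cells filled and `imputed_mask`
#'   marking them.  Observed cells are never altered.
#' @export
impute_lod <- function(matrix) {
  stopifnot(inherits(matrix, "log_intensity_matrix"))
  values <- matrix$values
  missing <- is.na(values)
  if (!any(missing)) return(matrix)
  for (j in seq_len(ncol(values))) {
    mj <- missing[, j]
    if (!any(mj)) next
    obs <- values[matrix$observed_mask[, j], j]
    if (length(obs) == 0)
      stop("no observed values in sample '", colnames(values)[j],
           "'; cannot impute its detection limit")
    values[mj, j] <- min(obs)
  }
  new_log_intensity_matrix(values, matrix$observed_mask,
                           matrix$imputed_mask | missing, matrix$design)
}

#' Parameters for normal-distribution (ND) imputation
#'
#' Perseus-style left-censored imputation: missing values are drawn from
#' a normal distribution whose mean is the dataset mean shifted down by
#' `shift` standard deviations and whose standard deviation is `width`
#' times the dataset standard deviation.
#'
#' @param shift Down-shift in dataset SD units (default 1.8).
#' @param width Width of the imputation distribution in dataset SD units
#'   (default 0.3); must be positive.
#' @param seed Integer seed for the draws.
#' @return An `nd_params` list.
#' @export
nd_params <- function(shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(is.numeric(shift), is.numeric(width), width > 0)
  structure(list(shift = shift, width = width, seed = as.integer(seed)),
            class = "nd_params")
}

#' Normal-distribution (ND) imputation
#'
#' Fills each missing cell with an independent draw from
#' `Normal(m - shift*s, (width*s)^2)` where `m` and `s` are the mean and
#' standard deviation of all observed log2 values in the whole matrix.
#' Draws are seeded: the same matrix, parameters and seed give
#' bit-identical output.  The global RNG state is left untouched.
#'
#' @param matrix A `log_intensity_matrix` from [log_transform()].
#' @param params An [nd_params()] object.
#' @return The matrix with all missing cells filled and `imputed_mask`
#'   marking them.  Observed cells are never altered.
#' @export
impute_nd <- function(matrix, params = nd_params()) {
  stopifnot(inherits(matrix, "log_intensity_matrix"),
            inherits(params, "nd_params"))
  values <- matrix$values
  obs <- values[matrix$observed_mask]
  if (length(obs) < 2)
    stop("need at least 2 observed values to model the dataset")
  m <- mean(obs)
  s <- stats::sd(obs)
  if (s == 0) stop("degenerate dataset: all observed values are equal")
  missing <- is.na(values)
  if (!any(missing)) return(matrix)
  draws <- with_seed(params$seed,
                     stats::rnorm(sum(missing),
                                  mean = m - params$shift * s,
                                  sd = params$width * s))
  values[missing] <- draws
  new_log_intensity_matrix(values, matrix$observed_mask,
                           matrix$imputed_mask | missing, matrix$design)
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-protein imputation counts by design group
#'
#' @param matrix An imputed `log_intensity_matrix`.
#' @return Data frame with columns `n_imputed_exp`, `n_imputed_ctrl`.
#' @keywords internal
imputation_counts <- function(matrix) {
  data.frame(
    n_imputed_exp = rowSums(matrix$imputed_mask[,
      group_index(matrix$design, "experimental"), drop = FALSE]),
    n_imputed_ctrl = rowSums(matrix$imputed_mask[,
      group_index(matrix$design, "control"), drop = FALSE]))
}
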