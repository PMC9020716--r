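# Synthetic proteomes and FRAP data with known ground truth.
#
# The proteome generator emulates the statistical structure of a
# proximity-labeling LFQ experiment: log-normal protein abundances, a
# small class of true bait-proximal proteins sitting near the detection
# limit that are enriched in experimental samples and left-censored
# (missing) in controls, a class of very abundant endogenously
# biotinylated background proteins (carboxylase-like) present in both
# groups, ordinary shared background, and decoy records carrying QC
# flags.

#' Configuration for the synthetic proteome generator
#'
#' Abundances are drawn on the log2 scale (log-normal intensities).
#' Interactors sit near the detection limit so that censoring makes them
#' missing-not-at-random in control samples, while carboxylase-like
#' proteins are far above the limit and quantified everywhere —
#' mirroring the abundance gap between proximity interactors and
#' endogenously biotinylated carboxylases in real pulldowns.
#'
#' @param n_interactors True bait-proximal proteins (default 12).
#' @param n_carboxylase_like Very abundant both-group background
#'   proteins (default 4, like the four major biotin-dependent
#'   carboxylases).
#' @param n_background Ordinary shared proteins (default 300).
#' @param n_decoys Records flagged reverse / contaminant / site-only or
#'   with a single razor peptide, spread evenly over the four defect
#'   kinds (default 30).
#' @param replicates_per_group Replicates per group (default 3).
#' @param interactor_mean,interactor_sd Log2 abundance of interactors in
#'   control conditions (default 20.5 +/- 0.5), just below the detection
#'   limit.
#' @param carboxylase_mean,carboxylase_sd Log2 abundance of
#'   carboxylase-like proteins (default 31 +/- 1).
#' @param background_mean,background_sd Log2 abundance of ordinary
#'   background (default 25 +/- 2).
#' @param interactor_effect Log2 enrichment added to interactors in
#'   experimental samples only (default 4).
#' @param bait_effect Log2 enrichment of the single simulated bait
#'   (default 6; baits top their own candidate lists).
#' @param detection_limit_log2 Left-censoring threshold on the log2
#'   scale (default 21); values below it are recorded as not quantified.
#' @param noise_sd_log2 Replicate-to-replicate log2 noise SD
#'   (default 0.4).
#' @param seed Integer seed.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(n_interactors = 12,
                                n_carboxylase_like = 4,
                                n_background = 300,
                                n_decoys = 30,
                                replicates_per_group = 3,
                                interactor_mean = 20.5,
                                interactor_sd = 0.5,
                                carboxylase_mean = 31,
                                carboxylase_sd = 1,
                                background_mean = 25,
                                background_sd = 2,
                                interactor_effect = 4,
                                bait_effect = 6,
                                detection_limit_log2 = 21,
                                noise_sd_log2 = 0.4,
                                seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_interactors, cfg$n_carboxylase_like,
              cfg$n_background, cfg$n_decoys)
  stopifnot(all(counts >= 0), cfg$replicates_per_group >= 2,
            cfg$noise_sd_log2 > 0)
  structure(cfg, class = "proteome_sim_config")
}

#' Generate a synthetic proteinGroups table with ground-truth labels
#'
#' Each protein draws a class-specific base log2 abundance; replicate
#' values add independent normal noise; interactors and the bait receive
#' `interactor_effect` (or `bait_effect`) extra log2 units in
#' experimental samples only; values below `detection_limit_log2` are
#' censored to "not quantified" (exported as 0 on the linear scale).
#' Decoy records receive QC flags and survive no filter.  Output is
#' deterministic for a given config (including its seed).
#'
#' @param config A [proteome_sim_config()].
#' @return List with `table` (a `protein_group_table`), `truth` (data
#'   frame of `group_id`, `class` in bait / interactor /
#'   carboxylase_like / background / decoy) and `pre_censor` (the log2
#'   value matrix before censoring, the oracle for which cells were
#'   censored).
#' @export
#' @examples
#' sim <- generate_proteome(proteome_sim_config(seed = 42))
#' table(sim$truth$class)
generate_proteome <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "proteome_sim_config"))
  with_seed(config$seed, {
    nrep <- config$replicates_per_group
    design <- sample_design(
      c(paste0("exp", seq_len(nrep)), paste0("ctl", seq_len(nrep))),
      rep(c("experimental", "control"), each = nrep))

    classes <- c("bait",
                 rep("interactor", config$n_interactors),
                 rep("carboxylase_like", config$n_carboxylase_like),
                 rep("background", config$n_background),
                 rep("decoy", config$n_decoys))
    n <- length(classes)
    ids <- c("BAIT1",
             sprintf("INT%03d", seq_len(config$n_interactors)),
             sprintf("CARB%02d", seq_len(config$n_carboxylase_like)),
             sprintf("BG%04d", seq_len(config$n_background)),
             sprintf("DEC%03d", seq_len(config$n_decoys)))

    base_mean <- c(bait = config$interactor_mean,
                   interactor = config$interactor_mean,
                   carboxylase_like = config$carboxylase_mean,
                   background = config$background_mean,
                   decoy = config$background_mean)[classes]
    base_sd <- c(bait = config$interactor_sd,
                 interactor = config$interactor_sd,
                 carboxylase_like = config$carboxylase_sd,
                 background = config$background_sd,
                 decoy = config$background_sd)[classes]
    base <- stats::rnorm(n, base_mean, base_sd)

    effect <- ifelse(classes == "bait", config$bait_effect,
                     ifelse(classes == "interactor",
                            config$interactor_effect, 0))
    is_exp <- design$group == "experimental"
    log2_vals <- base +
      outer(effect, as.numeric(is_exp)) +
      matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd_log2),
             n, nrow(design))
    dimnames(log2_vals) <- list(ids, design$sample_id)

    censored <- log2_vals < config$detection_limit_log2
    lfq <- ifelse(censored, 0, 2^log2_vals)

    # decoy defect kinds cycle: reverse, contaminant, site-only, 1 razor
    kind <- rep(c("reverse", "contaminant", "only_by_site", "low_razor"),
                length.out = config$n_decoys)
    is_decoy <- classes == "decoy"
    razor <- 2L + stats::rpois(n, 8)
    razor[is_decoy][kind == "low_razor"] <- 1L
    info <- data.frame(
      group_id = ids,
      protein_ids = ids,
      gene_names = tolower(ids),
      razor_unique_peptides = razor,
      is_reverse = replace(rep(FALSE, n), which(is_decoy)[kind == "reverse"],
                           TRUE),
      is_contaminant = replace(rep(FALSE, n),
                               which(is_decoy)[kind == "contaminant"], TRUE),
      only_identified_by_site = replace(rep(FALSE, n),
                                        which(is_decoy)[kind == "only_by_site"],
                                        TRUE),
      stringsAsFactors = FALSE)

    list(table = new_protein_group_table(info, lfq, design),
         truth = data.frame(group_id = ids, class = classes,
                            stringsAsFactors = FALSE),
         pre_censor = log2_vals)
  })
}

#' Write a simulated proteome to disk
#'
#' Writes the proteinGroups-dialect TSV, the sample design TSV and the
#' truth-label TSV, the same files a real analysis would start from.
#'
#' @param sim Result of [generate_proteome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(protein_groups = file.path(dir, "proteinGroups.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_protein_groups(sim$table, paths["protein_groups"])
  utils::write.table(as.data.frame(sim$table$design), paths["design"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a noisy single-exponential FRAP trace
#'
#' Pre-bleach points are exactly 1.0 (the normalized steady state);
#' post-bleach points follow `A * (1 - exp(-k * X)) + B` with `X`
#' measured from the first post-bleach time point, plus independent
#' normal noise.
#'
#' @param A Mobile fraction (> 0).
#' @param k Recovery rate in 1/s (> 0).
#' @param B Background remaining right after the bleach.
#' @param times Acquisition times in seconds, strictly increasing.
#' @param bleach_index 1-based index of the first post-bleach point.
#' @param noise_sd SD of additive noise on post-bleach points.
#' @param seed Integer seed.
#' @return A normalized `frap_trace` (its `raw` equals its `normalized`).
#' @export
generate_frap_trace <- function(A, k, B, times, bleach_index,
                                noise_sd = 0, seed = 1L) {
  stopifnot(A > 0, k > 0, noise_sd >= 0)
  times <- as.numeric(times)
  post <- bleach_index:length(times)
  x <- times[post] - times[bleach_index]
  y <- rep(1, length(times))
  model <- A * (1 - exp(-k * x)) + B
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(x), 0, noise_sd)) else 0
  y[post] <- model + noise
  frap_trace(times, y, bleach_index, normalized = y)
}

#' Render a FRAP trace as a synthetic image stack
#'
#' Each frame is a flat background plus a Gaussian spot whose integrated
#' amplitude follows the trace's raw intensity series, plus pixel noise.
#' Returns the stack together with a [region_pair()] sized to capture
#' the spot (inner) and the local background (ring), so that
#' [extract_trace()] on the stack recovers the input series.
#'
#' @param trace A `frap_trace` whose `raw` series gives the integrated
#'   spot amplitude per frame.
#' @param frame_shape `c(ny, nx)` pixels (default 64 x 64).
#' @param spot_center `c(x, y)` 0-based pixel coordinates of the spot.
#' @param spot_sigma Gaussian SD of the spot in pixels (default 2).
#' @param background_level Flat background intensity (default 50).
#' @param noise_sd SD of per-pixel noise (default 0).
#' @param seed Integer seed for pixel noise.
#' @return List with `stack` (array `[y, x, t]`) and `regions`.
#' @export
generate_frap_stack <- function(trace, frame_shape = c(64, 64),
                                spot_center = c(32, 32), spot_sigma = 2,
                                background_level = 50, noise_sd = 0,
                                seed = 1L) {
  stopifnot(inherits(trace, "frap_trace"), spot_sigma > 0)
  ny <- frame_shape[1]; nx <- frame_shape[2]
  half <- ceiling(4 * spot_sigma)
  cx <- spot_center[1]; cy <- spot_center[2]
  if (cx - half < 1 || cy - half < 1 ||
      cx + half > nx - 2 || cy + half > ny - 2)
    stop("spot (with its capture region) does not fit in the frame")

  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  kernel <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * spot_sigma^2))
  kernel <- kernel / sum(kernel)

  nt <- length(trace$times)
  stack <- array(background_level, c(ny, nx, nt))
  for (i in seq_len(nt))
    stack[, , i] <- stack[, , i] + trace$raw[i] * kernel
  if (noise_sd > 0)
    stack <- stack + with_seed(seed,
      array(stats::rnorm(length(stack), 0, noise_sd), dim(stack)))

  inner <- c(cx - half, cy - half, cx + half + 1, cy + half + 1)
  margin <- max(3, half)
  outer <- c(inner[1] - margin, inner[2] - margin,
             inner[3] + margin, inner[4] + margin)
  outer[1:2] <- pmax(outer[1:2], 0)
  outer[3] <- min(outer[3], nx)
  outer[4] <- min(outer[4], ny)
  list(stack = stack, regions = region_pair(inner, outer))
}
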