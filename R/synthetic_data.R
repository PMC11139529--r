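# Synthetic instrument output: calibration series under a linear detector
# response, batch peak-area tables with planted two-group structure plus
# outliers, spike-recovery designs, and random simple graphs. Every
# generator is deterministic under its seed.
#
# Default configuration mirrors the study design the package targets:
# 4 analytes, 6-level 2-fold serial-dilution calibration, 14 batches with
# latent groups of 5 and 6 plus 3 outliers, 0.5 g / 100 ml sample prep,
# and multiplicative (CV-style) detector noise of about 1% matching
# instrument-precision RSDs of roughly 1-3%.

#' Default simulation configuration
#'
#' @param seed Integer seed.
#' @param analytes data.frame `name, true_slope, true_intercept, top_conc`
#'   (peak-area response per ug/ml; top calibration level in ug/ml).
#' @param n_levels Calibration levels per analyte.
#' @param dilution_factor Serial-dilution factor between levels.
#' @param noise_cv Multiplicative noise CV (fraction of signal).
#' @param additive_noise_sd Optional additive noise SD (detector units).
#' @param batches Total number of batches.
#' @param group_means Matrix (groups x analytes) of true contents (w/w %).
#' @param group_sizes Sizes of the latent groups; must sum to
#'   `batches - n_outliers`.
#' @param group_sd Per-analyte within-group SD of true contents.
#' @param n_outliers Batches drawn from a shifted distribution.
#' @param outlier_shift_sd Outlier shift, in multiples of `group_sd`.
#' @param prep A [sample_prep()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       analytes = data.frame(
                         name = c("GA", "TEGG", "EA", "PEGG"),
                         true_slope = c(8.6962, 6.84, 43.0207, 5.6759),
                         true_intercept = c(10.2544, -61.1284, -89.5458, -50.9605),
                         top_conc = c(365, 1018, 123, 436),
                         stringsAsFactors = FALSE),
                       n_levels = 6,
                       dilution_factor = 2,
                       noise_cv = 0.01,
                       additive_noise_sd = 0,
                       batches = 14,
                       group_means = rbind(
                         g1 = c(GA = 4.0, TEGG = 4.5, EA = 0.62, PEGG = 2.65),
                         g2 = c(GA = 3.5, TEGG = 6.2, EA = 0.50, PEGG = 3.00)),
                       group_sizes = c(5, 6),
                       group_sd = c(GA = 0.35, TEGG = 0.55, EA = 0.06,
                                    PEGG = 0.20),
                       n_outliers = 3,
                       outlier_shift_sd = 4,
                       prep = sample_prep(0.5, 100, 1)) {
  stopifnot(noise_cv >= 0, all(analytes$true_slope > 0),
            nrow(group_means) == length(group_sizes))
  if (sum(group_sizes) != batches - n_outliers)
    stop("group sizes must sum to batches - n_outliers")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a calibration series
#'
#' For each analyte, `n_levels` serial dilutions from its top
#' concentration; area = slope * conc + intercept + noise, with
#' multiplicative noise ~ Normal(0, noise_cv * |slope * conc|) plus
#' optional additive noise.
#'
#' @param config A [sim_config()].
#' @return data.frame `analyte, conc_ug_ml, area` (calibration CSV rows).
#' @export
gen_calibration <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- lapply(seq_len(nrow(config$analytes)), function(i) {
    an <- config$analytes[i, ]
    conc <- serial_dilution_levels(an$top_conc, config$dilution_factor,
                                   config$n_levels)
    signal <- an$true_slope * conc + an$true_intercept
    noise <- stats::rnorm(length(conc), 0,
                          config$noise_cv * abs(an$true_slope * conc)) +
      if (config$additive_noise_sd > 0)
        stats::rnorm(length(conc), 0, config$additive_noise_sd) else 0
    data.frame(analyte = an$name, conc_ug_ml = conc, area = signal + noise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate batch peak areas with planted group structure
#'
#' True contents are drawn per batch and analyte from
#' Normal(group mean, group sd); outlier batches have their means shifted
#' by `outlier_shift_sd` group SDs. Contents are converted to solution
#' concentrations through the prep parameters and to areas through the
#' noiseless response line, then detector noise is added.
#'
#' @param config A [sim_config()].
#' @return List with `peaks` (data.frame `batch_id, analyte, area`) and
#'   `truth` (data.frame `batch_id, group, outlier`, plus one true-content
#'   column per analyte).
#' @export
gen_batches <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  analytes <- config$analytes$name
  n_groups <- length(config$group_sizes)
  group <- c(rep(seq_len(n_groups), config$group_sizes),
             rep(NA_integer_, config$n_outliers))
  outlier <- is.na(group)
  batch_id <- sprintf("S%d", seq_len(config$batches))
  truth <- data.frame(batch_id = batch_id, group = group, outlier = outlier,
                      stringsAsFactors = FALSE)
  contents <- matrix(NA_real_, config$batches, length(analytes),
                     dimnames = list(batch_id, analytes))
  for (b in seq_len(config$batches)) {
    g <- group[b]
    mu <- if (is.na(g)) {
      base <- config$group_means[1 + (b %% nrow(config$group_means)), ]
      base + config$outlier_shift_sd * config$group_sd *
        sign(stats::rnorm(length(analytes)))
    } else config$group_means[g, ]
    contents[b, ] <- pmax(stats::rnorm(length(analytes), mu, config$group_sd),
                          1e-6)
  }
  truth <- cbind(truth, as.data.frame(contents))
  rows <- lapply(seq_len(config$batches), function(b) {
    conc <- ww_to_conc(contents[b, ], config$prep)
    an <- config$analytes
    signal <- an$true_slope * conc + an$true_intercept
    noise <- stats::rnorm(length(conc), 0,
                          config$noise_cv * abs(an$true_slope * conc))
    data.frame(batch_id = batch_id[b], analyte = analytes,
               area = signal + noise, stringsAsFactors = FALSE)
  })
  list(peaks = do.call(rbind, rows), truth = truth)
}

#' Generate a spike-recovery design
#'
#' For each analyte, three spike levels (fractions of the native amount,
#' default 80/100/120%) with `n_rep` replicates each; the found amount is
#' native + spike perturbed by multiplicative noise.
#'
#' @param config A [sim_config()].
#' @param native_mg Named per-analyte native amounts (mg) in the test
#'   portion; defaults derived from group-1 means and the prep mass.
#' @param levels Spike levels as fractions of the native amount.
#' @param n_rep Replicates per level.
#' @return data.frame `analyte, sample_mg, spiked_mg, found_mg`.
#' @export
gen_recovery <- function(config = sim_config(), native_mg = NULL,
                         levels = c(0.8, 1.0, 1.2), n_rep = 3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  analytes <- config$analytes$name
  if (is.null(native_mg))
    native_mg <- config$group_means[1, analytes] / 100 *
      config$prep$mass_g * 1000
  rows <- lapply(analytes, function(an) {
    nat <- native_mg[[an]]
    do.call(rbind, lapply(levels, function(lv) {
      spike <- nat * lv
      found <- (nat + spike) *
        (1 + stats::rnorm(n_rep, 0, max(config$noise_cv, 1e-12)))
      data.frame(analyte = an, sample_mg = nat, spiked_mg = spike,
                 found_mg = found, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Generate a uniform random simple graph
#'
#' `n_edges` edges sampled uniformly without replacement from all node
#' pairs; deterministic under `seed`.
#'
#' @param n_nodes Number of nodes (labelled `T1..Tn`).
#' @param n_edges Number of edges, <= n(n-1)/2.
#' @param seed Integer seed.
#' @return `interaction_network`.
#' @export
gen_network <- function(n_nodes, n_edges, seed = 1) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges)
    stop("infeasible edge count: ", n_edges, " > ", max_edges)
  set.seed(seed)
  pairs <- t(utils::combn(n_nodes, 2))
  pick <- sample.int(nrow(pairs), n_edges)
  labels <- sprintf("T%d", seq_len(n_nodes))
  interaction_network(cbind(labels[pairs[pick, 1]], labels[pairs[pick, 2]]),
                      nodes = labels)
}
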