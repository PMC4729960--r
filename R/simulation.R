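#' Parameters of the synthetic fractionation-profile generator
#'
#' The simulator emulates the structure of a 10-plex LOPIT experiment:
#' each compartment class has a characteristic distribution across the ten
#' gradient fractions (a Dirichlet template with one peak channel), proteins
#' yield several PSMs whose reporter values scatter around the protein's
#' true profile with multiplicative lognormal noise, low-intensity reporters
#' drop out preferentially, a share of non-marker proteins carries a mixed
#' (two-compartment convex) localization, and a contamination knob `lambda`
#' compresses every true profile towards the population-average profile —
#' the first-order signature of reporter-ion interference in MS2-style
#' quantification.
#'
#' @param n_classes number of compartment classes K.
#' @param n_channels reporter channels C (default 10).
#' @param proteins_per_class proteins simulated per class.
#' @param markers_per_class proteins per class carrying a curated marker
#'   label (markers are always pure, never mixed).
#' @param psm_per_protein_mean mean of the zero-truncated Poisson PSM count.
#' @param class_templates optional K x C matrix of row-stochastic templates;
#'   by default each class gets a Dirichlet draw with concentration 50 on
#'   its peak channel and 1 elsewhere.
#' @param noise_sd sd of the per-channel multiplicative lognormal noise.
#' @param missing_rate marginal per-entry missingness probability
#'   (intensity-weighted: low-intensity reporters drop out more often).
#' @param contamination interference weight `lambda` in `[0, 1]`.
#' @param mixed_fraction share of non-marker proteins drawn as convex
#'   combinations of two class templates (mixing weight `theta ~ U(0.2, 0.8)`).
#' @param planted_n,planted_template optional unlabelled cluster of
#'   `planted_n` pure proteins with its own template (novelty-detection
#'   fixture).
#' @param abundance_sdlog sd(log) of the per-PSM abundance factor.
#' @param seed integer seed; the whole experiment is deterministic given it.
#' @export
simulation_params <- function(n_classes = 10L, n_channels = 10L,
                              proteins_per_class = 100L,
                              markers_per_class = 50L,
                              psm_per_protein_mean = 3,
                              class_templates = NULL,
                              noise_sd = 0.3, missing_rate = 0.05,
                              contamination = 0, mixed_fraction = 0.2,
                              planted_n = 0L, planted_template = NULL,
                              abundance_sdlog = 1, seed = 1L) {
  stopifnot(n_classes >= 1, n_channels >= 2,
            proteins_per_class >= 1,
            markers_per_class >= 0, markers_per_class <= proteins_per_class,
            psm_per_protein_mean >= 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate <= 1,
            contamination >= 0, contamination <= 1,
            mixed_fraction >= 0, mixed_fraction <= 1,
            planted_n >= 0)
  if (!is.null(class_templates)) {
    class_templates <- as.matrix(class_templates)
    stopifnot(nrow(class_templates) == n_classes,
              ncol(class_templates) == n_channels,
              all(class_templates >= 0),
              all(abs(rowSums(class_templates) - 1) < 1e-8))
  }
  if (planted_n > 0 && !is.null(planted_template))
    stopifnot(length(planted_template) == n_channels,
              abs(sum(planted_template) - 1) < 1e-8)
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 proteins_per_class = as.integer(proteins_per_class),
                 markers_per_class = as.integer(markers_per_class),
                 psm_per_protein_mean = psm_per_protein_mean,
                 class_templates = class_templates,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 contamination = contamination,
                 mixed_fraction = mixed_fraction,
                 planted_n = as.integer(planted_n),
                 planted_template = planted_template,
                 abundance_sdlog = abundance_sdlog,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# compartment names used for simulated classes (vocabulary-agnostic tools;
# realistic labels make fixtures readable)
.sim_class_names <- function(k) {
  pool <- c("mitochondrion", "endoplasmic_reticulum", "plasma_membrane",
            "lysosome", "peroxisome", "endosome", "cytosol",
            "nucleus_nonchromatin", "chromatin", "proteasome",
            "ribosome_40S", "ribosome_60S", "actin_cytoskeleton",
            "extracellular_matrix")
  if (k <= length(pool)) pool[seq_len(k)] else
    c(pool, paste0("compartment_", seq_len(k - length(pool))))
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# zero-truncated Poisson(lambda) via inverse CDF
.rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate a LOPIT-style experiment with known ground truth
#'
#' @param params a [simulation_params()] object.
#' @param truth_from optional `SimulatedExperiment` whose templates, protein
#'   identities, true profiles and marker set are reused so that only the
#'   measurement noise, PSM sampling and missingness are redrawn — i.e., a
#'   technical/biological replicate of the same underlying cell population.
#' @return a `SimulatedExperiment` list: `psms` (`PsmTable`), `truth`
#'   (data.frame with per-protein `class` — the dominant compartment —,
#'   `class2`/`theta` for mixed proteins, `is_marker`, `is_mixed`,
#'   `is_planted`), `markers` (`MarkerSet`), `templates`, `true_profiles`
#'   (protein x channel matrix after mixing and contamination), `params`.
#' @export
simulate_experiment <- function(params, truth_from = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(.derive_seed(params$seed, "simulate"))
  C <- params$n_channels
  channels <- if (C == 10) tmt10_channels() else
    sprintf("CH%02d", seq_len(C))
  cls <- .sim_class_names(params$n_classes)

  if (is.null(truth_from)) {
    if (is.null(params$class_templates)) {
      templates <- t(vapply(seq_len(params$n_classes), function(k) {
        alpha <- rep(1, C)
        alpha[((k - 1L) %% C) + 1L] <- 50
        .rdirichlet1(alpha)
      }, numeric(C)))
    } else templates <- params$class_templates
    dimnames(templates) <- list(cls, channels)
    gmean <- colMeans(templates)

    n_per <- params$proteins_per_class
    truth <- do.call(rbind, lapply(seq_len(params$n_classes), function(k) {
      data.frame(protein_id = sprintf("P_%s_%03d", cls[k], seq_len(n_per)),
                 class = cls[k], class2 = NA_character_, theta = NA_real_,
                 is_marker = seq_len(n_per) <= params$markers_per_class,
                 is_mixed = FALSE, is_planted = FALSE,
                 stringsAsFactors = FALSE)
    }))
    # mixed-localization proteins among the non-markers
    nonmark <- which(!truth$is_marker)
    if (params$mixed_fraction > 0 && length(nonmark) > 0 &&
        params$n_classes >= 2) {
      n_mix <- round(params$mixed_fraction * length(nonmark))
      mix_idx <- nonmark[sample.int(length(nonmark), n_mix)]
      truth$is_mixed[mix_idx] <- TRUE
      for (i in mix_idx) {
        partner <- sample(setdiff(cls, truth$class[i]), 1L)
        th <- stats::runif(1, 0.2, 0.8)
        # dominant compartment stays in `class`
        if (th >= 0.5) {
          truth$class2[i] <- partner; truth$theta[i] <- th
        } else {
          truth$class2[i] <- truth$class[i]
          truth$class[i] <- partner
          truth$theta[i] <- 1 - th
        }
      }
    }
    if (params$planted_n > 0) {
      pt <- params$planted_template
      if (is.null(pt)) {
        pt <- rep(1, C); pt[c(3L, ((7L - 1L) %% C) + 1L)] <- 25
        pt <- pt / sum(pt)
      }
      templates <- rbind(templates, planted = pt)
      truth <- rbind(truth, data.frame(
        protein_id = sprintf("P_planted_%03d", seq_len(params$planted_n)),
        class = "planted", class2 = NA_character_, theta = NA_real_,
        is_marker = FALSE, is_mixed = FALSE, is_planted = TRUE,
        stringsAsFactors = FALSE))
    }
    base <- templates[truth$class, , drop = FALSE]
    mixed <- which(truth$is_mixed)
    if (length(mixed))
      base[mixed, ] <- truth$theta[mixed] * templates[truth$class[mixed], ] +
        (1 - truth$theta[mixed]) * templates[truth$class2[mixed], ]
    profiles <- (1 - params$contamination) * base +
      params$contamination * matrix(gmean, nrow(base), C, byrow = TRUE)
    rownames(profiles) <- truth$protein_id
    markers <- marker_set(stats::setNames(truth$class[truth$is_marker],
                                          truth$protein_id[truth$is_marker]))
  } else {
    templates <- truth_from$templates
    truth <- truth_from$truth
    profiles <- truth_from$true_profiles
    markers <- truth_from$markers
    channels <- colnames(profiles)
  }

  n_psm <- .rztpois(nrow(truth), params$psm_per_protein_mean)
  prot_of_psm <- rep(seq_len(nrow(truth)), n_psm)
  total <- length(prot_of_psm)
  noise <- if (params$noise_sd > 0)
    matrix(exp(stats::rnorm(total * C, 0, params$noise_sd)), total, C)
  else matrix(1, total, C)
  abundance <- exp(stats::rnorm(total, log(1e5), params$abundance_sdlog))
  vals <- profiles[prot_of_psm, , drop = FALSE] * noise * abundance

  if (params$missing_rate > 0) {
    lv <- log(vals)
    lv[!is.finite(lv)] <- min(lv[is.finite(lv)], 0)
    w <- stats::plogis(-(lv - stats::median(lv)) / max(stats::sd(lv), 1e-9))
    p <- pmin(params$missing_rate * w / mean(w), 1)
    vals[stats::runif(length(vals)) < p] <- NA_real_
  }

  df <- data.frame(psm_id = sprintf("psm%06d", seq_len(total)),
                   protein_group = truth$protein_id[prot_of_psm],
                   stringsAsFactors = FALSE)
  df[channels] <- as.data.frame(vals)
  structure(list(psms = psm_table(df, channels = channels),
                 truth = truth, markers = markers,
                 templates = templates, true_profiles = profiles,
                 params = params),
            class = "SimulatedExperiment")
}

#' Named simulation presets used throughout the test battery
#'
#' * `C1` — easy two-class problem (template separation far exceeding the
#'   noise scale); sanity checks and convex-hull properties.
#' * `C2` — the standard ten-class condition: 100 proteins/class, 50
#'   markers/class, 3 PSMs/protein on average, lognormal noise sd 0.3, 5%
#'   missingness, 20% mixed-localization non-markers, no interference.
#' * `D1` — novelty-detection fixture: C2's class structure without mixed
#'   proteins, plus one unlabelled planted cluster of 25 proteins with its
#'   own bimodal template.
#' * `Q1` — interference sweep base: C2 without mixed proteins or
#'   missingness; sweep `contamination` over `q1_lambda_grid()`.
#'
#' @param name one of `"C1"`, `"C2"`, `"D1"`, `"Q1"`.
#' @param seed seed stored in the returned params.
#' @export
preset_config <- function(name, seed = 1L) {
  switch(name,
    C1 = simulation_params(n_classes = 2L, proteins_per_class = 60L,
                           markers_per_class = 20L, psm_per_protein_mean = 1,
                           noise_sd = 0.1, missing_rate = 0,
                           mixed_fraction = 0, seed = seed),
    C2 = simulation_params(seed = seed),
    D1 = simulation_params(mixed_fraction = 0, planted_n = 25L, seed = seed),
    Q1 = simulation_params(mixed_fraction = 0, missing_rate = 0, seed = seed),
    stop("unknown preset: ", name))
}

#' @rdname preset_config
#' @export
q1_lambda_grid <- function() c(0, 0.2, 0.4, 0.6)

#' Write a simulated experiment to disk (PSM table, truth, markers)
#' @param sim a `SimulatedExperiment`.
#' @param psm_path,truth_path,markers_path output TSV paths (`NULL` = skip).
#' @export
write_simulated_experiment <- function(sim, psm_path, truth_path = NULL,
                                       markers_path = NULL) {
  stopifnot(inherits(sim, "SimulatedExperiment"))
  utils::write.table(as.data.frame(sim$psms), psm_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  if (!is.null(markers_path)) write_markers(sim$markers, markers_path)
  invisible(psm_path)
}
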