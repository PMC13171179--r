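#' Configuration for the planted-morphotype simulator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' total length is log-normal; each remaining linear measurement follows a
#' group-specific allometric power law `trait = a * TL^b * exp(eps)` so that
#' on the corrected log-shape-ratio scale groups differ by mean offsets;
#' scale counts are Poisson with group-specific means. `separation` is
#' calibrated on the corrected scale: per-trait group-mean offsets are drawn
#' with variance `(separation * sd_t)^2 / 2`, making the RMS per-trait gap
#' between two groups equal `separation` within-group standard deviations.
#'
#' @param n_specimens total specimens N.
#' @param n_groups number of planted morphotype groups G.
#' @param proportions group proportions (default equal); must sum to 1.
#' @param n_morphometric number of morphometric traits, including TL.
#' @param n_meristic number of meristic (count) traits.
#' @param separation group separation in within-group SD units on the
#'   corrected scale (>= 0; 0 plants no group signal).
#' @param noise_sd residual SD of the log-shape ratios (> 0).
#' @param tl_meanlog,tl_sdlog log-normal parameters of total length (mm).
#' @param allometry_b optional G x (n_morphometric - 1) matrix of allometric
#'   exponents for the non-TL morphometric traits (default: isometry, b = 1).
#' @param meristic_family `"poisson"` (default) or `"nbinom"`
#'   (`size = 20` overdispersion).
#' @param species_scheme how species labels relate to planted groups:
#'   `"aligned"` (identical), `"shuffled"` (random permutation across
#'   specimens, destroying the correspondence) or `"split"` (each group split
#'   into two species).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_specimens = 484L, n_groups = 12L, proportions = NULL,
                       n_morphometric = 13L, n_meristic = 8L, separation = 3,
                       noise_sd = 0.15, tl_meanlog = 6, tl_sdlog = 0.35,
                       allometry_b = NULL,
                       meristic_family = c("poisson", "nbinom"),
                       species_scheme = c("shuffled", "aligned", "split"),
                       seed = 1L) {
  meristic_family <- match.arg(meristic_family)
  species_scheme <- match.arg(species_scheme)
  if (is.null(proportions)) proportions <- rep(1 / n_groups, n_groups)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            n_specimens >= 2L * n_groups,
            separation >= 0, noise_sd > 0,
            n_morphometric >= 2L, n_meristic >= 0L)
  structure(as.list(environment()), class = "sim_config")
}

sim_trait_names <- function(n_morph, n_mer) {
  morph <- c("TL", "SVL", "TAL", "HL", "HW", "HH", "HE", "HP", "HN",
             "MBW", "MBH", "CW", "CH")
  mer <- c("ven", "SC", "MID", "IOS", "so", "PO", "SL", "IL")
  list(
    morph = if (n_morph <= length(morph)) morph[seq_len(n_morph)]
            else c(morph, paste0("M", seq_len(n_morph - length(morph)))),
    mer = if (n_mer <= length(mer)) mer[seq_len(n_mer)]
          else c(mer, paste0("C", seq_len(n_mer - length(mer))))
  )
}

#' Simulate a planted-morphotype trait table
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_dataset` with `trait_table` (a validated
#'   [trait_table()]), `planted_labels` (group id per specimen) and
#'   `species_labels` (per the configured scheme; also stored inside the
#'   trait table as its species column).
#' @export
simulate_morphotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_groups
    N <- config$n_specimens
    sizes <- floor(config$proportions * N)
    rem <- N - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    groups <- rep(seq_len(G), sizes)

    nm <- config$n_morphometric
    nc <- config$n_meristic
    nms <- sim_trait_names(nm, nc)
    shape_traits <- nms$morph[-1L]          # non-TL morphometrics

    b <- config$allometry_b
    if (is.null(b)) b <- matrix(1, G, nm - 1L)
    stopifnot(nrow(b) == G, ncol(b) == nm - 1L)

    # per-trait baseline log shape ratios (trait/TL), biologically plausible
    base_ratio <- stats::runif(nm - 1L, -3, -0.3)
    # within-group SD on the corrected scale, per trait and group
    sd_shape <- sqrt(config$noise_sd^2 +
                       (b - 1)^2 * config$tl_sdlog^2)  # G x (nm-1)
    off_shape <- matrix(stats::rnorm(G * (nm - 1L)), G) *
      (config$separation * sd_shape / sqrt(2))
    off_tl <- stats::rnorm(G) * (config$separation * config$tl_sdlog / sqrt(2))

    ln_tl <- config$tl_meanlog + off_tl[groups] +
      stats::rnorm(N, 0, config$tl_sdlog)
    tl <- exp(ln_tl)

    morph <- matrix(NA_real_, N, nm, dimnames = list(NULL, nms$morph))
    morph[, 1L] <- tl
    for (t in seq_len(nm - 1L)) {
      ln_a <- base_ratio[t] + off_shape[groups, t]
      bt <- b[groups, t]
      morph[, t + 1L] <- exp(ln_a + bt * ln_tl +
                               stats::rnorm(N, 0, config$noise_sd))
    }

    mer <- NULL
    if (nc > 0L) {
      lambda_base <- exp(stats::runif(nc, log(5), log(150)))
      mer <- matrix(NA_integer_, N, nc, dimnames = list(NULL, nms$mer))
      for (t in seq_len(nc)) {
        s_t <- sqrt(lambda_base[t]) / (lambda_base[t] + 1)  # delta-method SD of log1p
        delta <- stats::rnorm(G) * (config$separation * s_t / sqrt(2))
        lam <- pmax(exp(log1p(lambda_base[t]) + delta[groups]) - 1, 0.1)
        mer[, t] <- if (config$meristic_family == "poisson") {
          stats::rpois(N, lam)
        } else {
          stats::rnbinom(N, size = 20, mu = lam)
        }
      }
    }

    species <- switch(config$species_scheme,
      aligned = paste0("sp", groups),
      shuffled = sample(paste0("sp", groups)),
      split = paste0("sp", groups, c("a", "b")[1L + (seq_len(N) %% 2L)])
    )

    df <- data.frame(specimen_id = sprintf("spec_%04d", seq_len(N)),
                     species = species, morph, check.names = FALSE)
    if (!is.null(mer)) df <- cbind(df, as.data.frame(mer))
    kinds <- c(stats::setNames(rep("morphometric", nm), nms$morph),
               stats::setNames(rep("meristic", nc), nms$mer))
    tab <- trait_table(df, kinds, tl_name = "TL",
                       id_col = "specimen_id", species_col = "species")
    structure(list(trait_table = tab, planted_labels = groups,
                   species_labels = species, config = config),
              class = "simulated_dataset")
  })
}

#' Default study-shaped simulation
#'
#' A fixture shaped like the empirical case study: 484 specimens, 13
#' morphometric plus 8 meristic traits, 12 planted groups at moderate
#' (3 SD) corrected-scale separation. It matches dimensions and data types
#' only, not real measurement values or covariance.
#'
#' @param seed integer seed.
#' @param separation group separation (default 3).
#' @return a `simulated_dataset` (see [simulate_morphotypes()]).
#' @export
default_porthidium_like <- function(seed = 1L, separation = 3) {
  simulate_morphotypes(sim_config(
    n_specimens = 484L, n_groups = 12L, n_morphometric = 13L, n_meristic = 8L,
    separation = separation, seed = seed
  ))
}

#' Write a simulated dataset to CSV
#'
#' @param sim a `simulated_dataset`.
#' @param path output CSV for the trait table.
#' @param labels_path optional CSV for the planted group labels.
#' @export
write_simulated_dataset <- function(sim, path, labels_path = NULL) {
  tab <- sim$trait_table
  df <- data.frame(specimen_id = tab$specimen_id, species = tab$species,
                   tab$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.csv(data.frame(specimen_id = tab$specimen_id,
                                planted_group = sim$planted_labels),
                     labels_path, row.names = FALSE)
  }
  invisible(path)
}
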