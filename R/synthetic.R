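#' Configuration for a synthetic plasma methylation cohort
#'
#' Defines the statistical structure the downstream analysis assumes: a
#' panel of genomic regions with a low hypermethylation background in
#' healthy plasma, a subset of truly informative regions (planted DMRs)
#' that are strongly methylated in tumor tissue, and a tumor-fraction
#' dilution model for the plasma signal of cancer patients. Methylated CpG
#' counts are beta-binomial (bisulfite counts are overdispersed relative to
#' binomial); detected CpG counts are Poisson around `coverage_mean`.
#'
#' For sample i and region r the latent methylation level is
#' \deqn{\mu_{ir} = (1 - f_i)\,b_r + f_i\, m_T}
#' where `b_r` is the region background, `m_T` = `tumor_beta_mean`, and the
#' tumor fraction `f_i` is uniform on `tumor_fraction_range` for cancer
#' plasma, scaled by `benign_effect_scale` for benign plasma, and 0 for
#' healthy plasma. Noise regions use `b_r` for every group. Tumor tissue
#' sits at `m_T` on informative regions; white blood cells (WBC) at `b_r`
#' everywhere.
#'
#' Default group sizes mirror a case-control model-building cohort with a
#' full spectrum of lung disease (190 cancer / 135 benign / 188 healthy
#' plasma; 20 tumor and 20 WBC tissue samples), a 165-region panel with 15
#' informative regions, and tumor fractions of 1-20\% so that desk-scale
#' runs carry signal; a stress preset at 0.1-1\% is available via
#' `tumor_fraction_range`.
#'
#' @param n_cancer,n_benign,n_healthy plasma sample counts per group.
#' @param n_tumor_tissue,n_wbc tissue sample counts.
#' @param n_regions total panel regions.
#' @param n_true_dmr planted informative regions (<= `n_regions`).
#' @param healthy_beta_mean mean healthy-plasma methylation background.
#' @param healthy_beta_dispersion beta-binomial intra-class correlation
#'   (0 = binomial; bisulfite data typically 0.05-0.2).
#' @param tumor_beta_mean methylation level of planted DMRs in tumor tissue.
#' @param tumor_fraction_range length-2 interval of per-sample ctDNA
#'   fraction for cancer plasma, within \[0, 1\].
#' @param benign_effect_scale fraction of the cancer effect present in
#'   benign samples (0 = benign identical to healthy in law).
#' @param coverage_mean mean detected CpG observations per region per sample.
#' @param stage_distribution named multinomial over TNM stages for cancer
#'   samples.
#' @param cea_params per-group log-normal parameters `c(meanlog, sdlog)` of
#'   the serum CEA marker (ng/mL); defaults give CEA a weak standalone
#'   cancer signal (AUC just under 0.6).
#' @param seed integer RNG seed; identical configs reproduce identical
#'   cohorts.
#' @return a list of class `cohort_config`.
#' @seealso [simulate_cohort()], [simulate_study()]
#' @export
cohort_config <- function(n_cancer = 190, n_benign = 135, n_healthy = 188,
                          n_tumor_tissue = 20, n_wbc = 20,
                          n_regions = 165, n_true_dmr = 15,
                          healthy_beta_mean = 0.02,
                          healthy_beta_dispersion = 0.1,
                          tumor_beta_mean = 0.6,
                          tumor_fraction_range = c(0.01, 0.2),
                          benign_effect_scale = 0.25,
                          coverage_mean = 200,
                          stage_distribution = c(I = 0.425, II = 0.15,
                                                 III = 0.2125, IV = 0.2125),
                          cea_params = list(
                            cancer = c(meanlog = log(2) + 0.134, sdlog = 0.5),
                            benign = c(meanlog = log(2) + 0.03, sdlog = 0.5),
                            healthy = c(meanlog = log(2), sdlog = 0.5)),
                          seed = 1L) {
  cfg <- list(
    n_cancer = check_count(n_cancer, "n_cancer"),
    n_benign = check_count(n_benign, "n_benign"),
    n_healthy = check_count(n_healthy, "n_healthy"),
    n_tumor_tissue = check_count(n_tumor_tissue, "n_tumor_tissue"),
    n_wbc = check_count(n_wbc, "n_wbc"),
    n_regions = check_count(n_regions, "n_regions", min = 1L),
    n_true_dmr = check_count(n_true_dmr, "n_true_dmr"),
    healthy_beta_mean = check_fraction(healthy_beta_mean,
                                       "healthy_beta_mean", open = TRUE),
    healthy_beta_dispersion = check_fraction(healthy_beta_dispersion,
                                             "healthy_beta_dispersion"),
    tumor_beta_mean = check_fraction(tumor_beta_mean, "tumor_beta_mean"),
    tumor_fraction_range = tumor_fraction_range,
    benign_effect_scale = check_fraction(benign_effect_scale,
                                         "benign_effect_scale"),
    coverage_mean = coverage_mean,
    stage_distribution = stage_distribution,
    cea_params = cea_params,
    seed = check_count(seed, "seed")
  )
  tfr <- tumor_fraction_range
  if (!is.numeric(tfr) || length(tfr) != 2 || any(!is.finite(tfr)) ||
      tfr[1] > tfr[2] || tfr[1] < 0 || tfr[2] > 1) {
    stop("'tumor_fraction_range' must be an ordered interval within [0, 1]",
         call. = FALSE)
  }
  if (cfg$n_true_dmr > cfg$n_regions) {
    stop("'n_true_dmr' must not exceed 'n_regions'", call. = FALSE)
  }
  if (!is.numeric(coverage_mean) || length(coverage_mean) != 1 ||
      coverage_mean <= 0) {
    stop("'coverage_mean' must be a positive number", call. = FALSE)
  }
  sd <- stage_distribution
  if (is.null(names(sd)) || any(sd < 0) || abs(sum(sd) - 1) > 1e-8) {
    stop("'stage_distribution' must be a named probability vector summing to 1",
         call. = FALSE)
  }
  for (g in c("cancer", "benign", "healthy")) {
    p <- cea_params[[g]]
    if (is.null(p) || length(p) != 2 || !is.numeric(p) || p[2] <= 0) {
      stop(sprintf("'cea_params$%s' must be c(meanlog, sdlog) with sdlog > 0", g),
           call. = FALSE)
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Region panel shared by all cohorts of one study: ids, mock coordinates
# (0-based half-open), per-region healthy background, informative flag.
draw_regions <- function(config) {
  n <- config$n_regions
  m <- config$healthy_beta_mean
  # Backgrounds vary modestly across regions: panel regions emulate a
  # pre-designed hypermethylation panel, screened to be quiet in healthy
  # plasma, so the spread around healthy_beta_mean is kept tight.
  conc <- 300
  background <- stats::rbeta(n, m * conc, (1 - m) * conc)
  informative <- rep(FALSE, n)
  informative[sample.int(n, config$n_true_dmr)] <- TRUE
  width <- 150L
  start <- as.integer(seq(10000L, by = 10000L, length.out = n))
  data.frame(
    region = sprintf("region_%03d", seq_len(n)),
    chrom = "chr1",
    start = start,
    end = start + width,
    background = background,
    informative = informative,
    stringsAsFactors = FALSE
  )
}

# Beta-binomial draw: size trials, mean mu, intra-class correlation rho.
rbetabinom <- function(n, size, mu, rho) {
  p <- mu
  mid <- mu > 0 & mu < 1 & rho > 0
  if (any(mid)) {
    a <- mu[mid] * (1 - rho) / rho
    b <- (1 - mu[mid]) * (1 - rho) / rho
    p[mid] <- stats::rbeta(sum(mid), a, b)
  }
  stats::rbinom(n, size, p)
}

#' Simulate one synthetic plasma/tissue cohort
#'
#' Draws a cohort under the generative model described in
#' [cohort_config()]. With a fixed config (including seed) the output is
#' reproducible exactly.
#'
#' @param config a [cohort_config()].
#' @param regions optional region table from a previous cohort of the same
#'   study, so multiple phases share the same panel, backgrounds, and
#'   planted DMRs; drawn fresh when NULL.
#' @param seed overrides `config$seed` (used by [simulate_study()] to give
#'   each phase its own derived stream).
#' @param id_prefix prefix for sample ids, to keep ids unique across phases.
#' @return an object of class `synthetic_cohort`: list with `counts` (a
#'   [meth_matrix()]), `samples` (sample sheet with group, stage, tumor
#'   size, histology, age, sex, smoking, CEA), `regions` (region table with
#'   ground-truth `informative` flags), `tumor_fraction` (latent per-sample
#'   ctDNA fraction), and `latent_mu` (latent methylation levels, retained
#'   for validation of recovery properties).
#' @export
simulate_cohort <- function(config, regions = NULL, seed = config$seed,
                            id_prefix = "") {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    if (is.null(regions)) regions <- draw_regions(config)

    groups <- c(rep("cancer", config$n_cancer),
                rep("benign", config$n_benign),
                rep("healthy", config$n_healthy),
                rep("tumor", config$n_tumor_tissue),
                rep("wbc", config$n_wbc))
    n <- length(groups)
    if (n == 0) stop("config describes an empty cohort", call. = FALSE)
    ids <- paste0(id_prefix, groups, "_",
                  formatC(stats::ave(seq_len(n), groups, FUN = seq_along),
                          width = 3, flag = "0"))

    tfr <- config$tumor_fraction_range
    f <- numeric(n)
    is_cancer <- groups == "cancer"
    is_benign <- groups == "benign"
    f[is_cancer] <- stats::runif(sum(is_cancer), tfr[1], tfr[2])
    f[is_benign] <- stats::runif(sum(is_benign), tfr[1], tfr[2]) *
      config$benign_effect_scale

    # latent methylation level per sample x region
    bg <- regions$background
    mu <- matrix(rep(bg, each = n), n, config$n_regions)
    inf <- regions$informative
    if (any(inf)) {
      plasma_eff <- f > 0
      mu[plasma_eff, inf] <- (1 - f[plasma_eff]) %o% bg[inf] +
        f[plasma_eff] %o% rep(config$tumor_beta_mean, sum(inf))
      mu[groups == "tumor", inf] <- config$tumor_beta_mean
    }
    dimnames(mu) <- list(ids, regions$region)

    detected <- matrix(stats::rpois(n * config$n_regions,
                                    config$coverage_mean),
                       n, config$n_regions, dimnames = dimnames(mu))
    methylated <- matrix(
      rbetabinom(n * config$n_regions, as.vector(detected), as.vector(mu),
                 config$healthy_beta_dispersion),
      n, config$n_regions, dimnames = dimnames(mu))

    stage <- rep(NA_character_, n)
    nc <- sum(is_cancer)
    if (nc > 0) {
      stage[is_cancer] <- sample(names(config$stage_distribution), nc,
                                 replace = TRUE,
                                 prob = config$stage_distribution)
    }
    tumor_size <- rep(NA_real_, n)
    # median ~2 cm, intentionally weighted to early disease
    tumor_size[is_cancer] <- round(stats::rlnorm(nc, log(2), 0.5), 1)
    histology <- rep(NA_character_, n)
    histology[is_cancer] <- sample(
      c("adenocarcinoma", "squamous", "small_cell", "large_cell"), nc,
      replace = TRUE, prob = c(0.55, 0.25, 0.12, 0.08))

    cea <- rep(NA_real_, n)
    for (g in c("cancer", "benign", "healthy")) {
      sel <- groups == g
      if (any(sel)) {
        p <- config$cea_params[[g]]
        cea[sel] <- round(stats::rlnorm(sum(sel), p[1], p[2]), 2)
      }
    }

    samples <- data.frame(
      sample = ids,
      group = groups,
      stage = stage,
      tumor_size_cm = tumor_size,
      histology = histology,
      age = round(stats::rnorm(n, 58, 11)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                       prob = c(0.5, 0.25, 0.25)),
      cea = cea,
      stringsAsFactors = FALSE
    )

    structure(list(
      counts = meth_matrix(methylated, detected),
      samples = samples,
      regions = regions,
      tumor_fraction = stats::setNames(f, ids),
      latent_mu = mu,
      config = config
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("synthetic_cohort:",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  %d regions (%d informative), seed %d\n",
              nrow(x$regions), sum(x$regions$informative), x$config$seed))
  invisible(x)
}

#' Simulate a multi-phase marker development study
#'
#' Generates the cohorts of a staged assay-development design sharing one
#' region panel (identical backgrounds and planted DMRs throughout):
#' a plasma discovery cohort, a tumor/WBC tissue verification cohort, a
#' cancer-vs-healthy plasma verification cohort, a model-building cohort,
#' and an independent validation cohort. Default phase sizes follow a
#' realistic staged case-control design (discovery 209/97/123
#' cancer/benign/healthy; tissue 20+20; plasma verification 88/81
#' cancer/healthy; training from `config`; validation 64/45/63).
#'
#' @param config a [cohort_config()]; its `n_cancer`/`n_benign`/`n_healthy`
#'   give the model-building (training) cohort sizes.
#' @param discovery,verification,validation length-3 integer vectors
#'   `c(cancer, benign, healthy)` of plasma sizes for the other phases.
#' @return list of class `synthetic_study` with elements `regions`,
#'   `discovery`, `tissue`, `verification`, `training`, `validation`.
#' @export
simulate_study <- function(config = cohort_config(),
                           discovery = c(209, 97, 123),
                           verification = c(88, 0, 81),
                           validation = c(64, 45, 63)) {
  stopifnot(inherits(config, "cohort_config"))
  regions <- with_seed(config$seed, draw_regions(config))
  phase_cfg <- function(sizes, tissue = FALSE) {
    cc <- config
    cc$n_cancer <- as.integer(sizes[1])
    cc$n_benign <- as.integer(sizes[2])
    cc$n_healthy <- as.integer(sizes[3])
    if (!tissue) {
      cc$n_tumor_tissue <- 0L
      cc$n_wbc <- 0L
    }
    cc
  }
  tissue_cfg <- config
  tissue_cfg$n_cancer <- 0L
  tissue_cfg$n_benign <- 0L
  tissue_cfg$n_healthy <- 0L
  structure(list(
    regions = regions,
    discovery = simulate_cohort(phase_cfg(discovery), regions,
                                seed = config$seed + 1L, id_prefix = "dis_"),
    tissue = simulate_cohort(tissue_cfg, regions,
                             seed = config$seed + 2L, id_prefix = "tis_"),
    verification = simulate_cohort(phase_cfg(verification), regions,
                                   seed = config$seed + 3L,
                                   id_prefix = "ver_"),
    training = simulate_cohort(
      phase_cfg(c(config$n_cancer, config$n_benign, config$n_healthy)),
      regions, seed = config$seed + 4L, id_prefix = "trn_"),
    validation = simulate_cohort(phase_cfg(validation), regions,
                                 seed = config$seed + 5L, id_prefix = "val_")
  ), class = "synthetic_study")
}

#' Simulate a qPCR plate readout for a cohort
#'
#' Emulates relative quantification of each marker against a stably
#' expressed reference gene: the marker Ct tracks the log2 abundance of
#' methylated template (`ct_ref - log2(mu)` plus Gaussian efficiency
#' noise), and reactions with no template are censored at `max_cycle`.
#' The reference-gene Ct is independent of disease state.
#'
#' @param cohort a `synthetic_cohort`.
#' @param markers region ids to assay (default: all regions).
#' @param efficiency_noise SD (cycles) of per-reaction noise; default 0.3.
#' @param max_cycle censoring limit (default 40).
#' @param seed RNG seed (default: cohort seed + 1000).
#' @return long data.frame with columns `sample`, `marker`, `ct_marker`,
#'   `ct_reference`.
#' @export
simulate_qpcr <- function(cohort, markers = NULL, efficiency_noise = 0.3,
                          max_cycle = 40,
                          seed = cohort$config$seed + 1000L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.numeric(efficiency_noise) || efficiency_noise < 0) {
    stop("'efficiency_noise' must be a non-negative number", call. = FALSE)
  }
  mu <- cohort$latent_mu
  if (is.null(markers)) markers <- colnames(mu)
  miss <- setdiff(markers, colnames(mu))
  if (length(miss)) {
    stop("unknown marker(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  mu <- mu[, markers, drop = FALSE]
  with_seed(seed, {
    n <- nrow(mu)
    k <- ncol(mu)
    ct_ref <- stats::rnorm(n, 25, 0.15)  # reference gene: disease-independent
    ref_mat <- matrix(rep(ct_ref, k), n, k)
    noise <- matrix(stats::rnorm(n * k, 0, efficiency_noise), n, k)
    ct <- ref_mat - log2(mu) + noise
    ct[!is.finite(ct) | ct > max_cycle] <- max_cycle
    data.frame(
      sample = rep(rownames(mu), k),
      marker = rep(markers, each = n),
      ct_marker = round(as.vector(ct), 3),
      ct_reference = round(as.vector(ref_mat), 3),
      stringsAsFactors = FALSE
    )
  })
}
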