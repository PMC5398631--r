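#' Simulation parameters for a two-cohort copy-number study
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults encode the study conditions the pipeline is meant to face:
#' two cohorts with slightly different chromosomal-instability (CIN)
#' prevalence, CIN tumors drawing independent per-arm gains/losses at a
#' high rate and non-CIN tumors at a low rate, one differential focal
#' region plus non-differential background regions, Beta-distributed
#' tumor purity, small Gaussian segment-level noise, and two genotype
#' populations under the Balding-Nichols model.
#'
#' @param n_east,n_west cohort sizes.
#' @param cin_prevalence_east,cin_prevalence_west probability a sample is
#'   CIN (defaults 0.51 and 0.59).
#' @param arm_rate_cin,arm_rate_noncin per-arm probability of a gain and
#'   (independently) of a loss, by CIN status (defaults 0.3 and 0.02).
#' @param arm_amplitude copy units added/removed by an arm event
#'   (default 1).
#' @param focal_regions data frame with columns `region_id`, `chrom`,
#'   `start`, `end`, `type` (AMP/DEL), `rate_east`, `rate_west`; NULL for
#'   the default layout built by [default_focal_regions()].
#' @param focal_amplitude copy units added/removed by a focal event
#'   (default 1).
#' @param purity_beta shape parameters of the Beta purity distribution
#'   (default c(5, 2)); `purity_beta_east` optionally overrides the
#'   Eastern cohort (lower-purity Eastern specimens are the default:
#'   c(3.5, 2.5)).
#' @param purity_range purity is scaled into this interval (default
#'   c(0.2, 1)).
#' @param fixed_purity if non-NULL, every sample gets exactly this purity
#'   (used by noise-free calibration runs).
#' @param marker_noise_sd standard deviation of Gaussian noise added to
#'   each observed segment value, copy units (default 0.05).
#' @param n_markers size of the shared pseudo-marker grid (default 10000).
#' @param n_snps germline SNP count (default 5000).
#' @param fst Balding-Nichols differentiation parameter in [0, 1)
#'   (default 0.1).
#' @param ancestral_freq_range interval for ancestral allele frequencies
#'   (default c(0.1, 0.9)).
#' @param cin_labeled_fraction fraction of samples whose true CIN label
#'   is exposed in the metadata (as a training set); the rest are UNKNOWN
#'   (default 0.5).
#' @param arms arm definitions (default [synthetic_arm_definitions()]).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return validated parameter list of class `simulation_params`.
#' @export
simulation_params <- function(n_east = 100L, n_west = 100L,
                              cin_prevalence_east = 0.51,
                              cin_prevalence_west = 0.59,
                              arm_rate_cin = 0.3, arm_rate_noncin = 0.02,
                              arm_amplitude = 1,
                              focal_regions = NULL, focal_amplitude = 1,
                              purity_beta = c(5, 2),
                              purity_beta_east = c(3.5, 2.5),
                              purity_range = c(0.2, 1),
                              fixed_purity = NULL,
                              marker_noise_sd = 0.05,
                              n_markers = 10000L, n_snps = 5000L, fst = 0.1,
                              ancestral_freq_range = c(0.1, 0.9),
                              cin_labeled_fraction = 0.5,
                              arms = synthetic_arm_definitions(),
                              seed = 1L) {
  p <- as.list(environment())
  if (is.null(p$focal_regions)) p$focal_regions <- default_focal_regions(arms)
  probs <- c(p$cin_prevalence_east, p$cin_prevalence_west, p$arm_rate_cin,
             p$arm_rate_noncin, p$focal_regions$rate_east, p$focal_regions$rate_west,
             p$cin_labeled_fraction)
  if (any(probs < 0 | probs > 1)) stop_fmt("simulation_params: probabilities must lie in [0,1]")
  if (p$fst < 0 || p$fst >= 1) stop_fmt("simulation_params: fst must lie in [0,1)")
  if (p$n_east < 1L || p$n_west < 1L) stop_fmt("simulation_params: cohorts need >= 1 sample")
  validate_focal_regions(p$focal_regions, arms)
  class(p) <- "simulation_params"
  p
}

validate_focal_regions <- function(regions, arms) {
  for (r in seq_len(nrow(regions))) {
    hit <- arms$chrom == regions$chrom[r] &
      arms$start <= regions$start[r] & arms$end >= regions$end[r]
    if (!any(hit))
      stop_fmt("focal region %s [%s:%.0f-%.0f] does not lie within a single arm",
               regions$region_id[r], regions$chrom[r], regions$start[r], regions$end[r])
    a <- arms[which(hit)[1L], ]
    if (regions$end[r] - regions$start[r] >= 0.5 * (a$end - a$start))
      stop_fmt("focal region %s covers >= 0.5 of arm %s and would not be focal",
               regions$region_id[r], a$arm)
  }
  invisible(regions)
}

#' Default focal-region layout
#'
#' One differential deletion region (planted at 27% in the Western and
#' 11% in the Eastern cohort, the magnitude of the one cohort-differential
#' focal event this class of study reports) plus two non-differential
#' background regions (one AMP, one DEL) on other arms, so specificity of
#' the differential test is always exercised alongside its power.
#'
#' @param arms arm data frame.
#' @return focal-region data frame.
#' @export
default_focal_regions <- function(arms = synthetic_arm_definitions()) {
  pick <- function(arm_name, frac_lo, frac_hi) {
    a <- arms[arms$arm == arm_name, ]
    len <- a$end - a$start
    c(chrom = a$chrom, start = round(a$start + frac_lo * len),
      end = round(a$start + frac_hi * len))
  }
  r1 <- pick("9p", 0.3, 0.34)   # differential deletion (PTPRD-like locus)
  r2 <- pick("6q", 0.5, 0.54)   # background amplification
  r3 <- pick("16q", 0.4, 0.44)  # background deletion
  data.frame(
    region_id = c("del_diff_9p", "amp_bg_6q", "del_bg_16q"),
    chrom = c(r1["chrom"], r2["chrom"], r3["chrom"]),
    start = as.numeric(c(r1["start"], r2["start"], r3["start"])),
    end = as.numeric(c(r1["end"], r2["end"], r3["end"])),
    type = c("DEL", "AMP", "DEL"),
    rate_east = c(0.11, 0.10, 0.10),
    rate_west = c(0.27, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Plant a focal event into one sample's profile
#'
#' Splits the profile's segment structure at the region boundaries and
#' shifts the copy value by `sign * amplitude` strictly inside the
#' region. When `arms` is supplied the region is checked to lie within a
#' single arm (a region spanning a centromere is not representable as a
#' focal event) and to be shorter than half that arm.
#'
#' @param segs one sample's segment data frame.
#' @param region list/row with `chrom`, `start`, `end`.
#' @param sign +1 (amplification) or -1 (deletion).
#' @param amplitude copy units (non-negative).
#' @param arms optional arm table for validation.
#' @return modified segment data frame.
#' @export
plant_focal_event <- function(segs, region, sign, amplitude, arms = NULL) {
  stopifnot(sign %in% c(-1, 1), amplitude >= 0)
  if (!is.null(arms))
    validate_focal_regions(data.frame(region_id = "region",
                                      chrom = region$chrom, start = region$start,
                                      end = region$end, stringsAsFactors = FALSE), arms)
  ch <- segs$chrom == region$chrom
  pieces <- segs[!ch, , drop = FALSE]
  for (i in which(ch)) {
    s <- segs[i, , drop = FALSE]
    cuts <- sort(unique(c(s$start, s$end,
                          pmin(pmax(c(region$start, region$end), s$start), s$end))))
    for (j in seq_len(length(cuts) - 1L)) {
      piece <- s
      piece$start <- cuts[j]
      piece$end <- cuts[j + 1L]
      piece$n_markers <- max(1L, as.integer(round(
        s$n_markers * (piece$end - piece$start) / (s$end - s$start))))
      if (piece$start >= region$start && piece$end <= region$end)
        piece$value <- max(0, piece$value + sign * amplitude)
      pieces <- rbind(pieces, piece)
    }
  }
  pieces <- pieces[order(suppressWarnings(as.numeric(pieces$chrom)), pieces$chrom,
                         pieces$start), , drop = FALSE]
  rownames(pieces) <- NULL
  pieces
}

#' Simulate a two-cohort study with planted ground truth
#'
#' Builds, per sample: a true tumor profile (per-arm segments at copy 2
#' plus independent arm gains/losses and planted focal events), then the
#' observed profile through the forward admixture model of
#' [admix_profile()] at the sample's drawn purity, renormalized so the
#' length-weighted mean reads diploid, plus Gaussian segment noise.
#' Germline genotypes are drawn under the Balding-Nichols model: per SNP
#' an ancestral frequency p0, population frequencies
#' `Beta(p0 (1-F)/F, (1-p0) (1-F)/F)` and binomial dosages. All output is
#' a deterministic function of `params$seed`.
#'
#' @param params a [simulation_params()] object.
#' @return list with elements `profiles` (observed segment table),
#'   `genotypes` (SNP x sample matrix), `purity` (purity-ploidy table,
#'   true values, `confident` = TRUE), `metadata`, `truth` (list:
#'   `samples` with true cohort/CIN/purity/ploidy, `focal_events` planted
#'   per sample, `region_rates` configured and realized rates,
#'   `true_profiles` the noiseless unmixed segment table), `arms`,
#'   `regions`, `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(derive_seed(params$seed, 0L))
  arms <- params$arms
  grid <- marker_grid(arms, params$n_markers)
  nE <- params$n_east; nW <- params$n_west
  ids <- c(sprintf("E%03d", seq_len(nE)), sprintf("W%03d", seq_len(nW)))
  cohort <- c(rep("EAST", nE), rep("WEST", nW))
  cin <- stats::rbinom(nE + nW, 1L,
                       ifelse(cohort == "EAST", params$cin_prevalence_east,
                              params$cin_prevalence_west)) == 1L

  markers_in <- function(chrom, start, end)
    max(1L, sum(grid$chrom == chrom & grid$pos >= start & grid$pos < end))

  base <- arms
  base$n_markers <- mapply(markers_in, arms$chrom, arms$start, arms$end)

  regions <- params$focal_regions
  profiles <- vector("list", length(ids))
  focal_events <- list()
  for (k in seq_along(ids)) {
    rate <- if (cin[k]) params$arm_rate_cin else params$arm_rate_noncin
    u_gain <- stats::runif(nrow(arms)) < rate
    u_loss <- stats::runif(nrow(arms)) < rate
    val <- 2 + params$arm_amplitude * (u_gain - u_loss)
    segs <- data.frame(sample = ids[k], chrom = base$chrom, start = base$start,
                       end = base$end, n_markers = base$n_markers,
                       value = pmax(0, val), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(regions))) {
      p_event <- if (cohort[k] == "EAST") regions$rate_east[r] else regions$rate_west[r]
      if (stats::runif(1L) < p_event) {
        segs <- plant_focal_event(segs, regions[r, ],
                                  sign = if (regions$type[r] == "AMP") 1 else -1,
                                  amplitude = params$focal_amplitude)
        focal_events[[length(focal_events) + 1L]] <-
          data.frame(sample_id = ids[k], region_id = regions$region_id[r],
                     type = regions$type[r], stringsAsFactors = FALSE)
      }
    }
    profiles[[k]] <- segs
  }
  true_profiles <- do.call(rbind, profiles)

  # purity and ploidy
  if (!is.null(params$fixed_purity)) {
    alpha <- rep(params$fixed_purity, length(ids))
  } else {
    sh <- ifelse(cohort == "EAST", 1L, 2L)
    shapes <- list(params$purity_beta_east %||% params$purity_beta, params$purity_beta)
    raw <- stats::rbeta(length(ids), vapply(sh, function(i) shapes[[i]][1L], 0),
                        vapply(sh, function(i) shapes[[i]][2L], 0))
    alpha <- params$purity_range[1L] + diff(params$purity_range) * raw
  }
  names(alpha) <- ids

  observed <- admix_profile(true_profiles, alpha)
  tau <- attr(observed, "tau")
  if (params$marker_noise_sd > 0)
    observed$value <- pmax(0, observed$value +
                             stats::rnorm(nrow(observed), 0, params$marker_noise_sd))

  # Balding-Nichols genotypes
  F <- params$fst
  p0 <- stats::runif(params$n_snps, params$ancestral_freq_range[1L],
                     params$ancestral_freq_range[2L])
  if (F > 0) {
    pE <- stats::rbeta(params$n_snps, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    pW <- stats::rbeta(params$n_snps, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  } else {
    pE <- p0; pW <- p0
  }
  G <- matrix(NA_integer_, params$n_snps, length(ids),
              dimnames = list(sprintf("snp%05d", seq_len(params$n_snps)), ids))
  for (k in seq_along(ids))
    G[, k] <- stats::rbinom(params$n_snps, 2L, if (cohort[k] == "EAST") pE else pW)

  labeled <- stats::runif(length(ids)) < params$cin_labeled_fraction
  metadata <- data.frame(
    sample_id = ids, cohort_label = cohort,
    subtype_label = ifelse(labeled, ifelse(cin, "CIN", "NON_CIN"), "UNKNOWN"),
    stringsAsFactors = FALSE
  )
  purity <- data.frame(sample_id = ids, alpha = unname(alpha), tau = unname(tau[ids]),
                       confident = TRUE, stringsAsFactors = FALSE)
  fe <- if (length(focal_events)) do.call(rbind, focal_events) else
    data.frame(sample_id = character(0), region_id = character(0),
               type = character(0), stringsAsFactors = FALSE)
  realized <- t(vapply(seq_len(nrow(regions)), function(r) {
    has <- ids %in% fe$sample_id[fe$region_id == regions$region_id[r]]
    c(realized_east = mean(has[cohort == "EAST"]),
      realized_west = mean(has[cohort == "WEST"]))
  }, numeric(2)))
  region_rates <- cbind(regions, as.data.frame(realized))

  list(profiles = observed, genotypes = G, purity = purity, metadata = metadata,
       truth = list(
         samples = data.frame(sample_id = ids, cohort = cohort, cin = cin,
                              alpha = unname(alpha), tau = unname(tau[ids]),
                              stringsAsFactors = FALSE),
         focal_events = fe, region_rates = region_rates,
         true_profiles = true_profiles),
       arms = arms, regions = regions, params = params)
}
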