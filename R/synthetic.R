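#' Configuration for the Lambert--Beer synthetic spectra generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' absorbance proportional to SSC in a fixed optical path, Gaussian-shaped
#' absorption bands near the characteristic carbohydrate wavelengths
#' (461, 469, 750 nm), plus the three corruptions the pretreatments are
#' designed to remove -- additive white noise, per-sample baseline offset,
#' and per-sample multiplicative scatter.
#'
#' The SSC population is a single truncated Gaussian on \eqn{[8, 18)}. Its
#' default mean/sd (12.63, 1.78) are the closed-form solution of
#' \eqn{P(SSC \ge 14) = 0.22} and \eqn{P(SSC < 10) = 0.07}, so the expected
#' grade proportions are approximately 22/71/7 per 100 samples.
#'
#' @param n_samples Number of samples to draw.
#' @param ssc_mean,ssc_sd Mean and sd of the SSC population (\eqn{^\circ}Brix).
#' @param band_centers Absorption band centres in nm.
#' @param band_widths Gaussian band sd in nm (recycled over bands).
#' @param band_strengths Peak molar-absorptivity surrogate, absorbance per
#'   \eqn{^\circ}Brix per unit path (recycled over bands).
#' @param path_length Fixed optical path scalar \eqn{l} (dimensionless; the
#'   10 mm cuvette is absorbed into the band strengths).
#' @param baseline_sd Sd of the per-sample additive baseline offset (AU).
#' @param scatter_sd Sd of the per-sample multiplicative scatter factor
#'   around 1 (unitless).
#' @param noise_sd Sd of i.i.d. additive noise per point (AU).
#' @param min_per_grade Minimum samples required in every grade; the SSC
#'   vector is redrawn (deterministically) until satisfied. Default 2 so all
#'   three grades are represented, as in a designed grading cohort.
#' @param wavelengths Wavelength grid; default 400--800 nm at 5 nm.
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_samples = 100L,
                             ssc_mean = 12.63, ssc_sd = 1.78,
                             band_centers = c(461, 469, 750),
                             band_widths = 30,
                             band_strengths = c(0.02, 0.02, 0.012),
                             path_length = 1,
                             baseline_sd = 0.01,
                             scatter_sd = 0.03,
                             noise_sd = 0.003,
                             min_per_grade = 2L,
                             wavelengths = default_grid(),
                             seed = 1L) {
  stopifnot(n_samples >= 1, ssc_sd > 0, path_length > 0,
            baseline_sd >= 0, scatter_sd >= 0, noise_sd >= 0,
            all(band_centers >= min(wavelengths)),
            all(band_centers <= max(wavelengths)))
  band_widths <- rep_len(band_widths, length(band_centers))
  band_strengths <- rep_len(band_strengths, length(band_centers))
  stopifnot(all(band_widths > 0), all(band_strengths > 0))
  structure(list(n_samples = as.integer(n_samples), ssc_mean = ssc_mean,
                 ssc_sd = ssc_sd, band_centers = band_centers,
                 band_widths = band_widths, band_strengths = band_strengths,
                 path_length = path_length, baseline_sd = baseline_sd,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 min_per_grade = as.integer(min_per_grade),
                 wavelengths = as.numeric(wavelengths),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Absorptivity curve of the synthetic band mixture
#'
#' \eqn{\epsilon(\lambda) = \sum_b s_b \exp(-(\lambda-c_b)^2 / (2 w_b^2))}.
#' @noRd
band_mixture <- function(config) {
  eps <- numeric(length(config$wavelengths))
  for (b in seq_along(config$band_centers)) {
    eps <- eps + config$band_strengths[b] *
      exp(-(config$wavelengths - config$band_centers[b])^2 /
            (2 * config$band_widths[b]^2))
  }
  eps
}

#' Draw from a truncated normal by rejection, with a retry cap
#' @noRd
rtruncnorm_capped <- function(n, mean, sd, lo, hi, max_tries = 1000L) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "truncated-normal sampling infeasible within retry cap (mean=%g, sd=%g)",
        mean, sd))
    }
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x < hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic spectrum set
#'
#' Draws \eqn{SSC_i} from the truncated Gaussian population and builds
#' \deqn{A_i(\lambda) = s_i [\,l \cdot SSC_i \cdot \epsilon(\lambda) + b_i\,] + e_i(\lambda)}
#' with \eqn{b_i \sim N(0, baseline\_sd)}, \eqn{s_i \sim N(1, scatter\_sd)},
#' \eqn{e \sim N(0, noise\_sd)} i.i.d. With all corruption parameters zero,
#' every wavelength column is an exact linear function of SSC. Deterministic
#' for a fixed config seed.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param scheme \code{\link{grade_scheme}} used to label the samples.
#' @return A \code{\link{spectrum_set}} with SSC and grades.
#' @export
generate_spectra <- function(config = synthetic_config(),
                             scheme = grade_scheme()) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- scheme$boundaries
  eps <- band_mixture(config)
  with_seed(config$seed, {
    ssc <- rtruncnorm_capped(config$n_samples, config$ssc_mean, config$ssc_sd,
                             b[1], b[4])
    if (config$min_per_grade > 0L) {
      tries <- 0L
      while (any(table(factor(assign_grade(ssc, scheme), levels = 1:3)) <
                 config$min_per_grade)) {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop(sprintf(
            "could not realise %d samples per grade (mean=%g, sd=%g)",
            config$min_per_grade, config$ssc_mean, config$ssc_sd))
        }
        ssc <- rtruncnorm_capped(config$n_samples, config$ssc_mean,
                                 config$ssc_sd, b[1], b[4])
      }
    }
    clean <- config$path_length * outer(ssc, eps)
    baseline <- stats::rnorm(config$n_samples, 0, config$baseline_sd)
    scatter <- stats::rnorm(config$n_samples, 1, config$scatter_sd)
    noise <- matrix(stats::rnorm(length(clean), 0, config$noise_sd),
                    nrow = config$n_samples)
    mat <- scatter * (clean + baseline) + noise
    spectrum_set(mat, config$wavelengths, ssc = ssc, scheme = scheme)
  })
}

#' Canned synthetic fixtures
#'
#' Small deterministic spectrum sets used in tests and documentation:
#' \describe{
#'   \item{clean}{all corruption off -- absorbance exactly linear in SSC.}
#'   \item{noisy}{additive noise only (baseline and scatter off).}
#'   \item{scattered}{strong baseline offset and multiplicative scatter, the
#'     defects derivative and normalisation pretreatments must remove.}
#' }
#'
#' @param kind One of \code{"clean"}, \code{"noisy"}, \code{"scattered"}.
#' @param seed Integer seed.
#' @param n_samples Sample count (default 40).
#' @return A \code{\link{spectrum_set}}.
#' @export
make_fixture <- function(kind = c("clean", "noisy", "scattered"), seed = 1L,
                         n_samples = 40L) {
  if (!is.character(kind) || !kind[1] %in% c("clean", "noisy", "scattered")) {
    stop("unknown fixture kind; valid kinds: clean, noisy, scattered")
  }
  kind <- kind[1]
  # small sets keep every grade represented; tiny ones only ask for presence
  mpg <- if (n_samples >= 20) 3L else 1L
  cfg <- switch(kind,
    clean = synthetic_config(n_samples = n_samples, baseline_sd = 0,
                             scatter_sd = 0, noise_sd = 0,
                             min_per_grade = mpg, seed = seed),
    noisy = synthetic_config(n_samples = n_samples, baseline_sd = 0,
                             scatter_sd = 0, noise_sd = 0.005,
                             min_per_grade = mpg, seed = seed),
    scattered = synthetic_config(n_samples = n_samples, baseline_sd = 0.15,
                                 scatter_sd = 0.08, noise_sd = 0.005,
                                 min_per_grade = mpg, seed = seed))
  generate_spectra(cfg)
}
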