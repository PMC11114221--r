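#' Receptor-channel affinity profile
#'
#' The channel-by-odorant matrix of mean maximum conductances (G_max, uS) at
#' the reference concentration, plus per-cell noise SDs and per-channel
#' odorant-free baselines. This is the generative model of the sensor array:
#' three hOR-functionalized channels (hOR51E1, hOR51E2, hOR52D1) responding
#' to the four short-chain fatty acids PA (propionic), BA (butyric), VA
#' (valeric) and HA (hexanoic acid).
#'
#' @param mean_gmax numeric channels x odorants matrix of mean G_max (uS) at
#'   `ref_ppm`, with dimnames.
#' @param noise_sd per-cell Gaussian noise SD (uS): a scalar or a matrix
#'   conformable with `mean_gmax`.
#' @param baseline_gmax per-channel conductance with no odorant (uS); every
#'   `mean_gmax` entry must exceed its channel baseline.
#' @param ref_ppm reference concentration (ppm) at which `mean_gmax` holds.
#' @return An object of class `affinity_profile`.
#' @seealso [default_affinity_profile()]
#' @export
affinity_profile <- function(mean_gmax, noise_sd, baseline_gmax, ref_ppm = 3) {
  stopifnot(is.matrix(mean_gmax), !is.null(rownames(mean_gmax)),
            !is.null(colnames(mean_gmax)), all(is.finite(mean_gmax)))
  if (length(noise_sd) == 1L)
    noise_sd <- matrix(noise_sd, nrow(mean_gmax), ncol(mean_gmax),
                       dimnames = dimnames(mean_gmax))
  stopifnot(identical(dim(noise_sd), dim(mean_gmax)), all(noise_sd >= 0))
  stopifnot(length(baseline_gmax) == nrow(mean_gmax))
  if (any(mean_gmax <= baseline_gmax))
    stop("affinity_profile: every mean_gmax must exceed its channel baseline")
  if (ref_ppm <= 0) stop("affinity_profile: ref_ppm must be > 0")
  structure(list(channels = rownames(mean_gmax),
                 odorants = colnames(mean_gmax),
                 mean_gmax = mean_gmax,
                 noise_sd = noise_sd,
                 baseline_gmax = stats::setNames(baseline_gmax, rownames(mean_gmax)),
                 ref_ppm = ref_ppm),
            class = "affinity_profile")
}

#' Default affinity profile of the three-channel SCFA array
#'
#' The PA column carries the measured G_max responses at 3 ppm (170.3, 146.1
#' and 119.6 uS for hOR51E1, hOR51E2 and hOR52D1). The remaining columns are
#' synthetic: no numeric values are published for them, so they are chosen to
#' preserve each channel's response rank order across odorants (hOR51E1
#' prefers short chains, hOR51E2 peaks at butyric acid, hOR52D1 prefers long
#' chains) with adjacent single-odorant responses about 3 noise SDs apart and
#' a minimum mixture-class separation of about 2.8 noise SDs. The noise SD
#' defaults to 4% of the matrix span.
#'
#' @return An `affinity_profile`.
#' @examples
#' p <- default_affinity_profile()
#' p$mean_gmax[, "PA"]
#' @export
default_affinity_profile <- function() {
  m <- matrix(c(170.3, 146.1, 119.6,
                156.3, 166.6, 132.1,
                125.0, 122.8, 139.3,
                118.9, 139.1, 159.3),
              nrow = 3, ncol = 4,
              dimnames = list(c("hOR51E1", "hOR51E2", "hOR52D1"),
                              c("PA", "BA", "VA", "HA")))
  affinity_profile(m, noise_sd = 0.04 * (max(m) - min(m)),
                   baseline_gmax = c(100, 95, 90), ref_ppm = 3)
}

#' @export
print.affinity_profile <- function(x, ...) {
  cat("Affinity profile (mean G_max, uS, at", x$ref_ppm, "ppm):\n")
  print(round(x$mean_gmax, 1))
  cat("baselines:", paste(round(x$baseline_gmax, 1), collapse = ", "),
      "uS; noise SD:", paste(unique(round(x$noise_sd, 3)), collapse = ", "), "uS\n")
  invisible(x)
}

.check_composition <- function(profile, composition) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  unknown <- setdiff(names(composition), profile$odorants)
  if (length(unknown))
    stop("unknown odorant(s): ", paste(unknown, collapse = ", "))
  if (any(composition <= 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must be positive and sum to 1")
  invisible(composition)
}

#' Expected mixture signal on one channel
#'
#' The theoretical mixture rule: each odorant contributes its fraction of the
#' total signal, and the mixture signal is the sum of the contributions,
#' \eqn{\sum_o f_o \, G_{max}[ch, o]}. For an equimolar n-mixture this is the
#' arithmetic mean of the component signals (each component is 1/n of the
#' total).
#'
#' @param profile an [affinity_profile()].
#' @param composition named numeric vector of odorant fractions summing to 1,
#'   e.g. `c(PA = 0.5, BA = 0.5)`.
#' @param channel channel identifier(s); default all channels.
#' @return Named vector of expected G_max (uS) at the reference concentration.
#' @export
mixture_signal <- function(profile, composition, channel = profile$channels) {
  stopifnot(inherits(profile, "affinity_profile"))
  .check_composition(profile, composition)
  stopifnot(all(channel %in% profile$channels))
  sig <- drop(profile$mean_gmax[channel, names(composition), drop = FALSE] %*%
                composition)
  stats::setNames(as.numeric(sig), channel)
}

.scaled_signal <- function(profile, composition, channel, total_ppm) {
  base <- profile$baseline_gmax[channel]
  delta <- mixture_signal(profile, composition, channel) - base
  as.numeric(base + delta * total_ppm / profile$ref_ppm)
}

.composition_string <- function(composition) {
  paste(sprintf("%s:%.10g", names(composition), composition), collapse = ";")
}

#' Parse a composition string
#'
#' Inverse of the `"PA:0.5;BA:0.5"` encoding used in response tables.
#'
#' @param s a composition string.
#' @return Named numeric vector of fractions.
#' @export
parse_composition <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed composition string: ", s)
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
}

#' Sample noisy sensing replicates
#'
#' Draws `n_replicates` G_max readings per channel for one sample
#' composition at a given total concentration. The expected signal scales
#' linearly with concentration between the channel baseline (0 ppm) and the
#' profile mean (at `ref_ppm`); noise is additive Gaussian with the
#' per-cell SD (composition-weighted for mixtures). Deterministic given
#' `seed`.
#'
#' @param profile an [affinity_profile()].
#' @param composition named fraction vector (see [mixture_signal()]).
#' @param total_ppm total odorant concentration (ppm, > 0).
#' @param n_replicates replicates per channel (>= 1).
#' @param seed integer RNG seed.
#' @param sample_prefix prefix for generated sample identifiers.
#' @return Data frame of response records with columns `sample_id`,
#'   `composition`, `total_ppm`, `channel`, `gmax_uS`.
#' @export
sample_responses <- function(profile, composition, total_ppm = profile$ref_ppm,
                             n_replicates = 1L, seed = 1L,
                             sample_prefix = "s") {
  stopifnot(inherits(profile, "affinity_profile"))
  .check_composition(profile, composition)
  if (!is.numeric(total_ppm) || total_ppm <= 0)
    stop("sample_responses: total_ppm must be > 0")
  if (n_replicates < 1) stop("sample_responses: n_replicates >= 1 required")
  ch <- profile$channels
  mu <- .scaled_signal(profile, composition, ch, total_ppm)
  sd_ch <- as.numeric(profile$noise_sd[ch, names(composition), drop = FALSE] %*%
                        composition)
  set.seed(as.integer(seed))
  n <- as.integer(n_replicates)
  g <- stats::rnorm(n * length(ch),
                    mean = rep(mu, each = n),
                    sd = rep(sd_ch, each = n))
  data.frame(
    sample_id = paste0(sample_prefix, rep(seq_len(n), times = length(ch))),
    composition = .composition_string(composition),
    total_ppm = total_ppm,
    channel = rep(ch, each = n),
    gmax_uS = g,
    stringsAsFactors = FALSE
  )
}

#' Build a concentration calibration curve
#'
#' Samples seeded noisy responses at each concentration, fits the slope by
#' ordinary least squares, and estimates the blank noise SD from replicate
#' blank (0 ppm, baseline-only) readings. Feeds [detection_limit()].
#'
#' @param profile an [affinity_profile()].
#' @param channel one channel identifier.
#' @param odorant one odorant identifier.
#' @param concentrations >= 3 strictly increasing concentrations (ppm).
#' @param n_replicates replicates per concentration.
#' @param n_blanks blank replicates used for the noise SD (>= 2).
#' @param noise_sd optional noise SD override (uS); default the profile cell.
#' @param seed integer RNG seed.
#' @return An object of class `calibration_curve`: list with `channel`,
#'   `odorant`, `points` (data frame), `slope` (uS/ppm), `intercept` and
#'   `blank_sd` (uS).
#' @export
make_calibration <- function(profile, channel, odorant,
                             concentrations = c(0.5, 1, 2, 3),
                             n_replicates = 4L, n_blanks = 10L,
                             noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(profile, "affinity_profile"),
            channel %in% profile$channels, odorant %in% profile$odorants)
  conc <- as.numeric(concentrations)
  if (length(conc) < 3) stop("make_calibration: need >= 3 concentrations")
  if (any(diff(conc) <= 0))
    stop("make_calibration: concentrations must be strictly increasing")
  if (any(conc <= 0)) stop("make_calibration: concentrations must be > 0")
  if (n_blanks < 2) stop("make_calibration: n_blanks >= 2 required")
  sd_cell <- if (is.null(noise_sd)) profile$noise_sd[channel, odorant] else noise_sd
  comp <- stats::setNames(1, odorant)
  set.seed(as.integer(seed))
  n <- as.integer(n_replicates)
  mu <- vapply(conc, function(cc) .scaled_signal(profile, comp, channel, cc), 0)
  pts <- data.frame(
    concentration_ppm = rep(conc, each = n),
    gmax_uS = stats::rnorm(length(conc) * n, rep(mu, each = n), sd_cell)
  )
  fit <- stats::lm(gmax_uS ~ concentration_ppm, data = pts)
  blanks <- stats::rnorm(as.integer(n_blanks), profile$baseline_gmax[channel],
                         sd_cell)
  structure(list(channel = channel, odorant = odorant, points = pts,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 blank_sd = stats::sd(blanks)),
            class = "calibration_curve")
}
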