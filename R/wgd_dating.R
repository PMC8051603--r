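#' Shared-event evolutionary-rate correction factors
#'
#' Lineages differ in synonymous substitution rate, so a polyploidy or
#' divergence event shared by several species leaves Ks peaks at different
#' positions. Aligning each species' shared-event peak onto the reference
#' (typically the slowest lineage, which has the smallest Ks) yields a
#' multiplicative factor `f_s = mu_reference / mu_s` per species.
#'
#' @param peak_means named numeric vector: species -> fitted peak mean for
#'   one shared event.
#' @param reference reference species name (factor 1).
#' @param step correction step label (1 = shared ancient event, e.g. the
#'   eudicot triplication; 2 = within-clade re-correction).
#' @return data.frame `species, factor, step, event_reference`.
#' @export
correction_factors <- function(peak_means, reference, step = 1L) {
  if (!reference %in% names(peak_means))
    stop("reference species '", reference, "' absent from peak means")
  if (any(!is.finite(peak_means)) || any(peak_means <= 0))
    stop("peak means must be positive and finite")
  data.frame(species = names(peak_means),
             factor = unname(peak_means[[reference]] / peak_means),
             step = as.integer(step),
             reference = reference,
             stringsAsFactors = FALSE)
}

#' Apply rate-correction factors to Ks values or peak means
#'
#' Corrected Ks = Ks x f_step1 x f_step2 (factors compose multiplicatively;
#' step-2 factors default to 1 for species they do not cover). For a
#' distribution of Ks between two different species, the geometric mean of
#' the two lineages' factors is applied.
#'
#' @param ks numeric Ks values (raw values or peak means).
#' @param factors data.frame from [correction_factors()]; rows from several
#'   steps may be concatenated with `rbind()`.
#' @param species species the values belong to; give `c(a, b)` for an
#'   inter-species distribution.
#' @return corrected numeric vector.
#' @export
apply_correction <- function(ks, factors, species) {
  species <- unique(species)
  if (length(species) < 1 || length(species) > 2)
    stop("species must name one genome or a pair")
  f_for <- function(sp) {
    rows <- factors[factors$species == sp, , drop = FALSE]
    if (!nrow(rows)) stop("no correction factors for species '", sp, "'")
    prod(rows$factor)
  }
  f <- vapply(species, f_for, numeric(1))
  scale <- if (length(f) == 2) sqrt(f[[1]] * f[[2]]) else f[[1]]
  unname(ks * scale)
}

#' Relative evolutionary rates against a reference lineage
#'
#' `rate_s = (mu_s / mu_reference - 1) x 100` per cent faster than the
#' reference (negative = slower).
#'
#' @inheritParams correction_factors
#' @return named numeric vector, percent faster per species.
#' @export
relative_rates <- function(peak_means, reference) {
  if (!reference %in% names(peak_means))
    stop("reference species '", reference, "' absent from peak means")
  if (any(!is.finite(peak_means)) || any(peak_means <= 0))
    stop("peak means must be positive and finite")
  (peak_means / peak_means[[reference]] - 1) * 100
}

#' Date an event from a corrected Ks peak
#'
#' `T = mu / (2 r)` with `r` the synonymous substitution rate per site per
#' year; the interval is `[(mu - sigma)/(2r), (mu + sigma)/(2r)]`, clipped
#' at 0, reported in million years (Mya). `r` has no default because
#' calibrations differ between studies; it must be supplied explicitly.
#'
#' @param mu corrected peak mean (Ks).
#' @param sigma peak standard deviation (Ks); 0 gives a point estimate.
#' @param clock_rate `r`, synonymous substitutions per site per year.
#' @return list `T_low, T_mid, T_high` in Mya.
#' @export
date_event <- function(mu, sigma = 0, clock_rate) {
  if (missing(clock_rate)) stop("date_event: clock_rate must be supplied")
  if (!is.finite(mu) || mu < 0) stop("date_event: mu must be non-negative")
  if (clock_rate <= 0) stop("date_event: clock_rate must be positive")
  to_mya <- function(k) max(k, 0) / (2 * clock_rate) / 1e6
  list(T_low = to_mya(mu - sigma), T_mid = to_mya(mu), T_high = to_mya(mu + sigma))
}

#' Dating report for several events/species
#'
#' @param peaks data.frame with columns `event, species, mu_raw, sigma`.
#' @param factors correction factor table (possibly both steps, rbind-ed).
#' @param clock_rate synonymous substitution rate per site per year.
#' @return data.frame `event species mu_raw mu_corrected sigma T_low T_mid
#'   T_high` (times in Mya).
#' @export
dating_report <- function(peaks, factors, clock_rate) {
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    mu_c <- apply_correction(peaks$mu_raw[i], factors, peaks$species[i])
    dt <- date_event(mu_c, peaks$sigma[i], clock_rate)
    data.frame(event = peaks$event[i], species = peaks$species[i],
               mu_raw = peaks$mu_raw[i], mu_corrected = mu_c,
               sigma = peaks$sigma[i],
               T_low = dt$T_low, T_mid = dt$T_mid, T_high = dt$T_high)
  })
  do.call(rbind, rows)
}
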