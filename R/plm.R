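#' Scan promoters for an IUPAC motif
#'
#' Reports every (possibly overlapping) start position at which the pattern
#' matches under IUPAC degeneracy, on the TSS-relative axis (-1 is the base
#' immediately upstream of the TSS, 0 the first UTR base).  Ambiguity codes
#' in the promoter sequence (N etc.) are literal and never match.  With
#' `strands = "both"` the reverse complement is also scanned and matches
#' are reported at their leftmost promoter-axis position.
#'
#' @param promoters Promoter tibble ([read_promoters()] /
#'   [simulate_promoters()]).
#' @param pattern IUPAC motif string.
#' @param strands `"fwd"` (promoter strand only, the default) or `"both"`.
#' @return A tibble `gene_id`, `position` (one row per occurrence).
#' @export
scan_motif <- function(promoters, pattern, strands = c("fwd", "both")) {
  strands <- match.arg(strands)
  validate_motifs(tibble(name = "m", pattern = pattern))
  subject <- Biostrings::DNAStringSet(promoters$sequence)
  names(subject) <- promoters$gene_id
  hit_starts <- function(pat) {
    Biostrings::startIndex(
      Biostrings::vmatchPattern(pat, subject, fixed = "subject"))
  }
  starts <- hit_starts(pattern)
  if (strands == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    if (rc != toupper(pattern)) {
      rc_starts <- hit_starts(rc)
      starts <- purrr::map2(starts, rc_starts, ~ sort(c(.x, .y)))
    }
  }
  purrr::map2_dfr(promoters$gene_id, seq_along(starts), function(gid, i) {
    s <- starts[[i]]
    if (is.null(s)) return(NULL)
    up <- promoters$upstream_length[i]
    tibble(gene_id = gid, position = as.integer(s - up - 1L))
  })
}

#' Bin motif occurrences into a positional profile
#'
#' Aggregates occurrence start positions over promoters into fixed-width
#' bins anchored at -`upstream`, covering the axis up to the longest UTR.
#' Each bin carries its occurrence count, its coverage (number of promoters
#' whose extent fully spans the bin) and the rate count/coverage, so that
#' variable UTR lengths do not fabricate positional trends.
#'
#' @param occurrences Output of [scan_motif()].
#' @param promoters The promoter tibble that was scanned.
#' @param bin_width Bin width in bases; must divide the background span
#'   (`upstream` - 300) so the regression region is whole bins.
#' @param upstream Upstream window length (axis origin is -`upstream`).
#' @return A tibble of class `motif_profile`: `bin_lo`, `bin_hi`,
#'   `midpoint`, `count`, `coverage`, `rate`, `region`
#'   (`"background"` for bins left of -300, else `"search"`), with
#'   attributes `n_promoters` and `bin_width`.
#' @export
build_profile <- function(occurrences, promoters, bin_width = 10,
                          upstream = 1000) {
  if ((upstream - 300) %% bin_width != 0) {
    abort("bin_width must divide the background span (upstream - 300)")
  }
  max_utr <- max(promoters$utr_length)
  breaks <- seq(-upstream, by = bin_width,
                length.out = ceiling((upstream + max_utr) / bin_width) + 1)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  count <- vapply(seq_along(lo), function(b) {
    sum(occurrences$position >= lo[b] & occurrences$position < hi[b])
  }, 0L)
  coverage <- vapply(seq_along(lo), function(b) {
    sum(-promoters$upstream_length <= lo[b] & promoters$utr_length >= hi[b])
  }, 0L)
  out <- tibble(bin_lo = as.integer(lo), bin_hi = as.integer(hi),
                midpoint = (lo + hi) / 2,
                count = count, coverage = coverage,
                rate = ifelse(coverage > 0, count / coverage, NA_real_),
                region = ifelse(hi <= -300, "background", "search"))
  attr(out, "n_promoters") <- nrow(promoters)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("motif_profile", class(out))
  out
}

#' Fit the linear positional background model
#'
#' Ordinary least squares of bin rate on bin midpoint over the background
#' region (bins fully left of -300 with full promoter coverage).  The model
#' provides a 95% upper prediction bound
#' `U(x) = a x + b + t(0.975, m - 2) s sqrt(1 + 1/m + (x - xbar)^2 / Sxx)`
#' against which search-region peaks are judged; a prediction (not mean)
#' interval because each search bin is a new observation.
#'
#' @param profile A [build_profile()] result.
#' @return An object of class `plm_model` with slope `a`, intercept `b`,
#'   residual SD `s`, number of background bins `m`, `xbar`, `sxx`.
#' @export
fit_background <- function(profile) {
  n_prom <- attr(profile, "n_promoters")
  bg <- profile[profile$region == "background" & profile$coverage == n_prom, ]
  if (nrow(bg) < 3) abort("need at least 3 fully covered background bins")
  x <- bg$midpoint
  if (sd(x) == 0) abort("zero variance in background bin midpoints")
  fit <- lm(rate ~ midpoint, data = bg)
  s <- sqrt(sum(fit$residuals^2) / (nrow(bg) - 2))
  structure(list(a = unname(fit$coefficients[2]),
                 b = unname(fit$coefficients[1]),
                 s = s, m = nrow(bg), xbar = mean(x),
                 sxx = sum((x - mean(x))^2)),
            class = "plm_model")
}

#' @rdname fit_background
#' @param model A `plm_model`.
#' @param x Axis positions at which to evaluate the 95% upper prediction
#'   bound.
#' @export
upper_bound <- function(model, x) {
  model$a * x + model$b +
    qt(0.975, model$m - 2) * model$s *
      sqrt(1 + 1 / model$m + (x - model$xbar)^2 / model$sxx)
}

#' @method tidy plm_model
#' @export
tidy.plm_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "midpoint"), estimate = c(x$b, x$a))
}

#' @method glance plm_model
#' @export
glance.plm_model <- function(x, ...) {
  tibble(sigma = x$s, n_background_bins = x$m)
}

#' Judge a motif profile against the background model
#'
#' A motif is preferentially located (PLM) when some bin of the search
#' region ([-300, UTR), restricted to bins covered by at least
#' `min_coverage` of the promoters) has a rate strictly above the model's
#' 95% upper prediction bound at the bin midpoint.  The peak is the bin of
#' maximal exceedance.
#'
#' @param profile A [build_profile()] result.
#' @param model The fitted [fit_background()] model.
#' @param min_coverage Minimum fraction of promoters a search bin must
#'   span to be eligible.
#' @return A one-row tibble `is_plm`, `peak_lo`, `peak_hi`, `peak_rate`,
#'   `bound_at_peak`, `n_search_bins`.
#' @export
detect_plm <- function(profile, model, min_coverage = 0.5) {
  n_prom <- attr(profile, "n_promoters")
  search <- profile[profile$region == "search" &
                      profile$coverage >= min_coverage * n_prom, ]
  if (nrow(search) == 0) abort("empty search region after coverage filter")
  u <- upper_bound(model, search$midpoint)
  exceed <- search$rate - u
  k <- which.max(exceed)
  tibble(is_plm = any(exceed > 0),
         peak_lo = search$bin_lo[k], peak_hi = search$bin_hi[k],
         peak_rate = search$rate[k], bound_at_peak = u[k],
         n_search_bins = nrow(search))
}

#' Positional motif (PLM) screen over a motif library
#'
#' For every motif: scan the UTR-filtered promoters, bin the occurrences,
#' fit the linear background on [-upstream, -300), and test the
#' [-300, UTR) region against the 95% upper prediction bound.
#'
#' @param promoters Promoter tibble; genes with `utr_length < min_utr` are
#'   dropped first.
#' @param motifs Motif library tibble ([read_motifs()]).
#' @param bin_width,min_coverage,strands Passed to the stages.
#' @param min_utr UTR filter.
#' @param upstream Upstream window length.
#' @return A tibble of class `plm_screen`: one row per motif with the
#'   [detect_plm()] fields plus `motif`, `pattern`, `n_occurrences`.
#' @export
run_plm <- function(promoters, motifs, bin_width = 10, min_coverage = 0.5,
                    strands = "fwd", min_utr = 10, upstream = 1000) {
  motifs <- validate_motifs(motifs)
  promoters <- promoters[promoters$utr_length >= min_utr, ]
  if (nrow(promoters) == 0) abort("no promoters left after UTR filter")
  out <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    occ <- scan_motif(promoters, motifs$pattern[i], strands = strands)
    profile <- build_profile(occ, promoters, bin_width = bin_width,
                             upstream = upstream)
    model <- fit_background(profile)
    res <- detect_plm(profile, model, min_coverage = min_coverage)
    dplyr::bind_cols(tibble(motif = motifs$name[i],
                            pattern = motifs$pattern[i],
                            n_occurrences = nrow(occ)), res)
  })
  inform(sprintf("%d of %d motif(s) preferentially located",
                 sum(out$is_plm), nrow(out)))
  class(out) <- c("plm_screen", class(out))
  out
}
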