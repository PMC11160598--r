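#' Calibrate a score threshold at a target false discovery rate
#'
#' On labeled held-out pairs, the raw FDR at a candidate threshold s is
#' FP / (TP + FP) among pairs scoring at least s. The q-value at s is the
#' minimum raw FDR over all thresholds at or below s (a running minimum
#' from the bottom of the ranking), which makes q non-increasing in score.
#' The returned operating threshold is the smallest score whose q-value
#' meets the target, i.e. the most inclusive acceptance set whose
#' estimated FDR is still within target.
#'
#' @param scored Tibble of held-out pairs with `score` and `label`.
#' @param target_fdr Target FDR in (0, 1); default 0.10.
#' @return An object of class `"fdr_calibration"`: a list with `threshold`
#'   (NA if no threshold meets the target), `target_fdr`, and `curve`, a
#'   tibble (`threshold`, `n_accepted`, `n_fp`, `raw_fdr`, `q_value`) with
#'   thresholds descending.
#' @export
#' @examples
#' scored <- tibble::tibble(score = c(.9, .8, .7, .6, .5),
#'                          label = c(1, 1, 0, 1, 0))
#' calibrate_fdr(scored, target_fdr = 0.3)$threshold
calibrate_fdr <- function(scored, target_fdr = 0.10) {
  if (target_fdr <= 0 || target_fdr >= 1) {
    stop("`target_fdr` must be in (0, 1)", call. = FALSE)
  }
  if (sum(scored$label) == 0) {
    stop("no positive pairs in the calibration set", call. = FALSE)
  }
  ord <- order(-scored$score)
  s <- scored$score[ord]
  y <- scored$label[ord]
  n <- seq_along(y)
  fp <- cumsum(1 - y)
  raw <- fp / n
  last <- !duplicated(s, fromLast = TRUE)
  curve <- tibble(
    threshold = s[last],
    n_accepted = n[last],
    n_fp = fp[last],
    raw_fdr = raw[last]
  )
  curve$q_value <- rev(cummin(rev(curve$raw_fdr)))
  ok <- curve$q_value <= target_fdr
  threshold <- if (any(ok)) min(curve$threshold[ok]) else NA_real_
  if (is.na(threshold)) {
    warning("no threshold reaches the target FDR; nothing would be accepted")
  }
  structure(list(threshold = threshold, target_fdr = target_fdr,
                 curve = curve),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf("<fdr_calibration> target=%.3g, threshold=%s (%d thresholds)\n",
              x$target_fdr,
              ifelse(is.na(x$threshold), "NA", format(x$threshold)),
              nrow(x$curve)))
  invisible(x)
}

#' Attach q-values and acceptance flags to a scored network
#'
#' Maps each pair's score through the calibration's step function
#' (the q-value of the largest calibrated threshold at or below the score)
#' and flags pairs whose q-value meets the calibration's target FDR.
#'
#' @param scored_network Tibble with a `score` column.
#' @param calibration An `"fdr_calibration"` object.
#' @return The input tibble with `q_value` and `accepted` columns.
#' @export
apply_fdr <- function(scored_network, calibration) {
  curve <- calibration$curve
  xs <- rev(curve$threshold)  # ascending
  qs <- rev(curve$q_value)
  q <- if (length(xs) == 1L) {
    rep(qs, nrow(scored_network))
  } else {
    stats::approx(xs, qs, xout = scored_network$score,
                  method = "constant", f = 0, rule = 2)$y
  }
  dplyr::mutate(scored_network,
                q_value = q,
                accepted = .data$q_value <= calibration$target_fdr)
}

#' Agreement of a scored network with an external pair set
#'
#' Bins pairs by score and compares, per bin, the observed overlap with an
#' externally defined pair set against the expectation under uniform
#' random pairing over the same node universe. Ratios above 1 indicate
#' enrichment; empty bins are flagged with `NA`.
#'
#' @param scored_network Tibble (`og_a`, `og_b`, `score`).
#' @param external_pairs Tibble (`og_a`, `og_b`) of externally supported
#'   pairs (order-insensitive); must be nonempty.
#' @param n_bins Number of equal-width score bins.
#' @return A tibble (`bin`, `score_lo`, `score_hi`, `n_pairs`,
#'   `n_external`, `expected`, `enrichment`).
#' @export
external_agreement <- function(scored_network, external_pairs, n_bins = 10L) {
  if (nrow(external_pairs) == 0L) {
    stop("`external_pairs` must be nonempty", call. = FALSE)
  }
  nodes <- unique(c(scored_network$og_a, scored_network$og_b))
  ext_key <- unique(pair_key(external_pairs$og_a, external_pairs$og_b))
  ext_in <- external_pairs[pair_key(external_pairs$og_a,
                                    external_pairs$og_b) %in% ext_key &
                             external_pairs$og_a %in% nodes &
                             external_pairs$og_b %in% nodes, ]
  n_universe <- choose(length(nodes), 2)
  p_ext <- length(unique(pair_key(ext_in$og_a, ext_in$og_b))) / n_universe
  brk <- seq(min(scored_network$score), max(scored_network$score),
             length.out = n_bins + 1L)
  bin <- cut(scored_network$score, breaks = brk, include.lowest = TRUE,
             labels = FALSE)
  is_ext <- pair_key(scored_network$og_a, scored_network$og_b) %in% ext_key
  purrr::map_dfr(seq_len(n_bins), function(b) {
    inb <- bin == b
    n_b <- sum(inb)
    obs <- sum(is_ext & inb)
    expd <- n_b * p_ext
    tibble(bin = b, score_lo = brk[b], score_hi = brk[b + 1L],
           n_pairs = n_b, n_external = obs, expected = expd,
           enrichment = ifelse(n_b == 0 | expd == 0, NA_real_, obs / expd))
  })
}
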