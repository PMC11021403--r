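#' Hyperbolic indifference discount rate of a choice item
#'
#' For a choice between an immediate amount `ss_amount` and a delayed
#' amount `ll_amount` after `ll_delay_days` days, returns the hyperbolic
#' discount rate `k* = (ll/ss - 1) / D` at which both options have equal
#' subjective value under `V = A / (1 + kD)`.
#'
#' @param item a one-row data.frame (or list) with fields `ss_amount`,
#'   `ll_amount`, `ll_delay_days`; vectors are accepted.
#' @return positive indifference rate(s), per day.
#' @examples
#' item_indifference_k(list(ss_amount = 14, ll_amount = 25, ll_delay_days = 19))
#' @export
item_indifference_k <- function(item) {
  ss <- item$ss_amount; ll <- item$ll_amount; d <- item$ll_delay_days
  if (any(d <= 0)) stop("larger-later delay must be positive")
  if (any(ss <= 0) || any(ll <= ss)) stop("need ll_amount > ss_amount > 0")
  (ll / ss - 1) / d
}

#' Generate an MCQ-style intertemporal choice item set
#'
#' Builds `n_items` choices between a smaller-immediate and a larger-later
#' reward across magnitude bands, each rendered in both a delay frame and a
#' date frame with identical amounts and delays. Within each band the
#' hyperbolic indifference rates are log-spaced over `k_range`, mirroring
#' the geometry of the 27-item Monetary Choice Questionnaire (bands defined
#' by the larger-later amount: small $25-35, medium $50-60, large $75-85).
#'
#' @param n_items total number of distinct choices (divisible by the number
#'   of bands); default 27.
#' @param bands named list of larger-later amount ranges, default the three
#'   MCQ bands.
#' @param k_range length-2 positive vector of indifference rates (per day)
#'   spanned log-uniformly within each band; default `c(0.0016, 0.25)`.
#' @param seed integer seed for the amount/delay draws.
#' @param date_anchor calendar date used to render the date frame.
#' @return data.frame of `2 * n_items` rows (both frames) with columns
#'   `item_id, ss_amount, ss_delay_days, ll_amount, ll_delay_days,
#'   magnitude_band, frame, render_date_anchor`.
#' @export
generate_item_set <- function(n_items = 27,
                              bands = list(small = c(25, 35),
                                           medium = c(50, 60),
                                           large = c(75, 85)),
                              k_range = c(0.0016, 0.25),
                              seed = 1,
                              date_anchor = as.Date("2022-11-11")) {
  if (!is.list(bands) || is.null(names(bands)) ||
      !all(vapply(bands, function(b) length(b) == 2 && b[1] < b[2], TRUE)))
    stop_config("invalid band spec: need a named list of increasing ranges")
  if (length(k_range) != 2 || any(k_range <= 0) || k_range[1] > k_range[2])
    stop_config("k_range must be positive and non-decreasing")
  nb <- length(bands)
  if (n_items %% nb != 0)
    stop_config("n_items (", n_items, ") not divisible by number of bands (", nb, ")")
  per_band <- n_items / nb
  set.seed(seed)
  rows <- list()
  for (b in seq_len(nb)) {
    ks <- if (k_range[1] == k_range[2]) rep(k_range[1], per_band) else
      exp(seq(log(k_range[1]), log(k_range[2]), length.out = per_band))
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    ll <- round(seq(lo, hi, length.out = per_band)[sample.int(per_band)])
    # pick delay, then the smaller-immediate amount that lands k* on target;
    # delays drawn so amounts stay plausible (ss within (0, ll))
    delay <- pmax(1L, as.integer(round(exp(stats::runif(per_band,
                                                        log(7), log(186))))))
    # smaller-immediate amount chosen so k* lands exactly on target
    ss <- ll / (1 + ks * delay)
    rows[[b]] <- data.frame(
      item_id = paste0(names(bands)[b], "_", seq_len(per_band)),
      ss_amount = ss, ss_delay_days = 0L,
      ll_amount = ll, ll_delay_days = delay,
      magnitude_band = names(bands)[b],
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, rows)
  both <- rbind(transform(items, frame = "delay"),
                transform(items, frame = "date"))
  both$render_date_anchor <- date_anchor
  rownames(both) <- NULL
  both
}
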