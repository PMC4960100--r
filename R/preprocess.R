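#' Per-probe summary table
#'
#' Mean, sample standard deviation (denominator n - 1), ascending ranks of
#' both (ties get the average rank), and their rank sum, per feature column.
#'
#' @param data a [labeled_dataset()] with at least 2 samples.
#' @return data frame with columns `feature_id`, `mean`, `sd`, `mean_rank`,
#'   `sd_rank`, `rank_sum`.
#' @export
probe_summary <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (nrow(data$features) < 2) {
    stop("at least 2 samples are required to compute probe SDs")
  }
  m <- colMeans(data$features)
  s <- apply(data$features, 2, sd)
  mr <- rank(m, ties.method = "average")
  sr <- rank(s, ties.method = "average")
  data.frame(feature_id = data$feature_ids, mean = m, sd = s,
             mean_rank = mr, sd_rank = sr, rank_sum = mr + sr,
             row.names = NULL)
}

#' Filter specification for probe selection
#'
#' @param mean_quantile,sd_quantile quantile thresholds in \[0, 1\] used by
#'   the `quantile_and` mode.
#' @param mode `"quantile_and"` keeps probes whose mean AND SD both lie at
#'   or above the stated quantiles of their empirical distributions (at the
#'   default 0.7/0.7 roughly `0.3 * 0.3 = 9%` of probes survive when mean
#'   and SD ranks are independent); `"top_k_ranksum"` keeps the `k` probes
#'   with the largest `rank(mean) + rank(sd)`.
#' @param k number of probes to keep in `top_k_ranksum` mode.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(mean_quantile = 0.7, sd_quantile = 0.7,
                        mode = c("quantile_and", "top_k_ranksum"), k = NULL) {
  mode <- match.arg(mode)
  for (q in c(mean_quantile, sd_quantile)) {
    if (!is.numeric(q) || q < 0 || q > 1) stop("quantiles must lie in [0, 1]")
  }
  if (mode == "top_k_ranksum") {
    if (is.null(k) || k < 1) stop("mode 'top_k_ranksum' requires k >= 1")
  }
  structure(list(mean_quantile = mean_quantile, sd_quantile = sd_quantile,
                 mode = mode, k = if (is.null(k)) NULL else as.integer(k)),
            class = "filter_spec")
}

#' Filter probes by mean and standard deviation
#'
#' Rank-based probe filtering as used on methylation beta-value matrices
#' before classification. In `quantile_and` mode a probe is kept when its
#' mean and its SD both reach the respective empirical quantile; in
#' `top_k_ranksum` mode the `k` probes with the largest
#' `rank(mean) + rank(sd)` are kept (ties at the cutoff broken by column
#' order). Column order of kept probes is preserved either way.
#'
#' @param data a [labeled_dataset()] (>= 2 samples, no missing values).
#' @param spec a [filter_spec()].
#' @return list with `filtered` (the reduced [labeled_dataset()]) and
#'   `kept_ids` (character vector of retained feature ids, with the applied
#'   thresholds attached as attributes).
#' @export
filter_probes <- function(data, spec = filter_spec()) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(spec, "filter_spec"))
  tab <- probe_summary(data)
  n_probes <- nrow(tab)
  if (spec$mode == "quantile_and") {
    if (all(tab$sd == 0)) {
      stop("all probes are constant (SD = 0): the SD quantile of a ",
           "degenerate distribution is ambiguous; use mode 'top_k_ranksum'")
    }
    mthr <- quantile(tab$mean, spec$mean_quantile, names = FALSE)
    sthr <- quantile(tab$sd, spec$sd_quantile, names = FALSE)
    keep <- which(tab$mean >= mthr & tab$sd >= sthr)
    thresholds <- c(mean = mthr, sd = sthr)
  } else {
    if (spec$k > n_probes) {
      stop("k = ", spec$k, " exceeds the number of probes (", n_probes, ")")
    }
    ord <- order(-tab$rank_sum, seq_len(n_probes))
    keep <- sort(ord[seq_len(spec$k)])
    thresholds <- c(min_rank_sum = min(tab$rank_sum[keep]))
  }
  if (length(keep) == 0) {
    stop("filter removed every probe (mean_quantile = ", spec$mean_quantile,
         ", sd_quantile = ", spec$sd_quantile, ")")
  }
  kept_ids <- data$feature_ids[keep]
  attr(kept_ids, "thresholds") <- thresholds
  attr(kept_ids, "mode") <- spec$mode
  list(filtered = subset_dataset(data, cols = keep), kept_ids = kept_ids)
}
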