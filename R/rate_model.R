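#' Power-law fit of collision growth with database size
#'
#' Fits `Y = c * X^m` by ordinary least squares of `log(Y)` on `log(X)`
#' (natural logs; `m` is base-invariant), where `X` is the simulated
#' database size and `Y` the number of sequences in multi-species clusters.
#' The exponent `m` is the growth *rate* of resolution loss: `m > 1` means
#' sequences are recruited into multi-species clusters super-linearly as
#' the database grows.  Points with `Y = 0` carry no information about a
#' multiplicative law and are excluded (no pseudocount), with the exclusion
#' count reported.
#'
#' @param x Database sizes (all > 0).
#' @param y Sequences in multi-species clusters at each size.
#' @return One-row tibble: `c`, `m`, `r_squared`, `n_points_used`,
#'   `n_points_dropped_zero`, `ok`, `reason`.  With fewer than two
#'   positive-`Y` points the fit is undefined (`ok = FALSE`, estimates
#'   `NA`).
#' @examples
#' x <- c(1000, 2000, 3000, 4000, 5000)
#' fit_rate(x, 0.02 * x^1.4)  # recovers c = 0.02, m = 1.4
#' @export
fit_rate <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y >= 0))
  pos <- y > 0
  n_drop <- sum(!pos)
  x <- x[pos]; y <- y[pos]
  if (length(x) < 2L || length(unique(x)) < 2L) {
    return(tibble(c = NA_real_, m = NA_real_, r_squared = NA_real_,
                  n_points_used = length(x), n_points_dropped_zero = n_drop,
                  ok = FALSE,
                  reason = "fewer than 2 distinct positive-Y points"))
  }
  fit <- lm(log(y) ~ log(x))
  # summary.lm warns on noiseless data (perfect fit), a legitimate input here
  s <- suppressWarnings(summary(fit))
  tibble(c = exp(unname(coef(fit)[1])), m = unname(coef(fit)[2]),
         r_squared = s$r.squared, n_points_used = length(x),
         n_points_dropped_zero = n_drop, ok = TRUE, reason = NA_character_)
}

#' Power-law fits for every marker family and threshold
#'
#' Applies [fit_rate()] per (marker, threshold) group of a collision-stats
#' table.  With replicates the default fits the per-size replicate medians,
#' matching how the growth curves are reported; `on = "all"` fits every
#' replicate point instead (more points, more variance insight).  A group
#' whose fit is undefined is reported as such without aborting the others.
#'
#' @param stats Row-bound [collision_summary()] rows.
#' @param on `"median"` or `"all"`.
#' @return Tibble with one row per (marker, threshold): `marker_id`,
#'   `threshold`, and the [fit_rate()] columns.
#' @export
fit_all <- function(stats, on = c("median", "all")) {
  on <- match.arg(on)
  groups <- stats %>% distinct(.data$marker_id, .data$threshold)
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- stats %>% filter(.data$marker_id %in% groups$marker_id[i] |
                            (is.na(.data$marker_id) &
                               is.na(groups$marker_id[i])),
                          .data$threshold == groups$threshold[i])
    if (on == "median") {
      g <- g %>% group_by(.data$db_size) %>%
        summarise(n_sequences_in_msc = median(.data$n_sequences_in_msc),
                  .groups = "drop")
    }
    out[[i]] <- dplyr::bind_cols(groups[i, ],
                                 fit_rate(g$db_size, g$n_sequences_in_msc))
  }
  bind_rows(out)
}

#' Write rate fits as TSV
#' @param fits Output of [fit_all()].
#' @param path Output TSV path.
#' @export
write_rate_fits <- function(fits, path) {
  write_tsv_plain(fits, path)
}
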