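#' Classify a genome's RIP-like activity from its enrichment profile
#'
#' Counts the defined k-mers enriched more than `fold` (default 2) in
#' non-coding versus coding sequence (`n_noncoding`), at repeats versus
#' non-coding sequence (`n_repeat`), and in both (`n_both`). The ratio
#' `n_both / n_noncoding` drives the categorical call:
#'
#' * `recent` — ratio > `ratio_recent` (0.5) and `n_both >= min_both` (10):
#'   more than half of the non-coding-enriched k-mers are also
#'   repeat-enriched, on at least 10 k-mers.
#' * `trace` — ratio in the closed band \[`ratio_trace_low`, `ratio_recent`\]
#'   (0.3-0.5): the signature persists in non-coding DNA from old, no longer
#'   annotated repeats, but recent activity is absent.
#' * `none` — everything else, including the corner case ratio > 0.5 with
#'   `n_both < min_both`, where the k-mer support is too thin to call recent
#'   activity (flagged in `flag_small_both` and warned about).
#' * `undetermined` — no k-mer is non-coding-enriched at all
#'   (`n_noncoding == 0`), so the ratio is undefined.
#'
#' @param profile Tibble from [enrichment_profile()] or
#'   [genome_enrichment_profile()].
#' @param fold Enrichment threshold applied to both ratios (strict `>`).
#' @param min_both Minimum `n_both` for a `recent` call.
#' @param ratio_recent Ratio threshold for `recent` (strict `>`).
#' @param ratio_trace_low Lower bound of the trace band (closed).
#' @return One-row tibble: n_noncoding, n_repeat, n_both, ratio, status,
#'   flag_small_both.
#' @export
classify_rip <- function(profile, fold = 2, min_both = 10,
                         ratio_recent = 0.5, ratio_trace_low = 0.3) {
  stopifnot(all(c("E_noncoding", "E_repeat", "defined_nc", "defined_rep")
                %in% names(profile)))
  enr_nc <- profile$defined_nc & !is.na(profile$E_noncoding) &
    profile$E_noncoding > fold
  enr_rep <- profile$defined_rep & !is.na(profile$E_repeat) &
    profile$E_repeat > fold
  n_noncoding <- sum(enr_nc)
  n_repeat <- sum(enr_rep)
  n_both <- sum(enr_nc & enr_rep)

  flag_small_both <- FALSE
  if (n_noncoding == 0) {
    status <- "undetermined"
    ratio <- NA_real_
  } else {
    ratio <- n_both / n_noncoding
    if (ratio > ratio_recent && n_both >= min_both) {
      status <- "recent"
    } else if (ratio >= ratio_trace_low && ratio <= ratio_recent) {
      status <- "trace"
    } else {
      status <- "none"
      if (ratio > ratio_recent && n_both < min_both) {
        flag_small_both <- TRUE
        warning("ratio > ", ratio_recent, " but n_both (", n_both, ") < ",
                min_both, ": classified 'none' (insufficient k-mer support)")
      }
    }
  }
  tibble::tibble(n_noncoding = n_noncoding, n_repeat = n_repeat,
                 n_both = n_both, ratio = ratio,
                 status = factor(status, levels = c("recent", "trace",
                                                    "none", "undetermined")),
                 flag_small_both = flag_small_both)
}
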