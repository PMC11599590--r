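## From raw per-sample read counts to filtered, pooled outcome profiles,
## category aggregates and knockout fold changes.

#' Filter raw counts and pool replicates/timepoints into outcome profiles
#'
#' Applies the screen's coverage filters on the raw per-sample counts, then
#' pools: (1) any target with fewer than `min_reads` mutated reads in any
#' (line, replicate, timepoint) sample — including targets missing entirely
#' from a sample — is dropped everywhere, so retained targets are comparable
#' across lines; (2) outcomes observed in exactly one read summed across all
#' samples are dropped; (3) surviving counts are summed over replicates and
#' timepoints into one profile per (target, line). Frequencies are fractions
#' of mutated reads, bounded between 0 and 1.
#'
#' @param counts tibble with columns `target`, `line`, `replicate`,
#'   `timepoint`, `outcome`, `count` (zero rows may be omitted).
#' @param min_reads minimum mutated reads per (target, sample) (default 100).
#' @return an `outcome_profiles` tibble: `target`, `line`, `outcome`,
#'   `count`, `total`, `freq`, with attributes `dropped_targets` and
#'   `dropped_outcomes`.
#' @export
filter_and_pool <- function(counts, min_reads = 100L) {
  stopifnot(all(c("target", "line", "replicate", "timepoint", "outcome", "count")
                %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != floor(counts$count))) {
    stop("counts must be non-negative integers")
  }
  grid_n <- nrow(dplyr::distinct(counts, .data$line, .data$replicate, .data$timepoint))
  totals <- counts |>
    dplyr::group_by(.data$target, .data$line, .data$replicate, .data$timepoint) |>
    dplyr::summarise(tot = sum(.data$count), .groups = "drop")
  by_target <- totals |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(n_samples = dplyr::n(), min_tot = min(.data$tot))
  keep <- by_target$target[by_target$n_samples == grid_n & by_target$min_tot >= min_reads]
  dropped_targets <- setdiff(unique(counts$target), keep)
  if (length(dropped_targets)) {
    message(sprintf("filter_and_pool: dropped %d target(s) below %d reads in some sample",
                    length(dropped_targets), min_reads))
  }

  singles <- counts |>
    dplyr::group_by(.data$target, .data$outcome) |>
    dplyr::summarise(s = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$s == 1L)

  pooled <- counts |>
    dplyr::filter(.data$target %in% keep) |>
    dplyr::anti_join(singles, by = c("target", "outcome")) |>
    dplyr::group_by(.data$target, .data$line, .data$outcome) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$count), freq = .data$count / .data$total) |>
    dplyr::ungroup()
  attr(pooled, "dropped_targets") <- dropped_targets
  attr(pooled, "dropped_outcomes") <- nrow(singles)
  class(pooled) <- c("outcome_profiles", class(pooled))
  pooled
}

#' Annotate profile outcomes with the indel algebra
#'
#' Joins each (target, outcome) against the target's candidate enumeration;
#' outcomes outside the enumeration window are parsed and classified
#' individually.
#'
#' @param profiles an [filter_and_pool()] result (or any tibble with
#'   `target` and `outcome`).
#' @param library named list of [target_site()]s covering the profiled
#'   targets.
#' @param mh_min microhomology threshold.
#' @return tibble keyed by (`target`, `outcome`) with `category`,
#'   `del_size`, `ins_size`, `mh_len`, `d`, `left_del`, `right_del`,
#'   `in_frame` and `directionality` (`NA` for insertion-bearing outcomes).
#' @export
annotate_outcomes <- function(profiles, library, mh_min = 2L) {
  keys <- dplyr::distinct(tibble::as_tibble(profiles[c("target", "outcome")]))
  out <- lapply(split(keys$outcome, keys$target), unique)
  rows <- lapply(names(out), function(tid) {
    target <- library[[tid]]
    if (is.null(target)) stop("target missing from library: ", tid)
    cs <- enumerate_candidates(target, mh_min = mh_min)
    cs <- tibble::as_tibble(cs)[, c("outcome", "category", "del_size", "ins_size",
                                    "mh_len", "d", "left_del", "right_del", "in_frame")]
    miss <- setdiff(out[[tid]], cs$outcome)
    if (length(miss)) {
      extra <- lapply(miss, function(dsc) {
        o <- parse_outcome(target, dsc)
        tibble::tibble(
          outcome = dsc, category = classify_outcome(target, o, mh_min = mh_min),
          del_size = o$del_size, ins_size = o$ins_size, mh_len = o$mh_len,
          d = if (is.na(o$mh_len)) NA_integer_ else o$del_size - o$mh_len,
          left_del = o$left_del, right_del = o$right_del,
          in_frame = is_in_frame(o)
        )
      })
      cs <- dplyr::bind_rows(cs, dplyr::bind_rows(extra))
    }
    cs <- cs[cs$outcome %in% out[[tid]], ]
    cs$target <- tid
    cs
  })
  ann <- dplyr::bind_rows(rows)
  ann$directionality <- ifelse(
    ann$ins_size == 0L & ann$del_size > 0L,
    pmax(ann$left_del, ann$right_del) / ann$del_size, NA_real_
  )
  ann
}

#' Aggregate an outcome profile into the ten-category frequency vector
#'
#' @inheritParams annotate_outcomes
#' @return tibble `target`, `line`, `category`, `freq`, complete over
#'   [outcome_categories()]; per (target, line) the frequencies sum to 1.
#' @export
aggregate_categories <- function(profiles, library, mh_min = 2L) {
  ann <- annotate_outcomes(profiles, library, mh_min = mh_min)
  agg <- profiles |>
    dplyr::inner_join(ann[c("target", "outcome", "category")],
                      by = c("target", "outcome")) |>
    dplyr::group_by(.data$target, .data$line, .data$category) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop")
  full <- tidyr::expand_grid(
    dplyr::distinct(agg[c("target", "line")]),
    category = .CATEGORIES
  )
  dplyr::left_join(full, agg, by = c("target", "line", "category")) |>
    dplyr::mutate(freq = dplyr::coalesce(.data$freq, 0)) |>
    dplyr::arrange(.data$target, .data$line, match(.data$category, .CATEGORIES))
}

#' Log2 fold changes of outcome or category frequencies versus control
#'
#' For every (target, unit, knockout line), `lfc = log2((f_ko + pc) /
#' (f_ctrl + pc))` with pseudocount `pc` in frequency units. Units absent
#' from both profiles give lfc 0 and are flagged (`both_absent`).
#'
#' @inheritParams annotate_outcomes
#' @param control control line label.
#' @param pc pseudocount in frequency units (default 0.001, i.e. 0.1%).
#' @param unit `"outcome"` (default) or `"category"`.
#' @return tibble `target`, `unit`, `line`, `f_ko`, `f_ctrl`, `lfc`,
#'   `both_absent`.
#' @export
lfc_table <- function(profiles, library = NULL, control = "control", pc = 0.001,
                      unit = c("outcome", "category"), mh_min = 2L) {
  unit <- match.arg(unit)
  stopifnot(pc > 0)
  if (!control %in% profiles$line) stop("control line not found: ", control)
  if (unit == "category") {
    if (is.null(library)) stop("library required for category-level fold changes")
    freqs <- aggregate_categories(profiles, library, mh_min = mh_min)
    freqs$unit <- freqs$category
  } else {
    freqs <- tibble::as_tibble(profiles)[, c("target", "line", "outcome", "freq")]
    freqs$unit <- freqs$outcome
  }
  wide <- freqs[c("target", "line", "unit", "freq")] |>
    tidyr::pivot_wider(names_from = "line", values_from = "freq", values_fill = 0)
  ko_lines <- setdiff(unique(profiles$line), control)
  out <- lapply(ko_lines, function(ln) {
    tibble::tibble(
      target = wide$target, unit = wide$unit, line = ln,
      f_ko = wide[[ln]], f_ctrl = wide[[control]],
      lfc = log2((wide[[ln]] + pc) / (wide[[control]] + pc)),
      both_absent = wide[[ln]] == 0 & wide[[control]] == 0
    )
  })
  dplyr::bind_rows(out)
}

#' Mean fold change across targets
#'
#' Per-target fold changes averaged over all targets, per (line, unit).
#'
#' @param lfc a [lfc_table()] result.
#' @return tibble `line`, `unit`, `mean_lfc`, `n_targets`.
#' @export
mean_lfc <- function(lfc) {
  lfc |>
    dplyr::group_by(.data$line, .data$unit) |>
    dplyr::summarise(mean_lfc = mean(.data$lfc),
                     n_targets = dplyr::n(), .groups = "drop")
}

#' Percentile bootstrap CI for the pooled PAM-proximal insertion share
#'
#' The share is `sum(prox) / sum(prox + dist)` over targets; resampling is
#' over targets (not reads), with percentile (2.5/97.5 for `conf = 0.95`)
#' limits. A single target gives a degenerate interval at the point
#' estimate.
#'
#' @param prox,dist per-target frequencies of PAM-proximal and PAM-distal
#'   matching 1 bp insertions.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `estimate`, `lo`, `hi`, `n_targets`.
#' @export
bootstrap_share_ci <- function(prox, dist, n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(length(prox) == length(dist), length(prox) >= 1L)
  n <- length(prox)
  est <- sum(prox) / sum(prox + dist)
  stat <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colSums(matrix(prox[idx], nrow = n)) /
      colSums(matrix((prox + dist)[idx], nrow = n))
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(stat, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lo = qs[1], hi = qs[2], n_targets = n)
}

## percentile bootstrap CI for a mean over targets
.bootstrap_mean_ci <- function(x, n_boot = 1000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  stat <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(x[idx], nrow = n))
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(stat, c(a, 1 - a), names = FALSE)
  list(estimate = mean(x), lo = qs[1], hi = qs[2])
}

#' Single-basepair insertion summaries by cut-flanking nucleotides
#'
#' For one cell line: (i) the mean absolute frequency of pure 1 bp
#' insertions per flanking dinucleotide pair; (ii) the relative PAM-proximal
#' share `prox / (prox + dist)` pooled over targets with *differing* flanks
#' (identical-flank targets, where the match is ambiguous, are excluded);
#' (iii) percentile bootstrap confidence intervals over targets.
#'
#' @inheritParams annotate_outcomes
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `by_pair` (tibble `distal`, `proximal`, `n_targets`,
#'   `mean_ins1`, `lo`, `hi`), `share` (list as [bootstrap_share_ci()]) and
#'   `per_target` (the underlying per-target frequencies).
#' @export
insertion_flank_summary <- function(profiles, library, n_boot = 1000L,
                                    seed = 1L, conf = 0.95, mh_min = 2L) {
  if (length(unique(profiles$line)) != 1L) {
    stop("insertion_flank_summary expects profiles from a single cell line")
  }
  ann <- annotate_outcomes(profiles, library, mh_min = mh_min)
  joined <- dplyr::inner_join(tibble::as_tibble(profiles), ann,
                              by = c("target", "outcome"))
  per_target <- joined |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      ins1 = sum(.data$freq[.data$ins_size == 1L & .data$del_size == 0L]),
      prox = sum(.data$freq[.data$ins_size == 1L & .data$del_size == 0L &
                              .data$category == "INS_PROX"]),
      dist = sum(.data$freq[.data$ins_size == 1L & .data$del_size == 0L &
                              .data$category == "INS_DIST"]),
      .groups = "drop"
    )
  per_target$distal <- vapply(library[per_target$target], pam_distal_flank, "")
  per_target$proximal <- vapply(library[per_target$target], pam_proximal_flank, "")

  pairs <- split(per_target, paste(per_target$distal, per_target$proximal))
  by_pair <- dplyr::bind_rows(lapply(pairs, function(d) {
    ci <- .bootstrap_mean_ci(d$ins1, n_boot = n_boot, seed = seed, conf = conf)
    tibble::tibble(distal = d$distal[1], proximal = d$proximal[1],
                   n_targets = nrow(d), mean_ins1 = ci$estimate,
                   lo = ci$lo, hi = ci$hi)
  }))
  absent <- 16L - nrow(by_pair)
  if (absent > 0L) {
    warning(sprintf("%d flanking pair(s) with no qualifying targets omitted", absent))
  }

  diff_fl <- per_target[per_target$distal != per_target$proximal, ]
  share <- if (nrow(diff_fl)) {
    bootstrap_share_ci(diff_fl$prox, diff_fl$dist, n_boot = n_boot,
                       seed = seed, conf = conf)
  } else {
    warning("no targets with differing flanking nucleotides; share omitted")
    NULL
  }
  list(by_pair = by_pair, share = share, per_target = per_target)
}
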