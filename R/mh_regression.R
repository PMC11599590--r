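## Exponential law linking deletion frequency to microhomology size and
## inter-copy distance: y_s = A * exp(B * d), fit per microhomology size s
## and cell line.

#' Collect microhomology deletion observations from profiles
#'
#' One observation per (microhomology deletion candidate, target, line):
#' `s = mh_len`, `d = del_size - mh_len` (bases strictly between the two
#' repeat copies; the start-to-start definition, which differs by a constant
#' per s, is available via `distance_def = "start"`), `y` = outcome
#' frequency. Candidates absent from a profile contribute `y = 0` (with
#' `include_zero = FALSE`, only observed outcomes are kept); restricting to
#' observed outcomes truncates the sampling noise at low frequencies and
#' biases the fitted amplitude upward. Deletions whose repeat copies overlap
#' (`mh_len > del_size`) are excluded. Observations with `s > 15` are
#' retained but flagged `in_fit_range = FALSE` and excluded from fitting by
#' default.
#'
#' @inheritParams annotate_outcomes
#' @param include_zero include zero-frequency candidate observations.
#' @param distance_def `"gap"` (default, `del_size - mh_len`) or `"start"`
#'   (`del_size`).
#' @return tibble `line`, `target`, `outcome`, `s`, `d`, `y`,
#'   `in_fit_range`.
#' @export
collect_mh_observations <- function(profiles, library, mh_min = 2L,
                                    include_zero = TRUE,
                                    distance_def = c("gap", "start")) {
  distance_def <- match.arg(distance_def)
  lines <- unique(profiles$line)
  rows <- lapply(names(library), function(tid) {
    cs <- enumerate_candidates(library[[tid]], mh_min = mh_min)
    mh <- tibble::as_tibble(cs)[cs$del_size > 0L & !is.na(cs$mh_len) &
                                  cs$mh_len >= mh_min & cs$d >= 0L, ]
    if (!nrow(mh)) return(NULL)
    dplyr::bind_rows(lapply(lines, function(ln) {
      tibble::tibble(line = ln, target = tid, outcome = mh$outcome,
                     s = mh$mh_len, d = mh$d, del_size = mh$del_size)
    }))
  })
  obs <- dplyr::bind_rows(rows)
  obs <- dplyr::left_join(
    obs,
    tibble::as_tibble(profiles)[, c("target", "line", "outcome", "freq")],
    by = c("target", "line", "outcome")
  )
  obs$y <- ifelse(is.na(obs$freq), 0, obs$freq)
  obs$freq <- NULL
  ## only targets actually profiled in that line contribute observations
  seen <- dplyr::distinct(tibble::as_tibble(profiles)[, c("target", "line")])
  obs <- dplyr::semi_join(obs, seen, by = c("target", "line"))
  if (!include_zero) obs <- obs[obs$y > 0, ]
  if (distance_def == "start") obs$d <- obs$del_size
  obs$del_size <- NULL
  obs$in_fit_range <- obs$s <= 15L
  obs
}

#' Fit the exponential microhomology law for one (s, line) stratum
#'
#' Nonlinear least squares of `y = A * exp(B * d)` on raw per-outcome
#' points, initialized at `A0 = max(y)`, `B0 = -0.1`. Underdetermined input
#' (fewer than 3 observations or fewer than 2 distinct distances) returns an
#' explicit no-fit row rather than NaNs.
#'
#' @param obs tibble with columns `d` and `y` (one (s, line) stratum).
#' @return one-row tibble `A`, `B`, `n_obs`, `converged`.
#' @export
fit_mh_exponential <- function(obs) {
  n <- nrow(obs)
  if (n < 3L || length(unique(obs$d)) < 2L) {
    return(tibble::tibble(A = NA_real_, B = NA_real_, n_obs = n, converged = FALSE))
  }
  a0 <- max(obs$y)
  if (a0 <= 0) a0 <- 1e-6
  do_fit <- function(a, b) {
    try(
      minpack.lm::nlsLM(
        y ~ A * exp(B * d), data = obs,
        start = list(A = a, B = b),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      silent = TRUE
    )
  }
  fit <- do_fit(a0, -0.1)
  if (inherits(fit, "try-error")) {
    ## nudge the start off the data maximum (degenerate initial Jacobian on
    ## flat response surfaces)
    fit <- do_fit(0.9 * a0, -0.05)
  }
  if (inherits(fit, "try-error")) {
    return(tibble::tibble(A = NA_real_, B = NA_real_, n_obs = n, converged = FALSE))
  }
  cf <- stats::coef(fit)
  tibble::tibble(A = unname(cf["A"]), B = unname(cf["B"]), n_obs = n,
                 converged = fit$convInfo$isConv %||% TRUE)
}

#' Fit the microhomology law over the s = 2..15 grid for every cell line
#'
#' @inheritParams collect_mh_observations
#' @param s_range microhomology sizes to fit (default 2:15).
#' @return tidy tibble `line`, `s`, `A`, `B`, `n_obs`, `converged` (no-fit
#'   strata carry `converged = FALSE` and NA coefficients).
#' @export
fit_mh_all <- function(profiles, library, s_range = 2:15, mh_min = 2L,
                       include_zero = TRUE, distance_def = c("gap", "start")) {
  obs <- collect_mh_observations(profiles, library, mh_min = mh_min,
                                 include_zero = include_zero,
                                 distance_def = distance_def)
  grid <- expand.grid(line = unique(profiles$line), s = s_range,
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    sub <- obs[obs$line == grid$line[i] & obs$s == grid$s[i] & obs$in_fit_range, ]
    cbind(tibble::tibble(line = grid$line[i], s = grid$s[i]),
          fit_mh_exponential(sub))
  }))
}
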