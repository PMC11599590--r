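## Synthetic screen generator: target libraries and per-cell-line read-count
## datasets with planted, recoverable structure.
##
## The generator plants its parameters in frequency units so that every
## planted quantity is exactly recoverable from the ground-truth
## distribution: microhomology deletion candidates get frequency
## A_s * exp(B_s * d) (s = microhomology size, d = bases between the two
## repeat copies), flank-matched 1 bp cut-site insertions get the configured
## total split by the proximal share, and the non-microhomology deletion
## baseline absorbs the residual mass with a geometric size decay. Category
## multipliers plant exact frequency fold changes: a category with
## multiplier k has its mass multiplied by exactly k, with categories at
## multiplier 1 absorbing the residual proportionally, so the planted log2
## fold change of category c is log2(k_c).

#' Default exponential microhomology law
#'
#' Frequency of a deletion using an s bp microhomology at inter-copy
#' distance d is `A_s * exp(B_s * d)`. Defaults make longer microhomologies
#' both more frequent at distance zero and slower-decaying with distance, as
#' observed for microhomology-mediated end joining.
#'
#' @return tibble with columns `s` (2..15), `A` (frequency units, > 0) and
#'   `B` (per bp, < 0).
#' @export
default_mh_law <- function() {
  s <- 2:15
  tibble::tibble(s = s, A = 0.06 * 1.2^(s - 2), B = -0.25 + 0.01 * (s - 2))
}

#' Default 1 bp insertion bias by cut-flanking nucleotides
#'
#' Targets with a PAM-distal T or A are roughly three times as
#' insertion-prone as those with a PAM-distal G or C (totals 0.29 vs 0.097),
#' and the PAM-proximal share of matched insertions is biased toward
#' matching a flanking T and away from a flanking G.
#'
#' @return tibble with columns `distal`, `proximal` (the flanking bases),
#'   `total` (frequency of flank-matched 1 bp insertions) and `prox_share`
#'   (share of that mass matching the proximal flank; `NA` when the flanks
#'   are identical and the split is undefined).
#' @export
default_insertion_bias <- function() {
  bases <- c("A", "C", "G", "T")
  score <- c(A = 1.5, C = 1.5, G = 1 / 3, T = 4)
  grid <- expand.grid(distal = bases, proximal = bases,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    distal = grid$distal,
    proximal = grid$proximal,
    total = ifelse(grid$distal %in% c("T", "A"), 0.29, 0.097),
    prox_share = ifelse(
      grid$distal == grid$proximal, NA_real_,
      0.63 * score[grid$proximal] / (score[grid$proximal] + score[grid$distal])
    )
  )
}

#' Generative parameters for one synthetic cell line
#'
#' @param line cell-line label; the control line must keep every category
#'   multiplier at 1.
#' @param category_multipliers named positive factors over
#'   [outcome_categories()]; the planted log2 fold change of category c
#'   versus control is `log2(multiplier_c)`. Missing names default to 1.
#' @param mh_law tibble as [default_mh_law()].
#' @param insertion_bias tibble as [default_insertion_bias()].
#' @param read_depth expected mutated reads per target, replicate and
#'   timepoint (Poisson; see `fixed_depth` in [sample_dataset()]).
#' @param n_replicates,n_timepoints replicate structure (>= 2 replicates).
#' @param nonmh_decay geometric decay ratio of the non-microhomology
#'   deletion baseline with deletion size.
#' @param other_ins_frac fraction of the residual mass given to insertions
#'   that are not flank-matched 1 bp cut-site insertions.
#' @return a `generative_params` object.
#' @export
generative_params <- function(line = "control",
                              category_multipliers = NULL,
                              mh_law = default_mh_law(),
                              insertion_bias = default_insertion_bias(),
                              read_depth = 2000,
                              n_replicates = 2L,
                              n_timepoints = 1L,
                              nonmh_decay = 0.85,
                              other_ins_frac = 0.05) {
  mult <- stats::setNames(rep(1, length(.CATEGORIES)), .CATEGORIES)
  if (!is.null(category_multipliers)) {
    bad <- setdiff(names(category_multipliers), .CATEGORIES)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    if (any(category_multipliers < 0)) stop("category multipliers must be >= 0")
    mult[names(category_multipliers)] <- category_multipliers
  }
  stopifnot(
    all(mh_law$A > 0), all(mh_law$B < 0), all(2:15 %in% mh_law$s),
    n_replicates >= 1L, n_timepoints >= 1L, read_depth > 0,
    nonmh_decay > 0, nonmh_decay <= 1, other_ins_frac >= 0, other_ins_frac < 1,
    all(is.na(insertion_bias$prox_share) |
          (insertion_bias$prox_share >= 0 & insertion_bias$prox_share <= 1)),
    all(insertion_bias$total >= 0)
  )
  structure(
    list(
      line = line, category_multipliers = mult, mh_law = mh_law,
      insertion_bias = insertion_bias, read_depth = read_depth,
      n_replicates = as.integer(n_replicates),
      n_timepoints = as.integer(n_timepoints),
      nonmh_decay = nonmh_decay, other_ins_frac = other_ins_frac
    ),
    class = "generative_params"
  )
}

#' Knockout parameter presets
#'
#' Documentation presets with category multipliers transcribed from the
#' direction and rough magnitude of the screen's knockout responses: NHEJ
#' cores (Lig4, Xlf, Xrcc5) deplete small indels and gain large deletions,
#' Nbn suppresses resection-dependent medium/long deletions and gains
#' 1 bp indels, Polq specifically depletes medium microhomology deletions,
#' Prkdc and Polm deplete PAM-proximal insertions.
#'
#' @param read_depth,n_replicates passed to [generative_params()].
#' @return named list of `generative_params`, including a control.
#' @export
line_presets <- function(read_depth = 2000, n_replicates = 2L) {
  mk <- function(line, ...) {
    m <- c(...)
    generative_params(line = line, category_multipliers = m,
                      read_depth = read_depth, n_replicates = n_replicates)
  }
  list(
    control = mk("control"),
    Nbn = mk("Nbn", DEL_MED_MH = 0.3, DEL_MED_NOMH = 0.35, DEL_LONG_MH = 0.25,
             DEL_LONG_NOMH = 0.4, DEL_1 = 2.2, INS_DIST = 1.8, INS_PROX = 1.6),
    Polq = mk("Polq", DEL_MED_MH = 0.33, DEL_LONG_NOMH = 1.8, INS_DIST = 1.2),
    Lig4 = mk("Lig4", INS_DIST = 0.02, INS_PROX = 0.1, DEL_1 = 0.4,
              DEL_LONG_MH = 1.5, DEL_LONG_NOMH = 2),
    Xlf = mk("Xlf", INS_DIST = 0.3, INS_PROX = 0.4, DEL_1 = 0.45,
             DEL_LONG_MH = 1.3, DEL_LONG_NOMH = 1.6),
    Xrcc5 = mk("Xrcc5", INS_DIST = 0.12, INS_PROX = 0.05, DEL_1 = 0.5,
               DEL_LONG_MH = 1.6, DEL_LONG_NOMH = 2),
    Prkdc = mk("Prkdc", INS_PROX = 0.2, INS_DIST = 0.85),
    Polm = mk("Polm", INS_PROX = 0.35, INS_DIST = 0.85)
  )
}

#' Generate a synthetic NGG target library
#'
#' Random target sequences in protospacer-5'-to-3' orientation with an NGG
#' PAM, cut-flanking dinucleotides cycled over the 16 possible pairs so the
#' library is approximately balanced, and at least 30 bases of context on
#' each side of the cut. Deterministic given the seed.
#'
#' @param n_targets number of targets (>= 1).
#' @param seed integer seed.
#' @param length sequence length (>= 79).
#' @return named list of [target_site()]s (class `target_library`).
#' @export
make_library <- function(n_targets, seed = 1L, length = 80L) {
  stopifnot(n_targets >= 1L, length >= 79L)
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(distal = bases, proximal = bases,
                       stringsAsFactors = FALSE)
  protospacer_start <- 23L
  pam_start <- protospacer_start + 20L
  cut <- pam_start - 3L
  lib <- with_seed(seed, {
    lapply(seq_len(n_targets), function(i) {
      chars <- sample(bases, length, replace = TRUE)
      pr <- pairs[((i - 1L) %% 16L) + 1L, ]
      chars[cut] <- pr$distal        # sequence[cut - 1], 0-based
      chars[cut + 1L] <- pr$proximal # sequence[cut]
      chars[pam_start + 2L] <- "G"
      chars[pam_start + 3L] <- "G"
      target_site(sprintf("T%04d", i), paste(chars, collapse = ""),
                  protospacer_start, pam_start)
    })
  })
  names(lib) <- vapply(lib, function(t) t$id, "")
  class(lib) <- "target_library"
  lib
}

## candidate weights for one line on a precomputed candidate_set; returns the
## exact outcome distribution (sums to 1)
.line_distribution <- function(cs, target, params, mh_min = 2L) {
  n <- nrow(cs)
  w <- numeric(n)

  law <- params$mh_law[order(params$mh_law$s), ]
  A <- stats::setNames(law$A, law$s)
  B <- stats::setNames(law$B, law$s)
  mh_rows <- cs$del_size > 0L & !is.na(cs$mh_len) & cs$mh_len >= mh_min &
    !is.na(cs$d) & cs$d >= 0L
  if (any(mh_rows)) {
    s_eff <- as.character(pmin(cs$mh_len[mh_rows], 15L))
    w[mh_rows] <- A[s_eff] * exp(B[s_eff] * cs$d[mh_rows])
  }

  dfl <- pam_distal_flank(target)
  pfl <- pam_proximal_flank(target)
  bias <- params$insertion_bias
  b <- bias[bias$distal == dfl & bias$proximal == pfl, ]
  ins1 <- cs$ins_size == 1L & cs$del_size == 0L & !is.na(cs$flank_match)
  if (nrow(b) == 1L && b$total > 0) {
    if (dfl == pfl) {
      w[ins1 & cs$flank_match == "BOTH"] <- b$total
    } else {
      w[ins1 & cs$flank_match == "DISTAL_ONLY"] <- b$total * (1 - b$prox_share)
      w[ins1 & cs$flank_match == "PROXIMAL_ONLY"] <- b$total * b$prox_share
    }
  }

  fixed_mass <- sum(w)
  if (fixed_mass >= 0.95) {
    stop(sprintf("planted microhomology/insertion mass %.3f leaves no room for the baseline (degenerate parameters)", fixed_mass))
  }
  resid <- 1 - fixed_mass
  other_ins <- w == 0 & cs$ins_size > 0L
  base_del <- w == 0 & cs$del_size > 0L
  fr_ins <- if (any(other_ins)) params$other_ins_frac else 0
  if (!any(base_del) && !any(other_ins)) stop("no baseline candidates (degenerate target)")
  if (!any(base_del)) fr_ins <- 1
  if (any(other_ins)) w[other_ins] <- resid * fr_ins / sum(other_ins)
  if (any(base_del)) {
    ## total baseline mass of size-L deletions decays geometrically in L,
    ## split evenly among that size's outcomes
    sz <- cs$del_size[base_del]
    n_per_size <- table(sz)
    g <- params$nonmh_decay^(sz - 1L) / as.vector(n_per_size[as.character(sz)])
    w[base_del] <- resid * (1 - fr_ins) * g / sum(g)
  }
  if (all(w == 0)) stop("all-zero weight vector (degenerate parameters)")

  ## exact category-fold-change planting
  mult <- params$category_multipliers[cs$category]
  if (any(mult != 1)) {
    mass <- tapply(w, cs$category, sum)
    k <- params$category_multipliers[names(mass)]
    planted <- k != 1
    new_planted <- sum(k[planted] * mass[planted])
    unit_mass <- sum(mass[!planted])
    if (new_planted >= 1) {
      stop("planted category masses exceed 1 (infeasible multipliers for this target)")
    }
    if (unit_mass <= 0) {
      stop("no multiplier-1 category mass available to absorb the planted residual")
    }
    scale <- stats::setNames(ifelse(planted, k, (1 - new_planted) / unit_mass),
                             names(mass))
    w <- w * scale[cs$category]
  }
  w / sum(w)
}

#' Exact outcome distribution planted for one target and line
#'
#' @param target a [target_site()].
#' @param params a [generative_params()].
#' @param mh_min microhomology threshold.
#' @return tibble with `outcome`, `category` and probability `p` (sums to
#'   1); support is the candidate set of the target.
#' @export
ground_truth_distribution <- function(target, params, mh_min = 2L) {
  cs <- enumerate_candidates(target, mh_min = mh_min)
  p <- .line_distribution(cs, target, params, mh_min = mh_min)
  out <- tibble::tibble(outcome = cs$outcome, category = cs$category, p = p)
  attr(out, "target_id") <- target$id
  attr(out, "line") <- params$line
  out
}

#' Sample a synthetic read-count dataset
#'
#' For every (target, line, replicate, timepoint) a multinomial read vector
#' is drawn from the line's exact planted distribution, at depth
#' `Poisson(read_depth)` (or exactly `read_depth` with `fixed_depth =
#' TRUE`). Deterministic given the seed.
#'
#' @param library a [make_library()] result (or list of `target_site`s).
#' @param params_per_line list of [generative_params()], one per cell line;
#'   at least one line must be a control (all multipliers 1).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes `targets.fasta`,
#'   `targets.tsv`, `counts.tsv` and `truth.json`.
#' @param fixed_depth use exactly `read_depth` reads per sample.
#' @param mh_min microhomology threshold.
#' @return list with `counts` (tibble `target`, `line`, `replicate`,
#'   `timepoint`, `outcome`, `count`), `truth` (tibble `line`, `target`,
#'   `outcome`, `category`, `p`), `library`, `seed` and `params`.
#' @export
sample_dataset <- function(library, params_per_line, seed = 1L, out_dir = NULL,
                           fixed_depth = FALSE, mh_min = 2L) {
  if (inherits(params_per_line, "generative_params")) {
    params_per_line <- list(params_per_line)
  }
  names(params_per_line) <- vapply(params_per_line, function(p) p$line, "")
  is_control <- vapply(params_per_line, function(p) all(p$category_multipliers == 1), TRUE)
  if (!any(is_control)) stop("params_per_line must include a control line (all multipliers 1)")

  cand <- lapply(library, enumerate_candidates, mh_min = mh_min)
  truth <- list()
  counts <- list()
  with_seed(seed, {
    for (ln in names(params_per_line)) {
      pp <- params_per_line[[ln]]
      for (tid in names(library)) {
        p <- .line_distribution(cand[[tid]], library[[tid]], pp, mh_min = mh_min)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          line = ln, target = tid, outcome = cand[[tid]]$outcome,
          category = cand[[tid]]$category, p = p
        )
        for (rep_i in seq_len(pp$n_replicates)) {
          for (tp in seq_len(pp$n_timepoints)) {
            depth <- if (fixed_depth) pp$read_depth else stats::rpois(1L, pp$read_depth)
            if (depth == 0L) next
            cnt <- as.vector(stats::rmultinom(1L, depth, p))
            nz <- cnt > 0L
            counts[[length(counts) + 1L]] <- tibble::tibble(
              target = tid, line = ln,
              replicate = sprintf("R%d", rep_i), timepoint = sprintf("T%d", tp),
              outcome = cand[[tid]]$outcome[nz], count = cnt[nz]
            )
          }
        }
      }
    }
  })
  out <- list(
    counts = dplyr::bind_rows(counts),
    truth = dplyr::bind_rows(truth),
    library = library,
    seed = as.integer(seed),
    params = params_per_line
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_target_library(library, file.path(out_dir, "targets.fasta"),
                         file.path(out_dir, "targets.tsv"))
    header <- "# repairscape counts; outcome grammar D:<start>-<end> / I:<gap>:<seq>, 0-based on the stored target sequence"
    cfile <- file.path(out_dir, "counts.tsv")
    writeLines(c(header, paste(names(out$counts), collapse = "\t")), cfile)
    readr::write_tsv(out$counts, cfile, append = TRUE, col_names = FALSE)
    truth_json <- lapply(split(out$truth, out$truth$line), function(d) {
      lapply(split(d, d$target), function(x) as.list(stats::setNames(x$p, x$outcome)))
    })
    jsonlite::write_json(
      list(seed = out$seed, truth = truth_json),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' Read a counts table written by [sample_dataset()]
#'
#' @param path counts.tsv path.
#' @return tibble of per-sample outcome read counts.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    target = "c", line = "c", replicate = "c",
                    timepoint = "c", outcome = "c", count = "i"
                  ))
}
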