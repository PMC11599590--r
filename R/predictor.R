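## Per-cell-line predictive model of outcome profiles: binary featurization
## of candidate outcomes and a shared-weight conditional softmax trained by
## minimizing KL divergence between measured and predicted profiles.

.DEL_SIZE_BINS <- c("1", "2", "3_4", "5_6", "7_9", "10_15", "16_30")
.MH_BINS <- c("0", "1", "2", "3", "4_6", "7p")
.OFF_BINS <- c("0", "1", "2", "3", "4_7", "8_15", "16p")

.bin_del_size <- function(L) {
  cut(L, c(0, 1, 2, 4, 6, 9, 15, 30), labels = .DEL_SIZE_BINS)
}
.bin_mh <- function(mh) {
  cut(mh, c(-1, 0, 1, 2, 3, 6, Inf), labels = .MH_BINS)
}
.bin_off <- function(x) {
  cut(abs(x), c(-1, 0, 1, 2, 3, 7, 15, Inf), labels = .OFF_BINS)
}

#' The binary feature registry
#'
#' A named, versioned list of the binary features computed for every
#' candidate outcome, covering deletion length (exact sizes and bins),
#' deletion boundary offsets from the cut, microhomology-length bins,
#' junction and cut-context nucleotides, inserted-sequence identity and gap
#' offset, frame, and pairwise combinations of selected families
#' (insertion identity x PAM-distal flank, deletion-size bin x
#' microhomology bin, left x right boundary offset bins, insertion length x
#' PAM-proximal flank). The registry (name vector + version) is fingerprinted;
#' models refuse to predict against a different registry.
#'
#' @return character vector of feature names with attributes `version` and
#'   `hash`.
#' @export
feature_registry <- function() {
  bases <- c("A", "C", "G", "T")
  ins_ids <- c(bases, as.vector(outer(bases, bases, paste0)))
  nm <- c(
    paste0("del_size_", 1:30),
    paste0("del_bin_", .DEL_SIZE_BINS),
    paste0("mh_bin_", .MH_BINS),
    paste0("left_off_", .OFF_BINS),
    paste0("right_off_", .OFF_BINS),
    paste0("junc_left_", bases),
    paste0("junc_right_", bases),
    paste0("ins_len_", 1:2),
    paste0("ins_seq_", ins_ids),
    paste0("ins_gap_", -3:3),
    c("is_del", "is_ins", "in_frame"),
    paste0("ctx_", rep(c("m2", "m1", "p1", "p2"), each = 4), "_", bases),
    paste0("ins_seq_", rep(ins_ids, each = 4), ".x.dist_", bases),
    paste0("del_bin_", rep(.DEL_SIZE_BINS, each = length(.MH_BINS)),
           ".x.mh_", .MH_BINS),
    paste0("left_", rep(.OFF_BINS, each = length(.OFF_BINS)), ".x.right_", .OFF_BINS),
    paste0("ins_len_", rep(1:2, each = 4), ".x.prox_", bases)
  )
  stopifnot(!anyDuplicated(nm))
  structure(nm, version = "repairscape-features/1",
            hash = .object_md5(list("repairscape-features/1", nm)))
}

#' Binary feature matrix for a candidate set
#'
#' Deterministic 0/1 encoding of every candidate over [feature_registry()];
#' every row has at least one active feature and identical outcomes in
#' identical local context get identical rows.
#'
#' @param cands an [enumerate_candidates()] result.
#' @param target the matching [target_site()].
#' @param registry a [feature_registry()] (defaults to the current one).
#' @return sparse `dgCMatrix`, candidates x features.
#' @export
featurize <- function(cands, target, registry = feature_registry()) {
  n <- nrow(cands)
  col <- stats::setNames(seq_along(registry), registry)
  cut <- target$cut
  chars <- target$chars
  is_del <- cands$del_size > 0L
  is_ins <- cands$ins_size > 0L
  if (any(is_del & is_ins)) stop("unknown outcome shape: mixed candidates are not enumerable")

  ii <- integer(0); jj <- character(0)
  add <- function(rows, names) {
    ok <- !is.na(names)
    ii <<- c(ii, rows[ok]); jj <<- c(jj, names[ok])
  }
  rows <- seq_len(n)

  dl <- which(is_del)
  if (length(dl)) {
    L <- cands$del_size[dl]
    mh <- cands$mh_len[dl]
    left_off <- cands$del_start[dl] - cut
    right_off <- cands$del_end[dl] - cut
    db <- as.character(.bin_del_size(L))
    mb <- as.character(.bin_mh(mh))
    lb <- as.character(.bin_off(left_off))
    rb <- as.character(.bin_off(right_off))
    add(dl, paste0("del_size_", pmin(L, 30L)))
    add(dl, paste0("del_bin_", db))
    add(dl, paste0("mh_bin_", mb))
    add(dl, paste0("left_off_", lb))
    add(dl, paste0("right_off_", rb))
    jl <- ifelse(cands$del_start[dl] > 0L, chars[cands$del_start[dl]], NA)
    jr <- ifelse(cands$del_end[dl] < length(chars), chars[cands$del_end[dl] + 1L], NA)
    add(dl, ifelse(is.na(jl), NA, paste0("junc_left_", jl)))
    add(dl, ifelse(is.na(jr), NA, paste0("junc_right_", jr)))
    add(dl, paste0("del_bin_", db, ".x.mh_", mb))
    add(dl, paste0("left_", lb, ".x.right_", rb))
    add(dl, rep("is_del", length(dl)))
  }
  il <- which(is_ins)
  if (length(il)) {
    m <- cands$ins_size[il]
    sq <- cands$ins_seq[il]
    ## gap offset of the equivalent representation closest to the cut
    gap <- pmin(pmax(cut, cands$gap_min[il]), cands$gap_max[il])
    add(il, paste0("ins_len_", m))
    add(il, paste0("ins_seq_", sq))
    off <- pmin(pmax(gap - cut, -3L), 3L)
    add(il, paste0("ins_gap_", off))
    dfl <- chars[cut]
    pfl <- chars[cut + 1L]
    add(il, paste0("ins_seq_", sq, ".x.dist_", dfl))
    add(il, paste0("ins_len_", m, ".x.prox_", pfl))
    add(il, rep("is_ins", length(il)))
  }
  ctx <- c(m2 = chars[cut - 1L], m1 = chars[cut], p1 = chars[cut + 1L],
           p2 = chars[cut + 2L])
  for (p in names(ctx)) add(rows, rep(paste0("ctx_", p, "_", ctx[[p]]), n))
  add(rows[cands$in_frame], rep("in_frame", sum(cands$in_frame)))

  bad <- setdiff(unique(jj), registry)
  if (length(bad)) stop("features outside the registry: ", paste(head(bad), collapse = ", "))
  x <- Matrix::sparseMatrix(i = ii, j = unname(col[jj]), x = 1,
                            dims = c(n, length(registry)),
                            dimnames = list(cands$outcome, registry))
  stopifnot(all(Matrix::rowSums(x) >= 1))
  x
}

#' Kullback-Leibler divergence between outcome distributions
#'
#' `sum(p * log(p / q))` in nats, after optional pseudocount smoothing and
#' renormalization of both arguments; zero iff `p == q`. The symmetrized
#' divergence `(D(p||q) + D(q||p)) / 2` is available via
#' `symmetric = TRUE`.
#'
#' @param p,q non-negative vectors over the same support.
#' @param pseudo pseudocount added to every component before
#'   renormalization (default 0).
#' @param symmetric return the symmetrized divergence.
#' @return non-negative number (possibly `Inf` without smoothing).
#' @export
kl_divergence <- function(p, q, pseudo = 0, symmetric = FALSE) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p + pseudo
  q <- q + pseudo
  if (sum(p) <= 0 || sum(q) <= 0) stop("zero-mass support after smoothing")
  p <- p / sum(p)
  q <- q / sum(q)
  d <- function(a, b) {
    i <- a > 0
    if (any(b[i] == 0)) return(Inf)
    sum(a[i] * log(a[i] / b[i]))
  }
  if (symmetric) (d(p, q) + d(q, p)) / 2 else d(p, q)
}

## Assemble the stacked training design: X (sparse), smoothed measured
## frequencies p, contiguous group index, and the excluded measured mass.
.predictor_design <- function(library, profiles, registry, pseudo_reads = 0.5,
                              mh_min = 2L) {
  prof <- tibble::as_tibble(profiles)
  tids <- intersect(names(library), unique(prof$target))
  if (!length(tids)) stop("no profiled targets found in the library")
  Xs <- list(); ps <- list(); groups <- list(); excluded <- list()
  for (k in seq_along(tids)) {
    tid <- tids[k]
    cs <- enumerate_candidates(library[[tid]], mh_min = mh_min)
    x <- featurize(cs, library[[tid]], registry)
    pr <- prof[prof$target == tid, ]
    cnt <- stats::setNames(rep(0, nrow(cs)), cs$outcome)
    hit <- pr$outcome %in% cs$outcome
    cnt[pr$outcome[hit]] <- pr$count[hit]
    excluded[[k]] <- tibble::tibble(
      target = tid,
      excluded_mass = sum(pr$count[!hit]) / max(1, sum(pr$count)),
      n_excluded = sum(!hit)
    )
    sm <- cnt + pseudo_reads
    Xs[[k]] <- x
    ps[[k]] <- sm / sum(sm)
    groups[[k]] <- rep(k, nrow(cs))
  }
  list(
    X = do.call(rbind, Xs),
    p = unlist(ps, use.names = FALSE),
    group = unlist(groups),
    targets = tids,
    idx = split(seq_along(unlist(groups)), unlist(groups)),
    excluded = dplyr::bind_rows(excluded)
  )
}

## loss and gradient of sum_t KL(p_t || softmax(X_t theta)) + lambda |theta|^2
.softmax_by_group <- function(score, idx) {
  q <- numeric(length(score))
  for (ix in idx) {
    e <- exp(score[ix] - max(score[ix]))
    q[ix] <- e / sum(e)
  }
  q
}

#' Train the conditional-softmax outcome predictor
#'
#' Minimizes `sum_t KL(measured_t || softmax(X_t theta)) + lambda *
#' |theta|^2` over the shared weight vector theta, where `measured_t` is the
#' target's pooled outcome counts on its candidate set with `pseudo_reads`
#' (0.5 by default) added to every candidate and renormalized. Measured
#' outcomes outside the enumeration limits are dropped from both numerator
#' and denominator, with the excluded mass logged per target. Optimization
#' is L-BFGS with the analytic gradient, run in restarts whose losses form
#' the (non-increasing) `loss_trace`; convergence is declared when the
#' relative loss change per restart falls below `rel_tol`.
#'
#' @param library named list of [target_site()]s (the training targets).
#' @param profiles pooled profiles of one cell line for those targets.
#' @param lambda L2 strength (default 0.01).
#' @param seed integer seed (recorded; initialization is at zero and the
#'   optimizer is deterministic).
#' @param pseudo_reads per-candidate read pseudocount (default 0.5).
#' @param maxit total L-BFGS iteration budget (default 500).
#' @param rel_tol relative-loss convergence tolerance (default 1e-6).
#' @param allow_partial return a non-converged model instead of erroring.
#' @param mh_min microhomology threshold for enumeration.
#' @return an `outcome_predictor`: list with `theta` (named), `registry_hash`,
#'   `lambda`, `seed`, `line`, `train_targets`, `loss_trace`, `converged`,
#'   `excluded` and `pseudo_reads`.
#' @export
train_predictor <- function(library, profiles, lambda = 0.01, seed = 1L,
                            pseudo_reads = 0.5, maxit = 500L, rel_tol = 1e-6,
                            allow_partial = FALSE, mh_min = 2L) {
  line <- unique(profiles$line)
  if (length(line) != 1L) stop("train_predictor expects profiles from a single cell line")
  registry <- feature_registry()
  dsn <- .predictor_design(library, profiles, registry, pseudo_reads, mh_min)
  X <- dsn$X; p <- dsn$p; idx <- dsn$idx
  const <- sum(ifelse(p > 0, p * log(p), 0))

  loss_fn <- function(theta) {
    score <- as.numeric(X %*% theta)
    ll <- 0
    for (ix in idx) {
      mx <- max(score[ix])
      lz <- mx + log(sum(exp(score[ix] - mx)))
      ll <- ll + sum(p[ix] * (score[ix] - lz))
    }
    const - ll + lambda * sum(theta^2)
  }
  grad_fn <- function(theta) {
    score <- as.numeric(X %*% theta)
    q <- .softmax_by_group(score, idx)
    as.numeric(Matrix::crossprod(X, q - p)) + 2 * lambda * theta
  }

  theta <- numeric(ncol(X))
  trace <- loss_fn(theta)
  converged <- FALSE
  chunk <- 100L
  used <- 0L
  while (used < maxit) {
    it <- min(chunk, maxit - used)
    opt <- stats::optim(theta, loss_fn, grad_fn, method = "L-BFGS-B",
                        control = list(maxit = it, factr = 10))
    theta <- opt$par
    used <- used + it
    prev <- trace[length(trace)]
    trace <- c(trace, opt$value)
    if (opt$value > prev + 1e-9) stop("training loss increased across restarts")
    if (abs(prev - opt$value) <= rel_tol * max(1e-12, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !allow_partial) {
    stop(sprintf("optimizer did not converge within %d iterations (relative tolerance %g); rerun with a larger maxit or allow_partial = TRUE", maxit, rel_tol))
  }
  structure(
    list(theta = stats::setNames(theta, registry), registry = registry,
         registry_hash = attr(registry, "hash"), lambda = lambda,
         seed = as.integer(seed), line = line, train_targets = dsn$targets,
         loss_trace = trace, converged = converged, excluded = dsn$excluded,
         pseudo_reads = pseudo_reads, mh_min = mh_min),
    class = "outcome_predictor"
  )
}

#' @export
print.outcome_predictor <- function(x, ...) {
  cat(sprintf(
    "<outcome_predictor> line %s: %d features, %d training targets, final loss %.4f (%s)\n",
    x$line, length(x$theta), length(x$train_targets),
    tail(x$loss_trace, 1), if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Predict the outcome profile of a target
#'
#' Softmax over the target's candidate set of the trained linear scores;
#' probabilities sum to 1.
#'
#' @param model an [train_predictor()] result.
#' @param target a [target_site()].
#' @return tibble `outcome`, `category`, `p`.
#' @export
predict_profile <- function(model, target) {
  registry <- feature_registry()
  if (!identical(attr(registry, "hash"), model$registry_hash)) {
    stop("feature registry hash mismatch: model was trained against a different registry")
  }
  cs <- enumerate_candidates(target, mh_min = model$mh_min)
  x <- featurize(cs, target, registry)
  score <- as.numeric(x %*% model$theta)
  e <- exp(score - max(score))
  tibble::tibble(outcome = cs$outcome, category = cs$category, p = e / sum(e))
}

#' Split target ids into training and held-out sets
#'
#' @param ids target identifiers.
#' @param test_frac held-out fraction (default 0.1).
#' @param seed integer seed.
#' @return list with `train` and `test` (disjoint; `test` non-empty).
#' @export
split_targets <- function(ids, test_frac = 0.1, seed = 1L) {
  n <- length(ids)
  n_test <- max(1L, round(test_frac * n))
  test <- with_seed(seed, sample(ids, n_test))
  list(train = setdiff(ids, test), test = test)
}

#' Evaluate a predictor on held-out profiles
#'
#' Per-target KL divergence between the smoothed measured profile and the
#' prediction (forward `D(measured || predicted)` and symmetrized), optional
#' replicate-versus-replicate KL when a second set of profiles is given, and
#' pooled Pearson correlations at three granularities: individual outcome
#' frequencies, ten-category aggregates, and the per-target in-frame
#' fraction.
#'
#' @param model an [train_predictor()] result.
#' @param library named list of [target_site()]s covering the test targets.
#' @param profiles held-out pooled profiles (one line).
#' @param replicate_profiles optional second measurement of the same
#'   targets (e.g. one replicate vs the other) for the reproducibility
#'   baseline.
#' @return list with `per_target` (tibble `target`, `kl`, `kl_sym`,
#'   `rep_kl`) and `pearson` (tibble `granularity`, `r`, `n`); the in-frame
#'   correlation is `NA` with fewer than 2 targets.
#' @export
evaluate_predictor <- function(model, library, profiles,
                               replicate_profiles = NULL) {
  prof <- tibble::as_tibble(profiles)
  tids <- intersect(names(library), unique(prof$target))
  if (!length(tids)) stop("empty test set")

  meas_tab <- list(); pred_tab <- list()
  per_target <- list()
  for (tid in tids) {
    target <- library[[tid]]
    cs <- enumerate_candidates(target, mh_min = model$mh_min)
    pred <- predict_profile(model, target)
    pr <- prof[prof$target == tid, ]
    cnt <- stats::setNames(rep(0, nrow(cs)), cs$outcome)
    hit <- pr$outcome %in% cs$outcome
    cnt[pr$outcome[hit]] <- pr$count[hit]
    meas_raw <- cnt / max(1, sum(cnt))
    sm <- cnt + model$pseudo_reads
    meas <- sm / sum(sm)
    kl <- kl_divergence(meas, pred$p)
    kls <- kl_divergence(meas, pred$p, symmetric = TRUE)
    rep_kl <- NA_real_
    if (!is.null(replicate_profiles)) {
      rp <- tibble::as_tibble(replicate_profiles)
      rp <- rp[rp$target == tid, ]
      if (nrow(rp)) {
        cnt2 <- stats::setNames(rep(0, nrow(cs)), cs$outcome)
        hit2 <- rp$outcome %in% cs$outcome
        cnt2[rp$outcome[hit2]] <- rp$count[hit2]
        sm2 <- cnt2 + model$pseudo_reads
        rep_kl <- kl_divergence(meas, sm2 / sum(sm2))
      }
    }
    per_target[[tid]] <- tibble::tibble(target = tid, kl = kl, kl_sym = kls,
                                        rep_kl = rep_kl)
    meas_tab[[tid]] <- tibble::tibble(
      target = tid, outcome = cs$outcome, category = cs$category,
      in_frame = cs$in_frame, measured = meas_raw, predicted = pred$p
    )
  }
  tab <- dplyr::bind_rows(meas_tab)
  cats <- tab |>
    dplyr::group_by(.data$target, .data$category) |>
    dplyr::summarise(measured = sum(.data$measured),
                     predicted = sum(.data$predicted), .groups = "drop")
  inf <- tab |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(measured = sum(.data$measured[.data$in_frame]),
                     predicted = sum(.data$predicted[.data$in_frame]),
                     .groups = "drop")
  pearson <- tibble::tibble(
    granularity = c("outcome", "category", "in_frame"),
    r = c(stats::cor(tab$measured, tab$predicted),
          stats::cor(cats$measured, cats$predicted),
          if (nrow(inf) >= 2L) stats::cor(inf$measured, inf$predicted) else NA_real_),
    n = c(nrow(tab), nrow(cats), nrow(inf))
  )
  list(per_target = dplyr::bind_rows(per_target), pearson = pearson)
}
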