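# Featurization, the KL/softmax training objective and profile prediction.

# exact profiles (counts at depth 1e6) generated from a linear model on the
# registry; used for recovery checks
theta_star_profiles <- function(lib, theta_star, line = "control") {
  reg <- feature_registry()
  dplyr::bind_rows(lapply(names(lib), function(tid) {
    cs <- enumerate_candidates(lib[[tid]])
    x <- featurize(cs, lib[[tid]], reg)
    sc <- as.numeric(x %*% theta_star)
    p <- exp(sc - max(sc)); p <- p / sum(p)
    tibble::tibble(target = tid, line = line, outcome = cs$outcome,
                   count = round(p * 1e6), total = 1e6, freq = p)
  }))
}

random_theta <- function(seed, sd = 0.5, density = 0.3) {
  reg <- feature_registry()
  set.seed(seed)
  stats::setNames(rnorm(length(reg), 0, sd) * rbinom(length(reg), 1, density), reg)
}

test_that("feature rows are binary, non-empty and context-sensitive", {
  lib <- make_library(2, seed = 91)
  reg <- feature_registry()
  for (t in lib) {
    cs <- enumerate_candidates(t)
    x <- featurize(cs, t, reg)
    expect_true(all(x@x == 1))
    expect_true(all(Matrix::rowSums(x) >= 1))
    expect_equal(nrow(x), nrow(cs))
  }
  # two 1 bp deletions differing only in flanking base differ in >= 1 feature
  t <- make_flank_target("A", "G", seed = 91)  # distinct flanks: two DEL_1s
  cs <- enumerate_candidates(t)
  d1 <- which(cs$del_size == 1)
  expect_gte(length(d1), 2L)
  x <- featurize(cs, t, reg)
  expect_gt(sum(abs(x[d1[1], ] - x[d1[2], ])), 0)
})

test_that("identical outcomes in identical local context share feature rows", {
  # two targets equal within +/- 35 of the cut but different elsewhere
  base <- make_library(1, seed = 92)[[1]]
  chars2 <- base$chars
  chars2[1:4] <- c("T", "T", "T", "T")
  t2 <- target_site("shifted", paste(chars2, collapse = ""),
                    base$protospacer_start, base$pam_start)
  reg <- feature_registry()
  c1 <- enumerate_candidates(base); c2 <- enumerate_candidates(t2)
  shared <- intersect(c1$outcome, c2$outcome)
  x1 <- featurize(c1, base, reg); x2 <- featurize(c2, t2, reg)
  expect_gt(length(shared), 100)
  expect_equal(as.matrix(x1[shared, ]), as.matrix(x2[shared, ]))
})

test_that("registry changes are detected at predict time", {
  lib <- make_library(3, seed = 93)
  prof <- theta_star_profiles(lib, random_theta(1))
  m <- train_predictor(lib, prof, lambda = 0.01, maxit = 200)
  m$registry_hash <- "tampered"
  expect_error(predict_profile(m, lib[[1]]), "registry hash mismatch")
})

test_that("KL divergence follows the closed forms and Gibbs' inequality", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(kl_divergence(c(1, 0), c(0, 1)), Inf)
  set.seed(94)
  for (i in 1:200) {
    p <- runif(8); q <- runif(8)
    expect_gte(kl_divergence(p, q), 0)
    expect_gte(kl_divergence(p, q, symmetric = TRUE), 0)
  }
  expect_lt(kl_divergence(c(1, 0), c(0.5, 0.5), pseudo = 0.5), log(2))
  expect_error(kl_divergence(c(0, 0), c(0, 0)), "zero-mass")
})

test_that("zero weights give the uniform profile and scores shift-invariantly", {
  lib <- make_library(2, seed = 95)
  prof <- theta_star_profiles(lib, random_theta(2))
  m <- train_predictor(lib, prof, lambda = 0.01, maxit = 150)
  m0 <- m
  m0$theta[] <- 0
  p0 <- predict_profile(m0, lib[[1]])
  expect_equal(p0$p, rep(1 / nrow(p0), nrow(p0)))
  expect_equal(sum(p0$p), 1, tolerance = 1e-12)
  # adding a constant to every candidate's score leaves predictions fixed:
  # the cut-context features are active for every candidate of a target
  ms <- m
  t1 <- lib[[1]]
  active_ctx <- paste0("ctx_", c("m2", "m1", "p1", "p2"), "_",
                       t1$chars[c(t1$cut - 1, t1$cut, t1$cut + 1, t1$cut + 2)])
  ms$theta[active_ctx] <- ms$theta[active_ctx] + 2.5
  expect_equal(predict_profile(ms, t1)$p, predict_profile(m, t1)$p,
               tolerance = 1e-9)
})

test_that("raising one candidate's score raises only its probability", {
  sc <- c(0.5, -0.2, 1.1, 0)
  soft <- function(s) { e <- exp(s - max(s)); e / sum(e) }
  p1 <- soft(sc)
  sc2 <- sc; sc2[2] <- sc2[2] + 0.7
  p2 <- soft(sc2)
  expect_gt(p2[2], p1[2])
  expect_true(all(p2[-2] < p1[-2]))
})

test_that("training recovers generator distributions and the loss is monotone", {
  lib <- make_library(12, seed = 96)
  theta_star <- random_theta(3)
  prof <- theta_star_profiles(lib, theta_star)
  sp <- split_targets(names(lib), test_frac = 0.25, seed = 1)
  m <- train_predictor(lib[sp$train], prof[prof$target %in% sp$train, ],
                       lambda = 1e-3, maxit = 400)
  expect_true(m$converged)
  expect_true(all(diff(m$loss_trace) <= 1e-9))
  kls <- vapply(sp$test, function(tid) {
    pr <- predict_profile(m, lib[[tid]])
    tp <- prof[prof$target == tid, ]
    kl_divergence(tp$freq[match(pr$outcome, tp$outcome)], pr$p)
  }, 0)
  expect_lt(mean(kls), 0.01)
})

test_that("extreme regularization collapses to the uniform profile", {
  lib <- make_library(2, seed = 97)
  prof <- theta_star_profiles(lib, random_theta(4))
  m <- train_predictor(lib, prof, lambda = 1e7, maxit = 100)
  p <- predict_profile(m, lib[[1]])
  expect_equal(p$p, rep(1 / nrow(p), nrow(p)), tolerance = 1e-4)
})

test_that("a single dominant outcome is predicted as lambda vanishes", {
  lib <- make_library(1, seed = 98)
  tid <- names(lib)
  cs <- enumerate_candidates(lib[[1]])
  prof <- tibble::tibble(target = tid, line = "control",
                         outcome = cs$outcome[1], count = 10^6L,
                         total = 10^6L, freq = 1)
  m <- train_predictor(lib, prof, lambda = 1e-8, maxit = 500)
  p <- predict_profile(m, lib[[1]])
  expect_gt(p$p[p$outcome == cs$outcome[1]], 0.95)
})

test_that("measured outcomes outside the enumeration window are logged", {
  lib <- make_library(1, seed = 99)
  tid <- names(lib)
  cs <- enumerate_candidates(lib[[1]])
  cut <- lib[[1]]$cut
  off <- sprintf("D:%d-%d", cut + 31, cut + 35)  # outside the window
  prof <- tibble::tibble(
    target = tid, line = "control",
    outcome = c(cs$outcome[1:5], off),
    count = c(100L, 80L, 60L, 40L, 20L, 50L), total = 350L,
    freq = c(100, 80, 60, 40, 20, 50) / 350
  )
  m <- train_predictor(lib, prof, lambda = 0.01, maxit = 200)
  expect_equal(m$excluded$excluded_mass, 50 / 350, tolerance = 1e-12)
  expect_equal(m$excluded$n_excluded, 1L)
})

test_that("evaluation reports sane granularities and replicate baselines", {
  lib <- make_library(10, seed = 100)
  pp <- list(control = generative_params(read_depth = 5000, n_replicates = 2L))
  sim <- sample_dataset(lib, pp, seed = 101)
  prof <- filter_and_pool(sim$counts)
  sp <- split_targets(names(lib), test_frac = 0.3, seed = 2)
  m <- train_predictor(lib[sp$train], prof[prof$target %in% sp$train, ],
                       lambda = 0.01, maxit = 300)
  # replicate profiles: pool each replicate separately
  r1 <- filter_and_pool(sim$counts[sim$counts$replicate == "R1", ], min_reads = 50)
  r2 <- filter_and_pool(sim$counts[sim$counts$replicate == "R2", ], min_reads = 50)
  ev <- evaluate_predictor(m, lib[sp$test],
                           r1[r1$target %in% sp$test, ],
                           replicate_profiles = r2[r2$target %in% sp$test, ])
  expect_true(all(ev$per_target$kl >= 0))
  expect_true(all(is.finite(ev$per_target$rep_kl)))
  expect_equal(ev$pearson$granularity, c("outcome", "category", "in_frame"))
  expect_true(all(abs(ev$pearson$r) <= 1, na.rm = TRUE))
  # predicted category masses sum to one per target
  for (tid in sp$test) {
    p <- predict_profile(m, lib[[tid]])
    expect_equal(sum(p$p), 1, tolerance = 1e-9)
    expect_equal(sum(tapply(p$p, p$category, sum)), 1, tolerance = 1e-9)
  }
  # in-frame correlation needs at least two targets
  ev1 <- evaluate_predictor(m, lib[sp$test[1]], r1[r1$target == sp$test[1], ])
  expect_true(is.na(ev1$pearson$r[ev1$pearson$granularity == "in_frame"]))
  expect_error(evaluate_predictor(m, lib["nope"], prof[0, ]), "empty test set")
})
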