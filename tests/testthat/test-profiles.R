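# Count filtering/pooling, category aggregation, fold changes and the 1 bp
# insertion summaries.

toy_counts <- function() {
  tibble::tibble(
    target = c(rep("A", 4), rep("B", 4), rep("C", 4)),
    line = "control",
    replicate = rep(c("R1", "R1", "R2", "R2"), 3),
    timepoint = "T1",
    outcome = rep(c("D:39-40", "I:40:T"), 6),
    count = c(80, 70, 90, 60,   # A: fine
              60, 39, 60, 50,   # B: R1 total 99 -> dropped
              200, 100, 150, 80)
  )
}

test_that("targets below the read floor in any sample are dropped everywhere", {
  expect_message(prof <- filter_and_pool(toy_counts(), min_reads = 100),
                 "dropped 1 target")
  expect_setequal(unique(prof$target), c("A", "C"))
  a <- prof[prof$target == "A", ]
  expect_equal(sum(a$count), 300)
  expect_equal(sum(a$freq), 1, tolerance = 1e-9)
})

test_that("single-read outcomes are removed and replicates pooled", {
  cnt <- tibble::tibble(
    target = "A", line = "control",
    replicate = c("R1", "R2", "R1"), timepoint = "T1",
    outcome = c("D:39-40", "D:39-40", "I:40:G"),
    count = c(103, 104, 1)
  )
  prof <- filter_and_pool(cnt, min_reads = 100)
  expect_false("I:40:G" %in% prof$outcome)
  expect_equal(prof$count[prof$outcome == "D:39-40"], 207)
  # a replicate pair (3, 4) pools to 7
  cnt2 <- tibble::tibble(
    target = "A", line = "control",
    replicate = c("R1", "R1", "R2", "R2"), timepoint = "T1",
    outcome = c("D:39-40", "I:40:G", "D:39-40", "I:40:G"),
    count = c(100, 3, 100, 4)
  )
  prof2 <- filter_and_pool(cnt2, min_reads = 100)
  expect_equal(prof2$count[prof2$outcome == "I:40:G"], 7)
})

test_that("a target missing from one line's samples is excluded everywhere", {
  cnt <- dplyr::bind_rows(
    toy_counts(),
    tibble::tibble(target = "A", line = "ko", replicate = c("R1", "R2"),
                   timepoint = "T1", outcome = "D:39-40", count = c(150, 150))
  )
  expect_message(prof <- filter_and_pool(cnt, min_reads = 100), "dropped")
  # B and C have no 'ko' samples at all, A has both lines
  expect_setequal(unique(prof$target), "A")
})

test_that("filter-then-pool matches an independent reference on random tables", {
  set.seed(61)
  for (rep in 1:5) {
    cnt <- expand.grid(
      target = c("t1", "t2", "t3"), line = c("control", "k1"),
      replicate = c("R1", "R2"), timepoint = "T1",
      outcome = c("D:39-40", "D:38-40", "I:40:A"),
      stringsAsFactors = FALSE
    )
    cnt$count <- rpois(nrow(cnt), 40)
    suppressMessages(prof <- filter_and_pool(cnt, min_reads = 100))
    # reference: explicit split/apply
    tot <- aggregate(count ~ target + line + replicate + timepoint, cnt, sum)
    bad <- unique(tot$target[tot$count < 100])
    osum <- aggregate(count ~ target + outcome, cnt, sum)
    single <- osum[osum$count == 1, c("target", "outcome")]
    ref <- cnt[!(cnt$target %in% bad), ]
    ref <- ref[!paste(ref$target, ref$outcome) %in% paste(single$target, single$outcome), ]
    ref <- aggregate(count ~ target + line + outcome, ref, sum)
    got <- as.data.frame(prof[c("target", "line", "outcome", "count")])
    got <- got[order(got$target, got$line, got$outcome), ]
    ref <- ref[order(ref$target, ref$line, ref$outcome), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(ref)))
  }
})

test_that("frequencies are invariant under uniform count scaling", {
  cnt <- toy_counts()
  suppressMessages(p1 <- filter_and_pool(cnt, min_reads = 10))
  cnt$count <- cnt$count * 5L
  suppressMessages(p2 <- filter_and_pool(cnt, min_reads = 10))
  m <- merge(p1, p2, by = c("target", "line", "outcome"))
  expect_equal(m$freq.x, m$freq.y)
})

test_that("category aggregation conserves frequency mass", {
  lib <- make_library(4, seed = 62)
  sim <- sample_dataset(lib, list(control = generative_params(read_depth = 800)),
                        seed = 63)
  prof <- filter_and_pool(sim$counts)
  cats <- aggregate_categories(prof, lib)
  sums <- tapply(cats$freq, paste(cats$target, cats$line), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a profile holding a single in-frame deletion is a unit vector
  one <- tibble::tibble(target = lib[[1]]$id, line = "control",
                        outcome = "D:37-40", count = 500L, total = 500L, freq = 1)
  v <- aggregate_categories(one, lib)
  expect_equal(sum(v$freq), 1)
  expect_equal(sum(v$freq == 1), 1L)
})

test_that("fold changes follow the closed form and are antisymmetric", {
  lib <- make_library(1, seed = 64)
  tid <- names(lib)
  prof <- tibble::tibble(
    target = tid, line = c("control", "ko"),
    outcome = "D:39-40", count = c(10L, 20L), total = c(100L, 100L),
    freq = c(0.10, 0.20)
  )
  lt <- lfc_table(prof, control = "control", pc = 0.001)
  expect_equal(lt$lfc, log2(0.201 / 0.101), tolerance = 1e-12)
  expect_equal(lt$lfc, 0.993, tolerance = 1e-3)
  # equal frequencies give exactly zero
  prof0 <- prof; prof0$freq <- 0.1; prof0$count <- 10L
  expect_equal(lfc_table(prof0, control = "control")$lfc, 0)
  # antisymmetry under swapping roles
  rev <- prof; rev$line <- rev(prof$line)
  expect_equal(lfc_table(prof, control = "control")$lfc,
               -lfc_table(rev, control = "control")$lfc)
  # unit absent from both profiles: flagged zero
  prof2 <- dplyr::bind_rows(
    prof,
    tibble::tibble(target = "x", line = c("control", "ko"), outcome = "D:39-40",
                   count = 0L, total = 100L, freq = 0)
  )
  lt2 <- lfc_table(prof2, control = "control")
  expect_equal(lt2$lfc[lt2$target == "x"], 0)
  expect_true(lt2$both_absent[lt2$target == "x"])
})

test_that("insertion summaries pool shares over differing-flank targets only", {
  bias <- default_insertion_bias()
  bias$prox_share[!is.na(bias$prox_share)] <- 0.3
  lib <- make_library(16, seed = 65)
  pp <- list(control = generative_params(insertion_bias = bias, read_depth = 2e4))
  sim <- sample_dataset(lib, pp, seed = 66)
  prof <- filter_and_pool(sim$counts)
  res <- insertion_flank_summary(prof, lib, n_boot = 200, seed = 2)
  # identical-flank targets are excluded from the share
  expect_equal(res$share$n_targets, sum(res$per_target$distal != res$per_target$proximal))
  expect_equal(res$share$estimate, 0.3, tolerance = 0.05)
  expect_true(res$share$lo <= res$share$estimate &&
                res$share$estimate <= res$share$hi)
  # absolute 1 bp insertion frequency reflects the planted flank bias
  ta <- res$per_target$distal %in% c("T", "A")
  expect_gt(mean(res$per_target$ins1[ta]), mean(res$per_target$ins1[!ta]))
})

test_that("bootstrap intervals are deterministic and degenerate for one target", {
  ci1 <- bootstrap_share_ci(c(0.02, 0.03), c(0.1, 0.12), n_boot = 500, seed = 9)
  ci2 <- bootstrap_share_ci(c(0.02, 0.03), c(0.1, 0.12), n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  one <- bootstrap_share_ci(0.02, 0.1, n_boot = 100, seed = 1)
  expect_equal(one$lo, one$estimate)
  expect_equal(one$hi, one$estimate)
})
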