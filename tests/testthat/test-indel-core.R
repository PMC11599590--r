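# The canonical outcome algebra: representation, deduplication,
# microhomology, classification, templating, directionality, frame.

mk7 <- function() {
  t <- target_site("t7", "TAGCAGC", 0, 0, check = FALSE)
  t$cut <- 4L
  t
}

test_that("canonicalize left-aligns repeats and is idempotent", {
  t <- mk7()
  o <- canonicalize(t, 4, 7, "")
  expect_equal(o$del_start, 1L)
  expect_equal(o$del_end, 4L)
  expect_equal(apply_outcome(t, o), "TAGC")
  o2 <- canonicalize(t, o$del_start, o$del_end, o$ins_seq)
  expect_equal(o2[c("del_start", "del_end", "ins_seq", "mh_len")],
               o[c("del_start", "del_end", "ins_seq", "mh_len")])

  t2 <- target_site("t4", "ACGT", 0, 0, check = FALSE)
  t2$cut <- 2L
  u <- canonicalize(t2, 1, 2, "")
  expect_equal(c(u$del_start, u$del_end), c(1L, 2L))
  expect_equal(u$mh_len, 0L)

  expect_error(canonicalize(t, 2, 2, ""), "wild-type")
  expect_error(canonicalize(t, 3, 9, ""), "invalid deletion")
  expect_error(canonicalize(t, 2, 2, "X"), "A/C/G/T")
})

test_that("pure insertions are anchored at the left-most equivalent gap", {
  t <- make_flank_target("T", "G", seed = 11)
  # inserting the PAM-distal base at the cut shifts left of the T run
  o <- canonicalize(t, t$cut, t$cut, "T")
  expect_lte(o$del_start, t$cut)
  expect_true(t$cut >= o$gap_min && t$cut <= o$gap_max)
  # every equivalent gap produces the same edited sequence
  edited0 <- apply_outcome(t, o)
  expect_equal(edited0, paste0(substr(t$sequence, 1, t$cut), "T",
                               substr(t$sequence, t$cut + 1, 80)))
})

test_that("apply_outcome edits by interval removal and insertion", {
  t <- mk7()
  expect_equal(apply_outcome(t, canonicalize(t, 1, 4, "")), "TAGC")
  o_ins <- canonicalize(t, 4, 4, "T")
  expect_equal(nchar(apply_outcome(t, o_ins)), 8L)
  o_del2 <- canonicalize(t, 3, 5, "")
  expect_equal(nchar(apply_outcome(t, o_del2)), 5L)
})

test_that("microhomology equals equivalence-class size minus one", {
  t <- mk7()
  expect_equal(microhomology_length(t, canonicalize(t, 1, 4, "")), 3L)
  t6 <- target_site("hp6", "AAAAAA", 0, 0, check = FALSE)
  t6$cut <- 3L
  expect_equal(microhomology_length(t6, canonicalize(t6, 2, 4, "")), 4L)
  t2 <- target_site("t4", "ACGT", 0, 0, check = FALSE)
  t2$cut <- 2L
  expect_equal(microhomology_length(t2, canonicalize(t2, 1, 2, "")), 0L)
  expect_error(microhomology_length(t, canonicalize(t, 2, 2, "T")),
               "pure deletions")
})

test_that("canonicalization and microhomology agree with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:50) {
    seq <- random_seq(40)
    t <- target_site("r", seq, 0, 23, check = FALSE)
    for (L in 1:6) {
      for (g in bf_deletion_groups(seq, L)) {
        edited <- NULL
        for (s in g$starts) {
          o <- canonicalize(t, s, s + L, "")
          expect_equal(o$del_start, g$canonical)
          expect_equal(o$mh_len, g$size - 1L)
          e <- apply_outcome(t, o)
          if (is.null(edited)) edited <- e else expect_identical(e, edited)
        }
      }
    }
  }
})

test_that("classification covers the ten categories per the size/MH rules", {
  t <- make_flank_target("T", "G", seed = 3)
  cut <- t$cut
  expect_equal(classify_outcome(t, canonicalize(t, cut - 1, cut)), "DEL_1")
  expect_equal(classify_outcome(t, canonicalize(t, cut - 1, cut + 1)), "DEL_2")

  # plant a 2 bp microhomology around a 5 bp deletion: GTxxxGT
  chars <- strsplit(strrep("ACGG", 20), "")[[1]]
  chars[38:39] <- c("G", "T"); chars[40:42] <- c("A", "C", "A")
  chars[43:44] <- c("G", "T"); chars[45:46] <- c("G", "G")
  tm <- target_site("mh2", paste(chars, collapse = ""), 23, check = FALSE)
  o5 <- canonicalize(tm, 37, 42, "")
  expect_gte(o5$mh_len, 2L)
  expect_equal(o5$del_size, 5L)
  expect_equal(classify_outcome(tm, o5), "DEL_MED_MH")
  expect_equal(classify_outcome(tm, o5, mh_min = 5L), "DEL_MED_NOMH")

  # flanks T|G: inserting T matches the PAM-distal template only
  expect_equal(classify_outcome(t, canonicalize(t, cut, cut, "T")), "INS_DIST")
  expect_equal(classify_outcome(t, canonicalize(t, cut, cut, "G")), "INS_PROX")
  tb <- make_flank_target("T", "T", seed = 4)
  expect_equal(classify_outcome(tb, canonicalize(tb, tb$cut, tb$cut, "T")), "INS_DIST")
  expect_equal(classify_outcome(tb, canonicalize(tb, tb$cut, tb$cut, "T"),
                                both_as = "proximal"), "INS_PROX")
  # neither-matching and >2 bp insertions fall into the OTHER classes
  tc <- make_flank_target("T", "G", seed = 5)
  expect_match(classify_outcome(tc, canonicalize(tc, tc$cut, tc$cut, "C")), "^OTHER_I")
  expect_match(classify_outcome(tc, canonicalize(tc, tc$cut, tc$cut, "ACA")), "^OTHER_I")
  # an insertion copying the 2 bases 5' of the deletion locus carries MH
  ins_mh <- paste0(substr(tc$sequence, tc$cut - 1, tc$cut), "A")
  expect_equal(classify_outcome(tc, canonicalize(tc, tc$cut, tc$cut, ins_mh)),
               "OTHER_I_MH")
})

test_that("classification is total over enumerated candidates", {
  lib <- make_library(4, seed = 9)
  for (t in lib) {
    cs <- enumerate_candidates(t)
    expect_tenfold_partition(cs$category)
    expect_equal(as.vector(table(factor(cs$category, outcome_categories()))) |> sum(),
                 nrow(cs))
  }
})

test_that("insertion templates match the flanks read from the cut outward", {
  t <- make_flank_target("T", "G", seed = 6)
  cut <- t$cut
  expect_equal(insertion_flank_match(t, canonicalize(t, cut, cut, "T")), "DISTAL_ONLY")
  expect_equal(insertion_flank_match(t, canonicalize(t, cut, cut, "G")), "PROXIMAL_ONLY")
  expect_equal(insertion_flank_match(t, canonicalize(t, cut, cut, "C")), "NEITHER")
  tb <- make_flank_target("T", "T", seed = 7)
  expect_equal(insertion_flank_match(tb, canonicalize(tb, tb$cut, tb$cut, "T")), "BOTH")
  # two-base templates read contiguously; a 1-of-2 match is NEITHER
  distal2 <- substr(t$sequence, cut - 1, cut)
  proximal2 <- substr(t$sequence, cut + 1, cut + 2)
  if (distal2 != proximal2) {
    expect_equal(insertion_flank_match(t, canonicalize(t, cut, cut, distal2)),
                 "DISTAL_ONLY")
    half <- paste0(substr(distal2, 1, 1),
                   setdiff(c("A", "C", "G", "T"),
                           c(substr(distal2, 2, 2), substr(proximal2, 2, 2)))[1])
    expect_equal(insertion_flank_match(t, canonicalize(t, cut, cut, half)), "NEITHER")
  }
  expect_error(insertion_flank_match(t, canonicalize(t, cut - 1, cut, "")),
               "pure insertion")
  expect_error(insertion_flank_match(t, canonicalize(t, cut + 3, cut + 3, "C")),
               "not at the cut")
})

test_that("directionality is max share of deleted bases on one side of the cut", {
  t <- make_crosshalf_target()  # unique representations across the cut
  cut <- t$cut
  expect_equal(directionality(t, canonicalize(t, cut, cut + 1)), 1)
  expect_equal(directionality(t, canonicalize(t, cut - 4, cut + 4)), 0.5)
  expect_equal(directionality(t, canonicalize(t, cut - 3, cut + 1)), 0.75)
  expect_equal(directionality(t, canonicalize(t, cut - 3, cut + 1), method = "diff"), 0.5)
  # deletions confined to one side score 1 (odd span: alternation blocks shifts)
  o1 <- canonicalize(t, cut - 6, cut - 1)
  expect_equal(o1$mh_len, 0L)
  expect_equal(directionality(t, o1), 1)
  expect_error(directionality(t, canonicalize(t, cut, cut, "A")), "pure deletions")
})

test_that("directionality is stable under re-canonicalization", {
  set.seed(12)
  lib <- make_library(4, seed = 13)
  for (t in lib) {
    cs <- enumerate_candidates(t)
    dels <- cs[cs$del_size > 0 & cs$del_size <= 10, ]
    pick <- sample(nrow(dels), 20)
    for (i in pick) {
      o <- canonicalize(t, dels$del_start[i], dels$del_end[i], "")
      # re-enter from any equivalent representation
      r <- o$gap_max
      o2 <- canonicalize(t, r, r + o$del_size, "")
      expect_equal(directionality(t, o2), directionality(t, o))
    }
  }
})

test_that("frame is the net length change modulo 3", {
  t <- make_flank_target("A", "C", seed = 10)
  cut <- t$cut
  expect_true(is_in_frame(canonicalize(t, cut - 2, cut + 1)))
  expect_false(is_in_frame(canonicalize(t, cut, cut, "A")))
  expect_true(is_in_frame(canonicalize(t, cut - 2, cut + 2, "C")))
})

test_that("outcome descriptors round-trip and normalize", {
  lib <- make_library(2, seed = 21)
  for (t in lib) {
    cs <- enumerate_candidates(t)
    set.seed(1)
    for (i in sample(nrow(cs), 40)) {
      o <- parse_outcome(t, cs$outcome[i])
      expect_identical(format_outcome(o), cs$outcome[i])
    }
  }
  t <- mk7()
  # non-canonical descriptor is normalized on read
  expect_identical(format_outcome(parse_outcome(t, "D:4-7")), "D:1-4")
  expect_error(parse_outcome(t, "D:x-y"), "malformed")
  expect_error(parse_outcome(t, "D:1-4+I:2:A"), "anchor")
})

test_that("outcomes away from the cut window are flagged", {
  t <- make_flank_target("A", "C", seed = 30)
  cut <- t$cut
  expect_true(canonicalize(t, cut - 1, cut)$in_window)
  expect_true(canonicalize(t, cut, cut, "C")$in_window)
  expect_false(canonicalize(t, cut - 20, cut - 15)$in_window)
  far_gap <- cut + 10
  o <- canonicalize(t, far_gap, far_gap, "C")
  if (o$gap_min > cut + 3) expect_false(o$in_window)
  # mixed outcome: deletion touching the cut keeps it in-window
  expect_true(canonicalize(t, cut - 1, cut + 1, "AA")$in_window)
})
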