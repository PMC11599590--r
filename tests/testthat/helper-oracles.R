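# Independent brute-force oracles, kept free of the package's canonical
# algebra: equivalence classes are formed by grouping raw edits on the
# identity of the edited string.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# all deletions of size L on seq, grouped by edited-string identity;
# returns per group: member starts (0-based), canonical (minimal) start,
# class size
bf_deletion_groups <- function(seq, L) {
  n <- nchar(seq)
  starts <- 0:(n - L)
  edited <- vapply(starts, function(s) {
    paste0(substr(seq, 1, s), substr(seq, s + L + 1, n))
  }, "")
  lapply(split(starts, edited), function(g) {
    list(starts = g, canonical = min(g), size = length(g))
  })
}

# brute-force candidate enumeration: all cut-intersecting deletions of size
# 1..max_del and insertions of 1..max_ins within ins_window of the cut,
# deduplicated by (edited sequence, del_size, ins_size)
bf_enumerate <- function(target, max_del = 30L, max_ins = 2L, ins_window = 3L) {
  seq <- target$sequence
  n <- nchar(seq)
  cut <- target$cut
  keys <- character(0)
  for (L in seq_len(max_del)) {
    for (s in max(0, cut - L):min(cut, n - L)) {
      edited <- paste0(substr(seq, 1, s), substr(seq, s + L + 1, n))
      keys <- c(keys, paste(edited, L, 0))
    }
  }
  bases <- c("A", "C", "G", "T")
  ins_all <- bases
  if (max_ins >= 2) ins_all <- c(ins_all, as.vector(outer(bases, bases, paste0)))
  for (g in (cut - ins_window):(cut + ins_window)) {
    for (sq in ins_all) {
      edited <- paste0(substr(seq, 1, g), sq, substr(seq, g + 1, n))
      keys <- c(keys, paste(edited, 0, nchar(sq)))
    }
  }
  unique(keys)
}

# target whose cut-spanning deletion candidates are all distinct: the left
# half uses {A,C}, the right half {G,T}, so every shift condition compares
# bases from different halves
make_repeat_free_target <- function(seed = 1) {
  set.seed(seed)
  left <- sample(c("A", "C"), 40, replace = TRUE)
  right <- sample(c("G", "T"), 40, replace = TRUE)
  right[5:6] <- "G"  # NGG PAM at pam_start + 1..2 (0-based 44, 45)
  target_site("repeatfree", paste(c(left, right), collapse = ""), 23,
              check = FALSE)
}

make_homopolymer_target <- function(base = "A", len = 80L) {
  target_site("homopolymer", strrep(base, len), 23, check = FALSE)
}

# a target with prescribed cut-flanking bases and otherwise repeat-poor
# context around the cut
make_flank_target <- function(distal, proximal, seed = 1) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
  chars[40] <- distal    # sequence[cut - 1], cut = 40
  chars[41] <- proximal  # sequence[cut]
  chars[45:46] <- "G"
  target_site(paste0("fl_", distal, proximal), paste(chars, collapse = ""), 23)
}

# cut-crossing deletions on this target have a unique representation: the
# two halves alternate over disjoint alphabets, so no shift condition that
# compares a base from each side can hold
make_crosshalf_target <- function() {
  chars <- c(rep(c("A", "C"), 20), rep(c("G", "T"), 20))
  chars[45:46] <- "G"
  target_site("crosshalf", paste(chars, collapse = ""), 23, check = FALSE)
}

expect_tenfold_partition <- function(labels) {
  expect_true(all(labels %in% outcome_categories()))
}
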