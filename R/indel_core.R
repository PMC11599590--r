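## Canonical algebra of Cas9 editing outcomes.
##
## Coordinates are 0-based and half-open throughout. A deletion [del_start,
## del_end) removes sequence positions del_start .. del_end-1; an insertion
## sits at the gap del_start (between positions del_start-1 and del_start).
## Two raw outcomes are equivalent when they have the same deletion and
## insertion size and produce byte-identical edited sequences; the canonical
## representative is the left-most equivalent one.

## One elementary left shift of (ds, de, ins) that preserves the edited
## sequence, or NULL when none exists. chars is the 0-based sequence as a
## character vector (S[p] == chars[p + 1]).
.shift_left1 <- function(chars, ds, de, ins) {
  if (ds <= 0L) return(NULL)
  m <- length(ins)
  if (m == 0L) {
    if (chars[ds] != chars[de]) return(NULL)
  } else {
    if (ins[m] != chars[de]) return(NULL)
    ins <- c(chars[ds], ins[-m])
  }
  list(ds = ds - 1L, de = de - 1L, ins = ins)
}

.shift_right1 <- function(chars, ds, de, ins) {
  n <- length(chars)
  if (de >= n) return(NULL)
  m <- length(ins)
  if (m == 0L) {
    if (chars[ds + 1L] != chars[de + 1L]) return(NULL)
  } else {
    if (ins[1L] != chars[ds + 1L]) return(NULL)
    ins <- c(ins[-1L], chars[de + 1L])
  }
  list(ds = ds + 1L, de = de + 1L, ins = ins)
}

#' Canonicalize a raw Cas9 editing outcome
#'
#' Reduces a (deletion interval, inserted sequence) pair to the unique
#' left-most representative of its equivalence class: all outcomes with the
#' same deletion/insertion sizes that produce a byte-identical edited
#' sequence. Canonicalization is idempotent. The size of the equivalence
#' class, minus one, is the microhomology length of a pure deletion.
#'
#' The left/right split of deleted bases around the cut (used by
#' [directionality()]) is computed on the representation whose interval
#' midpoint is closest to the cut (ties toward the left-most), so that
#' representation ambiguity does not inflate directionality.
#'
#' @param target a [target_site()].
#' @param del_start,del_end 0-based half-open deletion interval; equal values
#'   denote a pure insertion at that gap.
#' @param ins_seq inserted sequence (possibly empty).
#' @return an object of class `cas9_outcome` with fields `del_start`,
#'   `del_end`, `ins_seq`, `del_size`, `ins_size`, `net_change`, `mh_len`
#'   (pure deletions; `NA` otherwise), `left_del`, `right_del`, `gap_min`,
#'   `gap_max` (range of equivalent left anchors) and `in_window` (whether
#'   the outcome touches the cut region: some equivalent deletion interval
#'   intersects the two cut-adjacent bases, or some equivalent insertion gap
#'   lies within 3 of the cut).
#' @export
#' @examples
#' t <- target_site("t", strrep("ACGT", 20), 23, check = FALSE)
#' canonicalize(t, 41, 44, "")
canonicalize <- function(target, del_start, del_end, ins_seq = "") {
  chars <- target$chars
  n <- length(chars)
  ds <- as.integer(del_start)
  de <- as.integer(del_end)
  if (is.na(ds) || is.na(de) || ds < 0L || ds > de || de > n) {
    stop("invalid deletion interval")
  }
  ins <- if (nzchar(ins_seq)) strsplit(toupper(ins_seq), "", fixed = TRUE)[[1]] else character(0)
  .assert_nucleotides(ins, "ins_seq")
  L <- de - ds
  m <- length(ins)
  if (L == 0L && m == 0L) stop("wild-type is not an outcome")

  repeat {
    nxt <- .shift_left1(chars, ds, de, ins)
    if (is.null(nxt)) break
    ds <- nxt$ds; de <- nxt$de; ins <- nxt$ins
  }
  ## count equivalent representations to the right of the canonical one
  n_right <- 0L
  r_ds <- ds; r_de <- de; r_ins <- ins
  repeat {
    nxt <- .shift_right1(chars, r_ds, r_de, r_ins)
    if (is.null(nxt)) break
    r_ds <- nxt$ds; r_de <- nxt$de; r_ins <- nxt$ins
    n_right <- n_right + 1L
  }

  cut <- target$cut
  gap_min <- ds
  gap_max <- ds + n_right

  ## left/right split on the midpoint-closest-to-cut representation
  if (L > 0L) {
    starts <- gap_min:gap_max
    mid_dist <- abs(starts + L / 2 - cut)
    r <- starts[which.min(mid_dist)]
    left_del <- max(0L, min(r + L, cut) - r)
    right_del <- L - left_del
  } else {
    left_del <- right_del <- 0L
  }

  del_window <- L > 0L && gap_min <= cut && (gap_max + L - 1L) >= (cut - 1L)
  ins_window <- m > 0L &&
    (cut >= gap_min && cut <= gap_max ||
       min(abs(gap_min - cut), abs(gap_max - cut)) <= 3L)

  structure(
    list(
      target_id = target$id,
      del_start = ds,
      del_end = de,
      ins_seq = paste(ins, collapse = ""),
      del_size = L,
      ins_size = m,
      net_change = m - L,
      mh_len = if (L > 0L && m == 0L) n_right else NA_integer_,
      left_del = left_del,
      right_del = right_del,
      gap_min = gap_min,
      gap_max = gap_max,
      in_window = del_window || ins_window
    ),
    class = "cas9_outcome"
  )
}

#' @export
print.cas9_outcome <- function(x, ...) {
  cat(sprintf(
    "<cas9_outcome> %s (del %d bp, ins %d bp, mh %s, window %s)\n",
    format_outcome(x), x$del_size, x$ins_size,
    ifelse(is.na(x$mh_len), "-", x$mh_len), x$in_window
  ))
  invisible(x)
}

#' Apply an outcome to the target sequence
#'
#' @param target a [target_site()].
#' @param o a `cas9_outcome` (or anything with `del_start`, `del_end`,
#'   `ins_seq`).
#' @return the edited nucleotide string; its length is
#'   `nchar(target$sequence) + o$net_change`.
#' @export
apply_outcome <- function(target, o) {
  s <- target$sequence
  n <- nchar(s)
  paste0(
    substr(s, 1L, o$del_start),
    o$ins_seq,
    substr(s, o$del_end + 1L, n)
  )
}

#' Microhomology length of a pure deletion
#'
#' The number of distinct equal-size deletion intervals producing the same
#' edited sequence, minus one; equivalently the length of the maximal exact
#' repeat shared by the two deletion junctions. Undefined (an error) for
#' outcomes carrying insertions, whose "microhomology" is insertion-flank
#' identity and is handled by [classify_outcome()].
#'
#' @inheritParams apply_outcome
#' @return non-negative integer.
#' @export
microhomology_length <- function(target, o) {
  if (o$ins_size > 0L) stop("microhomology_length is defined for pure deletions only")
  o$mh_len
}

.FLANK_LEVELS <- c("DISTAL_ONLY", "PROXIMAL_ONLY", "BOTH", "NEITHER")

## re-represent a canonical pure insertion at gap `gap` (must be equivalent)
.ins_at_gap <- function(target, o, gap) {
  ins <- strsplit(o$ins_seq, "", fixed = TRUE)[[1]]
  ds <- o$del_start; de <- o$del_end
  if (gap < o$gap_min || gap > o$gap_max) stop("gap not reachable by equivalent shifts")
  while (ds < gap) {
    nxt <- .shift_right1(target$chars, ds, de, ins)
    ds <- nxt$ds; de <- nxt$de; ins <- nxt$ins
  }
  paste(ins, collapse = "")
}

#' Match of an inserted sequence to the cut-flanking template
#'
#' For a pure insertion of 1-2 bp whose equivalence class includes the cut
#' gap, the inserted sequence is compared to the `ins_size` bases immediately
#' 5' of the cut (the PAM-distal template, read toward the cut) and the
#' `ins_size` bases immediately 3' of the cut (the PAM-proximal template).
#' Two-base templates are read contiguously from the cut outward on each
#' side; partial matches count as `NEITHER`. `BOTH` is only possible when the
#' two templates are identical strings.
#'
#' @inheritParams apply_outcome
#' @return one of `"DISTAL_ONLY"`, `"PROXIMAL_ONLY"`, `"BOTH"`, `"NEITHER"`.
#' @export
insertion_flank_match <- function(target, o) {
  if (o$del_size != 0L || o$ins_size < 1L || o$ins_size > 2L) {
    stop("insertion_flank_match requires a pure insertion of 1-2 bp")
  }
  cut <- target$cut
  if (cut < o$gap_min || cut > o$gap_max) {
    stop("insertion gap is not at the cut in any equivalent representation")
  }
  ins <- .ins_at_gap(target, o, cut)
  m <- o$ins_size
  distal <- paste(target$chars[(cut - m + 1L):cut], collapse = "")
  proximal <- paste(target$chars[(cut + 1L):(cut + m)], collapse = "")
  d <- ins == distal
  p <- ins == proximal
  if (d && p) "BOTH" else if (d) "DISTAL_ONLY" else if (p) "PROXIMAL_ONLY" else "NEITHER"
}

.CATEGORIES <- c(
  "DEL_1", "DEL_2", "DEL_MED_MH", "DEL_MED_NOMH", "DEL_LONG_MH",
  "DEL_LONG_NOMH", "INS_PROX", "INS_DIST", "OTHER_I_MH", "OTHER_I_NOMH"
)

#' The ten outcome categories
#'
#' @return character vector of the ten category labels, in display order:
#'   1 bp deletions, 2 bp deletions, medium (3-9 bp) deletions with/without
#'   microhomology, long (10+ bp) deletions with/without microhomology,
#'   1-2 bp cut-site insertions matching the PAM-proximal or PAM-distal
#'   flank, and other insertion-containing outcomes with/without an
#'   insertion-flank microhomology match.
#' @export
outcome_categories <- function() .CATEGORIES

## does ins_seq share an exact match of >= mh_min bases with the sequence
## flanking the edit locus (context_window bases each side)?
.ins_flank_mh <- function(target, o, mh_min, context_window = 10L) {
  if (o$ins_size < mh_min) return(FALSE)
  s <- target$sequence
  n <- nchar(s)
  left <- substr(s, max(1L, o$del_start - context_window + 1L), o$del_start)
  right <- substr(s, o$del_end + 1L, min(n, o$del_end + context_window))
  ctx <- c(left, right)
  for (i in seq_len(o$ins_size - mh_min + 1L)) {
    kmer <- substr(o$ins_seq, i, i + mh_min - 1L)
    if (any(grepl(kmer, ctx, fixed = TRUE))) return(TRUE)
  }
  FALSE
}

#' Classify a canonical outcome into one of the ten categories
#'
#' Pure deletions are classified by size (1, 2, 3-9, 10+) and, for sizes 3+,
#' by microhomology (`mh_len >= mh_min`). Pure insertions of 1-2 bp whose
#' equivalence class includes the cut gap are classified by their match to
#' the flanking templates: `DISTAL_ONLY` (and, by default, `BOTH`) to
#' `INS_DIST`, `PROXIMAL_ONLY` to `INS_PROX`. Everything else (longer
#' insertions, off-cut insertions, `NEITHER` matches and mixed
#' insertion-deletions) falls into `OTHER_I_MH` when the inserted sequence
#' has an exact match of `mh_min`+ bases to the sequence flanking the edit
#' locus, else `OTHER_I_NOMH`. The classification is total and deterministic
#' given `mh_min`.
#'
#' @inheritParams apply_outcome
#' @param mh_min microhomology threshold in bp (default 2).
#' @param both_as category for insertions matching both identical flanks:
#'   `"distal"` (default; templated fill-in of the PAM-distal overhang is the
#'   dominant mechanism) or `"proximal"`.
#' @param context_window bases of flanking sequence searched for
#'   insertion-flank microhomology.
#' @return one of [outcome_categories()].
#' @export
classify_outcome <- function(target, o, mh_min = 2L, both_as = c("distal", "proximal"),
                             context_window = 10L) {
  both_as <- match.arg(both_as)
  L <- o$del_size
  m <- o$ins_size
  if (m == 0L) {
    if (L == 1L) return("DEL_1")
    if (L == 2L) return("DEL_2")
    mh <- o$mh_len >= mh_min
    if (L <= 9L) return(if (mh) "DEL_MED_MH" else "DEL_MED_NOMH")
    return(if (mh) "DEL_LONG_MH" else "DEL_LONG_NOMH")
  }
  if (L == 0L && m <= 2L && target$cut >= o$gap_min && target$cut <= o$gap_max) {
    fm <- insertion_flank_match(target, o)
    if (fm == "DISTAL_ONLY") return("INS_DIST")
    if (fm == "PROXIMAL_ONLY") return("INS_PROX")
    if (fm == "BOTH") return(if (both_as == "distal") "INS_DIST" else "INS_PROX")
  }
  if (.ins_flank_mh(target, o, mh_min, context_window)) "OTHER_I_MH" else "OTHER_I_NOMH"
}

#' Directionality of a deletion around the cut
#'
#' The asymmetry of a pure deletion about the cut site,
#' `max(left_del, right_del) / del_size`, computed on the representation
#' whose midpoint is closest to the cut. A deletion confined to one side of
#' the cut has directionality 1; any 1 bp deletion has directionality 1 by
#' definition.
#'
#' @inheritParams apply_outcome
#' @param method `"max"` (default) for `max(L, R)/total`; `"diff"` for the
#'   alternative `|L - R|/total`.
#' @return a number in `[0.5, 1]` (`[0, 1]` for `"diff"`).
#' @export
directionality <- function(target, o, method = c("max", "diff")) {
  method <- match.arg(method)
  if (o$ins_size > 0L || o$del_size < 1L) {
    stop("directionality is defined for pure deletions only")
  }
  if (method == "max") {
    max(o$left_del, o$right_del) / o$del_size
  } else {
    abs(o$left_del - o$right_del) / o$del_size
  }
}

#' Is an outcome in-frame?
#'
#' True iff the net length change is a multiple of 3.
#'
#' @param o a `cas9_outcome`.
#' @return logical.
#' @export
is_in_frame <- function(o) o$net_change %% 3L == 0L

#' Format / parse the outcome descriptor grammar
#'
#' Outcomes are serialized as `D:<del_start>-<del_end>` and/or
#' `I:<gap>:<seq>` joined by `+`, with absolute 0-based coordinates on the
#' stored target sequence. Canonical form is mandatory on write;
#' `parse_outcome()` accepts non-canonical descriptors and normalizes them.
#'
#' @param o a `cas9_outcome`.
#' @return `format_outcome`: a descriptor string. `parse_outcome`: a
#'   canonical `cas9_outcome`.
#' @export
format_outcome <- function(o) {
  parts <- character(0)
  if (o$del_size > 0L) parts <- c(parts, sprintf("D:%d-%d", o$del_start, o$del_end))
  if (o$ins_size > 0L) parts <- c(parts, sprintf("I:%d:%s", o$del_start, o$ins_seq))
  paste(parts, collapse = "+")
}

#' @rdname format_outcome
#' @param target a [target_site()].
#' @param desc descriptor string.
#' @export
parse_outcome <- function(target, desc) {
  parts <- strsplit(desc, "+", fixed = TRUE)[[1]]
  ds <- de <- NA_integer_
  gap <- NA_integer_
  ins <- ""
  for (p in parts) {
    if (grepl("^D:\\d+-\\d+$", p)) {
      xs <- as.integer(strsplit(sub("^D:", "", p), "-", fixed = TRUE)[[1]])
      ds <- xs[1]; de <- xs[2]
    } else if (grepl("^I:\\d+:[ACGTacgt]+$", p)) {
      xs <- strsplit(sub("^I:", "", p), ":", fixed = TRUE)[[1]]
      gap <- as.integer(xs[1]); ins <- xs[2]
    } else {
      stop(sprintf("malformed outcome descriptor part: '%s'", p))
    }
  }
  if (is.na(ds)) {
    if (is.na(gap)) stop(sprintf("empty outcome descriptor: '%s'", desc))
    ds <- de <- gap
  } else if (!is.na(gap) && gap != ds) {
    stop("mixed outcome descriptor must anchor the insertion at the deletion start")
  }
  canonicalize(target, ds, de, ins)
}
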