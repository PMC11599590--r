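## Candidate outcome enumeration.
##
## The candidate universe at a target is every insertion of 1..max_ins
## nucleotides at gaps within ins_window of the cut, plus every deletion of
## 1..max_del bases whose interval (in at least one equivalent
## representation) intersects the two cut-adjacent bases. Candidates are
## canonicalized and deduplicated; the predictor's softmax is defined over
## this set and the synthetic generator's distributions are supported on it.

## per-session memo of enumerated candidate sets, keyed by sequence + limits
.candidate_cache <- new.env(parent = emptyenv())

## run length of TRUE ending at each position (1-based)
.run_end <- function(x) {
  if (!length(x)) return(integer(0))
  i <- seq_along(x)
  i - cummax(i * !x)
}

## Vectorized enumeration of canonical cut-spanning deletions of size
## 1..max_del: one row per equivalence class, with mh_len = class size - 1.
.deletion_candidates <- function(target, max_del = 30L) {
  chars <- target$chars
  n <- length(chars)
  cut <- target$cut
  rows <- vector("list", max_del)
  for (L in seq_len(max_del)) {
    ## eq[j] (1-based j) <=> S[j-1] == S[j-1+L]
    eq <- chars[1:(n - L)] == chars[(1L + L):n]
    f <- .run_end(eq)           # TRUE-run ending at j
    h <- rev(.run_end(rev(eq))) # TRUE-run starting at j
    s <- max(0L, cut - L):min(cut, n - L) # candidate 0-based starts
    lshift <- ifelse(s == 0L, 0L, f[s])
    rshift <- ifelse(s + 1L > n - L, 0L, h[s + 1L])
    ds_min <- s - lshift
    mh <- lshift + rshift
    keep <- !duplicated(ds_min)
    rows[[L]] <- tibble::tibble(
      del_start = ds_min[keep], del_size = L, mh_len = mh[keep]
    )
  }
  out <- dplyr::bind_rows(rows)
  out$del_end <- out$del_start + out$del_size
  ## midpoint-closest-to-cut representation for the left/right split
  r <- pmin(pmax(cut - ceiling(out$del_size / 2), out$del_start),
            out$del_start + out$mh_len)
  out$left_del <- pmax(0L, pmin(r + out$del_size, cut) - r)
  out$right_del <- out$del_size - out$left_del
  out$gap_min <- out$del_start
  out$gap_max <- out$del_start + out$mh_len
  out
}

#' Enumerate the candidate outcome set of a target
#'
#' All insertions of 1 to `max_ins` nucleotides at gaps within `ins_window`
#' of the cut, and all deletions of 1 to `max_del` bases spanning the cut
#' (intersecting the two cut-adjacent bases in at least one equivalent
#' representation), canonicalized and deduplicated so that no two candidates
#' yield identical edited sequences.
#'
#' @param target a [target_site()].
#' @param max_del maximum deletion size (default 30).
#' @param max_ins maximum insertion size (default 2).
#' @param ins_window maximum distance of the insertion gap from the cut
#'   (default 3).
#' @param mh_min microhomology threshold used for category labels.
#' @return a `candidate_set`: a tibble with one row per canonical candidate
#'   and columns `outcome` (descriptor string), `del_start`, `del_end`,
#'   `ins_seq`, `del_size`, `ins_size`, `mh_len` (`NA` for insertions), `d`
#'   (bases between microhomology copies, `del_size - mh_len`), `left_del`,
#'   `right_del`, `gap_min`, `gap_max`, `flank_match` (1-2 bp cut
#'   insertions; `NA` otherwise), `category` and `in_frame`. Attribute
#'   `target_id` records the source target.
#' @export
enumerate_candidates <- function(target, max_del = 30L, max_ins = 2L,
                                 ins_window = 3L, mh_min = 2L) {
  key <- paste(target$id, target$sequence, target$cut, max_del, max_ins,
               ins_window, mh_min, sep = "\r")
  hit <- .candidate_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(target$chars)
  cut <- target$cut
  if (cut - max_del < 0L || cut + max_del > n) {
    stop("target too short for the requested deletion window")
  }
  dels <- .deletion_candidates(target, max_del)
  dels$ins_seq <- ""
  dels$ins_size <- 0L
  dels$d <- dels$del_size - dels$mh_len
  dels$flank_match <- NA_character_
  dels$category <- ifelse(
    dels$del_size == 1L, "DEL_1",
    ifelse(dels$del_size == 2L, "DEL_2",
      ifelse(dels$del_size <= 9L,
        ifelse(dels$mh_len >= mh_min, "DEL_MED_MH", "DEL_MED_NOMH"),
        ifelse(dels$mh_len >= mh_min, "DEL_LONG_MH", "DEL_LONG_NOMH")
      )
    )
  )

  bases <- c("A", "C", "G", "T")
  ins_strings <- bases
  if (max_ins >= 2L) {
    for (k in 2:max_ins) {
      ins_strings <- c(ins_strings, as.vector(outer(ins_strings[nchar(ins_strings) == k - 1L],
                                                    bases, paste0)))
    }
  }
  gaps <- (cut - ins_window):(cut + ins_window)
  seen <- character(0)
  ins_rows <- list()
  for (g in gaps) {
    for (sq in ins_strings) {
      o <- canonicalize(target, g, g, sq)
      key <- format_outcome(o)
      if (key %in% seen) next
      seen <- c(seen, key)
      fm <- if (o$ins_size <= 2L && cut >= o$gap_min && cut <= o$gap_max) {
        insertion_flank_match(target, o)
      } else {
        NA_character_
      }
      ins_rows[[length(ins_rows) + 1L]] <- tibble::tibble(
        del_start = o$del_start, del_size = 0L, mh_len = NA_integer_,
        del_end = o$del_end, left_del = 0L, right_del = 0L,
        gap_min = o$gap_min, gap_max = o$gap_max,
        ins_seq = o$ins_seq, ins_size = o$ins_size, d = NA_integer_,
        flank_match = fm,
        category = classify_outcome(target, o, mh_min = mh_min)
      )
    }
  }
  out <- dplyr::bind_rows(dels, dplyr::bind_rows(ins_rows))
  out$in_frame <- (out$ins_size - out$del_size) %% 3L == 0L
  out$outcome <- ifelse(
    out$del_size > 0L,
    sprintf("D:%d-%d", out$del_start, out$del_end),
    sprintf("I:%d:%s", out$del_start, out$ins_seq)
  )
  out <- out[, c(
    "outcome", "del_start", "del_end", "ins_seq", "del_size", "ins_size",
    "mh_len", "d", "left_del", "right_del", "gap_min", "gap_max",
    "flank_match", "category", "in_frame"
  )]
  stopifnot(!anyDuplicated(out$outcome))
  attr(out, "target_id") <- target$id
  attr(out, "limits") <- list(max_del = max_del, max_ins = max_ins,
                              ins_window = ins_window, mh_min = mh_min)
  class(out) <- c("candidate_set", class(out))
  if (length(ls(.candidate_cache)) > 2048L) {
    rm(list = ls(.candidate_cache), envir = .candidate_cache)
  }
  assign(key, out, envir = .candidate_cache)
  out
}
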