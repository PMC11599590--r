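#' Construct a Cas9 target site
#'
#' A target site stores the full stored sequence of a synthetic target in
#' protospacer-5'-to-3' orientation, together with the 0-based protospacer and
#' PAM coordinates. The blunt Cas9 cut locus is derived as `pam_start - 3`, a
#' *gap* index: gap `g` lies between sequence positions `g - 1` and `g`
#' (0-based), i.e. between the 17th and 18th protospacer bases. The base
#' immediately 5' of the cut is the PAM-distal flank, the base immediately 3'
#' is the PAM-proximal flank.
#'
#' @param id target identifier.
#' @param sequence nucleotide string over A/C/G/T.
#' @param protospacer_start 0-based index of the first protospacer base.
#' @param pam_start 0-based index of the PAM's N; defaults to
#'   `protospacer_start + 20`.
#' @param check validate the NGG PAM, the protospacer/PAM spacing and the
#'   30 bp of context required on each side of the cut. `check = FALSE`
#'   permits degenerate sites (e.g. homopolymers) for exploring the outcome
#'   algebra; such sites cannot come from a real NGG library.
#' @return an object of class `target_site`.
#' @export
#' @examples
#' t <- target_site("t1", paste(rep("ACGT", 20), collapse = ""), 23, check = FALSE)
#' t$cut
target_site <- function(id, sequence, protospacer_start,
                        pam_start = protospacer_start + 20L, check = TRUE) {
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  .assert_nucleotides(chars)
  protospacer_start <- as.integer(protospacer_start)
  pam_start <- as.integer(pam_start)
  cut <- pam_start - 3L
  n <- length(chars)
  if (check) {
    if (pam_start != protospacer_start + 20L) {
      stop("pam_start must equal protospacer_start + 20")
    }
    if (pam_start + 2L >= n) stop("sequence too short to contain the PAM")
    if (!(chars[pam_start + 2L] == "G" && chars[pam_start + 3L] == "G")) {
      stop("no NGG PAM at pam_start (positions pam_start+1..pam_start+2)")
    }
    if (cut < 30L || n - cut < 30L) {
      stop("need >= 30 bases of sequence on each side of the cut")
    }
    if (n < 79L) stop("target sequence must be at least 79 bases")
  }
  structure(
    list(
      id = as.character(id),
      sequence = sequence,
      chars = chars,
      protospacer_start = protospacer_start,
      pam_start = pam_start,
      cut = cut
    ),
    class = "target_site"
  )
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf(
    "<target_site> %s (%d bp), protospacer %d, PAM %d, cut gap %d, flanks %s|%s\n",
    x$id, nchar(x$sequence), x$protospacer_start, x$pam_start, x$cut,
    pam_distal_flank(x), pam_proximal_flank(x)
  ))
  invisible(x)
}

#' Cut-flanking nucleotides
#'
#' The PAM-distal flank is the base immediately 5' of the cut
#' (`sequence[cut - 1]`); the PAM-proximal flank is the base immediately 3'
#' (`sequence[cut]`).
#'
#' @param target a [target_site()].
#' @return single character.
#' @export
pam_distal_flank <- function(target) target$chars[target$cut]

#' @rdname pam_distal_flank
#' @export
pam_proximal_flank <- function(target) target$chars[target$cut + 1L]

#' Write / read a target library as FASTA + TSV sidecar
#'
#' The FASTA holds full sequences keyed by id; `targets.tsv` holds
#' `id`, `protospacer_start`, `pam_start` (0-based, stated in the header).
#'
#' @param library a list of [target_site()] objects.
#' @param fasta,tsv file paths.
#' @return `read_target_library` returns a named list of `target_site`s.
#' @export
write_target_library <- function(library, fasta, tsv) {
  seqs <- Biostrings::DNAStringSet(vapply(library, function(t) t$sequence, ""))
  names(seqs) <- vapply(library, function(t) t$id, "")
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- tibble::tibble(
    id = names(seqs),
    protospacer_start = vapply(library, function(t) t$protospacer_start, 0L),
    pam_start = vapply(library, function(t) t$pam_start, 0L)
  )
  header <- "# repairscape target library; coordinates 0-based; cut gap = pam_start - 3"
  writeLines(c(header, paste(names(tab), collapse = "\t")), tsv)
  readr::write_tsv(tab, tsv, append = TRUE, col_names = FALSE)
  invisible(list(fasta = fasta, tsv = tsv))
}

#' @rdname write_target_library
#' @export
read_target_library <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- readr::read_tsv(tsv, comment = "#", show_col_types = FALSE)
  lib <- lapply(seq_len(nrow(tab)), function(i) {
    target_site(
      id = tab$id[i],
      sequence = as.character(seqs[[tab$id[i]]]),
      protospacer_start = tab$protospacer_start[i],
      pam_start = tab$pam_start[i]
    )
  })
  names(lib) <- tab$id
  class(lib) <- "target_library"
  lib
}
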