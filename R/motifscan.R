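# IQ-like calmodulin-binding motif scanner.
#
# Two consensus classes are reported, longest class first:
#   IQ_full : [FILV] Q x x x [RK] G x x x [RK]   (11 residues)
#   IQ_like : [FILVM] Q x x x [RK] x x x x       (10 residues; the relaxed
#             class covers motifs lacking the canonical G/basic anchors,
#             as in CatSperz, whose motif is "IQ-like" rather than strict IQ)
# The anchor is the [FILVM]-Q dipeptide opening the motif — the residue
# pair whose mutation to alanine abolishes calmodulin-family binding.
# Coordinates are 0-based, half-open.

IQ_FULL_REGEX <- "[FILV]Q[A-Z]{3}[RK]G[A-Z]{3}[RK]"
IQ_LIKE_REGEX <- "[FILVM]Q[A-Z]{3}[RK][A-Z]{4}"
IQ_FULL_LEN <- 11L
IQ_LIKE_LEN <- 10L

# All (possibly overlapping) match starts of a fixed-length pattern,
# via lookahead so overlaps are not swallowed.
overlapping_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a protein sequence for IQ-like motifs
#'
#' Reports all non-overlapping matches, preferring the longer, stricter
#' `IQ_full` class: full matches are placed greedily left to right, then
#' relaxed `IQ_like` matches are added wherever they do not overlap an
#' already-placed hit.
#'
#' @param seq Protein sequence (standard residues; `X` allowed, matches
#'   only the wildcard positions).
#' @return Data frame with 0-based half-open `start`, `end`, `match`,
#'   `class` and `anchor` (0-based position of the \[FILVM\] of the
#'   anchor dipeptide). Zero rows if no motif.
#' @export
find_iq_like <- function(seq) {
  seq <- toupper(seq)
  check_alphabet(seq)
  occupied <- rep(FALSE, nchar(seq))
  hits <- list()
  place <- function(starts, len, class) {
    for (s in starts) {
      span <- s:(s + len - 1)
      if (any(occupied[span])) next
      occupied[span] <<- TRUE
      hits[[length(hits) + 1]] <<- data.frame(
        start = s - 1L, end = s + len - 1L,
        match = substr(seq, s, s + len - 1),
        class = class, anchor = s - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  place(overlapping_starts(seq, IQ_FULL_REGEX), IQ_FULL_LEN, "IQ_full")
  place(overlapping_starts(seq, IQ_LIKE_REGEX), IQ_LIKE_LEN, "IQ_like")
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), class = character(0),
                      anchor = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag motif hits near the C-terminus
#'
#' A hit is C-terminal when its anchor lies within the final `window`
#' residues. The default window of 21 matches the deletion length that
#' abolishes binding when the C-terminus is truncated.
#'
#' @param hits Data frame from [find_iq_like].
#' @param seq_length Length of the scanned sequence.
#' @param window Number of terminal residues (default 21).
#' @return Logical vector, one flag per hit.
#' @export
report_cterminal <- function(hits, seq_length, window = 21) {
  if (window <= 0) stop("report_cterminal: window must be > 0", call. = FALSE)
  hits$anchor >= seq_length - window
}

#' Scan a FASTA file of protein sequences for IQ-like motifs
#'
#' @param path FASTA path (sequences need not be aligned; gaps stripped).
#' @param window C-terminal window passed to [report_cterminal].
#' @return Data frame: taxon, start, end, class, match, anchor,
#'   c_terminal.
#' @export
scan_fasta_iq <- function(path, window = 21) {
  aln <- read_fasta(path, aligned = FALSE)
  res <- lapply(names(aln$members), function(taxon) {
    seq <- gsub("-", "", aln$members[[taxon]], fixed = TRUE)
    hits <- find_iq_like(seq)
    if (nrow(hits) == 0) return(NULL)
    hits$taxon <- taxon
    hits$c_terminal <- report_cterminal(hits, nchar(seq), window)
    hits
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(taxon = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      match = character(0), anchor = integer(0),
                      c_terminal = logical(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[, c("taxon", "start", "end", "class", "match", "anchor", "c_terminal")]
}
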