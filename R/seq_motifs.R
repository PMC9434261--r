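# Sequence utilities supporting the substrate-specificity argument:
# scanning for the C-terminal motif whose arginine stabilises the
# D-stereocentre of meso-DAP, trimming chloroplast transit peptides, and
# a documented pairwise-identity measure. Coordinates are 1-based
# throughout, matching residue naming conventions (e.g. "leucine 63").

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")

.check_residues <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% .AA_ALPHABET)
  if (length(bad))
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1])
  invisible(chars)
}

#' DAP-specificity motif patterns
#'
#' The literal motifs observed in MurE ligases that position the
#' D-stereocentre of meso-DAP (DNPR and relatives: DNPK, and the grass
#' and pine variants DNPA and DNSR, plus DDPR whose arginine is retained
#' in promiscuous ligases), together with the generalised class
#' `[D][ND][PS][RKA]` that covers them.
#'
#' @return Named list with `literal` (character vector) and `class`
#'   (a 4-position regular expression).
#' @export
dap_motif_patterns <- function() {
  list(literal = c("DNPR", "DNPK", "DNPA", "DNSR", "DDPR"),
       class = "[D][ND][PS][RKA]")
}

#' Scan a protein sequence for DAP-specificity motifs
#'
#' Finds all non-overlapping occurrences of the generalised motif class;
#' each hit is labelled with the literal motif name when the matched
#' substring is one of the known literals, otherwise with the class
#' pattern itself.
#'
#' @param seq A single amino-acid sequence (one-letter code; the 20
#'   standard residues plus X). Invalid characters raise an error naming
#'   the offending position.
#' @param patterns A pattern set as returned by [dap_motif_patterns()].
#' @return A data frame with columns `pattern`, `start` (1-based) and
#'   `match`, ordered by position; zero rows if no hit.
#' @examples
#' scan_dap_motif("AAADNPRAAA")  # one hit, DNPR at position 4
#' @export
scan_dap_motif <- function(seq, patterns = dap_motif_patterns()) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) > 0) .check_residues(seq)
  hits <- gregexpr(patterns$class, seq)[[1]]
  if (hits[1] == -1)
    return(data.frame(pattern = character(0), start = integer(0),
                      match = character(0)))
  start <- as.integer(hits)
  match <- substring(seq, start, start + attr(hits, "match.length") - 1L)
  data.frame(
    pattern = ifelse(match %in% patterns$literal, match, patterns$class),
    start = start, match = match)
}

#' Trim an N-terminal transit peptide
#'
#' Returns the suffix of the sequence beginning at `start` (1-based,
#' inclusive), e.g. `start = 63` removes a predicted 62-residue
#' chloroplast transit peptide.
#'
#' @param seq A single amino-acid sequence.
#' @param start 1-based residue index of the first retained residue.
#' @return The trimmed sequence (length `nchar(seq) - start + 1`).
#' @export
trim_transit_peptide <- function(seq, start) {
  stopifnot(is.character(seq), length(seq) == 1, length(start) == 1)
  if (start < 1 || start > nchar(seq))
    stop("start must lie within 1..", nchar(seq))
  substring(seq, start)
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment (via Biostrings) with match score
#' +1, mismatch 0, gap opening 10 and gap extension 0.5; identity is the
#' number of identical aligned columns divided by the total alignment
#' length (including gap columns) times 100. This is a documented,
#' reproducible identity measure, not a reimplementation of any
#' particular alignment server's internals.
#'
#' @param a,b Amino-acid sequences (non-empty).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("AAAA", "AATA")  # 75
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  .check_residues(a); .check_residues(b)
  mat <- matrix(0, length(.AA_ALPHABET), length(.AA_ALPHABET),
                dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]] &
                   strsplit(p, "")[[1]] != "-")
  100 * matches / cols
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
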