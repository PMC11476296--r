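#' @include AllClasses.R
NULL

# Average residue frequencies of a generic (SwissProt-like) proteome, used
# as the background composition for simulated non-protamines.
BACKGROUND_FREQ <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92) / 100

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; record order and full header lines (including
#' spaces) are preserved. An empty file yields an empty set. Records with
#' an empty sequence are a parse error naming the offending header.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] with headers as names.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MARYRR"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path) {
  stopIfNot(file.exists(path), sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  empty <- which(Biostrings::width(seqs) == 0L)
  if (length(empty))
    stop(sprintf("empty sequence for record '%s' in %s",
                 names(seqs)[empty[1]], path), call. = FALSE)
  out <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(out) <- names(seqs)
  out
}

#' Write protein sequences to FASTA
#'
#' Standard multi-record FASTA with 60-column line wrapping. Identifiers
#' are written verbatim on the header line.
#'
#' @param records An [Biostrings::AAStringSet] (or named character vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(records, path) {
  if (is.character(records)) records <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(records, filepath = path, width = 60L)
  invisible(path)
}

#' Validate a sequence for featurization
#'
#' A sequence passes when every residue belongs to the 20-letter standard
#' alphabet and its length is at least `lambda + 1`, so that every
#' correlation factor up to lag `lambda` averages over at least one residue
#' pair. Ambiguity/non-standard codes (B, J, O, U, X, Z) fail rather than
#' being substituted, since the physicochemical scales cover only the 20
#' standard residues.
#'
#' @param sequence A single character string or `AAString`.
#' @param lambda Maximum correlation lag the sequence must support.
#' @return A list with `pass` (logical), `reason`
#'   (`"NONSTANDARD_RESIDUE"`, `"TOO_SHORT"` or `NA`) and `detail`.
#' @examples
#' validateSequence("ACDEFGHIKLM", lambda = 10)  # minimal admissible length
#' validateSequence("MARXRR", lambda = 2)
#' @export
validateSequence <- function(sequence, lambda = 10L) {
  seq <- toupper(as.character(sequence))
  stopIfNot(length(seq) == 1L, "validateSequence expects a single sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad))
    return(list(pass = FALSE, reason = "NONSTANDARD_RESIDUE",
                detail = paste(bad, collapse = ",")))
  if (length(chars) < lambda + 1L)
    return(list(pass = FALSE, reason = "TOO_SHORT",
                detail = sprintf("length %d < %d", length(chars), lambda + 1L)))
  list(pass = TRUE, reason = NA_character_, detail = NA_character_)
}

#' Simulate a protamine-like benchmark dataset
#'
#' Generates a labeled two-class set of synthetic protein sequences.
#' Positives emulate protamines: short sequences whose residues are drawn
#' i.i.d. with arginine at `posArgFraction` and the remaining probability
#' mass spread over a background tilted towards serine, lysine, cysteine,
#' glycine and valine (the residues protamine sequences are otherwise rich
#' in). Negatives are drawn from an average-proteome background
#' composition. Reproducible under `seed`.
#'
#' @param nPos,nNeg Number of positive / negative sequences.
#' @param posLengthRange,negLengthRange Integer length ranges (inclusive).
#' @param posArgFraction Target arginine proportion in positives, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return An [Biostrings::AAStringSet] with `mcols()$label` (1 = protamine).
#' @examples
#' bench <- simulateProtamineBenchmark(nPos = 5, nNeg = 5, seed = 1)
#' S4Vectors::mcols(bench)$label
#' @export
simulateProtamineBenchmark <- function(nPos = 200L, nNeg = 200L,
                                       posLengthRange = c(25L, 70L),
                                       negLengthRange = c(50L, 300L),
                                       posArgFraction = 0.6,
                                       seed = NULL) {
  stopIfNot(nPos >= 1L && nNeg >= 1L, "nPos and nNeg must be >= 1")
  stopIfNot(posArgFraction > 0 && posArgFraction < 1,
            "posArgFraction must lie strictly in (0, 1)")
  stopIfNot(min(posLengthRange, negLengthRange) >= 11L,
            "length ranges must be at least lambda + 1 = 11")

  # residual composition of positives: protamine-associated residues get
  # extra weight over a flat floor
  posWeights <- setNames(rep(1, 20), AA20)
  posWeights[c("S", "K", "C", "G", "V")] <- 4
  posWeights["R"] <- 0
  posProb <- posWeights / sum(posWeights) * (1 - posArgFraction)
  posProb["R"] <- posArgFraction

  negProb <- BACKGROUND_FREQ[AA20]

  withSeed(seed, {
    drawOne <- function(range, prob) {
      lens <- seq.int(range[1], range[2])
      len <- lens[sample.int(length(lens), 1L)]
      paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = "")
    }
    pos <- vapply(seq_len(nPos), function(i) drawOne(posLengthRange, posProb),
                  character(1))
    neg <- vapply(seq_len(nNeg), function(i) drawOne(negLengthRange, negProb),
                  character(1))
    out <- Biostrings::AAStringSet(c(pos, neg))
    names(out) <- c(sprintf("pos%03d", seq_len(nPos)),
                    sprintf("neg%03d", seq_len(nNeg)))
    S4Vectors::mcols(out)$label <- rep(c(1L, 0L), c(nPos, nNeg))
    out
  })
}

#' Position-specific residue frequencies
#'
#' For ragged-length sequence sets, the percentage at position j is taken
#' over the sequences that actually reach position j (per-position coverage
#' denominators), so every covered column sums to 100. Positions are
#' reported 1-based.
#'
#' @param records An [Biostrings::AAStringSet] or character vector.
#' @return A [PositionFrequencyMatrix-class].
#' @examples
#' positionFrequencyMatrix(c("RRS", "RRS", "RRS"))
#' @export
positionFrequencyMatrix <- function(records) {
  seqs <- toupper(as.character(records))
  stopIfNot(length(seqs) >= 1L, "at least one sequence required")
  lens <- nchar(seqs)
  lmax <- max(lens)
  counts <- matrix(0, nrow = 20L, ncol = lmax,
                   dimnames = list(AA20, sprintf("pos%d", seq_len(lmax))))
  for (s in seqs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- chars %in% AA20
    idx <- cbind(match(chars[keep], AA20), which(keep))
    counts[idx] <- counts[idx] + 1
  }
  coverage <- vapply(seq_len(lmax), function(j) sum(lens >= j), integer(1))
  freq <- counts
  covered <- coverage > 0L
  freq[, covered] <- sweep(counts[, covered, drop = FALSE], 2L,
                           colSums(counts[, covered, drop = FALSE]), "/") * 100
  methods::new("PositionFrequencyMatrix", freq = freq, coverage = coverage)
}

#' Export a position-frequency matrix as CSV
#'
#' Rows are the 20 residues in alphabetical one-letter order; columns are
#' 1-based positions. A trailing row `n_at_position` carries the coverage.
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writePositionFrequencies <- function(pfm, path) {
  out <- rbind(pfm@freq, n_at_position = pfm@coverage)
  write.csv(out, path, row.names = TRUE)
  invisible(path)
}
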