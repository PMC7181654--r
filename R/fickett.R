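# Fickett TESTCODE lookup tables, transcribed from the original 1982
# publication of the statistic (position and composition parameters, their
# probability-of-coding lookup values, and the parameter weights).
.fickett <- list(
    positionBreaks = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
    contentBreaks  = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21,
                       0.19, 0.17, 0),
    positionProb = list(
        A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
        C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
        G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
        T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
    contentProb = list(
        A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
        C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
        G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
        T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
    positionWeight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    contentWeight  = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14))

.fickettLookup <- function(value, breaks, probs) {
    probs[which(value >= breaks)[1L]]
}

.asSeqChar <- function(seq) {
    if (methods::is(seq, "DNAString") || methods::is(seq, "RNAString"))
        seq <- as.character(seq)
    stopifnot(is.character(seq), length(seq) == 1L)
    chartr("u", "T", toupper(seq))
}

#' Fickett TESTCODE coding-potential score
#'
#' Computes the eight Fickett parameters of a transcript - for each base,
#' the position asymmetry `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` over the
#' three codon positions, and the base's composition fraction - maps each
#' through the published probability lookup tables and returns the weighted
#' sum. Higher scores indicate coding sequence; the classic TESTCODE coding
#' bound is 0.74 (see [classifyTranscript()]).
#'
#' The score is case-insensitive and strand-specific (a reverse complement
#' generally scores differently). `N` characters are excluded from all
#' counts wherever they occur; more than 10% non-ACGTN characters is an
#' error, as is a sequence shorter than 200 nt.
#'
#' @param seq a nucleotide string (character, `DNAString`).
#' @return the Fickett score (numeric scalar).
#' @examples
#' fickettScore(paste(rep("ACGT", 75), collapse = ""))
#' @export
fickettScore <- function(seq) {
    s <- .asSeqChar(seq)
    if (nchar(s) < 200L) stop("sequence shorter than 200 nt")
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- !(ch %in% c("A", "C", "G", "T", "N"))
    if (mean(bad) > 0.10) stop("more than 10% non-ACGTN characters")
    ch <- ch[!bad & ch != "N"]
    n <- length(ch)
    pos <- (seq_len(n) - 1L) %% 3L + 1L
    score <- 0
    for (b in c("A", "C", "G", "T")) {
        cnt <- vapply(1:3, function(f) sum(ch[pos == f] == b), numeric(1))
        posVal <- max(cnt) / (min(cnt) + 1)
        score <- score + .fickett$positionWeight[[b]] *
            .fickettLookup(posVal, .fickett$positionBreaks,
                           .fickett$positionProb[[b]])
        score <- score + .fickett$contentWeight[[b]] *
            .fickettLookup(sum(ch == b) / n, .fickett$contentBreaks,
                           .fickett$contentProb[[b]])
    }
    unname(score)
}

#' Longest open reading frame and its coverage
#'
#' Scans the three forward frames for `ATG ... {TAA, TAG, TGA}` spans (stop
#' codon included in the length) and reports the longest span and its
#' fraction of the transcript length. With no complete ORF the result is
#' `(0, 0)`; with `openEnd = TRUE` an ORF lacking an in-sequence stop is
#' counted to the sequence end instead (off by default - transcripts are
#' assumed complete). Only the forward strand is scanned unless
#' `reverse = TRUE`, in which case the reverse complement's frames are
#' scanned too.
#'
#' @param seq a nucleotide string (character, `DNAString`).
#' @param openEnd count stop-less ORFs to the sequence end (default FALSE).
#' @param reverse also scan the reverse complement (default FALSE).
#' @return list with `coverage` (in `[0, 1]`) and `longest_orf_bp`.
#' @examples
#' orfCoverage("ATGTAA")  # minimal ORF: coverage 1
#' @export
orfCoverage <- function(seq, openEnd = FALSE, reverse = FALSE) {
    s <- .asSeqChar(seq)
    L <- nchar(s)
    if (L == 0L) stop("empty sequence")
    if (L < 3L) return(list(coverage = 0, longest_orf_bp = 0L))
    scan1 <- function(s) {
        best <- 0L
        for (f in 0:2) {
            ncod <- (nchar(s) - f) %/% 3L
            if (ncod < 1L) next
            codons <- substring(s, f + 1L + 3L * (seq_len(ncod) - 1L),
                                f + 3L * seq_len(ncod))
            open <- NA_integer_
            for (i in seq_len(ncod)) {
                cd <- codons[i]
                if (is.na(open) && cd == "ATG") open <- i
                else if (!is.na(open) &&
                         cd %in% c("TAA", "TAG", "TGA")) {
                    best <- max(best, (i - open + 1L) * 3L)
                    open <- NA_integer_
                }
            }
            if (openEnd && !is.na(open))
                best <- max(best, (ncod - open + 1L) * 3L)
        }
        best
    }
    best <- scan1(s)
    if (reverse)
        best <- max(best, scan1(as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s)))))
    list(coverage = best / L, longest_orf_bp = best)
}

#' Coding / noncoding verdict from the two scores
#'
#' `coding` iff both scores reach their cutoffs; `noncoding` iff both fall
#' below; `indeterminate` otherwise. Monotone: raising either score never
#' flips a coding verdict to noncoding.
#'
#' @param fickett Fickett score (see [fickettScore()]).
#' @param coverage ORF coverage (see [orfCoverage()]).
#' @param fickettCutoff default 0.74 (the classic TESTCODE coding bound).
#' @param coverageCutoff default 0.5.
#' @return `"coding"`, `"noncoding"` or `"indeterminate"`.
#' @export
classifyTranscript <- function(fickett, coverage, fickettCutoff = 0.74,
                               coverageCutoff = 0.5) {
    if (is.na(fickett) || is.na(coverage)) return("indeterminate")
    f <- fickett >= fickettCutoff
    c_ <- coverage >= coverageCutoff
    if (f && c_) "coding" else if (!f && !c_) "noncoding"
    else "indeterminate"
}

#' Coding-potential report for a set of transcripts
#'
#' Runs [fickettScore()], [orfCoverage()] and [classifyTranscript()] on every
#' sequence of a FASTA file or `DNAStringSet`. Sequences shorter than 200 nt
#' get `NA` Fickett scores (and an `indeterminate` verdict) with a warning.
#'
#' @param x path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @inheritParams classifyTranscript
#' @return data.frame `transcript_id`, `fickett_score`, `orf_coverage`,
#'   `longest_orf_bp`, `verdict`.
#' @export
codingPotentialReport <- function(x, fickettCutoff = 0.74,
                                  coverageCutoff = 0.5) {
    seqs <- if (is.character(x) && length(x) == 1L && file.exists(x))
        Biostrings::readDNAStringSet(x) else x
    stopifnot(methods::is(seqs, "DNAStringSet"))
    ids <- names(seqs)
    short <- Biostrings::width(seqs) < 200L
    if (any(short))
        warning(sum(short), " sequence(s) shorter than 200 nt: ",
                "Fickett score not computed")
    rows <- lapply(seq_along(seqs), function(i) {
        s <- as.character(seqs[[i]])
        fick <- if (short[i]) NA_real_ else fickettScore(s)
        orf <- orfCoverage(s)
        data.frame(transcript_id = ids[i], fickett_score = fick,
                   orf_coverage = orf$coverage,
                   longest_orf_bp = orf$longest_orf_bp,
                   verdict = classifyTranscript(fick, orf$coverage,
                                                fickettCutoff,
                                                coverageCutoff),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
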