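.AA_CHARS <- "ARNDCQEGHILKMFPSTWYVBZX*"

.check_protein <- function(x, name) {
  x <- toupper(gsub("\\s", "", x))
  bad <- setdiff(strsplit(x, "")[[1]], strsplit(.AA_CHARS, "")[[1]])
  if (length(bad)) stop("invalid residue character(s) in ", name, ": ",
                        paste(unique(bad), collapse = ", "))
  x
}

.load_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch alignment of two protein sequences under a
#' substitution matrix (BLOSUM62 by default) and affine gap costs: a gap of
#' length L costs `open + extend * (L - 1)`. Terminal gaps are penalized
#' like internal ones unless `end_gap_free = TRUE`.
#'
#' @param seq_a,seq_b protein sequences (character strings).
#' @param matrix substitution matrix name from Biostrings (e.g. "BLOSUM62")
#'   or a numeric matrix.
#' @param open gap opening penalty (positive; charged to the first gap
#'   column of a run).
#' @param extend gap extension penalty (positive; each further gap column).
#' @param end_gap_free if TRUE, terminal gaps are free (overlap alignment).
#' @return an `hv_alignment`: list with `seq_a`, `seq_b`, `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), and `score`.
#' @examples
#' global_align_affine("AAW", "AW")  # score 7: 4 + 11 - 8
#' @export
global_align_affine <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                open = 8, extend = 1, end_gap_free = FALSE) {
  seq_a <- .check_protein(seq_a, "seq_a")
  seq_b <- .check_protein(seq_b, "seq_b")
  mat <- .load_matrix(matrix)
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na == 0 && nb == 0) stop("both sequences are empty")
  if (na == 0 || nb == 0) {
    ## degenerate all-gap alignment: one run spanning the longer sequence
    L <- max(na, nb)
    ali <- list(seq_a = seq_a, seq_b = seq_b,
                aligned_a = if (na) seq_a else strrep("-", L),
                aligned_b = if (nb) seq_b else strrep("-", L),
                score = if (end_gap_free) 0 else -(open + extend * (L - 1)))
    return(structure(ali, class = "hv_alignment"))
  }
  ## Biostrings charges open + extend * L for a gap of length L; shifting the
  ## opening penalty by one extension reproduces open + extend * (L - 1).
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, substitutionMatrix = mat,
    gapOpening = open - extend, gapExtension = extend,
    type = if (end_gap_free) "overlap" else "global")
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 aligned_a = as.character(Biostrings::alignedPattern(pa)),
                 aligned_b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "hv_alignment")
}

#' Construct an alignment from pre-aligned (gapped) sequences
#'
#' For alignments produced elsewhere (e.g. a multiple-alignment tool with
#' manual register edits) supply the two gapped rows directly; the score is
#' recomputed with [column_scores()].
#'
#' @param aligned_a,aligned_b equal-length gapped protein strings (`-` gaps).
#' @inheritParams global_align_affine
#' @return an `hv_alignment`.
#' @export
hv_alignment <- function(aligned_a, aligned_b, matrix = "BLOSUM62",
                         open = 8, extend = 1) {
  aligned_a <- toupper(gsub("\\s", "", aligned_a))
  aligned_b <- toupper(gsub("\\s", "", aligned_b))
  if (nchar(aligned_a) != nchar(aligned_b)) stop("aligned rows differ in length")
  ali <- structure(list(seq_a = gsub("-", "", aligned_a, fixed = TRUE),
                        seq_b = gsub("-", "", aligned_b, fixed = TRUE),
                        aligned_a = aligned_a, aligned_b = aligned_b,
                        score = NA_real_),
                   class = "hv_alignment")
  ali$score <- sum(column_scores(ali, matrix = matrix, open = open,
                                 extend = extend)$score)
  ali
}

#' @export
print.hv_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment, %d columns, score %.1f\n",
              nchar(x$aligned_a), x$score))
  a <- x$aligned_a; b <- x$aligned_b
  for (i in seq(1, nchar(a), by = 60)) {
    j <- min(i + 59, nchar(a))
    cat(substr(a, i, j), "\n", substr(b, i, j), "\n\n", sep = "")
  }
  invisible(x)
}

#' Per-column alignment scores
#'
#' Residue-residue columns score `matrix[a, b]`; the first column of each
#' gap run scores `-open` and subsequent columns of the run `-extend`.
#' Columns with gaps in both rows are invalid.
#'
#' @param alignment an `hv_alignment`.
#' @inheritParams global_align_affine
#' @return data.frame with `column`, `a`, `b`, `score`, and `gap_state`
#'   (`"none"`, `"open"`, `"extend"`).
#' @export
column_scores <- function(alignment, matrix = "BLOSUM62", open = 8, extend = 1) {
  stopifnot(inherits(alignment, "hv_alignment"))
  mat <- .load_matrix(matrix)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (any(a == "-" & b == "-")) stop("column with gaps in both rows")
  gap <- a == "-" | b == "-"
  run_first <- gap & !c(FALSE, gap[-length(gap)])
  score <- numeric(length(a))
  score[!gap] <- mat[cbind(a[!gap], b[!gap])]
  score[gap & run_first] <- -open
  score[gap & !run_first] <- -extend
  gap_state <- ifelse(!gap, "none", ifelse(run_first, "open", "extend"))
  data.frame(column = seq_along(a), a = a, b = b, score = score,
             gap_state = gap_state)
}

#' Per-residue divergence scale
#'
#' Converts per-column similarity scores into a 0-1 divergence scale indexed
#' by the reference sequence's residue numbering: divergence is the
#' deviation from the average similarity, \eqn{d_i = \bar w - w_i}, computed
#' on columns carrying a reference residue (gap-in-reference columns are
#' dropped and their penalties assigned to the preceding reference residue,
#' or the following one at the N-terminus); the profile is then smoothed by
#' centered adjacent averaging over `window` residues (truncated
#' symmetrically at the termini) and min-max rescaled to `[0, 1]`. With
#' `smooth_first = FALSE` the rescaling precedes the smoothing instead (in
#' which case the extremes need not touch 0 and 1).
#'
#' @param scores a data.frame from [column_scores()].
#' @param reference `"a"` or `"b"`: which row's residue numbering indexes
#'   the output.
#' @param window smoothing window in residues (odd, >= 1; 1 disables
#'   smoothing).
#' @param smooth_first if TRUE (default) smooth the deviation profile before
#'   min-max rescaling.
#' @return numeric vector of divergence values in `[0, 1]`, one per
#'   reference residue, with attributes `window` and `normalization`
#'   (`c(min, max)` of the pre-rescale profile).
#' @export
divergence_scale <- function(scores, reference = c("a", "b"), window = 5,
                             smooth_first = TRUE) {
  reference <- match.arg(reference)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  ref <- scores[[reference]]
  is_res <- ref != "-"
  if (!any(is_res)) stop("reference row has no residues")
  w <- numeric(sum(is_res))
  ridx <- cumsum(is_res)           # reference residue index per column
  w[ridx[is_res]] <- scores$score[is_res]
  ## fold gap-in-reference penalties into the flanking reference residue
  for (j in which(!is_res)) {
    k <- if (ridx[j] >= 1) ridx[j] else 1
    w[k] <- w[k] + scores$score[j]
  }
  d <- mean(w) - w
  smooth <- function(x) {
    if (window == 1) return(x)
    half <- (window - 1) / 2
    vapply(seq_along(x), function(i) {
      h <- min(half, i - 1, length(x) - i)   # symmetric truncation at termini
      mean(x[(i - h):(i + h)])
    }, numeric(1))
  }
  rescale <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(list(v = rep(0, length(x)), rng = rng))
    list(v = (x - rng[1]) / diff(rng), rng = rng)
  }
  if (smooth_first) {
    sm <- smooth(d)
    rs <- rescale(sm)
    out <- rs$v
  } else {
    rs <- rescale(d)
    out <- smooth(rs$v)
  }
  structure(out, window = window, normalization = rs$rng,
            names = as.character(seq_along(out)))
}

#' Percent identity of an alignment
#'
#' 100 times the number of identical residue columns over a denominator:
#' the full alignment length (default), the shorter sequence length, or the
#' number of gapless columns.
#'
#' @param alignment an `hv_alignment`.
#' @param denominator `"alignment"`, `"shorter"`, or `"gapless"`.
#' @return percent identity.
#' @export
percent_identity <- function(alignment,
                             denominator = c("alignment", "shorter", "gapless")) {
  stopifnot(inherits(alignment, "hv_alignment"))
  denominator <- match.arg(denominator)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (!length(a)) stop("empty alignment")
  ident <- sum(a == b & a != "-")
  den <- switch(denominator,
                alignment = length(a),
                shorter = min(nchar(alignment$seq_a), nchar(alignment$seq_b)),
                gapless = sum(a != "-" & b != "-"))
  100 * ident / den
}

#' Count substitutions between two sequences
#'
#' Number of aligned residue pairs that differ. Equal-length ungapped
#' sequences are compared positionally; otherwise a global alignment is
#' computed first. Gapped positions are not counted as substitutions but
#' reported in the `gaps` attribute.
#'
#' @param seq_a,seq_b protein sequences, or an `hv_alignment` as `seq_a`.
#' @inheritParams global_align_affine
#' @return integer substitution count with attribute `gaps`.
#' @export
count_substitutions <- function(seq_a, seq_b = NULL, matrix = "BLOSUM62",
                                open = 8, extend = 1) {
  if (inherits(seq_a, "hv_alignment")) {
    ali <- seq_a
  } else {
    seq_a <- .check_protein(seq_a, "seq_a")
    seq_b <- .check_protein(seq_b, "seq_b")
    ali <- if (nchar(seq_a) == nchar(seq_b))
      hv_alignment(seq_a, seq_b, matrix = matrix, open = open, extend = extend)
    else global_align_affine(seq_a, seq_b, matrix = matrix, open = open,
                             extend = extend)
  }
  a <- strsplit(ali$aligned_a, "")[[1]]
  b <- strsplit(ali$aligned_b, "")[[1]]
  res <- a != "-" & b != "-"
  structure(sum(res & a != b), gaps = sum(!res))
}
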