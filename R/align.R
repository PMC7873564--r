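# Deterministic global alignment (Needleman-Wunsch / Gotoh with affine gaps).
# The DP is written out here rather than delegated so that the tie-break
# order (diagonal > up > left, match state preferred on state ties) is
# fixed and the traceback fully reproducible.

.blosum_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#' @return Numeric matrix of substitution scores (from Biostrings).
#' @export
blosum62 <- function() {
  if (is.null(.blosum_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$BLOSUM62 <- e$BLOSUM62
  }
  .blosum_cache$BLOSUM62
}

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal global alignment of two protein sequences under a substitution
#' matrix and affine gap penalties: a gap of length L costs
#' `gap_open + gap_extend * L`. Ties in the dynamic program are broken
#' deterministically: diagonal over up (gap in `b`) over left (gap in
#' `a`), and the match state is preferred when states tie, so the output
#' alignment is unique.
#'
#' @param a,b [protein_seq()] objects (or plain strings).
#' @param substitution substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 0.5).
#' @return Object of class `pairwise_alignment` with fields `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `n_identical`,
#'   `n_columns` and `score`.
#' @export
align_global <- function(a, b, substitution = blosum62(),
                         gap_open = 10, gap_extend = 0.5) {
  if (is.character(a)) a <- protein_seq(a, id = "a")
  if (is.character(b)) b <- protein_seq(b, id = "b")
  av <- seq_chars(a); bv <- seq_chars(b)
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  go <- gap_open + gap_extend   # cost of the first gapped residue
  ge <- gap_extend
  NEG <- -1e18

  sub <- substitution[av, bv, drop = FALSE]  # n x m lookup

  # M: a_i aligned to b_j; X: gap in b (consume a_i, "up");
  # Y: gap in a (consume b_j, "left")
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) X[2L:(n + 1L), 1L] <- -(go + ge * (0:(n - 1L)))
  if (m > 0L) Y[1L, 2L:(m + 1L)] <- -(go + ge * (0:(m - 1L)))

  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sub[i - 1L, j - 1L]
      X[i, j] <- max(M[i - 1L, j] - go, X[i - 1L, j] - ge)
      Y[i, j] <- max(M[i, j - 1L] - go, Y[i, j - 1L] - ge)
    }
  }

  eps <- 1e-9
  states <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  best <- max(states)
  state <- which(states >= best - eps)[1L]  # prefer M > X > Y
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {            # M: consume both
      out_a <- c(av[i], out_a); out_b <- c(bv[j], out_b)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which(prev >= max(prev) - eps)[1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {     # X: consume a_i, gap in b
      out_a <- c(av[i], out_a); out_b <- c("-", out_b)
      from_m <- M[i, j + 1L] - go
      from_x <- X[i, j + 1L] - ge
      state <- if (from_m >= from_x - eps) 1L else 2L
      i <- i - 1L
    } else {                      # Y: consume b_j, gap in a
      out_a <- c("-", out_a); out_b <- c(bv[j], out_b)
      from_m <- M[i + 1L, j] - go
      from_y <- Y[i + 1L, j] - ge
      state <- if (from_m >= from_y - eps) 1L else 3L
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }

  n_id <- sum(out_a == out_b & out_a != "-")
  structure(
    list(aligned_a = paste(out_a, collapse = ""),
         aligned_b = paste(out_b, collapse = ""),
         n_identical = n_id, n_columns = length(out_a), score = best,
         id_a = a$id, id_b = b$id,
         offset_a = a$numbering_offset, offset_b = b$numbering_offset),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, %d identical, score %.1f\n",
              x$id_a, x$id_b, x$n_columns, x$n_identical, x$score))
  av <- strsplit(x$aligned_a, "")[[1]]
  bv <- strsplit(x$aligned_b, "")[[1]]
  for (s in seq(1, x$n_columns, by = width)) {
    e <- min(s + width - 1, x$n_columns)
    cat(" ", paste(av[s:e], collapse = ""), "\n")
    cat(" ", paste(ifelse(av[s:e] == bv[s:e], "|", " "), collapse = ""), "\n")
    cat(" ", paste(bv[s:e], collapse = ""), "\n")
  }
  invisible(x)
}

#' Column map of an alignment
#'
#' For each alignment column, the full-length residue number in each
#' sequence (NA at gap columns), using the numbering offsets carried by
#' the aligned sequences.
#'
#' @param aln a [align_global()] result.
#' @return data.frame with columns `column`, `a`, `b`, `pos_a`, `pos_b`.
#' @export
alignment_columns <- function(aln) {
  av <- strsplit(aln$aligned_a, "")[[1]]
  bv <- strsplit(aln$aligned_b, "")[[1]]
  pos_a <- ifelse(av == "-", NA_integer_, cumsum(av != "-") + aln$offset_a - 1L)
  pos_b <- ifelse(bv == "-", NA_integer_, cumsum(bv != "-") + aln$offset_b - 1L)
  data.frame(column = seq_along(av), a = av, b = bv,
             pos_a = pos_a, pos_b = pos_b, stringsAsFactors = FALSE)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * n_identical / denominator`, where the denominator is the number
#' of alignment columns (default; gap columns count against identity),
#' or the length of the shorter or longer input. Because rounding
#' conventions for printed identity values vary, the result carries both
#' the unrounded value and its round-half-up and truncated integer forms.
#'
#' @param aln a [align_global()] result.
#' @param convention denominator convention.
#' @return Object of class `percent_identity` with fields `percent`
#'   (unrounded), `round_half_up`, `truncated`, `denominator`,
#'   `convention`.
#' @export
percent_identity <- function(aln, convention = c("columns", "shorter", "longer")) {
  convention <- match.arg(convention)
  len_a <- sum(strsplit(aln$aligned_a, "")[[1]] != "-")
  len_b <- sum(strsplit(aln$aligned_b, "")[[1]] != "-")
  den <- switch(convention,
                columns = aln$n_columns,
                shorter = min(len_a, len_b),
                longer = max(len_a, len_b))
  p <- 100 * aln$n_identical / den
  structure(list(percent = p,
                 round_half_up = floor(p + 0.5),
                 truncated = trunc(p),
                 denominator = den, convention = convention),
            class = "percent_identity")
}

#' @export
print.percent_identity <- function(x, ...) {
  cat(sprintf("%.2f%% identity (%s denominator = %d; %d round-half-up, %d truncated)\n",
              x$percent, x$convention, x$denominator,
              x$round_half_up, x$truncated))
  invisible(x)
}
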