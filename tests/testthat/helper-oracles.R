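# Independent oracles used across the suite: exhaustive alignment
# enumeration, brute-force all-pairs contact scans, random rigid motions.

# score a gapped alignment (two equal-length character vectors) under
# substitution scores and affine gaps: a gap of length L costs open + ext * L
score_gapped_alignment <- function(ca, cb, sub, open = 10, ext = 0.5) {
  stopifnot(length(ca) == length(cb))
  s <- 0
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") s <- s + sub[ca[k], cb[k]]
  }
  for (row in list(ca, cb)) {
    r <- rle(row == "-")
    s <- s - sum(open + ext * r$lengths[r$values])
  }
  s
}

# exhaustive enumeration of every global alignment (no gap-gap columns);
# returns the maximum score. Only feasible for sequences of length <= 5.
brute_align_score <- function(a, b, sub = blosum62(), open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_gapped_alignment(ca, cb, sub, open, ext))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1L, j + 1L, c(ca, av[i]), c(cb, bv[j]))
    }
    if (i <= length(av)) rec(i + 1L, j, c(ca, av[i]), c(cb, "-"))
    if (j <= length(bv)) rec(i, j + 1L, c(ca, "-"), c(cb, bv[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# brute-force all-pairs native-contact scan
brute_contacts <- function(coords, resno, cutoff, min_sep) {
  out <- list()
  n <- nrow(coords)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d <= cutoff && abs(resno[i] - resno[j]) >= min_sep) {
      out <- c(out, list(c(i, j, d)))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), ref_dist = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), ref_dist = m[, 3])
}

# brute-force residue-pair contact scan between two atom index sets
brute_residue_contacts <- function(s, a, b, cutoff) {
  pairs <- list()
  for (i in a) for (j in b) {
    d <- sqrt(sum((atom_coords(s, i) - atom_coords(s, j))^2))
    key <- paste(s$atom$chain[i], s$atom$resno[i],
                 s$atom$chain[j], s$atom$resno[j])
    if (is.null(pairs[[key]]) || d < pairs[[key]]) pairs[[key]] <- d
  }
  keep <- names(pairs)[unlist(pairs) <= cutoff]
  sort(keep)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_protein_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# random Calpha toy structure with two chains
random_two_chain_structure <- function(n_res = 20L, spread = 15) {
  atoms <- do.call(rbind, lapply(c("A", "B"), function(ch) {
    data.frame(chain = ch, resno = seq_len(n_res), resid = "ALA",
               elety = "CA", elesy = "C",
               x = runif(n_res, 0, spread) + ifelse(ch == "B", spread / 2, 0),
               y = runif(n_res, 0, spread),
               z = runif(n_res, 0, spread), stringsAsFactors = FALSE)
  }))
  structure3d(atoms)
}
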