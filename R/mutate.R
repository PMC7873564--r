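# Interspecies replacement mutants of the receptor domain, specified in
# full-length numbering, plus cysteine bridge classification by alignment
# to an annotated reference.

#' Mutation specification
#'
#' A set of point edits in full-length numbering. Each edit gives the
#' position, the residue expected there (verified before applying) and
#' the replacement, with `"-"` denoting deletion.
#'
#' @param label human-readable mutant label.
#' @param positions integer vector of full-length positions (strictly increasing).
#' @param from expected one-letter codes at those positions.
#' @param to replacement codes, `"-"` for deletion.
#' @return Object of class `mutation_spec`.
#' @export
mutation_spec <- function(label, positions, from, to) {
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(from), length(from) == length(to))
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("edit positions must be strictly increasing")
  }
  ok <- from %in% AA1 & (to %in% AA1 | to == "-")
  if (!all(ok)) stop("edits must use one-letter amino-acid codes ('-' = deletion)")
  structure(list(label = label,
                 edits = data.frame(pos = positions, from = from, to = to,
                                    stringsAsFactors = FALSE)),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s: %d edit(s)\n", x$label, nrow(x$edits)))
  print(x$edits, row.names = FALSE)
  invisible(x)
}

#' Parse a compact mutant label
#'
#' Understands the compact notation used for interspecies replacement
#' mutants: `"E41Q"` (single substitution), `"N66-"` (single deletion),
#' and the stretch form `"KQYPR79-83TPCLD"` (replace the run starting at
#' 79 and ending at 83).
#'
#' @param label compact mutant label.
#' @return A [mutation_spec()].
#' @export
parse_mutation_label <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Z]+)([0-9]+)(?:-([0-9]+))?([A-Z]+|-)$", label))[[1]]
  if (length(m) == 0L) stop(sprintf("cannot parse mutant label '%s'", label))
  from <- strsplit(m[2], "")[[1]]
  start <- as.integer(m[3])
  to_str <- m[5]
  if (nzchar(m[4])) {
    end <- as.integer(m[4])
    if (end - start + 1L != length(from)) {
      stop(sprintf("'%s': range %d-%d does not match %d listed residues",
                   label, start, end, length(from)))
    }
  }
  positions <- start + seq_along(from) - 1L
  to <- if (to_str == "-") rep("-", length(from)) else strsplit(to_str, "")[[1]]
  if (length(to) != length(from)) {
    stop(sprintf("'%s': replacement length does not match", label))
  }
  mutation_spec(label, positions, from, to)
}

#' The eight interspecies replacement mutants of the human domain
#'
#' Replacement mutants of the human FcuR Ig-like domain carrying the
#' corresponding mouse residues: KVEG24-27QLNV, E41Q, M42L, EM41-42QL,
#' N66- (deletion), KQYPR79-83TPCLD, Y81C and N109K.
#'
#' @return Named list of [mutation_spec()] objects.
#' @export
fcmur_mutants <- function() {
  labels <- c("KVEG24-27QLNV", "E41Q", "M42L", "EM41-42QL",
              "N66-", "KQYPR79-83TPCLD", "Y81C", "N109K")
  specs <- lapply(labels, parse_mutation_label)
  names(specs) <- c("24-27", "E41Q", "M42L", "41-42",
                    "N66-", "79-83", "Y81C", "N109K")
  specs
}

#' Read mutation specs from a YAML or JSON file
#'
#' Expected layout: a list of entries with `label` and `edits`, each edit
#' `{pos, from, to}` with `to: "-"` for deletion.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return List of [mutation_spec()] objects.
#' @export
read_mutation_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads bare Y/N as booleans; map them back to the residues
  unbool <- function(x) {
    vapply(x, function(v) {
      if (is.logical(v)) (if (v) "Y" else "N") else as.character(v)
    }, "")
  }
  lapply(raw, function(entry) {
    e <- do.call(rbind, lapply(entry$edits, as.data.frame))
    mutation_spec(entry$label, e$pos, unbool(e$from), unbool(e$to))
  })
}

#' Apply a mutation spec to a sequence
#'
#' Verifies every `from` residue, then applies substitutions and
#' deletions. The numbering offset is retained, so reports keep the
#' original full-length numbering of the unmutated protein; deletions
#' shorten the local sequence.
#'
#' @param seq a [protein_seq()].
#' @param spec a [mutation_spec()].
#' @return The mutated `protein_seq` (id suffixed with the mutant label).
#' @export
apply_mutation <- function(seq, spec) {
  chars <- seq_chars(seq)
  local <- spec$edits$pos - seq$numbering_offset + 1L
  if (any(local < 1L | local > length(chars))) {
    stop(sprintf("%s: edit position outside the sequence", spec$label))
  }
  found <- chars[local]
  bad <- which(found != spec$edits$from)
  if (length(bad) > 0L) {
    k <- bad[1]
    stop(sprintf("%s: expected %s at position %d but found %s",
                 spec$label, spec$edits$from[k], spec$edits$pos[k], found[k]))
  }
  chars[local] <- spec$edits$to
  chars <- chars[chars != "-"]
  out <- protein_seq(paste(chars, collapse = ""),
                     id = paste0(seq$id, ":", spec$label),
                     numbering_offset = seq$numbering_offset)
  out
}

#' Reverse spec of a substitution-only mutation
#' @param spec a [mutation_spec()] with no deletions.
#' @return The inverse [mutation_spec()].
#' @export
reverse_mutation <- function(spec) {
  if (any(spec$edits$to == "-")) stop("deletions are not invertible")
  mutation_spec(paste0("rev:", spec$label), spec$edits$pos,
                spec$edits$to, spec$edits$from)
}

#' Classify cysteines as bridged or free by alignment to a reference
#'
#' Each cysteine of `seq` is mapped through the pairwise alignment to the
#' reference sequence; if its column holds a reference cysteine annotated
#' as a bridge partner, it is classified `bridged`, otherwise `free`.
#' The reported reference position is the human-aligned column position,
#' which is the numbering convention used for cross-species residue
#' comparison.
#'
#' @param seq a [protein_seq()] whose cysteines are to be classified.
#' @param reference annotated reference [protein_seq()] (e.g., the human
#'   domain).
#' @param aln alignment of `reference` (as `a`) vs `seq` (as `b`), from
#'   [align_global()].
#' @param bridges list of bridge pairs in reference full-length numbering.
#' @return data.frame with `pos_seq` (full-length in `seq`), `pos_ref`
#'   (human-aligned column position) and `class` (`bridged`/`free`).
#' @export
cysteine_topology <- function(seq, reference, aln,
                              bridges = list(c(37L, 104L), c(49L, 58L))) {
  cols <- alignment_columns(aln)
  if (!identical(gsub("-", "", aln$aligned_b), seq$residues) ||
      !identical(gsub("-", "", aln$aligned_a), reference$residues)) {
    stop("alignment does not match reference (a) and seq (b)")
  }
  bridged_pos <- unlist(bridges)
  cys <- which(cols$b == "C")
  if (length(cys) == 0L) {
    return(data.frame(pos_seq = integer(0), pos_ref = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  pos_ref <- cols$pos_a[cys]
  if (any(is.na(pos_ref))) {
    stop("a cysteine falls in a column not covered by the reference")
  }
  ref_res <- vapply(pos_ref, function(p) residue_at(reference, p), "")
  cls <- ifelse(pos_ref %in% bridged_pos & ref_res == "C", "bridged", "free")
  data.frame(pos_seq = cols$pos_b[cys], pos_ref = pos_ref, class = cls,
             stringsAsFactors = FALSE)
}
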