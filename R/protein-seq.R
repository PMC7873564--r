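#' @importFrom stats sd setNames lm coef predict var median
#' @importFrom utils head tail
NULL

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein sequence with full-length numbering
#'
#' A `protein_seq` holds a stretch of one-letter amino-acid codes together
#' with a `numbering_offset`: the full-length residue number (counted from
#' the initiator Met of the complete protein) of the first residue held.
#' The full-length number of the residue at local index `i` (1-based) is
#' `i + numbering_offset - 1`.
#'
#' @param residues string of one-letter amino-acid codes (no gaps).
#' @param id sequence identifier.
#' @param numbering_offset full-length number of the first residue (>= 1).
#' @return An object of class `protein_seq`.
#' @export
protein_seq <- function(residues, id = "seq", numbering_offset = 1L) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  res <- strsplit(residues, "")[[1]]
  bad <- which(!res %in% AA1)
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid letter '%s' at position %d", res[bad[1]], bad[1]))
  }
  if (!is.numeric(numbering_offset) || numbering_offset < 1) {
    stop("numbering_offset must be >= 1")
  }
  structure(
    list(id = id, residues = residues,
         numbering_offset = as.integer(numbering_offset)),
    class = "protein_seq"
  )
}

#' @export
print.protein_seq <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<protein_seq> %s: %d aa, full-length numbering %d-%d\n",
              x$id, n, x$numbering_offset, x$numbering_offset + n - 1L))
  cat(" ", x$residues, "\n")
  invisible(x)
}

#' @export
length.protein_seq <- function(x) nchar(x$residues)

seq_chars <- function(x) strsplit(x$residues, "")[[1]]

#' Parse a printed domain sequence
#'
#' Strips typesetting artifacts (hyphens, whitespace, digits) from a
#' sequence printed in running text and validates that what remains is
#' drawn from the 20-letter amino-acid alphabet.
#'
#' @param raw_text the printed sequence, possibly with embedded hyphens,
#'   line breaks or position numbers.
#' @param id sequence identifier.
#' @return A [protein_seq()] with `numbering_offset = 1` (call
#'   [anchor_numbering()] to attach full-length numbering).
#' @export
parse_domain_sequence <- function(raw_text, id = "seq") {
  stripped <- gsub("[-[:space:][:digit:]]", "", raw_text)
  if (!nzchar(stripped)) stop("no sequence left after stripping")
  protein_seq(toupper(stripped), id = id, numbering_offset = 1L)
}

#' Anchor full-length numbering by a unique motif
#'
#' Sets the numbering offset of a sequence so that the first residue of
#' `motif` carries the given full-length residue number.
#'
#' @param seq a [protein_seq()].
#' @param motif short amino-acid motif that occurs exactly once in `seq`.
#' @param motif_full_position full-length number of the motif's first residue.
#' @return The re-anchored `protein_seq`.
#' @export
anchor_numbering <- function(seq, motif, motif_full_position) {
  hits <- gregexpr(motif, seq$residues, fixed = TRUE)[[1]]
  n_hits <- if (hits[1] == -1L) 0L else length(hits)
  if (n_hits != 1L) {
    stop(sprintf("motif '%s' occurs %d times in %s (must occur exactly once)",
                 motif, n_hits, seq$id))
  }
  offset <- motif_full_position - hits[1] + 1L
  if (offset < 1L) stop("anchoring would give a numbering offset < 1")
  seq$numbering_offset <- as.integer(offset)
  seq
}

#' Full-length residue numbers of a sequence
#' @param seq a [protein_seq()].
#' @return Integer vector of full-length numbers, one per residue.
#' @export
full_positions <- function(seq) {
  seq_len(nchar(seq$residues)) + seq$numbering_offset - 1L
}

#' Residue at a full-length position
#' @param seq a [protein_seq()].
#' @param position full-length residue number(s).
#' @return One-letter code(s).
#' @export
residue_at <- function(seq, position) {
  local <- position - seq$numbering_offset + 1L
  n <- nchar(seq$residues)
  if (any(local < 1L | local > n)) {
    stop(sprintf("position(s) outside %s numbering range %d-%d",
                 seq$id, seq$numbering_offset, seq$numbering_offset + n - 1L))
  }
  seq_chars(seq)[local]
}

# The human and mouse FcuR Ig-like domain sequences (GenBank NP_005440 and
# NP_081252) as printed for modelling; embedded hyphens in the printed text
# are typesetting artifacts and are stripped by the parser.
.HU_DOMAIN_RAW <- paste0(
  "LRILPEVKVEGELGGSVTIKCPLPEMHVRIYLCREMAGSGTCGTVVSTTNFIKAEYKGRVTLKQYPRK",
  "-NLFLVEVTQLTESDSGVYACGAGMNTDRGKTQKVTLNVHS")
.MO_DOMAIN_RAW <- paste0(
  "LRVLPEVQLNVEWGGSIIIECPLPQLHVRMYLCRQMAKPGICSTVVSN",
  "-TFVKKEYERRVTLTPCLDKKLFLVEMTQLTENDDGIYACGVGMKTDKGKTQKITLNVHN")

#' Built-in human and mouse FcuR Ig-like domain sequences
#'
#' Returns the human (108 aa) and mouse (107 aa) Ig-like domain sequences
#' used throughout the package, with human full-length numbering anchored
#' by the unique `KVEG` motif at positions 24-27 (counted from the
#' initiator Met of the 390-aa human receptor) and mouse numbering
#' anchored by the corresponding `QLNV` motif.
#'
#' @return Named list with elements `human` and `mouse`, each a
#'   [protein_seq()].
#' @export
fcmur_domain_seqs <- function() {
  hu <- parse_domain_sequence(.HU_DOMAIN_RAW, id = "huFcmR-Ig")
  mo <- parse_domain_sequence(.MO_DOMAIN_RAW, id = "moFcmR-Ig")
  hu <- anchor_numbering(hu, "KVEG", 24L)
  mo <- anchor_numbering(mo, "QLNV", 24L)
  list(human = hu, mouse = mo)
}

#' Functional region map of the human FcuR Ig-like domain
#'
#' Named regions (inclusive full-length ranges) of the human domain: the
#' A beta-strand, the three CDR loops and the DE loop, plus the disulfide
#' bridges and the conserved salt bridge. CDR boundaries are approximate
#' (exact limits are structure-prediction dependent) and configurable;
#' the residues known to matter for IgM binding (E41/M42 in CDR1, N66 in
#' CDR2, K79-R83 in the DE loop, N109 in CDR3) must fall inside them.
#'
#' @param regions named list of `c(start, end)` full-length ranges.
#' @param disulfides list of `c(pos1, pos2)` bridge pairs.
#' @param salt_bridge two positions forming the conserved salt bridge.
#' @return Object of class `region_map`.
#' @export
fcmur_regions <- function(regions = list(A_strand = c(24L, 27L),
                                         CDR1 = c(38L, 42L),
                                         CDR2 = c(65L, 66L),
                                         DE_loop = c(79L, 83L),
                                         CDR3 = c(105L, 110L)),
                          disulfides = list(c(37L, 104L), c(49L, 58L)),
                          salt_bridge = c(75L, 98L)) {
  mandatory <- list(CDR1 = c(41L, 42L), CDR2 = 66L, DE_loop = c(79L, 83L),
                    CDR3 = 109L, A_strand = c(24L, 27L))
  for (nm in names(mandatory)) {
    rng <- regions[[nm]]
    if (is.null(rng)) stop(sprintf("region '%s' is required", nm))
    if (any(mandatory[[nm]] < rng[1] | mandatory[[nm]] > rng[2])) {
      stop(sprintf("region '%s' must contain residue(s) %s",
                   nm, paste(mandatory[[nm]], collapse = ", ")))
    }
  }
  rmat <- do.call(rbind, regions)
  # loop regions must not overlap one another
  for (i in seq_len(nrow(rmat))) for (j in seq_len(nrow(rmat))) {
    if (i < j && rmat[i, 1] <= rmat[j, 2] && rmat[j, 1] <= rmat[i, 2]) {
      stop(sprintf("regions '%s' and '%s' overlap",
                   rownames(rmat)[i], rownames(rmat)[j]))
    }
  }
  structure(list(regions = regions, disulfides = disulfides,
                 salt_bridge = salt_bridge),
            class = "region_map")
}

#' Check that every annotated position resolves to a residue
#' @param map a [fcmur_regions()] region map.
#' @param seq a [protein_seq()] carrying the annotated numbering.
#' @return Invisibly `TRUE`; errors if a position is unresolvable.
#' @export
validate_region_map <- function(map, seq) {
  pos <- c(unlist(map$regions), unlist(map$disulfides), map$salt_bridge)
  residue_at(seq, pos)  # errors on out-of-range
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file (single- or multi-record).
#' @return List of [protein_seq()] objects, one per record.
#' @export
read_fasta_seqs <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(i) {
    parse_domain_sequence(as.character(set[[i]]), id = names(set)[i])
  })
}

#' Write protein sequences to a FASTA file
#' @param seqs a [protein_seq()] or list of them.
#' @param path output file.
#' @return Invisibly `path`.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (inherits(seqs, "protein_seq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
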