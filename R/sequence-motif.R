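# Degenerate-template motif scanning and PDZ P-position mapping.
#
# PDZ domains recognize short peptide stretches either at the extreme
# C-terminus of a partner or, less commonly, inside it ("internal" motifs).
# The scanner below searches protein sequences with degenerate residue-class
# templates of the kind derived from peptide-phage display against the Dvl2
# PDZ domain, scoring windows with conservative-substitution credit, and maps
# hits onto the field's P-position nomenclature (P0 at the residue engaging
# the carboxylate-binding loop, negative indices toward the N-terminus).

#' Construct a protein sequence record
#'
#' @param id Sequence identifier.
#' @param residues One-letter residue string (20 canonical letters or `X`;
#'   lowercase input is uppercased).
#' @param numbering_offset 1-based index of the first residue in the
#'   full-length protein, so hits can be reported in full-length numbering.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, numbering_offset = 1L) {
  residues <- toupper(as.character(residues))
  if (is.na(residues) || nchar(residues) == 0L)
    stopf("sequence '%s': residues must be non-empty", id)
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X", "-"))
  if (length(bad))
    stopf("sequence '%s': invalid residue letter(s): %s", id,
          paste(bad, collapse = ", "))
  structure(list(id = as.character(id), residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa, numbering from %d)\n",
              x$id, nchar(x$residues), x$numbering_offset))
  invisible(x)
}

#' Default residue-class table for motif templates
#'
#' Maps class symbols to residue sets: `X` is any residue, `Φa`
#' (aliphatic) is \{A,V,L,I,M\}, `Φs` (short-side-chain hydrophilic) is
#' exactly \{S,T\}. ASCII aliases `Phi_a`/`Phi_s` are accepted when typing
#' the Greek letter is inconvenient.
#'
#' @return Named list of character vectors.
#' @export
residue_class_table <- function() {
  phi_a <- c("A", "V", "L", "I", "M")
  phi_s <- c("S", "T")
  tab <- list(X = AA_ALPHABET)
  tab[["Φa"]] <- phi_a
  tab[["Φs"]] <- phi_s
  tab[["Phi_a"]] <- phi_a
  tab[["Phi_s"]] <- phi_s
  tab
}

#' Conservative substitution groups used for partial scoring credit
#'
#' @return List of character vectors: \{D,E\}, \{N,Q\}, \{S,T\}, \{K,R\},
#'   \{F,Y,W\}, \{A,V,L,I,M\}.
#' @export
conservative_groups <- function() {
  list(c("D", "E"), c("N", "Q"), c("S", "T"), c("K", "R"),
       c("F", "Y", "W"), c("A", "V", "L", "I", "M"))
}

#' Parse a dash-delimited degenerate motif template
#'
#' Tokens may be class symbols from the [residue_class_table()], single
#' residue letters, or alternations like `"D/G"`.
#'
#' @param spec Template string, e.g. `"W-Φs-D-X-P"`.
#' @param table Residue-class table; see [residue_class_table()].
#' @param name Template name; defaults to `spec` itself.
#' @return An object of class `motif_template` with one residue set per
#'   position.
#' @export
parse_template <- function(spec, table = residue_class_table(), name = spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stopf("template spec must be a non-empty string")
  tokens <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stopf("template spec '%s' contains an empty token", spec)
  sets <- lapply(tokens, function(tok) {
    if (tok %in% names(table)) return(table[[tok]])
    if (grepl("^[A-Z](/[A-Z])+$", tok)) {
      s <- strsplit(tok, "/", fixed = TRUE)[[1]]
      bad <- setdiff(s, AA_ALPHABET)
      if (length(bad)) stopf("unknown residue '%s' in token '%s'", bad[1], tok)
      return(s)
    }
    if (tok %in% AA_ALPHABET) return(tok)
    stopf("unknown template symbol '%s'", tok)
  })
  structure(list(name = name, symbols = tokens, sets = sets),
            class = "motif_template")
}

#' @export
print.motif_template <- function(x, ...) {
  cat(sprintf("<motif_template> %s (%d positions)\n", x$name,
              length(x$sets)))
  invisible(x)
}

#' The three internal-peptide search templates
#'
#' The degenerate templates used to search GEF-family sequences for a
#' Dvl2-PDZ binding internal motif: `X-Y-G-W-Φa-D/G`,
#' `X-W-Φa-D-G-P` and `W-Φs-D-X-P`.
#'
#' @return List of three `motif_template` objects, in search order.
#' @export
pdz_internal_templates <- function() {
  specs <- c("X-Y-G-W-Φa-D/G", "X-W-Φa-D-G-P", "W-Φs-D-X-P")
  lapply(specs, parse_template)
}

# Per-position scores for a window: 1 for class membership, s_cons for a
# conservative substitution (residue shares a substitution group with a
# class member), 0 otherwise. 'X' in the target never matches.
score_window <- function(chars, template, s_cons, groups) {
  vapply(seq_along(chars), function(i) {
    res <- chars[i]
    set <- template$sets[[i]]
    if (res == "X" || res == "-") return(0)
    if (res %in% set) return(1)
    for (g in groups) if (res %in% g && length(intersect(g, set))) return(s_cons)
    0
  }, numeric(1))
}

#' Scan a protein sequence with degenerate motif templates
#'
#' Every window of each template's length is scored as the mean of
#' per-position scores (1 for class membership, `s_cons` for a conservative
#' substitution, 0 otherwise). Windows passing both the score and the
#' strict-mismatch thresholds are returned, sorted by decreasing score, then
#' start position, then template order. Overlapping hits from different
#' templates are all reported.
#'
#' @param seq A `protein_sequence` (or plain string).
#' @param templates List of `motif_template`s; defaults to
#'   [pdz_internal_templates()].
#' @param min_score Minimum window score in \[0, 1\].
#' @param max_strict_mismatches Maximum number of zero-scoring positions.
#' @param s_cons Score credited to a conservative substitution.
#' @param groups Substitution groups; see [conservative_groups()].
#' @return A data frame of class `motif_hits` with columns `sequence_id`,
#'   `template`, `start`, `end` (1-based inclusive, full-length numbering),
#'   `matched`, `score`, `mismatches`.
#' @export
scan_motifs <- function(seq, templates = pdz_internal_templates(),
                        min_score = 0.8, max_strict_mismatches = 1L,
                        s_cons = 0.5, groups = conservative_groups()) {
  if (is.character(seq)) seq <- protein_sequence("seq", seq)
  stopifnot(inherits(seq, "protein_sequence"))
  if (min_score < 0 || min_score > 1) stopf("min_score must lie in [0, 1]")
  chars <- strsplit(toupper(seq$residues), "")[[1]]
  n <- length(chars)
  rows <- list()
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    w <- length(tmpl$sets)
    if (n < w) next
    for (pos in seq_len(n - w + 1L)) {
      sc <- score_window(chars[pos:(pos + w - 1L)], tmpl, s_cons, groups)
      score <- mean(sc)
      n_strict <- sum(sc == 0)
      if (score >= min_score && n_strict <= max_strict_mismatches) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = seq$id, template = tmpl$name,
          start = seq$numbering_offset + pos - 1L,
          end = seq$numbering_offset + pos + w - 2L,
          matched = paste(chars[pos:(pos + w - 1L)], collapse = ""),
          score = score, mismatches = n_strict,
          template_order = ti, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(sequence_id = character(), template = character(),
                      start = integer(), end = integer(),
                      matched = character(), score = numeric(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(-out$score, out$start, out$template_order), , drop = FALSE]
    out$template_order <- NULL
    rownames(out) <- NULL
  }
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Map peptide residues onto PDZ P-position nomenclature
#'
#' Under the default anchor rule the aspartate whose side chain mimics a
#' ligand's free C-terminal carboxylate is assigned P0; residues toward the
#' C-terminus get P1, P2, ... and residues toward the N-terminus get
#' P-1, P-2, ...
#'
#' @param peptide One-letter peptide string.
#' @param anchor Anchor rule; only `"aspartate-carboxylate-mimic"` is defined.
#' @param anchor_index Explicit 1-based anchor position, required when the
#'   peptide holds more than one aspartate (the ambiguity is surfaced, not
#'   guessed).
#' @return A data frame of class `pdz_position_map` with columns `index`,
#'   `residue`, `p` (signed P index).
#' @export
assign_pdz_positions <- function(peptide,
                                 anchor = "aspartate-carboxylate-mimic",
                                 anchor_index = NULL) {
  anchor <- match.arg(anchor)
  chars <- strsplit(toupper(peptide), "")[[1]]
  if (is.null(anchor_index)) {
    asp <- which(chars == "D")
    if (length(asp) == 0L)
      stopf("peptide '%s' contains no aspartate anchor", peptide)
    if (length(asp) > 1L)
      stopf("peptide '%s' contains %d aspartates (positions %s); supply anchor_index",
            peptide, length(asp), paste(asp, collapse = ", "))
    anchor_index <- asp
  }
  anchor_index <- as.integer(anchor_index)
  if (anchor_index < 1L || anchor_index > length(chars))
    stopf("anchor_index %d outside peptide", anchor_index)
  out <- data.frame(index = seq_along(chars), residue = chars,
                    p = seq_along(chars) - anchor_index,
                    stringsAsFactors = FALSE)
  class(out) <- c("pdz_position_map", "data.frame")
  out
}

#' Per-column identity fraction of a pre-aligned sequence set
#'
#' Each column's conservation is the count of its most frequent non-gap
#' residue divided by the non-gap count; gaps (`-`) enter neither numerator
#' nor denominator. Columns that are all gaps are `NA`.
#'
#' @param aligned List of equal-length `protein_sequence`s or strings
#'   (alignment construction is out of scope).
#' @return Numeric vector of per-column identity fractions in \[0, 1\].
#' @export
conservation_profile <- function(aligned) {
  seqs <- vapply(aligned, function(s) {
    if (inherits(s, "protein_sequence")) s$residues else toupper(s)
  }, character(1))
  if (length(seqs) < 2L) stopf("need at least 2 aligned sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stopf("aligned sequences differ in length (%s)",
          paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs, ""))
  apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    max(table(col)) / length(col)
  })
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return List of `protein_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(names(recs), function(nm)
    protein_sequence(nm, as.character(recs[[nm]])))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs List of `protein_sequence` objects.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, function(s) strsplit(s$residues, "")[[1]]),
                      names = vapply(seqs, `[[`, character(1), "id"),
                      file.out = path)
  invisible(path)
}

#' Write motif hits to a TSV file
#'
#' Columns: `sequence_id`, `template`, `start`, `end`, `matched`, `score`,
#' `mismatches`, `P0_index` (full-length index of the anchor aspartate within
#' the matched window, `NA` when the window holds no unique aspartate).
#'
#' @param hits A `motif_hits` data frame from [scan_motifs()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  p0 <- vapply(seq_len(nrow(hits)), function(i) {
    m <- tryCatch(assign_pdz_positions(hits$matched[i]), error = function(e) NULL)
    if (is.null(m)) return(NA_integer_)
    hits$start[i] + m$index[m$p == 0] - 1L
  }, integer(1))
  out <- cbind(as.data.frame(hits), P0_index = p0)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
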